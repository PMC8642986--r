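#' Mean interspecific divergence per species pair
#'
#' Collapses a pairwise distance matrix to one summary value per unordered
#' species pair: by default the mean of all between-species sequence-pair
#' distances. Species pairs are the pairing unit for marker-versus-marker
#' rank tests — with 65 species fully crossed this yields choose(65, 2) =
#' 2080 paired observations.
#'
#' @param m A `k2p_dist` object.
#' @param specimens Specimen metadata.
#' @param summary `"mean"` (default), `"min"` or `"median"` of the
#'   sequence-pair distances.
#' @param exclude_groups Groups dropped first (default hybrids).
#' @return Tibble: `species1`, `species2` (alphabetical within the pair),
#'   `n_pairs`, `divergence`. Saturated pairs are excluded from the summary.
#' @export
species_pair_divergence <- function(m, specimens,
                                    summary = c("mean", "min", "median"),
                                    exclude_groups = "hybrid") {
  summary <- match.arg(summary)
  fn <- switch(summary, mean = mean, min = min, median = stats::median)
  parts <- partition_distances(m, specimens, exclude_groups)
  inter <- parts |>
    dplyr::filter(.data$class == "interspecific",
                  is.finite(.data$distance)) |>
    dplyr::mutate(sp_a = pmin(.data$species1, .data$species2),
                  sp_b = pmax(.data$species1, .data$species2))
  if (nrow(inter) == 0L) abort("no interspecific distances")
  inter |>
    dplyr::group_by(species1 = .data$sp_a, species2 = .data$sp_b) |>
    dplyr::summarise(n_pairs = dplyr::n(), divergence = fn(.data$distance),
                     .groups = "drop")
}

#' Paired Wilcoxon signed-rank comparison of two markers
#'
#' Compares paired divergence values (one pair per shared species pair)
#' between a `before` and an `after` marker. Zero differences are dropped;
#' absolute differences are ranked with midranks for ties; `W_plus` and
#' `W_minus` are the rank sums of positive (`after > before`) and negative
#' differences. The p-value is exact (full sign-flip distribution, computed
#' by convolution) for `N <= 25` and a normal approximation with continuity
#' and tie corrections otherwise. The common-language effect size is
#' `W_minus / (W_minus + W_plus)`: 0 when the `after` marker dominates every
#' pair, 1 when `before` dominates.
#'
#' @param before,after Equal-length numeric vectors of paired divergences.
#' @param marker_before,marker_after Optional marker names for reporting.
#' @param alpha Significance level for the verdict (default 0.05).
#' @return An object of class `marker_comparison` with fields
#'   `marker_before`, `marker_after`, `n`, `w_minus`, `w_plus`, `p_value`,
#'   `cl_effect` and `verdict` (`"<winner> >> <loser>"` or `"ns"`). [tidy()]
#'   and [glance()] return it as a one-row tibble.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3), c(2, 3, 4), "rbcL", "ITS2")
wilcoxon_signed_rank <- function(before, after,
                                 marker_before = "before",
                                 marker_after = "after", alpha = 0.05) {
  if (length(before) != length(after)) {
    abort("before/after must have equal lengths")
  }
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) abort("all paired differences are zero (N = 0)")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  p <- if (n <= 25L) {
    signed_rank_exact_p(r, w_plus)
  } else {
    signed_rank_normal_p(r, w_plus)
  }
  cl <- w_minus / (w_minus + w_plus)
  verdict <- if (p < alpha) {
    if (w_minus > w_plus) {
      paste(marker_before, ">>", marker_after)
    } else {
      paste(marker_after, ">>", marker_before)
    }
  } else "ns"
  structure(list(marker_before = marker_before, marker_after = marker_after,
                 n = n, w_minus = w_minus, w_plus = w_plus, p_value = p,
                 cl_effect = cl, verdict = verdict),
            class = "marker_comparison")
}

# exact two-sided p for the signed-rank statistic with midranks: the null
# distribution of W_plus over all 2^N sign assignments, computed by
# convolution over doubled (hence integer) ranks
signed_rank_exact_p <- function(r, w_plus) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (v in r2) {
    g <- f / 2
    g[(v + 1L):(total + 1L)] <- g[(v + 1L):(total + 1L)] + f[1L:(total + 1L - v)] / 2
    f <- g
  }
  w2 <- as.integer(round(2 * w_plus))
  lower <- sum(f[seq_len(w2 + 1L)])
  upper <- sum(f[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(lower, upper))
}

# normal approximation with continuity correction and the midrank tie
# correction in the variance
signed_rank_normal_p <- function(r, w_plus) {
  n <- length(r)
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  z <- (w_plus - mu - sign(w_plus - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * pnorm(-abs(z)))
}

#' @export
print.marker_comparison <- function(x, ...) {
  cat(sprintf("<marker_comparison> %s vs %s: N = %d, W- = %.1f, W+ = %.1f\n",
              x$marker_before, x$marker_after, x$n, x$w_minus, x$w_plus))
  cat(sprintf("  p = %.3g, common-language effect = %.2f, verdict: %s\n",
              x$p_value, x$cl_effect, x$verdict))
  invisible(x)
}

#' @describeIn wilcoxon_signed_rank One-row tibble of all fields.
#' @param x A `marker_comparison`.
#' @param ... Unused.
#' @method tidy marker_comparison
#' @export
tidy.marker_comparison <- function(x, ...) {
  tibble(marker_before = x$marker_before, marker_after = x$marker_after,
         n = x$n, w_minus = x$w_minus, w_plus = x$w_plus,
         p_value = x$p_value, cl_effect = x$cl_effect, verdict = x$verdict)
}

#' @describeIn wilcoxon_signed_rank Alias of [tidy()] for this object.
#' @method glance marker_comparison
#' @export
glance.marker_comparison <- function(x, ...) tidy.marker_comparison(x)

#' Compare interspecific divergence between two markers of a dataset
#'
#' Convenience wrapper: computes [species_pair_divergence()] for both
#' markers, pairs them on shared species pairs, and runs
#' [wilcoxon_signed_rank()].
#'
#' @param d A `barcode_dataset`.
#' @param marker_before,marker_after Marker names in `d`.
#' @param min_overlap Passed to [k2p_matrix()].
#' @param summary Species-pair summary statistic (see
#'   [species_pair_divergence()]).
#' @return A `marker_comparison`.
#' @export
compare_markers <- function(d, marker_before, marker_after,
                            min_overlap = 50L, summary = "mean") {
  div <- lapply(c(marker_before, marker_after), function(mk) {
    species_pair_divergence(k2p_matrix(d$alignments[[mk]], min_overlap),
                            d$specimens, summary = summary)
  })
  paired <- dplyr::inner_join(div[[1L]], div[[2L]],
                              by = c("species1", "species2"),
                              suffix = c("_before", "_after"))
  if (nrow(paired) == 0L) abort("no shared species pairs between markers")
  wilcoxon_signed_rank(paired$divergence_before, paired$divergence_after,
                       marker_before, marker_after)
}
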