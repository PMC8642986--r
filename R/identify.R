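#' Best Match species identification
#'
#' Leave-one-out nearest-neighbour identification: every sequence in turn is
#' a query against all remaining sequences. The verdict is `success` when the
#' (unique-species) closest match is conspecific, `ambiguous` when the set of
#' closest matches mixes the query's species with another, and `incorrect`
#' when every closest match belongs to other species. Only queries with at
#' least one conspecific in the pool are scored — a singleton can never be
#' matched correctly, so including it would measure sampling, not the marker.
#'
#' @param m A `k2p_dist` object.
#' @param specimens Specimen metadata.
#' @param tie_tol Distances within this absolute tolerance of the minimum are
#'   tied (default 1e-12, i.e. exact ties up to floating-point noise).
#' @return Tibble with one row per query: `query_id`, `species`, `verdict`,
#'   `best_distance`, `best_match_ids`, `best_match_species` (both
#'   `;`-collapsed), `threshold_used` (`NA` for plain Best Match).
#' @export
best_match <- function(m, specimens, tie_tol = 1e-12) {
  bm_engine(m, specimens, threshold = NA_real_, tie_tol = tie_tol)
}

#' Best Close Match threshold from intraspecific distances
#'
#' The 95th percentile of all intraspecific pairwise distances, with linear
#' interpolation between order statistics. This is the data-driven reading of
#' a "95% pairwise distance threshold"; a fixed distance cutoff can instead
#' be passed directly to [best_close_match()].
#'
#' @param intra_distances Numeric vector of intraspecific pairwise distances
#'   (non-finite values are dropped).
#' @return The threshold, a single number.
#' @export
bcm_threshold <- function(intra_distances) {
  x <- intra_distances[is.finite(intra_distances)]
  if (length(x) < 1L) abort("need at least one intraspecific distance")
  unname(quantile(x, 0.95, type = 7))
}

#' Best Close Match species identification
#'
#' Best Match with a distance ceiling: a query whose closest match lies
#' strictly above the threshold is `unidentified`; otherwise the Best Match
#' rules decide among the matches under the threshold. Because the closest
#' match drives the Best Match verdict, Best Close Match can only demote
#' verdicts to `unidentified`, never improve them.
#'
#' @inheritParams best_match
#' @param threshold Distance ceiling. `NULL` (default) computes
#'   [bcm_threshold()] from the intraspecific distances of `m` itself
#'   (hybrid-group specimens excluded).
#' @return As [best_match()], with `threshold_used` filled in.
#' @export
best_close_match <- function(m, specimens, threshold = NULL,
                             tie_tol = 1e-12) {
  if (is.null(threshold)) {
    parts <- partition_distances(m, specimens)
    threshold <- bcm_threshold(
      parts$distance[parts$class == "intraspecific"])
  }
  bm_engine(m, specimens, threshold = threshold, tie_tol = tie_tol)
}

# shared BM/BCM engine; threshold = NA means plain Best Match
bm_engine <- function(m, specimens, threshold, tie_tol) {
  info <- species_of(m$ids, specimens)
  sp <- info$species
  counts <- table(sp)
  valid <- sp %in% names(counts)[counts >= 2L]
  queries <- which(valid)
  if (length(queries) == 0L) abort("no query has a valid conspecific")

  rows <- lapply(queries, function(i) {
    d <- m$d[i, ]
    d[i] <- NA_real_
    cand <- which(is.finite(d))
    if (length(cand) == 0L) {
      abort(paste0("query ", m$ids[i], " has no non-missing distance"))
    }
    best <- min(d[cand])
    if (!is.na(threshold) && best > threshold) {
      return(tibble(query_id = m$ids[i], species = sp[i],
                    verdict = "unidentified", best_distance = best,
                    best_match_ids = NA_character_,
                    best_match_species = NA_character_,
                    threshold_used = threshold))
    }
    ties <- cand[d[cand] <= best + tie_tol]
    tie_species <- unique(sp[ties])
    verdict <- if (all(tie_species == sp[i])) {
      "success"
    } else if (sp[i] %in% tie_species) {
      "ambiguous"
    } else {
      "incorrect"
    }
    tibble(query_id = m$ids[i], species = sp[i], verdict = verdict,
           best_distance = best,
           best_match_ids = paste(m$ids[ties], collapse = ";"),
           best_match_species = paste(tie_species, collapse = ";"),
           threshold_used = threshold)
  })
  dplyr::bind_rows(rows)
}

#' Summarise identification verdicts
#'
#' @param results Output of [best_match()] or [best_close_match()].
#' @return One-row tibble: `n_queries`, counts per verdict, and `success_pct`
#'   (percent of queries with verdict `success`).
#' @export
summarize_identification <- function(results) {
  verdicts <- c("success", "ambiguous", "incorrect", "unidentified")
  counts <- table(factor(results$verdict, levels = verdicts))
  tibble(n_queries = nrow(results),
         n_success = counts[["success"]],
         n_ambiguous = counts[["ambiguous"]],
         n_incorrect = counts[["incorrect"]],
         n_unidentified = counts[["unidentified"]],
         success_pct = 100 * counts[["success"]] / nrow(results))
}
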