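#' Watterson's theta for a set of aligned sequences
#'
#' The per-site estimator `theta_W = S / (a_{n-1} * L)` with
#' `a_{n-1} = sum_{i=1}^{n-1} 1/i`, where `S` counts segregating columns
#' (>= 2 distinct unambiguous bases) among the `L` columns free of gaps and
#' ambiguity codes across the whole subset (complete deletion).
#'
#' @param aln Character matrix of the sequences to estimate from (n >= 2).
#' @return Per-site theta, a single number.
#' @export
#' @examples
#' aln <- rbind(a = strsplit("AAAAAAAAAA", "")[[1]],
#'              b = strsplit("AAAAAAAAAG", "")[[1]])
#' watterson_theta(aln)  # S = 1, n = 2, a_1 = 1, L = 10 -> 0.1
watterson_theta <- function(aln) {
  n <- nrow(aln)
  if (is.null(n) || n < 2L) abort("need >= 2 sequences")
  X <- matrix(encode_nt(aln), nrow = n)
  complete <- colSums(is.na(X)) == 0L
  L <- sum(complete)
  if (L == 0L) abort("no complete columns to estimate from")
  S <- segregating_sites(X[, complete, drop = FALSE])
  a <- sum(1 / seq_len(n - 1L))
  S / (a * L)
}

segregating_sites <- function(X) {
  sum(vapply(seq_len(ncol(X)), function(j) {
    b <- X[, j]
    b <- b[!is.na(b)]
    length(unique(b)) >= 2L
  }, logical(1)))
}

#' Nucleotide diversity (pi) for a set of aligned sequences
#'
#' Mean per-site proportion of differing sites (p-distance, pairwise
#' deletion) over all unordered sequence pairs. The conventional estimator of
#' per-site heterozygosity; for two sequences it equals the p-distance, and
#' for n = 2 it coincides with Watterson's theta on gap-free data.
#'
#' @param aln Character matrix of the sequences (n >= 2).
#' @return Per-site pi, a single number.
#' @export
nucleotide_pi <- function(aln) {
  n <- nrow(aln)
  if (is.null(n) || n < 2L) abort("need >= 2 sequences")
  X <- matrix(encode_nt(aln), nrow = n)
  pairs <- combn(n, 2L)
  pd <- apply(pairs, 2L, function(ij) {
    x <- X[ij[1L], ]; y <- X[ij[2L], ]
    ok <- !is.na(x) & !is.na(y)
    if (!any(ok)) return(NA_real_)
    sum(x[ok] != y[ok]) / sum(ok)
  })
  mean(pd, na.rm = TRUE)
}

#' Per-population genetic diversity table
#'
#' Watterson's theta and nucleotide diversity for every species x population
#' x marker combination with enough sequences. Populations default to
#' collection sites. Records below `min_n` sequences are skipped — diversity
#' is conventionally estimated only where more than two individuals were
#' collected.
#'
#' @param d A `barcode_dataset`.
#' @param markers Markers to estimate for (default: all in `d`).
#' @param min_n Minimum sequences per record (default 3).
#' @param by_population Estimate per population (default) or pooled per
#'   species (`population_id = "ALL"`).
#' @param exclude_groups Specimen groups excluded (default hybrids).
#' @return Tibble: `marker`, `species`, `population_id`, `n`, `L`
#'   (complete columns used for theta), `S` (segregating sites), `theta_w`,
#'   `pi` — both per site.
#' @export
diversity_table <- function(d, markers = NULL, min_n = 3L,
                            by_population = TRUE,
                            exclude_groups = "hybrid") {
  if (is.null(markers)) markers <- names(d$alignments)
  sp <- dplyr::filter(d$specimens, !(.data$group %in% exclude_groups))
  if (!by_population) sp$population_id <- "ALL"
  rows <- list()
  for (marker in markers) {
    aln <- d$alignments[[marker]]
    present <- dplyr::filter(sp, .data$specimen_id %in% rownames(aln))
    groups <- split(present$specimen_id,
                    list(present$species, present$population_id),
                    drop = TRUE)
    for (g in names(groups)) {
      ids <- groups[[g]]
      if (length(ids) < min_n) next
      sub <- aln[ids, , drop = FALSE]
      info <- present[match(ids[1L], present$specimen_id), ]
      X <- matrix(encode_nt(sub), nrow = nrow(sub))
      complete <- colSums(is.na(X)) == 0L
      L <- sum(complete)
      if (L == 0L) next
      S <- segregating_sites(X[, complete, drop = FALSE])
      rows[[length(rows) + 1L]] <- tibble(
        marker = marker, species = info$species,
        population_id = info$population_id, n = length(ids),
        L = L, S = S,
        theta_w = S / (sum(1 / seq_len(length(ids) - 1L)) * L),
        pi = nucleotide_pi(sub))
    }
  }
  dplyr::bind_rows(rows)
}

#' Partition intraspecific distances by population
#'
#' Splits every intraspecific pairwise distance into within-population and
#' between-population classes, the layout behind scatter plots contrasting
#' local and range-wide variability of each species.
#'
#' @param m A `k2p_dist` object.
#' @param specimens Specimen metadata with `population_id`.
#' @param exclude_groups Groups dropped first (default hybrids).
#' @return Tibble: `species`, `id1`, `id2`, `population1`, `population2`,
#'   `distance`, `class` (`"within_population"`/`"between_population"`).
#' @export
population_distance_partition <- function(m, specimens,
                                          exclude_groups = "hybrid") {
  parts <- partition_distances(m, specimens, exclude_groups)
  pop <- setNames(specimens$population_id, specimens$specimen_id)
  parts |>
    dplyr::filter(.data$class == "intraspecific") |>
    dplyr::mutate(population1 = unname(pop[.data$id1]),
                  population2 = unname(pop[.data$id2]),
                  class = ifelse(.data$population1 == .data$population2,
                                 "within_population", "between_population")) |>
    dplyr::select(species = "species1", "id1", "id2", "population1",
                  "population2", "distance", "class")
}
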