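#' Kimura 2-parameter distance between two aligned sequences
#'
#' Computes the K2P distance `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`,
#' where `P` and `Q` are the transition and transversion proportions over
#' comparable sites. Sites where either sequence carries a gap, `N`, or an
#' ambiguity code are excluded (pairwise deletion); the model has no defined
#' treatment for ambiguous observations.
#'
#' @param a,b Aligned sequences of equal length: character strings or
#'   character vectors of single letters.
#' @param min_overlap Minimum number of comparable sites; below it the
#'   distance is reported missing (`NA`).
#' @return A single number; `NA` if fewer than `min_overlap` comparable
#'   sites; `Inf` as a flagged saturation sentinel when `1 - 2P - Q <= 0` or
#'   `1 - 2Q <= 0` (the logarithm is undefined, as when distance software
#'   reports such pairs as undefined).
#' @export
#' @examples
#' k2p_distance("ACGTACGTAC", "ACGTACGTGC")
k2p_distance <- function(a, b, min_overlap = 1L) {
  if (is.character(a) && length(a) == 1L) a <- strsplit(toupper(a), "")[[1]]
  if (is.character(b) && length(b) == 1L) b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b)) abort("sequences have unequal lengths")
  x <- encode_nt(toupper(a))
  y <- encode_nt(toupper(b))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_overlap) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  diff <- x != y
  # transitions: A<->G (1,3) and C<->T (2,4); both members same parity class
  purine <- function(z) z == 1L | z == 3L
  ti <- diff & (purine(x) == purine(y))
  P <- sum(ti) / n
  Q <- sum(diff & !ti) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(Inf)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' All-pairs K2P distance matrix for one alignment
#'
#' Computes every pairwise K2P distance with pairwise deletion, together with
#' the number of comparable sites behind each entry. Implemented with matrix
#' cross-products over base indicator matrices, so it scales to community
#' alignments; [k2p_distance()] is the independent per-pair reference.
#'
#' @param aln Character matrix alignment (rows = specimens) or named vector
#'   of equal-length sequence strings.
#' @param min_overlap Entries backed by fewer comparable sites than this are
#'   reported missing (`NA`). Default 50, a conservative floor for the
#'   several-hundred-bp barcode markers.
#' @return An object of class `k2p_dist`: list with `ids`, `d` (symmetric
#'   numeric matrix, zero diagonal, `NA` = insufficient overlap, `Inf` =
#'   saturated), and `overlap` (integer matrix of comparable-site counts).
#' @export
k2p_matrix <- function(aln, min_overlap = 50L) {
  if (!is.matrix(aln)) aln <- seq_to_matrix(aln)
  if (nrow(aln) < 2L) abort("need at least two sequences")
  X <- matrix(encode_nt(aln), nrow = nrow(aln))
  V <- !is.na(X)
  storage.mode(V) <- "double"
  ind <- lapply(1:4, function(b) {
    I <- X == b
    I[is.na(I)] <- FALSE
    storage.mode(I) <- "double"
    I
  })
  comparable <- tcrossprod(V)
  matches <- Reduce(`+`, lapply(ind, tcrossprod))
  transitions <- tcrossprod(ind[[1]], ind[[3]]) + tcrossprod(ind[[3]], ind[[1]]) +
    tcrossprod(ind[[2]], ind[[4]]) + tcrossprod(ind[[4]], ind[[2]])
  P <- transitions / comparable
  Q <- (comparable - matches - transitions) / comparable
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- -0.5 * log(pmax(w1, 0)) - 0.25 * log(pmax(w2, 0))
  d[w1 <= 0 | w2 <= 0] <- Inf
  d[comparable < min_overlap] <- NA_real_
  diag(d) <- 0
  # numerical symmetry is exact here, but enforce it defensively
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  structure(list(ids = rownames(aln), d = `dimnames<-`(d, list(rownames(aln), rownames(aln))),
                 overlap = `dimnames<-`(matrix(as.integer(comparable), nrow(aln)),
                                        list(rownames(aln), rownames(aln)))),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  n <- length(x$ids)
  off <- x$d[upper.tri(x$d)]
  cat("<k2p_dist>", n, "specimens,", sum(is.na(off)), "missing pairs,",
      sum(is.infinite(off)), "saturated pairs\n")
  invisible(x)
}

#' @describeIn k2p_matrix Long-format tibble of the upper triangle
#'   (`id1`, `id2`, `distance`, `overlap`).
#' @param x A `k2p_dist` object.
#' @param ... Unused.
#' @method tidy k2p_dist
#' @export
tidy.k2p_dist <- function(x, ...) {
  ut <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(id1 = x$ids[ut[, 1]], id2 = x$ids[ut[, 2]],
         distance = x$d[ut], overlap = x$overlap[ut])
}

# species label lookup for the ids of a distance matrix
species_of <- function(ids, specimens) {
  idx <- match(ids, specimens$specimen_id)
  if (anyNA(idx)) {
    abort(paste0("specimen missing from metadata: ", ids[is.na(idx)][1L]))
  }
  specimens[idx, , drop = FALSE]
}

#' Partition pairwise distances into intra- and interspecific classes
#'
#' Every non-missing off-diagonal pair is assigned to exactly one class by
#' comparing the species labels of its two specimens. Hybrid-group specimens
#' are excluded by default, as is conventional when summarising marker
#' variability (hybrids carry additive parental signal, not species signal).
#'
#' @param m A `k2p_dist` object.
#' @param specimens Specimen metadata containing the matrix ids.
#' @param exclude_groups Specimen groups dropped before partitioning.
#' @return Tibble with `id1`, `id2`, `species1`, `species2`, `distance`,
#'   `class` (`"intraspecific"`/`"interspecific"`). Saturated pairs keep
#'   their `Inf` sentinel and are excluded from downstream min/max summaries.
#' @export
partition_distances <- function(m, specimens, exclude_groups = "hybrid") {
  info <- species_of(m$ids, specimens)
  keep <- !(info$group %in% exclude_groups)
  long <- tidy(m)
  sp <- setNames(info$species, m$ids)
  kp <- setNames(keep, m$ids)
  long |>
    dplyr::filter(kp[.data$id1], kp[.data$id2], !is.na(.data$distance)) |>
    dplyr::mutate(species1 = unname(sp[.data$id1]),
                  species2 = unname(sp[.data$id2]),
                  class = ifelse(.data$species1 == .data$species2,
                                 "intraspecific", "interspecific")) |>
    dplyr::select("id1", "id2", "species1", "species2", "distance", "class")
}

#' Per-marker alignment and distance summary
#'
#' One row of descriptive statistics for a marker: counts, GC content,
#' variable and gapped columns, and the extreme intra-/interspecific K2P
#' distances, mirroring the summary tables used when several candidate
#' barcode loci are characterised side by side.
#'
#' @param aln Character matrix alignment.
#' @param specimens Specimen metadata.
#' @param marker Optional marker name carried into the output.
#' @param min_overlap Passed to [k2p_matrix()].
#' @param exclude_groups Groups excluded from all statistics (default
#'   hybrids).
#' @return One-row tibble: `marker`, `n_sequences`, `n_species`,
#'   `n_species_valid` (species with >= 2 sequences), `pct_valid_conspecific`
#'   (percent of sequences with at least one conspecific), `gc_content` (%),
#'   `variable_sites`, `gap_columns` (columns containing a gap in >= 1
#'   sequence), `alignment_length`, `max_intraspecific`,
#'   `max_interspecific`.
#' @export
summarize_marker <- function(aln, specimens, marker = NA_character_,
                             min_overlap = 50L, exclude_groups = "hybrid") {
  info <- species_of(rownames(aln), specimens)
  keep <- !(info$group %in% exclude_groups)
  m <- aln[keep, , drop = FALSE]
  sp <- info$species[keep]

  # GC over bases whose GC status is unambiguous (A/C/G/T plus S = G|C and
  # W = A|T); gaps, N and the remaining ambiguity codes are ignored
  tab <- table(factor(as.vector(m), levels = IUPAC_CODES))
  gc_num <- tab[["G"]] + tab[["C"]] + tab[["S"]]
  gc_den <- gc_num + tab[["A"]] + tab[["T"]] + tab[["W"]]
  gc <- if (gc_den > 0) 100 * gc_num / gc_den else NA_real_

  is_base <- matrix(!is.na(encode_nt(m)), nrow = nrow(m))
  variable_sites <- sum(vapply(seq_len(ncol(m)), function(j) {
    b <- m[is_base[, j], j]
    length(unique(b)) >= 2L
  }, logical(1)))
  gap_columns <- sum(colSums(m == "-") > 0L)

  counts <- table(sp)
  valid_species <- names(counts)[counts >= 2L]

  max_intra <- max_inter <- NA_real_
  if (nrow(m) >= 2L) {
    parts <- partition_distances(k2p_matrix(m, min_overlap), specimens,
                                 exclude_groups)
    fin <- parts[is.finite(parts$distance), ]
    intra <- fin$distance[fin$class == "intraspecific"]
    inter <- fin$distance[fin$class == "interspecific"]
    if (length(intra)) max_intra <- max(intra)
    if (length(inter)) max_inter <- max(inter)
  }

  tibble(marker = marker,
         n_sequences = nrow(m),
         n_species = length(counts),
         n_species_valid = length(valid_species),
         pct_valid_conspecific = 100 * sum(sp %in% valid_species) / length(sp),
         gc_content = gc,
         variable_sites = variable_sites,
         gap_columns = gap_columns,
         alignment_length = ncol(m),
         max_intraspecific = max_intra,
         max_interspecific = max_inter)
}

#' Barcode-gap analysis
#'
#' For each species, compares its maximum intraspecific K2P distance with its
#' minimum distance to any heterospecific specimen. A species shows a barcode
#' gap when the minimum interspecific distance strictly exceeds the maximum
#' intraspecific distance (the point falls above the 1:1 line of the classic
#' scatter plot). Species represented by a single sequence have no defined
#' maximum intraspecific distance and are excluded from the percentage
#' denominator; saturated (infinite) distances are excluded from the min/max
#' summaries.
#'
#' @param m A `k2p_dist` object.
#' @param specimens Specimen metadata.
#' @param exclude_groups Groups dropped before analysis (default hybrids).
#' @return A tibble of class `gap_table`: `species`, `n`, `max_intra`,
#'   `min_inter`, `has_gap`, `counted`, with attribute `percent_with_gap`
#'   (percent of counted species with a gap, one decimal). Retrieve the
#'   overall number with [glance()].
#' @export
barcode_gap <- function(m, specimens, exclude_groups = "hybrid") {
  parts <- partition_distances(m, specimens, exclude_groups)
  all_sp <- sort(unique(c(parts$species1, parts$species2)))
  if (length(all_sp) < 2L) abort("barcode gap analysis needs >= 2 species")
  fin <- parts[is.finite(parts$distance), ]
  intra <- fin |>
    dplyr::filter(.data$class == "intraspecific") |>
    dplyr::group_by(species = .data$species1) |>
    dplyr::summarise(max_intra = max(.data$distance), .groups = "drop")
  inter_long <- dplyr::bind_rows(
    dplyr::select(dplyr::filter(fin, .data$class == "interspecific"),
                  species = "species1", distance = "distance"),
    dplyr::select(dplyr::filter(fin, .data$class == "interspecific"),
                  species = "species2", distance = "distance"))
  inter <- inter_long |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(min_inter = min(.data$distance), .groups = "drop")

  info <- species_of(m$ids, specimens)
  ns <- info |>
    dplyr::filter(!(.data$group %in% exclude_groups)) |>
    dplyr::count(.data$species)

  out <- tibble(species = all_sp) |>
    dplyr::left_join(ns, by = "species") |>
    dplyr::rename(n = "n") |>
    dplyr::left_join(intra, by = "species") |>
    dplyr::left_join(inter, by = "species") |>
    dplyr::mutate(has_gap = ifelse(is.na(.data$max_intra), NA,
                                   .data$min_inter > .data$max_intra),
                  counted = !is.na(.data$max_intra) & !is.na(.data$min_inter))
  pct <- round(100 * mean(out$has_gap[out$counted]), 1)
  structure(out, percent_with_gap = pct,
            class = c("gap_table", class(out)))
}

#' @describeIn barcode_gap One-row summary: species counts and
#'   `percent_with_gap`.
#' @param x A `gap_table`.
#' @param ... Unused.
#' @method glance gap_table
#' @export
glance.gap_table <- function(x, ...) {
  tibble(n_species = nrow(x),
         n_counted = sum(x$counted),
         n_with_gap = sum(x$has_gap[x$counted]),
         percent_with_gap = attr(x, "percent_with_gap"))
}

#' @describeIn barcode_gap Scatter plot of maximum intraspecific versus
#'   minimum interspecific distance with the 1:1 reference line; points above
#'   the line show a barcode gap.
#' @param object A `gap_table`.
#' @param ... Unused.
#' @method autoplot gap_table
#' @export
autoplot.gap_table <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$counted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$max_intra, y = .data$min_inter,
                                   colour = .data$has_gap)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey40") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "maximum intraspecific K2P distance",
                  y = "minimum interspecific K2P distance",
                  colour = "barcode gap",
                  subtitle = sprintf("%.1f%% of species show a gap",
                                     attr(object, "percent_with_gap"))) +
    ggplot2::theme_minimal()
}

#' Write / read a distance matrix as long-format TSV
#'
#' @param m A `k2p_dist` object.
#' @param path Output path.
#' @return `path` invisibly (writer); a `k2p_dist` (reader).
#' @export
write_distances <- function(m, path) {
  readr::write_tsv(tidy(m), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_distances
#' @export
read_distances <- function(path) {
  long <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  ids <- unique(c(long$id1, long$id2))
  n <- length(ids)
  d <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  ov <- matrix(0L, n, n, dimnames = list(ids, ids))
  i <- match(long$id1, ids); j <- match(long$id2, ids)
  d[cbind(i, j)] <- d[cbind(j, i)] <- long$distance
  ov[cbind(i, j)] <- ov[cbind(j, i)] <- long$overlap
  diag(d) <- 0
  structure(list(ids = ids, d = d, overlap = ov), class = "k2p_dist")
}
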