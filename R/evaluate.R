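#' Evaluate every candidate barcode of a dataset
#'
#' The full evaluation loop: enumerates all single- and multi-marker
#' candidate barcodes ([enumerate_barcodes()]), concatenates each
#' ([concatenate_markers()]), and scores it with the three method families —
#' genetic distance (barcode-gap percentage), similarity (Best Match and
#' Best Close Match success percentages with the data-driven threshold), and
#' phylogeny (bootstrap NJ monophyly percentage, plus externally supplied
#' trees when given; the reported monophyly column is the minimum across
#' methods, the conservative choice). Hybrid-group specimens are excluded
#' from species-level scoring throughout.
#'
#' @param d A `barcode_dataset`.
#' @param markers Markers to combine (default: all in `d`).
#' @param boot_reps Bootstrap replicates for NJ support (default 1000).
#' @param seed Optional master seed; fixes every random step of the run.
#' @param min_support Monophyly support threshold in percent (strict).
#' @param min_overlap Minimum comparable sites per distance.
#' @param bcm_cutoff Fixed Best Close Match distance ceiling; `NULL`
#'   (default) derives the 95th-percentile threshold per barcode.
#' @param external_trees Optional named list: barcode name -> list of
#'   `phylo` trees from other methods, scored with [monophyly_assess()].
#' @return Tibble of class `barcode_evaluation`, one row per candidate:
#'   `barcode`, `n_markers`, `length`, `n_specimens`, `n_species`,
#'   `gap_pct`, `threshold`, `bm_pct`, `bcm_pct`, `nj_monophyly_pct`,
#'   `monophyly_pct` (minimum across tree methods).
#' @export
evaluate_barcodes <- function(d, markers = NULL, boot_reps = 1000L,
                              seed = NULL, min_support = 50,
                              min_overlap = 50L, bcm_cutoff = NULL,
                              external_trees = NULL) {
  if (is.null(markers)) markers <- names(d$alignments)
  specs <- enumerate_barcodes(markers)
  run <- function() {
    rows <- lapply(seq_len(nrow(specs)), function(i) {
      evaluate_one_barcode(d, specs$name[i], specs$markers[[i]],
                           boot_reps = boot_reps,
                           min_support = min_support,
                           min_overlap = min_overlap,
                           bcm_cutoff = bcm_cutoff,
                           external_trees = external_trees[[specs$name[i]]])
    })
    dplyr::bind_rows(rows)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(out, class = c("barcode_evaluation", class(out)),
            seed = seed, boot_reps = boot_reps)
}

evaluate_one_barcode <- function(d, name, mks, boot_reps, min_support,
                                 min_overlap, bcm_cutoff, external_trees) {
  aln <- suppressMessages(concatenate_markers(d, mks))
  keep <- d$specimens$specimen_id[d$specimens$group != "hybrid"]
  aln <- aln[intersect(rownames(aln), keep), , drop = FALSE]
  info <- species_of(rownames(aln), d$specimens)

  na_row <- tibble(barcode = name, n_markers = length(mks),
                   length = ncol(aln), n_specimens = nrow(aln),
                   n_species = dplyr::n_distinct(info$species),
                   gap_pct = NA_real_, threshold = NA_real_,
                   bm_pct = NA_real_, bcm_pct = NA_real_,
                   nj_monophyly_pct = NA_real_, monophyly_pct = NA_real_)
  if (nrow(aln) < 3L || dplyr::n_distinct(info$species) < 2L) return(na_row)

  m <- k2p_matrix(aln, min_overlap)

  gap_pct <- tryCatch(
    attr(barcode_gap(m, d$specimens), "percent_with_gap"),
    error = function(e) NA_real_)

  parts <- partition_distances(m, d$specimens)
  intra <- parts$distance[parts$class == "intraspecific"]
  threshold <- if (!is.null(bcm_cutoff)) {
    bcm_cutoff
  } else {
    tryCatch(bcm_threshold(intra), error = function(e) NA_real_)
  }

  bm_pct <- tryCatch(
    summarize_identification(best_match(m, d$specimens))$success_pct,
    error = function(e) NA_real_)
  bcm_pct <- if (is.na(threshold)) NA_real_ else tryCatch(
    summarize_identification(
      best_close_match(m, d$specimens, threshold))$success_pct,
    error = function(e) NA_real_)

  nj_pct <- tryCatch({
    mc <- complete_distance(m)
    sub <- aln[mc$ids, , drop = FALSE]
    sub_info <- species_of(mc$ids, d$specimens)
    if (length(mc$ids) < 3L || dplyr::n_distinct(sub_info$species) < 2L) {
      NA_real_
    } else {
      tree <- suppressWarnings(
        bootstrap_support(sub, n_reps = boot_reps,
                          min_overlap = min_overlap))
      attr(monophyly_assess(tree, d$specimens, min_support),
           "monophyly_pct")
    }
  }, error = function(e) NA_real_)

  mono_all <- nj_pct
  if (!is.null(external_trees)) {
    ext <- vapply(external_trees, function(tr) {
      tryCatch(attr(monophyly_assess(tr, d$specimens, min_support),
                    "monophyly_pct"),
               error = function(e) NA_real_)
    }, numeric(1))
    mono_all <- suppressWarnings(min(c(nj_pct, ext), na.rm = TRUE))
    if (!is.finite(mono_all)) mono_all <- NA_real_
  }

  tibble(barcode = name, n_markers = length(mks), length = ncol(aln),
         n_specimens = nrow(aln),
         n_species = dplyr::n_distinct(info$species),
         gap_pct = gap_pct, threshold = threshold,
         bm_pct = bm_pct, bcm_pct = bcm_pct,
         nj_monophyly_pct = nj_pct, monophyly_pct = mono_all)
}

#' @describeIn evaluate_barcodes Grouped bar chart of the headline
#'   percentages per candidate barcode.
#' @param object A `barcode_evaluation`.
#' @param ... Unused.
#' @method autoplot barcode_evaluation
#' @export
autoplot.barcode_evaluation <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::select("barcode", "gap_pct", "bm_pct", "bcm_pct",
                  "monophyly_pct") |>
    tidyr::pivot_longer(-"barcode", names_to = "metric",
                        values_to = "percent")
  df$barcode <- factor(df$barcode, levels = unique(object$barcode))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$barcode, y = .data$percent,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "success rate (%)", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Write / read an evaluation report as TSV
#'
#' @param x A `barcode_evaluation` (or any tibble of result rows).
#' @param path File path.
#' @return `path` invisibly (writer); a tibble (reader).
#' @export
write_report <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
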