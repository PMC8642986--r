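#' Strict-majority consensus sequence of a species
#'
#' Per column, the base carried by a strict majority of the given sequences;
#' columns without a strict majority (or whose majority state is a gap,
#' `N` or an ambiguity code) are `NA` and are excluded from hybrid
#' diagnostics.
#'
#' @param aln Character matrix alignment.
#' @param ids Row names to build the consensus from (default: all rows).
#' @return Character vector of length `ncol(aln)` with `NA` where no
#'   unambiguous strict-majority base exists.
#' @export
consensus_sequence <- function(aln, ids = rownames(aln)) {
  m <- aln[ids, , drop = FALSE]
  apply(m, 2L, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    top <- names(tab)[1L]
    if (tab[1L] > nrow(m) / 2 && top %in% c("A", "C", "G", "T")) top
    else NA_character_
  })
}

#' Diagnostic sites between two parental species and a putative hybrid
#'
#' Diagnostic columns are those where the two parental consensuses carry
#' different unambiguous bases. At each, an F1 hybrid is expected to be
#' heterozygous, i.e. to carry the two-base IUPAC code comprising exactly the
#' two parental bases (A/G -> R, C/T -> Y, A/C -> M, G/T -> K, A/T -> W,
#' C/G -> S).
#'
#' @param parent1,parent2 Parental consensus sequences (character vectors,
#'   `NA` allowed), equal length.
#' @param hybrid The hybrid's sequence (character vector or string), same
#'   length.
#' @return Tibble: `column` (1-based), `parent1_base`, `parent2_base`,
#'   `hybrid_base`, `is_heterozygous_match`.
#' @export
diagnostic_sites <- function(parent1, parent2, hybrid) {
  if (is.character(hybrid) && length(hybrid) == 1L) {
    hybrid <- strsplit(toupper(hybrid), "")[[1]]
  }
  if (length(parent1) != length(parent2) ||
      length(parent1) != length(hybrid)) {
    abort("sequences have unequal lengths")
  }
  bases <- c("A", "C", "G", "T")
  diag_cols <- which(parent1 %in% bases & parent2 %in% bases &
                       parent1 != parent2)
  if (length(diag_cols) == 0L) {
    return(tibble(column = integer(), parent1_base = character(),
                  parent2_base = character(), hybrid_base = character(),
                  is_heterozygous_match = logical()))
  }
  expected <- AMBIG2[paste0(pmin(parent1[diag_cols], parent2[diag_cols]),
                            pmax(parent1[diag_cols], parent2[diag_cols]))]
  tibble(column = diag_cols,
         parent1_base = parent1[diag_cols],
         parent2_base = parent2[diag_cols],
         hybrid_base = hybrid[diag_cols],
         is_heterozygous_match = hybrid[diag_cols] == unname(expected))
}

#' Infer the parental species pair of a putative hybrid
#'
#' Scores every unordered pair of candidate species by the fraction of their
#' diagnostic columns at which the putative hybrid is heterozygous, and calls
#' the pair maximising that fraction, provided enough diagnostic columns
#' exist and the fraction clears the call threshold. Genuine F1s sit at or
#' near 100%; non-hybrids fall well below. The score is symmetric in parent
#' order; ties between distinct best pairs are reported unresolved.
#'
#' @param aln Nuclear marker alignment (character matrix).
#' @param specimens Specimen metadata.
#' @param hybrid_id Specimen id of the putative hybrid.
#' @param candidates Candidate parent species (default: all non-hybrid
#'   species with sequences in `aln`, minus the hybrid's own label).
#' @param min_sites Minimum diagnostic columns for a pair to be scored
#'   (default 3).
#' @param call_threshold Minimum heterozygous fraction to call a hybrid
#'   (default 0.8).
#' @param tie_tol Fractions within this tolerance are tied.
#' @return One-row tibble: `hybrid_id`, `parent1`, `parent2`,
#'   `n_diagnostic`, `n_heterozygous`, `fraction`, `call` (`"called"`,
#'   `"unresolved"` or `"no_call"`).
#' @export
infer_parent_pair <- function(aln, specimens, hybrid_id, candidates = NULL,
                              min_sites = 3L, call_threshold = 0.8,
                              tie_tol = 1e-12) {
  if (!hybrid_id %in% rownames(aln)) {
    abort(paste0("hybrid has no sequence: ", hybrid_id))
  }
  info <- species_of(rownames(aln), specimens)
  hyb_species <- info$species[rownames(aln) == hybrid_id][1L]
  if (is.null(candidates)) {
    candidates <- sort(setdiff(
      unique(info$species[info$group != "hybrid"]), hyb_species))
  }
  if (length(candidates) < 2L) abort("need >= 2 candidate parent species")
  cons <- lapply(setNames(candidates, candidates), function(s) {
    consensus_sequence(aln, rownames(aln)[info$species == s &
                                            rownames(aln) != hybrid_id])
  })
  hyb <- aln[hybrid_id, ]
  pairs <- combn(candidates, 2L, simplify = FALSE)
  scored <- purrr::map_dfr(pairs, function(pr) {
    ds <- diagnostic_sites(cons[[pr[1L]]], cons[[pr[2L]]], hyb)
    tibble(parent1 = pr[1L], parent2 = pr[2L],
           n_diagnostic = nrow(ds),
           n_heterozygous = sum(ds$is_heterozygous_match),
           fraction = ifelse(nrow(ds) >= min_sites,
                             sum(ds$is_heterozygous_match) / nrow(ds),
                             NA_real_))
  })
  scored <- dplyr::filter(scored, !is.na(.data$fraction))
  no_call <- tibble(hybrid_id = hybrid_id, parent1 = NA_character_,
                    parent2 = NA_character_, n_diagnostic = NA_integer_,
                    n_heterozygous = NA_integer_, fraction = NA_real_,
                    call = "no_call")
  if (nrow(scored) == 0L) return(no_call)
  best <- max(scored$fraction)
  if (best < call_threshold) {
    no_call$fraction <- best
    return(no_call)
  }
  top <- dplyr::filter(scored, .data$fraction >= best - tie_tol)
  if (nrow(top) > 1L) {
    return(dplyr::mutate(
      dplyr::slice(dplyr::select(top, -"fraction"), 1L),
      hybrid_id = hybrid_id, fraction = best, call = "unresolved",
      .before = 1L) |>
        dplyr::select("hybrid_id", "parent1", "parent2", "n_diagnostic",
                      "n_heterozygous", "fraction", "call"))
  }
  dplyr::mutate(top, hybrid_id = hybrid_id, call = "called", .before = 1L) |>
    dplyr::select("hybrid_id", "parent1", "parent2", "n_diagnostic",
                  "n_heterozygous", "fraction", "call")
}

#' Maternal parent from chloroplast markers
#'
#' Chloroplast markers are maternally inherited in these taxa, so the parent
#' whose chloroplast consensus is closer to the hybrid's chloroplast
#' sequences is the matrilineal parent. Mismatches are summed across the
#' supplied chloroplast markers; the call requires a margin of at least one
#' substitution, otherwise the parentage is unresolved.
#'
#' @param d A `barcode_dataset`.
#' @param hybrid_id Specimen id of the hybrid.
#' @param parent1,parent2 Candidate parental species labels.
#' @param chloroplast_markers Markers to use (must be present in `d`).
#' @return One-row tibble: `hybrid_id`, `maternal_parent` (`NA` if
#'   unresolved), `mismatches_parent1`, `mismatches_parent2`, `n_sites`.
#' @export
maternal_parent <- function(d, hybrid_id, parent1, parent2,
                            chloroplast_markers) {
  mm <- c(0L, 0L)
  n_sites <- 0L
  used <- 0L
  for (marker in chloroplast_markers) {
    aln <- d$alignments[[marker]]
    if (is.null(aln) || !hybrid_id %in% rownames(aln)) next
    info <- species_of(rownames(aln), d$specimens)
    hyb <- aln[hybrid_id, ]
    for (k in 1:2) {
      par_sp <- c(parent1, parent2)[k]
      ids <- rownames(aln)[info$species == par_sp &
                             rownames(aln) != hybrid_id]
      if (length(ids) == 0L) next
      cons <- consensus_sequence(aln, ids)
      ok <- cons %in% c("A", "C", "G", "T") & hyb %in% c("A", "C", "G", "T")
      mm[k] <- mm[k] + sum(cons[ok] != hyb[ok])
      n_sites <- n_sites + sum(ok)
      used <- used + 1L
    }
  }
  if (used < 2L) abort("chloroplast sequences missing for hybrid or parents")
  mother <- if (abs(mm[1L] - mm[2L]) >= 1L) {
    c(parent1, parent2)[which.min(mm)]
  } else NA_character_
  tibble(hybrid_id = hybrid_id, maternal_parent = mother,
         mismatches_parent1 = mm[1L], mismatches_parent2 = mm[2L],
         n_sites = n_sites)
}

#' Full hybrid report for a dataset
#'
#' For every specimen in the `hybrid` group: infers the parental species pair
#' from heterozygous diagnostic sites in the nuclear marker, then assigns the
#' maternal parent from the chloroplast markers.
#'
#' @param d A `barcode_dataset`.
#' @param nuclear Nuclear marker name (e.g. `"ITS2"`).
#' @param chloroplast Chloroplast marker names.
#' @param ... Passed to [infer_parent_pair()].
#' @return Tibble with one row per hybrid specimen: parent-pair call joined
#'   with the maternal assignment.
#' @export
hybrid_report <- function(d, nuclear, chloroplast, ...) {
  hybrids <- d$specimens$specimen_id[d$specimens$group == "hybrid"]
  aln <- d$alignments[[nuclear]]
  rows <- lapply(hybrids, function(h) {
    if (!h %in% rownames(aln)) {
      return(tibble(hybrid_id = h, parent1 = NA_character_,
                    parent2 = NA_character_, n_diagnostic = NA_integer_,
                    n_heterozygous = NA_integer_, fraction = NA_real_,
                    call = "no_sequence", maternal_parent = NA_character_))
    }
    call <- infer_parent_pair(aln, d$specimens, h, ...)
    mother <- NA_character_
    if (call$call == "called") {
      mat <- tryCatch(
        maternal_parent(d, h, call$parent1, call$parent2, chloroplast),
        error = function(e) NULL)
      if (!is.null(mat)) mother <- mat$maternal_parent
    }
    dplyr::mutate(call, maternal_parent = mother)
  })
  dplyr::bind_rows(rows)
}

#' Collapse individuals into haplotypes over one or more markers
#'
#' Extracts the variant columns of the given individuals — single-nucleotide
#' variants plus indels, where a maximal contiguous run of gap-discordant
#' columns counts as one indel event — and groups individuals carrying
#' identical variant states into haplotypes. The route used to show that
#' infraspecific taxa (e.g. subspecies) carry distinct haplotypes.
#'
#' @param d A `barcode_dataset` (or a single character-matrix alignment).
#' @param ids Specimen ids to collapse (must be present in every marker
#'   used).
#' @param markers Markers to concatenate over (default: all; ignored when
#'   `d` is a matrix).
#' @return List of class `haplotype_table`: `variants` (tibble: `type`
#'   `"SNV"`/`"indel"`, `start`, `end` in concatenated coordinates),
#'   `assignment` (tibble: `specimen_id`, `haplotype` index), and counts
#'   `n_haplotypes`, `n_snv`, `n_indel`.
#' @export
haplotype_collapse <- function(d, ids, markers = NULL) {
  m <- if (is.matrix(d)) {
    d
  } else {
    if (is.null(markers)) markers <- names(d$alignments)
    concatenate_markers(d, markers)
  }
  missing_ids <- setdiff(ids, rownames(m))
  if (length(missing_ids) > 0L) {
    abort(paste0("individual missing from alignment: ", missing_ids[1L]))
  }
  m <- m[ids, , drop = FALSE]
  gap_disc <- apply(m, 2L, function(col) {
    any(col == "-") && !all(col == "-")
  })
  # indel events: maximal runs of gap-discordant columns
  runs <- rle(gap_disc)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  indels <- tibble(type = "indel", start = starts[runs$values],
                   end = ends[runs$values])
  snv_cols <- which(!gap_disc & vapply(seq_len(ncol(m)), function(j) {
    b <- m[, j]
    b <- b[b != "-"]
    length(unique(b)) >= 2L
  }, logical(1)))
  snvs <- tibble(type = "SNV", start = snv_cols, end = snv_cols)
  variants <- dplyr::arrange(dplyr::bind_rows(snvs, indels), .data$start)
  state <- vapply(seq_along(ids), function(i) {
    paste(vapply(seq_len(nrow(variants)), function(v) {
      paste0(m[i, variants$start[v]:variants$end[v]], collapse = "")
    }, character(1)), collapse = "|")
  }, character(1))
  hap <- match(state, unique(state))
  structure(list(variants = variants,
                 assignment = tibble(specimen_id = ids, haplotype = hap),
                 n_haplotypes = length(unique(hap)),
                 n_snv = nrow(snvs), n_indel = nrow(indels)),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("<haplotype_table>", nrow(x$assignment), "individuals,",
      x$n_snv, "SNVs,", x$n_indel, "indels,",
      x$n_haplotypes, "haplotypes\n")
  invisible(x)
}
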