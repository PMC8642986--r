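# single-letter abbreviations for the four classic plant barcode markers
MARKER_ABBREV <- c(ITS2 = "I", rbcL = "R", matK = "M", `trnH-psbA` = "T")

# canonical marker ordering: I, R, M, T for the classic four, then any
# user-defined markers in the order given
canonical_marker_order <- function(markers) {
  classic <- intersect(names(MARKER_ABBREV), markers)
  c(classic, setdiff(markers, classic))
}

barcode_name <- function(markers) {
  ab <- ifelse(markers %in% names(MARKER_ABBREV),
               MARKER_ABBREV[markers], markers)
  paste(ab, collapse = "+")
}

#' Enumerate candidate barcodes from a marker set
#'
#' All non-empty marker subsets, each a candidate barcode: four markers give
#' 15 candidates (4 singles, 6 pairs, 4 triples, 1 quadruple). Names use the
#' conventional single letters I, R, M, T for ITS2, rbcL, matK and trnH-psbA
#' (e.g. `"I+R+T"`); other markers keep their full names.
#'
#' @param markers Character vector of available marker names (>= 1, no
#'   duplicates).
#' @return Tibble with `name`, `markers` (list-column of ordered marker
#'   subsets) and `n_markers`, ordered by subset size then canonical marker
#'   order.
#' @export
enumerate_barcodes <- function(markers) {
  if (length(markers) < 1L) abort("need at least one marker")
  if (anyDuplicated(markers)) abort("duplicate marker names")
  markers <- canonical_marker_order(markers)
  subsets <- unlist(lapply(seq_along(markers), function(k) {
    combn(markers, k, simplify = FALSE)
  }), recursive = FALSE)
  tibble(name = vapply(subsets, barcode_name, character(1)),
         markers = subsets,
         n_markers = lengths(subsets))
}

#' Concatenate marker alignments end-to-end
#'
#' Joins the per-marker sequences of each individual into one supermatrix in
#' the given marker order. By default only specimens present in every
#' constituent marker are retained (complete-case): padding absentees with
#' gaps would mix pairwise-deletion semantics across markers. Set
#' `pad_missing = TRUE` to instead keep the union of specimens, filling
#' absent blocks with gaps, for sensitivity analysis.
#'
#' @param d A `barcode_dataset`.
#' @param markers Ordered character vector of markers to concatenate.
#' @param pad_missing Pad specimens missing a constituent marker with all-gap
#'   blocks instead of dropping them.
#' @return Character matrix of the concatenated alignment with attribute
#'   `blocks`: a tibble of 1-based inclusive marker coordinates (`marker`,
#'   `start`, `end`). Dropped specimens are reported via a message.
#' @export
concatenate_markers <- function(d, markers, pad_missing = FALSE) {
  missing_m <- setdiff(markers, names(d$alignments))
  if (length(missing_m) > 0L) {
    abort(paste0("marker not in dataset: ", missing_m[1L]))
  }
  alns <- d$alignments[markers]
  if (length(markers) == 1L) {
    out <- alns[[1L]]
    attr(out, "blocks") <- tibble(marker = markers, start = 1L,
                                  end = ncol(out))
    return(out)
  }
  id_sets <- lapply(alns, rownames)
  ids <- if (pad_missing) {
    d$specimens$specimen_id[d$specimens$specimen_id %in%
                              unique(unlist(id_sets))]
  } else {
    Reduce(intersect, id_sets)
  }
  if (length(ids) == 0L) {
    abort("no specimen present in all constituent markers")
  }
  dropped <- setdiff(unique(unlist(id_sets)), ids)
  if (length(dropped) > 0L) {
    message(length(dropped), " specimen(s) dropped: missing >=1 constituent marker")
  }
  blocks <- vector("list", length(markers))
  pieces <- vector("list", length(markers))
  at <- 1L
  for (k in seq_along(markers)) {
    m <- alns[[k]]
    piece <- matrix("-", nrow = length(ids), ncol = ncol(m),
                    dimnames = list(ids, NULL))
    present <- intersect(ids, rownames(m))
    piece[present, ] <- m[present, , drop = FALSE]
    pieces[[k]] <- piece
    blocks[[k]] <- tibble(marker = markers[k], start = at,
                          end = at + ncol(m) - 1L)
    at <- at + ncol(m)
  }
  out <- do.call(cbind, pieces)
  attr(out, "blocks") <- dplyr::bind_rows(blocks)
  out
}
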