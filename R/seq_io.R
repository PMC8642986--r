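#' Construct a barcode dataset
#'
#' A barcode dataset bundles a specimen metadata table with one aligned
#' sequence matrix per marker. Specimens may be absent from any alignment
#' (failed amplification or sequencing is the norm for some plant markers);
#' every sequence, however, must belong to a specimen in the metadata table.
#'
#' @param specimens A data frame with at least `specimen_id`, `species` and
#'   `site_id` columns. Optional columns: `group` (one of `true_mangrove`,
#'   `associate`, `coastal`, `hybrid`, `introduced`), `population_id`
#'   (defaults to `site_id`), `latitude`, `longitude`.
#' @param alignments A named list of alignments, one per marker. Each element
#'   is either a character matrix (rows = specimens, columns = alignment
#'   positions, rownames = specimen ids) or a named character vector of
#'   equal-length sequence strings. The alphabet is IUPAC nucleotide codes
#'   plus `-`; input case is ignored and stored uppercase.
#'
#' @return An object of class `barcode_dataset`: a list with elements
#'   `specimens` (a tibble) and `alignments` (a named list of character
#'   matrices).
#' @export
#' @examples
#' meta <- tibble::tibble(
#'   specimen_id = c("s1", "s2"), species = c("A x", "A x"), site_id = "st1"
#' )
#' aln <- c(s1 = "ACGTACGT", s2 = "ACGTACGA")
#' d <- barcode_dataset(meta, list(rbcL = aln))
#' d
barcode_dataset <- function(specimens, alignments = list()) {
  specimens <- as_tibble(specimens)
  required <- c("specimen_id", "species", "site_id")
  missing_cols <- setdiff(required, names(specimens))
  if (length(missing_cols) > 0L) {
    abort(paste0("specimen table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  specimens$specimen_id <- as.character(specimens$specimen_id)
  specimens$species <- as.character(specimens$species)
  specimens$site_id <- as.character(specimens$site_id)
  if (!"group" %in% names(specimens)) specimens$group <- "true_mangrove"
  if (!"population_id" %in% names(specimens)) {
    specimens$population_id <- specimens$site_id
  }
  specimens$population_id <- ifelse(is.na(specimens$population_id),
                                    specimens$site_id,
                                    as.character(specimens$population_id))
  if (!"latitude" %in% names(specimens)) specimens$latitude <- NA_real_
  if (!"longitude" %in% names(specimens)) specimens$longitude <- NA_real_

  alignments <- lapply(alignments, function(a) {
    m <- if (is.matrix(a)) {
      a[] <- toupper(a)
      a
    } else {
      seq_to_matrix(a)
    }
    if (is.null(rownames(m))) {
      abort("alignment sequences must be named by specimen_id")
    }
    m
  })

  d <- structure(list(specimens = specimens, alignments = alignments),
                 class = "barcode_dataset")
  validate_barcode_dataset(d)
  d
}

#' Validate a barcode dataset
#'
#' Checks the invariants of a [barcode_dataset()]: unique specimen ids,
#' non-empty species labels, known group labels, equal sequence lengths
#' within each alignment, IUPAC-only characters, and that every sequence
#' belongs to a specimen in the metadata table.
#'
#' @param d A `barcode_dataset`.
#' @return `d`, invisibly. Errors describe the first violated invariant.
#' @export
validate_barcode_dataset <- function(d) {
  sp <- d$specimens
  if (anyDuplicated(sp$specimen_id)) {
    abort(paste0("duplicate specimen_id: ",
                 sp$specimen_id[duplicated(sp$specimen_id)][1L]))
  }
  if (any(is.na(sp$species) | sp$species == "")) {
    abort("species labels must be non-empty")
  }
  bad_group <- setdiff(unique(sp$group), SPECIMEN_GROUPS)
  if (length(bad_group) > 0L) {
    abort(paste0("unknown specimen group: ", bad_group[1L]))
  }
  if (length(d$alignments) == 0L) {
    warn("dataset has no alignments")
  }
  if (length(d$alignments) > 0L && is.null(names(d$alignments))) {
    abort("alignments must be named by marker")
  }
  for (marker in names(d$alignments)) {
    m <- d$alignments[[marker]]
    bad <- setdiff(unique(as.vector(m)), IUPAC_CODES)
    if (length(bad) > 0L) {
      abort(paste0("non-IUPAC character '", bad[1L], "' in marker ", marker))
    }
    if (anyDuplicated(rownames(m))) {
      abort(paste0("duplicate specimen_id in marker ", marker))
    }
    orphan <- setdiff(rownames(m), sp$specimen_id)
    if (length(orphan) > 0L) {
      abort(paste0("sequence without metadata record in marker ", marker,
                   ": ", orphan[1L]))
    }
  }
  invisible(d)
}

#' @export
print.barcode_dataset <- function(x, ...) {
  cat("<barcode_dataset>\n")
  cat("  specimens:", nrow(x$specimens), "|",
      dplyr::n_distinct(x$specimens$species), "species |",
      dplyr::n_distinct(x$specimens$site_id), "sites\n")
  for (marker in names(x$alignments)) {
    m <- x$alignments[[marker]]
    cat(sprintf("  %-10s %4d sequences x %5d bp\n", marker, nrow(m), ncol(m)))
  }
  invisible(x)
}

#' Markers present in a dataset
#' @param d A `barcode_dataset`.
#' @return Character vector of marker names.
#' @export
markers <- function(d) names(d$alignments)

#' Extract one marker alignment
#' @param d A `barcode_dataset`.
#' @param marker Marker name.
#' @return Character matrix (specimens x positions).
#' @export
alignment <- function(d, marker) {
  if (!marker %in% names(d$alignments)) {
    abort(paste0("no alignment for marker ", marker))
  }
  d$alignments[[marker]]
}

#' Read a barcode dataset from FASTA files and a metadata table
#'
#' Each FASTA file holds one pre-aligned marker (equal record lengths; this
#' package consumes alignments, it does not compute them). FASTA headers may
#' be bare specimen ids or the `specimen_id|species|site_id` convenience
#' dialect written by [write_barcode_dataset()]; everything after the first
#' `|` is ignored because the metadata table is authoritative.
#'
#' @param fasta_paths Named character vector or list, marker name -> path.
#' @param metadata_path Path to a tab-delimited UTF-8 table with a header
#'   naming at least `specimen_id`, `species`, `site_id`.
#' @return A validated [barcode_dataset()]. Specimens present in the metadata
#'   but absent from a FASTA are retained as sequence-missing; sequences with
#'   no metadata row raise an error.
#' @export
read_barcode_dataset <- function(fasta_paths, metadata_path) {
  fasta_paths <- unlist(fasta_paths)
  if (is.null(names(fasta_paths)) || any(names(fasta_paths) == "")) {
    abort("fasta_paths must be named by marker")
  }
  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          progress = FALSE)
  alignments <- lapply(fasta_paths, read_aligned_fasta)
  barcode_dataset(meta, alignments)
}

# read one aligned FASTA into a character matrix, taking the first
# |-delimited header field as the specimen id
read_aligned_fasta <- function(path) {
  recs <- ape::read.FASTA(path)
  seqs <- toupper(vapply(as.character(recs), paste0, "", collapse = ""))
  names(seqs) <- vapply(strsplit(names(seqs), "|", fixed = TRUE), `[[`, "", 1L)
  seq_to_matrix(seqs)
}

#' Write a barcode dataset to disk
#'
#' Writes one aligned FASTA per marker (headers
#' `>specimen_id|species|site_id`) plus a `metadata.tsv` table. Together with
#' [read_barcode_dataset()] this round-trips a dataset exactly (sequence
#' content and metadata; record order follows the metadata table).
#'
#' @param d A `barcode_dataset`.
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of written paths, invisibly.
#' @export
write_barcode_dataset <- function(d, out_dir) {
  validate_barcode_dataset(d)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta_path <- file.path(out_dir, "metadata.tsv")
  readr::write_tsv(d$specimens, meta_path, progress = FALSE)
  paths <- c(metadata = meta_path)
  for (marker in names(d$alignments)) {
    m <- d$alignments[[marker]]
    ids <- rownames(m)
    sp <- d$specimens[match(ids, d$specimens$specimen_id), ]
    fa_path <- file.path(out_dir, paste0(marker, ".fasta"))
    lines <- character(2L * length(ids))
    lines[c(TRUE, FALSE)] <- paste0(">", ids, "|", sp$species, "|", sp$site_id)
    lines[c(FALSE, TRUE)] <- matrix_to_seq(m)
    writeLines(lines, fa_path)
    paths[[marker]] <- fa_path
  }
  invisible(paths)
}

#' Specimen metadata as a tibble
#' @param d A `barcode_dataset`.
#' @return The specimen tibble.
#' @export
specimen_table <- function(d) d$specimens
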