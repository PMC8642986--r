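#' Neighbor-joining tree from a K2P distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) with two guarantees layered
#' on top: the input must be complete (no missing or saturated entries —
#' imputation is refused, the caller filters specimens instead, e.g. with
#' [complete_distance()]), and negative branch lengths are clamped to zero
#' with the deficit transferred to the adjacent ancestral branch, a standard
#' cosmetic repair that leaves most path lengths intact.
#'
#' @param m A `k2p_dist` object, `dist`, or square numeric matrix.
#' @return An unrooted `phylo` tree whose tips are the specimen ids. On
#'   additive input the tree's path lengths reproduce the matrix exactly.
#' @export
nj_tree <- function(m) {
  d <- as_dist_matrix(m)
  if (nrow(d) < 3L) abort("neighbor joining needs >= 3 taxa")
  if (any(!is.finite(d))) {
    abort("distance matrix has missing or saturated entries; filter first (see complete_distance)")
  }
  clamp_negative_edges(ape::nj(stats::as.dist(d)))
}

as_dist_matrix <- function(m) {
  if (inherits(m, "k2p_dist")) return(m$d)
  if (inherits(m, "dist")) return(as.matrix(m))
  if (is.matrix(m)) return(m)
  abort("cannot interpret distance input")
}

# clamp negative branch lengths to 0, moving the deficit onto the branch
# leading into the same node so that distances through it are preserved
clamp_negative_edges <- function(tree) {
  for (pass in 1:10) {
    neg <- which(tree$edge.length < 0)
    if (length(neg) == 0L) break
    for (e in neg) {
      parent_edge <- which(tree$edge[, 2] == tree$edge[e, 1])
      if (length(parent_edge) == 1L) {
        tree$edge.length[parent_edge] <-
          tree$edge.length[parent_edge] + tree$edge.length[e]
      }
      tree$edge.length[e] <- 0
    }
  }
  tree$edge.length <- pmax(tree$edge.length, 0)
  tree
}

#' Drop specimens until a distance matrix is complete
#'
#' Greedily removes the specimen involved in the most missing or saturated
#' entries until every off-diagonal entry is finite, so the matrix can feed
#' [nj_tree()].
#'
#' @param m A `k2p_dist` object.
#' @return A `k2p_dist` restricted to the retained specimens.
#' @export
complete_distance <- function(m) {
  d <- m$d
  repeat {
    bad <- !is.finite(d)
    diag(bad) <- FALSE
    if (!any(bad)) break
    worst <- which.max(rowSums(bad))
    d <- d[-worst, -worst, drop = FALSE]
  }
  keep <- rownames(d)
  structure(list(ids = keep, d = d,
                 overlap = m$overlap[keep, keep, drop = FALSE]),
            class = "k2p_dist")
}

# canonical bipartition keys of the internal edges of an unrooted tree:
# each internal edge splits the tips in two; the key is the sorted tip set
# of the side NOT containing the alphabetically first tip label, so it is
# invariant to rooting and to tip ordering across trees on the same tips
bipartition_keys <- function(tree) {
  n <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  anchor <- min(labels)
  keys <- vapply(seq_along(pp), function(k) {
    set <- pp[[k]]
    if (length(set) < 2L || length(set) > n - 2L) return(NA_character_)
    if (anchor %in% labels[set]) set <- setdiff(seq_len(n), set)
    paste(sort(labels[set]), collapse = "\r")
  }, character(1))
  names(keys) <- n + seq_along(pp)  # internal node numbers
  keys
}

canonical_key <- function(tips, all_tips) {
  if (min(all_tips) %in% tips) tips <- setdiff(all_tips, tips)
  paste(sort(tips), collapse = "\r")
}

#' Neighbor-joining tree with nonparametric bootstrap support
#'
#' Builds the point-estimate NJ tree from the full alignment, then resamples
#' alignment columns with replacement `n_reps` times, rebuilds an NJ tree per
#' replicate, and annotates each internal edge of the point tree with the
#' percentage of replicates containing the same bipartition. Support attaches
#' to bipartitions, so the values are invariant to rooting.
#'
#' @param aln Character matrix alignment (>= 3 sequences).
#' @param n_reps Number of bootstrap replicates (>= 1); 1000 is conventional
#'   for barcode studies.
#' @param seed Optional integer; fixes the resampling stream so repeated runs
#'   give identical supports.
#' @param min_overlap Passed to [k2p_matrix()] for the point matrix.
#' @return A `phylo` tree with `node.label` holding percent support for
#'   internal edges (`NA` for the root and trivial splits).
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed = NULL,
                              min_overlap = 50L) {
  if (n_reps < 1L) abort("n_reps must be >= 1")
  if (nrow(aln) < 3L) abort("need >= 3 sequences")
  run <- function() {
    point <- nj_tree(fill_nonfinite(k2p_matrix(aln, min_overlap)))
    keys <- bipartition_keys(point)
    counts <- setNames(rep(0L, length(keys)), names(keys))
    L <- ncol(aln)
    for (r in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_m <- fill_nonfinite(k2p_matrix(aln[, cols, drop = FALSE],
                                         min_overlap = 1L), quiet = TRUE)
      rep_keys <- bipartition_keys(nj_tree(rep_m))
      hit <- keys %in% rep_keys & !is.na(keys)
      counts[hit] <- counts[hit] + 1L
    }
    support <- ifelse(is.na(keys), NA_real_, 100 * counts / n_reps)
    # a zero-length internal edge carries no signal: report it unresolved
    n_tip <- length(point$tip.label)
    for (i in seq_along(support)) {
      node <- n_tip + i
      into <- which(point$edge[, 2] == node)
      if (length(into) == 1L && point$edge.length[into] <= 1e-12) {
        support[i] <- NA_real_
      }
    }
    point$node.label <- as.character(round(support, 1))
    point$node.label[is.na(support)] <- ""
    point
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# replace missing/saturated entries by a large finite value so a tree can
# still be built; bootstrap replicates do this silently
fill_nonfinite <- function(m, quiet = FALSE) {
  bad <- !is.finite(m$d)
  diag(bad) <- FALSE
  if (any(bad)) {
    cap <- if (any(is.finite(m$d[upper.tri(m$d)]))) {
      1.5 * max(m$d[upper.tri(m$d)][is.finite(m$d[upper.tri(m$d)])], 0.1)
    } else 1
    if (!quiet) {
      warn(sprintf("replacing %d non-finite distance entries with %.3f",
                   sum(bad) / 2, cap))
    }
    m$d[bad] <- cap
  }
  m
}

#' Assess species monophyly on a tree
#'
#' A species is monophyletic when one internal edge of the tree separates
#' exactly its individuals from everything else; when the tree carries
#' bootstrap supports, that edge must additionally be supported by strictly
#' more than `min_support` percent of replicates. Species with a single
#' individual are counted monophyletic by convention. With `partition_by`,
#' the tree is scored separately inside each taxon partition (as when trees
#' are built per taxonomic order), and a species alone in its partition
#' counts as monophyletic.
#'
#' @param tree A `phylo` tree; `node.label` may hold percent supports.
#' @param specimens Specimen metadata covering all tips.
#' @param min_support Support threshold in percent; the rule is strict
#'   (`support > min_support`). Ignored when the tree carries no supports.
#' @param partition_by Optional name of a metadata column defining taxon
#'   partitions scored separately.
#' @return Tibble of class `monophyly_report`: `species`, `n_tips`,
#'   `is_monophyletic`, `support`, `counted`; attribute `monophyly_pct` is
#'   the percentage of counted species that are monophyletic ([glance()]
#'   retrieves it).
#' @export
monophyly_assess <- function(tree, specimens, min_support = 50,
                             partition_by = NULL) {
  info <- species_of(tree$tip.label, specimens)
  if (!is.null(partition_by)) {
    parts <- split(tree$tip.label, info[[partition_by]])
    out <- dplyr::bind_rows(lapply(parts, function(tips) {
      sub_info <- species_of(tips, specimens)
      if (dplyr::n_distinct(sub_info$species) == 1L) {
        return(tibble(species = unique(sub_info$species),
                      n_tips = length(tips), is_monophyletic = TRUE,
                      support = NA_real_, counted = TRUE))
      }
      sub <- ape::keep.tip(tree, tips)
      as_tibble(monophyly_core(sub, specimens, min_support))
    }))
    out <- dplyr::arrange(out, .data$species)
  } else {
    out <- monophyly_core(tree, specimens, min_support)
  }
  pct <- 100 * mean(out$is_monophyletic[out$counted])
  structure(out, monophyly_pct = pct,
            class = c("monophyly_report", class(out)))
}

monophyly_core <- function(tree, specimens, min_support) {
  info <- species_of(tree$tip.label, specimens)
  n_tip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  clades <- lapply(pp, function(s) sort(labels[s]))
  has_support <- !is.null(tree$node.label) &&
    any(suppressWarnings(!is.na(as.numeric(tree$node.label))))
  support_of <- if (has_support) {
    suppressWarnings(as.numeric(tree$node.label))
  } else NULL

  species <- sort(unique(info$species))
  rows <- lapply(species, function(s) {
    tips <- sort(tree$tip.label[info$species == s])
    if (length(tips) == 1L || length(tips) == n_tip) {
      return(tibble(species = s, n_tips = length(tips),
                    is_monophyletic = TRUE, support = NA_real_,
                    counted = TRUE))
    }
    # the split separating the species exists if some node's clade is
    # exactly the species' tips, or exactly their complement; prefer the
    # direct clade's node for the support value
    comp <- sort(setdiff(tree$tip.label, tips))
    hit <- which(vapply(clades, identical, logical(1), y = tips))
    if (length(hit) == 0L) {
      hit <- which(vapply(clades, identical, logical(1), y = comp))
    }
    if (length(hit) == 0L) {
      return(tibble(species = s, n_tips = length(tips),
                    is_monophyletic = FALSE, support = NA_real_,
                    counted = TRUE))
    }
    supp <- if (!is.null(support_of)) support_of[hit[1L]] else NA_real_
    mono <- if (!is.null(support_of) && !is.na(supp)) {
      supp > min_support
    } else TRUE
    tibble(species = s, n_tips = length(tips), is_monophyletic = mono,
           support = supp, counted = TRUE)
  })
  dplyr::bind_rows(rows)
}

#' @describeIn monophyly_assess One-row summary with `monophyly_pct`.
#' @param x A `monophyly_report`.
#' @param ... Unused.
#' @method glance monophyly_report
#' @export
glance.monophyly_report <- function(x, ...) {
  tibble(n_species = nrow(x),
         n_counted = sum(x$counted),
         n_monophyletic = sum(x$is_monophyletic[x$counted]),
         monophyly_pct = attr(x, "monophyly_pct"))
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that turn
#' malformed input into errors and preserve support values stored as internal
#' node labels — the ingestion route for externally built (e.g. likelihood or
#' Bayesian) trees that are scored but never constructed here.
#'
#' @param path File path.
#' @param tree A `phylo` object.
#' @return `read_newick`: a `phylo`. `write_newick`: `path`, invisibly.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  open <- lengths(regmatches(txt, gregexpr("(", txt, fixed = TRUE)))
  close <- lengths(regmatches(txt, gregexpr(")", txt, fixed = TRUE)))
  if (open != close) abort("malformed Newick: unbalanced parentheses")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tree)) abort("malformed Newick input")
  tree
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
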