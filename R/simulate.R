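#' Default marker model table for the community simulator
#'
#' Four markers emulating the classic plant barcode panel: a slow,
#' near-universally recoverable plastid coding region (rbcL-like), a fast
#' GC-rich nuclear spacer (ITS2-like), and two plastid regions with ~70%
#' recovery, one of them indel-rich (matK- and trnH-psbA-like). Lengths, GC
#' content and recovery probabilities follow the values reported for the four
#' markers in large mangrove-community surveys (570/679/902/1411 bp;
#' 44.1/59.7/33.9/27.6% GC; 98.6/87.9/70.0/72.8% recovery); substitution-rate
#' multipliers are chosen so realised interspecific divergences reproduce the
#' observed ordering (ITS2 fastest among the comparable markers, rbcL
#' slowest).
#'
#' @return Tibble with columns `marker`, `length`, `rate`, `kappa`, `gc`,
#'   `indel_events`, `recovery`, `genome`.
#' @export
default_markers <- function() {
  tibble(
    marker = c("rbcL", "ITS2", "matK", "trnH-psbA"),
    length = c(570L, 679L, 902L, 1411L),
    rate = c(0.38, 1.0, 0.55, 1.10),
    kappa = 2,
    gc = c(0.441, 0.597, 0.339, 0.276),
    indel_events = c(0L, 3L, 10L, 40L),
    recovery = c(0.986, 0.879, 0.700, 0.728),
    genome = c("chloroplast", "nuclear", "chloroplast", "chloroplast"))
}

#' Simulation configuration
#'
#' Parameters of the community generator. Defaults emulate the sampling
#' design of a multi-site mangrove barcode survey: a Yule species tree, 3-6
#' individuals per species per site, a handful of populations per species,
#' per-site nucleotide diversity around 0.001, and F1 hybrids between random
#' species pairs.
#'
#' @param n_species Number of species (>= 2).
#' @param markers Marker model table, see [default_markers()].
#' @param birth Yule birth rate for the species tree.
#' @param tree_depth Root-to-tip depth in expected substitutions per site at
#'   rate multiplier 1.
#' @param n_populations Populations (sites) sampled per species.
#' @param individuals_per_population Integer vector; each population draws
#'   its sample size uniformly from it (default `3:6`).
#' @param theta Per-site nucleotide diversity within a population at rate
#'   multiplier 1 (each marker realises `theta * rate`).
#' @param between_population_divergence Expected extra per-site divergence
#'   between populations of one species at rate 1.
#' @param n_hybrids Number of F1 hybrid individuals to emit.
#' @param hybrid_parent_rule How parent pairs are drawn: `"distinct"`
#'   (default) samples pairs whose members are diagnosably distinct — each
#'   parent's patristic distance to every non-parent species is at least
#'   `min_parent_divergence`, so the F1's heterozygous signature cannot be
#'   confused with a third species; `"random"` samples any species pair.
#' @param min_parent_divergence Patristic distance floor (expected
#'   substitutions per site at rate multiplier 1) for the `"distinct"` rule.
#' @param nuclear_marker Marker in which hybrids are heterozygous.
#' @param group_weights Sampling weights for specimen groups.
#' @param n_sites Size of the shared site pool populations are drawn from.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 24L,
                       markers = default_markers(),
                       birth = 1,
                       tree_depth = 0.35,
                       n_populations = 2L,
                       individuals_per_population = 3:6,
                       theta = 0.001,
                       between_population_divergence = 0.001,
                       n_hybrids = 2L,
                       hybrid_parent_rule = c("distinct", "random"),
                       min_parent_divergence = 0.05,
                       nuclear_marker = "ITS2",
                       group_weights = c(true_mangrove = 28, associate = 12,
                                         coastal = 32),
                       n_sites = 8L) {
  cfg <- list(n_species = as.integer(n_species), markers = as_tibble(markers),
              birth = birth, tree_depth = tree_depth,
              n_populations = as.integer(n_populations),
              individuals_per_population = as.integer(individuals_per_population),
              theta = theta,
              between_population_divergence = between_population_divergence,
              n_hybrids = as.integer(n_hybrids),
              hybrid_parent_rule = match.arg(hybrid_parent_rule),
              min_parent_divergence = min_parent_divergence,
              nuclear_marker = nuclear_marker,
              group_weights = group_weights, n_sites = as.integer(n_sites))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_species < 2L) abort("n_species must be >= 2")
  m <- cfg$markers
  if (any(m$recovery < 0 | m$recovery > 1)) {
    abort("recovery probabilities must be in [0, 1]")
  }
  if (any(m$rate <= 0) || any(m$kappa <= 0)) abort("rates must be > 0")
  if (any(m$gc < 0 | m$gc > 1)) abort("gc must be in [0, 1]")
  if (cfg$theta < 0 || cfg$between_population_divergence < 0) {
    abort("diversity parameters must be >= 0")
  }
  if (cfg$n_hybrids > 0L && cfg$n_species < 2L) {
    abort("hybrids require >= 2 species")
  }
  if (cfg$n_hybrids > 0L && !cfg$nuclear_marker %in% m$marker) {
    abort("nuclear_marker must be one of the configured markers")
  }
  if (cfg$n_populations > cfg$n_sites) {
    abort("n_populations cannot exceed n_sites")
  }
  invisible(cfg)
}

# one K2P substitution of an encoded base (1=A, 2=C, 3=G, 4=T):
# transition with probability kappa/(kappa+2), else one of two transversions
substitute_base <- function(b, kappa) {
  if (stats::runif(1) < kappa / (kappa + 2)) {
    c(3L, 4L, 1L, 2L)[b]  # A<->G, C<->T
  } else {
    targets <- if (b == 1L || b == 3L) c(2L, 4L) else c(1L, 3L)
    targets[sample.int(2L, 1L)]
  }
}

# evolve an encoded sequence along a branch of t expected substitutions/site
mutate_seq <- function(codes, t, kappa) {
  if (t <= 0) return(codes)
  k <- rpois(length(codes), t)
  for (i in which(k > 0L & !is.na(codes))) {
    b <- codes[i]
    for (j in seq_len(k[i])) b <- substitute_base(b, kappa)
    codes[i] <- b
  }
  codes
}

# evolve a root sequence down a phylo tree; returns a matrix of tip
# sequences (rows in tip.label order)
evolve_along_tree <- function(tree, root_codes, rate, kappa) {
  n_tip <- length(tree$tip.label)
  seqs <- vector("list", n_tip + tree$Nnode)
  root <- n_tip + 1L
  seqs[[root]] <- root_codes
  edges <- reorder(tree, "cladewise")$edge
  lens <- reorder(tree, "cladewise")$edge.length
  for (e in seq_len(nrow(edges))) {
    parent <- edges[e, 1L]; child <- edges[e, 2L]
    seqs[[child]] <- mutate_seq(seqs[[parent]], lens[e] * rate, kappa)
  }
  out <- do.call(rbind, seqs[seq_len(n_tip)])
  rownames(out) <- tree$tip.label
  out
}

# Kingman coalescent sample of n sequences around an ancestral sequence;
# mutation rate theta/2 per site per unit branch length, so E[pi] = theta
# and E[S] = a_{n-1} * L * theta
coalescent_sample <- function(ancestral, n, theta, kappa) {
  if (n == 1L) return(matrix(ancestral, nrow = 1L))
  tr <- ape::rcoal(n)
  evolve_along_tree(tr, ancestral, rate = theta / 2, kappa = kappa)
}

#' Simulate a multi-marker community barcode dataset with ground truth
#'
#' Generates a complete study-shaped dataset: (1) a Yule species tree;
#' (2) per-marker ancestral sequences evolved along it under a two-rate
#' (transition/transversion) substitution process with per-marker rate
#' multipliers; (3) per species and population, a population-private
#' divergence step followed by a Kingman-coalescent sample of individuals
#' with per-site diversity `theta * rate`, so between-population distances
#' stochastically exceed within-population ones; (4) shared gap columns
#' inserted as indel events on random clades for indel-rich markers;
#' (5) each individual's each marker dropped independently with one minus the
#' marker's recovery probability; (6) F1 hybrids carrying two-base IUPAC
#' codes at all parental diagnostic sites of the nuclear marker and their
#' designated mother's chloroplast sequences. Alignment holds by construction
#' — no realignment step exists or is needed.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed; a fixed seed makes the output
#'   byte-identical across runs.
#' @return List with elements `dataset` (a [barcode_dataset()]) and `truth`,
#'   the ground-truth manifest: `species_tree` (Newick), `hybrids` (tibble:
#'   `hybrid_id`, `parent1`, `parent2`, `mother`), `theta` (tibble of
#'   per-species/population/marker simulated diversity), and `config`.
#' @export
simulate_community <- function(cfg = sim_config(), seed = NULL) {
  validate_sim_config(cfg)
  run <- function() simulate_community_impl(cfg)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

simulate_community_impl <- function(cfg) {
  n_sp <- cfg$n_species
  tree <- ape::rphylo(n_sp, birth = cfg$birth, death = 0)
  tree$tip.label <- sprintf("Species_%02d", seq_len(n_sp))
  depth <- max(ape::node.depth.edgelength(tree)[seq_len(n_sp)])
  tree$edge.length <- tree$edge.length * cfg$tree_depth / depth

  groups <- sample(names(cfg$group_weights), n_sp, replace = TRUE,
                   prob = cfg$group_weights)
  site_pool <- sprintf("SITE_%02d", seq_len(cfg$n_sites))

  # sampling design: populations and individuals per species
  design <- lapply(seq_len(n_sp), function(s) {
    sites <- sample(site_pool, cfg$n_populations)
    lapply(sites, function(st) {
      n_ind <- if (length(cfg$individuals_per_population) == 1L) {
        cfg$individuals_per_population
      } else {
        sample(cfg$individuals_per_population, 1L)
      }
      list(site = st, n = n_ind)
    })
  })

  specimens <- list()
  counter <- 0L
  for (s in seq_len(n_sp)) {
    for (p in design[[s]]) {
      for (i in seq_len(p$n)) {
        counter <- counter + 1L
        specimens[[counter]] <- tibble(
          specimen_id = sprintf("SP%04d", counter),
          species = tree$tip.label[s], group = groups[s],
          site_id = p$site, population_id = p$site)
      }
    }
  }
  meta <- dplyr::bind_rows(specimens)

  # hybrid registry
  hybrids <- NULL
  if (cfg$n_hybrids > 0L) {
    all_pairs <- combn(tree$tip.label, 2L, simplify = FALSE)
    if (cfg$hybrid_parent_rule == "distinct") {
      # parents must be at least min_parent_divergence from each other and
      # from every species outside the pair, so F1 diagnosis is well-posed
      D <- stats::cophenetic(tree)
      sep <- vapply(all_pairs, function(pr) {
        others <- setdiff(tree$tip.label, pr)
        min(D[pr[1L], pr[2L]], D[pr[1L], others], D[pr[2L], others])
      }, numeric(1))
      eligible <- all_pairs[sep >= cfg$min_parent_divergence]
      if (length(eligible) == 0L) eligible <- all_pairs[which.max(sep)]
      picked <- eligible[sample.int(length(eligible), cfg$n_hybrids,
                                    replace = TRUE)]
    } else {
      picked <- sample(all_pairs, min(cfg$n_hybrids, length(all_pairs)))
    }
    hybrids <- purrr::map_dfr(seq_along(picked), function(i) {
      pr <- picked[[i]]
      tibble(hybrid_id = sprintf("HYB%02d", i),
             parent1 = pr[1L], parent2 = pr[2L],
             mother = sample(pr, 1L))
    })
    mother_site <- vapply(hybrids$mother, function(mo) {
      design[[match(mo, tree$tip.label)]][[1L]]$site
    }, character(1))
    meta <- dplyr::bind_rows(meta, tibble(
      specimen_id = hybrids$hybrid_id,
      species = paste(hybrids$parent1, "x", hybrids$parent2),
      group = "hybrid", site_id = mother_site,
      population_id = mother_site))
  }

  alignments <- list()
  theta_rows <- list()
  for (r in seq_len(nrow(cfg$markers))) {
    mk <- cfg$markers[r, ]
    L <- mk$length
    root <- sample.int(4L, L, replace = TRUE,
                       prob = c((1 - mk$gc) / 2, mk$gc / 2, mk$gc / 2,
                                (1 - mk$gc) / 2))
    tip_seqs <- evolve_along_tree(tree, root, mk$rate, mk$kappa)
    theta_m <- cfg$theta * mk$rate

    # gap masks per species from clade-shared indel events
    gap_mask <- matrix(FALSE, n_sp, L,
                       dimnames = list(tree$tip.label, NULL))
    if (mk$indel_events > 0L) {
      all_nodes <- setdiff(seq_len(n_sp + tree$Nnode), n_sp + 1L)
      for (ev in seq_len(mk$indel_events)) {
        node <- sample(all_nodes, 1L)
        affected <- if (node <= n_sp) node else
          intersect(unlist(ape::prop.part(tree)[node - n_sp]), seq_len(n_sp))
        len <- sample.int(8L, 1L)
        start <- sample.int(L - len + 1L, 1L)
        gap_mask[affected, start:(start + len - 1L)] <- TRUE
      }
    }

    seq_rows <- list()
    for (s in seq_len(n_sp)) {
      sp_name <- tree$tip.label[s]
      sp_meta <- meta[meta$species == sp_name, ]
      pops <- split(sp_meta$specimen_id, sp_meta$population_id)
      for (pop_id in names(pops)) {
        ids <- pops[[pop_id]]
        pop_anc <- mutate_seq(tip_seqs[s, ],
                              cfg$between_population_divergence / 2 * mk$rate,
                              mk$kappa)
        ind <- coalescent_sample(pop_anc, length(ids), theta_m, mk$kappa)
        rownames(ind) <- ids
        seq_rows[[paste(s, pop_id)]] <- ind
        theta_rows[[length(theta_rows) + 1L]] <- tibble(
          marker = mk$marker, species = sp_name, population_id = pop_id,
          n = length(ids), theta_sim = theta_m)
      }
    }
    codes <- do.call(rbind, seq_rows)

    chars <- matrix(c("A", "C", "G", "T")[codes], nrow = nrow(codes),
                    dimnames = list(rownames(codes), NULL))
    # apply species gap masks
    sp_of <- meta$species[match(rownames(chars), meta$specimen_id)]
    for (s in seq_len(n_sp)) {
      cols <- which(gap_mask[s, ])
      if (length(cols)) chars[sp_of == tree$tip.label[s], cols] <- "-"
    }

    # hybrids: IUPAC merge in the nuclear marker, maternal copy elsewhere
    if (!is.null(hybrids)) {
      hyb_chars <- t(vapply(seq_len(nrow(hybrids)), function(i) {
        p1 <- match(hybrids$parent1[i], tree$tip.label)
        p2 <- match(hybrids$parent2[i], tree$tip.label)
        mo <- match(hybrids$mother[i], tree$tip.label)
        if (mk$marker == cfg$nuclear_marker) {
          a <- c("A", "C", "G", "T")[tip_seqs[p1, ]]
          b <- c("A", "C", "G", "T")[tip_seqs[p2, ]]
          out <- ifelse(a == b, a,
                        unname(AMBIG2[paste0(pmin(a, b), pmax(a, b))]))
        } else {
          out <- c("A", "C", "G", "T")[tip_seqs[mo, ]]
        }
        out[gap_mask[mo, ]] <- "-"
        out
      }, character(L)))
      rownames(hyb_chars) <- hybrids$hybrid_id
      chars <- rbind(chars, hyb_chars)
    }

    # recovery: drop each individual's marker independently
    keep <- stats::runif(nrow(chars)) <= mk$recovery
    alignments[[mk$marker]] <- chars[keep, , drop = FALSE]
  }

  dataset <- barcode_dataset(meta, alignments)
  truth <- list(species_tree = ape::write.tree(tree),
                hybrids = hybrids %||% tibble(
                  hybrid_id = character(), parent1 = character(),
                  parent2 = character(), mother = character()),
                theta = dplyr::bind_rows(theta_rows),
                config = cfg)
  list(dataset = dataset, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
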