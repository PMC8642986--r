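test_that("NJ reproduces the 4-taxon additive worked example exactly", {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["C", "D"] <- d["D", "C"] <- 7
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  tr <- nj_tree(d)
  # additivity: path lengths reproduce the matrix
  expect_equal(stats::cophenetic(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
  # topology AB|CD with tip branches 1,2,3,4 and internal branch 1
  expect_equal(sort(tr$edge.length), c(1, 1, 2, 3, 4))
  tipn <- setNames(seq_len(4), tr$tip.label)
  tip_edge_len <- tr$edge.length[match(tipn[LETTERS[1:4]], tr$edge[, 2])]
  expect_equal(tip_edge_len, c(1, 2, 3, 4), ignore_attr = TRUE)
})

test_that("3 taxa resolve in closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_equal(stats::cophenetic(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
})

test_that("NJ recovers random additive matrices exactly", {
  skip_if_not_installed("phangorn")
  set.seed(21)
  for (i in 1:10) {
    ra <- random_additive(sample(5:10, 1))
    tr <- nj_tree(ra$d)
    expect_equal(phangorn::RF.dist(ape::unroot(ra$tree), tr), 0)
    expect_equal(stats::cophenetic(tr)[rownames(ra$d), colnames(ra$d)],
                 ra$d, tolerance = 1e-8)
  }
})

test_that("NJ refuses missing entries and tiny inputs", {
  d <- matrix(c(0, NA, 1, NA, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d), "missing or saturated")
  expect_error(nj_tree(d[1:2, 1:2]), ">= 3 taxa")
})

test_that("complete_distance drops the fewest offenders", {
  d <- matrix(stats::runif(25), 5, 5); d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:5), paste0("s", 1:5))
  d["s1", c("s2", "s3", "s4")] <- NA
  d[c("s2", "s3", "s4"), "s1"] <- NA
  mc <- complete_distance(as_k2p_dist(d))
  expect_setequal(mc$ids, c("s2", "s3", "s4", "s5"))
  expect_true(all(is.finite(mc$d)))
})

test_that("bootstrap supports diagnostic species columns near 100%", {
  # four species, each with 30 private diagnostic columns; alignment long
  # enough that interspecific divergence stays far from K2P saturation
  L <- 400L
  base <- strsplit(random_seq(L), "")[[1]]
  mk_species <- function(block) {
    s <- base
    s[block] <- chartr("ACGT", "GTAC", s[block])
    s
  }
  blocks <- split(1:120, rep(1:4, each = 30))
  seqs <- list()
  for (sp in 1:4) for (ind in 1:2) {
    s <- mk_species(blocks[[sp]])
    # private substitutions on the second individual avoid exact NJ ties
    # (identical sequences make the replicate trees' resolution arbitrary)
    if (ind == 2) {
      own <- 360 + (sp - 1) * 3 + 1:3
      s[own] <- chartr("ACGT", "GTAC", s[own])
    }
    seqs[[paste0("sp", sp, "_", ind)]] <- s
  }
  m <- do.call(rbind, seqs)
  meta <- meta_for(rownames(m), rep(paste0("Sp", 1:4), each = 2))
  tr <- bootstrap_support(m, n_reps = 100, seed = 5, min_overlap = 20L)
  rep_tr <- bootstrap_support(m, n_reps = 100, seed = 5, min_overlap = 20L)
  # determinism under a fixed seed
  expect_identical(ape::write.tree(tr), ape::write.tree(rep_tr))
  mono <- monophyly_assess(tr, meta, min_support = 50)
  expect_true(all(mono$is_monophyletic))
  expect_true(all(mono$support[mono$n_tips > 1] >= 99, na.rm = TRUE))
})

test_that("an all-identical alignment yields unresolved supports", {
  m <- do.call(rbind, rep(list(strsplit(random_seq(100), "")[[1]]), 5))
  rownames(m) <- paste0("s", 1:5)
  tr <- bootstrap_support(m, n_reps = 20, seed = 1, min_overlap = 10L)
  expect_true(all(tr$node.label %in% ""))
  expect_error(bootstrap_support(m, n_reps = 0), "n_reps")
})

test_that("monophyly follows the bipartition + support rule", {
  good <- ape::read.tree(text = "((a1:1,a2:1)100:1,(b1:1,b2:1)100:1):0;")
  meta <- meta_for(c("a1", "a2", "b1", "b2"), c("A", "A", "B", "B"))
  rep1 <- monophyly_assess(good, meta)
  expect_true(all(rep1$is_monophyletic))
  expect_equal(attr(rep1, "monophyly_pct"), 100)

  mixed <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1):0;")
  rep2 <- monophyly_assess(mixed, meta)
  expect_false(any(rep2$is_monophyletic))
  expect_equal(attr(rep2, "monophyly_pct"), 0)

  # a supported clade at 45% fails the strict > 50 rule
  weak <- ape::read.tree(text = "((a1:1,a2:1)45:1,(b1:1,b2:1)80:1):0;")
  rep3 <- monophyly_assess(weak, meta, min_support = 50)
  expect_false(rep3$is_monophyletic[rep3$species == "A"])
  expect_true(rep3$is_monophyletic[rep3$species == "B"])
})

test_that("monophyly verdicts are invariant to re-rooting", {
  set.seed(8)
  ra <- random_additive(8)
  tr <- ra$tree
  meta <- meta_for(tr$tip.label, sample(c("A", "A", "B", "B", "C", "C",
                                          "D", "D")))
  base_rep <- monophyly_assess(ape::unroot(tr), meta)
  for (i in 1:5) {
    node <- sample(setdiff(unique(tr$edge[, 2]),
                           seq_along(tr$tip.label)), 1)
    rerooted <- ape::root(tr, node = node, resolve.root = TRUE)
    rep_i <- monophyly_assess(rerooted, meta)
    expect_equal(base_rep$is_monophyletic, rep_i$is_monophyletic)
  }
})

test_that("singletons and taxon partitions count as monophyletic", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,c1:1):1):0;")
  meta <- meta_for(c("a1", "a2", "b1", "c1"), c("A", "A", "B", "C"))
  rep1 <- monophyly_assess(tr, meta)
  expect_true(all(rep1$is_monophyletic[rep1$species %in% c("B", "C")]))

  # partitioned scoring: a species alone in its partition is monophyletic
  meta$order <- c("Ord1", "Ord1", "Ord1", "Ord2")
  rep2 <- monophyly_assess(tr, meta, partition_by = "order")
  expect_true(rep2$is_monophyletic[rep2$species == "C"])
  expect_equal(nrow(rep2), 3L)
})

test_that("paraphyletic fixture fails monophyly", {
  f <- fixture_suite()$paraphyly
  m <- k2p_matrix(f$dataset$alignments$mk, min_overlap = 1L)
  tr <- nj_tree(m)
  rep <- monophyly_assess(tr, specimen_table(f$dataset))
  expect_equal(setNames(rep$is_monophyletic, rep$species),
               f$expected$monophyletic)
  expect_equal(attr(rep, "monophyly_pct"), f$expected$monophyly_pct,
               tolerance = 1e-10)
})

test_that("Newick round-trips and rejects malformed input", {
  tr <- ape::rtree(6)
  tr$node.label <- as.character(seq_len(tr$Nnode) * 10)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  tr2 <- read_newick(path)
  expect_equal(ape::write.tree(tr), ape::write.tree(tr2))
  expect_equal(tr2$node.label, tr$node.label)

  bad <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a,b),(c,d);", bad)
  expect_error(read_newick(bad), "malformed")
})
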