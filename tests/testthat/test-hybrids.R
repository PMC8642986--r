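test_that("diagnostic sites follow the IUPAC heterozygote definition", {
  # parents A vs G, hybrid R: heterozygous match
  ds <- diagnostic_sites(c("A", "C", "T"), c("G", "C", "T"),
                         c("R", "C", "T"))
  expect_equal(nrow(ds), 1L)
  expect_equal(ds$column, 1L)
  expect_true(ds$is_heterozygous_match)

  # parents identical at a column: not diagnostic
  ds2 <- diagnostic_sites(c("A", "A"), c("A", "A"), c("R", "A"))
  expect_equal(nrow(ds2), 0L)

  # every two-base code
  p1 <- c("A", "C", "A", "G", "A", "C")
  p2 <- c("G", "T", "C", "T", "T", "G")
  hyb <- c("R", "Y", "M", "K", "W", "S")
  ds3 <- diagnostic_sites(p1, p2, hyb)
  expect_true(all(ds3$is_heterozygous_match))
  # the wrong code does not match
  ds4 <- diagnostic_sites(p1, p2, c("Y", "R", "K", "M", "S", "W"))
  expect_false(any(ds4$is_heterozygous_match))

  expect_error(diagnostic_sites(c("A", "C"), c("G",  "C", "T"), c("R", "C")),
               "unequal")
})

test_that("a hand-built 30-bp toy counts 5 diagnostic and 4 heterozygous", {
  p1 <- rep("A", 30)
  p2 <- rep("A", 30)
  p2[c(3, 9, 15, 21, 27)] <- "G"          # 5 diagnostic columns
  hyb <- rep("A", 30)
  hyb[c(3, 9, 15, 21)] <- "R"             # heterozygous at 4 of them
  ds <- diagnostic_sites(p1, p2, hyb)
  expect_equal(nrow(ds), 5L)
  expect_equal(sum(ds$is_heterozygous_match), 4L)
})

test_that("parent-pair inference recovers the fixture trio and is symmetric", {
  f <- fixture_suite()$hybrid_trio
  d <- f$dataset
  call <- infer_parent_pair(alignment(d, "nuc"), specimen_table(d), "H1")
  expect_equal(call$call, "called")
  expect_setequal(c(call$parent1, call$parent2), f$expected$parent_pair)
  expect_equal(call$n_diagnostic, f$expected$n_diagnostic)
  expect_equal(call$n_heterozygous, f$expected$n_heterozygous)

  # symmetry in candidate order
  call2 <- infer_parent_pair(alignment(d, "nuc"), specimen_table(d), "H1",
                             candidates = c("Sp_P2", "Sp_P1", "Sp_P3"))
  expect_setequal(c(call2$parent1, call2$parent2),
                  c(call$parent1, call$parent2))

  # a non-hybrid individual yields no call
  none <- infer_parent_pair(alignment(d, "nuc"), specimen_table(d), "P3a")
  expect_equal(none$call, "no_call")
})

test_that("tied parent pairs are reported unresolved", {
  # two candidate pairs with identical heterozygous fractions by symmetry
  b <- rep("A", 30)
  x <- b; x[1:6] <- "G"
  y <- b; y[7:12] <- "G"
  hyb <- b; hyb[c(1:6, 7:12)] <- "R"
  m <- rbind(X1 = x, X2 = x, Y1 = y, Y2 = y, B1 = b, B2 = b, H = hyb)
  meta <- dplyr::bind_rows(
    meta_for(c("X1", "X2", "Y1", "Y2", "B1", "B2"),
             rep(c("Sp_X", "Sp_Y", "Sp_B"), each = 2)),
    dplyr::mutate(meta_for("H", "Sp_X x Sp_B"), group = "hybrid"))
  # H is heterozygous at every X/B diagnostic column (1:6) and every Y/B
  # diagnostic column (7:12): pairs (X,B) and (Y,B) tie at fraction 1
  call <- infer_parent_pair(m, meta, "H")
  expect_equal(call$call, "unresolved")
})

test_that("maternal assignment uses chloroplast proximity with a margin", {
  f <- fixture_suite()$hybrid_trio
  d <- f$dataset
  mat <- maternal_parent(d, "H1", "Sp_P1", "Sp_P2", "cp")
  expect_equal(mat$maternal_parent, f$expected$mother)
  expect_equal(mat$mismatches_parent1, 0L)
  expect_equal(mat$mismatches_parent2, 4L)

  # equidistant parents are unresolved: hybrid cp halfway between
  b <- rep("A", 40)
  p1 <- b; p1[1:2] <- "G"
  p2 <- b; p2[3:4] <- "G"
  hy <- b; hy[c(1, 3)] <- "G"   # 1 mismatch to each parent
  m <- rbind(P1a = p1, P1b = p1, P2a = p2, P2b = p2, H = hy)
  meta <- dplyr::bind_rows(
    meta_for(c("P1a", "P1b", "P2a", "P2b"),
             rep(c("Sp_1", "Sp_2"), each = 2)),
    dplyr::mutate(meta_for("H", "Sp_1 x Sp_2"), group = "hybrid"))
  dd <- barcode_dataset(meta, list(cp = m))
  mat2 <- maternal_parent(dd, "H", "Sp_1", "Sp_2", "cp")
  expect_true(is.na(mat2$maternal_parent))
})

test_that("the full hybrid report joins parent pair and matriline", {
  f <- fixture_suite()$hybrid_trio
  rep <- hybrid_report(f$dataset, nuclear = "nuc", chloroplast = "cp")
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$call, "called")
  expect_equal(rep$maternal_parent, f$expected$mother)
})

test_that("haplotype collapsing counts SNVs, indels and haplotypes", {
  f <- fixture_suite()$subspecies
  d <- f$dataset
  ids <- specimen_table(d)$specimen_id
  hap <- haplotype_collapse(d, ids, markers = c("m1", "m2"))
  expect_equal(hap$n_snv, f$expected$n_snv)
  expect_equal(hap$n_indel, f$expected$n_indel)
  expect_equal(hap$n_haplotypes, f$expected$n_haplotypes)
  # group-concordant assignment
  expect_equal(hap$assignment$haplotype, f$expected$groups)

  # all identical: one haplotype
  m <- do.call(rbind, rep(list(rep("A", 20)), 4))
  rownames(m) <- paste0("s", 1:4)
  hap2 <- haplotype_collapse(m, rownames(m))
  expect_equal(hap2$n_haplotypes, 1L)
  expect_equal(hap2$n_snv, 0L)
  expect_equal(hap2$n_indel, 0L)
})

test_that("haplotype count is invariant to individual order and SNV column shuffles", {
  f <- fixture_suite()$subspecies
  d <- f$dataset
  ids <- specimen_table(d)$specimen_id
  base <- haplotype_collapse(d, ids, markers = c("m1", "m2"))
  perm_ids <- sample(ids)
  hap_perm <- haplotype_collapse(d, perm_ids, markers = c("m1", "m2"))
  expect_equal(hap_perm$n_haplotypes, base$n_haplotypes)

  # SNV-only alignment: column permutation cannot change the haplotype count
  m1 <- alignment(d, "m1")
  perm_cols <- sample(ncol(m1))
  h1 <- haplotype_collapse(m1, ids)
  h2 <- haplotype_collapse(m1[, perm_cols], ids)
  expect_equal(h1$n_haplotypes, h2$n_haplotypes)
})

test_that("simulated F1s are heterozygous at every diagnostic site of their parents", {
  cfg <- sim_config(n_species = 5,
                    markers = default_markers()[1:2, ] |>
                      dplyr::mutate(recovery = 1, indel_events = 0L),
                    n_populations = 1L, individuals_per_population = 3,
                    theta = 0, between_population_divergence = 0,
                    n_hybrids = 2L)
  sim <- simulate_community(cfg, seed = 23)
  d <- sim$dataset
  aln <- alignment(d, "ITS2")
  info <- specimen_table(d)
  for (i in seq_len(nrow(sim$truth$hybrids))) {
    h <- sim$truth$hybrids[i, ]
    p1_ids <- info$specimen_id[info$species == h$parent1]
    p2_ids <- info$specimen_id[info$species == h$parent2]
    ds <- diagnostic_sites(consensus_sequence(aln, p1_ids),
                           consensus_sequence(aln, p2_ids),
                           aln[h$hybrid_id, ])
    expect_gt(nrow(ds), 0L)
    expect_true(all(ds$is_heterozygous_match))
  }
})
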