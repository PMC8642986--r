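test_that("K2P distance matches its closed form on canonical cases", {
  a20 <- paste(rep("A", 20), collapse = "")
  expect_identical(k2p_distance(a20, a20), 0)
  # 2 transitions / 20 sites: P = 0.1, Q = 0
  b <- paste(c("G", "G", rep("A", 18)), collapse = "")
  expect_equal(k2p_distance(a20, b), 0.111572, tolerance = 1e-5)
  expect_equal(k2p_distance(a20, b), oracle_k2p(a20, b), tolerance = 1e-12)
  # 2 transitions + 2 transversions: P = Q = 0.1
  c_ <- paste(c("G", "G", "C", "C", rep("A", 16)), collapse = "")
  expect_equal(k2p_distance(a20, c_), 0.234123, tolerance = 1e-5)
  # saturation sentinel
  t20 <- paste(rep("T", 20), collapse = "")
  g20 <- paste(rep("G", 20), collapse = "")
  expect_identical(k2p_distance(t20, g20), Inf)
  # pairwise deletion and the overlap floor
  expect_true(is.na(k2p_distance("AC--", "AC--", min_overlap = 3)))
  expect_error(k2p_distance("ACG", "AC"), "unequal")
})

test_that("K2P agrees with an established implementation on random pairs", {
  skip_if_not_installed("ape")
  set.seed(42)
  for (i in 1:25) {
    a <- random_seq(120)
    b <- random_seq(120)
    ref <- ape::dist.dna(ape::as.DNAbin(rbind(
      a = strsplit(tolower(a), "")[[1]],
      b = strsplit(tolower(b), "")[[1]])), model = "K80",
      pairwise.deletion = TRUE)
    mine <- k2p_distance(a, b)
    if (is.finite(mine)) expect_equal(mine, as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("the matrix path equals independent per-pair recomputation", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    L <- sample(c(60L, 90L), 1)
    seqs <- vapply(seq_len(n), function(i) random_seq(L), "")
    # sprinkle gaps and ambiguity codes
    m <- seq_to_mat <- do.call(rbind, strsplit(seqs, ""))
    m[sample(length(m), L)] <- sample(c("-", "N", "R", "Y"), L, replace = TRUE)
    rownames(m) <- paste0("s", seq_len(n))
    dm <- k2p_matrix(m, min_overlap = 10L)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      expect_identical(dm$d[i, j], dm$d[j, i])
      expect_equal(dm$d[i, j], k2p_distance(m[i, ], m[j, ], min_overlap = 10L),
                   tolerance = 1e-12)
    }
    expect_true(all(diag(dm$d) == 0))
  }
})

test_that("K2P dominates the p-distance (Jensen ordering)", {
  set.seed(99)
  for (i in 1:30) {
    a <- random_seq(150)
    b <- random_seq(150)
    va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
    p <- mean(va != vb)
    d <- k2p_distance(a, b)
    expect_gte(d, p - 1e-12)
  }
})

test_that("a pair overlapping only at gap columns is missing", {
  m <- rbind(s1 = c("A", "C", "-", "-"),
             s2 = c("-", "-", "G", "T"),
             s3 = c("A", "C", "G", "T"))
  dm <- k2p_matrix(m, min_overlap = 1L)
  expect_true(is.na(dm$d["s1", "s2"]))
  expect_false(is.na(dm$d["s1", "s3"]))
})

test_that("distance partition matches combinatorial enumeration", {
  # 2 species x 2 individuals: 2 intra pairs, 4 inter pairs
  d <- matrix(stats::runif(16, 0.01, 0.2), 4, 4)
  d <- (d + t(d)) / 2; diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  sp <- c("A", "A", "B", "B")
  parts <- partition_distances(as_k2p_dist(d), meta_for(rownames(d), sp))
  expect_equal(sum(parts$class == "intraspecific"), 2L)
  expect_equal(sum(parts$class == "interspecific"), 4L)

  # all conspecific: no inter pairs
  parts2 <- partition_distances(as_k2p_dist(d),
                                meta_for(rownames(d), rep("A", 4)))
  expect_equal(sum(parts2$class == "interspecific"), 0L)

  # random labels vs brute force
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    dd <- matrix(stats::runif(n * n), n, n); dd <- (dd + t(dd)) / 2
    diag(dd) <- 0
    dimnames(dd) <- list(paste0("x", 1:n), paste0("x", 1:n))
    labels <- sample(LETTERS[1:3], n, replace = TRUE)
    parts <- partition_distances(as_k2p_dist(dd),
                                 meta_for(rownames(dd), labels))
    n_intra <- sum(vapply(1:(n - 1), function(i) {
      sum(labels[(i + 1):n] == labels[i])
    }, numeric(1)))
    expect_equal(sum(parts$class == "intraspecific"), n_intra)
    expect_equal(nrow(parts), choose(n, 2))
  }
})

test_that("marker summary matches hand counts on a toy alignment", {
  #          1    2    3    4    5    6
  m <- rbind(s1 = c("A", "C", "G", "T", "A", "-"),
             s2 = c("A", "C", "G", "C", "A", "C"),
             s3 = c("A", "T", "G", "C", "-", "C"))
  meta <- meta_for(c("s1", "s2", "s3"), c("X", "X", "Y"))
  s <- summarize_marker(m, meta, marker = "toy", min_overlap = 1L)
  expect_equal(s$alignment_length, 6L)
  expect_equal(s$variable_sites, 2L)   # columns 2 and 4
  expect_equal(s$gap_columns, 2L)      # columns 5 and 6
  # bases: col1 AAA, col2 CCT, col3 GGG, col4 TCC, col5 AA, col6 CC
  # G+C = 3 + 3 + 2 + 2 = ... count: G:3 (col3), C: col2 CC=2, col4 CC=2,
  # col6 CC=2, T: col2 1, col4 1; A: col1 3, col5 2
  # GC = 3 + 6 = 9 of 16 unambiguous bases
  expect_equal(s$gc_content, 100 * 9 / 16)
  expect_equal(s$n_species_valid, 1L)  # only X has >= 2 sequences
  expect_equal(s$pct_valid_conspecific, 100 * 2 / 3)
})

test_that("identical sequences give zero variability", {
  m <- do.call(rbind, rep(list(strsplit("ACGTACGT", "")[[1]]), 3))
  rownames(m) <- paste0("s", 1:3)
  s <- summarize_marker(m, meta_for(rownames(m), rep("A", 3)),
                        min_overlap = 1L)
  expect_equal(s$variable_sites, 0L)
  expect_equal(s$max_intraspecific, 0)
  dm <- k2p_matrix(m, min_overlap = 1L)
  expect_true(all(dm$d == 0))
})

test_that("barcode gap verdicts follow the strict 1:1 rule", {
  # two clean species: both gapped
  d <- matrix(0.2, 4, 4)
  d[1, 2] <- d[2, 1] <- 0.01
  d[3, 4] <- d[4, 3] <- 0.01
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  g <- barcode_gap(as_k2p_dist(d), meta_for(rownames(d), c("A", "A", "B", "B")))
  expect_true(all(g$has_gap))
  expect_equal(attr(g, "percent_with_gap"), 100)

  # equality is not a gap
  d2 <- d
  d2[1, 3] <- d2[3, 1] <- 0.01   # min inter for A equals max intra
  g2 <- barcode_gap(as_k2p_dist(d2),
                    meta_for(rownames(d2), c("A", "A", "B", "B")))
  expect_false(g2$has_gap[g2$species == "A"])

  # single species is an error
  expect_error(barcode_gap(as_k2p_dist(d), meta_for(rownames(d), rep("A", 4))),
               ">= 2 species")
})

test_that("gap percentage is invariant to reordering and label renaming", {
  set.seed(5)
  n <- 9
  d <- matrix(stats::runif(n * n, 0, 0.3), n, n); d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(paste0("s", 1:n), paste0("s", 1:n))
  sp <- c("A", "A", "A", "B", "B", "C", "C", "C", "C")
  g1 <- barcode_gap(as_k2p_dist(d), meta_for(rownames(d), sp))
  perm <- sample(n)
  dp <- d[perm, perm]
  g2 <- barcode_gap(as_k2p_dist(dp), meta_for(rownames(dp), sp[perm]))
  expect_equal(attr(g1, "percent_with_gap"), attr(g2, "percent_with_gap"))
  # renaming species preserves the percentage
  ren <- setNames(c("Zeta", "Eta", "Theta"), c("A", "B", "C"))
  g3 <- barcode_gap(as_k2p_dist(d), meta_for(rownames(d), unname(ren[sp])))
  expect_equal(attr(g1, "percent_with_gap"), attr(g3, "percent_with_gap"))
})

test_that("hand-built 3-species gap failure case scores 66.7%", {
  f <- fixture_suite()$gap_failure
  g <- barcode_gap(k2p_matrix(f$dataset$alignments$mk, min_overlap = 1L),
                   specimen_table(f$dataset))
  expect_equal(attr(g, "percent_with_gap"), f$expected$percent_with_gap)
  expect_equal(setNames(g$has_gap, g$species), f$expected$has_gap)
})

test_that("distance long-format TSV round-trips", {
  set.seed(2)
  m <- do.call(rbind, lapply(1:4, function(i) strsplit(random_seq(80), "")[[1]]))
  rownames(m) <- paste0("s", 1:4)
  dm <- k2p_matrix(m, min_overlap = 10L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distances(dm, path)
  dm2 <- read_distances(path)
  expect_equal(dm2$d[dm$ids, dm$ids], dm$d)
})
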