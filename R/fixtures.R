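# Deterministic hand-built fixture datasets with frozen expected verdicts.
# All sequences are variants of a repeating ACGT backbone; substitutions are
# transitions (A<->G, C<->T), so K2P distances are strictly monotone in the
# number of differing sites and every expected ordering below was checked by
# counting symmetric differences of the mutated-position sets by hand.

backbone <- function(L) {
  rep(c("A", "C", "G", "T"), length.out = L)
}

# apply transitions at 1-based positions
ts_at <- function(seq, positions) {
  map <- c(A = "G", G = "A", C = "T", T = "C")
  seq[positions] <- map[seq[positions]]
  seq
}

fixture_meta <- function(ids, species, group = "true_mangrove",
                         site = "SITE_01") {
  tibble(specimen_id = ids, species = species, group = group, site_id = site)
}

#' Library of hand-checked fixture datasets
#'
#' Small deterministic datasets, each engineered to exercise one behaviour of
#' the pipeline, shipped with its expected verdicts (hand-checked once and
#' frozen): a perfect barcode gap, an engineered gap failure, Best Match tie
#' cases, a paraphyletic species, an F1 hybrid trio, subspecies haplotypes,
#' and a missing-marker pattern for concatenation.
#'
#' @return Named list; each element is a list with `dataset` (a
#'   [barcode_dataset()]) and `expected` (a list of frozen expectations).
#' @export
fixture_suite <- function() {
  list(
    perfect_gap = fixture_perfect_gap(),
    gap_failure = fixture_gap_failure(),
    bm_ties = fixture_bm_ties(),
    paraphyly = fixture_paraphyly(),
    hybrid_trio = fixture_hybrid_trio(),
    subspecies = fixture_subspecies(),
    missing_marker = fixture_missing_marker()
  )
}

fixture_perfect_gap <- function() {
  b <- backbone(60)
  seqs <- rbind(
    A1 = b,
    A2 = ts_at(b, 1),
    B1 = ts_at(b, 11:22),
    B2 = ts_at(b, c(11:22, 2)),
    C1 = ts_at(b, 31:45),
    C2 = ts_at(b, c(31:45, 3)))
  meta <- fixture_meta(rownames(seqs),
                       rep(c("Sp_A", "Sp_B", "Sp_C"), each = 2))
  list(dataset = barcode_dataset(meta, list(mk = seqs)),
       expected = list(percent_with_gap = 100,
                       bm_verdicts = setNames(rep("success", 6),
                                              rownames(seqs)),
                       bm_success_pct = 100))
}

fixture_gap_failure <- function() {
  b <- backbone(60)
  seqs <- rbind(
    A1 = ts_at(b, 1:12),
    A2 = ts_at(b, c(1:12, 50)),
    B1 = b,
    B2 = ts_at(b, 51),
    C1 = ts_at(b, 21:22),
    C2 = ts_at(b, c(21:22, 31:40)))
  meta <- fixture_meta(rownames(seqs),
                       rep(c("Sp_A", "Sp_B", "Sp_C"), each = 2))
  # Sp_C: max intra = 10 sites (C1 vs C2) but C1 sits 2 sites from B1,
  # so its nearest heterospecific is closer than its farthest conspecific
  list(dataset = barcode_dataset(meta, list(mk = seqs)),
       expected = list(percent_with_gap = 66.7,
                       has_gap = c(Sp_A = TRUE, Sp_B = TRUE, Sp_C = FALSE),
                       bm_verdicts = c(A1 = "success", A2 = "success",
                                       B1 = "success", B2 = "success",
                                       C1 = "incorrect", C2 = "success")))
}

fixture_bm_ties <- function() {
  b <- backbone(100)
  seqs <- rbind(
    A1 = ts_at(b, c(1, 2)),
    A2 = ts_at(b, c(1, 3)),
    B1 = ts_at(b, c(1, 4)),
    B2 = ts_at(b, c(1, 4, 5, 6)),
    E1 = ts_at(b, c(2, 4)),
    E2 = ts_at(b, c(2, 4, 31, 32, 33)))
  meta <- fixture_meta(rownames(seqs),
                       rep(c("Sp_A", "Sp_B", "Sp_E"), each = 2))
  # symmetric-difference counts give: A1/A2/B1 tie at 2 sites with mixed
  # species (ambiguous); B2 unique nearest B1 (success); E1 ties A1 and B1
  # at 2 sites, both heterospecific (incorrect); E2 nearest E1 at 3 sites
  list(dataset = barcode_dataset(meta, list(mk = seqs)),
       expected = list(
         bm_verdicts = c(A1 = "ambiguous", A2 = "ambiguous",
                         B1 = "ambiguous", B2 = "success",
                         E1 = "incorrect", E2 = "success"),
         # K2P for 2 transitions over 100 sites is ~0.0204, so a 0.015
         # ceiling strands every query
         strict_threshold = 0.015,
         bcm_verdicts_strict = setNames(rep("unidentified", 6),
                                        rownames(seqs))))
}

fixture_paraphyly <- function() {
  b <- backbone(120)
  seqs <- rbind(
    p1 = ts_at(b, 1:10),
    q1 = ts_at(b, c(1:10, 21)),
    p2 = ts_at(b, 41:50),
    q2 = ts_at(b, c(41:50, 61)),
    r1 = ts_at(b, 81:95),
    r2 = ts_at(b, c(81:95, 99)))
  meta <- fixture_meta(rownames(seqs),
                       c("Sp_P", "Sp_Q", "Sp_P", "Sp_Q", "Sp_R", "Sp_R"))
  # p1 pairs with q1 and p2 with q2, so Sp_P and Sp_Q are interleaved
  list(dataset = barcode_dataset(meta, list(mk = seqs)),
       expected = list(monophyletic = c(Sp_P = FALSE, Sp_Q = FALSE,
                                        Sp_R = TRUE),
                       monophyly_pct = 100 / 3))
}

fixture_hybrid_trio <- function() {
  b <- backbone(60)
  nuc <- rbind(
    P1a = b, P1b = b,
    P2a = ts_at(b, c(5, 15, 25, 35, 45, 55)),
    P2b = ts_at(b, c(5, 15, 25, 35, 45, 55)),
    P3a = ts_at(b, c(7, 17, 27, 37, 47, 57)),
    P3b = ts_at(b, c(7, 17, 27, 37, 47, 57)),
    H1 = replace(b, c(5, 15, 25, 35, 45, 55), "R"))
  cp <- rbind(
    P1a = b, P1b = b,
    P2a = ts_at(b, c(2, 12, 22, 32)),
    P2b = ts_at(b, c(2, 12, 22, 32)),
    P3a = ts_at(b, c(8, 18, 28, 38)),
    P3b = ts_at(b, c(8, 18, 28, 38)),
    H1 = b)  # maternal copy of Sp_P1
  meta <- dplyr::bind_rows(
    fixture_meta(c("P1a", "P1b", "P2a", "P2b", "P3a", "P3b"),
                 rep(c("Sp_P1", "Sp_P2", "Sp_P3"), each = 2)),
    fixture_meta("H1", "Sp_P1 x Sp_P2", group = "hybrid"))
  # backbone positions 5,15,... alternate A and G, so the hybrid's R code
  # is the exact two-base IUPAC code of the parental pair at all six
  # diagnostic columns
  list(dataset = barcode_dataset(meta, list(nuc = nuc, cp = cp)),
       expected = list(parent_pair = c("Sp_P1", "Sp_P2"),
                       n_diagnostic = 6L, n_heterozygous = 6L,
                       mother = "Sp_P1"))
}

fixture_subspecies <- function() {
  b1 <- backbone(40)
  b2 <- backbone(40)
  g2_m2 <- ts_at(b2, 8)
  g2_m2[20:23] <- "-"
  m1 <- rbind(
    g1a = b1, g1b = b1,
    g2a = ts_at(b1, 5), g2b = ts_at(b1, 5),
    g3a = ts_at(b1, 15), g3b = ts_at(b1, 15))
  m2 <- rbind(
    g1a = b2, g1b = b2,
    g2a = g2_m2, g2b = g2_m2,
    g3a = b2, g3b = b2)
  meta <- fixture_meta(rownames(m1),
                       rep(c("Sub_one", "Sub_two", "Sub_three"), each = 2))
  # variants: m1 SNVs at 5 and 15; m2 SNV at 8 and one 4-column indel run
  list(dataset = barcode_dataset(meta, list(m1 = m1, m2 = m2)),
       expected = list(n_snv = 3L, n_indel = 1L, n_haplotypes = 3L,
                       groups = rep(1:3, each = 2)))
}

fixture_missing_marker <- function() {
  b <- backbone(30)
  x <- rbind(s1 = b, s2 = ts_at(b, 1), s3 = ts_at(b, 2))
  y <- rbind(s1 = backbone(20), s2 = ts_at(backbone(20), 3))
  meta <- fixture_meta(c("s1", "s2", "s3"),
                       c("Sp_A", "Sp_A", "Sp_B"))
  list(dataset = barcode_dataset(meta, list(X = x, Y = y)),
       expected = list(retained = c("s1", "s2"), dropped = "s3",
                       concat_length = 50L))
}
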