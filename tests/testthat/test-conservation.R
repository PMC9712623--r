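mk_cons_matrix <- function(rows, ref) {
  ref_alignment("cons", ref,
                matrix(unlist(strsplit(rows, "")), length(rows), nchar(ref),
                       byrow = TRUE,
                       dimnames = list(paste0("e", seq_along(rows)), NULL)))
}

test_that("window conservation handles identity, exclusion, and Bonferroni", {
  set.seed(2)
  ref <- rand_dna(40)
  # all elements identical to consensus: zero variance -> p = 1 everywhere
  m_id <- mk_cons_matrix(rep(ref, 6), ref)
  w_id <- window_conservation(m_id)
  expect_true(all(w_id$mean_conservation == 1))
  expect_true(all(w_id$p_raw == 1))
  expect_false(any(w_id$significant))

  # element with 5 gaps in the first window is excluded there
  gapped <- paste0("-----", substr(ref, 6, 40))
  m_g <- mk_cons_matrix(c(rep(ref, 5), gapped), ref)
  w_g <- window_conservation(m_g)
  expect_equal(w_g$n_elements[1], 5L)  # gapped element dropped in window 0
  expect_equal(w_g$n_elements[11], 6L) # fully clean window keeps all

  # Bonferroni multiplies by window count and caps at 1
  set.seed(9)
  rows <- vapply(1:8, function(i) mutate_sequence(ref, 0.05, 0.05), "")
  m_r <- mk_cons_matrix(rows, ref)
  w_r <- window_conservation(m_r)
  nwin <- nrow(w_r)
  expect_equal(w_r$p_bonferroni, pmin(w_r$p_raw * nwin, 1))

  expect_error(window_conservation(mk_cons_matrix("ACGT", "ACGT")),
               "shorter")
})

test_that("shared conserved windows intersect across species", {
  mk <- function(starts, sig) {
    data.frame(window_start = starts, significant = starts %in% sig)
  }
  per <- list(s1 = mk(0:9, c(2, 3, 7)), s2 = mk(0:9, c(3, 7, 8)),
              s3 = mk(0:9, c(3, 5, 7)))
  sh <- shared_conserved_windows(per)
  expect_equal(sh$windows, c(3, 7))
  # window significant in only some species is excluded
  expect_false(2 %in% sh$windows)
  # merged intervals: windows 3 and 7 of width 10 merge into [3, 17)
  expect_equal(sh$intervals, data.frame(start = 3L, end = 17L))
  expect_length(shared_conserved_windows(list(s1 = mk(0:5, integer())))$windows,
                0)

  # motif fully inside a shared window region is reported
  consensus <- paste0(strrep("A", 3), "GCTGAGTCATG", strrep("A", 26))
  m <- motif_from_consensus("JUN", "GCTGAGTCATG", soft = c(1, 11))
  per2 <- list(s1 = mk(0:30, 0:20), s2 = mk(0:30, 0:20))
  sh2 <- shared_conserved_windows(per2, consensus = consensus,
                                  motifs = list(JUN = m))
  expect_true(any(sh2$motifs$motif == "JUN" & sh2$motifs$offset == 3))
})

test_that("exact retention expectation: zero rates and single-k-mer product", {
  # note: a k-mer scan p-value cannot go below 4^-k, so short test motifs
  # use an explicit p_threshold on that scale
  m <- motif_from_consensus("sharp", "ACGTT", conc = 0.97,
                            p_threshold = 1e-3)
  sub0 <- substitution_model("none", 0, 0)
  expect_equal(expected_motif_conservation("ACGTT", m, sub0), 1.0)

  # singleton matching set (verified), stay 0.9 per site -> 0.9^5
  expect_equal(matching_kmers(m, both_strands = FALSE), "ACGTT")
  sub <- substitution_model("s", 0.0667, 1 - 0.9 - 0.0667)
  expect_equal(
    expected_motif_conservation("ACGTT", m, sub, both_strands = FALSE),
    0.9^5, tolerance = 1e-12)

  expect_error(expected_motif_conservation("ACG", m, sub0), "length")
  expect_error(substitution_model("bad", 0.7, 0.6), "exceed")
})

test_that("exact expectation equals exhaustive enumeration for k <= 6 PWMs", {
  set.seed(31)
  pwms <- c(
    lapply(4:6, function(k) motif_model(paste0("r", k), rand_pwm(k))),
    list(motif_from_consensus("c5", "TGACG", conc = 0.9),
         motif_from_consensus("c6soft", "TGACGT", soft = c(1, 6))))
  sub <- substitution_model("sp", 0.08, 0.04)
  for (m in pwms) {
    anc <- motif_consensus(m)
    for (bs in c(TRUE, FALSE)) {
      for (p in c(0.01, 0.05)) {
        expect_equal(
          expected_motif_conservation(anc, m, sub, p_threshold = p,
                                      both_strands = bs),
          oracle_expected_retention(anc, m, sub, both_strands = bs,
                                    p_threshold = p),
          tolerance = 1e-12, info = paste(m$name, bs, p))
      }
    }
  }
})

test_that("expectation is monotone non-increasing in both rates", {
  m <- motif_from_consensus("mono", "ACGTA", conc = 0.97,
                            p_threshold = 1e-3)
  grid <- seq(0, 0.2, by = 0.05)
  vals_ti <- vapply(grid, function(r) {
    expected_motif_conservation("ACGTA", m,
                                substitution_model("x", r, 0.05),
                                both_strands = FALSE)
  }, 0)
  vals_tv <- vapply(grid, function(r) {
    expected_motif_conservation("ACGTA", m,
                                substitution_model("x", 0.05, r),
                                both_strands = FALSE)
  }, 0)
  expect_true(all(diff(vals_ti) <= 1e-12))
  expect_true(all(diff(vals_tv) <= 1e-12))
})

test_that("simulated retention agrees with the exact expectation", {
  m <- motif_from_consensus("sim", "TGACTCA" , conc = 0.9)
  stopifnot(m$k == 7)
  sub <- substitution_model("sp", 0.06, 0.03)
  anc <- "TGACTCA"
  expP <- expected_motif_conservation(anc, m, sub)
  sims <- simulate_motif_conservation(rep(anc, 40), m, sub,
                                      n_sims = 1000, seed = 5)
  expect_equal(length(sims), 1000L)
  band <- 3 * sqrt(expP * (1 - expP) / 1000)
  expect_lt(abs(mean(sims) - expP), band)
  # determinism and zero-rate behaviour
  sims2 <- simulate_motif_conservation(rep(anc, 40), m, sub,
                                       n_sims = 1000, seed = 5)
  expect_identical(sims, sims2)
  sims0 <- simulate_motif_conservation(rep(anc, 10), m,
                                       substitution_model("z", 0, 0),
                                       n_sims = 10, seed = 1)
  expect_true(all(sims0 == 1))
  expect_error(simulate_motif_conservation(character(), m, sub), "empty")
})

test_that("observed retention excludes gapped elements", {
  m <- motif_from_consensus("obs", "ACGTA", conc = 0.97,
                            p_threshold = 1e-3)
  ref <- paste0("ACGTA", "GGGGG")
  rows <- c("ACGTAGGGGG",   # retains
            "ACGTTGGGGG",   # single mismatch: lost (singleton matching set)
            "AC-TAGGGGG",   # gap in span: excluded
            "ACGTAGG-GG")   # gap outside span: included, retains
  mat <- mk_cons_matrix(rows, ref)
  res <- observed_motif_conservation(mat, c(0, 5), m,
                                     both_strands = FALSE)
  expect_equal(res$n_elements, 3L)
  expect_equal(res$observed_fraction, 2 / 3)

  all_gap <- mk_cons_matrix(c("-----GGGGG", "--G--GGGGG"), ref)
  expect_error(observed_motif_conservation(all_gap, c(0, 5), m), "gapped")
  none <- mk_cons_matrix(rep("TTTTTGGGGG", 3), ref)
  expect_equal(
    observed_motif_conservation(none, c(0, 5), m,
                                both_strands = FALSE)$observed_fraction, 0)
})

test_that("proportion test matches closed-form z arithmetic", {
  r <- proportion_test(0.693, 0.448, 100)
  expect_equal(r$z, (0.693 - 0.448) / sqrt(0.448 * 0.552 / 100),
               tolerance = 1e-12)
  expect_equal(r$z, 4.9267, tolerance = 1e-4)
  expect_lt(r$p_value, 0.05)
  expect_equal(proportion_test(0.4, 0.4, 50)$z, 0)
  expect_equal(proportion_test(0.4, 0.4, 50)$p_value, 1)
  expect_error(proportion_test(0.5, 0.5, 0), "at least 1")
  expect_error(proportion_test(0.5, 1, 10), "strictly")
})
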