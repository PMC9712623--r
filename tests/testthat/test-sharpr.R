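test_that("ridge step inference closed forms hold", {
  # one tile covering all 5 steps, lambda = 1, score 6: x(1/5 + 1) = 6/5
  d <- tiling_design("el", 50, data.frame(offset = 0, score = 6),
                     tile_len = 50, step = 10)
  expect_equal(infer_step_activities(d, 1), rep(1, 5), tolerance = 1e-12)

  # tiles covering exactly one step each: step = M / (1 + lambda)
  d1 <- tiling_design("el", 50,
                      data.frame(offset = seq(0, 40, 10),
                                 score = c(3, -1, 0, 2, 5)),
                      tile_len = 10, step = 10)
  for (lam in c(0.5, 1, 50)) {
    expect_equal(infer_step_activities(d1, lam),
                 c(3, -1, 0, 2, 5) / (1 + lam), tolerance = 1e-12)
  }

  # all-zero scores give all-zero steps; linearity in the scores
  d0 <- tiling_design("el", 50, data.frame(offset = c(0, 10), score = 0),
                      tile_len = 30, step = 10)
  expect_equal(infer_step_activities(d0, 1), rep(0, 5))
  dA <- tiling_design("el", 50, data.frame(offset = c(0, 10),
                                           score = c(2, -1)),
                      tile_len = 30, step = 10)
  dB <- tiling_design("el", 50, data.frame(offset = c(0, 10),
                                           score = 3 * c(2, -1)),
                      tile_len = 30, step = 10)
  expect_equal(3 * infer_step_activities(dA, 1),
               infer_step_activities(dB, 1), tolerance = 1e-12)
})

test_that("step-value norm shrinks monotonically in lambda to zero", {
  set.seed(8)
  for (i in 1:50) {
    L <- sample(c(200, 310, 360), 1)
    offs <- seq(0, L - 160, by = 10)
    d <- tiling_design("el", L,
                       data.frame(offset = offs, score = rnorm(length(offs))),
                       tile_len = 160, step = 10)
    lams <- c(0.1, 1, 10, 100, 1e4)
    norms <- vapply(lams, function(l) {
      sqrt(sum(infer_step_activities(d, l)^2))
    }, 0)
    expect_true(all(diff(norms) < 1e-12))
    expect_lt(norms[length(norms)], 1e-2)
  }
})

test_that("noiseless tile scores are reconstructed faithfully", {
  set.seed(15)
  L <- 360
  offs <- seq(0, L - 160, by = 10)
  profile <- rnorm(L / 10)
  W <- matrix(0, length(offs), L / 10)
  for (i in seq_along(offs)) {
    W[i, (offs[i] / 10 + 1):(offs[i] / 10 + 16)] <- 1 / 16
  }
  M <- as.vector(W %*% profile)
  d <- tiling_design("el", L, data.frame(offset = offs, score = M))
  # in the light-penalty limit the fit reproduces scores in col(W)
  sv <- infer_step_activities(d, 0.001)
  expect_gt(cor(as.vector(W %*% sv), M), 0.99)
  # at lambda = 1 fitted scores still track the inputs, shrunken
  sv1 <- infer_step_activities(d, 1)
  expect_gt(cor(as.vector(W %*% sv1), M), 0.5)
  # and for one-step tiles reconstruction is exact up to uniform shrinkage
  d1 <- tiling_design("el", 50, data.frame(offset = seq(0, 40, 10),
                                           score = rnorm(5)),
                      tile_len = 10, step = 10)
  expect_equal(cor(infer_step_activities(d1, 1), d1$tiles$score), 1)
})

test_that("nucleotide track combines priors, normalises, and interpolates", {
  basal0 <- basal_background(list(0))
  # identical step vectors at both priors combine to either
  nt <- nucleotide_track(c(1, 1), c(1, 1), basal0, L = 20, s = 10)
  expect_equal(nt, rep(1, 20))
  # steps (0, 1): midpoint between centers 5 and 15 is 0.5
  nt2 <- nucleotide_track(c(0, 0), c(0, 2), basal0, L = 20, s = 10)
  expect_equal(nt2[10], 0.45)   # nucleotide center 9.5
  expect_equal(nt2[11], 0.55)
  expect_equal((nt2[10] + nt2[11]) / 2, 0.5)
  # constant extrapolation beyond terminal centers
  expect_equal(nt2[1:5], rep(0, 5))
  expect_equal(nt2[16:20], rep(1, 5))
  # basal mean subtraction makes basal tracks average zero
  bb <- basal_background(list(c(0.3, 0.5), c(0.4, 0.4)))
  expect_equal(bb$mean, 0.4)
  nt3 <- nucleotide_track(c(0.3, 0.5), c(0.3, 0.5), bb, L = 20, s = 10)
  expect_equal(mean(nt3), 0)
  expect_error(nucleotide_track(c(1, 2), c(1, 2, 3), basal0, 30), "equal")
})

test_that("track summary sums activity and calls 3-SD peaks", {
  basal <- structure(list(mean = 0, sd = 0.1, n = 100),
                     class = "basal_background")
  vals <- rep(0, 50)
  s0 <- summarize_track(vals, basal)
  expect_equal(s0$sharpr_sum, 0)
  expect_equal(nrow(s0$peaks), 0L)

  vals[21:30] <- c(0.2, 0.4, rep(0.5, 6), 0.4, 0.2)
  s1 <- summarize_track(vals, basal)
  expect_equal(s1$sharpr_sum, sum(vals))
  # values of 0.2 at the shoulders sit below the 0.3 threshold
  expect_equal(s1$peaks, data.frame(start = 21L, end = 29L))
  # threshold is strictly greater than peak_k * sd
  expect_equal(nrow(summarize_track(rep(0.3, 10), basal, peak_k = 3)$peaks),
               0L)
  expect_equal(nrow(summarize_track(rep(0.31, 10), basal, peak_k = 3)$peaks),
               1L)
  # sums are additive under concatenation
  s2 <- summarize_track(vals[1:25], basal)
  s3 <- summarize_track(vals[26:50], basal)
  expect_equal(s2$sharpr_sum + s3$sharpr_sum, s1$sharpr_sum)
})

test_that("planted high-activity regions are recovered as peaks", {
  recovered <- 0
  for (seed in 1:20) {
    set.seed(seed)
    L <- 360
    n_steps <- L / 10
    profile <- rep(0, n_steps)
    profile[15:20] <- 1  # planted active region, steps 15..20 (0-based 140..200)
    offs <- seq(0, L - 160, by = 10)
    W <- matrix(0, length(offs), n_steps)
    for (i in seq_along(offs)) {
      W[i, (offs[i] / 10 + 1):(offs[i] / 10 + 16)] <- 1 / 16
    }
    M <- as.vector(W %*% profile) + rnorm(length(offs), 0, 0.05)
    d <- tiling_design("el", L, data.frame(offset = offs, score = M))
    null_steps <- lapply(1:30, function(i) {
      dn <- tiling_design("n", L, data.frame(
        offset = offs, score = rnorm(length(offs), 0, 0.05)))
      (infer_step_activities(dn, 1) + infer_step_activities(dn, 50)) / 2
    })
    basal <- basal_background(null_steps)
    tr <- activity_track(d, basal)
    hit <- nrow(tr$peaks) > 0 &&
      any(tr$peaks$end > 140 & tr$peaks$start < 200)
    recovered <- recovered + hit
  }
  expect_gte(recovered, 18)
})

test_that("tiling designs are rebuilt from scored fragments", {
  frag <- data.frame(
    fragment_id = c("a_tile000", "a_tile010", "b_tile000", "basalish"),
    element_id = c("a", "a", "b", "x"),
    kind = c("tile", "tile", "tile", "motif_focus"),
    offset = c(0L, 10L, 0L, 0L),
    sequence = "", flagged = FALSE)
  design <- structure(list(fragments = frag, tile_len = 30, tile_step = 10),
                      class = "mpra_design")
  tab <- structure(data.frame(
    element_id = c("a_tile000", "a_tile010", "b_tile000"),
    E = c(1, 2, 3)), class = c("enrichment_table", "data.frame"))
  tds <- tiling_designs_from_scores(tab, design, c(a = 40L, b = 40L))
  expect_equal(names(tds), c("a", "b"))
  expect_equal(tds$a$tiles$score, c(1, 2))
  expect_equal(tds$b$L, 40L)
})
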