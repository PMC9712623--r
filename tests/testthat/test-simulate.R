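test_that("subfamily simulation is deterministic and respects zero rates", {
  p <- tiny_params()
  s1 <- simulate_subfamily(p, seed = 7)
  s2 <- simulate_subfamily(p, seed = 7)
  expect_identical(s1, s2)
  s3 <- simulate_subfamily(p, seed = 8)
  expect_false(identical(s1$sequences$bases, s3$sequences$bases))

  p0 <- tiny_params(trans_s_ti = 0, trans_s_tv = 0, indel_rate = 0)
  p0$species$branch_length <- c(0, 0)
  s0 <- simulate_subfamily(p0, seed = 1)
  root <- s0$sequences$bases[s0$sequences$role == "consensus"]
  non_ctrl <- s0$sequences$role != "control"
  expect_true(all(s0$sequences$bases[non_ctrl] == root))
})

test_that("simulated tree is valid newick with named internal nodes", {
  p <- tiny_params()
  sim <- simulate_subfamily(p, seed = 2)
  tr <- ape::read.tree(text = sim$truth$tree)
  expect_equal(ape::Ntip(tr), p$n_transposition_leaves)
  expect_true("root" %in% tr$node.label)
  # every tip has a sequence and per-species descendants
  expect_true(all(tr$tip.label %in% sim$sequences$id))
  for (sp in p$species$species) {
    expect_true(all(paste0(tr$tip.label, "_", sp) %in% sim$sequences$id))
  }
})

test_that("planted effects are exact with zero noise and recomputable by scanning", {
  p <- tiny_params(activity_noise_sd = 0)
  sim <- simulate_subfamily(p, seed = 3)
  truth <- sim$truth
  # presence recomputable from sequence (cross-module invariant)
  for (m in names(truth$motif_models)) {
    rescanned <- vapply(sim$sequences$bases, function(s) {
      nrow(scan_motif(s, truth$motif_models[[m]])) > 0
    }, TRUE, USE.NAMES = FALSE)
    expect_equal(unname(truth$motif_presence[, m]), rescanned)
  }
  # activity difference between carriers and non-carriers of one motif,
  # holding the other fixed, equals its planted effect exactly
  pres <- truth$motif_presence
  act <- truth$true_activity
  for (m in seq_along(p$planted_motifs)) {
    other <- pres[, -m, drop = FALSE]
    same_other <- rowSums(other) == ncol(other)  # other motifs all present
    with_m <- act[pres[, m] & same_other]
    without_m <- act[!pres[, m] & same_other]
    if (length(with_m) && length(without_m)) {
      expect_equal(mean(with_m) - mean(without_m),
                   p$planted_motifs[[m]]$effect, tolerance = 1e-12)
    }
  }
})

test_that("divergence from the root increases with speciation branch length", {
  lens <- c(0.005, 0.02, 0.06)
  div <- matrix(NA_real_, 100, 3)
  for (s in 1:100) {
    p <- simulation_params(
      root_length = 120, n_transposition_leaves = 2,
      species = data.frame(species = c("s1", "s2", "s3"),
                           branch_length = lens),
      indel_rate = 0, n_shuffled_controls = 0)
    sim <- simulate_subfamily(p, seed = s)
    seqs <- sim$sequences
    for (k in 1:3) {
      sp <- seqs[seqs$species %in% paste0("s", k), ]
      anc <- seqs$bases[match(sub("_s\\d$", "", sp$id), seqs$id)]
      div[s, k] <- mean(mapply(function(a, b) {
        mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      }, anc, sp$bases))
    }
  }
  rho <- cor(rep(lens, each = 100), as.vector(div), method = "spearman")
  expect_gt(rho, 0)
  # and mean divergence is ordered
  expect_true(all(diff(colMeans(div)) > 0))
})

test_that("library design tiles elements with a right-anchored final tile", {
  set.seed(21)
  refseq <- rand_dna(360)
  seqs <- c(e310 = rand_dna(310), e364 = rand_dna(364), e100 = rand_dna(100))
  des <- build_library_design(seqs, c(root = refseq),
                              tile_elements = names(seqs))
  t310 <- des$fragments[des$fragments$element_id == "e310" &
                          des$fragments$kind == "tile", ]
  expect_equal(t310$offset, seq(0L, 150L, by = 10L))
  expect_equal(nrow(t310), 16L)
  expect_equal(t310$sequence[16], substr(seqs[["e310"]], 151, 310))

  t364 <- des$fragments[des$fragments$element_id == "e364" &
                          des$fragments$kind == "tile", ]
  expect_equal(max(t364$offset), 204L)  # right-anchored final tile
  expect_equal(sort(t364$offset)[1:3], c(0L, 10L, 20L))

  t100 <- des$fragments[des$fragments$element_id == "e100" &
                          des$fragments$kind == "tile", ]
  expect_equal(nrow(t100), 1L)
  expect_true(t100$flagged)
  expect_equal(t100$sequence, unname(seqs["e100"]))
})

test_that("mutagenesis fragments write the fixed replacement strings", {
  p <- tiny_params(activity_noise_sd = 0, indel_rate = 0)
  sim <- simulate_subfamily(p, seed = 5)
  seqs <- setNames(sim$sequences$bases, sim$sequences$id)
  ref <- c(root = seqs[["root"]])
  defs <- default_motif_defs(sim$truth)
  pres <- sim$truth$motif_presence
  present_ids <- sim$sequences$id[sim$sequences$role == "present_day"]
  with_jun <- present_ids[pres[present_ids, "JUN"]][1]
  without_jun <- present_ids[!pres[present_ids, "JUN"]]
  mut <- data.frame(element_id = with_jun, motif = "JUN", mode = "loss")
  if (length(without_jun)) {
    mut <- rbind(mut, data.frame(element_id = without_jun[1], motif = "JUN",
                                 mode = "gain"))
  }
  des <- build_library_design(seqs, ref, mutagenesis = mut,
                              motif_defs = defs)
  loss <- des$fragments[grepl("JUN_loss", des$fragments$fragment_id), ]
  expect_equal(nrow(loss), 1L)
  expect_true(grepl("TCACCAATGGT", loss$sequence, fixed = TRUE))
  # loss fragment no longer carries the motif
  expect_equal(nrow(scan_motif(loss$sequence,
                               sim$truth$motif_models$JUN)), 0L)
  if (length(without_jun)) {
    gain <- des$fragments[grepl("JUN_gain", des$fragments$fragment_id), ]
    expect_true(grepl("GCTGAGTCATG", gain$sequence, fixed = TRUE))
    expect_gt(nrow(scan_motif(gain$sequence,
                              sim$truth$motif_models$JUN)), 0L)
  }
  expect_true(all(c("mutant_id", "native_id") %in% names(des$pairs)))
})

test_that("barcode counts follow the design and the stated marginals", {
  p <- tiny_params()
  sim <- simulate_subfamily(p, seed = 2)
  seqs <- setNames(sim$sequences$bases, sim$sequences$id)
  des <- build_library_design(seqs, c(root = seqs[["root"]]))
  cts <- simulate_mpra_counts(sim$truth, des, seed = 11)
  cts2 <- simulate_mpra_counts(sim$truth, des, seed = 11)
  expect_identical(cts, cts2)

  tab <- table(cts$element_id)
  expect_true(all(tab[setdiff(names(tab), "basal")] == 10))
  expect_equal(unname(tab["basal"]), 300L)
  expect_false(anyDuplicated(cts$barcode) > 0)

  # DNA total concentrates around n_barcodes * depth
  n <- nrow(cts)
  expected <- n * p$dna_mean_depth
  # NB variance: mu + mu^2/size per barcode
  sd_tot <- sqrt(n * (p$dna_mean_depth +
                        p$dna_mean_depth^2 / p$nb_dispersion))
  expect_lt(abs(sum(cts$dna) - expected), 3 * sd_tot)

  p_bad <- tiny_params(dna_mean_depth = 0)
  expect_error(simulate_mpra_counts(sim$truth, des, params = p_bad),
               "positive")
})

test_that("near-Poisson null counts give RNA/DNA ratios at the basal level", {
  p <- tiny_params(activity_noise_sd = 0, activity_baseline = 0,
                   nb_dispersion = 1e6)
  # strip planted effects so every fragment is null
  p$planted_motifs <- lapply(p$planted_motifs, function(m) {
    m$effect <- 0
    m
  })
  sim <- simulate_subfamily(p, seed = 4)
  seqs <- setNames(sim$sequences$bases, sim$sequences$id)
  des <- build_library_design(seqs, c(root = seqs[["root"]]))
  cts <- simulate_mpra_counts(sim$truth, des, seed = 9)
  el <- cts$element_id != "basal"
  ratio <- sum(cts$rna_1[el]) / sum(cts$dna[el])
  basal_ratio <- sum(cts$rna_1[!el]) / sum(cts$dna[!el])
  n <- sum(el) * p$dna_mean_depth
  se <- 3 / sqrt(n)  # generous Poisson-scale bound on the ratio of sums
  expect_lt(abs(ratio - basal_ratio), 3 * se)
})
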