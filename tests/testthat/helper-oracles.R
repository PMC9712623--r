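# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementations.

# Exhaustive global-alignment oracle: enumerate every alignment as a path
# of moves (M = aligned pair, X = ref base over gap, Y = gap over query
# base) and score each complete alignment by scanning its gap runs.
# Exponential; only for short sequences.
oracle_align_best <- function(ref, query, match = 1, mismatch = -1,
                              gap_open = -2, gap_ext = -0.5) {
  r <- strsplit(ref, "")[[1]]
  q <- strsplit(query, "")[[1]]
  score_alignment <- function(cols) {
    # cols: character vector of "M"/"X"/"Y"
    s <- 0
    i <- 0L
    j <- 0L
    runs <- rle(cols)
    for (t in seq_along(runs$values)) {
      v <- runs$values[t]
      len <- runs$lengths[t]
      if (v == "M") {
        for (u in seq_len(len)) {
          s <- s + if (r[i + u] == q[j + u]) match else mismatch
        }
        i <- i + len
        j <- j + len
      } else {
        s <- s + gap_open + (len - 1) * gap_ext
        if (v == "X") i <- i + len else j <- j + len
      }
    }
    s
  }
  best <- -Inf
  rec <- function(i, j, cols) {
    if (i == length(r) && j == length(q)) {
      sc <- score_alignment(cols)
      if (sc > best) best <<- sc
      return(invisible(NULL))
    }
    if (i < length(r) && j < length(q)) rec(i + 1L, j + 1L, c(cols, "M"))
    if (i < length(r)) rec(i + 1L, j, c(cols, "X"))
    if (j < length(q)) rec(i, j + 1L, c(cols, "Y"))
  }
  rec(0L, 0L, character())
  best
}

# Biostrings as an independently implemented affine-gap aligner.
# Its gap of length L costs gapOpening + L * gapExtension, so the
# open/(L-1)*ext convention maps to opening = -(open - ext), ext = -ext.
oracle_align_biostrings <- function(ref, query, match = 1, mismatch = -1,
                                    gap_open = -2, gap_ext = -0.5) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    ref, query, substitutionMatrix = mat,
    gapOpening = -(gap_open - gap_ext), gapExtension = -gap_ext,
    type = "global"))
}

# Two-sided Fisher p by direct binomial-coefficient summation.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  if (m + n2 == 0 || k == 0 || k == m + n2) return(1)
  support <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, support) + lchoose(n2, k - support) -
    lchoose(m + n2, k)
  p <- exp(logp)
  obs <- exp(lchoose(m, a) + lchoose(n2, k - a) - lchoose(m + n2, k))
  sum(p[p <= obs * (1 + 1e-7)])
}

# Exhaustive neutral motif-retention expectation: enumerate all 4^k
# k-mers, test each with scan_motif, and sum substitution-path
# probabilities for the matching ones.
oracle_expected_retention <- function(ancestral_kmer, motif, sub,
                                      both_strands = TRUE,
                                      p_threshold = motif$p_threshold) {
  k <- motif$k
  anc <- match(strsplit(ancestral_kmer, "")[[1]], c("A", "C", "G", "T"))
  st <- sub$s_transition
  sv <- sub$s_transversion
  P <- matrix(sv / 2, 4, 4)
  diag(P) <- 1 - st - sv
  P[1, 3] <- st; P[3, 1] <- st; P[2, 4] <- st; P[4, 2] <- st
  grid <- as.matrix(expand.grid(rep(list(1:4), k)))
  total <- 0
  for (i in seq_len(nrow(grid))) {
    km <- paste(c("A", "C", "G", "T")[grid[i, ]], collapse = "")
    if (nrow(scan_motif(km, motif, p_threshold = p_threshold,
                        both_strands = both_strands)) > 0) {
      total <- total + prod(P[cbind(anc, grid[i, ])])
    }
  }
  total
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A random softish PWM (rows renormalised random weights).
rand_pwm <- function(k, sharp = 2) {
  p <- matrix(runif(k * 4)^sharp, k, 4)
  p / rowSums(p)
}

# Small simulation params for fast tests.
tiny_params <- function(...) {
  simulation_params(
    n_transposition_leaves = 6,
    species = data.frame(species = c("spA", "spB"),
                         branch_length = c(0.01, 0.04)),
    n_shuffled_controls = 3, ...)
}
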