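#' Sliding-window conservation against the consensus
#'
#' For each window of `width` consensus positions (step `step`), each
#' element's conservation is its fraction of compared positions matching
#' the consensus; positions where either the element or the consensus has
#' a gap or degenerate base are excluded, and elements with `max_excluded`
#' or more excluded positions in a window are dropped for that window.
#' Each window is tested for increased conservation relative to the values
#' pooled over all windows (one-sided Welch t-test), with Bonferroni
#' correction over windows.
#'
#' @param matrix A `ref_alignment` whose reference is the consensus.
#' @param width,step Window geometry (defaults 10 and 1).
#' @param max_excluded Per-element exclusion rule: dropped from a window
#'   when excluded positions reach this count (default 5, half the
#'   window).
#' @param alpha Threshold on the Bonferroni-adjusted p (default 0.05).
#' @return `data.frame(window_start, n_elements, mean_conservation,
#'   t_statistic, p_raw, p_bonferroni, significant)`; `window_start` is
#'   0-based on the consensus. Windows with fewer than two contributing
#'   elements or a degenerate pooled variance report p = 1.
#' @export
window_conservation <- function(matrix, width = 10, step = 1,
                                max_excluded = 5, alpha = 0.05) {
  stopifnot(inherits(matrix, "ref_alignment"))
  L <- matrix$ref_length
  if (L < width) stop("consensus shorter than window width", call. = FALSE)
  mat <- matrix$mat
  refc <- strsplit(matrix$ref_seq, "")[[1]]
  refm <- matrix(refc, nrow(mat), ncol(mat), byrow = TRUE)
  comp <- (mat == "A" | mat == "C" | mat == "G" | mat == "T") &
    (refm == "A" | refm == "C" | refm == "G" | refm == "T")
  matchm <- comp & mat == refm
  # rolling window sums along columns
  roll <- function(X) {
    cs <- cbind(0, t(apply(X, 1L, cumsum)))
    starts <- seq.int(1L, L - width + 1L, by = step)
    cs[, starts + width, drop = FALSE] - cs[, starts, drop = FALSE]
  }
  n_comp <- roll(comp)
  n_match <- roll(matchm)
  excluded <- width - n_comp
  vals <- n_match / n_comp
  vals[excluded >= max_excluded] <- NA
  n_w <- colSums(!is.na(vals))
  m_w <- colMeans(vals, na.rm = TRUE)
  v_w <- apply(vals, 2L, var, na.rm = TRUE)
  allv <- vals[!is.na(vals)]
  m_all <- mean(allv)
  v_all <- var(allv)
  n_all <- length(allv)
  nwin <- ncol(vals)
  se2 <- v_w / n_w + v_all / n_all
  tstat <- (m_w - m_all) / sqrt(se2)
  df <- se2^2 / ((v_w / n_w)^2 / pmax(n_w - 1L, 1L) +
                   (v_all / n_all)^2 / (n_all - 1L))
  p_raw <- pt(tstat, df, lower.tail = FALSE)
  degenerate <- n_w < 2L | !is.finite(tstat) | !is.finite(df) | se2 == 0
  p_raw[degenerate] <- 1
  tstat[degenerate] <- NA
  p_bonf <- pmin(p_raw * nwin, 1)
  data.frame(window_start = seq.int(0L, L - width, by = step),
             n_elements = n_w, mean_conservation = m_w,
             t_statistic = tstat, p_raw = p_raw, p_bonferroni = p_bonf,
             significant = p_bonf < alpha, row.names = NULL)
}

#' Windows conserved in every species, with motifs they contain
#'
#' Intersects the significant window sets of per-species
#' [window_conservation()] results; optionally reports motifs whose scan
#' hits on the consensus fall fully inside the union of shared windows.
#'
#' @param per_species Named list of `window_conservation` results.
#' @param consensus Consensus sequence (required for motif reporting).
#' @param motifs Named list of `motif_model`s (optional).
#' @param width Window width used (default 10).
#' @return List with `windows` (shared significant window starts),
#'   `intervals` (merged 0-based half-open intervals they cover), and
#'   `motifs` (`data.frame(motif, offset, strand)` of fully contained
#'   hits, when motifs are given).
#' @export
shared_conserved_windows <- function(per_species, consensus = NULL,
                                     motifs = NULL, width = 10) {
  stopifnot(length(per_species) >= 1L)
  sets <- lapply(per_species, function(w) w$window_start[w$significant])
  shared <- Reduce(intersect, sets)
  shared <- sort(shared)
  intervals <- data.frame(start = integer(), end = integer())
  if (length(shared)) {
    ir <- IRanges::reduce(IRanges::IRanges(shared + 1L, shared + width))
    intervals <- data.frame(start = IRanges::start(ir) - 1L,
                            end = IRanges::end(ir))
  }
  hits <- NULL
  if (!is.null(motifs) && !is.null(consensus)) {
    rows <- list()
    for (m in names(motifs)) {
      h <- scan_motif(consensus, motifs[[m]])
      if (!nrow(h)) next
      k <- motifs[[m]]$k
      inside <- vapply(h$offset, function(o) {
        any(o >= intervals$start & o + k <= intervals$end)
      }, TRUE)
      if (any(inside)) {
        rows[[m]] <- data.frame(motif = m, offset = h$offset[inside],
                                strand = h$strand[inside],
                                stringsAsFactors = FALSE)
      }
    }
    hits <- if (length(rows)) do.call(rbind, rows) else
      data.frame(motif = character(), offset = integer(),
                 strand = character())
    rownames(hits) <- NULL
  }
  list(windows = shared, intervals = intervals, motifs = hits)
}

#' Exact neutral motif-retention probability
#'
#' Probability that a child of the ancestral k-mer, mutated one step under
#' the per-site transition/transversion model, still matches the motif:
#' the sum over the motif's matching k-mer set of the product of per-site
#' change probabilities (stay `1 - s_ti - s_tv`, transition `s_ti`, each
#' specific transversion `s_tv / 2`).
#'
#' @param ancestral_kmer Ancestral sequence of the motif region (length
#'   `motif$k`, A/C/G/T only).
#' @param motif A `motif_model`.
#' @param sub A `substitution_model`.
#' @param p_threshold,both_strands Matching rule (see
#'   [matching_kmers()]).
#' @return Expected retention probability in `[0, 1]`.
#' @export
expected_motif_conservation <- function(ancestral_kmer, motif, sub,
                                        p_threshold = motif$p_threshold,
                                        both_strands = TRUE) {
  check_alphabet(ancestral_kmer, "ancestral k-mer", allow_n = FALSE)
  if (nchar(ancestral_kmer) != motif$k) {
    stop("ancestral k-mer length must equal motif width", call. = FALSE)
  }
  P <- .substitution_matrix(sub)
  anc <- seq_to_ints(ancestral_kmer)
  kmers <- matching_kmers(motif, p_threshold, both_strands)
  if (!length(kmers)) return(0)
  sum(vapply(kmers, function(km) {
    child <- seq_to_ints(km)
    prod(P[cbind(anc, child)])
  }, 0))
}

#' Simulate neutral motif retention across elements
#'
#' Each simulation independently mutates every site of each element's
#' motif-region sequence under the substitution model and records the
#' fraction of elements whose mutated region still contains a motif hit
#' (same matching rule as [scan_motif()]).
#'
#' @param element_kmers Character vector of motif-region sequences
#'   (gap-free, one per element, each of length `motif$k`).
#' @param motif A `motif_model`.
#' @param sub A `substitution_model`.
#' @param n_sims Number of simulations (default 1000).
#' @param seed RNG seed.
#' @param p_threshold,both_strands Matching rule.
#' @return Numeric vector of length `n_sims`: retained fraction per
#'   simulation.
#' @export
simulate_motif_conservation <- function(element_kmers, motif, sub,
                                        n_sims = 1000, seed = 1L,
                                        p_threshold = motif$p_threshold,
                                        both_strands = TRUE) {
  if (!length(element_kmers)) stop("empty element set", call. = FALSE)
  k <- motif$k
  if (any(nchar(element_kmers) != k)) {
    stop("all motif regions must have length ", k, call. = FALSE)
  }
  for (s in element_kmers) check_alphabet(s, "motif region", allow_n = FALSE)
  set.seed(seed)
  thr <- .motif_threshold_int(motif, p_threshold)
  int_f <- motif$int_scores
  int_r <- motif$int_scores[k:1, 4:1, drop = FALSE]
  base0 <- do.call(rbind, lapply(element_kmers, seq_to_ints))
  n_el <- nrow(base0)
  partner <- c(3L, 4L, 1L, 2L)
  tv1 <- c(2L, 1L, 2L, 1L)
  tv2 <- c(4L, 3L, 4L, 3L)
  st <- sub$s_transition
  sv <- sub$s_transversion
  vapply(seq_len(n_sims), function(i) {
    u <- matrix(runif(n_el * k), n_el, k)
    pick <- matrix(runif(n_el * k) < 0.5, n_el, k)
    b <- base0
    ti_sel <- u < st
    tv_sel <- u >= st & u < st + sv
    b[ti_sel] <- partner[base0[ti_sel]]
    b[tv_sel & pick] <- tv1[base0[tv_sel & pick]]
    b[tv_sel & !pick] <- tv2[base0[tv_sel & !pick]]
    pos <- cbind(rep(seq_len(k), each = n_el), as.vector(b))
    sf <- rowSums(matrix(int_f[pos], n_el))
    kept <- sf >= thr
    if (both_strands) {
      sr <- rowSums(matrix(int_r[pos], n_el))
      kept <- kept | sr >= thr
    }
    mean(kept)
  }, 0)
}

#' Observed motif retention across aligned elements
#'
#' Fraction of elements whose bases projected onto the motif's reference
#' span still contain a motif hit. Elements with any gap in the span are
#' excluded from the denominator.
#'
#' @param matrix A `ref_alignment`.
#' @param span `c(start, end)` 0-based half-open motif span on the
#'   reference.
#' @param motif A `motif_model`.
#' @param p_threshold,both_strands Matching rule.
#' @return List with `observed_fraction`, `n_elements` (denominator), and
#'   `retained` (named logical over included elements).
#' @export
observed_motif_conservation <- function(matrix, span, motif,
                                        p_threshold = motif$p_threshold,
                                        both_strands = TRUE) {
  stopifnot(inherits(matrix, "ref_alignment"),
            span[1L] >= 0, span[2L] <= matrix$ref_length,
            span[2L] - span[1L] >= motif$k)
  cols <- (span[1L] + 1L):span[2L]
  sub <- matrix$mat[, cols, drop = FALSE]
  gapped <- rowSums(sub == "-") > 0L
  if (all(gapped)) stop("all elements gapped in the motif span",
                        call. = FALSE)
  sub <- sub[!gapped, , drop = FALSE]
  seqs <- apply(sub, 1L, paste, collapse = "")
  retained <- vapply(seqs, function(s) {
    nrow(scan_motif(s, motif, p_threshold, both_strands)) > 0L
  }, TRUE)
  list(observed_fraction = mean(retained), n_elements = length(retained),
       retained = retained)
}

#' One-sample test of proportions for observed vs expected retention
#'
#' Two-sided z-test `z = (obs - exp) / sqrt(exp (1 - exp) / n)`.
#'
#' @param observed_fraction Observed retention fraction.
#' @param expected_p Expected retention probability, strictly inside
#'   (0, 1).
#' @param n Number of elements (>= 1).
#' @return List with `z` and `p_value`.
#' @export
proportion_test <- function(observed_fraction, expected_p, n) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (expected_p <= 0 || expected_p >= 1) {
    stop("expected_p must be strictly between 0 and 1", call. = FALSE)
  }
  z <- (observed_fraction - expected_p) /
    sqrt(expected_p * (1 - expected_p) / n)
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}
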