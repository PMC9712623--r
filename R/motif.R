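#' Construct a position weight matrix motif model
#'
#' Builds the probability matrix, pseudocounted log-odds (log2 against the
#' background), and integer-scaled scores used for scanning. Score
#' thresholds corresponding to a scan p-value are derived by exact dynamic
#' programming over the score distribution under the background (see
#' [motif_score_threshold()]).
#'
#' @param name Motif name.
#' @param prob k x 4 matrix of base probabilities (columns A, C, G, T);
#'   each row must sum to 1 within 1e-9.
#' @param background Background base frequencies (default uniform 0.25).
#' @param pseudocount Added to probabilities (rows renormalised) before
#'   log-odds, avoiding -Inf for zero cells.
#' @param p_threshold Default scan p-value threshold.
#' @return Object of class `motif_model`.
#' @export
motif_model <- function(name, prob, background = rep(0.25, 4),
                        pseudocount = 1e-3, p_threshold = 1e-4) {
  prob <- as.matrix(prob)
  stopifnot(ncol(prob) == 4L, nrow(prob) >= 4L,
            all(abs(rowSums(prob) - 1) < 1e-9), all(prob >= 0),
            length(background) == 4L, all(background > 0))
  colnames(prob) <- DNA_BASES
  padj <- (prob + pseudocount) / (1 + 4 * pseudocount)
  log_odds <- log2(sweep(padj, 2L, background, "/"))
  int_scores <- round(log_odds * 1000)
  structure(list(name = name, k = nrow(prob), prob = prob,
                 background = background, pseudocount = pseudocount,
                 log_odds = log_odds, int_scores = int_scores,
                 p_threshold = p_threshold),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model '%s' (k = %d, consensus %s)\n",
              x$name, x$k, motif_consensus(x)))
  invisible(x)
}

#' Build a soft PWM from a consensus k-mer
#'
#' Each position concentrates `conc` probability on the consensus base and
#' spreads the rest uniformly; positions listed in `soft` get `soft_conc`
#' instead, mimicking the degenerate positions of real binding motifs.
#'
#' @param name Motif name.
#' @param kmer Consensus sequence over A/C/G/T.
#' @param conc Probability on the consensus base (default 0.85).
#' @param soft Integer positions to soften (default none).
#' @param soft_conc Consensus-base probability at soft positions.
#' @param ... Passed to [motif_model()].
#' @return A `motif_model`.
#' @export
motif_from_consensus <- function(name, kmer, conc = 0.85, soft = integer(),
                                 soft_conc = 0.55, ...) {
  check_alphabet(kmer, "consensus k-mer", allow_n = FALSE)
  ints <- seq_to_ints(kmer)
  k <- length(ints)
  prob <- matrix((1 - conc) / 3, k, 4)
  prob[cbind(seq_len(k), ints)] <- conc
  for (i in soft) {
    prob[i, ] <- (1 - soft_conc) / 3
    prob[i, ints[i]] <- soft_conc
  }
  motif_model(name, prob, ...)
}

#' Consensus (argmax) sequence of a motif
#' @param motif A `motif_model`.
#' @return Character scalar.
#' @export
motif_consensus <- function(motif) {
  paste(DNA_BASES[apply(motif$prob, 1L, which.max)], collapse = "")
}

#' Per-position information content of a motif
#'
#' IC at position i is `2 + sum_b p_ib log2 p_ib` bits, the information of
#' the position frequency matrix against a uniform background.
#'
#' @param motif A `motif_model`.
#' @return Numeric vector of length `motif$k`, in bits.
#' @export
motif_ic <- function(motif) {
  p <- motif$prob
  plogp <- ifelse(p > 0, p * log2(p), 0)
  2 + rowSums(plogp)
}

# Exact distribution of the integer window score under the background, as a
# list(scores, tail) with tail[i] = P(S >= scores[i]).
.motif_score_dist <- function(int_scores, background) {
  k <- nrow(int_scores)
  mins <- sum(apply(int_scores, 1L, min))
  maxs <- sum(apply(int_scores, 1L, max))
  width <- maxs - mins + 1L
  dist <- numeric(width)
  # probability vector indexed by (score - running minimum + 1)
  dist[1L] <- 1
  run_min <- 0L
  run_max <- 0L
  for (i in seq_len(k)) {
    row <- int_scores[i, ]
    new_min <- run_min + min(row)
    new_max <- run_max + max(row)
    newd <- numeric(new_max - new_min + 1L)
    for (b in 1:4) {
      sh <- row[b] - min(row)
      idx <- seq_len(run_max - run_min + 1L)
      newd[idx + sh] <- newd[idx + sh] + background[b] * dist[idx]
    }
    dist <- newd
    run_min <- new_min
    run_max <- new_max
  }
  scores <- seq.int(mins, maxs)
  list(scores = scores, prob = dist,
       tail = rev(cumsum(rev(dist))))
}

#' Score threshold for a motif at a given scan p-value
#'
#' Computes, by exact dynamic programming over the log-odds score
#' distribution under the background model, the smallest score `t` such
#' that `P(score >= t) <= p` for a random background window. Windows
#' scoring at or above `t` are reported by [scan_motif()].
#'
#' @param motif A `motif_model`.
#' @param p_threshold Scan p-value in (0, 1].
#' @return Threshold on the log2 odds score (numeric scalar; `Inf` when no
#'   achievable score is rare enough).
#' @export
motif_score_threshold <- function(motif, p_threshold = motif$p_threshold) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  .motif_threshold_int(motif, p_threshold) / 1000
}

.threshold_cache <- new.env(parent = emptyenv())

.motif_threshold_int <- function(motif, p_threshold) {
  key <- paste(c(motif$int_scores, motif$background, p_threshold),
               collapse = ",")
  hit <- .threshold_cache[[key]]
  if (!is.null(hit)) return(hit)
  d <- .motif_score_dist(motif$int_scores, motif$background)
  ok <- d$tail <= p_threshold + 1e-12
  thr <- if (!any(ok)) max(d$scores) + 1L else d$scores[which(ok)[1L]]
  .threshold_cache[[key]] <- thr
  thr
}

#' Scan a sequence for motif hits
#'
#' Scores every ungapped window of length `motif$k` against the motif
#' log-odds and reports windows at or above the threshold derived from
#' `p_threshold` (see [motif_score_threshold()]). Windows containing `N`
#' are disqualified. On the minus strand the reverse complement of the
#' window is scored; offsets always refer to the forward sequence, 0-based.
#'
#' @param seq Sequence string over A/C/G/T/N.
#' @param motif A `motif_model`.
#' @param p_threshold Scan p-value in (0, 1].
#' @param both_strands Scan the minus strand as well (default TRUE).
#' @return `data.frame` with columns `offset` (0-based), `strand`, `score`
#'   (log2 odds), sorted by offset. Zero rows when the sequence is shorter
#'   than the motif or nothing passes.
#' @export
scan_motif <- function(seq, motif, p_threshold = motif$p_threshold,
                       both_strands = TRUE) {
  stopifnot(inherits(motif, "motif_model"),
            p_threshold > 0, p_threshold <= 1)
  empty <- data.frame(offset = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  s <- seq_to_ints(seq)
  k <- motif$k
  nwin <- length(s) - k + 1L
  if (nwin < 1L) return(empty)
  thr <- .motif_threshold_int(motif, p_threshold)
  W <- matrix(0L, k, nwin)
  for (i in seq_len(k)) W[i, ] <- s[i:(i + nwin - 1L)]
  valid <- colSums(is.na(W)) == 0L
  Wx <- W
  Wx[is.na(Wx)] <- 1L
  score_with <- function(int_mat) {
    colSums(matrix(int_mat[cbind(rep(seq_len(k), nwin), as.vector(Wx))],
                   nrow = k))
  }
  fwd <- score_with(motif$int_scores)
  res <- list()
  hit <- valid & fwd >= thr
  if (any(hit)) {
    res[[1L]] <- data.frame(offset = which(hit) - 1L, strand = "+",
                            score = fwd[hit] / 1000, stringsAsFactors = FALSE)
  }
  if (both_strands) {
    rc_int <- motif$int_scores[k:1, 4:1, drop = FALSE]
    rev_sc <- score_with(rc_int)
    hit2 <- valid & rev_sc >= thr
    if (any(hit2)) {
      res[[length(res) + 1L]] <-
        data.frame(offset = which(hit2) - 1L, strand = "-",
                   score = rev_sc[hit2] / 1000, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out[order(out$offset, out$strand), , drop = FALSE]
}

#' Enumerate all k-mers matching a motif
#'
#' Returns every k-mer whose scan score reaches the threshold implied by
#' `p_threshold` (on either strand when `both_strands`), by branch-and-bound
#' over the log-odds matrix. This is the matching set used by the neutral
#' motif-retention expectation.
#'
#' @inheritParams scan_motif
#' @return Character vector of k-mers.
#' @export
matching_kmers <- function(motif, p_threshold = motif$p_threshold,
                           both_strands = TRUE) {
  thr <- .motif_threshold_int(motif, p_threshold)
  enum <- function(int_mat) {
    k <- nrow(int_mat)
    suffix_max <- rev(cumsum(rev(apply(int_mat, 1L, max))))
    suffix_max <- c(suffix_max, 0)
    acc <- new.env(parent = emptyenv())
    acc$res <- character()
    rec <- function(i, score, prefix) {
      if (i > k) {
        acc$res <- c(acc$res, paste(prefix, collapse = ""))
        return(invisible(NULL))
      }
      for (b in 1:4) {
        s2 <- score + int_mat[i, b]
        if (s2 + suffix_max[i + 1L] >= thr) {
          rec(i + 1L, s2, c(prefix, DNA_BASES[b]))
        }
      }
    }
    rec(1L, 0, character())
    acc$res
  }
  hits <- enum(motif$int_scores)
  if (both_strands) {
    rc_int <- motif$int_scores[motif$k:1, 4:1, drop = FALSE]
    hits <- union(hits, enum(rc_int))
  }
  sort(hits)
}
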