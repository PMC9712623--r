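#' Per-position association of sequence variation with activity (TE-WAS)
#'
#' For every retained column of the reference alignment, elements are
#' split into carriers of the column's major allele (the modal A/C/G/T,
#' ties broken alphabetically) and non-carriers (another unambiguous
#' base); gaps and N are treated as missing. A two-sided Fisher's exact
#' test on the carrier-by-activity 2x2 table yields the position p-value.
#' Monomorphic columns (no non-carrier) are excluded.
#'
#' @param matrix A `ref_alignment`.
#' @param labels Named logical vector: TRUE for active elements. Must
#'   cover the matrix's elements; both classes must be non-empty.
#' @param alpha Significance threshold on the raw p-value (default 5e-5).
#' @return `data.frame` with `ref_position` (0-based), `major_allele`,
#'   `tie` (major allele tie-broken), 2x2 counts
#'   `carrier_active`, `noncarrier_active`, `carrier_inactive`,
#'   `noncarrier_inactive`, `p_value`, `significant`.
#' @export
associate_positions <- function(matrix, labels, alpha = 5e-5) {
  stopifnot(inherits(matrix, "ref_alignment"))
  labels <- labels[matrix$element_ids]
  if (anyNA(labels)) stop("labels missing for some elements", call. = FALSE)
  if (!any(labels) || all(labels)) {
    stop("need at least one active and one inactive element", call. = FALSE)
  }
  mat <- matrix$mat
  counts <- vapply(DNA_BASES, function(b) colSums(mat == b),
                   numeric(ncol(mat)))
  major_idx <- max.col(counts, ties.method = "first")
  tie <- rowSums(counts == counts[cbind(seq_len(nrow(counts)),
                                        major_idx)]) > 1L
  major <- DNA_BASES[major_idx]
  majorm <- matrix(major, nrow(mat), ncol(mat), byrow = TRUE)
  validb <- mat == "A" | mat == "C" | mat == "G" | mat == "T"
  carrier <- validb & mat == majorm
  noncar <- validb & mat != majorm
  a <- colSums(carrier[labels, , drop = FALSE])
  b <- colSums(noncar[labels, , drop = FALSE])
  cc <- colSums(carrier[!labels, , drop = FALSE])
  d <- colSums(noncar[!labels, , drop = FALSE])
  keep <- matrix$retained & (b + d) > 0L
  ft <- fisher_exact_2x2(a[keep], b[keep], cc[keep], d[keep])
  data.frame(ref_position = which(keep) - 1L, major_allele = major[keep],
             tie = tie[keep], carrier_active = a[keep],
             noncarrier_active = b[keep], carrier_inactive = cc[keep],
             noncarrier_inactive = d[keep], p_value = ft$p,
             significant = ft$p < alpha, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Information-content overrepresentation of motifs among significant
#' positions
#'
#' For each motif placed on the reference, sums the per-position
#' information content (from the motif's position frequency matrix under
#' a uniform background) over significant positions falling inside the
#' motif span, and compares against a null built by uniformly re-drawing
#' the same number of positions from all tested positions. A motif is
#' reported when a one-sided t-test of the null distribution against the
#' observed statistic gives p < 0.05 and at least `min_sig_in_motif`
#' significant positions lie in the span.
#'
#' @param sig_positions Integer vector of significant reference positions
#'   (0-based); must be a subset of `tested_positions`.
#' @param motifs List of `list(model = motif_model, span = c(start, end))`
#'   with spans 0-based half-open on the reference; names are motif names.
#' @param tested_positions Integer vector of all tested positions.
#' @param n_shuffles Number of null draws (default 1000; < 100 warns).
#' @param min_sig_in_motif Minimum significant positions inside the span.
#' @param seed RNG seed for the shuffles.
#' @return `data.frame` per motif: `motif`, `span_start`, `span_end`,
#'   `n_sig_in_motif`, `observed_ic_sum`, `null_mean`, `p_value`,
#'   `reported`; the null sums are attached as attribute `null_ic_sums`
#'   (matrix, shuffles x motifs).
#' @export
motif_ic_overrepresentation <- function(sig_positions, motifs,
                                        tested_positions,
                                        n_shuffles = 1000,
                                        min_sig_in_motif = 2, seed = 1L) {
  if (!all(sig_positions %in% tested_positions)) {
    stop("sig_positions must be a subset of tested_positions", call. = FALSE)
  }
  if (n_shuffles < 100) {
    warning("fewer than 100 shuffles gives an unstable null")
  }
  set.seed(seed)
  nsig <- length(sig_positions)
  draws <- matrix(0L, n_shuffles, nsig)
  if (nsig) {
    for (s in seq_len(n_shuffles)) {
      draws[s, ] <- sample(tested_positions, nsig)
    }
  }
  mnames <- names(motifs) %||% vapply(motifs, function(m) m$model$name, "")
  res <- lapply(seq_along(motifs), function(i) {
    span <- motifs[[i]]$span
    ic <- motif_ic(motifs[[i]]$model)
    ic_at <- function(pos) {
      inside <- pos >= span[1L] & pos < span[2L]
      sum(ic[pos[inside] - span[1L] + 1L])
    }
    obs <- ic_at(sig_positions)
    nulls <- apply(draws, 1L, ic_at)
    n_in <- sum(sig_positions >= span[1L] & sig_positions < span[2L])
    p <- if (sd(nulls) == 0) {
      if (obs > mean(nulls)) 0 else 1
    } else {
      t.test(nulls, mu = obs, alternative = "less")$p.value
    }
    data.frame(motif = mnames[i], span_start = span[1L], span_end = span[2L],
               n_sig_in_motif = n_in, observed_ic_sum = obs,
               null_mean = mean(nulls), p_value = p,
               reported = p < 0.05 & n_in >= min_sig_in_motif,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "null_ic_sums") <- vapply(seq_along(motifs), function(i) {
    span <- motifs[[i]]$span
    ic <- motif_ic(motifs[[i]]$model)
    apply(draws, 1L, function(pos) {
      inside <- pos >= span[1L] & pos < span[2L]
      sum(ic[pos[inside] - span[1L] + 1L])
    })
  }, numeric(n_shuffles))
  out
}

#' Motif presence enrichment in active vs inactive elements
#'
#' Two-sided Fisher's exact test per motif on the has-hit x active 2x2
#' table, Bonferroni-adjusted across motifs (the native equivalent of an
#' AME-style enrichment with the inactive set as background).
#'
#' @param active_ids,inactive_ids Element ids of the two groups (both
#'   non-empty, disjoint).
#' @param motif_hits Either a `data.frame(element_id, motif)` of hits or
#'   a named list of element-id vectors per motif.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return `data.frame(motif, with_active, with_inactive, odds_ratio,
#'   p_raw, p_bonferroni, significant)`; motifs absent from every element
#'   are skipped with a message.
#' @export
motif_presence_enrichment <- function(active_ids, inactive_ids, motif_hits,
                                      alpha = 0.05) {
  if (!length(active_ids) || !length(inactive_ids)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (is.data.frame(motif_hits)) {
    motif_hits <- split(motif_hits$element_id, motif_hits$motif)
  }
  rows <- list()
  for (m in names(motif_hits)) {
    hit_ids <- motif_hits[[m]]
    if (!length(intersect(hit_ids, c(active_ids, inactive_ids)))) {
      message("motif ", m, " absent from all elements; skipped")
      next
    }
    a <- sum(active_ids %in% hit_ids)
    b <- length(active_ids) - a
    cc <- sum(inactive_ids %in% hit_ids)
    d <- length(inactive_ids) - cc
    ft <- fisher_exact_2x2(a, b, cc, d)
    rows[[m]] <- data.frame(motif = m, with_active = a, with_inactive = cc,
                            odds_ratio = ft$odds_ratio, p_raw = ft$p,
                            stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    stop("no motif present in any element", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(out$p_raw * nrow(out), 1)
  out$significant <- out$p_bonferroni < alpha
  rownames(out) <- NULL
  out
}
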