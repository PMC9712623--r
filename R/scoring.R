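#' Aggregate barcode counts per element and apply the count filter
#'
#' Sums DNA and per-replicate RNA counts over each element's barcodes.
#' Elements are retained only if the DNA total and every RNA replicate
#' total reach `min_total` (default 5), mirroring the standard MPRA
#' low-count filter.
#'
#' @param counts `data.frame(barcode, element_id, dna, rna_1..rna_R)`;
#'   barcodes must be unique.
#' @param min_total Minimum summed count in the DNA pool and in each RNA
#'   replicate (default 5).
#' @return `data.frame(element_id, dna, rna_1..rna_R, retained)`.
#' @export
aggregate_and_filter <- function(counts, min_total = 5) {
  rna_cols <- grep("^rna_", names(counts), value = TRUE)
  stopifnot(length(rna_cols) >= 1L,
            all(c("barcode", "element_id", "dna") %in% names(counts)))
  if (anyDuplicated(counts$barcode)) {
    stop("barcodes must be unique", call. = FALSE)
  }
  agg <- stats::aggregate(counts[, c("dna", rna_cols)],
                          by = list(element_id = counts$element_id), sum)
  rna_ok <- rowSums(agg[, rna_cols, drop = FALSE] < min_total) == 0L
  agg$retained <- agg$dna >= min_total & rna_ok
  agg[order(agg$element_id), , drop = FALSE]
}

#' Basal-normalised log2 enrichment scores
#'
#' Counts of retained elements are scaled to counts per million (CPM) per
#' column; expression per replicate is RNA CPM / DNA CPM; expression is
#' divided by the mean basal-construct expression pooled over replicates;
#' the enrichment score is the log2 of that normalised expression, and the
#' element score is the mean across replicates.
#'
#' @param aggregated Output of [aggregate_and_filter()].
#' @param basal_ids Element ids of basal promoter-only constructs; at
#'   least one must be retained.
#' @return Object of class `enrichment_table`: `data.frame` with
#'   `element_id`, per-replicate scores `E_1..E_R`, and mean `E`;
#'   attribute `basal_mean_expression` records the normaliser.
#' @export
enrichment_scores <- function(aggregated, basal_ids) {
  rna_cols <- grep("^rna_", names(aggregated), value = TRUE)
  ret <- aggregated[aggregated$retained, , drop = FALSE]
  basal_rows <- ret$element_id %in% basal_ids
  if (!any(basal_rows)) stop("no retained basal element", call. = FALSE)
  cpm <- function(x) x / sum(x) * 1e6
  dna_cpm <- cpm(ret$dna)
  expr <- vapply(rna_cols, function(cl) cpm(ret[[cl]]) / dna_cpm,
                 numeric(nrow(ret)))
  basal_mean <- mean(expr[basal_rows, , drop = FALSE])
  E_r <- log2(expr / basal_mean)
  colnames(E_r) <- sub("^rna_", "E_", rna_cols)
  out <- data.frame(element_id = ret$element_id, E_r, E = rowMeans(E_r),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "basal_mean_expression") <- basal_mean
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Call active elements at an enrichment-score threshold
#'
#' Active means a strictly greater enrichment score than the threshold
#' (an element at exactly the threshold is inactive). Multiple named
#' thresholds can coexist as separate columns.
#'
#' @param table An `enrichment_table`.
#' @param threshold Enrichment-score cutoff (default 1, i.e. more than
#'   twofold over basal; 0.5 is the conventional relaxed cutoff for
#'   low-activity contexts).
#' @param name Column name for the calls (default `active_<threshold>`
#'   tidied, or `active` for the default threshold).
#' @return The table with a logical call column appended.
#' @export
classify_active <- function(table, threshold = 1,
                            name = if (threshold == 1) "active" else
                              paste0("active_", threshold)) {
  stopifnot(is.finite(threshold))
  table[[name]] <- table$E > threshold
  table
}

#' Mutagenesis effect sizes from mutant/native fragment pairs
#'
#' The effect of a motif mutation is the log2 ratio of the mutant's
#' normalised expression to its native sequence's, i.e. `E_mutant -
#' E_native`. Pairs with a missing (filtered-out) member are skipped.
#' Group summaries report the mean effect and the corresponding mean
#' fold-change `2^mean(effect)`.
#'
#' @param table An `enrichment_table`.
#' @param pairs `data.frame(mutant_id, native_id)` plus optional grouping
#'   columns (e.g. `motif`, `mode`), carried through to the output.
#' @return List with `effects` (per-pair `data.frame` incl. `effect`) and
#'   `groups` (per motif x mode mean effect, mean fold-change, n) when
#'   grouping columns are present.
#' @export
mutagenesis_effect <- function(table, pairs) {
  stopifnot(all(c("mutant_id", "native_id") %in% names(pairs)))
  E <- setNames(table$E, table$element_id)
  keep <- pairs$mutant_id %in% names(E) & pairs$native_id %in% names(E)
  if (any(!keep)) {
    message(sum(!keep), " pair(s) skipped: member not retained")
  }
  eff <- pairs[keep, , drop = FALSE]
  eff$effect <- unname(E[eff$mutant_id] - E[eff$native_id])
  groups <- NULL
  gcols <- intersect(c("motif", "mode"), names(eff))
  if (length(gcols) && nrow(eff)) {
    groups <- stats::aggregate(eff["effect"], by = eff[gcols], function(x) x)
    groups <- do.call(rbind, lapply(split(eff, eff[gcols], drop = TRUE),
      function(g) {
        data.frame(g[1L, gcols, drop = FALSE],
                   mean_effect = mean(g$effect),
                   fold_change = 2^mean(g$effect),
                   se = sd(g$effect) / sqrt(nrow(g)), n = nrow(g),
                   row.names = NULL)
      }))
  }
  list(effects = eff, groups = groups)
}

#' Compare two groups of effects or scores (two-tailed Mann-Whitney U)
#'
#' @param x,y Numeric vectors.
#' @return p-value of the two-sided rank-sum test.
#' @export
mwu_test <- function(x, y) {
  wilcox.test(x, y, alternative = "two.sided", exact = FALSE)$p.value
}
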