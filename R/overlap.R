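#' Construct a merged annotation set
#'
#' Intervals are 0-based half-open (BED convention) and are merged
#' (sorted, overlaps and bookended runs collapsed) on construction;
#' strand is ignored.
#'
#' @param name Annotation name.
#' @param intervals `data.frame(chrom, start, end)` with 0-based
#'   half-open coordinates.
#' @return Object of class `annotation_set` with merged intervals.
#' @export
annotation_set <- function(name, intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$end < intervals$start)) {
    stop("negative-length interval in annotation", call. = FALSE)
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    intervals$chrom,
    IRanges::IRanges(intervals$start + 1L, intervals$end)))
  merged <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                       start = GenomicRanges::start(gr) - 1L,
                       end = GenomicRanges::end(gr),
                       stringsAsFactors = FALSE)
  structure(list(name = name, intervals = merged, granges = gr,
                 merged = TRUE),
            class = "annotation_set")
}

#' Read a BED3+ file into a data.frame of 0-based half-open intervals
#'
#' @param path BED file path.
#' @return `data.frame(chrom, start, end, name)` (`name` when a 4th
#'   column exists).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "name"
  df[, seq_len(min(4L, ncol(df))), drop = FALSE]
}

#' Overlap elements with an annotation set
#'
#' Computes, per element, the total overlapped bases against the merged
#' annotation and flags elements whose overlap reaches `min_frac` of the
#' element length (default 0.5). Elements on chromosomes absent from the
#' annotation simply count as non-overlapping.
#'
#' @param elements `data.frame(element_id, chrom, start, end)`, 0-based
#'   half-open.
#' @param annotation An `annotation_set`.
#' @param min_frac Minimum overlapped fraction of element length
#'   (default 0.5).
#' @return `data.frame(element_id, length, overlap_bp, overlapped,
#'   annotation)`.
#' @export
overlap_elements <- function(elements, annotation, min_frac = 0.5) {
  stopifnot(inherits(annotation, "annotation_set"),
            all(c("element_id", "chrom", "start", "end") %in%
                  names(elements)))
  if (any(elements$end < elements$start)) {
    stop("negative-length element interval", call. = FALSE)
  }
  egr <- GenomicRanges::GRanges(
    elements$chrom, IRanges::IRanges(elements$start + 1L, elements$end))
  hits <- GenomicRanges::findOverlaps(egr, annotation$granges)
  ov_bp <- integer(nrow(elements))
  if (length(hits)) {
    pint <- GenomicRanges::pintersect(
      egr[S4Vectors::queryHits(hits)],
      annotation$granges[S4Vectors::subjectHits(hits)])
    w <- tapply(GenomicRanges::width(pint), S4Vectors::queryHits(hits), sum)
    ov_bp[as.integer(names(w))] <- as.integer(w)
  }
  len <- elements$end - elements$start
  data.frame(element_id = elements$element_id, length = len,
             overlap_bp = ov_bp, overlapped = ov_bp >= min_frac * len,
             annotation = annotation$name, stringsAsFactors = FALSE)
}

#' Genome-level Fisher enrichment of elements in an annotation
#'
#' Builds a 2x2 table in the style of interval-level Fisher enrichment:
#' elements overlapping / not overlapping the annotation (at `min_frac`
#' of their length), annotation intervals not hit by any element, and an
#' estimated count of remaining genomic "slots"
#' (`genome_size / mean annotation interval length` minus the other three
#' cells, floored at 0). Reports the two-sided exact p, the sample odds
#' ratio, and a Haldane-corrected odds ratio (0.5 added to each cell).
#'
#' @param elements `data.frame(element_id, chrom, start, end)`.
#' @param annotation An `annotation_set` with at least one interval.
#' @param genome_size Genome length in bp (at least the annotated bp).
#' @param min_frac Overlap rule passed to [overlap_elements()].
#' @return List with `table` (2x2 matrix), `odds_ratio`,
#'   `odds_ratio_haldane`, `p_value`, and the per-element `overlaps`.
#' @export
fisher_enrichment <- function(elements, annotation, genome_size,
                              min_frac = 0.5) {
  if (!nrow(elements) || !nrow(annotation$intervals)) {
    stop("elements and annotation must both be non-empty", call. = FALSE)
  }
  ann_bp <- sum(annotation$intervals$end - annotation$intervals$start)
  if (genome_size < ann_bp) {
    stop("genome_size smaller than annotated bases", call. = FALSE)
  }
  ov <- overlap_elements(elements, annotation, min_frac = min_frac)
  n11 <- sum(ov$overlapped)
  n12 <- sum(!ov$overlapped)
  egr <- GenomicRanges::GRanges(
    elements$chrom, IRanges::IRanges(elements$start + 1L, elements$end))
  hit_ann <- unique(S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(egr, annotation$granges)))
  n21 <- nrow(annotation$intervals) - length(hit_ann)
  mean_len <- ann_bp / nrow(annotation$intervals)
  n22 <- max(0, round(genome_size / mean_len) - n11 - n12 - n21)
  ft <- fisher_exact_2x2(n11, n12, n21, n22)
  tab <- matrix(c(n11, n12, n21, n22), 2, byrow = TRUE,
                dimnames = list(c("elements", "background"),
                                c("in_annotation", "not_in_annotation")))
  list(table = tab, odds_ratio = ft$odds_ratio,
       odds_ratio_haldane = ((n11 + 0.5) * (n22 + 0.5)) /
         ((n12 + 0.5) * (n21 + 0.5)),
       p_value = ft$p, overlaps = ov)
}

#' Motif association with annotation-overlapping elements
#'
#' Two-sided Fisher's exact test per motif on the motif-presence x
#' annotation-overlap 2x2 table, Bonferroni-corrected over motifs.
#'
#' @param overlaps Output of [overlap_elements()] (or any data frame
#'   with `element_id` and logical `overlapped`).
#' @param motif_hits `data.frame(element_id, motif)` or a named list of
#'   element-id vectors per motif.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return `data.frame(motif, with_overlap, without_overlap, odds_ratio,
#'   p_raw, p_bonferroni, significant)`.
#' @export
motif_annotation_association <- function(overlaps, motif_hits,
                                         alpha = 0.05) {
  if (!any(overlaps$overlapped) || all(overlaps$overlapped)) {
    stop("need both overlapping and non-overlapping elements",
         call. = FALSE)
  }
  res <- motif_presence_enrichment(
    overlaps$element_id[overlaps$overlapped],
    overlaps$element_id[!overlaps$overlapped], motif_hits, alpha = alpha)
  names(res)[names(res) == "with_active"] <- "with_overlap"
  names(res)[names(res) == "with_inactive"] <- "without_overlap"
  res
}
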