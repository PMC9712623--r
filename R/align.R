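#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch alignment over A/C/G/T/N with affine gaps: a gap of
#' length L costs `gap_open + (L - 1) * gap_ext`. Traceback ties are broken
#' deterministically, preferring aligned pairs over a gap in the query row
#' over a gap in the reference row.
#'
#' @param ref,query Sequences (character scalars) or named character
#'   vectors of length 1; names become `ref_id`/`query_id`.
#' @param match,mismatch,gap_open,gap_ext Scoring parameters. Defaults
#'   +1/-1/-2/-0.5.
#' @param ref_id,query_id Identifiers (default taken from names, else
#'   "ref"/"query").
#' @return Object of class `pairwise_alignment`: list with `ref_id`,
#'   `query_id`, `ref_row`, `query_row` (gapped strings), `score`, and
#'   `identity` (match fraction over columns where both rows have a
#'   non-gap, non-N base).
#' @export
global_align <- function(ref, query, match = 1, mismatch = -1,
                         gap_open = -2, gap_ext = -0.5,
                         ref_id = NULL, query_id = NULL) {
  ref_id <- ref_id %||% names(ref) %||% "ref"
  query_id <- query_id %||% names(query) %||% "query"
  ref <- toupper(unname(ref))
  query <- toupper(unname(query))
  if (!is_string(ref) || !nzchar(ref)) {
    stop("reference sequence must be non-empty", call. = FALSE)
  }
  check_alphabet(ref, sprintf("reference '%s'", ref_id))
  if (nzchar(query)) check_alphabet(query, sprintf("query '%s'", query_id))
  res <- .align_affine_cpp(ref, query, match, mismatch, gap_open, gap_ext)
  rr <- strsplit(res$ref_row, "")[[1]]
  qr <- strsplit(res$query_row, "")[[1]]
  comp <- rr %in% DNA_BASES & qr %in% DNA_BASES
  identity <- if (any(comp)) mean(rr[comp] == qr[comp]) else 0
  structure(list(ref_id = ref_id, query_id = query_id,
                 ref_row = res$ref_row, query_row = res$query_row,
                 score = res$score, identity = identity),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("pairwise_alignment %s vs %s: score %.2f, identity %.3f\n",
              x$ref_id, x$query_id, x$score, x$identity))
  invisible(x)
}

#' Construct a reference alignment matrix from pre-aligned rows
#'
#' For inputs already projected onto reference coordinates (one character
#' per reference position per element; `-` for gaps). The retained mask
#' marks columns where at least `min_presence` of elements have a base.
#'
#' @param ref_id Reference identifier.
#' @param ref_seq Ungapped reference sequence.
#' @param mat Character matrix, elements x reference positions, entries in
#'   A/C/G/T/N/-. Row names are element ids.
#' @param min_presence Minimum non-gap fraction for a column to be
#'   retained (default 0.20).
#' @return Object of class `ref_alignment`.
#' @export
ref_alignment <- function(ref_id, ref_seq, mat, min_presence = 0.20) {
  ref_seq <- toupper(ref_seq)
  mat <- toupper(mat)
  stopifnot(is.matrix(mat), ncol(mat) == nchar(ref_seq),
            !is.null(rownames(mat)))
  retained <- colMeans(mat != "-") >= min_presence
  structure(list(ref_id = ref_id, ref_seq = ref_seq,
                 ref_length = nchar(ref_seq), mat = mat,
                 element_ids = rownames(mat), retained = retained,
                 min_presence = min_presence),
            class = "ref_alignment")
}

#' @export
print.ref_alignment <- function(x, ...) {
  cat(sprintf("ref_alignment on %s: %d elements x %d positions (%d retained)\n",
              x$ref_id, nrow(x$mat), x$ref_length, sum(x$retained)))
  invisible(x)
}

#' Combine pairwise alignments onto common reference coordinates
#'
#' Projects each query onto the (shared) reference: one matrix column per
#' reference position; query insertions relative to the reference are
#' dropped. Columns with a base (not a gap) in fewer than `min_presence`
#' of elements are flagged as not retained.
#'
#' @param alignments List of `pairwise_alignment` objects sharing one
#'   reference (same `ref_id` and ungapped reference sequence).
#' @param min_presence Retention rule (default 0.20: columns with bases in
#'   < 20% of elements are masked).
#' @return A `ref_alignment` with one row per query, in input order.
#' @export
project_to_reference <- function(alignments, min_presence = 0.20) {
  stopifnot(length(alignments) >= 1L,
            all(vapply(alignments, inherits, TRUE, "pairwise_alignment")))
  ungap <- function(a) gsub("-", "", a$ref_row, fixed = TRUE)
  ref_seq <- ungap(alignments[[1L]])
  ref_id <- alignments[[1L]]$ref_id
  for (a in alignments) {
    if (!identical(a$ref_id, ref_id) || !identical(ungap(a), ref_seq)) {
      stop("alignments do not share a common reference", call. = FALSE)
    }
  }
  L <- nchar(ref_seq)
  ids <- vapply(alignments, `[[`, "", "query_id")
  if (anyDuplicated(ids)) stop("duplicated query ids", call. = FALSE)
  mat <- matrix("-", length(alignments), L, dimnames = list(ids, NULL))
  for (i in seq_along(alignments)) {
    rr <- strsplit(alignments[[i]]$ref_row, "")[[1]]
    qr <- strsplit(alignments[[i]]$query_row, "")[[1]]
    keep <- rr != "-"
    mat[i, ] <- qr[keep]
  }
  ref_alignment(ref_id, ref_seq, mat, min_presence = min_presence)
}

#' Extract the query sequence aligned to a reference window
#'
#' For each alignment, returns the query subsequence aligned to the
#' half-open reference window `[start, end)`, including query insertions
#' that fall strictly inside the window. Elements shorter than `min_len`,
#' longer than `max_len`, or containing a forbidden subsequence are
#' excluded with a recorded reason.
#'
#' @param alignments List of `pairwise_alignment` objects on one reference.
#' @param window Integer vector `c(start, end)`, 0-based half-open on the
#'   reference.
#' @param min_len,max_len Length bounds on the extracted sequence
#'   (defaults 70 and 160).
#' @param forbidden Character vector of forbidden subsequences (e.g.
#'   cloning restriction sites).
#' @return `data.frame` with columns `element_id`, `sequence`, `length`,
#'   `included`, `reason`.
#' @export
extract_reference_window <- function(alignments, window, min_len = 70,
                                     max_len = 160,
                                     forbidden = character()) {
  stopifnot(length(window) == 2L)
  start <- window[1L]
  end <- window[2L]
  ref_len <- nchar(gsub("-", "", alignments[[1L]]$ref_row, fixed = TRUE))
  if (start < 0 || start >= end || end > ref_len) {
    stop(sprintf("window [%d,%d) out of range for reference of length %d",
                 start, end, ref_len), call. = FALSE)
  }
  one <- function(a) {
    rr <- strsplit(a$ref_row, "")[[1]]
    qr <- strsplit(a$query_row, "")[[1]]
    refpos <- cumsum(rr != "-")  # 1-based ref position at/preceding column
    inside <- (rr != "-" & refpos >= start + 1L & refpos <= end) |
      (rr == "-" & refpos >= start + 1L & refpos <= end - 1L)
    bases <- qr[inside]
    paste(bases[bases != "-"], collapse = "")
  }
  seqs <- vapply(alignments, one, "")
  ids <- vapply(alignments, `[[`, "", "query_id")
  len <- nchar(seqs)
  reason <- rep("", length(seqs))
  reason[len < min_len] <- "too_short"
  reason[len > max_len] <- "too_long"
  if (length(forbidden)) {
    hasf <- Reduce(`|`, lapply(forbidden, function(f) {
      grepl(f, seqs, fixed = TRUE)
    }))
    reason[reason == "" & hasf] <- "forbidden_subsequence"
  }
  data.frame(element_id = ids, sequence = seqs, length = len,
             included = reason == "", reason = reason,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Estimate transition/transversion substitution probabilities
#'
#' Pools mismatch counts between the reference and a subset of elements of
#' a reference alignment matrix. Only columns where both the reference and
#' the element carry an unambiguous base (A/C/G/T) are counted. Transitions
#' are A<->G and C<->T; everything else is a transversion.
#'
#' @param matrix A `ref_alignment`.
#' @param element_subset Element ids to pool over (default all).
#' @param species Label stored on the result (default "all").
#' @return Object of class `substitution_model`: list with `species`,
#'   `s_transition`, `s_transversion` (per-site probabilities), and
#'   `aligned_bases`.
#' @export
estimate_titv <- function(matrix, element_subset = NULL, species = "all") {
  stopifnot(inherits(matrix, "ref_alignment"))
  ids <- element_subset %||% matrix$element_ids
  missing_ids <- setdiff(ids, matrix$element_ids)
  if (length(missing_ids)) {
    stop("unknown element ids: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  sub <- matrix$mat[ids, , drop = FALSE]
  refc <- strsplit(matrix$ref_seq, "")[[1]]
  refm <- matrix(refc, nrow(sub), ncol(sub), byrow = TRUE)
  ok <- sub %in% DNA_BASES & refm %in% DNA_BASES
  dim(ok) <- dim(sub)
  aligned <- sum(ok)
  if (aligned == 0L) stop("zero aligned bases", call. = FALSE)
  mism <- ok & sub != refm
  ti <- sum(mism & TRANSITION_PARTNER[refm] == sub, na.rm = TRUE)
  tv <- sum(mism) - ti
  substitution_model(species, ti / aligned, tv / aligned, aligned)
}

#' Construct a substitution model
#'
#' Two-parameter per-site model: stay probability `1 - s_transition -
#' s_transversion`, transition probability `s_transition`, and each of the
#' two specific transversions `s_transversion / 2`.
#'
#' @param species Label.
#' @param s_transition,s_transversion Per-site probabilities, summing to
#'   at most 1.
#' @param aligned_bases Number of aligned bases behind the estimate.
#' @return Object of class `substitution_model`.
#' @export
substitution_model <- function(species, s_transition, s_transversion,
                               aligned_bases = NA_integer_) {
  stopifnot(s_transition >= 0, s_transversion >= 0)
  if (s_transition + s_transversion > 1) {
    stop("s_transition + s_transversion must not exceed 1", call. = FALSE)
  }
  structure(list(species = species, s_transition = s_transition,
                 s_transversion = s_transversion,
                 aligned_bases = aligned_bases),
            class = "substitution_model")
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf(
    "substitution_model [%s]: ti %.4g, tv %.4g (%s aligned bases)\n",
    x$species, x$s_transition, x$s_transversion,
    format(x$aligned_bases)))
  invisible(x)
}

# 4x4 per-site base-change probability matrix (rows ancestral A,C,G,T)
.substitution_matrix <- function(sub) {
  st <- sub$s_transition
  sv <- sub$s_transversion
  P <- matrix(sv / 2, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  diag(P) <- 1 - st - sv
  for (b in DNA_BASES) P[b, TRANSITION_PARTNER[b]] <- st
  P
}
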