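#' Read a multi-record FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning a named
#' character vector of uppercase sequences.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences (gaps allowed).
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Dump a reference alignment as gapped (A2M-style) FASTA
#'
#' The reference sequence is written first, then one gapped row per element
#' projected onto reference coordinates.
#'
#' @param matrix A `ref_alignment` object (see [project_to_reference()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(matrix, path) {
  stopifnot(inherits(matrix, "ref_alignment"))
  rows <- apply(matrix$mat, 1L, paste, collapse = "")
  seqs <- c(setNames(matrix$ref_seq, matrix$ref_id), rows)
  write_fasta(seqs, path)
}

#' Read motifs from a minimal MEME-format file
#'
#' Parses `MOTIF` blocks with `letter-probability matrix` sections (the
#' minimal MEME motif format used by motif databases and scanning tools).
#'
#' @param path Path to a MEME motif file.
#' @param pseudocount,p_threshold Passed to [motif_model()].
#' @return Named list of `motif_model` objects.
#' @export
read_meme <- function(path, pseudocount = 1e-3, p_threshold = 1e-4) {
  if (!file.exists(path)) stop("MEME file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  midx <- grep("^MOTIF\\s", lines)
  if (!length(midx)) stop("no MOTIF blocks in ", path, call. = FALSE)
  out <- list()
  for (i in seq_along(midx)) {
    header <- strsplit(trimws(lines[midx[i]]), "\\s+")[[1]]
    name <- header[2]
    to <- if (i < length(midx)) midx[i + 1] - 1L else length(lines)
    block <- lines[midx[i]:to]
    lp <- grep("letter-probability matrix", block)
    if (!length(lp)) stop("motif ", name, " lacks a letter-probability matrix",
                          call. = FALSE)
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", block[lp[1]]))
    rows <- block[(lp[1] + 1L):(lp[1] + w)]
    prob <- do.call(rbind, lapply(strsplit(trimws(rows), "\\s+"), as.numeric))
    out[[name]] <- motif_model(name, prob, pseudocount = pseudocount,
                               p_threshold = p_threshold)
  }
  out
}

#' Write motifs to a minimal MEME-format file
#'
#' @param motifs List of `motif_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (m in motifs) {
    writeLines(sprintf("MOTIF %s", m$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", m$k), con)
    writeLines(apply(m$prob, 1L, function(r) paste(sprintf("%.6f", r),
                                                   collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}
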