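#' Tiling design for activity deconvolution
#'
#' @param element_id Element id.
#' @param element_length Length L of the element.
#' @param tiles `data.frame(offset, score)`: tile start offsets (0-based)
#'   and their enrichment scores.
#' @param tile_len,step Tile length and step (defaults 160 and 10).
#' @return Object of class `tiling_design`.
#' @export
tiling_design <- function(element_id, element_length, tiles,
                          tile_len = 160, step = 10) {
  stopifnot(all(c("offset", "score") %in% names(tiles)),
            nrow(tiles) >= 1L,
            all(tiles$offset >= 0),
            all(tiles$offset + pmin(tile_len, element_length) <=
                  element_length))
  structure(list(element_id = element_id, L = element_length,
                 tile_len = tile_len, step = step,
                 tiles = tiles[order(tiles$offset), , drop = FALSE]),
            class = "tiling_design")
}

# tiles x steps averaging matrix: W[i, j] = 1/k_i when tile i fully covers
# step j (k_i = number of steps it covers); the element's final step may be
# shorter than `step`.
.design_matrix <- function(design) {
  s <- design$step
  L <- design$L
  n_steps <- ceiling(L / s)
  step_start <- (seq_len(n_steps) - 1L) * s
  step_end <- pmin(step_start + s, L)
  offs <- design$tiles$offset
  tl <- pmin(design$tile_len, L)
  W <- matrix(0, nrow(design$tiles), n_steps)
  for (i in seq_len(nrow(design$tiles))) {
    covered <- step_start >= offs[i] & step_end <= offs[i] + tl
    if (!any(covered)) {
      stop("tile at offset ", offs[i], " covers no full step", call. = FALSE)
    }
    W[i, covered] <- 1 / sum(covered)
  }
  W
}

#' Ridge inference of step activities from tiled enrichment scores
#'
#' Models each tile's enrichment score as the average of the latent
#' activities of the steps it covers and returns the maximum a posteriori
#' step activities under a zero-mean Gaussian prior: `(W'W + lambda I)^-1
#' W' M`, with `W` the tile-averaging design matrix and `M` the tile
#' scores. `lambda` plays the role of the prior variance parameter of
#' tiling deconvolution (conventional settings 1 and 50).
#'
#' @param design A `tiling_design`.
#' @param lambda Ridge penalty (> 0).
#' @return Numeric vector of step activities (one per `step`-bp bin).
#' @export
infer_step_activities <- function(design, lambda) {
  stopifnot(inherits(design, "tiling_design"), lambda > 0)
  W <- .design_matrix(design)
  M <- design$tiles$score
  A <- crossprod(W) + lambda * diag(ncol(W))
  as.vector(solve(A, crossprod(W, M)))
}

#' Basal background from shuffled-element step activities
#'
#' @param step_values_list List of combined step-activity vectors of the
#'   shuffled basal (control) elements.
#' @return Object of class `basal_background`: list(mean, sd, n).
#' @export
basal_background <- function(step_values_list) {
  v <- unlist(step_values_list, use.names = FALSE)
  stopifnot(length(v) >= 1L)
  structure(list(mean = mean(v), sd = if (length(v) > 1L) sd(v) else 0,
                 n = length(v)),
            class = "basal_background")
}

#' Per-nucleotide activity track from two-prior step inferences
#'
#' Combines the step activities inferred at the two prior settings by
#' their unweighted mean, subtracts the basal background mean, and
#' linearly interpolates between step centers (center of step j at `j*s +
#' s/2`, 0-based) with constant extrapolation beyond the terminal
#' centers.
#'
#' @param step_values_1,step_values_2 Step activities at the two prior
#'   settings (equal length).
#' @param basal A `basal_background` (its mean is subtracted); use
#'   `basal_background(list(0))` for no normalisation.
#' @param L Element length.
#' @param s Step size (default 10).
#' @return Numeric vector of length `L` of basal-normalised nucleotide
#'   activities.
#' @export
nucleotide_track <- function(step_values_1, step_values_2, basal, L,
                             s = 10) {
  if (length(step_values_1) != length(step_values_2)) {
    stop("step vectors must have equal length", call. = FALSE)
  }
  combined <- (step_values_1 + step_values_2) / 2 - basal$mean
  centers <- (seq_along(combined) - 1L) * s + s / 2
  pos <- seq_len(L) - 0.5  # nucleotide centers, 0-based coordinates
  if (length(combined) == 1L) return(rep(combined, L))
  approx(centers, combined, xout = pos, rule = 2)$y
}

#' Summarise an activity track: element sum and peak intervals
#'
#' The element activity is the sum of nucleotide activities. Peaks are
#' maximal runs of positions whose (basal-normalised) activity exceeds
#' `peak_k` basal standard deviations (default 3).
#'
#' @param nucleotide_values Basal-normalised nucleotide activities.
#' @param basal A `basal_background`.
#' @param peak_k Peak threshold in basal standard deviations (default 3).
#' @return List with `sharpr_sum` and `peaks`
#'   (`data.frame(start, end)`, 0-based half-open).
#' @export
summarize_track <- function(nucleotide_values, basal, peak_k = 3) {
  above <- nucleotide_values > peak_k * basal$sd
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  peaks <- data.frame(start = starts[r$values] - 1L, end = ends[r$values])
  list(sharpr_sum = sum(nucleotide_values), peaks = peaks)
}

#' Full activity-track pipeline for one tiled element
#'
#' Runs the two-prior ridge inference, combines, normalises to basal, and
#' summarises.
#'
#' @param design A `tiling_design`.
#' @param basal A `basal_background`.
#' @param varpriors The two prior settings (default `c(1, 50)`).
#' @param peak_k Peak threshold (default 3).
#' @return Object of class `activity_track`: list with `element_id`,
#'   `step_values` (per prior), `combined_step_values`,
#'   `nucleotide_values`, `sharpr_sum`, `peaks`.
#' @export
activity_track <- function(design, basal, varpriors = c(1, 50),
                           peak_k = 3) {
  stopifnot(length(varpriors) == 2L)
  sv <- lapply(varpriors, function(l) infer_step_activities(design, l))
  names(sv) <- paste0("lambda_", varpriors)
  nt <- nucleotide_track(sv[[1L]], sv[[2L]], basal, design$L, design$step)
  summ <- summarize_track(nt, basal, peak_k = peak_k)
  structure(list(element_id = design$element_id, step_values = sv,
                 combined_step_values = (sv[[1L]] + sv[[2L]]) / 2,
                 nucleotide_values = nt, sharpr_sum = summ$sharpr_sum,
                 peaks = summ$peaks),
            class = "activity_track")
}

#' @export
print.activity_track <- function(x, ...) {
  cat(sprintf("activity_track %s: sum %.3f, %d peak(s)\n",
              x$element_id, x$sharpr_sum, nrow(x$peaks)))
  invisible(x)
}

#' Build tiling designs from an enrichment table and a library design
#'
#' Joins per-fragment enrichment scores back onto the tile fragments of
#' an [build_library_design()] design, one `tiling_design` per tiled
#' element.
#'
#' @param table An `enrichment_table`.
#' @param design An `mpra_design`.
#' @param element_lengths Named integer vector of element lengths.
#' @return Named list of `tiling_design` objects (elements with no
#'   retained tiles are dropped).
#' @export
tiling_designs_from_scores <- function(table, design, element_lengths) {
  tiles <- design$fragments[design$fragments$kind == "tile", , drop = FALSE]
  E <- setNames(table$E, table$element_id)
  tiles$score <- unname(E[tiles$fragment_id])
  tiles <- tiles[!is.na(tiles$score), , drop = FALSE]
  out <- lapply(split(tiles, tiles$element_id), function(g) {
    tiling_design(g$element_id[1L], element_lengths[[g$element_id[1L]]],
                  data.frame(offset = g$offset, score = g$score),
                  tile_len = design$tile_len, step = design$tile_step)
  })
  out
}
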