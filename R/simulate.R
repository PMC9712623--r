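#' Default parameters for the synthetic TE-subfamily simulator
#'
#' The generator emulates a two-phase evolutionary history: a transposition
#' phase (a Yule birth tree of element copies with per-branch
#' transition/transversion substitution probabilities) followed by a
#' speciation phase (each transposition-phase leaf acquires one descendant
#' copy per species, diverged according to that species' branch length).
#' Two activating motifs are planted in the root; element activity is
#' linear in motif dosage on the log2 scale. Reporter counts are
#' overdispersed negative binomial with 10 barcodes per tested fragment
#' and 300 for the basal promoter construct, three RNA replicates and one
#' DNA pool.
#'
#' @param root_length Root sequence length (default 360).
#' @param planted_motifs List of planted motifs, each a list with `name`,
#'   `consensus` (k-mer written into the root), `position` (0-based offset
#'   in the root), `effect` (log2 activity contribution), and optional
#'   `soft` positions for the PWM. Defaults are a JUN-like (AP-1) and a
#'   DBP-like (CEBP-related) motif with effects equal to log2 of 1.68-
#'   and 2.36-fold.
#' @param n_transposition_leaves Number of transposition-phase leaves
#'   (default 40).
#' @param species `data.frame(species, branch_length)` for the speciation
#'   phase; branch lengths are substitutions/site from the
#'   transposition-phase leaf to the present-day copy.
#' @param trans_s_ti,trans_s_tv Per-branch transition/transversion
#'   probabilities per site during the transposition phase.
#' @param indel_rate Per-site probability of an indel event per branch.
#' @param activity_baseline,activity_noise_sd Log2 activity baseline and
#'   per-element noise standard deviation.
#' @param barcodes_per_element,basal_barcodes,rna_replicates Barcoding and
#'   replicate structure (defaults 10, 300, 3).
#' @param dna_mean_depth Mean DNA count per barcode.
#' @param nb_dispersion Negative binomial size parameter per barcode
#'   (larger is closer to Poisson).
#' @param n_shuffled_controls Number of shuffled-reference control
#'   elements (default 30); their tiles define the basal background for
#'   activity-track normalisation.
#' @param seed Mandatory default seed for the simulation functions.
#' @return Named list of parameters.
#' @export
simulation_params <- function(root_length = 360,
                              planted_motifs = list(
                                list(name = "JUN", consensus = "GCTGAGTCATG",
                                     position = 60, effect = log2(1.68),
                                     soft = c(1L, 11L)),
                                list(name = "DBP", consensus = "ATTATGTAACC",
                                     position = 24, effect = log2(2.36),
                                     soft = c(1L, 11L))),
                              n_transposition_leaves = 40,
                              species = data.frame(
                                species = c("human", "chimp", "gorilla",
                                            "gibbon", "baboon"),
                                branch_length = c(0.007, 0.012, 0.015,
                                                  0.030, 0.045)),
                              trans_s_ti = 0.015, trans_s_tv = 0.0075,
                              indel_rate = 0.001,
                              activity_baseline = 0.2,
                              activity_noise_sd = 0.25,
                              barcodes_per_element = 10,
                              basal_barcodes = 300,
                              rna_replicates = 3,
                              dna_mean_depth = 100,
                              nb_dispersion = 25,
                              n_shuffled_controls = 30,
                              seed = 1L) {
  stopifnot(root_length > 0, n_transposition_leaves >= 1,
            nrow(species) >= 1,
            trans_s_ti >= 0, trans_s_tv >= 0, trans_s_ti + trans_s_tv <= 1,
            indel_rate >= 0, indel_rate <= 1,
            all(species$branch_length >= 0, species$branch_length <= 1),
            is.finite(vapply(planted_motifs, `[[`, 0, "effect")),
            !is.null(seed))
  as.list(environment())
}

#' Apply per-site substitutions and indels to a sequence
#'
#' Each site independently transitions with probability `s_ti`, takes one
#' of the two transversions (equal probability) with total probability
#' `s_tv`, and otherwise stays. Indel events occur per site at
#' `indel_rate`: half deletions, half insertions of random bases, lengths
#' geometric (p = 0.5) capped at `indel_max`. `N` bases are left
#' untouched. Uses the current RNG state.
#'
#' @param seq Sequence string.
#' @param s_ti,s_tv Per-site transition / total transversion probability.
#' @param indel_rate Per-site indel event probability (default 0).
#' @param indel_max Maximum indel length (default 9).
#' @return Mutated sequence string.
#' @export
mutate_sequence <- function(seq, s_ti, s_tv, indel_rate = 0, indel_max = 9) {
  stopifnot(s_ti + s_tv <= 1)
  ints <- seq_to_ints(seq)
  L <- length(ints)
  if (L == 0L) return("")
  if (s_ti + s_tv > 0) {
    u <- runif(L)
    partner <- c(3L, 4L, 1L, 2L)
    tv1 <- c(2L, 1L, 2L, 1L)
    tv2 <- c(4L, 3L, 4L, 3L)
    pick2 <- runif(L) < 0.5
    known <- !is.na(ints)
    do_ti <- known & u < s_ti
    do_tv <- known & u >= s_ti & u < s_ti + s_tv
    ints[do_ti] <- partner[ints[do_ti]]
    ints[do_tv & pick2] <- tv1[ints[do_tv & pick2]]
    ints[do_tv & !pick2] <- tv2[ints[do_tv & !pick2]]
  }
  if (indel_rate > 0) {
    events <- which(runif(L) < indel_rate)
    for (i in rev(events)) {
      len <- min(rgeom(1L, 0.5) + 1L, indel_max)
      if (runif(1L) < 0.5) {  # deletion starting at i
        drop <- i:min(i + len - 1L, length(ints))
        ints <- ints[-drop]
      } else {               # insertion after i
        ins <- sample.int(4L, len, replace = TRUE)
        ints <- append(ints, ins, after = i)
      }
    }
  }
  ints_to_seq(ints)
}

#' Simulate a TE subfamily with planted motifs and known truth
#'
#' Generates a root sequence with planted motif consensus k-mers, grows a
#' Yule transposition tree to `n_transposition_leaves` leaves with
#' per-branch substitutions and indels, then derives one present-day copy
#' per species per leaf using that species' branch length (transition :
#' transversion 2:1). Shuffled copies of the root are appended as control
#' elements. True activity of every element is `baseline + sum(effect *
#' motif presence) + noise`, with presence determined by [scan_motif()] on
#' the generated sequence, so truth is recomputable from sequence alone.
#'
#' @param params See [simulation_params()].
#' @param seed Integer seed (default `params$seed`).
#' @return List with `sequences` (`data.frame(id, species, role, bases)`;
#'   roles: `consensus` root, `tree_intermediate`, `ortholog_ancestor`
#'   transposition leaves, `present_day`, `control`) and `truth` (list:
#'   `tree` newick string with named internal nodes, `motif_models`,
#'   `motif_presence` logical matrix, `true_activity`, `noise`, `params`).
#' @export
simulate_subfamily <- function(params = simulation_params(),
                               seed = params$seed) {
  set.seed(seed)
  p <- params
  root <- sample(DNA_BASES, p$root_length, replace = TRUE)
  for (m in p$planted_motifs) {
    km <- strsplit(m$consensus, "")[[1]]
    stopifnot(m$position >= 0, m$position + length(km) <= p$root_length)
    root[(m$position + 1L):(m$position + length(km))] <- km
  }
  root_seq <- paste(root, collapse = "")

  # transposition phase: Yule birth process
  seqs <- list(root_seq)
  parent <- c(NA_integer_)
  children <- list(integer())
  tips <- 1L
  while (length(tips) < p$n_transposition_leaves) {
    split_node <- if (length(tips) == 1L) tips else sample(tips, 1L)
    for (ch in 1:2) {
      seqs[[length(seqs) + 1L]] <- mutate_sequence(
        seqs[[split_node]], p$trans_s_ti, p$trans_s_tv, p$indel_rate)
      parent[length(seqs)] <- split_node
      children[[length(seqs)]] <- integer()
      children[[split_node]] <- c(children[[split_node]], length(seqs))
    }
    tips <- c(setdiff(tips, split_node),
              length(seqs) - 1L, length(seqs))
  }
  is_leaf <- lengths(children) == 0L
  node_name <- character(length(seqs))
  node_name[1L] <- "root"
  node_name[is_leaf] <- sprintf("el%02d", seq_len(sum(is_leaf)))
  inner <- which(!is_leaf)[-1L]
  node_name[inner] <- sprintf("anc%02d", seq_along(inner))

  newick <- function(i) {
    if (is_leaf[i]) return(node_name[i])
    paste0("(", paste(vapply(children[[i]], newick, ""), collapse = ","),
           ")", node_name[i])
  }
  tree <- paste0(newick(1L), ";")

  # speciation phase
  ids <- node_name
  species <- rep(NA_character_, length(seqs))
  role <- ifelse(is_leaf, "ortholog_ancestor", "tree_intermediate")
  role[1L] <- "consensus"
  bases <- unlist(seqs)
  for (leaf in which(is_leaf)) {
    for (r in seq_len(nrow(p$species))) {
      d <- p$species$branch_length[r]
      child <- mutate_sequence(seqs[[leaf]], 2 * d / 3, d / 3, p$indel_rate)
      ids <- c(ids, paste0(node_name[leaf], "_", p$species$species[r]))
      species <- c(species, p$species$species[r])
      role <- c(role, "present_day")
      bases <- c(bases, child)
    }
  }
  # shuffled-root control elements
  rootc <- strsplit(root_seq, "")[[1]]
  for (i in seq_len(p$n_shuffled_controls)) {
    ids <- c(ids, sprintf("shuf%02d", i))
    species <- c(species, NA_character_)
    role <- c(role, "control")
    bases <- c(bases, paste(sample(rootc), collapse = ""))
  }
  sequences <- data.frame(id = ids, species = species, role = role,
                          bases = bases, stringsAsFactors = FALSE)

  motif_models <- lapply(p$planted_motifs, function(m) {
    motif_from_consensus(m$name, m$consensus, soft = m$soft %||% integer())
  })
  names(motif_models) <- vapply(p$planted_motifs, `[[`, "", "name")
  presence <- vapply(motif_models, function(mod) {
    vapply(sequences$bases, function(s) {
      nrow(scan_motif(s, mod)) > 0L
    }, TRUE, USE.NAMES = FALSE)
  }, logical(nrow(sequences)))
  rownames(presence) <- sequences$id
  effects <- vapply(p$planted_motifs, `[[`, 0, "effect")
  noise <- if (p$activity_noise_sd > 0) {
    rnorm(nrow(sequences), 0, p$activity_noise_sd)
  } else {
    numeric(nrow(sequences))
  }
  names(noise) <- sequences$id
  true_activity <- p$activity_baseline +
    as.vector(presence %*% effects) + noise
  names(true_activity) <- sequences$id

  list(sequences = sequences,
       truth = list(tree = tree, motif_models = motif_models,
                    motif_presence = presence,
                    true_activity = true_activity, noise = noise,
                    params = p, seed = seed))
}

#' Motif definitions used by the mutagenesis fragments
#'
#' Replacement strings for motif gain/loss mutagenesis: loss writes a
#' low-information replacement over the motif span; gain writes the motif
#' consensus over the motif-aligned region of an element lacking it.
#'
#' @param truth Truth list from [simulate_subfamily()] supplying models
#'   and reference spans of the planted motifs.
#' @return Named list per motif: `model`, `loss`, `gain`, `ref_span`
#'   (0-based half-open on the reference).
#' @export
default_motif_defs <- function(truth) {
  defs <- list(
    JUN = list(loss = "TCACCAATGGT", gain = "GCTGAGTCATG"),
    DBP = list(loss = "TCCCACAGCAT", gain = "ATTATGTAACC"))
  out <- list()
  for (m in truth$params$planted_motifs) {
    d <- defs[[m$name]] %||% list(loss = strrep("A", nchar(m$consensus)),
                                  gain = m$consensus)
    out[[m$name]] <- list(model = truth$motif_models[[m$name]],
                          loss = d$loss, gain = d$gain,
                          ref_span = c(m$position,
                                       m$position + nchar(m$consensus)))
  }
  out
}

#' Build an MPRA library design from element sequences
#'
#' Produces motif-focused fragments (each element's sequence aligned to a
#' reference window, with length and restriction-site filters), 160-bp
#' tiles at 10-bp steps (final tile right-anchored so the element end is
#' covered; elements shorter than one tile yield a single flagged
#' full-length tile), and motif mutagenesis fragments that substitute
#' fixed replacement strings at motif-aligned positions of the windowed
#' sequence.
#'
#' @param sequences Named character vector of element sequences.
#' @param reference Named length-1 character vector: the reference
#'   sequence elements are aligned to.
#' @param window `c(start, end)` 0-based half-open window on the
#'   reference (default first 160 bp).
#' @param tile_len,tile_step Tiling geometry (defaults 160 and 10).
#' @param tile_elements Ids of elements to tile (default none).
#' @param mutagenesis `data.frame(element_id, motif, mode)` with mode
#'   `"gain"` or `"loss"`, or NULL.
#' @param motif_defs Named list per motif with `model`, `loss`, `gain`,
#'   `ref_span` (see [default_motif_defs()]). Required when `mutagenesis`
#'   is given.
#' @param min_len,max_len,forbidden Window extraction filters (see
#'   [extract_reference_window()]).
#' @return Object of class `mpra_design`: list with `fragments`
#'   (`data.frame(fragment_id, element_id, kind, offset, sequence,
#'   flagged)`), `window_table`, `pairs` (mutant/native fragment pairs),
#'   `alignments`, and the design parameters.
#' @export
build_library_design <- function(sequences, reference, window = c(0, 160),
                                 tile_len = 160, tile_step = 10,
                                 tile_elements = NULL, mutagenesis = NULL,
                                 motif_defs = NULL, min_len = 70,
                                 max_len = 160, forbidden = character()) {
  stopifnot(tile_len >= tile_step, length(reference) == 1L,
            !is.null(names(sequences)))
  ref_id <- names(reference)
  alignments <- lapply(names(sequences), function(id) {
    global_align(reference, sequences[[id]], ref_id = ref_id, query_id = id)
  })
  names(alignments) <- names(sequences)
  wt <- extract_reference_window(alignments, window, min_len = min_len,
                                 max_len = max_len, forbidden = forbidden)
  frag <- data.frame(fragment_id = paste0(wt$element_id, "_mf"),
                     element_id = wt$element_id, kind = "motif_focus",
                     offset = 0L, sequence = wt$sequence,
                     flagged = FALSE, stringsAsFactors = FALSE)
  frag <- frag[wt$included, , drop = FALSE]

  for (el in tile_elements %||% character()) {
    s <- sequences[[el]]
    if (is.null(s)) stop("unknown tile element: ", el, call. = FALSE)
    L <- nchar(s)
    if (L < tile_len) {
      offs <- 0L
      flag <- TRUE
    } else {
      offs <- seq.int(0L, L - tile_len, by = tile_step)
      if (max(offs) < L - tile_len) offs <- c(offs, L - tile_len)
      flag <- FALSE
    }
    tl <- pmin(tile_len, L)
    frag <- rbind(frag, data.frame(
      fragment_id = sprintf("%s_tile%03d", el, offs), element_id = el,
      kind = "tile", offset = as.integer(offs),
      sequence = substring(s, offs + 1L, offs + tl),
      flagged = flag, stringsAsFactors = FALSE))
  }

  pairs <- data.frame(mutant_id = character(), native_id = character(),
                      motif = character(), mode = character(),
                      stringsAsFactors = FALSE)
  if (!is.null(mutagenesis) && nrow(mutagenesis)) {
    stopifnot(!is.null(motif_defs))
    for (r in seq_len(nrow(mutagenesis))) {
      el <- mutagenesis$element_id[r]
      mo <- mutagenesis$motif[r]
      mode <- match.arg(mutagenesis$mode[r], c("gain", "loss"))
      def <- motif_defs[[mo]]
      if (is.null(def)) stop("no motif_defs entry for ", mo, call. = FALSE)
      wrow <- which(wt$element_id == el)
      if (!length(wrow) || !wt$included[wrow]) {
        message("mutagenesis element ", el, " not in windowed library; skipped")
        next
      }
      wseq <- wt$sequence[wrow]
      if (mode == "loss") {
        hits <- scan_motif(wseq, def$model)
        if (!nrow(hits)) {
          message("no ", mo, " hit in ", el, " for loss mutagenesis; skipped")
          next
        }
        span <- c(hits$offset[1L] + 1L, hits$offset[1L] + def$model$k)
        repl <- def$loss
      } else {
        span <- .window_query_span(alignments[[el]], window, def$ref_span)
        if (is.null(span)) {
          message("motif region of ", el, " is fully deleted; skipped")
          next
        }
        repl <- def$gain
      }
      mseq <- paste0(substring(wseq, 1L, span[1L] - 1L), repl,
                     substring(wseq, span[2L] + 1L, nchar(wseq)))
      frag <- rbind(frag, data.frame(
        fragment_id = sprintf("%s_%s_%s", el, mo, mode), element_id = el,
        kind = "mutagenesis", offset = 0L, sequence = mseq,
        flagged = FALSE, stringsAsFactors = FALSE))
      pairs <- rbind(pairs, data.frame(
        mutant_id = sprintf("%s_%s_%s", el, mo, mode),
        native_id = paste0(el, "_mf"), motif = mo, mode = mode,
        stringsAsFactors = FALSE))
    }
  }
  structure(list(fragments = frag, window_table = wt, pairs = pairs,
                 alignments = alignments, reference = reference,
                 window = window, tile_len = tile_len,
                 tile_step = tile_step),
            class = "mpra_design")
}

# 1-based [start,end] span, within the window-extracted query sequence, of
# query bases aligned to reference span ref_span (0-based half-open).
# NULL when the element has no bases in the span.
.window_query_span <- function(a, window, ref_span) {
  rr <- strsplit(a$ref_row, "")[[1]]
  qr <- strsplit(a$query_row, "")[[1]]
  refpos <- cumsum(rr != "-")
  inside <- (rr != "-" & refpos >= window[1L] + 1L & refpos <= window[2L]) |
    (rr == "-" & refpos >= window[1L] + 1L & refpos <= window[2L] - 1L)
  qin <- qr[inside]
  rin <- refpos[inside]
  gapless <- qin != "-"
  qidx <- cumsum(gapless)            # window-seq coordinate per column
  span_cols <- which(gapless & rin >= ref_span[1L] + 1L &
                       rin <= ref_span[2L])
  if (!length(span_cols)) return(NULL)
  c(min(qidx[span_cols]), max(qidx[span_cols]))
}

#' @export
print.mpra_design <- function(x, ...) {
  cat(sprintf(
    "mpra_design: %d fragments (%s)\n", nrow(x$fragments),
    paste(sprintf("%s=%d", names(table(x$fragments$kind)),
                  as.integer(table(x$fragments$kind))), collapse = ", ")))
  invisible(x)
}

#' Simulate barcode-level MPRA counts for a library design
#'
#' DNA counts per barcode are negative binomial with mean
#' `dna_mean_depth`; RNA counts per replicate have mean scaled by
#' `2^activity` of the fragment. Fragment activity is `baseline +
#' sum(effect * motif presence in the fragment sequence) + the element's
#' planted noise`; basal promoter-only constructs have activity exactly 0
#' and carry `basal_barcodes` barcodes.
#'
#' @param truth Truth list from [simulate_subfamily()].
#' @param design An `mpra_design`.
#' @param params See [simulation_params()] (default: the truth's params).
#' @param seed Integer seed.
#' @return `data.frame(barcode, element_id, dna, rna_1..rna_R)`; the
#'   `element_id` column holds the tested fragment id, with basal
#'   barcodes under id `"basal"`.
#' @export
simulate_mpra_counts <- function(truth, design, params = truth$params,
                                 seed = truth$seed + 1L) {
  stopifnot(inherits(design, "mpra_design"))
  if (params$dna_mean_depth <= 0) {
    stop("dna_mean_depth must be positive", call. = FALSE)
  }
  set.seed(seed)
  effects <- vapply(params$planted_motifs, `[[`, 0, "effect")
  frag <- design$fragments
  act <- vapply(seq_len(nrow(frag)), function(i) {
    pres <- vapply(truth$motif_models, function(mod) {
      nrow(scan_motif(frag$sequence[i], mod)) > 0L
    }, TRUE)
    nz <- truth$noise[frag$element_id[i]]
    if (is.na(nz)) nz <- 0
    params$activity_baseline + sum(effects * pres) + nz
  }, 0)
  frag_ids <- c(frag$fragment_id, "basal")
  nbc <- c(rep(params$barcodes_per_element, nrow(frag)),
           params$basal_barcodes)
  act <- c(act, 0)
  element_id <- rep(frag_ids, nbc)
  barcode <- paste0(element_id, "_bc",
                    unlist(lapply(nbc, seq_len), use.names = FALSE))
  n <- length(barcode)
  mu_rna <- params$dna_mean_depth * 2^rep(act, nbc)
  out <- data.frame(barcode = barcode, element_id = element_id,
                    dna = rnbinom(n, size = params$nb_dispersion,
                                  mu = params$dna_mean_depth),
                    stringsAsFactors = FALSE)
  for (r in seq_len(params$rna_replicates)) {
    out[[paste0("rna_", r)]] <- rnbinom(n, size = params$nb_dispersion,
                                        mu = mu_rna)
  }
  out
}
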