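PIPELINE_CONFIG_KEYS <- c("mode", "seed", "simulation", "inputs", "params",
                          "stages", "overlap", "out_dir")

#' Resolve a pipeline configuration
#'
#' Accepts a YAML file path or a list; unknown top-level keys are
#' rejected. Defaults run the bundled synthetic dataset end to end with
#' the conventional stage parameters (count filter 5, active threshold 1,
#' association alpha 5e-5, 160/10 tiling, priors 1 and 50, peak threshold
#' 3 SD, 10-bp conservation windows, 1000 simulations).
#'
#' @param config YAML path or named list of overrides.
#' @return Resolved configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), PIPELINE_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(
    mode = "synthetic", seed = 1L, simulation = list(), inputs = list(),
    params = list(min_total = 5, active_threshold = 1, tewas_alpha = 5e-5,
                  tile_len = 160, tile_step = 10, varpriors = c(1, 50),
                  peak_sd = 3, window_width = 10, max_excluded = 5,
                  n_sims = 1000, n_tewas_shuffles = 1000,
                  n_tile_elements = 20, n_mutagenesis_pairs = 15,
                  scan_p = 1e-4),
    stages = list(tewas = TRUE, sharpr = TRUE, conservation = TRUE,
                  overlap = FALSE),
    overlap = list(), out_dir = NULL)
  cfg <- modifyList(defaults, config)
  cfg$params <- modifyList(defaults$params, cfg$params %||% list())
  cfg$stages <- modifyList(defaults$stages, cfg$stages %||% list())
  cfg
}

.write_stage_tsv <- function(df, path, stage, seed, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage: %s | tepra %s | seed: %s | %s", stage,
                     as.character(utils::packageVersion("tepra")), seed,
                     paste(sprintf("%s=%s", names(params),
                                   vapply(params, paste, "", collapse = ",")),
                           collapse = " ")), con)
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Run the analysis pipeline end to end
#'
#' Executes, in dependency order: data simulation (or loading), library
#' design and barcode-count simulation, enrichment scoring and activity
#' calls, the per-position association scan with motif
#' information-content overrepresentation, ridge activity-track
#' deconvolution of tiled fragments with basal normalisation and peak
#' calls, per-species substitution-rate estimation with exact, simulated,
#' and observed motif retention, and (when configured) annotation-overlap
#' enrichment. Deterministic given `seed`.
#'
#' @param config See [pipeline_config()].
#' @return Named list of stage results; written as TSV/JSON under
#'   `out_dir` when configured (each file carries a header naming the
#'   stage, parameters, and seed).
#' @export
run_pipeline <- function(config = list()) {
  cfg <- pipeline_config(config)
  pp <- cfg$params
  seed <- cfg$seed
  out <- list(config = cfg)

  if (identical(cfg$mode, "synthetic")) {
    simp <- do.call(simulation_params, modifyList(
      cfg$simulation %||% list(), list(seed = seed)))
    sim <- simulate_subfamily(simp, seed = seed)
    sequences <- sim$sequences
    truth <- sim$truth
    reference <- setNames(
      sequences$bases[sequences$role == "consensus"], "root")
    motif_models <- truth$motif_models
    basal_ids <- "basal"
  } else {
    fa <- cfg$inputs$fasta
    if (is.null(fa) || !file.exists(fa %||% "")) {
      stop("input FASTA not found: ", fa %||% "<missing>", call. = FALSE)
    }
    seqs <- read_fasta(fa)
    ref_id <- cfg$inputs$reference_id %||% names(seqs)[1L]
    reference <- setNames(seqs[[ref_id]], ref_id)
    sequences <- data.frame(id = names(seqs), species = NA_character_,
                            role = ifelse(names(seqs) == ref_id,
                                          "consensus", "present_day"),
                            bases = unname(seqs), stringsAsFactors = FALSE)
    truth <- NULL
    motif_models <- if (!is.null(cfg$inputs$motifs)) {
      read_meme(cfg$inputs$motifs, p_threshold = pp$scan_p)
    } else {
      list()
    }
    basal_ids <- cfg$inputs$basal_ids %||% "basal"
  }
  present <- sequences[sequences$role == "present_day", , drop = FALSE]
  out$sequences <- sequences

  # --- library design + counts -------------------------------------------
  if (identical(cfg$mode, "synthetic")) {
    ancestors <- sequences$id[sequences$role %in%
                                c("tree_intermediate", "ortholog_ancestor")]
    set.seed(seed + 101L)
    tile_ids <- c(head(ancestors, pp$n_tile_elements),
                  sequences$id[sequences$role == "control"])
    defs <- default_motif_defs(truth)
    mut <- do.call(rbind, lapply(names(defs), function(m) {
      pres <- truth$motif_presence[present$id, m]
      with_m <- head(present$id[pres], pp$n_mutagenesis_pairs)
      wo_m <- head(present$id[!pres], pp$n_mutagenesis_pairs)
      rows <- list()
      if (length(with_m)) {
        rows$loss <- data.frame(element_id = with_m, motif = m,
                                mode = "loss")
      }
      if (length(wo_m)) {
        rows$gain <- data.frame(element_id = wo_m, motif = m,
                                mode = "gain")
      }
      if (length(rows)) do.call(rbind, rows) else NULL
    }))
    design <- build_library_design(
      setNames(sequences$bases, sequences$id), reference,
      window = c(0, pp$tile_len), tile_len = pp$tile_len,
      tile_step = pp$tile_step, tile_elements = tile_ids,
      mutagenesis = mut, motif_defs = defs)
    counts <- simulate_mpra_counts(truth, design, seed = seed + 1L)
  } else {
    ct <- cfg$inputs$counts
    if (is.null(ct) || !file.exists(ct %||% "")) {
      stop("input count table not found: ", ct %||% "<missing>",
           call. = FALSE)
    }
    counts <- read.delim(ct, stringsAsFactors = FALSE, comment.char = "#")
    design <- NULL
  }
  out$design <- design

  # --- scoring ------------------------------------------------------------
  agg <- aggregate_and_filter(counts, min_total = pp$min_total)
  scores <- enrichment_scores(agg, basal_ids = basal_ids)
  scores <- classify_active(scores, threshold = pp$active_threshold)
  out$scores <- scores
  if (!is.null(design) && nrow(design$pairs)) {
    out$mutagenesis <- mutagenesis_effect(scores, design$pairs)
  }

  # --- TE-WAS -------------------------------------------------------------
  if (isTRUE(cfg$stages$tewas) && nrow(present)) {
    aln <- lapply(seq_len(nrow(present)), function(i) {
      global_align(reference, present$bases[i],
                   query_id = present$id[i])
    })
    mat <- project_to_reference(aln)
    E <- setNames(scores$E, scores$element_id)
    mf_ids <- paste0(present$id, "_mf")
    labels <- setNames(!is.na(E[mf_ids]) &
                         E[mf_ids] > pp$active_threshold, present$id)
    keep <- present$id[mf_ids %in% scores$element_id]
    matk <- ref_alignment(mat$ref_id, mat$ref_seq,
                          mat$mat[keep, , drop = FALSE])
    out$alignment <- mat
    assoc <- NULL
    if (any(labels[keep]) && !all(labels[keep])) {
      assoc <- associate_positions(matk, labels[keep],
                                   alpha = pp$tewas_alpha)
    } else {
      message("tewas stage skipped: all elements in one activity class")
    }
    out$tewas <- assoc
    if (!is.null(assoc) && length(motif_models)) {
      spans <- lapply(motif_models, function(m) {
        h <- scan_motif(reference[[1L]], m)
        if (!nrow(h)) return(NULL)
        list(model = m, span = c(h$offset[1L], h$offset[1L] + m$k))
      })
      spans <- Filter(Negate(is.null), spans)
      if (length(spans)) {
        out$tewas_motifs <- motif_ic_overrepresentation(
          assoc$ref_position[assoc$significant], spans,
          assoc$ref_position, n_shuffles = pp$n_tewas_shuffles,
          seed = seed + 2L)
      }
    }
  }

  # --- activity tracks ----------------------------------------------------
  if (isTRUE(cfg$stages$sharpr) && !is.null(design) &&
      any(design$fragments$kind == "tile")) {
    lens <- setNames(nchar(sequences$bases), sequences$id)
    tds <- tiling_designs_from_scores(scores, design, lens)
    ctrl <- intersect(names(tds),
                      sequences$id[sequences$role == "control"])
    basal <- if (length(ctrl)) {
      basal_background(lapply(tds[ctrl], function(d) {
        (infer_step_activities(d, pp$varpriors[1L]) +
           infer_step_activities(d, pp$varpriors[2L])) / 2
      }))
    } else {
      basal_background(list(0))
    }
    tracks <- lapply(tds[setdiff(names(tds), ctrl)], activity_track,
                     basal = basal, varpriors = pp$varpriors,
                     peak_k = pp$peak_sd)
    out$basal <- basal
    out$tracks <- tracks
    out$sharpr_sums <- data.frame(
      element_id = names(tracks),
      sharpr_sum = vapply(tracks, `[[`, 0, "sharpr_sum"),
      n_peaks = vapply(tracks, function(t) nrow(t$peaks), 0L),
      row.names = NULL, stringsAsFactors = FALSE)
  }

  # --- conservation -------------------------------------------------------
  if (isTRUE(cfg$stages$conservation) && !is.null(out$alignment) &&
      length(motif_models)) {
    mat <- out$alignment
    species <- unique(present$species)
    species <- species[!is.na(species)]
    cons <- list()
    for (sp in species) {
      ids <- present$id[present$species %in% sp]
      sub <- estimate_titv(mat, ids, species = sp)
      spm <- ref_alignment(mat$ref_id, mat$ref_seq,
                           mat$mat[ids, , drop = FALSE])
      wins <- window_conservation(spm, width = pp$window_width,
                                  max_excluded = pp$max_excluded)
      mot <- list()
      for (m in names(motif_models)) {
        mod <- motif_models[[m]]
        h <- scan_motif(reference[[1L]], mod)
        if (!nrow(h)) next
        span <- c(h$offset[1L], h$offset[1L] + mod$k)
        anc <- substr(reference[[1L]], span[1L] + 1L, span[2L])
        expP <- expected_motif_conservation(anc, mod, sub)
        obs <- observed_motif_conservation(spm, span, mod)
        sims <- simulate_motif_conservation(
          rep(anc, obs$n_elements), mod, sub, n_sims = pp$n_sims,
          seed = seed + 3L)
        pt <- proportion_test(obs$observed_fraction, expP,
                              obs$n_elements)
        mot[[m]] <- data.frame(
          motif = m, species = sp, expected_p = expP,
          observed_fraction = obs$observed_fraction,
          n_elements = obs$n_elements, sim_mean = mean(sims),
          prop_test_p = pt$p_value, stringsAsFactors = FALSE)
      }
      cons[[sp]] <- list(substitution = sub, windows = wins,
                         motifs = do.call(rbind, mot))
    }
    if (length(cons)) {
      out$conservation <- cons
      out$shared_windows <- shared_conserved_windows(
        lapply(cons, `[[`, "windows"), consensus = reference[[1L]],
        motifs = motif_models, width = pp$window_width)
    }
  }

  # --- annotation overlap -------------------------------------------------
  if (isTRUE(cfg$stages$overlap)) {
    ob <- cfg$overlap
    for (f in c("elements_bed", "annotation_bed")) {
      if (is.null(ob[[f]]) || !file.exists(ob[[f]])) {
        stop("overlap stage input not found: ", f, call. = FALSE)
      }
    }
    els <- read_bed(ob$elements_bed)
    els$element_id <- els$name %||% sprintf("el%d", seq_len(nrow(els)))
    ann <- annotation_set(basename(ob$annotation_bed),
                          read_bed(ob$annotation_bed))
    out$overlap <- fisher_enrichment(els, ann,
                                     genome_size = ob$genome_size %||% 3e9,
                                     min_frac = ob$min_frac %||% 0.5)
  }

  if (!is.null(cfg$out_dir)) .write_pipeline_outputs(out, cfg)
  out
}

.write_pipeline_outputs <- function(out, cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  yaml::write_yaml(cfg[setdiff(names(cfg), "out_dir")],
                   file.path(cfg$out_dir, "config_resolved.yaml"))
  .write_stage_tsv(out$scores, file.path(cfg$out_dir, "scores.tsv"),
                   "scoring", seed, cfg$params["min_total"])
  if (!is.null(out$tewas)) {
    .write_stage_tsv(out$tewas, file.path(cfg$out_dir, "tewas.tsv"),
                     "tewas", seed, cfg$params["tewas_alpha"])
  }
  if (!is.null(out$sharpr_sums)) {
    .write_stage_tsv(out$sharpr_sums,
                     file.path(cfg$out_dir, "sharpr_sums.tsv"),
                     "sharpr", seed, cfg$params["varpriors"])
    bg <- do.call(rbind, lapply(out$tracks, function(t) {
      data.frame(element_id = t$element_id,
                 pos = seq_along(t$nucleotide_values) - 1L,
                 value = t$nucleotide_values)
    }))
    .write_stage_tsv(bg, file.path(cfg$out_dir, "nucleotide_tracks.tsv"),
                     "sharpr", seed)
    peaks <- do.call(rbind, lapply(out$tracks, function(t) {
      if (!nrow(t$peaks)) return(NULL)
      data.frame(chrom = t$element_id, start = t$peaks$start,
                 end = t$peaks$end)
    }))
    if (!is.null(peaks)) {
      write.table(peaks, file.path(cfg$out_dir, "peaks.bed"),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
  }
  if (!is.null(out$conservation)) {
    mot <- do.call(rbind, lapply(out$conservation, `[[`, "motifs"))
    if (!is.null(mot)) {
      .write_stage_tsv(mot, file.path(cfg$out_dir,
                                      "motif_conservation.tsv"),
                       "conservation", seed, cfg$params["n_sims"])
    }
  }
  jsonlite::write_json(
    list(seed = seed,
         n_elements = nrow(out$sequences),
         n_scored = nrow(out$scores),
         n_active = sum(out$scores$active %||% FALSE)),
    file.path(cfg$out_dir, "summary.json"), auto_unbox = TRUE)
  invisible(NULL)
}
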