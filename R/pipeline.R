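# End-to-end pipeline: simulate (or read BED) -> tensorize -> train -> score
# -> calibrate -> Q-score -> interpret -> write scored BED + diagnostics.

#' Assemble a run configuration
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed for the run.
#' @param simulate A [generator_config()] plus `count`, for simulate mode; NULL
#'   to read real data.
#' @param peaks_bed,crms_bed,cell_line Input paths and cell line for real-data
#'   mode.
#' @param model A [model_config()] (defaults to [artificial_profile()] in
#'   simulate mode).
#' @param window_bp,squish_factor,crumb_enabled,crumb_fraction Tensor options;
#'   crumbing should be enabled for sparse real data only.
#' @param min_peaks CRM filter threshold (real-data mode).
#' @param normalize Apply the group-bias normalization and per-TR
#'   standardization (otherwise raw scores are written, flagged "raw").
#' @param mc_sample_size,cap Normalization parameters.
#' @param run_qscore,run_interpret Toggle the diagnostic stages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, simulate = NULL, peaks_bed = NULL,
                       crms_bed = NULL, cell_line = NULL, model = NULL,
                       window_bp = 3200L, squish_factor = 10L,
                       crumb_enabled = !is.null(peaks_bed),
                       crumb_fraction = 0.1, min_peaks = 100L,
                       normalize = TRUE, mc_sample_size = 10000L, cap = 10,
                       run_qscore = TRUE, run_interpret = TRUE) {
  if (is.null(simulate) && (is.null(peaks_bed) || is.null(crms_bed) ||
                            is.null(cell_line))) {
    stop("need either a simulate block or peaks_bed + crms_bed + cell_line")
  }
  if (is.null(model)) {
    model <- if (!is.null(simulate)) artificial_profile(seed = seed) else
      model_config(seed = seed)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, peaks_bed = peaks_bed,
                 crms_bed = crms_bed, cell_line = cell_line, model = model,
                 window_bp = as.integer(window_bp),
                 squish_factor = as.integer(squish_factor),
                 crumb_enabled = crumb_enabled,
                 crumb_fraction = crumb_fraction,
                 min_peaks = as.integer(min_peaks), normalize = normalize,
                 mc_sample_size = as.integer(mc_sample_size), cap = cap,
                 run_qscore = run_qscore, run_interpret = run_interpret),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the [run_config()] arguments; the `simulate` block
#' additionally accepts `count` and every [generator_config()] field, and the
#' `model` block every [model_config()] field.
#'
#' @param path YAML file path.
#' @param ... Overrides applied after reading.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) {
    # YAML 1.1 parses the bare keys "n"/"y" as booleans; map them back
    names(y$simulate)[names(y$simulate) == "FALSE"] <- "n"
    names(y$simulate)[names(y$simulate) == "TRUE"] <- "y"
    count <- y$simulate$count
    gc_args <- y$simulate[setdiff(names(y$simulate), "count")]
    y$simulate <- do.call(generator_config, gc_args)
    attr(y$simulate, "count") <- count
  }
  if (!is.null(y$model)) y$model <- do.call(model_config, y$model)
  y <- utils::modifyList(y, list(...))
  do.call(run_config, y)
}

#' Run the full scoring pipeline
#'
#' Emits, under `config$out_dir`: the scored BED (`scored.bed`), the raw score
#' table (`scores.tsv`), the per-source weights report (`weights.tsv`, when
#' normalizing), the Q-score contribution matrix (`qscore.tsv`), the group
#' estimates (`groups.tsv`), the training loss curve (`loss.csv`) and a JSON
#' run manifest (`manifest.json`) from which every output is regenerable.
#'
#' @param config A [run_config()].
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the trained model, score table, weights,
#'   Q-score report and output paths.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  stage_times <- c()
  tick <- function(stage) {
    stage_times[stage] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    t0 <<- Sys.time()
  }

  mcfg <- config$model
  if (!is.null(config$simulate)) {
    count <- attr(config$simulate, "count")
    if (is.null(count)) count <- 3000L
    say("simulating %d artificial CRMs", count)
    batch <- generate_batch(config$simulate, count, seed = config$seed,
                            tensors = TRUE,
                            squish_factor = config$squish_factor,
                            kernel_len = mcfg$kernel_len)
    catalog <- batch$catalog
    set <- batch$tensors
    rem <- as_remap_peaks(batch)
    peaks <- rem$peaks
    # window tensors are anchored at 0 within each region: score with the
    # region-local coordinates, write the genomic ones
    apk <- artificial_peaks(batch)
    score_df <- data.frame(start = apk$start, end = apk$end,
                           dataset = peaks$dataset,
                           regulator = peaks$regulator)
    window_of <- apk$crm_id
    export_roles(batch, file.path(config$out_dir, "roles.tsv"))
  } else {
    say("reading %s (cell line %s)", config$peaks_bed, config$cell_line)
    rd <- read_remap_bed(config$peaks_bed, config$cell_line)
    catalog <- rd$catalog
    sorted <- rd$peaks[order(rd$peaks$chrom, rd$peaks$start), ]
    regions <- read_crm_bed(config$crms_bed)
    regions <- regions[order(regions$chrom, regions$start), ]
    if (anyNA(regions$peak_count)) {
      regions <- crm_peak_counts(sorted, regions)
    }
    regions <- filter_crms(regions, config$min_peaks)
    if (nrow(regions) == 0) stop("no CRMs pass the min_peaks filter")
    asg <- assign_peaks(sorted, regions)
    tens <- list()
    peaks_list <- list()
    for (i in seq_len(nrow(regions))) {
      idx <- asg$assigned[[as.character(regions$crm_id[i])]]
      if (is.null(idx) || length(idx) == 0) next
      tw <- prepare_tensors(regions[i, ], sorted[idx, ], catalog,
                            window_bp = config$window_bp,
                            squish_factor = config$squish_factor,
                            kernel_len = mcfg$kernel_len,
                            crumb_enabled = config$crumb_enabled,
                            crumb_fraction = config$crumb_fraction)
      for (w in seq_along(tw)) {
        tens[[length(tens) + 1L]] <- tw[[w]]
        peaks_list[[length(peaks_list) + 1L]] <-
          cbind(sorted[idx, ], window = length(tens))
      }
    }
    set <- tensor_set(tens)
    pk_all <- do.call(rbind, peaks_list)
    peaks <- pk_all
    score_df <- pk_all
    window_of <- pk_all$window
  }
  tick("data")

  say("training on %d tensors of %s", ncol(set$data),
      paste(set$shape, collapse = "x"))
  model <- build_model(mcfg, set$shape)
  model <- train_model(model, set, verbose = verbose)
  utils::write.table(data.frame(epoch = seq_along(model$loss_history),
                                loss = model$loss_history),
                     file.path(config$out_dir, "loss.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)
  tick("train")

  say("scoring %d peaks", nrow(peaks))
  recon <- reconstruct_set(model, set)
  raw_by_window <- score_peaks_set(set, recon, score_df, window_of, catalog)
  scores <- peaks
  scores$window <- window_of
  scores$window_score <- raw_by_window
  key <- if (!is.null(peaks$line_index)) peaks$line_index else
    seq_len(nrow(peaks))
  merged <- tapply(raw_by_window, key, function(v) merge_windows(v[!is.na(v)]))
  tick("score")

  qrep <- NULL
  if (config$run_qscore) {
    say("computing Q-score")
    qrep <- qscore(model, set, catalog, max_crms = config$mc_sample_size,
                   seed = config$seed)
    write_qscore_report(qrep, file.path(config$out_dir, "qscore.tsv"))
    tick("qscore")
  }

  weights <- NULL
  upeaks <- peaks[!duplicated(key), , drop = FALSE]
  final_tab <- data.frame(upeaks, raw = as.vector(merged[as.character(unique(key))]))
  if (!is.null(final_tab$line_index)) {
    final_tab <- final_tab[order(final_tab$line_index), , drop = FALSE]
  }
  if (config$normalize) {
    say("computing normalization weights")
    weights <- normalization_weights(model, set, catalog, cap = config$cap,
                                     mc_sample_size = config$mc_sample_size,
                                     seed = config$seed)
    write_weights_report(weights, catalog,
                         file.path(config$out_dir, "weights.tsv"))
    final_tab <- apply_weights(final_tab, weights, catalog)
    final_tab <- standardize_by_tr(final_tab)
    out_scores <- final_tab$final
    score_kind <- "normalized"
  } else {
    out_scores <- final_tab$raw
    score_kind <- "raw"
  }
  tick("normalize")

  groups <- NULL
  if (config$run_interpret) {
    say("estimating correlation groups")
    groups <- estimate_groups(model, catalog, set = set)
    write_group_estimates(groups, file.path(config$out_dir, "groups.tsv"))
    tick("interpret")
  }

  bed_path <- file.path(config$out_dir, "scored.bed")
  write_scored_bed(final_tab, out_scores, bed_path)
  utils::write.table(cbind(final_tab, score_kind = score_kind),
                     file.path(config$out_dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(package = "anopeak",
                   version = as.character(utils::packageVersion("anopeak")),
                   r_version = R.version.string,
                   seed = config$seed, score_kind = score_kind,
                   model = config$model[setdiff(names(config$model),
                                                "loss_weights")],
                   simulate_mode = !is.null(config$simulate),
                   n_tensors = ncol(set$data), n_peaks = nrow(final_tab),
                   best_epoch = model$best_epoch,
                   epochs_run = length(model$loss_history),
                   final_loss = model$loss_history[model$best_epoch],
                   q = if (!is.null(qrep)) qrep$Q else NULL,
                   stage_seconds = as.list(stage_times))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: %s", bed_path)
  invisible(list(model = model, scores = final_tab, weights = weights,
                 qscore = qrep, groups = groups, catalog = catalog,
                 out_dir = config$out_dir, bed = bed_path))
}
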