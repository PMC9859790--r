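#' Preprocess one continuous recording into clean epochs
#'
#' The standard chain: zero-phase band-pass + notch filtering, pooling into
#' frontal/posterior virtual electrodes, stimulus-locked epoching on the
#' marked onsets, baseline correction over the pre-stimulus window, and
#' peak-to-peak artifact rejection. The order (filter, pool, epoch) is the
#' conventional one; filtering and pooling are both linear time-invariant, so
#' the order of those two is immaterial up to float tolerance.
#'
#' @param recording an [eeg_recording()] with the four physical channels.
#' @param events marker data frame (needs the `onset_column`).
#' @param spec a [filter_spec()].
#' @param reject_threshold_uV artifact rejection threshold.
#' @param tmin_ms,tmax_ms epoch window.
#' @param onset_column marker column to lock epochs to.
#' @param pool_first if `TRUE`, pool before filtering (exposed for
#'   cross-checks; the default matches the standard narrative order).
#' @return a baseline-corrected, artifact-flagged `epoch_set`.
#' @export
preprocess_recording <- function(recording, events, spec = filter_spec(),
                                 reject_threshold_uV = 60,
                                 tmin_ms = -200, tmax_ms = 600,
                                 onset_column = "marked_sample",
                                 pool_first = FALSE) {
  x <- if (pool_first) {
    apply_filters(pool_electrodes(recording), spec)
  } else {
    pool_electrodes(apply_filters(recording, spec))
  }
  ep <- extract_epochs(x, events, tmin_ms, tmax_ms, onset_column)
  ep <- baseline_correct(ep)
  reject_artifacts(ep, reject_threshold_uV)
}

#' Quantify one participant-cell: conditional averages, difference wave, peaks
#'
#' Averages the retained oddball and control epochs on the posterior virtual
#' electrode, forms the difference wave, and measures the P300 (local max,
#' 400-600 ms) and N200 (local min, 150-250 ms) on the difference wave.
#'
#' @param epochs a preprocessed `epoch_set`.
#' @param context label for error messages.
#' @return list with `oddball`, `control`, `difference` ([erp_waveform()]s)
#'   and `peaks` (two-row data frame).
#' @export
measure_erp <- function(epochs, context = NULL) {
  odd <- average_condition(epochs, "oddball", "posterior", context)
  ctl <- average_condition(epochs, "control", "posterior", context)
  diff <- difference_wave(odd, ctl)
  peaks <- rbind(find_peak(diff, "P300"), find_peak(diff, "N200"))
  list(oddball = odd, control = ctl, difference = diff, peaks = peaks)
}

#' Preprocess and quantify a whole simulated (or adapted) study
#'
#' Runs [preprocess_recording()] and [measure_erp()] on every
#' participant-cell, collects peak and rejection tables, applies the
#' participant-exclusion rule (more than `max_rejected_fraction` of all
#' epochs rejected), and assembles the per-measure cell matrices (P300
#' amplitude, reaction time, error count) over retained participants.
#'
#' @param study a `study_dataset` from [generate_study()] (or the same shape).
#' @param spec a [filter_spec()].
#' @param reject_threshold_uV artifact threshold.
#' @param max_rejected_fraction participant-exclusion threshold.
#' @return object of class `processed_study`: `peaks`, `rejection`,
#'   `quality`, `waves` (per participant-cell difference waves),
#'   `exclusion`, `p300`, `rt`, `errors` (cell matrices over retained
#'   participants), `retained`.
#' @export
process_study <- function(study, spec = filter_spec(),
                          reject_threshold_uV = 60,
                          max_rejected_fraction = 0.5) {
  cells <- design_cells()
  n <- length(study$participants)
  peaks <- list(); rej <- list(); qual <- list(); waves <- list()
  p300 <- matrix(NA_real_, n, 4, dimnames = list(NULL, cells))
  for (i in seq_len(n)) {
    for (cl in cells) {
      sess <- study$participants[[i]][[cl]]
      ctx <- sprintf("participant %d, cell %s", i, cl)
      q <- quality_gate(sess$recording)
      q$participant <- i; q$cell <- cl
      qual[[length(qual) + 1L]] <- q
      ep <- preprocess_recording(sess$recording, sess$events, spec,
                                 reject_threshold_uV)
      rej[[length(rej) + 1L]] <- data.frame(
        participant = i, cell = cl,
        n_epochs = length(ep$rejected),
        n_rejected = sum(ep$rejected),
        n_dropped_boundary = ep$n_dropped_boundary)
      me <- measure_erp(ep, ctx)
      pk <- me$peaks; pk$participant <- i; pk$cell <- cl
      peaks[[length(peaks) + 1L]] <- pk
      waves[[paste(i, cl, sep = ":")]] <- me$difference
      p300[i, cl] <- pk$amplitude_uV[pk$component == "P300"]
    }
  }
  peaks <- do.call(rbind, peaks)
  rejection <- do.call(rbind, rej)
  quality <- do.call(rbind, qual)
  excl <- exclude_participants(rejection, max_rejected_fraction)
  keep <- as.integer(excl$retained)
  beh <- behavioural_summary(study$participants[keep])
  structure(list(
    peaks = peaks, rejection = rejection, quality = quality, waves = waves,
    exclusion = excl,
    p300 = cell_matrix(p300[keep, , drop = FALSE]),
    rt = beh$rt, errors = beh$errors,
    retained = keep
  ), class = "processed_study")
}

#' Grand-average difference waves per design cell
#'
#' @param processed a `processed_study`.
#' @return named list of grand-average [erp_waveform()]s, one per cell,
#'   over retained participants.
#' @export
grand_difference_waves <- function(processed) {
  cells <- design_cells()
  out <- lapply(cells, function(cl) {
    ws <- processed$waves[paste(processed$retained, cl, sep = ":")]
    grand_average(unname(ws))
  })
  names(out) <- cells
  out
}

#' End-to-end pipeline configuration
#'
#' Bundles every stage's parameters with a stage list, so a full run (or any
#' suffix of it) is reproducible from one object. Round-trips through YAML
#' via [write_run_config()] / [read_run_config()].
#'
#' @param study a [study_config()].
#' @param filter a [filter_spec()].
#' @param reject_threshold_uV artifact rejection threshold.
#' @param max_rejected_fraction participant exclusion threshold.
#' @param alpha interaction decomposition threshold.
#' @param stages ordered subset of `simulate`, `preprocess`, `erp`, `stats`.
#' @return object of class `run_config`.
#' @export
run_config <- function(study = study_config(), filter = filter_spec(),
                       reject_threshold_uV = 60, max_rejected_fraction = 0.5,
                       alpha = 0.05,
                       stages = c("simulate", "preprocess", "erp", "stats")) {
  stages <- match.arg(stages, c("simulate", "preprocess", "erp", "stats"),
                      several.ok = TRUE)
  structure(list(study = study, filter = filter,
                 reject_threshold_uV = reject_threshold_uV,
                 max_rejected_fraction = max_rejected_fraction,
                 alpha = alpha, stages = stages),
            class = "run_config")
}

#' Run the end-to-end pipeline
#'
#' simulate -> preprocess -> erp -> stats, or any suffix starting from a
#' provided dataset. With `out_dir`, writes peak, rejection and quality
#' tables, grand-average waveforms, effect and follow-up tables, a cell-mean
#' summary, and a log echoing every parameter, the seed, rejection rates and
#' exclusions; a rerun with the same configuration is bit-identical.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory (created if needed).
#' @param study optional pre-built `study_dataset`; skips the simulate stage.
#' @return list with `study`, `processed`, `analysis` (stages not run are
#'   `NULL`), invisibly.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL, study = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage_err <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }
  if (is.null(study) && "simulate" %in% config$stages) {
    study <- stage_err("simulate", generate_study(config$study))
  }
  processed <- NULL; analysis <- NULL
  if (!is.null(study) && any(c("preprocess", "erp") %in% config$stages)) {
    processed <- stage_err("preprocess",
                           process_study(study, config$filter,
                                         config$reject_threshold_uV,
                                         config$max_rejected_fraction))
  }
  if (!is.null(processed) && "stats" %in% config$stages) {
    analysis <- stage_err("stats",
                          analyze_study(p300 = processed$p300, rt = processed$rt,
                                        errors = processed$errors,
                                        alpha = config$alpha))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wtsv <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(processed)) {
      wtsv(processed$peaks, "peaks.tsv")
      wtsv(processed$rejection, "rejection.tsv")
      wtsv(processed$quality, "quality.tsv")
      gw <- grand_difference_waves(processed)
      gdf <- data.frame(time_ms = gw[[1]]$time_ms)
      for (cl in names(gw)) gdf[[cl]] <- gw[[cl]]$values
      wtsv(gdf, "grand_difference_waves.tsv")
    }
    if (!is.null(analysis)) {
      for (meas in names(analysis)) {
        wtsv(analysis[[meas]]$anova, sprintf("effects_%s.tsv", meas))
        if (!is.null(analysis[[meas]]$followups)) {
          wtsv(analysis[[meas]]$followups, sprintf("followups_%s.tsv", meas))
        }
        wtsv(analysis[[meas]]$cells_within, sprintf("cells_%s.tsv", meas))
      }
      summ <- do.call(rbind, lapply(names(analysis), function(meas) {
        cbind(measure = meas, analysis[[meas]]$cells_within)
      }))
      wtsv(summ, "cell_summary.tsv")
      # machine-readable twin of the effect/contrast/cell tables
      writeLines(yaml::as.yaml(lapply(unclass(analysis), function(x) {
        list(anova = unclass_deep(as.list(x$anova)),
             followups = if (!is.null(x$followups))
               unclass_deep(as.list(x$followups)),
             cells_within = unclass_deep(as.list(x$cells_within)),
             cells_between = unclass_deep(as.list(x$cells_between)))
      })), file.path(out_dir, "analysis.yaml"))
    }
    log_lines <- c(
      "# pipeline run log",
      yaml::as.yaml(unclass_deep(config)),
      if (!is.null(processed)) c(
        sprintf("overall_rejection_rate: %.4f",
                sum(processed$rejection$n_rejected) / sum(processed$rejection$n_epochs)),
        sprintf("excluded_participants: [%s]",
                paste(processed$exclusion$excluded, collapse = ", ")),
        sprintf("retained_participants: %d", length(processed$retained)))
    )
    writeLines(log_lines, file.path(out_dir, "log.txt"))
  }
  invisible(list(study = study, processed = processed, analysis = analysis))
}

# Strip S3 classes recursively so yaml serialisation is plain; element names
# (e.g. the design-cell names of the mean vectors) are kept.
unclass_deep <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    x <- lapply(x, unclass_deep)
    attributes(x) <- if (is.null(nm)) NULL else list(names = nm)
    x
  } else if (!is.null(names(x))) {
    as.list(x)                     # named atomics serialise as maps
  } else {
    unclass(x)
  }
}
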