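#' Write / read a continuous recording as delimited text
#'
#' Tab-separated, one row per sample: `time_s` plus one column per channel in
#' microvolts, preceded by comment lines carrying the sampling rate and
#' reference. Values are written with 6 decimals, so
#' `read_recording(write_recording(x))` reproduces `x` to 1e-6 uV. Unknown
#' extra columns are preserved on read.
#'
#' @param recording an [eeg_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  n <- nrow(recording$signals)
  df <- data.frame(time_s = sprintf("%.6f", (0:(n - 1)) / recording$fs))
  for (ch in colnames(recording$signals)) {
    df[[ch]] <- sprintf("%.6f", recording$signals[, ch])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate_hz: %g", recording$fs),
               sprintf("# reference: %s", recording$reference)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @param required_channels channels that must be present; a missing one is
#'   an error naming the file and channel.
#' @export
read_recording <- function(path, required_channels = muse_channels()) {
  header <- readLines(path, n = 10)
  meta <- grep("^#", header, value = TRUE)
  get_meta <- function(key, default) {
    hit <- grep(paste0("^# ", key, ":"), meta, value = TRUE)
    if (length(hit) == 0) return(default)
    trimws(sub(paste0("^# ", key, ":"), "", hit[1]))
  }
  fs <- as.numeric(get_meta("sampling_rate_hz", "256"))
  ref <- get_meta("reference", "FPz")
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE)
  missing <- setdiff(required_channels, names(df))
  assert_that(length(missing) == 0, "file '%s' is missing channel(s): %s",
              path, paste(missing, collapse = ", "))
  chans <- setdiff(names(df), "time_s")
  eeg_recording(as.matrix(df[, chans, drop = FALSE]), fs = fs, reference = ref)
}

#' Write / read an event stream as delimited text
#'
#' @param events marker data frame (`type`, `nominal_sample`,
#'   `marked_sample`, `responded`, `rt_ms`, plus any extra columns).
#' @param path file path.
#' @return `path` (write) or the events data frame (read).
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
}

#' Serialize a simulated study to a directory tree
#'
#' Layout: `participant_<i>/<cell>/{eeg.tsv,events.tsv}` plus a `manifest.tsv`
#' (participant, cell, paths, lag) and the configuration as `config.yaml`.
#'
#' @param study a `study_dataset`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (i in seq_along(study$participants)) {
    for (cl in design_cells()) {
      sub <- file.path(dir, sprintf("participant_%02d", i), cl)
      dir.create(sub, recursive = TRUE, showWarnings = FALSE)
      sess <- study$participants[[i]][[cl]]
      write_recording(sess$recording, file.path(sub, "eeg.tsv"))
      write_events(sess$events, file.path(sub, "events.tsv"))
      manifest[[length(manifest) + 1L]] <- data.frame(
        participant = i, cell = cl,
        eeg = file.path(sprintf("participant_%02d", i), cl, "eeg.tsv"),
        events = file.path(sprintf("participant_%02d", i), cl, "events.tsv"),
        lag_ms = sess$lag_ms)
    }
  }
  utils::write.table(do.call(rbind, manifest), file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(yaml::as.yaml(unclass_deep(study$config)),
             file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_study
#' @return `read_study()` returns a `study_dataset`-shaped list suitable for
#'   [process_study()].
#' @export
read_study <- function(dir) {
  man <- utils::read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                           sep = "\t", check.names = FALSE)
  ids <- sort(unique(man$participant))
  participants <- lapply(ids, function(i) {
    cells <- lapply(design_cells(), function(cl) {
      row <- man[man$participant == i & man$cell == cl, ]
      assert_that(nrow(row) == 1, "manifest lacks participant %d cell %s", i, cl)
      list(recording = read_recording(file.path(dir, row$eeg)),
           events = read_events(file.path(dir, row$events)),
           lag_ms = row$lag_ms)
    })
    names(cells) <- design_cells()
    cells
  })
  structure(list(config = NULL, participants = participants),
            class = "study_dataset")
}

#' Serialize an epoch set to a directory of delimited matrices
#'
#' One TSV per channel (rows = samples with a `time_ms` column, one column
#' per epoch) plus a `manifest.tsv` carrying the per-epoch metadata and
#' rejection flags and an `info.yaml` with the scalar fields.
#'
#' @param epochs an `epoch_set`.
#' @param dir output directory (created).
#' @return `dir` (write) / the reconstructed `epoch_set` (read).
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "epoch_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in dimnames(epochs$data)[[3]]) {
    m <- epochs$data[, , ch, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    df <- data.frame(time_ms = sprintf("%.6f", epochs$time_ms))
    for (j in seq_len(ncol(m))) df[[sprintf("epoch_%04d", j)]] <-
        sprintf("%.6f", m[, j])
    utils::write.table(df, file.path(dir, paste0(ch, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  man <- cbind(epochs$info, rejected = epochs$rejected)
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(yaml::as.yaml(list(fs = epochs$fs,
                                baseline_corrected = epochs$baseline_corrected,
                                n_dropped_boundary = epochs$n_dropped_boundary)),
             file.path(dir, "info.yaml"))
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  info <- yaml::read_yaml(file.path(dir, "info.yaml"))
  man <- utils::read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                           sep = "\t", check.names = FALSE)
  chans <- sub("\\.tsv$", "",
               setdiff(list.files(dir, pattern = "\\.tsv$"), "manifest.tsv"))
  mats <- lapply(chans, function(ch) {
    df <- utils::read.table(file.path(dir, paste0(ch, ".tsv")), header = TRUE,
                            sep = "\t", check.names = FALSE)
    list(time_ms = df$time_ms, m = as.matrix(df[, -1, drop = FALSE]))
  })
  dat <- array(0, dim = c(length(mats[[1]]$time_ms), nrow(man), length(chans)),
               dimnames = list(NULL, NULL, chans))
  for (k in seq_along(chans)) dat[, , k] <- mats[[k]]$m
  structure(list(data = dat, time_ms = mats[[1]]$time_ms,
                 info = man[, setdiff(names(man), "rejected"), drop = FALSE],
                 rejected = man$rejected,
                 n_dropped_boundary = info$n_dropped_boundary,
                 fs = info$fs, baseline_corrected = info$baseline_corrected),
            class = "epoch_set")
}

#' Write / read a pipeline configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` (write) or the reconstructed [run_config()] (read).
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  writeLines(yaml::as.yaml(unclass_deep(config)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  task <- do.call(task_config, y$study$task)
  study_args <- y$study
  study_args$task <- task
  study_args$cell_p300_means <- unlist(y$study$cell_p300_means)
  study_args$cell_rt_means <- unlist(y$study$cell_rt_means)
  run_config(
    study = do.call(study_config, study_args),
    filter = do.call(filter_spec, y$filter),
    reject_threshold_uV = y$reject_threshold_uV,
    max_rejected_fraction = y$max_rejected_fraction,
    alpha = y$alpha,
    stages = y$stages
  )
}

#' Adapter for externally deposited studies (stub)
#'
#' Public mobile-EEG oddball deposits come in heterogeneous layouts; this
#' adapter defines the interface such data must be mapped to — the
#' [write_study()] directory tree (per participant-cell `eeg.tsv` +
#' `events.tsv` plus a manifest) — after which [read_study()] and
#' [process_study()] run unchanged. No concrete deposit layout is bundled, so
#' calling this stub is an informative error describing the mapping.
#'
#' @param dir directory holding the external deposit.
#' @return does not return; raises an error describing the expected layout.
#' @export
read_external_study <- function(dir) {
  stop(paste(
    "no adapter is bundled for external deposits:",
    "convert the deposit to the write_study() layout",
    "(participant_<i>/<cell>/{eeg.tsv,events.tsv} with a manifest.tsv,",
    "cells inside_pre/inside_post/outside_pre/outside_post,",
    "eeg.tsv columns time_s, TP9, AF7, AF8, TP10 in microvolts,",
    "events.tsv columns type, nominal_sample, marked_sample, responded, rt_ms)",
    "and use read_study()."), call. = FALSE)
}
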