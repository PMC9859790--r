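#' Filter specification
#'
#' Zero-phase (dual-pass) Butterworth band-pass plus band-stop notch.
#' Defaults: 0.1-30 Hz pass-band and a 60 Hz notch (58-62 Hz stop-band),
#' 2nd order per pass (4th-order effective after the forward-backward pass).
#'
#' @param highpass high-pass edge, Hz.
#' @param lowpass low-pass edge, Hz.
#' @param notch notch centre, Hz (`NULL` disables).
#' @param notch_halfwidth half width of the stop band, Hz.
#' @param order Butterworth order per pass.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(highpass = 0.1, lowpass = 30, notch = 60,
                        notch_halfwidth = 2, order = 2) {
  assert_that(highpass > 0 && highpass < lowpass,
              "need 0 < highpass < lowpass")
  assert_that(order >= 1, "order must be >= 1")
  structure(list(highpass = highpass, lowpass = lowpass, notch = notch,
                 notch_halfwidth = notch_halfwidth, order = as.integer(order)),
            class = "filter_spec")
}

# Direct-form IIR with zero initial conditions, all columns at once
# (compiled direct-form II transposed).
iir_filter <- function(b, a, x) {
  df2_filter(as.numeric(b), as.numeric(a), x)
}

# Forward-backward filtering with odd-reflection padding at both ends.
# Padding suppresses edge transients (important for the 0.1 Hz high-pass);
# the pad is clipped to n - 1 samples. x is a samples x channels matrix.
zero_phase_filter <- function(b, a, x, pad) {
  n <- nrow(x)
  pad <- min(pad, n - 1L)
  if (pad > 0) {
    front <- 2 * x[rep(1L, pad), , drop = FALSE] - x[(pad + 1L):2L, , drop = FALSE]
    back <- 2 * x[rep(n, pad), , drop = FALSE] - x[(n - 1L):(n - pad), , drop = FALSE]
    ext <- rbind(front, x, back)
  } else ext <- x
  y <- iir_filter(b, a, ext)
  y <- iir_filter(b, a, y[nrow(y):1, , drop = FALSE])
  y <- y[nrow(y):1, , drop = FALSE]
  y[(pad + 1L):(pad + n), , drop = FALSE]
}

#' Apply zero-phase band-pass and notch filters
#'
#' Each channel is filtered forward and backward (so phase distortion
#' cancels) with a Butterworth band-pass and then a Butterworth band-stop
#' notch. Output length equals input length.
#'
#' @param recording an [eeg_recording()].
#' @param spec a [filter_spec()].
#' @return the filtered [eeg_recording()].
#' @export
apply_filters <- function(recording, spec = filter_spec()) {
  stopifnot(inherits(recording, "eeg_recording"), inherits(spec, "filter_spec"))
  nyq <- recording$fs / 2
  assert_that(spec$lowpass < nyq, "lowpass edge must be below Nyquist (%g Hz)", nyq)
  if (!is.null(spec$notch)) {
    assert_that(spec$notch + spec$notch_halfwidth < nyq,
                "notch band must be below Nyquist (%g Hz)", nyq)
  }
  bp <- signal::butter(spec$order, c(spec$highpass, spec$lowpass) / nyq, "pass")
  bs <- if (!is.null(spec$notch)) {
    signal::butter(spec$order,
                   c(spec$notch - spec$notch_halfwidth,
                     spec$notch + spec$notch_halfwidth) / nyq, "stop")
  }
  pad <- min(nrow(recording$signals) - 1L, 3L * round(recording$fs))
  out <- zero_phase_filter(bp$b, bp$a, recording$signals, pad)
  if (!is.null(bs)) out <- zero_phase_filter(bs$b, bs$a, out, pad)
  colnames(out) <- colnames(recording$signals)
  recording$signals <- out
  recording
}

#' Per-channel signal-quality report (rolling variance gate)
#'
#' Mirrors the acquisition-time quality criterion of consumer headband
#' protocols: a channel passes when the variance in every non-overlapping
#' 1-second window stays below the threshold. Offline the gate is advisory: it
#' is reported and logged, never used to drop data silently.
#'
#' @param recording an [eeg_recording()].
#' @param window_s window length in seconds.
#' @param threshold variance threshold in uV^2 (strict `<` passes).
#' @return data frame with one row per channel: `channel`, `max_variance`,
#'   `pass`.
#' @export
quality_gate <- function(recording, window_s = 1, threshold = 200) {
  stopifnot(inherits(recording, "eeg_recording"))
  w <- round(window_s * recording$fs)
  n <- nrow(recording$signals)
  assert_that(n >= w, "recording shorter than the quality window")
  n_win <- n %/% w
  res <- apply(recording$signals, 2, function(x) {
    m <- matrix(x[seq_len(n_win * w)], nrow = w)
    max((colSums(m^2) - colSums(m)^2 / w) / (w - 1))
  })
  data.frame(channel = colnames(recording$signals),
             max_variance = as.numeric(res),
             pass = as.numeric(res) < threshold,
             row.names = NULL)
}

#' Pool physical channels into frontal and posterior virtual electrodes
#'
#' frontal = mean(AF7, AF8) per sample; posterior = mean(TP9, TP10).
#'
#' @param recording an [eeg_recording()] containing the four channels.
#' @return an [eeg_recording()] with channels `frontal` and `posterior`.
#' @export
pool_electrodes <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  have <- colnames(recording$signals)
  missing <- setdiff(muse_channels(), have)
  assert_that(length(missing) == 0, "missing channel(s): %s",
              paste(missing, collapse = ", "))
  s <- recording$signals
  pooled <- cbind(frontal = (s[, "AF7"] + s[, "AF8"]) / 2,
                  posterior = (s[, "TP9"] + s[, "TP10"]) / 2)
  recording$signals <- pooled
  recording
}

#' Extract stimulus-locked epochs
#'
#' Per marker, slices `[onset - round(|tmin|/1000 * fs), onset +
#' round(tmax/1000 * fs)]` inclusive (51 pre + 154 post + onset = 206 samples
#' at 256 Hz for the default -200..+600 ms window). Markers whose window
#' exceeds the recording are dropped and counted. Sample indices are 0-based;
#' the onset sample belongs to the post-stimulus side (time 0).
#'
#' @param recording a filtered, pooled [eeg_recording()].
#' @param events data frame of markers; the column named by `onset_column`
#'   holds 0-based onset samples.
#' @param tmin_ms,tmax_ms epoch window relative to onset, ms.
#' @param onset_column which marker column to lock to (`"marked_sample"` in
#'   the standard pipeline; `"nominal_sample"` for lag-free checks).
#' @return object of class `epoch_set`: list with `data` (array time x epoch
#'   x channel), `time_ms`, `info` (marker rows kept), `rejected` (all
#'   `FALSE` initially), `n_dropped_boundary`, `fs`, `baseline_corrected`.
#' @export
extract_epochs <- function(recording, events, tmin_ms = -200, tmax_ms = 600,
                           onset_column = "marked_sample") {
  stopifnot(inherits(recording, "eeg_recording"))
  assert_that(onset_column %in% names(events),
              "events lack onset column '%s'", onset_column)
  fs <- recording$fs
  pre <- ms_to_samples(abs(tmin_ms), fs)
  post <- ms_to_samples(tmax_ms, fs)
  n <- nrow(recording$signals)
  onsets <- events[[onset_column]]
  keep <- onsets - pre >= 0 & onsets + post <= n - 1L
  n_dropped <- sum(!keep)
  if (!any(keep)) {
    warning("no markers with a complete epoch window; empty epoch set")
  }
  onsets <- onsets[keep]
  rel <- (-pre):post
  time_ms <- rel / fs * 1000
  chans <- colnames(recording$signals)
  dat <- array(0, dim = c(length(rel), length(onsets), length(chans)),
               dimnames = list(NULL, NULL, chans))
  if (length(onsets) > 0) {
    idx <- outer(rel, onsets, `+`) + 1L       # samples x epochs, 1-based
    for (ch in chans) dat[, , ch] <- recording$signals[, ch][idx]
  }
  structure(list(
    data = dat, time_ms = time_ms,
    info = events[keep, , drop = FALSE],
    rejected = rep(FALSE, length(onsets)),
    n_dropped_boundary = n_dropped, fs = fs,
    baseline_corrected = FALSE
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set> %d epochs x %d samples (%.0f..%.0f ms) x %d channel(s); %d rejected, %d dropped at boundary\n",
    dim(x$data)[2], dim(x$data)[1], min(x$time_ms), max(x$time_ms),
    dim(x$data)[3], sum(x$rejected), x$n_dropped_boundary))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the pre-stimulus window
#' (time < 0 ms; with the default window, the 200 ms preceding onset).
#'
#' @param epochs an [extract_epochs()] result containing the pre-stimulus window.
#' @return the corrected `epoch_set` (`baseline_corrected = TRUE`).
#' @export
baseline_correct <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  base_idx <- which(epochs$time_ms < 0)
  assert_that(length(base_idx) > 0, "epochs lack a pre-stimulus baseline window")
  for (ch in seq_len(dim(epochs$data)[3])) {
    means <- colMeans(epochs$data[base_idx, , ch, drop = FALSE])
    epochs$data[, , ch] <- sweep(epochs$data[, , ch, drop = FALSE], 2, means)
  }
  epochs$baseline_corrected <- TRUE
  epochs
}

#' Flag artifact epochs by peak-to-peak range
#'
#' An epoch is rejected when the within-epoch range (max - min) exceeds the
#' threshold on *any* channel (strict `>`: exactly 60 uV is retained).
#'
#' @param epochs a baseline-corrected `epoch_set`.
#' @param threshold_uV rejection threshold, uV.
#' @return the `epoch_set` with `rejected` flags and a `rejection_rate` field.
#' @export
reject_artifacts <- function(epochs, threshold_uV = 60) {
  stopifnot(inherits(epochs, "epoch_set"))
  n_ep <- dim(epochs$data)[2]
  rej <- rep(FALSE, n_ep)
  for (ch in seq_len(dim(epochs$data)[3])) {
    m <- epochs$data[, , ch, drop = FALSE]
    dim(m) <- dim(m)[1:2]
    rng <- apply(m, 2, function(v) max(v) - min(v))
    rej <- rej | (rng > threshold_uV)
  }
  epochs$rejected <- rej
  epochs$rejection_rate <- if (n_ep > 0) mean(rej) else NA_real_
  epochs
}

#' Exclude participants with excessive artifact rejection
#'
#' A participant is excluded when strictly more than `max_rejected_fraction`
#' of their epochs (pooled over all sessions) were rejected; exactly the
#' threshold is retained.
#'
#' @param rejection data frame with columns `participant`, `n_epochs`,
#'   `n_rejected` (one row per participant-session or per participant).
#' @param max_rejected_fraction exclusion threshold.
#' @return list with `retained` and `excluded` participant ids and the
#'   per-participant `fractions`.
#' @export
exclude_participants <- function(rejection, max_rejected_fraction = 0.5) {
  assert_that(all(c("participant", "n_epochs", "n_rejected") %in% names(rejection)),
              "rejection table needs participant, n_epochs, n_rejected")
  tot <- tapply(rejection$n_epochs, rejection$participant, sum)
  rej <- tapply(rejection$n_rejected, rejection$participant, sum)
  frac <- as.numeric(rej / tot)
  ids <- names(tot)
  excluded <- ids[frac > max_rejected_fraction]
  retained <- setdiff(ids, excluded)
  if (length(retained) == 0) {
    stop("all participants excluded by the artifact criterion", call. = FALSE)
  }
  list(retained = retained, excluded = excluded,
       fractions = stats::setNames(frac, ids))
}
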