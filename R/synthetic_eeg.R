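#' Continuous EEG recording container
#'
#' @param signals numeric matrix, samples x channels, in microvolts; column
#'   names are channel labels (the simulator uses TP9, AF7, AF8, TP10).
#' @param fs sampling rate in Hz.
#' @param reference reference electrode label.
#' @return object of class `eeg_recording`.
#' @export
eeg_recording <- function(signals, fs = 256, reference = "FPz") {
  signals <- as.matrix(signals)
  assert_that(fs > 0, "sampling rate must be > 0")
  assert_that(!is.null(colnames(signals)), "signals must have channel names")
  structure(list(signals = signals, fs = fs, reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x %d channels (%s) @ %g Hz, ref %s (%.1f s)\n",
              nrow(x$signals), ncol(x$signals),
              paste(colnames(x$signals), collapse = ", "),
              x$fs, x$reference, nrow(x$signals) / x$fs))
  invisible(x)
}

#' ERP template: a negative N200 and a positive P300 Gaussian
#'
#' The component waveshape is modelled as the sum of two Gaussian bumps: a
#' negative one around 200 ms (N200) and a positive one around 400 ms (P300).
#' Widths are Gaussian standard deviations in milliseconds.
#'
#' @param p300_amplitude P300 peak amplitude in microvolts (0 suppresses it).
#' @param n200_amplitude N200 peak amplitude in microvolts (negative).
#' @param n200_latency,p300_latency peak latencies in ms post-stimulus.
#' @param n200_width,p300_width Gaussian SDs in ms, > 0.
#' @return object of class `erp_template`.
#' @export
erp_template <- function(p300_amplitude,
                         n200_amplitude = -1.0,
                         n200_latency = 200, n200_width = 30,
                         p300_latency = 400, p300_width = 60) {
  assert_that(n200_width > 0 && p300_width > 0, "template widths must be > 0")
  assert_that(n200_latency >= 0 && p300_latency >= 0,
              "latencies must be non-negative")
  structure(list(n200_amplitude = n200_amplitude, n200_latency = n200_latency,
                 n200_width = n200_width, p300_amplitude = p300_amplitude,
                 p300_latency = p300_latency, p300_width = p300_width),
            class = "erp_template")
}

#' Evaluate an ERP template on a sample grid
#'
#' @param template an [erp_template()].
#' @param sampling_rate Hz.
#' @param duration_ms template support, from 0 to `duration_ms` post-stimulus;
#'   must cover both component latencies.
#' @return numeric vector of length `round(duration_ms/1000 * fs) + 1`.
#' @export
make_erp_template <- function(template, sampling_rate = 256, duration_ms = 600) {
  stopifnot(inherits(template, "erp_template"))
  assert_that(duration_ms >= max(template$n200_latency, template$p300_latency),
              "duration_ms must cover both component latencies")
  t_ms <- (0:ms_to_samples(duration_ms, sampling_rate)) / sampling_rate * 1000
  template$n200_amplitude * exp(-(t_ms - template$n200_latency)^2 /
                                  (2 * template$n200_width^2)) +
    template$p300_amplitude * exp(-(t_ms - template$p300_latency)^2 /
                                    (2 * template$p300_width^2))
}

#' Study-level simulation configuration
#'
#' Defines a 2 (location: inside, outside) x 2 (time: pre, post) fully
#' within-subject oddball study on a 4-channel headband. Per-cell P300
#' amplitude and reaction-time targets default to the canonical mobile-EEG
#' walking-study cell means; noise and artifact levels default to values
#' calibrated so that, at n = 30 with four 100-trial blocks per cell, the
#' location x time interaction is detectable with moderate power and roughly
#' 30% of epochs are rejected by the 60 uV artifact criterion (see the
#' methods vignette for the calibration arithmetic).
#'
#' @param n_participants number of simulated participants (>= 2).
#' @param cell_p300_means named numeric, oddball P300 amplitude (uV) per cell
#'   (`design_cells()` order).
#' @param cell_rt_means named numeric, mean reaction time (ms) per cell.
#' @param between_participant_sd_uV SD of the participant-level P300 offset.
#' @param between_participant_sd_ms SD of the participant-level RT offset.
#' @param trial_noise_sd SD (uV) of the single-trial P300 amplitude around the
#'   cell mean (applied to P300-bearing trials).
#' @param rt_sd_ms SD (ms) of the single-trial reaction time.
#' @param rt_shift_ms shift of the shifted-lognormal RT distribution.
#' @param noise_amplitude RMS (uV) of the 1/f background noise.
#' @param noise_exponent spectral exponent of the background (1 = pink).
#' @param blink_rate blinks per minute (Poisson).
#' @param blink_amplitude blink peak amplitude (uV) on the frontal channels.
#' @param blink_duration_ms blink duration (raised-cosine lobe).
#' @param blink_posterior_scale blink attenuation on TP9/TP10.
#' @param erp_frontal_scale ERP attenuation on AF7/AF8.
#' @param marker_lag_mean_ms,marker_lag_sd_ms Bluetooth marker lag: one
#'   constant per recording, drawn Normal(mean, sd) across recordings.
#' @param error_rate per-trial probability of a behavioural error (miss on
#'   oddball, false alarm on control).
#' @param n200_amplitude N200 peak amplitude (uV), shared by both conditions.
#' @param sampling_rate Hz.
#' @param task a [task_config()] describing each cell's oddball session.
#' @param seed master seed expanded into per-participant, per-cell sub-streams.
#' @return object of class `study_config`.
#' @export
study_config <- function(n_participants = 30,
                         cell_p300_means = c(inside_pre = 1.5, inside_post = 1.6,
                                             outside_pre = 1.4, outside_post = 2.4),
                         cell_rt_means = c(inside_pre = 220.1, inside_post = 218.1,
                                           outside_pre = 221.0, outside_post = 213.3),
                         between_participant_sd_uV = 2.0,
                         between_participant_sd_ms = 25,
                         trial_noise_sd = 8,
                         rt_sd_ms = 85,
                         rt_shift_ms = 100,
                         noise_amplitude = 4,
                         noise_exponent = 1,
                         blink_rate = 22,
                         blink_amplitude = 150,
                         blink_duration_ms = 300,
                         blink_posterior_scale = 0.5,
                         erp_frontal_scale = 0.3,
                         marker_lag_mean_ms = 19,
                         marker_lag_sd_ms = 5,
                         error_rate = 0.003,
                         n200_amplitude = -1.0,
                         sampling_rate = 256,
                         task = task_config(),
                         seed = 1L) {
  assert_that(n_participants >= 2, "n_participants must be >= 2")
  assert_that(all(c(between_participant_sd_uV, between_participant_sd_ms,
                    trial_noise_sd, rt_sd_ms, noise_amplitude, blink_rate,
                    marker_lag_sd_ms) >= 0), "SDs and rates must be >= 0")
  assert_that(error_rate >= 0 && error_rate <= 1, "error_rate must be in [0, 1]")
  cells <- design_cells()
  cell_p300_means <- cell_p300_means[cells]
  cell_rt_means <- cell_rt_means[cells]
  assert_that(!anyNA(cell_p300_means) && !anyNA(cell_rt_means),
              "cell means must be named for all four design cells")
  structure(list(
    n_participants = as.integer(n_participants),
    cell_p300_means = cell_p300_means, cell_rt_means = cell_rt_means,
    between_participant_sd_uV = between_participant_sd_uV,
    between_participant_sd_ms = between_participant_sd_ms,
    trial_noise_sd = trial_noise_sd, rt_sd_ms = rt_sd_ms,
    rt_shift_ms = rt_shift_ms,
    noise_amplitude = noise_amplitude, noise_exponent = noise_exponent,
    blink_rate = blink_rate, blink_amplitude = blink_amplitude,
    blink_duration_ms = blink_duration_ms,
    blink_posterior_scale = blink_posterior_scale,
    erp_frontal_scale = erp_frontal_scale,
    marker_lag_mean_ms = marker_lag_mean_ms,
    marker_lag_sd_ms = marker_lag_sd_ms,
    error_rate = error_rate, n200_amplitude = n200_amplitude,
    sampling_rate = sampling_rate, task = task,
    seed = as.integer(seed)
  ), class = "study_config")
}

#' Variance-matched reduced configuration for replicate simulations
#'
#' Monte-Carlo studies (power, bias, calibration) need hundreds of simulated
#' studies; running every replicate at the full four-blocks-of-100 session
#' length is wasteful. This configuration shrinks each cell to one 50-trial
#' block and rescales the noise sources so the standard error of every
#' cell-level estimate matches the full-scale design:
#' with `K` retained oddballs and `L` retained controls, the P300 cell-mean
#' SD is `sqrt(trial_noise_sd^2 / K + noise_amplitude^2 (1/K + 1/L) r^2)`
#' (with `r` the per-epoch residual factor), and the RT cell SD is
#' `rt_sd_ms / sqrt(hits)`; equating those between 400 trials at the default
#' noise levels and 50 trials yields `noise_amplitude = 1.41`,
#' `trial_noise_sd = 2.83`, `rt_sd_ms = 30` (see the methods vignette).
#' Everything else (n = 30, cell means, blink rate, lag model) is unchanged.
#'
#' @param seed master seed for the replicate.
#' @param ... overrides passed on to [study_config()].
#' @return a [study_config()].
#' @export
replicate_study_config <- function(seed, ...) {
  study_config(task = task_config(n_blocks = 1, trials_per_block = 50),
               noise_amplitude = 1.41, trial_noise_sd = 2.83, rt_sd_ms = 30,
               seed = seed, ...)
}

muse_channels <- function() c("TP9", "AF7", "AF8", "TP10")
frontal_channels <- function() c("AF7", "AF8")
posterior_channels <- function() c("TP9", "TP10")

#' Generate 1/f^a background noise
#'
#' White Gaussian noise spectrally shaped in the frequency domain so the
#' power spectrum falls as `f^-noise_exponent`, then normalised to the target
#' RMS. The DC bin is zeroed.
#'
#' @param duration_s duration in seconds (> 0).
#' @param config a [study_config()] (fields `noise_amplitude`,
#'   `noise_exponent`, `sampling_rate`).
#' @return numeric vector of `round(duration_s * fs)` samples (one channel).
#' @export
generate_background <- function(duration_s, config = study_config()) {
  assert_that(duration_s > 0, "duration must be > 0")
  shaped_noise(round(duration_s * config$sampling_rate), 1L, config)[, 1]
}

# 1/f^a shaped Gaussian noise, n samples x n_channels. The FFT length is
# padded to a 2-3-5-smooth value (mixed-radix FFTs crawl on near-prime
# lengths) and channels are generated pairwise through one complex FFT
# (the spectral envelope is real and symmetric, so the real and imaginary
# parts carry two independent shaped channels).
shaped_noise <- function(n, n_channels, config) {
  if (config$noise_amplitude == 0) return(matrix(0, n, n_channels))
  nfft <- stats::nextn(n, c(2, 3, 5))
  k <- 0:(nfft - 1)
  f <- pmin(k, nfft - k) * config$sampling_rate / nfft  # folded frequency per bin
  scale <- numeric(nfft)
  pos <- f > 0
  scale[pos] <- f[pos]^(-config$noise_exponent / 2)
  out <- matrix(0, n, n_channels)
  ch <- 1L
  while (ch <= n_channels) {
    if (ch + 1L <= n_channels) {
      w <- complex(real = stats::rnorm(nfft), imaginary = stats::rnorm(nfft))
      z <- stats::fft(stats::fft(w) * scale, inverse = TRUE)[seq_len(n)] / nfft
      out[, ch] <- Re(z)
      out[, ch + 1L] <- Im(z)
      ch <- ch + 2L
    } else {
      w <- stats::rnorm(nfft)
      out[, ch] <- Re(stats::fft(stats::fft(w) * scale,
                                 inverse = TRUE))[seq_len(n)] / nfft
      ch <- ch + 1L
    }
  }
  out <- sweep(out, 2, colMeans(out))
  sweep(out, 2, config$noise_amplitude / sqrt(colMeans(out^2)), "*")
}

# Raised-cosine blink lobe; odd length so the grid hits the peak exactly.
blink_template <- function(amplitude, duration_ms, fs) {
  n <- ms_to_samples(duration_ms, fs) + 1L
  if (n %% 2L == 0L) n <- n + 1L
  amplitude * 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n)))
}

#' Inject blink artifacts into a recording
#'
#' Blinks are raised-cosine lobes at Poisson-random onsets: full amplitude on
#' the frontal channels (AF7, AF8), attenuated (default 0.5x) on the
#' posterior channels (TP9, TP10).
#'
#' @param recording an [eeg_recording()] with the four headband channels.
#' @param config a [study_config()].
#' @return list with elements `recording` (contaminated copy) and
#'   `blink_onsets` (0-based onset samples, exhaustive, sorted).
#' @export
inject_blinks <- function(recording, config = study_config()) {
  stopifnot(inherits(recording, "eeg_recording"))
  n <- nrow(recording$signals)
  tmpl <- blink_template(config$blink_amplitude, config$blink_duration_ms,
                         recording$fs)
  assert_that(length(tmpl) < n, "blink template must be shorter than recording")
  if (config$blink_rate == 0) {
    return(list(recording = recording, blink_onsets = integer(0)))
  }
  n_blinks <- stats::rpois(1, config$blink_rate * n / recording$fs / 60)
  if (n_blinks == 0) {
    return(list(recording = recording, blink_onsets = integer(0)))
  }
  onsets <- sort(sample.int(n - length(tmpl) + 1L, n_blinks, replace = TRUE) - 1L)
  sig <- recording$signals
  for (o in onsets) {
    idx <- (o + 1L):(o + length(tmpl))
    for (ch in frontal_channels()) sig[idx, ch] <- sig[idx, ch] + tmpl
    for (ch in posterior_channels()) {
      sig[idx, ch] <- sig[idx, ch] + config$blink_posterior_scale * tmpl
    }
  }
  recording$signals <- sig
  list(recording = recording, blink_onsets = onsets)
}

#' Simulate one continuous oddball recording with event markers
#'
#' Builds the recording as an exact superposition of 1/f background noise,
#' blink artifacts, and condition-appropriate ERP templates added at each
#' nominal stimulus onset: full amplitude on the posterior channels,
#' `erp_frontal_scale` on the frontal ones. Single-trial P300 amplitudes of
#' P300-bearing trials are jittered Normal(0, `trial_noise_sd`).
#'
#' Event marking emulates a Bluetooth-lagged stream: one constant per-recording
#' lag is drawn Normal(`marker_lag_mean_ms`, `marker_lag_sd_ms`); the marked
#' sample is the sample that had arrived when the stimulus was drawn, i.e.
#' `marked_sample = nominal_sample - lag_in_samples`, so the ERP appears
#' `lag` milliseconds *after* the marker. The lag does not vary within a
#' recording.
#'
#' @param seq a `trial_sequence` (nonempty).
#' @param templates list with `erp_template` entries `oddball` and `control`.
#' @param config a [study_config()].
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @param keep_components if `TRUE`, attach the background / blink / ERP
#'   component matrices as attribute `"components"` (for superposition checks).
#' @return list with `recording` ([eeg_recording()]), `events` (data frame:
#'   sequence columns + `nominal_sample`, `marked_sample`), `lag_ms`,
#'   `blink_onsets`.
#' @export
generate_recording <- function(seq, templates, config = study_config(),
                               seed = NULL, keep_components = FALSE) {
  assert_that(nrow(seq) > 0, "trial sequence must be nonempty")
  stopifnot(inherits(templates$oddball, "erp_template"),
            inherits(templates$control, "erp_template"))
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sampling_rate
  lead_in <- fs                                   # 1 s lead-in before first trial
  ev <- sequence_to_onsets(seq, fs, lead_in_samples = lead_in)
  n <- max(ev$nominal_sample) + ms_to_samples(1000, fs) + 1L  # 1 s tail

  chans <- muse_channels()
  bg <- shaped_noise(n, 4L, config)
  colnames(bg) <- chans
  blank <- eeg_recording(matrix(0, n, 4, dimnames = list(NULL, chans)), fs)
  bl <- inject_blinks(blank, config)
  blink_mat <- bl$recording$signals

  # Per-condition shapes: shared N200 + unit P300 bump, composed per trial.
  tmpl_len <- ms_to_samples(600, fs) + 1L
  shapes <- lapply(templates, function(tp) {
    base <- make_erp_template(erp_template(p300_amplitude = 0,
                                           n200_amplitude = tp$n200_amplitude,
                                           n200_latency = tp$n200_latency,
                                           n200_width = tp$n200_width), fs, 600)
    p300u <- make_erp_template(erp_template(p300_amplitude = 1, n200_amplitude = 0,
                                            p300_latency = tp$p300_latency,
                                            p300_width = tp$p300_width), fs, 600)
    list(base = base, p300u = p300u, amp = tp$p300_amplitude)
  })
  if (length(make_erp_template(templates$oddball, fs, 600)) >
      min(ms_to_samples(seq$fixation_ms + seq$stimulus_ms, fs))) {
    warning("ERP template longer than shortest inter-stimulus interval; overlap allowed")
  }

  erp_mat <- matrix(0, n, 4, dimnames = list(NULL, chans))
  post_col <- rep(0, n)
  for (i in seq_len(nrow(ev))) {
    sh <- shapes[[ev$type[i]]]
    amp <- sh$amp
    if (amp != 0 && config$trial_noise_sd > 0) {
      amp <- amp + stats::rnorm(1, 0, config$trial_noise_sd)
    }
    idx <- (ev$nominal_sample[i] + 1L):(ev$nominal_sample[i] + tmpl_len)
    post_col[idx] <- post_col[idx] + sh$base + amp * sh$p300u
  }
  for (ch in posterior_channels()) erp_mat[, ch] <- post_col
  for (ch in frontal_channels()) erp_mat[, ch] <- config$erp_frontal_scale * post_col

  sig <- bg + blink_mat + erp_mat
  rec <- eeg_recording(sig, fs)
  if (keep_components) {
    attr(rec, "components") <- list(background = bg, blinks = blink_mat, erp = erp_mat)
  }

  lag_ms <- stats::rnorm(1, config$marker_lag_mean_ms, config$marker_lag_sd_ms)
  ev$marked_sample <- ev$nominal_sample - ms_to_samples(lag_ms, fs)

  list(recording = rec, events = ev, lag_ms = lag_ms, blink_onsets = bl$blink_onsets)
}

#' Simulate behavioural responses for one session
#'
#' Oddball-trial reaction times follow a shifted lognormal with mean
#' `cell_rt_means[cell] + participant_shift` and SD `rt_sd_ms`; misses
#' (oddball without response) and false alarms (response to a control) occur
#' independently with probability `error_rate`. Missed trials carry no RT.
#'
#' @param seq a `trial_sequence`.
#' @param cell one of [design_cells()].
#' @param config a [study_config()].
#' @param participant_shift participant-level RT offset in ms.
#' @param seed optional seed.
#' @return data frame with columns `responded` (logical) and `rt_ms`.
#' @export
generate_behaviour <- function(seq, cell, config = study_config(),
                               participant_shift = 0, seed = NULL) {
  cell <- match.arg(cell, design_cells())
  if (!is.null(seed)) set.seed(seed)
  target <- config$cell_rt_means[[cell]] + participant_shift
  m <- target - config$rt_shift_ms
  assert_that(m > 0, "RT target must exceed the lognormal shift (%g ms)",
              config$rt_shift_ms)
  n <- nrow(seq)
  draw_rt <- function(k) {
    if (k == 0) return(numeric(0))
    if (config$rt_sd_ms == 0) return(rep(target, k))
    sdlog2 <- log(1 + config$rt_sd_ms^2 / m^2)
    config$rt_shift_ms + stats::rlnorm(k, log(m) - sdlog2 / 2, sqrt(sdlog2))
  }
  err <- stats::runif(n) < config$error_rate
  is_odd <- seq$type == "oddball"
  responded <- (is_odd & !err) | (!is_odd & err)
  rt <- rep(NA_real_, n)
  rt[responded] <- draw_rt(sum(responded))
  data.frame(responded = responded, rt_ms = rt)
}

#' Simulate a full 2 x 2 within-subject study
#'
#' For each participant, draws one P300 offset and one RT offset (Normal,
#' between-participant SDs; the RT offset is truncated at +/- 3 SD so the
#' shifted-lognormal RT mean stays above its shift) applied identically to
#' that participant's four sessions, then simulates one oddball session
#' (recording + events + behaviour) per design cell. The master seed is expanded into
#' per-participant, per-cell sub-streams, so datasets are bit-identical for
#' identical configurations and adding participants does not reshuffle
#' existing ones.
#'
#' @param config a [study_config()].
#' @return object of class `study_dataset`: list with `config` and
#'   `participants`, each participant a list of four cells, each cell a list
#'   with `recording`, `events` (markers + `responded`, `rt_ms`), `lag_ms`,
#'   `blink_onsets`, `p300_truth` (the participant-and-cell true amplitude).
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  cells <- design_cells()
  participants <- vector("list", config$n_participants)
  for (i in seq_len(config$n_participants)) {
    set.seed(derive_seed(config$seed, i, 0))
    shift_uV <- stats::rnorm(1, 0, config$between_participant_sd_uV)
    # RT offsets truncated at +/- 3 SD so no cell's mean RT can fall below
    # the lognormal shift (a physically impossible parameterisation)
    s_ms <- config$between_participant_sd_ms
    shift_ms <- max(-3 * s_ms, min(3 * s_ms, stats::rnorm(1, 0, s_ms)))
    p_cells <- vector("list", length(cells))
    names(p_cells) <- cells
    for (ci in seq_along(cells)) {
      set.seed(derive_seed(config$seed, i, ci))
      tc <- config$task
      tc$seed <- NULL                       # sub-stream already seeded
      sq <- generate_trial_sequence(tc)
      amp <- config$cell_p300_means[[cells[ci]]] + shift_uV
      templates <- list(
        oddball = erp_template(p300_amplitude = amp,
                               n200_amplitude = config$n200_amplitude),
        control = erp_template(p300_amplitude = 0,
                               n200_amplitude = config$n200_amplitude)
      )
      sim <- generate_recording(sq, templates, config)
      beh <- generate_behaviour(sq, cells[ci], config, shift_ms)
      sim$events$responded <- beh$responded
      sim$events$rt_ms <- beh$rt_ms
      p_cells[[ci]] <- list(recording = sim$recording, events = sim$events,
                            lag_ms = sim$lag_ms, blink_onsets = sim$blink_onsets,
                            p300_truth = amp)
    }
    participants[[i]] <- p_cells
  }
  structure(list(config = config, participants = participants),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d participants x %d cells (%s), seed %d\n",
              length(x$participants), length(design_cells()),
              paste(design_cells(), collapse = ", "), x$config$seed))
  invisible(x)
}
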