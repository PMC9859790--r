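# Shared fixtures and independent oracles used across test files.

# Small, fast task: one 20-trial block.
quick_task <- function(seed = NULL, trials = 20, blocks = 1) {
  task_config(n_blocks = blocks, trials_per_block = trials, seed = seed)
}

# Fully deterministic, noise-free study configuration (single recording use).
noiseless_config <- function(..., task = quick_task()) {
  study_config(noise_amplitude = 0, blink_rate = 0, trial_noise_sd = 0,
               between_participant_sd_uV = 0, between_participant_sd_ms = 0,
               rt_sd_ms = 0, error_rate = 0, marker_lag_sd_ms = 0,
               task = task, ...)
}

# A four-channel zero recording of n samples.
zero_recording <- function(n, fs = 256) {
  eeg_recording(matrix(0, n, 4, dimnames = list(NULL, c("TP9", "AF7", "AF8", "TP10"))),
                fs = fs)
}

# Independent brute-force peak scan: largest strict local extremum in window
# (random continuous waves have no ties, so plateau logic is irrelevant here).
oracle_peak <- function(values, time_ms, window, maximum = TRUE) {
  v <- if (maximum) values else -values
  best <- NA_integer_; best_val <- -Inf
  for (i in seq_along(v)) {
    if (i == 1 || i == length(v)) next
    if (time_ms[i] < window[1] || time_ms[i] > window[2]) next
    if (v[i] > v[i - 1] && v[i] > v[i + 1] && v[i] > best_val) {
      best <- i; best_val <- v[i]
    }
  }
  if (is.na(best)) {
    inw <- which(time_ms >= window[1] & time_ms <= window[2])
    best <- inw[which.max(v[inw])]
    local <- FALSE
  } else local <- TRUE
  list(amplitude = values[best], latency = time_ms[best], is_local = local)
}

# A smooth random waveform on the standard epoch axis.
random_smooth_wave <- function(time_ms) {
  n <- length(time_ms)
  x <- stats::rnorm(n)
  sm <- stats::filter(x, rep(1 / 7, 7), sides = 2)
  sm[is.na(sm)] <- 0
  erp_waveform(as.numeric(sm), time_ms, kind = "difference")
}

# Standard -200..+600 ms epoch time axis at fs.
epoch_axis <- function(fs = 256) {
  (-round(0.2 * fs):round(0.6 * fs)) / fs * 1000
}

# Random cell matrix with participant structure.
random_cell_matrix <- function(n = 12, sd_subj = 1, sd_noise = 1) {
  m <- matrix(stats::rnorm(n * 4, sd = sd_noise), n, 4,
              dimnames = list(NULL, design_cells()))
  m + stats::rnorm(n, sd = sd_subj)
}

# Independent RM-ANOVA oracle via stats::aov with an Error stratum.
oracle_aov <- function(m) {
  n <- nrow(m)
  d <- data.frame(
    y = as.vector(m),
    subj = factor(rep(seq_len(n), 4)),
    loc = factor(rep(c("in", "in", "out", "out"), each = n)),
    time = factor(rep(c("pre", "post", "pre", "post"), each = n))
  )
  fit <- stats::aov(y ~ loc * time + Error(subj / (loc * time)), data = d)
  s <- summary(fit)
  get_f <- function(stratum, term) {
    tab <- s[[stratum]][[1]]
    tab[trimws(rownames(tab)) == term, "F value"]
  }
  c(location = get_f("Error: subj:loc", "loc"),
    time = get_f("Error: subj:time", "time"),
    location_x_time = get_f("Error: subj:loc:time", "loc:time"))
}
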