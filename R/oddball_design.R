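#' Oddball task configuration
#'
#' Parameters of the visual oddball task: rare target ("oddball") circles
#' among frequent standards ("control"), in blocks with an exact target
#' proportion and a cap on consecutive targets. Defaults follow the classic
#' mobile-EEG oddball protocol: four blocks of 100 trials, 30% oddballs,
#' at most two oddballs in a row, stimuli shown 800-1200 ms, preceded by a
#' fixation cross of 200-500 ms.
#'
#' @param n_blocks number of blocks.
#' @param trials_per_block trials in each block.
#' @param oddball_proportion fraction of oddball trials per block, in (0, 1);
#'   the per-block oddball count is `round(oddball_proportion * trials_per_block)`
#'   (0 is allowed and yields an all-control sequence).
#' @param max_oddball_run maximum number of consecutive oddballs (>= 1).
#' @param stimulus_duration_range_ms length-2 numeric, stimulus duration range.
#' @param fixation_duration_range_ms length-2 numeric, fixation duration range.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return object of class `task_config`.
#' @export
task_config <- function(n_blocks = 4,
                        trials_per_block = 100,
                        oddball_proportion = 0.30,
                        max_oddball_run = 2,
                        stimulus_duration_range_ms = c(800, 1200),
                        fixation_duration_range_ms = c(200, 500),
                        seed = NULL) {
  assert_that(n_blocks >= 1 && trials_per_block >= 1,
              "n_blocks and trials_per_block must be >= 1")
  assert_that(oddball_proportion >= 0 && oddball_proportion < 1,
              "oddball_proportion must lie in [0, 1)")
  assert_that(max_oddball_run >= 1, "max_oddball_run must be >= 1")
  assert_that(length(stimulus_duration_range_ms) == 2 &&
                stimulus_duration_range_ms[1] <= stimulus_duration_range_ms[2],
              "stimulus_duration_range_ms must be a non-decreasing interval")
  assert_that(length(fixation_duration_range_ms) == 2 &&
                fixation_duration_range_ms[1] <= fixation_duration_range_ms[2],
              "fixation_duration_range_ms must be a non-decreasing interval")
  structure(list(
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    oddball_proportion = oddball_proportion,
    max_oddball_run = as.integer(max_oddball_run),
    stimulus_duration_range_ms = as.numeric(stimulus_duration_range_ms),
    fixation_duration_range_ms = as.numeric(fixation_duration_range_ms),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "task_config")
}

# Longest run of TRUE in a logical vector.
longest_run <- function(x) {
  if (!any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Generate a constrained oddball trial sequence
#'
#' Per block, exactly `round(oddball_proportion * trials_per_block)` oddballs
#' are placed among the controls by rejection-resampling whole-block
#' permutations until no run of more than `max_oddball_run` consecutive
#' oddballs remains (capped at 10,000 attempts per block, then an error).
#' Stimulus and fixation durations are drawn uniformly over their ranges and
#' rounded to 1 ms.
#'
#' @param config a [task_config()].
#' @param max_attempts rejection-sampling cap per block.
#' @return a `data.frame` of class `trial_sequence` with columns `block`,
#'   `trial`, `type` ("oddball"/"control"), `stimulus_ms`, `fixation_ms`.
#' @export
generate_trial_sequence <- function(config = task_config(), max_attempts = 10000L) {
  stopifnot(inherits(config, "task_config"))
  n_odd <- round_half_away(config$oddball_proportion * config$trials_per_block)
  n_ctl <- config$trials_per_block - n_odd
  # Feasibility: n_odd oddballs in runs of <= r need at least ceil(n_odd/r) - 1
  # separating controls.
  if (n_odd > 0 &&
      n_ctl < ceiling(n_odd / config$max_oddball_run) - 1) {
    stop(sprintf(
      "run-length constraint unsatisfiable: %d oddballs, %d controls, max run %d",
      n_odd, n_ctl, config$max_oddball_run), call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  blocks <- vector("list", config$n_blocks)
  base_types <- c(rep(TRUE, n_odd), rep(FALSE, n_ctl))
  for (b in seq_len(config$n_blocks)) {
    if (n_odd == 0L) {
      types <- base_types
    } else {
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        types <- base_types[sample.int(config$trials_per_block)]
        if (longest_run(types) <= config$max_oddball_run) { ok <- TRUE; break }
      }
      if (!ok) stop(sprintf(
        "could not satisfy run-length constraint in block %d after %d attempts",
        b, max_attempts), call. = FALSE)
    }
    stim <- round(stats::runif(config$trials_per_block,
                               config$stimulus_duration_range_ms[1],
                               config$stimulus_duration_range_ms[2]))
    fix <- round(stats::runif(config$trials_per_block,
                              config$fixation_duration_range_ms[1],
                              config$fixation_duration_range_ms[2]))
    blocks[[b]] <- data.frame(
      block = b,
      trial = seq_len(config$trials_per_block),
      type = ifelse(types, "oddball", "control"),
      stimulus_ms = stim,
      fixation_ms = fix,
      stringsAsFactors = FALSE
    )
  }
  seq_df <- do.call(rbind, blocks)
  rownames(seq_df) <- NULL
  class(seq_df) <- c("trial_sequence", "data.frame")
  attr(seq_df, "config") <- config
  seq_df
}

#' Convert a trial sequence to stimulus onset samples
#'
#' Each trial is a fixation followed by a stimulus; the stimulus onset of
#' trial i falls at the cumulative sum of all earlier fixation and stimulus
#' durations plus trial i's own fixation. Every duration is converted to
#' samples individually (rounding half away from zero) before summing, so the
#' gap between consecutive onsets equals the sample-converted stimulus + next
#' fixation exactly. Sample indices are 0-based.
#'
#' @param seq a `trial_sequence`.
#' @param sampling_rate sampling rate in Hz.
#' @param lead_in_samples samples of recording before the first fixation.
#' @return `data.frame` with the sequence columns plus `nominal_sample`
#'   (0-based stimulus onset sample), strictly increasing.
#' @export
sequence_to_onsets <- function(seq, sampling_rate = 256, lead_in_samples = 0L) {
  assert_that(sampling_rate > 0, "sampling_rate must be > 0")
  if (nrow(seq) == 0L) {
    out <- seq
    out$nominal_sample <- integer(0)
    return(out)
  }
  fix_s <- ms_to_samples(seq$fixation_ms, sampling_rate)
  stim_s <- ms_to_samples(seq$stimulus_ms, sampling_rate)
  # onset_i = lead_in + sum_{j<i}(fix_j + stim_j) + fix_i
  onsets <- as.integer(lead_in_samples) +
    cumsum(fix_s) + c(0L, cumsum(stim_s)[-length(stim_s)])
  out <- as.data.frame(seq)
  out$nominal_sample <- as.integer(onsets)
  out
}
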