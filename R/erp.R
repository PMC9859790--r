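#' ERP waveform container
#'
#' @param values numeric vector, uV per sample.
#' @param time_ms time axis in ms, same length as `values`.
#' @param kind `"oddball"`, `"control"` or `"difference"`.
#' @param level `"participant"` or `"grand"`.
#' @param n_epochs number of epochs averaged (for difference waves, a named
#'   vector with both parent counts).
#' @return object of class `erp_waveform`.
#' @export
erp_waveform <- function(values, time_ms, kind, level = "participant",
                         n_epochs = NA_integer_) {
  assert_that(length(values) == length(time_ms),
              "values and time axis must have equal length")
  structure(list(values = as.numeric(values), time_ms = as.numeric(time_ms),
                 kind = kind, level = level, n_epochs = n_epochs),
            class = "erp_waveform")
}

#' @export
print.erp_waveform <- function(x, ...) {
  cat(sprintf("<erp_waveform> %s (%s), %d samples %.0f..%.0f ms\n",
              x$kind, x$level, length(x$values), min(x$time_ms), max(x$time_ms)))
  invisible(x)
}

#' Average retained epochs of one condition
#'
#' Pointwise mean over the retained (non-rejected) epochs of the requested
#' condition on one channel.
#'
#' @param epochs an `epoch_set` whose `info` has a `type` column.
#' @param condition `"oddball"` or `"control"`.
#' @param channel channel name, default `"posterior"`.
#' @param context optional label used in error messages (participant/cell).
#' @return an [erp_waveform()].
#' @export
average_condition <- function(epochs, condition, channel = "posterior",
                              context = NULL) {
  stopifnot(inherits(epochs, "epoch_set"))
  assert_that(channel %in% dimnames(epochs$data)[[3]],
              "channel '%s' not present", channel)
  sel <- !epochs$rejected & epochs$info$type == condition
  if (!any(sel)) {
    stop(sprintf("no retained %s epochs%s", condition,
                 if (is.null(context)) "" else paste0(" (", context, ")")),
         call. = FALSE)
  }
  m <- epochs$data[, sel, channel, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  erp_waveform(rowMeans(m), epochs$time_ms, kind = condition,
               n_epochs = sum(sel))
}

#' Difference wave: oddball minus control
#'
#' @param oddball,control [erp_waveform()]s on the same time axis.
#' @return an [erp_waveform()] of kind `"difference"`.
#' @export
difference_wave <- function(oddball, control) {
  stopifnot(inherits(oddball, "erp_waveform"), inherits(control, "erp_waveform"))
  assert_that(length(oddball$time_ms) == length(control$time_ms) &&
                all(oddball$time_ms == control$time_ms),
              "waveforms have mismatched time axes")
  erp_waveform(oddball$values - control$values, oddball$time_ms,
               kind = "difference", level = oddball$level,
               n_epochs = c(oddball = oddball$n_epochs[[1]],
                            control = control$n_epochs[[1]]))
}

#' Grand average across participants
#'
#' Unweighted pointwise mean of per-participant waveforms of one kind.
#'
#' @param waves list of [erp_waveform()]s with equal axes and identical kind.
#' @return an [erp_waveform()] with `level = "grand"`.
#' @export
grand_average <- function(waves) {
  assert_that(length(waves) >= 1, "need at least one waveform")
  stopifnot(all(vapply(waves, inherits, TRUE, "erp_waveform")))
  kinds <- unique(vapply(waves, function(w) w$kind, ""))
  assert_that(length(kinds) == 1, "cannot grand-average mixed kinds: %s",
              paste(kinds, collapse = ", "))
  axes_ok <- all(vapply(waves, function(w) {
    length(w$time_ms) == length(waves[[1]]$time_ms) &&
      all(w$time_ms == waves[[1]]$time_ms)
  }, TRUE))
  assert_that(axes_ok, "waveforms have mismatched time axes")
  vals <- rowMeans(vapply(waves, function(w) w$values,
                          numeric(length(waves[[1]]$values))))
  erp_waveform(vals, waves[[1]]$time_ms, kind = kinds, level = "grand",
               n_epochs = length(waves))
}

# Indices (within v) of local-extremum run starts: a run of equal values is a
# local maximum iff it exceeds the values on both sides; the run's first
# sample represents it. Wave endpoints are never local extrema.
local_maxima_starts <- function(v) {
  r <- rle(v)
  k <- length(r$values)
  if (k < 3) return(integer(0))
  starts <- cumsum(c(1L, r$lengths[-k]))
  cand <- 2:(k - 1)
  ok <- r$values[cand] > r$values[cand - 1] & r$values[cand] > r$values[cand + 1]
  starts[cand[ok]]
}

#' Locate a component peak in a measurement window
#'
#' P300: the local maximum (strictly greater than both neighbours; a plateau
#' is represented by its first sample) with the largest value inside the
#' window (default 400-600 ms). N200: symmetric, local minima in 150-250 ms.
#' If the window contains no interior local extremum, the window endpoint
#' extremum is returned with `is_local_extremum = FALSE`. Ties take the
#' earliest sample.
#'
#' @param wave an [erp_waveform()].
#' @param component `"P300"` or `"N200"`.
#' @param window optional length-2 ms window overriding the component default.
#' @return one-row data frame: `component`, `amplitude_uV`, `latency_ms`,
#'   `window_lo_ms`, `window_hi_ms`, `is_local_extremum`.
#' @export
find_peak <- function(wave, component = c("P300", "N200"), window = NULL) {
  stopifnot(inherits(wave, "erp_waveform"))
  component <- match.arg(component)
  if (is.null(window)) {
    window <- if (component == "P300") c(400, 600) else c(150, 250)
  }
  assert_that(window[1] >= min(wave$time_ms) && window[2] <= max(wave$time_ms),
              "window [%g, %g] ms outside the wave's time axis", window[1], window[2])
  v <- if (component == "P300") wave$values else -wave$values
  in_win <- which(wave$time_ms >= window[1] & wave$time_ms <= window[2])
  starts <- local_maxima_starts(v)
  cand <- intersect(starts, in_win)
  if (length(cand) > 0) {
    best <- cand[which.max(v[cand])]
    is_local <- TRUE
  } else {
    best <- in_win[which.max(v[in_win])]
    is_local <- FALSE
  }
  data.frame(component = component,
             amplitude_uV = wave$values[best],
             latency_ms = wave$time_ms[best],
             window_lo_ms = window[1], window_hi_ms = window[2],
             is_local_extremum = is_local,
             stringsAsFactors = FALSE)
}
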