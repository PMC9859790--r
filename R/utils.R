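# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic commercial rounding used for every millisecond-to-sample
#' conversion in the package (base `round()` rounds half to even, which would
#' make onset arithmetic depend on parity).
#'
#' @param x numeric vector.
#' @return integer vector, halves rounded away from zero.
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 2.4))
#' @export
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Milliseconds to samples, rounding half away from zero.
ms_to_samples <- function(ms, fs) {
  round_half_away(ms * fs / 1000)
}

#' Derive a reproducible sub-seed
#'
#' Expands one global seed into independent sub-stream seeds keyed by small
#' integer indices (participant, cell, replicate ...), so that e.g. adding
#' participants to a simulated study does not reshuffle existing ones.
#' All arithmetic stays below 2^53, the result below 2^31.
#'
#' @param seed integer master seed.
#' @param ... non-negative integer indices identifying the sub-stream.
#' @return an integer seed in `[0, 2147483646]`.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- (as.numeric(seed) %% 97003) * 30011
  primes <- c(7907, 104729, 15485863, 32452843, 49979687)
  for (k in seq_along(idx)) {
    p <- primes[((k - 1) %% length(primes)) + 1]
    h <- (h + (as.numeric(idx[k]) + 1) * p) %% 2147483647
    h <- (h * 48271) %% 2147483647
  }
  as.integer(h %% 2147483647)
}

# Stop unless `cond`; message built with sprintf.
assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

# The four design cells, in canonical order.
#' Design cell labels of the 2 x 2 (location x time) within-subject design
#' @return character vector of the four cell names.
#' @export
design_cells <- function() {
  c("inside_pre", "inside_post", "outside_pre", "outside_post")
}
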