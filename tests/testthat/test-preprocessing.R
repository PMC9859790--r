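# Amplitude of the f0 component, by projection onto sin/cos at f0 (robust to
# broadband transients, unlike an RMS ratio).
probe_amplitude <- function(x, f0, fs, idx) {
  t <- (idx - 1) / fs
  2 * sqrt(mean(x[idx] * sin(2 * pi * f0 * t))^2 +
             mean(x[idx] * cos(2 * pi * f0 * t))^2)
}

test_that("quality gate passes quiet channels and fails high-variance ones", {
  rec <- zero_recording(256 * 5)
  q <- quality_gate(rec)
  expect_true(all(q$pass))
  # one second of alternating +/-20 uV on TP10: variance ~400 uV^2
  rec$signals[257:512, "TP10"] <- rep(c(-20, 20), 128)
  q2 <- quality_gate(rec)
  expect_false(q2$pass[q2$channel == "TP10"])
  expect_true(all(q2$pass[q2$channel != "TP10"]))
  expect_gt(q2$max_variance[q2$channel == "TP10"], 399)
})

test_that("the filter contract holds: notch depth, passband fidelity, DC removal", {
  fs <- 256; n <- fs * 20
  t <- (0:(n - 1)) / fs
  mid <- (5 * fs):(15 * fs)
  sig <- cbind(TP9 = sin(2 * pi * 60 * t), AF7 = sin(2 * pi * 10 * t),
               AF8 = rep(10, n), TP10 = 0)
  f <- apply_filters(eeg_recording(sig, fs))
  expect_lt(probe_amplitude(f$signals[, "TP9"], 60, fs, mid), 0.01)   # >= 99%
  gain10 <- probe_amplitude(f$signals[, "AF7"], 10, fs, mid)
  expect_gt(gain10, 0.95); expect_lt(gain10, 1.05)
  # zero phase lag at 10 Hz: cross-correlation peak at lag 0
  cc <- stats::ccf(f$signals[mid, "AF7"], sig[mid, "AF7"], lag.max = 10,
                   plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # DC: judge after the (long) 0.1 Hz transient, in the deep middle
  expect_lt(max(abs(f$signals[(8 * fs):(12 * fs), "AF8"])), 0.1)
})

test_that("filtering is zero-phase: a symmetric pulse keeps its peak sample", {
  fs <- 256; n <- fs * 8
  pulse <- exp(-((1:n) - n / 2)^2 / (2 * 10^2))
  sig <- matrix(pulse, n, 4, dimnames = list(NULL, c("TP9", "AF7", "AF8", "TP10")))
  f <- apply_filters(eeg_recording(sig, fs))
  expect_equal(which.max(f$signals[, "TP9"]), n / 2)
})

test_that("cutoffs at or above Nyquist are rejected", {
  rec <- zero_recording(2560)
  expect_error(apply_filters(rec, filter_spec(lowpass = 130)), "Nyquist")
})

test_that("electrode pooling equals the per-sample mean oracle", {
  sig <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 2, 4,
                dimnames = list(NULL, c("TP9", "AF7", "AF8", "TP10")))
  p <- pool_electrodes(eeg_recording(sig, 256))
  expect_equal(p$signals[, "posterior"], c((1 + 7) / 2, (2 + 8) / 2))
  expect_equal(p$signals[, "frontal"], c((3 + 5) / 2, (4 + 6) / 2))
  set.seed(31)
  sig <- matrix(rnorm(4000), 1000, 4,
                dimnames = list(NULL, c("TP9", "AF7", "AF8", "TP10")))
  p <- pool_electrodes(eeg_recording(sig, 256))
  expect_equal(p$signals[, "frontal"], rowMeans(sig[, c("AF7", "AF8")]))
  expect_equal(p$signals[, "posterior"], rowMeans(sig[, c("TP9", "TP10")]))
  bad <- eeg_recording(sig[, c("TP9", "AF7", "AF8")], 256)
  expect_error(pool_electrodes(bad), "TP10")
})

test_that("pooling and filtering commute within float tolerance", {
  set.seed(5)
  sig <- matrix(rnorm(4 * 2560), 2560, 4,
                dimnames = list(NULL, c("TP9", "AF7", "AF8", "TP10")))
  rec <- eeg_recording(sig, 256)
  a <- pool_electrodes(apply_filters(rec))
  b <- apply_filters(pool_electrodes(rec))
  expect_equal(a$signals, b$signals, tolerance = 1e-8)
})

test_that("epoch extraction slices exactly and drops boundary markers", {
  fs <- 256
  sig <- matrix(seq_len(2 * 2000), 2000, 2,
                dimnames = list(NULL, c("frontal", "posterior")))
  rec <- eeg_recording(sig, fs)
  ev <- data.frame(marked_sample = c(10L, 500L, 1990L))
  expect_warning(empty <- extract_epochs(rec, ev[0, , drop = FALSE]), "no markers")
  ep <- extract_epochs(rec, ev)
  expect_equal(ep$n_dropped_boundary, 2)   # 10 lacks pre-window, 1990 post-window
  expect_equal(dim(ep$data)[2], 1)
  # manual slice oracle: 0-based onset 500 -> rows 450..655 (1-based)
  expect_equal(ep$data[, 1, "posterior"], sig[(500 - 51 + 1):(500 + 154 + 1), 2])
  expect_equal(length(ep$time_ms), 206)
  expect_equal(range(ep$time_ms), c(-51, 154) / fs * 1000)
  # conservation: markers = kept + dropped
  ev2 <- data.frame(marked_sample = seq(100L, 1800L, by = 100L))
  ep2 <- extract_epochs(rec, ev2)
  expect_equal(dim(ep2$data)[2] + ep2$n_dropped_boundary, nrow(ev2))
  expect_equal(dim(ep2$data)[2], nrow(ev2))
})

test_that("baseline correction zeroes the pre-stimulus mean and is linear", {
  fs <- 256
  rec <- eeg_recording(matrix(5, 2000, 2,
                              dimnames = list(NULL, c("frontal", "posterior"))), fs)
  ep <- baseline_correct(extract_epochs(rec, data.frame(marked_sample = 500L)))
  expect_true(all(ep$data == 0))
  set.seed(12)
  sig_a <- matrix(rnorm(4000), 2000, 2,
                  dimnames = list(NULL, c("frontal", "posterior")))
  sig_b <- matrix(rnorm(4000), 2000, 2,
                  dimnames = list(NULL, c("frontal", "posterior")))
  ev <- data.frame(marked_sample = c(300L, 900L, 1500L))
  bc <- function(s) baseline_correct(extract_epochs(eeg_recording(s, fs), ev))
  base_idx <- which(bc(sig_a)$time_ms < 0)
  expect_lt(max(abs(colMeans(bc(sig_a)$data[base_idx, , ]))), 1e-9)
  expect_equal(bc(sig_a + sig_b)$data, bc(sig_a)$data + bc(sig_b)$data)
})

test_that("artifact rejection matches a brute-force range oracle on 1000 epochs", {
  set.seed(9)
  n_ep <- 1000
  dat <- array(rnorm(206 * n_ep * 2, sd = 10), dim = c(206, n_ep, 2),
               dimnames = list(NULL, NULL, c("frontal", "posterior")))
  ep <- structure(list(data = dat, time_ms = epoch_axis(),
                       info = data.frame(type = rep("oddball", n_ep)),
                       rejected = rep(FALSE, n_ep), n_dropped_boundary = 0L,
                       fs = 256, baseline_corrected = TRUE),
                  class = "epoch_set")
  ep <- reject_artifacts(ep, 60)
  oracle <- vapply(seq_len(n_ep), function(i) {
    any(vapply(1:2, function(ch) {
      v <- dat[, i, ch]; (max(v) - min(v)) > 60
    }, logical(1)))
  }, logical(1))
  expect_identical(ep$rejected, oracle)
  expect_equal(ep$rejection_rate, mean(oracle))
  expect_true(any(oracle) && !all(oracle))  # the fixture exercises both branches
})

test_that("constructed contamination rejects exactly the contaminated epochs", {
  dat <- array(0, dim = c(206, 20, 2),
               dimnames = list(NULL, NULL, c("frontal", "posterior")))
  contaminated <- c(3, 8, 15)
  for (i in contaminated) dat[100, i, 1] <- 150
  ep <- structure(list(data = dat, time_ms = epoch_axis(),
                       info = data.frame(type = rep("control", 20)),
                       rejected = rep(FALSE, 20), n_dropped_boundary = 0L,
                       fs = 256, baseline_corrected = TRUE),
                  class = "epoch_set")
  ep <- reject_artifacts(ep, 60)
  expect_identical(which(ep$rejected), as.integer(contaminated))
})

test_that("participant exclusion uses a strict more-than-half rule", {
  rej <- data.frame(participant = c(1, 2, 3),
                    n_epochs = c(100, 100, 100),
                    n_rejected = c(51, 50, 10))
  out <- exclude_participants(rej)
  expect_setequal(out$excluded, "1")     # 51% out
  expect_true("2" %in% out$retained)     # exactly 50% stays
  expect_error(
    exclude_participants(data.frame(participant = 1, n_epochs = 10,
                                    n_rejected = 10)),
    "all participants excluded")
})

test_that("a 32-participant cohort with two noisy members retains 30", {
  rej <- data.frame(participant = rep(1:32, each = 4),
                    n_epochs = 100,
                    n_rejected = c(rep(30, 4 * 30), rep(80, 8)))
  out <- exclude_participants(rej)
  expect_length(out$retained, 30)
  expect_setequal(out$excluded, c("31", "32"))
})
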