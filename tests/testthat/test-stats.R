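test_that("cell matrices are validated and column-normalised", {
  m <- matrix(1:8, 2, 4, dimnames = list(NULL, rev(design_cells())))
  cm <- cell_matrix(m)
  expect_equal(colnames(cm), design_cells())
  expect_error(cell_matrix(m[1, , drop = FALSE]), "at least 2")
  m[1, 1] <- NA
  expect_error(cell_matrix(m), "missing")
})

test_that("behavioural summaries follow the hit/false-alarm/miss definitions", {
  ev <- data.frame(type = c("oddball", "oddball", "control", "control"),
                   responded = c(TRUE, TRUE, FALSE, FALSE),
                   rt_ms = c(200, 220, NA, NA))
  cell_events <- setNames(rep(list(ev), 4), design_cells())
  out <- behavioural_summary(list(cell_events, cell_events))
  expect_true(all(out$rt == 210))
  expect_true(all(out$errors == 0))
  ev2 <- data.frame(type = c("oddball", "oddball", "control"),
                    responded = c(TRUE, FALSE, TRUE),   # one miss + one false alarm
                    rt_ms = c(250, NA, 300))
  cell_events2 <- setNames(rep(list(ev2), 4), design_cells())
  out2 <- behavioural_summary(list(cell_events2, cell_events2))
  expect_true(all(out2$errors == 2))
  expect_true(all(out2$rt == 250))
})

test_that("cells with no responded oddballs are flagged as RT-undefined", {
  good <- data.frame(type = c("oddball", "control"),
                     responded = c(TRUE, FALSE), rt_ms = c(210, NA))
  bad <- data.frame(type = c("oddball", "control"),
                    responded = c(FALSE, FALSE), rt_ms = c(NA, NA))
  cells <- setNames(rep(list(good), 4), design_cells())
  cells_bad <- cells; cells_bad$inside_pre <- bad
  expect_warning(
    expect_error(behavioural_summary(list(cells_bad, cells)), "missing"),
    "no responded oddballs")
})

test_that("between-subject cell intervals achieve nominal coverage", {
  set.seed(606)
  hits <- matrix(0, 400, 4)
  truth <- c(1.5, 1.6, 1.4, 2.4)
  for (r in 1:400) {
    m <- matrix(rnorm(15 * 4, mean = rep(truth, each = 15)), 15, 4,
                dimnames = list(NULL, design_cells())) + rnorm(15)
    ci <- between_subject_ci(m)
    hits[r, ] <- ci$ci_lo <= truth & truth <= ci$ci_hi
  }
  cov <- colMeans(hits)
  expect_true(all(cov > 0.91) && all(cov < 0.99))
})

test_that("identical cells give F = 0, p = 1 for every effect", {
  m <- matrix(2.5, 5, 4, dimnames = list(NULL, design_cells()))
  an <- rm_anova_2x2(m)
  expect_equal(an$F, c(0, 0, 0))
  expect_equal(an$p, c(1, 1, 1))
})

test_that("the ANOVA matches the aov oracle and a hand-built 4-participant case", {
  m <- matrix(c(2, 4, 3, 5,
                3, 5, 4, 7,
                1, 2, 2, 6,
                4, 6, 5, 9), 4, 4, byrow = TRUE,
              dimnames = list(NULL, design_cells()))
  an <- rm_anova_2x2(m)
  ref <- oracle_aov(m)
  expect_equal(an$F, unname(ref[an$effect]), tolerance = 1e-10)
  set.seed(55)
  for (i in 1:20) {
    m <- random_cell_matrix(n = 8)
    an <- rm_anova_2x2(m)
    ref <- oracle_aov(m)
    expect_equal(an$F, unname(ref[an$effect]), tolerance = 1e-8)
  }
})

test_that("sums of squares decompose the total exactly", {
  set.seed(66)
  for (i in 1:25) {
    m <- random_cell_matrix(n = sample(4:40, 1))
    an <- rm_anova_2x2(m)
    lhs <- attr(an, "ss_total")
    rhs <- attr(an, "ss_participants") + sum(an$SS_effect) + sum(an$SS_error)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("each F equals the square of its paired contrast t", {
  set.seed(8)
  for (i in 1:25) {
    m <- random_cell_matrix(n = 10)
    an <- rm_anova_2x2(m)
    t_loc <- paired_t(rowMeans(m[, 1:2]), rowMeans(m[, 3:4]))$t
    t_time <- paired_t(rowMeans(m[, c(2, 4)]), rowMeans(m[, c(1, 3)]))$t
    t_int <- paired_t(m[, 2] - m[, 1], m[, 4] - m[, 3])$t
    expect_equal(an$F[an$effect == "location"], t_loc^2, tolerance = 1e-10)
    expect_equal(an$F[an$effect == "time"], t_time^2, tolerance = 1e-10)
    expect_equal(an$F[an$effect == "location_x_time"], t_int^2, tolerance = 1e-10)
  }
})

test_that("degenerate ANOVA inputs warn and report infinite F", {
  m <- matrix(c(1, 2, 1, 2,
                2, 3, 2, 3,
                3, 4, 3, 4), 3, 4, byrow = TRUE,
              dimnames = list(NULL, design_cells()))
  # time effect is exactly +1 for every participant: zero error variance
  expect_warning(an <- rm_anova_2x2(m), "zero error variance")
  expect_equal(an$F[an$effect == "time"], Inf)
  expect_equal(an$p[an$effect == "time"], 0)
})

test_that("paired t matches the closed form and t.test", {
  out <- paired_t(c(2, 3, 4), c(1, 1, 1))
  expect_equal(out$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(out$df, 2)
  expect_equal(out$cohens_d, 2)
  same <- paired_t(1:5, 1:5)
  expect_equal(c(same$t, same$p, same$cohens_d), c(0, 1, 0))
  set.seed(4)
  a <- rnorm(20); b <- rnorm(20)
  ours <- paired_t(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  expect_warning(inf <- paired_t(c(2, 3), c(1, 2)), "zero-variance")
  expect_equal(inf$t, Inf)
  # alternative standardiser
  avg <- paired_t(a, b, d_method = "average")
  expect_equal(avg$cohens_d, mean(a - b) / mean(c(sd(a), sd(b))))
})

test_that("within-subject CIs remove participant offsets and match the oracle", {
  base <- c(1, 2, 3, 4)
  m <- matrix(rep(base, each = 6), 6, 4, dimnames = list(NULL, design_cells()))
  m <- m + c(0, 5, -3, 10, 2, 7)            # pure participant offsets
  ci <- within_subject_ci(m)
  expect_equal(ci$halfwidth, rep(0, 4), tolerance = 1e-10)
  set.seed(23)
  m2 <- random_cell_matrix(n = 15)
  ci2 <- within_subject_ci(m2)
  m3 <- m2; m3[4, ] <- m3[4, ] + 100        # constant shift of one participant
  expect_equal(within_subject_ci(m3)$halfwidth, ci2$halfwidth, tolerance = 1e-9)
  # step-by-step oracle
  centred <- m2 - rowMeans(m2) + mean(m2)
  half <- qt(0.975, 14) * apply(centred, 2, sd) * sqrt(4 / 3) / sqrt(15)
  expect_equal(ci2$halfwidth, unname(half))
  expect_equal(ci2$mean, unname(colMeans(m2)))
})

test_that("analyze_study decomposes a significant interaction as published", {
  set.seed(31)
  n <- 20
  eff <- matrix(0, n, 4, dimnames = list(NULL, design_cells()))
  eff[, "outside_post"] <- 1.5
  m <- cell_matrix(eff + matrix(rnorm(n * 4, sd = 0.4), n, 4) + rnorm(n, sd = 1))
  res <- analyze_study(p300 = m)
  an <- res$p300$anova
  expect_lte(an$p[an$effect == "location_x_time"], 0.05)
  fu <- res$p300$followups
  expect_equal(fu$contrast, c("inside_post_vs_pre", "outside_post_vs_pre"))
  expect_lte(fu$p[2], 0.001)
  expect_gt(fu$p[1], 0.05)
  expect_s3_class(res, "study_analysis")
  # no interaction -> no follow-ups
  null_m <- cell_matrix(matrix(rnorm(n * 4), n, 4,
                               dimnames = list(NULL, design_cells())))
  expect_null(analyze_study(p300 = null_m)$p300$followups)
})
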