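#' Build a participants x cells matrix
#'
#' Canonical container for one measure of the 2 x 2 fully repeated-measures
#' design: one row per participant, columns `inside_pre`, `inside_post`,
#' `outside_pre`, `outside_post`.
#'
#' @param values numeric matrix (or coercible) with the four design-cell
#'   columns; extra column order is normalised.
#' @return numeric matrix of class `cell_matrix`.
#' @export
cell_matrix <- function(values) {
  m <- as.matrix(values)
  assert_that(all(design_cells() %in% colnames(m)),
              "cell matrix needs columns %s", paste(design_cells(), collapse = ", "))
  m <- m[, design_cells(), drop = FALSE]
  assert_that(nrow(m) >= 2, "need at least 2 participants")
  assert_that(!anyNA(m), "fully repeated design: no missing cells allowed")
  class(m) <- c("cell_matrix", class(m))
  m
}

#' Behavioural summaries per design cell
#'
#' Reaction time: mean RT over oddball trials with a response. Errors: count
#' of false alarms (response to a control) plus misses (no response to an
#' oddball).
#'
#' @param study_events list (participants) of lists (cells) of event data
#'   frames with columns `type`, `responded`, `rt_ms` — e.g. the `events`
#'   entries of a [generate_study()] dataset.
#' @return list with `rt` and `errors` [cell_matrix()]es.
#' @export
behavioural_summary <- function(study_events) {
  cells <- design_cells()
  n <- length(study_events)
  rt <- matrix(NA_real_, n, 4, dimnames = list(NULL, cells))
  er <- matrix(NA_real_, n, 4, dimnames = list(NULL, cells))
  for (i in seq_len(n)) {
    for (cl in cells) {
      ev <- study_events[[i]][[cl]]
      if (is.list(ev) && !is.data.frame(ev) && !is.null(ev$events)) ev <- ev$events
      hit <- ev$type == "oddball" & ev$responded
      if (!any(hit)) {
        warning(sprintf("participant %d, cell %s: no responded oddballs; RT undefined",
                        i, cl))
      } else {
        rt[i, cl] <- mean(ev$rt_ms[hit])
      }
      er[i, cl] <- sum(ev$type == "oddball" & !ev$responded) +
        sum(ev$type == "control" & ev$responded)
    }
  }
  list(rt = cell_matrix(rt), errors = cell_matrix(er))
}

# Two-sided p from an F(1, df2) statistic, honouring infinities.
f_p <- function(f, df2) {
  if (!is.finite(f)) return(0)
  stats::pf(f, 1, df2, lower.tail = FALSE)
}

#' 2 x 2 fully repeated-measures ANOVA
#'
#' Classical within-subject decomposition for a two-factor (location x time)
#' design with one observation per participant and cell: each effect's sum of
#' squares comes from the marginal means, its error term from the
#' participant x effect interaction; `F = MS_effect / MS_error` with
#' df (1, n-1). Effect size is partial eta squared,
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param m a [cell_matrix()].
#' @return data frame of class `rm_anova`: one row per effect (`location`,
#'   `time`, `location_x_time`) with `SS_effect`, `SS_error`, `df1`, `df2`,
#'   `F`, `p`, `eta_sq_partial`, plus attributes `ss_total`,
#'   `ss_participants`.
#' @export
rm_anova_2x2 <- function(m) {
  m <- cell_matrix(m)
  n <- nrow(m)
  grand <- mean(m)
  subj <- rowMeans(m)
  # marginal means: location (inside = cols 1:2), time (pre = cols c(1,3))
  loc_means <- c(inside = mean(m[, 1:2]), outside = mean(m[, 3:4]))
  time_means <- c(pre = mean(m[, c(1, 3)]), post = mean(m[, c(2, 4)]))
  cellm <- colMeans(m)

  ss_loc <- 2 * n * sum((loc_means - grand)^2)
  ss_time <- 2 * n * sum((time_means - grand)^2)
  loc_of <- c(1, 1, 2, 2); time_of <- c(1, 2, 1, 2)
  ss_int <- n * sum((cellm - loc_means[loc_of] - time_means[time_of] + grand)^2)
  ss_subj <- 4 * sum((subj - grand)^2)

  m_loc <- cbind(rowMeans(m[, 1:2]), rowMeans(m[, 3:4]))
  ss_loc_err <- 2 * sum(sweep(sweep(m_loc, 1, subj), 2, loc_means - grand) ^ 2)
  m_time <- cbind(rowMeans(m[, c(1, 3)]), rowMeans(m[, c(2, 4)]))
  ss_time_err <- 2 * sum(sweep(sweep(m_time, 1, subj), 2, time_means - grand) ^ 2)
  ss_total <- sum((m - grand)^2)
  # three-way residual, computed definitionally (not by subtraction) so the
  # SS-sum identity is a genuine invariant
  A_dev <- loc_means - grand
  B_dev <- time_means - grand
  AB_dev <- cellm - loc_means[loc_of] - time_means[time_of] + grand
  AS_dev <- sweep(sweep(m_loc, 1, subj), 2, A_dev)      # m_ia - subj_i - loc_a + grand
  BS_dev <- sweep(sweep(m_time, 1, subj), 2, B_dev)
  fit <- matrix(grand, n, 4) + (subj - grand) +
    matrix(A_dev[loc_of], n, 4, byrow = TRUE) +
    matrix(B_dev[time_of], n, 4, byrow = TRUE) +
    matrix(AB_dev, n, 4, byrow = TRUE) +
    AS_dev[, loc_of] + BS_dev[, time_of]
  ss_int_err <- sum((m - fit)^2)

  one_effect <- function(name, ss_eff, ss_err) {
    if (ss_eff <= .Machine$double.eps * 100 * max(1, ss_total)) {
      f <- 0; p <- 1
    } else if (ss_err <= .Machine$double.eps * 100 * max(1, ss_total)) {
      warning(sprintf("zero error variance for effect '%s'; F reported as Inf", name))
      f <- Inf; p <- 0
    } else {
      f <- (ss_eff / 1) / (ss_err / (n - 1))
      p <- f_p(f, n - 1)
    }
    eta <- if (ss_eff + ss_err > 0) ss_eff / (ss_eff + ss_err) else 0
    data.frame(effect = name, SS_effect = ss_eff, SS_error = ss_err,
               df1 = 1L, df2 = n - 1L, F = f, p = p, eta_sq_partial = eta,
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_effect("location", ss_loc, ss_loc_err),
               one_effect("time", ss_time, ss_time_err),
               one_effect("location_x_time", ss_int, ss_int_err))
  attr(out, "ss_total") <- ss_total
  attr(out, "ss_participants") <- ss_subj
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' Dependent-samples t test with Cohen's d
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = a - b` and the sample SD
#' (n-1 denominator); two-sided p on n-1 df. Cohen's d defaults to the
#' paired-difference form `d_z = mean(d) / sd(d)`; `d_method = "average"`
#' divides by the mean of the two condition SDs instead.
#'
#' @param a,b numeric vectors of equal length >= 2 (paired observations).
#' @param d_method `"dz"` (default) or `"average"`.
#' @return one-row data frame: `t`, `df`, `p`, `cohens_d`, `mean_diff`.
#' @export
paired_t <- function(a, b, d_method = c("dz", "average")) {
  d_method <- match.arg(d_method)
  assert_that(length(a) == length(b) && length(a) >= 2,
              "a and b must have equal length >= 2")
  d <- a - b
  n <- length(d)
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0) { t <- 0; p <- 1 } else {
      warning("zero-variance differences with nonzero mean; t reported as Inf")
      t <- sign(md) * Inf; p <- 0
    }
  } else {
    t <- md / (sdd / sqrt(n))
    p <- 2 * stats::pt(abs(t), n - 1, lower.tail = FALSE)
  }
  denom <- if (d_method == "dz") sdd else mean(c(stats::sd(a), stats::sd(b)))
  d_es <- if (denom == 0) 0 else md / denom
  data.frame(t = t, df = n - 1L, p = p, cohens_d = d_es, mean_diff = md)
}

#' Cousineau-Morey within-subject confidence intervals
#'
#' Observations are participant-mean-centred (`x - participant mean + grand
#' mean`), cell SDs of the centred data are inflated by the Morey factor
#' `sqrt(c / (c - 1))` for `c = 4` cells, and the half-width is
#' `t_{(1+level)/2, n-1} * SD_corrected / sqrt(n)`.
#'
#' @param m a [cell_matrix()].
#' @param level confidence level.
#' @return data frame: `cell`, `mean`, `ci_lo`, `ci_hi`, `halfwidth`.
#' @export
within_subject_ci <- function(m, level = 0.95) {
  m <- cell_matrix(m)
  n <- nrow(m); k <- ncol(m)
  centred <- m - rowMeans(m) + mean(m)
  sds <- apply(centred, 2, stats::sd) * sqrt(k / (k - 1))
  half <- stats::qt((1 + level) / 2, n - 1) * sds / sqrt(n)
  mu <- colMeans(m)
  data.frame(cell = colnames(m), mean = as.numeric(mu),
             ci_lo = as.numeric(mu - half), ci_hi = as.numeric(mu + half),
             halfwidth = as.numeric(half), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Plain between-subject t confidence intervals per cell
#'
#' @param m a [cell_matrix()].
#' @param level confidence level.
#' @return data frame as in [within_subject_ci()].
#' @export
between_subject_ci <- function(m, level = 0.95) {
  m <- cell_matrix(m)
  n <- nrow(m)
  sds <- apply(m, 2, stats::sd)
  half <- stats::qt((1 + level) / 2, n - 1) * sds / sqrt(n)
  mu <- colMeans(m)
  data.frame(cell = colnames(m), mean = as.numeric(mu),
             ci_lo = as.numeric(mu - half), ci_hi = as.numeric(mu + half),
             halfwidth = as.numeric(half), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Full inferential analysis of a 2 x 2 within-subject study
#'
#' Runs the repeated-measures ANOVA on each supplied measure; whenever the
#' location x time interaction reaches `alpha`, decomposes it with dependent
#' t tests (post vs pre within each location). Also tabulates cell means with
#' within-subject and between-subject 95% confidence intervals.
#'
#' @param p300 [cell_matrix()] of P300 amplitudes (uV); may be `NULL`.
#' @param rt [cell_matrix()] of mean reaction times (ms); may be `NULL`.
#' @param errors [cell_matrix()] of error counts; may be `NULL`.
#' @param alpha interaction-decomposition threshold.
#' @param ci_level confidence level for the cell summaries.
#' @return object of class `study_analysis`: per measure, `anova`,
#'   `followups` (possibly `NULL`), `cells_within`, `cells_between`.
#' @export
analyze_study <- function(p300 = NULL, rt = NULL, errors = NULL,
                          alpha = 0.05, ci_level = 0.95) {
  measures <- Filter(Negate(is.null),
                     list(p300 = p300, rt = rt, errors = errors))
  assert_that(length(measures) > 0, "no measures supplied")
  out <- lapply(measures, function(m) {
    m <- cell_matrix(m)
    an <- rm_anova_2x2(m)
    fu <- NULL
    if (an$p[an$effect == "location_x_time"] <= alpha) {
      fu <- rbind(
        cbind(contrast = "inside_post_vs_pre",
              paired_t(m[, "inside_post"], m[, "inside_pre"])),
        cbind(contrast = "outside_post_vs_pre",
              paired_t(m[, "outside_post"], m[, "outside_pre"]))
      )
    }
    list(anova = an, followups = fu,
         cells_within = within_subject_ci(m, ci_level),
         cells_between = between_subject_ci(m, ci_level))
  })
  structure(out, class = "study_analysis")
}

#' @export
print.study_analysis <- function(x, ...) {
  for (meas in names(x)) {
    cat(sprintf("== %s ==\n", meas))
    an <- x[[meas]]$anova
    for (i in seq_len(nrow(an))) {
      cat(sprintf("  %-16s F(%d,%d) = %.2f, p = %.3f, partial eta^2 = %.3f\n",
                  an$effect[i], an$df1[i], an$df2[i], an$F[i], an$p[i],
                  an$eta_sq_partial[i]))
    }
    fu <- x[[meas]]$followups
    if (!is.null(fu)) {
      for (i in seq_len(nrow(fu))) {
        cat(sprintf("  %-20s t(%d) = %.2f, p = %.3f, d = %.3f\n",
                    fu$contrast[i], fu$df[i], fu$t[i], fu$p[i], fu$cohens_d[i]))
      }
    }
    cw <- x[[meas]]$cells_within
    for (i in seq_len(nrow(cw))) {
      cat(sprintf("  %-13s %.1f [%.1f, %.1f]\n",
                  cw$cell[i], cw$mean[i], cw$ci_lo[i], cw$ci_hi[i]))
    }
  }
  invisible(x)
}
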