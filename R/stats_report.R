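#' Dahlberg method error
#'
#' Technical error of measurement between duplicate determinations:
#' `sqrt(sum(d^2) / (2 n))` with `d` the paired differences. Symmetric in
#' its arguments and exactly zero for identical series.
#'
#' @param first,second Equal-length numeric series of repeated
#'   measurements.
#' @return Dahlberg error (same units as the input).
#' @export
dahlberg_error <- function(first, second) {
  if (length(first) != length(second) || length(first) < 2L) {
    abort("dahlberg_error needs two equal-length series, n >= 2",
          "rotometry_invalid_input")
  }
  d <- first - second
  sqrt(sum(d^2) / (2 * length(d)))
}

#' Intraclass correlation (two-way, absolute agreement, single measure)
#'
#' ICC(A,1) from the standard two-way mean-squares decomposition, the
#' usual choice for operator-agreement studies of continuous
#' measurements:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#' The consistency formulation ICC(C,1) is exposed as an option.
#'
#' @param ratings Numeric matrix, `n` items x `k >= 2` raters/occasions.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @return ICC value in \[-1, 1\].
#' @export
icc_agreement <- function(ratings, type = c("agreement", "consistency")) {
  type <- match.arg(type)
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 5L || k < 2L || anyNA(ratings)) {
    abort("icc needs >= 5 complete items over >= 2 raters",
          "rotometry_invalid_input")
  }
  grand <- mean(ratings)
  if (sum((ratings - grand)^2) < 1e-24) {
    abort("zero total variance: ICC undefined", "rotometry_undefined_icc")
  }
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((sweep(sweep(ratings, 1L, row_m), 2L, col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "agreement") {
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  } else {
    (msr - mse) / (msr + (k - 1) * mse)
  }
}

#' Normality-gated paired comparison
#'
#' Shapiro-Wilk on the paired differences selects the branch: paired t
#' when the normality p-value is at least `alpha`, Wilcoxon signed-rank
#' otherwise (two-sided; zero differences dropped; normal approximation
#' with tie correction once more than 25 non-zero differences remain).
#' Both branch results are returned so the selection is auditable.
#'
#' @param prescribed,achieved Equal-length numeric series.
#' @param alpha Normality gate level.
#' @return List of class `comparison_result`: `test` (`"paired_t"` or
#'   `"wilcoxon"`), `statistic`, `p_value`, `normality_p`, `degenerate`,
#'   and the full `t_test` / `wilcoxon_test` objects.
#' @export
paired_compare <- function(prescribed, achieved, alpha = 0.05) {
  if (length(prescribed) != length(achieved) || length(prescribed) < 6L) {
    abort("paired_compare needs equal-length series, n >= 6",
          "rotometry_invalid_input")
  }
  d <- achieved - prescribed
  if (all(d == 0)) {
    return(structure(list(test = "degenerate", statistic = NA_real_,
                          p_value = 1, normality_p = NA_real_,
                          degenerate = TRUE), class = "comparison_result"))
  }
  sw <- stats::shapiro.test(d)
  tt <- stats::t.test(achieved, prescribed, paired = TRUE)
  nz <- sum(d != 0)
  wt <- suppressWarnings(
    stats::wilcox.test(achieved, prescribed, paired = TRUE,
                       exact = nz <= 25L, correct = TRUE))
  use_t <- sw$p.value >= alpha
  structure(list(
    test = if (use_t) "paired_t" else "wilcoxon",
    statistic = unname(if (use_t) tt$statistic else wt$statistic),
    p_value = unname(if (use_t) tt$p.value else wt$p.value),
    normality_p = sw$p.value,
    degenerate = FALSE,
    t_test = tt, wilcoxon_test = wt), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison: %s, p = %.4g (normality p = %.3g)>\n",
              x$test, x$p_value, x$normality_p))
  invisible(x)
}

#' Regression of accuracy on prescription
#'
#' Ordinary least squares of accuracy (%) on prescribed rotation (deg)
#' within one group: the slope is the change in accuracy per additional
#' degree of prescription, with Student-t 95% confidence interval and
#' two-sided p-value.
#'
#' @param records Rotation records for one group (needs `accuracy_pct`
#'   and `prescribed_deg`).
#' @param min_n Minimum group size.
#' @return List of class `regression_result`: `beta`, `ci` (length 2),
#'   `p_value`, `intercept`, `n`.
#' @export
accuracy_regression <- function(records, min_n = 10L) {
  r <- records[!records$excluded & is.finite(records$accuracy_pct), ,
               drop = FALSE]
  if (nrow(r) < min_n) {
    abort(sprintf("accuracy_regression needs >= %d records", min_n),
          "rotometry_invalid_input")
  }
  if (stats::sd(r$prescribed_deg) < 1e-12) {
    abort("zero variance in prescription: degenerate design",
          "rotometry_degenerate")
  }
  fit <- stats::lm(accuracy_pct ~ prescribed_deg, data = r)
  # exact fits trip lm's "essentially perfect fit" warning; that regime
  # is handled explicitly below
  sfit <- suppressWarnings(summary(fit))
  sm <- sfit$coefficients
  ci <- unname(suppressWarnings(stats::confint(fit))["prescribed_deg", ])
  beta <- unname(sm["prescribed_deg", "Estimate"])
  p <- unname(sm["prescribed_deg", "Pr(>|t|)"])
  scale <- mean(abs(r$accuracy_pct)) + 1
  if (!is.finite(p) || sfit$sigma < 1e-10 * scale) {
    # (numerically) zero residual variance: the observed slope is exact
    p <- if (abs(beta) < 1e-8 * scale) 1 else 0
    ci <- c(beta, beta)
  }
  structure(list(beta = beta,
                 ci = ci,
                 p_value = p,
                 intercept = unname(sm["(Intercept)", "Estimate"]),
                 n = nrow(r)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression: beta = %.3f [%.3f, %.3f], p = %.3g, n = %d>\n",
    x$beta, x$ci[1L], x$ci[2L], x$p_value, x$n))
  invisible(x)
}

#' Paired-t sample size from the noncentral t distribution
#'
#' Smallest integer `n` such that a two-sided one-sample/paired t test
#' with noncentrality `d * sqrt(n)` on `n - 1` degrees of freedom
#' reaches the requested power. At effect size 0.6, alpha 0.05 and power
#' 0.80 this gives 24 pairs.
#'
#' @param d Effect size (mean difference over SD of differences), > 0.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Integer sample size (>= 2).
#' @export
paired_t_sample_size <- function(d, alpha = 0.05, power = 0.80) {
  stopifnot_scalar_number(alpha, "alpha")
  stopifnot_scalar_number(power, "power")
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0) {
    abort("effect size d must be > 0", "rotometry_invalid_input")
  }
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    abort("alpha and power must lie in (0, 1)", "rotometry_invalid_input")
  }
  for (n in 2:1000000) {
    if (paired_t_power(n, d, alpha) >= power) return(n)
  }
  abort("requested power unreachable", "rotometry_invalid_input")
}

#' @rdname paired_t_sample_size
#' @param n Sample size (pairs).
#' @export
paired_t_power <- function(n, d, alpha = 0.05) {
  df <- n - 1
  crit <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  stats::pt(-crit, df, ncp) + 1 - stats::pt(crit, df, ncp)
}

#' Emit the report tables for a cohort of rotation records
#'
#' Writes four CSVs mirroring the study's result tables plus a
#' run-metadata JSON: `table1_prescription_achieved.csv` (descriptives
#' with the gated paired-comparison p-value per group),
#' `table2_accuracy.csv`, `table3_fope_direction.csv`, and
#' `table4_regression.csv` (accuracy-on-prescription slope per group).
#' Reruns with the same inputs are byte-identical.
#'
#' @param records Data frame from [build_records()] (or path to its CSV).
#' @param out_dir Output directory.
#' @param alpha Significance level.
#' @param seed Seed recorded in the metadata (provenance only).
#' @return Invisibly, the vector of files written.
#' @export
build_report <- function(records, out_dir, alpha = 0.05, seed = NULL) {
  if (is.character(records)) {
    if (!file.exists(records)) {
      abort(sprintf("records stage output missing: %s", records),
            "rotometry_stage_error")
    }
    records <- utils::read.csv(records)
    records$fope_bin <- factor(records$fope_bin,
                               levels = levels(fope_bin(0)))
    records$direction <- factor(records$direction,
                                levels = c("under", "right", "over"))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  summ <- group_summary(records)

  pvals <- tests <- rep(NA_real_, nrow(summ))
  tests <- character(nrow(summ))
  kept <- records[!records$excluded, , drop = FALSE]
  for (i in seq_len(nrow(summ))) {
    g <- if (summ$tooth_type[i] == "total") {
      kept[kept$arch == summ$arch[i], , drop = FALSE]
    } else {
      kept[kept$arch == summ$arch[i] &
             kept$tooth_type == summ$tooth_type[i], , drop = FALSE]
    }
    res <- tryCatch(paired_compare(g$prescribed_deg, g$achieved_deg,
                                   alpha = alpha),
                    rotometry_error = function(e) NULL)
    if (!is.null(res)) {
      pvals[i] <- res$p_value
      tests[i] <- res$test
    }
  }

  t1 <- cbind(summ[, c("group", "arch", "tooth_type", "n",
                       "presc_mean", "presc_sd", "presc_ci_l",
                       "presc_ci_u", "ach_mean", "ach_sd", "ach_ci_l",
                       "ach_ci_u", "mean_perf", "mean_perf_sd",
                       "mean_perf_ci_l", "mean_perf_ci_u",
                       "mean_abs_perf")],
              data.frame(test = tests, p_value = pvals))
  t2 <- summ[, c("group", "arch", "tooth_type", "n", "acc_mean",
                 "acc_sd", "acc_ci_l", "acc_ci_u")]
  t3 <- summ[, c("group", "arch", "tooth_type", "n",
                 "n_under", "pct_under", "n_right", "pct_right",
                 "n_over", "pct_over",
                 "n_fope_le1", "pct_fope_le1", "n_fope_1_2",
                 "pct_fope_1_2", "n_fope_2_4", "pct_fope_2_4",
                 "n_fope_gt4", "pct_fope_gt4")]

  regs <- list()
  for (i in which(summ$tooth_type != "total")) {
    g <- kept[kept$arch == summ$arch[i] &
                kept$tooth_type == summ$tooth_type[i], , drop = FALSE]
    res <- tryCatch(accuracy_regression(g),
                    rotometry_error = function(e) NULL)
    regs[[length(regs) + 1L]] <- data.frame(
      group = summ$group[i], arch = summ$arch[i],
      tooth_type = summ$tooth_type[i],
      n = if (is.null(res)) nrow(g) else res$n,
      beta = if (is.null(res)) NA_real_ else res$beta,
      ci_l = if (is.null(res)) NA_real_ else res$ci[1L],
      ci_u = if (is.null(res)) NA_real_ else res$ci[2L],
      p_value = if (is.null(res)) NA_real_ else res$p_value)
  }
  t4 <- do.call(rbind, regs)

  files <- file.path(out_dir, c(
    "table1_prescription_achieved.csv", "table2_accuracy.csv",
    "table3_fope_direction.csv", "table4_regression.csv"))
  utils::write.csv(t1, files[1L], row.names = FALSE)
  utils::write.csv(t2, files[2L], row.names = FALSE)
  utils::write.csv(t3, files[3L], row.names = FALSE)
  utils::write.csv(t4, files[4L], row.names = FALSE)

  meta <- list(
    n_records = nrow(records), n_excluded = sum(records$excluded),
    alpha = alpha, seed = seed,
    package_version = as.character(utils::packageVersion("rotometry")),
    notes = c(
      "regressions pool teeth across cases, ignoring within-case clustering",
      "no multiple-testing correction across per-tooth comparisons"))
  meta_file <- file.path(out_dir, "run_metadata.json")
  jsonlite::write_json(meta, meta_file, auto_unbox = TRUE, digits = NA)
  invisible(c(files, meta_file))
}
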