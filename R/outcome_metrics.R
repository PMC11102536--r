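#' Direction of the performance error
#'
#' Performance is achieved minus prescribed rotation (degrees).
#' Under-performance is a difference below -1 degree, right-performance
#' lies in \[-1, 1\] (boundaries inclusive), over-performance is above
#' +1 degree.
#'
#' @param performance Numeric vector of performance values (deg).
#' @return Factor with levels `under`, `right`, `over`.
#' @export
classify_direction <- function(performance) {
  if (!all(is.finite(performance))) {
    abort("performance must be finite", "rotometry_invalid_input")
  }
  out <- ifelse(performance < -1, "under",
                ifelse(performance > 1, "over", "right"))
  factor(out, levels = c("under", "right", "over"))
}

#' Frequencies-of-performance-error (FOPE) bin
#'
#' Bins the absolute performance into four ranges: at most 1 degree,
#' more than 1 up to 2, more than 2 up to 4, and above 4 degrees.
#' Intervals are half-open on unrounded values, so exactly 1 falls in
#' the first bin.
#'
#' @param abs_performance Non-negative numeric vector (deg).
#' @return Factor with levels `<=1`, `(1,2]`, `(2,4]`, `>4`.
#' @export
fope_bin <- function(abs_performance) {
  if (!all(is.finite(abs_performance)) || any(abs_performance < 0)) {
    abort("abs_performance must be finite and non-negative",
          "rotometry_invalid_input")
  }
  cut(abs_performance, breaks = c(-Inf, 1, 2, 4, Inf),
      labels = c("<=1", "(1,2]", "(2,4]", ">4"), right = TRUE)
}

#' Build per-tooth rotation records
#'
#' Derives the outcome variables from angle measurements: accuracy
#' (achieved / prescribed x 100), performance (achieved - prescribed),
#' its absolute value, the FOPE bin and the direction class. Records
#' with prescribed rotation below the clinical cutoff (2 degrees by
#' default, accounting for superimposition error) are marked excluded
#' and carry the reason; summaries ignore them.
#'
#' Measurements are expected with prescribed >= 0 (the measurement layer
#' re-signs both angles by the prescribed direction); a negative achieved
#' value means the tooth rotated opposite to plan, giving a negative
#' accuracy and direction `under`.
#'
#' @param measurements Data frame with at least `prescribed_deg` and
#'   `achieved_deg`; `case_id`, `arch`, `fdi`, `tooth_type` are carried
#'   through when present.
#' @param cutoff_deg Exclusion cutoff for prescribed rotations (deg).
#' @return Data frame of rotation records with an `excluded` flag.
#' @export
build_records <- function(measurements, cutoff_deg = 2) {
  stopifnot_scalar_number(cutoff_deg, "cutoff_deg", lower = 0)
  m <- as.data.frame(measurements)
  if (!all(c("prescribed_deg", "achieved_deg") %in% names(m))) {
    abort("measurements need prescribed_deg and achieved_deg columns",
          "rotometry_invalid_input")
  }
  presc <- m$prescribed_deg
  ach <- m$achieved_deg
  if (any(presc < 0, na.rm = TRUE)) {
    abort("prescribed_deg must be non-negative (re-sign upstream)",
          "rotometry_invalid_input")
  }
  excluded <- presc < cutoff_deg
  if (any(presc == 0 & !excluded)) {
    abort("prescribed rotation of 0 with inclusion requested: accuracy undefined",
          "rotometry_undefined_accuracy")
  }
  perf <- ach - presc
  out <- data.frame(
    case_id = if ("case_id" %in% names(m)) m$case_id else NA_character_,
    arch = if ("arch" %in% names(m)) m$arch else fdi_arch(m$fdi),
    fdi = if ("fdi" %in% names(m)) m$fdi else NA_integer_,
    tooth_type = if ("tooth_type" %in% names(m)) m$tooth_type
      else fdi_tooth_type(m$fdi),
    prescribed_deg = presc,
    achieved_deg = ach,
    accuracy_pct = ifelse(presc > 0, ach / presc * 100, NA_real_),
    performance_deg = perf,
    abs_performance_deg = abs(perf),
    fope_bin = fope_bin(abs(perf)),
    direction = classify_direction(perf),
    excluded = excluded,
    exclusion_reason = ifelse(excluded,
                              sprintf("prescribed below %g deg cutoff",
                                      cutoff_deg), ""))
  rownames(out) <- NULL
  out
}

ci_t <- function(mean, sd, n, level = 0.95) {
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * sd / sqrt(n)
  c(mean - half, mean + half)
}

summarise_group <- function(g, key) {
  n <- nrow(g)
  d <- g$achieved_deg - g$prescribed_deg
  mp <- abs(mean(d))          # |mean difference|: the table statistic
  sd_d <- stats::sd(d)
  stat <- function(x) {
    ci <- ci_t(mean(x), stats::sd(x), n)
    c(mean(x), stats::sd(x), ci)
  }
  pr <- stat(g$prescribed_deg)
  ac <- stat(g$achieved_deg)
  acc <- stat(g$accuracy_pct)
  mp_ci <- ci_t(mp, sd_d, n)
  dir_n <- table(g$direction)
  fope_n <- table(g$fope_bin)
  data.frame(
    group = key[1L], arch = key[2L], tooth_type = key[3L], n = n,
    presc_mean = pr[1L], presc_sd = pr[2L],
    presc_ci_l = pr[3L], presc_ci_u = pr[4L],
    ach_mean = ac[1L], ach_sd = ac[2L],
    ach_ci_l = ac[3L], ach_ci_u = ac[4L],
    acc_mean = acc[1L], acc_sd = acc[2L],
    acc_ci_l = acc[3L], acc_ci_u = acc[4L],
    mean_perf = mp, mean_perf_sd = sd_d,
    mean_perf_ci_l = mp_ci[1L], mean_perf_ci_u = mp_ci[2L],
    mean_abs_perf = mean(abs(d)),
    n_under = as.integer(dir_n[["under"]]),
    n_right = as.integer(dir_n[["right"]]),
    n_over = as.integer(dir_n[["over"]]),
    pct_under = dir_n[["under"]] / n * 100,
    pct_right = dir_n[["right"]] / n * 100,
    pct_over = dir_n[["over"]] / n * 100,
    n_fope_le1 = as.integer(fope_n[["<=1"]]),
    n_fope_1_2 = as.integer(fope_n[["(1,2]"]]),
    n_fope_2_4 = as.integer(fope_n[["(2,4]"]]),
    n_fope_gt4 = as.integer(fope_n[[">4"]]),
    pct_fope_le1 = fope_n[["<=1"]] / n * 100,
    pct_fope_1_2 = fope_n[["(1,2]"]] / n * 100,
    pct_fope_2_4 = fope_n[["(2,4]"]] / n * 100,
    pct_fope_gt4 = fope_n[[">4"]] / n * 100,
    row.names = NULL)
}

#' Group summaries of rotation records
#'
#' Per tooth-type-within-arch group (plus an arch total row): n, mean,
#' SD and Student-t 95% confidence intervals for prescription, achieved
#' movement and accuracy; mean performance computed as the absolute
#' value of the mean achieved-minus-prescribed difference (with
#' `mean_abs_perf = mean(|difference|)` as a stricter supplementary
#' column); and FOPE and direction counts with percentages. Excluded
#' records are dropped first. Groups with fewer than 2 records are
#' omitted with a warning.
#'
#' @param records Data frame from [build_records()].
#' @param by `"tooth_type"` (default; grouped within arch with per-arch
#'   totals) or `"arch"` (totals only).
#' @return Data frame, one row per group.
#' @export
group_summary <- function(records, by = c("tooth_type", "arch")) {
  by <- match.arg(by)
  r <- records[!records$excluded, , drop = FALSE]
  if (nrow(r) == 0L) {
    abort("no records remain after exclusion", "rotometry_invalid_input")
  }
  groups <- list()
  for (arch in unique(r$arch)) {
    ra <- r[r$arch == arch, , drop = FALSE]
    if (by == "tooth_type") {
      for (tt in tooth_types()) {
        g <- ra[ra$tooth_type == tt, , drop = FALSE]
        if (nrow(g) == 0L) next
        if (nrow(g) < 2L) {
          warning(sprintf("group %s/%s has < 2 records; omitted",
                          arch, tt))
          next
        }
        groups[[length(groups) + 1L]] <-
          summarise_group(g, c(paste(arch, tt), arch, tt))
      }
    }
    groups[[length(groups) + 1L]] <-
      summarise_group(ra, c(paste("total", arch), arch, "total"))
  }
  do.call(rbind, groups)
}
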