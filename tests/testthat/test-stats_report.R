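test_that("Dahlberg error matches its closed form and is symmetric", {
  x <- c(3, 5, 2, 8, 7, 1, 4, 6)
  expect_equal(dahlberg_error(x, x), 0)
  expect_equal(dahlberg_error(x + 1, x), sqrt(8 / 16))
  set.seed(5)
  y <- x + rnorm(8)
  expect_equal(dahlberg_error(x, y), sqrt(sum((x - y)^2) / 16))
  expect_equal(dahlberg_error(x, y), dahlberg_error(y, x))
  expect_error(dahlberg_error(x, y[1:5]),
               class = "rotometry_invalid_input")
})

test_that("ICC agreement behaves across known variance regimes", {
  set.seed(8)
  item <- rnorm(50, 10, 3)
  expect_equal(icc_agreement(cbind(item, item)), 1, tolerance = 1e-12)

  # noise far larger than the item variance -> ICC near zero
  iccs <- replicate(20, {
    it <- rnorm(30, 0, 1)
    icc_agreement(cbind(it + rnorm(30, 0, 10), it + rnorm(30, 0, 10)))
  })
  expect_lt(mean(abs(iccs)), 0.2)

  # item:error variance 9:1 -> ICC about 0.9
  it <- rnorm(1000, 0, 3)
  r <- cbind(it + rnorm(1000, 0, 1), it + rnorm(1000, 0, 1))
  expect_equal(icc_agreement(r), 0.9, tolerance = 0.03)

  # invariance to a common additive shift
  expect_equal(icc_agreement(r + 100), icc_agreement(r),
               tolerance = 1e-9)
  expect_error(icc_agreement(matrix(5, 10, 2)),
               class = "rotometry_undefined_icc")
  expect_error(icc_agreement(cbind(1:3, 1:3)),
               class = "rotometry_invalid_input")
})

test_that("paired_compare gates on normality and handles degeneracy", {
  x <- rnorm(30, 10, 3)
  deg <- paired_compare(x, x)
  expect_true(deg$degenerate)
  expect_equal(deg$p_value, 1)

  set.seed(12)
  picks <- replicate(400, {
    p <- rnorm(30, 8, 2)
    a <- p + rnorm(30, 0, 1)
    paired_compare(p, a)$test
  })
  # Gaussian differences: t branch selected ~95% of the time
  expect_gt(mean(picks == "paired_t"), 0.90)
  expect_lt(mean(picks == "paired_t"), 0.99)

  skew <- replicate(200, {
    p <- rnorm(30, 8, 2)
    a <- p + rlnorm(30, 0, 1)
    paired_compare(p, a)$test
  })
  expect_gt(mean(skew == "wilcoxon"), 0.5)

  expect_error(paired_compare(1:5, 2:6),
               class = "rotometry_invalid_input")
})

test_that("accuracy regression recovers lines and rejects bad designs", {
  rec <- function(presc, acc) {
    data.frame(prescribed_deg = presc, accuracy_pct = acc,
               excluded = FALSE)
  }
  # flat response
  flat <- accuracy_regression(rec(seq(2, 20, length.out = 12),
                                  rep(80, 12)))
  expect_equal(flat$beta, 0, tolerance = 1e-9)
  expect_gte(flat$p_value, 0.99)

  # two distinct prescribed values: slope is the finite difference
  two <- accuracy_regression(rec(rep(c(4, 10), each = 6),
                                 rep(c(90, 72), each = 6)))
  expect_equal(two$beta, (72 - 90) / (10 - 4), tolerance = 1e-9)

  # seeded linear truth recovered inside its CI
  set.seed(14)
  p <- runif(40, 2, 15)
  fit <- accuracy_regression(rec(p, 90 - 1.5 * p + rnorm(40, 0, 8)))
  expect_true(fit$ci[1L] <= -1.5 && -1.5 <= fit$ci[2L])
  expect_true(fit$ci[1L] <= fit$beta && fit$beta <= fit$ci[2L])

  expect_error(accuracy_regression(rec(rep(5, 12), rnorm(12, 80, 5))),
               class = "rotometry_degenerate")
  expect_error(accuracy_regression(rec(1:5, rnorm(5))),
               class = "rotometry_invalid_input")
})

test_that("paired-t sample size matches theory and simulation", {
  expect_equal(paired_t_sample_size(0.6, 0.05, 0.80), 24L)
  # agreement with stats::power.t.test at several effect sizes
  for (d in c(0.4, 0.8)) {
    n_ours <- paired_t_sample_size(d, 0.05, 0.80)
    n_ref <- ceiling(power.t.test(delta = d, sd = 1, sig.level = 0.05,
                                  power = 0.80, type = "paired")$n)
    expect_equal(n_ours, n_ref)
  }
  # monotone in effect size and in power
  expect_true(paired_t_sample_size(0.3) >= paired_t_sample_size(0.6))
  expect_true(paired_t_sample_size(0.6, power = 0.9) >=
                paired_t_sample_size(0.6, power = 0.8))
  expect_lte(paired_t_sample_size(3), 5)
  expect_gte(paired_t_sample_size(3), 2)
  expect_error(paired_t_sample_size(0), class = "rotometry_invalid_input")

  # the returned n is minimal: Monte-Carlo power straddles 0.80
  n <- paired_t_sample_size(0.6, 0.05, 0.80)
  sim_power <- function(n, reps = 50000L) {
    set.seed(17)
    m <- matrix(rnorm(reps * n, 0.6, 1), ncol = n)
    means <- rowMeans(m)
    sds <- sqrt(rowSums((m - means)^2) / (n - 1))
    tstat <- means / (sds / sqrt(n))
    mean(abs(tstat) > qt(0.975, n - 1))
  }
  expect_equal(sim_power(n), paired_t_power(n, 0.6), tolerance = 0.01)
  expect_gte(sim_power(n) + 0.006, 0.80)      # 3 MC SEs of slack
  expect_lt(sim_power(n - 1L) - 0.006, 0.80)
})

test_that("build_report writes deterministic tables and metadata", {
  set.seed(19)
  n <- 60
  meas <- data.frame(
    case_id = rep(c("a", "b"), each = n / 2),
    arch = rep(c("mandibular", "maxillary"), n / 2),
    fdi = rep(c(31L, 14L), n / 2),
    tooth_type = rep(c("central_incisor", "first_premolar"), n / 2),
    prescribed_deg = runif(n, 2.5, 15),
    achieved_deg = NA)
  meas$achieved_deg <- meas$prescribed_deg * 0.8 + rnorm(n, 0, 1)
  records <- build_records(meas)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- build_report(records, d1, seed = 19)
  f2 <- build_report(records, d2, seed = 19)
  expect_length(f1, 5L)
  expect_true(all(file.exists(f1)))
  csvs <- grep("csv$", f1, value = TRUE)
  for (k in seq_along(csvs)) {
    expect_identical(readLines(csvs[k]),
                     readLines(grep("csv$", f2, value = TRUE)[k]))
  }
  t1 <- read.csv(file.path(d1, "table1_prescription_achieved.csv"))
  # one row per tooth-type group plus one total per arch
  expect_equal(nrow(t1), 4L)
  expect_true(all(t1$test %in% c("paired_t", "wilcoxon", "degenerate")))

  # missing upstream file names the stage
  expect_error(build_report(file.path(d1, "nope.csv"), d2),
               class = "rotometry_stage_error")
})
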