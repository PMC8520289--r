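test_that("stratification is a partition and the headline filter is arithmetic", {
  td <- generate_trials(synth_config(n_studies = 60), seed = 31)
  res <- evaluate_trials(td)
  st <- stratify_results(res)
  expect_false(any(is.na(st$size_band)) || any(is.na(st$rate_band)))
  counts <- table(st$size_band, st$rate_band)
  expect_equal(sum(counts), nrow(res))
  # (95/100 vs 92/100) has pooled rate 0.935 -> high-success small-n stratum
  one <- evaluate_trials(as_trial_data(data.frame(
    study_id = "X", comparison_id = "X_C1",
    treat_successes = 95L, treat_total = 100L,
    ctrl_successes = 92L, ctrl_total = 100L, margin_pct = 10)))
  expect_equal(unique(one$avg_success_rate), 0.935)
  expect_equal(nrow(high_success_small_n(one)), 5)
  # rate exactly 0.90 is excluded by the strict > 0.90 rule
  edge <- one; edge$avg_success_rate <- 0.90
  expect_equal(nrow(high_success_small_n(edge)), 0)
})

test_that("is_one_to_one applies the configurable ratio threshold", {
  expect_true(is_one_to_one(100, 100))
  expect_true(is_one_to_one(110, 100))
  expect_false(is_one_to_one(200, 100))
  expect_true(is_one_to_one(200, 100, ratio_max = 2))
})

test_that("loess_curve reproduces polynomials and matches the WLS oracle", {
  set.seed(6)
  x <- sort(runif(50, 10, 400))
  # exactly linear data are reproduced
  y_lin <- 3 + 0.01 * x
  fit <- loess_curve(x, y_lin, span = 0.75)
  expect_equal(fit$fit, 3 + 0.01 * fit$n, tolerance = 1e-6)
  # constant data give a constant curve
  fit_c <- loess_curve(x, rep(2.5, 50), span = 0.5)
  expect_equal(fit_c$fit, rep(2.5, 100), tolerance = 1e-9)
  # noisy data match the naive per-gridpoint tricube WLS oracle
  y <- 5 + 40 / sqrt(x) + rnorm(50, 0, 0.3)
  grid <- seq(min(x), max(x), length.out = 25)
  fit_n <- loess_curve(x, y, span = 0.75, grid = grid)
  expect_equal(fit_n$fit, oracle_loess(x, y, 0.75, grid), tolerance = 1e-4)
  expect_error(loess_curve(x[1:5], y[1:5]), "at least 10")
})

test_that("subsample_large preserves rates and design ratio", {
  td <- as_trial_data(data.frame(
    study_id = c("A", "B", "C"), comparison_id = c("A1", "B1", "C1"),
    treat_successes = c(300L, 274L, 80L), treat_total = c(400L, 300L, 100L),
    ctrl_successes = c(225L, 270L, 75L), ctrl_total = c(300L, 300L, 100L),
    margin_pct = c(10, 10, 10)))
  set.seed(123)
  sub <- subsample_large(td)
  # small trial untouched
  expect_identical(sub[3, c("x1", "n1", "x2", "n2")],
                   td[3, c("x1", "n1", "x2", "n2")])
  # drawn sizes come from the menu; the 4:3 design ratio is preserved
  expect_true(sub$n2[1] %in% c(50, 100, 150, 200))
  expect_equal(sub$n1[1], round(sub$n2[1] * 400 / 300))
  # success rates preserved to the rounding bound 0.5/new_total
  for (i in 1:2) {
    expect_lte(abs(sub$x1[i] / sub$n1[i] - td$x1[i] / td$n1[i]),
               0.5 / sub$n1[i])
    expect_lte(abs(sub$x2[i] / sub$n2[i] - td$x2[i] / td$n2[i]),
               0.5 / sub$n2[i])
  }
  # stated rounding rule: rate 0.75 at size 100 -> 75; 0.913 at 150 -> 137
  expect_equal(round(100 * 0.75), 75)
  rate_b <- td$x2[2] / td$n2[2]                       # 270/300 = 0.9
  expect_equal(sub$x2[2], round(sub$n2[2] * rate_b))
})

test_that("subsampling is reproducible under a seed and varies across seeds", {
  td <- generate_trials(synth_config(n_studies = 40, arm_median = 300,
                                     arm_iqr = c(220, 420)), seed = 77)
  set.seed(10); a <- subsample_large(td)
  set.seed(10); b <- subsample_large(td)
  expect_identical(a, b)
  set.seed(11); c3 <- subsample_large(td)
  expect_false(identical(a$n1, c3$n1))
})

test_that("sensitivity_sweep passes through when no trial is large", {
  td <- generate_trials(synth_config(n_studies = 20, arm_median = 60,
                                     arm_iqr = c(40, 80)), seed = 12)
  out <- sensitivity_sweep(td, seed = 5)
  expect_equal(out$n_subsampled, 0)
  expect_identical(out$sweep, out$original)
  # inherited invariants on a dataset that does get subsampled
  td2 <- generate_trials(synth_config(n_studies = 30, arm_median = 280,
                                      arm_iqr = c(180, 420)), seed = 13)
  out2 <- sensitivity_sweep(td2, seed = 5)
  expect_gt(out2$n_subsampled, 0)
  ni_cols <- grep("^ni_", names(out2$sweep), value = TRUE)
  for (col in ni_cols) expect_true(all(diff(out2$sweep[[col]]) >= 0))
  expect_true(all(out2$sweep$agreement >= 0 & out2$sweep$agreement <= 1))
})

test_that("synthetic high-success small-n stratum orders Wald below MN", {
  cfg <- synth_config(n_studies = 120, arm_median = 60, arm_iqr = c(40, 80),
                      rate_median = 0.95, rate_iqr = c(0.92, 0.97))
  res <- evaluate_trials(generate_trials(cfg, seed = 2026))
  sub <- high_success_small_n(res)
  expect_gt(length(unique(sub$comparison_id)), 10)
  med_w <- median(sub$width_pct[sub$method == "wald"])
  med_mn <- median(sub$width_pct[sub$method == "miettinen_nurminen"])
  expect_lt(med_w, med_mn)
})
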