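#' Configuration for the synthetic trial-cohort generator
#'
#' Defaults emulate the cohort characteristics of published antibiotic
#' non-inferiority trials: smallest-arm size with median 182 and IQR
#' (101, 291), average treatment success rate with median 0.84 and IQR
#' (0.78, 0.91), 94.6% of comparisons randomized 1:1, margins concentrated
#' at 10 percentage points, a minority of trials reporting failures, a few
#' multi-arm studies sharing one control arm, and 8/224 comparisons without
#' a specified margin.
#'
#' @param n_studies number of studies to generate.
#' @param arm_median,arm_iqr median and IQR (length-2) of the smallest arm
#'   size; sizes are log-normal, calibrated to match the median exactly and
#'   the IQR on the log scale.
#' @param rate_median,rate_iqr median and IQR of the per-study true success
#'   rate; rates are logit-normal, calibrated the same way.
#' @param prop_1to1 probability a study is randomized 1:1 (others use 2:1).
#' @param prop_failure_reported probability a study reports failures.
#' @param prop_missing_margin probability the margin is unspecified.
#' @param margin_choices,margin_probs candidate margins (percentage points)
#'   and their sampling weights.
#' @param prop_multiarm probability a study has two treatment arms sharing
#'   one control arm.
#' @param min_arm smallest admissible arm size.
#' @param seed optional integer seed baked into the config.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_studies = 213,
                         arm_median = 182, arm_iqr = c(101, 291),
                         rate_median = 0.84, rate_iqr = c(0.78, 0.91),
                         prop_1to1 = 0.946,
                         prop_failure_reported = 0.15,
                         prop_missing_margin = 8 / 224,
                         margin_choices = c(10, 12.5, 15),
                         margin_probs = c(0.8, 0.1, 0.1),
                         prop_multiarm = 10 / 213,
                         min_arm = 10,
                         seed = NULL) {
  stopifnot(n_studies >= 0, arm_iqr[1] < arm_median, arm_median < arm_iqr[2],
            rate_iqr[1] < rate_median, rate_median < rate_iqr[2],
            rate_iqr[1] > 0, rate_iqr[2] < 1,
            prop_1to1 >= 0, prop_1to1 <= 1,
            prop_failure_reported >= 0, prop_failure_reported <= 1,
            prop_missing_margin >= 0, prop_missing_margin <= 1,
            length(margin_choices) == length(margin_probs),
            all(margin_probs >= 0), min_arm >= 2)
  structure(as.list(environment()), class = "synth_config")
}

# Two-parameter calibration on a transformed scale: the median pins the
# location, the IQR pins the spread via the normal quartile 0.6744898.
.calib <- function(median, iqr, trans) {
  z75 <- stats::qnorm(0.75)
  c(mu = trans(median), sigma = (trans(iqr[2]) - trans(iqr[1])) / (2 * z75))
}

.logit <- function(p) log(p / (1 - p))
.expit <- function(x) 1 / (1 + exp(-x))

#' Generate a synthetic trial-comparison cohort
#'
#' Draws per-study smallest-arm sizes (log-normal), true success rates
#' (logit-normal, shared by both arms — the non-inferiority null), binomial
#' arm outcomes, allocation ratios, margins and reporting orientation from a
#' [synth_config()], then validates the cohort through the same path as data
#' read from disk.
#'
#' @param config a `synth_config`.
#' @param seed optional integer seed, overriding `config$seed`.
#' @return A `trial_data` data frame.
#' @export
generate_trials <- function(config = synth_config(), seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  ns <- config$n_studies
  if (ns == 0) {
    empty <- as_trial_data(data.frame(study_id = character(),
                                      comparison_id = character(),
                                      treat_successes = integer(),
                                      treat_total = integer(),
                                      ctrl_successes = integer(),
                                      ctrl_total = integer()))
    return(empty)
  }
  ca <- .calib(config$arm_median, config$arm_iqr, log)
  cr <- .calib(config$rate_median, config$rate_iqr, .logit)
  rows <- vector("list", ns)
  for (s in seq_len(ns)) {
    n_small <- max(config$min_arm,
                   round(exp(stats::rnorm(1, ca["mu"], ca["sigma"]))))
    p <- .expit(stats::rnorm(1, cr["mu"], cr["sigma"]))
    p <- min(max(p, 0.02), 0.995)
    one_to_one <- stats::runif(1) < config$prop_1to1
    multi <- stats::runif(1) < config$prop_multiarm
    n_treat_arms <- if (multi) 2L else 1L
    n_ctrl <- n_small
    n_treat <- if (one_to_one) n_small else 2L * n_small
    margin <- if (stats::runif(1) < config$prop_missing_margin) NA_real_
              else config$margin_choices[sample.int(length(config$margin_choices),
                                                    1, prob = config$margin_probs)]
    as_failures <- stats::runif(1) < config$prop_failure_reported
    x_ctrl <- stats::rbinom(1, n_ctrl, p)
    arm_rows <- lapply(seq_len(n_treat_arms), function(a) {
      x_treat <- stats::rbinom(1, n_treat, p)
      r <- data.frame(
        study_id = sprintf("S%04d", s),
        comparison_id = sprintf("S%04d_C%d", s, a),
        treat_successes = if (as_failures) NA_integer_ else x_treat,
        treat_failures = if (as_failures) n_treat - x_treat else NA_integer_,
        treat_total = n_treat,
        ctrl_successes = if (as_failures) NA_integer_ else x_ctrl,
        ctrl_failures = if (as_failures) n_ctrl - x_ctrl else NA_integer_,
        ctrl_total = n_ctrl,
        margin_pct = margin,
        analysis_population = sample(c("ITT", "PP", "unspecified"), 1,
                                     prob = c(0.5, 0.3, 0.2)),
        year = sample(2001:2019, 1),
        reported_ci_method = sample(c("wald", "miettinen_nurminen", "newcombe",
                                      "agresti_caffo", NA), 1,
                                    prob = c(0.18, 0.12, 0.05, 0.01, 0.64)),
        randomization_label = if (one_to_one) "1:1" else "2:1",
        stringsAsFactors = FALSE)
      r
    })
    rows[[s]] <- do.call(rbind, arm_rows)
  }
  as_trial_data(do.call(rbind, rows))
}

#' A fixed six-comparison fixture dataset
#'
#' Small hand-written cohort exercising every code path: an ordinary 1:1
#' trial, a degenerate 100%-success arm, a failure-reported trial, a missing
#' margin, and a two-treatment-arm study sharing one control (one of its
#' comparisons randomized 2:1).  Shipped in CSV form as
#' `system.file("extdata", "example_trials.csv", package = "rdci")`.
#'
#' @param raw logical; if `TRUE` return the raw schema data frame (as
#'   written to CSV) instead of validated `trial_data`.
#' @return A `trial_data` data frame with 6 comparisons (or the raw schema).
#' @export
generate_fixture <- function(raw = FALSE) {
  df <- data.frame(
    study_id = c("S1", "S2", "S3", "S4", "S5", "S5"),
    comparison_id = c("S1_C1", "S2_C1", "S3_C1", "S4_C1", "S5_C1", "S5_C2"),
    treat_successes = c(80L, 60L, NA, 150L, 190L, 95L),
    treat_failures = c(NA, NA, 5L, NA, NA, NA),
    treat_total = c(100L, 60L, 120L, 182L, 200L, 100L),
    ctrl_successes = c(78L, 58L, NA, 148L, 90L, 90L),
    ctrl_failures = c(NA, NA, 8L, NA, NA, NA),
    ctrl_total = c(100L, 60L, 118L, 180L, 100L, 100L),
    margin_pct = c(10, 10, 12.5, NA, 10, 10),
    analysis_population = c("ITT", "ITT", "PP", "unspecified", "ITT", "ITT"),
    year = c(2012L, 2015L, 2008L, 2019L, 2010L, 2010L),
    reported_ci_method = c("wald", NA, "miettinen_nurminen", NA, "newcombe",
                           "newcombe"),
    randomization_label = c("1:1", "1:1", "1:1", "1:1", "2:1", "1:1"),
    stringsAsFactors = FALSE
  )
  if (raw) df else as_trial_data(df)
}
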