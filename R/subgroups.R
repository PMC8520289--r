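# Default stratification bands.  Success bands are half-open (lo, hi], so the
# headline high-success band is "rate above 0.90"; size bands likewise with
# the headline small-trial band at smallest arm <= 100.
RD_RATE_BREAKS <- c(0, 0.30, 0.70, 0.80, 0.90, 1)
RD_SIZE_BREAKS <- c(0, 100, 200, Inf)

#' Stratify evaluated comparisons by arm size and success rate
#'
#' Partitions comparisons into bands of smallest arm size and average
#' success rate (pooled successes over pooled patients).  Every comparison
#' falls in exactly one stratum.
#'
#' @param results an `rd_results` data frame from [evaluate_trials()].
#' @param rate_breaks,size_breaks band edges; bands are half-open `(lo, hi]`.
#' @return The results with `size_band` and `rate_band` factor columns added.
#' @export
stratify_results <- function(results, rate_breaks = RD_RATE_BREAKS,
                             size_breaks = RD_SIZE_BREAKS) {
  stopifnot(is.data.frame(results),
            all(diff(rate_breaks) > 0), all(diff(size_breaks) > 0))
  results$size_band <- cut(results$smallest_arm_n, size_breaks,
                           include.lowest = TRUE)
  results$rate_band <- cut(results$avg_success_rate, rate_breaks,
                           include.lowest = TRUE)
  results
}

#' The high-success / small-trial subgroup
#'
#' Selects comparisons with average success rate strictly above `min_rate`
#' and smallest arm size at most `max_n` — the regime where the five methods
#' disagree most.
#'
#' @param results an `rd_results` data frame.
#' @param max_n largest smallest-arm size admitted, default 100.
#' @param min_rate exclusive lower bound on the average success rate,
#'   default 0.90.
#' @return Subset of `results`.
#' @export
high_success_small_n <- function(results, max_n = 100, min_rate = 0.90) {
  stopifnot(is.data.frame(results))
  results[results$smallest_arm_n <= max_n & results$avg_success_rate > min_rate, ]
}

#' Identify comparisons randomized approximately 1:1
#'
#' The source trials label their allocation, but as a computable rule a
#' comparison counts as approximately 1:1 when the larger arm is at most
#' `ratio_max` times the smaller.
#'
#' @param n1,n2 arm totals.
#' @param ratio_max allocation-ratio threshold, default 1.2.
#' @return Logical vector.
#' @export
is_one_to_one <- function(n1, n2, ratio_max = 1.2) {
  stopifnot(all(n1 >= 1), all(n2 >= 1), ratio_max >= 1)
  pmax(n1, n2) / pmin(n1, n2) <= ratio_max
}

#' Smoothed width-versus-size curve
#'
#' Local polynomial regression (degree 2, tricube weights) of a per-method
#' quantity against smallest arm size, evaluated on a size grid; the smooth
#' behind width-versus-sample-size displays.
#'
#' @param n numeric predictor (smallest arm size).
#' @param y response (CI width or width difference, percentage points).
#' @param span loess span in (0, 1], default 0.75.
#' @param grid evaluation points; defaults to 100 points spanning `n`.
#' @return Data frame with columns `n` and `fit`.
#' @export
loess_curve <- function(n, y, span = 0.75, grid = NULL) {
  stopifnot(length(n) == length(y), span > 0, span <= 1)
  if (length(n) < 10) stop("need at least 10 points for a loess curve")
  if (is.null(grid)) grid <- seq(min(n), max(n), length.out = 100)
  fit <- stats::loess(y ~ n, data = data.frame(n = n, y = y), span = span,
                      degree = 2, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  data.frame(n = grid, fit = stats::predict(fit, newdata = data.frame(n = grid)))
}

#' Subsample large trials to small-trial sizes
#'
#' For every comparison whose smallest arm exceeds 200 patients, draws one
#' new size uniformly from `sizes` for the smaller arm, scales the other arm
#' by the original allocation ratio, and sets successes to
#' `round(new_total * original rate)`, preserving each arm's success rate up
#' to rounding.  Comparisons at or below the threshold pass through
#' unchanged.  Reproducible under a fixed RNG state.
#'
#' @param trials a `trial_data` data frame.
#' @param sizes candidate new sizes, default `c(50, 100, 150, 200)`.
#' @param threshold smallest-arm size above which a trial is subsampled.
#' @return A `trial_data` data frame of the same shape.
#' @export
subsample_large <- function(trials, sizes = c(50, 100, 150, 200),
                            threshold = 200) {
  stopifnot(is.data.frame(trials), all(sizes >= 1))
  out <- trials
  small <- pmin(trials$n1, trials$n2)
  big_idx <- which(small > threshold)
  if (!length(big_idx)) return(out)
  draw <- sample(sizes, length(big_idx), replace = TRUE)
  for (k in seq_along(big_idx)) {
    i <- big_idx[k]
    ratio <- max(trials$n1[i], trials$n2[i]) / small[i]
    new_small <- draw[k]
    new_big <- as.integer(round(new_small * ratio))
    if (trials$n1[i] <= trials$n2[i]) {
      new_n1 <- new_small; new_n2 <- new_big
    } else {
      new_n1 <- new_big; new_n2 <- new_small
    }
    out$x1[i] <- as.integer(round(new_n1 * trials$x1[i] / trials$n1[i]))
    out$n1[i] <- as.integer(new_n1)
    out$x2[i] <- as.integer(round(new_n2 * trials$x2[i] / trials$n2[i]))
    out$n2[i] <- as.integer(new_n2)
  }
  out
}

#' Margin sweep after subsampling large trials
#'
#' Sensitivity analysis: reruns the margin sweep on a copy of the dataset in
#' which every trial with smallest arm above 200 has been subsampled to a
#' random small size with the same success rates.
#'
#' @param trials a `trial_data` data frame.
#' @param margins_pct margin grid, default `0:20`.
#' @param level confidence level.
#' @param seed optional integer seed for the size draws.
#' @return List with `sweep` (the subsampled [margin_sweep()] result),
#'   `original` (the plain sweep) and `n_subsampled`.
#' @export
sensitivity_sweep <- function(trials, margins_pct = 0:20, level = 0.95,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sub <- subsample_large(trials)
  res_orig <- evaluate_trials(trials, level)
  res_sub <- evaluate_trials(sub, level)
  list(sweep = margin_sweep(res_sub, margins_pct),
       original = margin_sweep(res_orig, margins_pct),
       n_subsampled = sum(pmin(trials$n1, trials$n2) > 200))
}
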