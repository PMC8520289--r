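.coverage_result <- function(method, n1, n2, p1, p2, level,
                             coverage, left, right, ew, engine, reps = NA) {
  structure(list(method = method, n1 = n1, n2 = n2, p1 = p1, p2 = p2,
                 level = level, coverage = coverage,
                 left_noncoverage = left, right_noncoverage = right,
                 expected_width = ew, engine = engine, reps = reps),
            class = "rd_coverage")
}

#' @export
print.rd_coverage <- function(x, ...) {
  cat(sprintf("%s coverage (%s) at n=(%d,%d), p=(%.3f,%.3f), level %.2f\n",
              x$method, x$engine, x$n1, x$n2, x$p1, x$p2, x$level))
  cat(sprintf("  coverage %.5f (left %.5f, right %.5f), E[width] %.5f\n",
              x$coverage, x$left_noncoverage, x$right_noncoverage,
              x$expected_width))
  invisible(x)
}

#' @export
as.data.frame.rd_coverage <- function(x, ...) {
  data.frame(method = x$method, n1 = x$n1, n2 = x$n2, p1 = x$p1, p2 = x$p2,
             level = x$level, coverage = x$coverage,
             left_noncoverage = x$left_noncoverage,
             right_noncoverage = x$right_noncoverage,
             expected_width = x$expected_width, engine = x$engine,
             stringsAsFactors = FALSE)
}

# limits for every outcome of the (n1+1) x (n2+1) sample space, as a list of
# (x1, x2, lower, upper) with one row per outcome
.enumerate_limits <- function(method, n1, n2, level) {
  x1 <- rep(0:n1, times = n2 + 1)
  x2 <- rep(0:n2, each = n1 + 1)
  lim <- .limits_for(method, x1, rep.int(n1, length(x1)),
                     x2, rep.int(n2, length(x2)), level)
  list(x1 = x1, x2 = x2, lower = lim[, 1], upper = lim[, 2])
}

#' Exact coverage probability by enumeration
#'
#' Enumerates all `(n1+1)(n2+1)` outcomes of two independent binomials,
#' computes the interval for each, and sums the outcome probabilities for
#' which the interval covers the true difference `p1 - p2`.  Intervals are
#' treated as closed: a limit exactly at the true difference counts as
#' covered.
#'
#' @param method one of `"wald"`, `"agresti_caffo"`, `"newcombe"`,
#'   `"miettinen_nurminen"`, `"scas"`.
#' @param n1,n2 arm sizes (enumeration is quadratic; keep below ~200).
#' @param p1,p2 true success proportions.
#' @param level nominal two-sided confidence level.
#' @return An `rd_coverage` object with coverage, the left and right
#'   non-coverage components and the expected interval width.
#' @export
exact_coverage <- function(method, n1, n2, p1, p2, level = 0.95) {
  stopifnot(method %in% RD_METHODS, n1 >= 1, n2 >= 1,
            p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  .check_level(level)
  e <- .enumerate_limits(method, n1, n2, level)
  pr <- stats::dbinom(e$x1, n1, p1) * stats::dbinom(e$x2, n2, p2)
  d <- p1 - p2
  left <- sum(pr[e$lower > d])     # interval entirely above the truth
  right <- sum(pr[e$upper < d])    # interval entirely below the truth
  cov <- sum(pr[e$lower <= d & e$upper >= d])
  ew <- sum(pr * (e$upper - e$lower))
  .coverage_result(method, n1, n2, p1, p2, level, cov, left, right, ew, "exact")
}

#' Monte-Carlo coverage probability
#'
#' Simulates `reps` pairs of binomial outcomes and reports the fraction of
#' intervals covering the true difference.  Intervals are computed once per
#' distinct observed table, so large `reps` stay cheap.
#'
#' @inheritParams exact_coverage
#' @param reps number of simulated trials, at least 1.
#' @param seed optional integer seed.
#' @return An `rd_coverage` object (engine `"monte_carlo"`).
#' @export
mc_coverage <- function(method, n1, n2, p1, p2, level = 0.95,
                        reps = 10000, seed = NULL) {
  stopifnot(method %in% RD_METHODS, reps >= 1)
  .check_level(level)
  if (!is.null(seed)) set.seed(seed)
  x1 <- stats::rbinom(reps, n1, p1)
  x2 <- stats::rbinom(reps, n2, p2)
  key <- x1 * (n2 + 1L) + x2
  tab <- table(key)
  ux <- as.integer(names(tab))
  ux1 <- ux %/% (n2 + 1L); ux2 <- ux %% (n2 + 1L)
  lim <- .limits_for(method, ux1, rep.int(n1, length(ux1)),
                     ux2, rep.int(n2, length(ux2)), level)
  w <- as.numeric(tab) / reps
  d <- p1 - p2
  left <- sum(w[lim[, 1] > d])
  right <- sum(w[lim[, 2] < d])
  cov <- sum(w[lim[, 1] <= d & lim[, 2] >= d])
  ew <- sum(w * (lim[, 2] - lim[, 1]))
  .coverage_result(method, n1, n2, p1, p2, level, cov, left, right, ew,
                   "monte_carlo", reps)
}
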