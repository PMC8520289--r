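RD_METHODS <- c("wald", "agresti_caffo", "newcombe", "miettinen_nurminen", "scas")

# Width ordering used to break exact width ties when a single "most
# conservative" winner per comparison is required (widest-on-average first).
RD_CONSERVATISM_ORDER <- c("miettinen_nurminen", "scas", "newcombe",
                           "agresti_caffo", "wald")

.check_table <- function(x1, n1, x2, n2) {
  stopifnot(length(x1) == length(n1), length(x2) == length(n2),
            length(x1) == length(x2))
  bad <- !is.finite(x1) | !is.finite(n1) | !is.finite(x2) | !is.finite(n2) |
    x1 < 0 | x2 < 0 | n1 < 1 | n2 < 1 | x1 > n1 | x2 > n2 |
    x1 != round(x1) | x2 != round(x2) | n1 != round(n1) | n2 != round(n2)
  if (any(bad))
    stop("invalid 2x2 table(s): need integer 0 <= successes <= total, total >= 1 (rows ",
         paste(which(bad), collapse = ", "), ")")
  invisible(NULL)
}

.check_level <- function(level) {
  stopifnot(is.numeric(level), length(level) == 1, level > 0, level < 1)
  invisible(NULL)
}

.zcrit <- function(level) stats::qnorm(1 - (1 - level) / 2)

.new_rd_ci <- function(method, estimate, lower, upper, level) {
  structure(list(method = method, estimate = unname(estimate),
                 lower = unname(lower), upper = unname(upper), level = level,
                 width = unname(upper - lower)),
            class = "rd_ci")
}

#' @export
print.rd_ci <- function(x, ...) {
  cat(sprintf("%s %.0f%% CI for risk difference\n", x$method, 100 * x$level))
  cat(sprintf("  estimate %.4f, CI (%.4f, %.4f), width %.4f\n",
              x$estimate, x$lower, x$upper, x$width))
  invisible(x)
}

#' @export
as.data.frame.rd_ci <- function(x, ...) {
  data.frame(method = x$method, estimate = x$estimate, lower = x$lower,
             upper = x$upper, width = x$width, level = x$level,
             stringsAsFactors = FALSE)
}

# ---- closed-form methods (vectorised internals) ----------------------------

.wald_limits <- function(x1, n1, x2, n2, level) {
  p1 <- x1 / n1; p2 <- x2 / n2
  d <- p1 - p2
  se <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  z <- .zcrit(level)
  cbind(lower = pmax(d - z * se, -1), upper = pmin(d + z * se, 1))
}

.ac_limits <- function(x1, n1, x2, n2, level) {
  .wald_limits(x1 + 1, n1 + 2, x2 + 1, n2 + 2, level)
}

.wilson_limits <- function(x, n, level) {
  z <- .zcrit(level)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  cbind(lower = pmax(centre - half, 0), upper = pmin(centre + half, 1))
}

.newcombe_limits <- function(x1, n1, x2, n2, level) {
  p1 <- x1 / n1; p2 <- x2 / n2
  d <- p1 - p2
  w1 <- .wilson_limits(x1, n1, level)
  w2 <- .wilson_limits(x2, n2, level)
  lower <- d - sqrt((p1 - w1[, "lower"])^2 + (w2[, "upper"] - p2)^2)
  upper <- d + sqrt((w1[, "upper"] - p1)^2 + (p2 - w2[, "lower"])^2)
  cbind(lower = lower, upper = upper)
}

# ---- restricted MLE under p1 - p2 = d (vectorised over tables and d) -------

# Closed-form solution of the cubic score equation for the constrained MLE of
# the control-arm proportion (Miettinen & Nurminen 1985).  All arguments are
# recycled to a common length.  Degenerate cubics (discriminant collapses to
# zero) fall back to a bounded one-dimensional likelihood maximisation.
.rmle_p2 <- function(x1, n1, x2, n2, d) {
  m <- max(length(x1), length(d))
  x1 <- rep_len(x1, m); n1 <- rep_len(n1, m)
  x2 <- rep_len(x2, m); n2 <- rep_len(n2, m); d <- rep_len(d, m)
  N <- n1 + n2
  L3 <- N
  L2 <- (n1 + 2 * n2) * d - N - (x1 + x2)
  L1 <- (n2 * d - N - 2 * x2) * d + x1 + x2
  L0 <- x2 * d * (1 - d)
  q <- L2^3 / (3 * L3)^3 - L1 * L2 / (6 * L3^2) + L0 / (2 * L3)
  p <- sign(q) * sqrt(pmax(L2^2 / (3 * L3)^2 - L1 / (3 * L3), 0))
  a <- (pi + acos(pmin(pmax(q / p^3, -1), 1))) / 3
  p2 <- 2 * p * cos(a) - L2 / (3 * L3)
  lo <- pmax(0, -d); hi <- pmin(1, 1 - d)
  p2 <- pmin(pmax(p2, lo), hi)
  bad <- !is.finite(p2) | abs(p)^3 < 1e-300
  if (any(bad)) {
    ll <- function(x, n, pr) {
      out <- numeric(length(pr))
      inb <- pr > 0 & pr < 1
      out[inb] <- x * log(pr[inb]) + (n - x) * log1p(-pr[inb])
      out[!inb & pr <= 0] <- ifelse(x == 0, 0, -Inf)
      out[!inb & pr >= 1] <- ifelse(x == n, 0, -Inf)
      out
    }
    for (i in which(bad)) {
      f <- function(pr) ll(x1[i], n1[i], pr + d[i]) + ll(x2[i], n2[i], pr)
      if (hi[i] - lo[i] < 1e-12) p2[i] <- lo[i]
      else p2[i] <- stats::optimize(f, c(lo[i], hi[i]), maximum = TRUE,
                                    tol = 1e-12)$maximum
    }
  }
  p2
}

#' Restricted maximum likelihood estimates under a fixed risk difference
#'
#' Maximises the two-binomial log-likelihood subject to the constraint
#' `p1 - p2 = d`, using the closed-form cubic solution of the constrained
#' score equation.  These constrained proportions drive the
#' Miettinen-Nurminen score statistic and its skewness-corrected variant.
#'
#' @param x1,n1 successes and total in the treatment arm.
#' @param x2,n2 successes and total in the control arm.
#' @param d hypothesised risk difference, strictly inside (-1, 1).
#' @return Numeric vector `c(p1, p2)` of constrained proportions.
#' @examples
#' restricted_mle(8, 10, 6, 10, d = 0)
#' @export
restricted_mle <- function(x1, n1, x2, n2, d) {
  .check_table(x1, n1, x2, n2)
  stopifnot(length(d) == 1, is.finite(d), abs(d) < 1)
  p2 <- .rmle_p2(x1, n1, x2, n2, d)
  c(p1 = p2 + d, p2 = p2)
}

# Constrained variance of the difference, with the N/(N-1) inflation of
# Miettinen & Nurminen.  Vectorised.
.mn_variance <- function(n1, n2, p1t, p2t) {
  N <- n1 + n2
  (p1t * (1 - p1t) / n1 + p2t * (1 - p2t) / n2) * N / (N - 1)
}

.mn_z <- function(x1, n1, x2, n2, d) {
  p2t <- .rmle_p2(x1, n1, x2, n2, d)
  p1t <- p2t + d
  V <- .mn_variance(rep_len(n1, length(p2t)), rep_len(n2, length(p2t)), p1t, p2t)
  dh <- rep_len(x1 / n1 - x2 / n2, length(p2t))
  z <- (dh - rep_len(d, length(p2t))) / sqrt(V)
  degen <- V <= 0
  if (any(degen))
    z[degen] <- ifelse(dh[degen] == rep_len(d, length(p2t))[degen], 0,
                       sign(dh[degen] - rep_len(d, length(p2t))[degen]) * Inf)
  z
}

# Skewness-corrected score statistic: z - gamma * (z^2 - 1), with
# gamma = mu3 / (6 V^{3/2}) built from the constrained third central moment.
.scas_stat <- function(x1, n1, x2, n2, d) {
  p2t <- .rmle_p2(x1, n1, x2, n2, d)
  p1t <- p2t + d
  m <- length(p2t)
  n1 <- rep_len(n1, m); n2 <- rep_len(n2, m)
  V <- .mn_variance(n1, n2, p1t, p2t)
  dh <- rep_len(x1, m) / n1 - rep_len(x2, m) / n2
  dd <- rep_len(d, m)
  mu3 <- p1t * (1 - p1t) * (1 - 2 * p1t) / n1^2 -
    p2t * (1 - p2t) * (1 - 2 * p2t) / n2^2
  z <- (dh - dd) / sqrt(V)
  g <- mu3 / (6 * V^1.5)
  out <- z - g * (z^2 - 1)
  degen <- !is.finite(V) | V <= 0
  if (any(degen))
    out[degen] <- ifelse(dh[degen] == dd[degen], 0,
                         sign(dh[degen] - dd[degen]) * Inf)
  out
}

#' Miettinen-Nurminen score statistic
#'
#' Signed z-value of the score test of `H0: p1 - p2 = d`, using restricted
#' MLE proportions and the N/(N-1) variance inflation.
#'
#' @inheritParams restricted_mle
#' @return Signed z-value; zero at the observed difference, positive below it.
#' @export
mn_score <- function(x1, n1, x2, n2, d) {
  .check_table(x1, n1, x2, n2)
  stopifnot(length(d) == 1, is.finite(d), abs(d) < 1)
  as.numeric(.mn_z(x1, n1, x2, n2, d))
}

# ---- score-interval inversion (vectorised over tables) ---------------------

# Finds, for each table, the root of statfun(d) = +crit nearest the point
# estimate on [-1, dhat] (lower limit) and of statfun(d) = -crit on [dhat, 1]
# (upper limit).  A coarse outward scan brackets the sign change nearest dhat
# (the skewness-corrected statistic need not be monotone far from dhat),
# then bisection refines it to `tol`.  Sides with no sign change return the
# boundary value -1 or 1 exactly.
.invert_score <- function(x1, n1, x2, n2, level, statfun,
                          nscan = 512L, tol = 1e-8, maxit = 200L) {
  m <- length(x1)
  crit <- .zcrit(level)
  dh <- x1 / n1 - x2 / n2
  eps <- 1e-10
  out <- matrix(NA_real_, m, 2, dimnames = list(NULL, c("lower", "upper")))
  for (side in c("lower", "upper")) {
    sgn <- if (side == "lower") 1 else -1          # target: statfun = sgn*crit
    a <- pmin(pmax(dh, -1 + eps), 1 - eps)         # scan start (point estimate)
    b <- if (side == "lower") rep(-1 + eps, m) else rep(1 - eps, m)
    step <- (b - a) / nscan
    # scan outward from the point estimate toward the boundary and bracket the
    # sign change of f(d) = statfun(d) - sgn*crit nearest the point estimate
    prev_d <- a
    prev_f <- statfun(x1, n1, x2, n2, a) - sgn * crit
    lo <- a; hi <- a
    found <- rep(FALSE, m)
    for (k in seq_len(nscan)) {
      cur_d <- a + k * step
      cur_f <- statfun(x1, n1, x2, n2, cur_d) - sgn * crit
      new <- !found & is.finite(cur_f) & is.finite(prev_f) &
        (sign(cur_f) != sign(prev_f) | cur_f == 0)
      lo[new] <- prev_d[new]
      hi[new] <- cur_d[new]
      found <- found | new
      if (all(found)) break
      prev_d <- cur_d
      prev_f <- cur_f
    }
    res <- if (side == "lower") rep(-1, m) else rep(1, m)
    idx <- which(found)
    if (length(idx)) {
      la <- lo[idx]; lb <- hi[idx]
      xi1 <- x1[idx]; ni1 <- n1[idx]; xi2 <- x2[idx]; ni2 <- n2[idx]
      fa <- statfun(xi1, ni1, xi2, ni2, la) - sgn * crit
      for (it in seq_len(maxit)) {
        mid <- (la + lb) / 2
        fm <- statfun(xi1, ni1, xi2, ni2, mid) - sgn * crit
        takea <- sign(fm) == sign(fa) & fm != 0
        la[takea] <- mid[takea]; fa[takea] <- fm[takea]
        lb[!takea] <- mid[!takea]
        if (max(abs(lb - la)) < tol) break
      }
      if (max(abs(lb - la)) >= tol)
        stop("score-interval bisection failed to converge within ", maxit,
             " iterations (bracket width ", max(abs(lb - la)), ")")
      res[idx] <- (la + lb) / 2
    }
    out[, side] <- res
  }
  # degenerate dh at the boundary: that side's limit is the boundary itself
  out[, "lower"] <- pmin(out[, "lower"], dh)
  out[, "upper"] <- pmax(out[, "upper"], dh)
  out
}

# ---- exported single-table interfaces ---------------------------------------

#' Wald confidence interval for a risk difference
#'
#' Normal-approximation interval `d +/- z * sqrt(p1 q1/n1 + p2 q2/n2)`,
#' truncated to `[-1, 1]`.  Zero-variance tables (all arms at 0% or 100%)
#' collapse to a zero-width interval at the point estimate, the well-known
#' Wald degeneracy.
#'
#' @inheritParams restricted_mle
#' @param level two-sided confidence level in (0, 1), default 0.95.
#' @return An object of class `rd_ci`.
#' @examples
#' ci_wald(8, 10, 6, 10)
#' @export
ci_wald <- function(x1, n1, x2, n2, level = 0.95) {
  .check_table(x1, n1, x2, n2); .check_level(level)
  lim <- .wald_limits(x1, n1, x2, n2, level)
  .new_rd_ci("wald", x1 / n1 - x2 / n2, lim[1, 1], lim[1, 2], level)
}

#' Agresti-Caffo adjusted Wald interval
#'
#' Adds one success and one failure to each arm and applies the Wald formula
#' to the augmented counts; the interval is centred at the augmented
#' estimate, not at the raw difference.
#'
#' @inheritParams ci_wald
#' @return An object of class `rd_ci`; `estimate` is the raw difference.
#' @export
ci_agresti_caffo <- function(x1, n1, x2, n2, level = 0.95) {
  .check_table(x1, n1, x2, n2); .check_level(level)
  lim <- .ac_limits(x1, n1, x2, n2, level)
  .new_rd_ci("agresti_caffo", x1 / n1 - x2 / n2, lim[1, 1], lim[1, 2], level)
}

#' Wilson score interval for a single proportion
#'
#' @param x,n successes and total for one arm.
#' @param level two-sided confidence level in (0, 1).
#' @return An object of class `rd_ci` (method `"wilson"`, limits in `[0, 1]`).
#' @export
ci_wilson <- function(x, n, level = 0.95) {
  stopifnot(length(x) == 1, length(n) == 1, x >= 0, n >= 1, x <= n)
  .check_level(level)
  lim <- .wilson_limits(x, n, level)
  .new_rd_ci("wilson", x / n, lim[1, 1], lim[1, 2], level)
}

#' Newcombe hybrid score interval
#'
#' Combines the two arms' Wilson score intervals by the square-and-add rule:
#' the distance from each Wilson limit to its arm proportion contributes in
#' quadrature to the corresponding limit of the difference.
#'
#' @inheritParams ci_wald
#' @return An object of class `rd_ci`.
#' @export
ci_newcombe <- function(x1, n1, x2, n2, level = 0.95) {
  .check_table(x1, n1, x2, n2); .check_level(level)
  lim <- .newcombe_limits(x1, n1, x2, n2, level)
  .new_rd_ci("newcombe", x1 / n1 - x2 / n2, lim[1, 1], lim[1, 2], level)
}

#' Miettinen-Nurminen score interval
#'
#' Inverts the score test of `p1 - p2 = d` with restricted-MLE variance and
#' the N/(N-1) inflation: the limits are the two roots of `|z(d)| = z_crit`.
#' A side on which the statistic never reaches the critical value returns the
#' boundary -1 or 1 exactly.
#'
#' @inheritParams ci_wald
#' @return An object of class `rd_ci`.
#' @export
ci_mn <- function(x1, n1, x2, n2, level = 0.95) {
  .check_table(x1, n1, x2, n2); .check_level(level)
  lim <- .invert_score(x1, n1, x2, n2, level, .mn_z)
  .new_rd_ci("miettinen_nurminen", x1 / n1 - x2 / n2, lim[1, 1], lim[1, 2], level)
}

#' Skewness-corrected asymptotic score interval
#'
#' Augments the Miettinen-Nurminen score statistic with a skewness term:
#' the limits are roots of `z(d) - gamma(d) (z(d)^2 - 1) = +/- z_crit`, where
#' `gamma = mu3 / (6 V^{3/2})` uses the constrained third central moment of
#' the difference.  With the skewness coefficient forced to zero the interval
#' reduces exactly to the Miettinen-Nurminen interval.
#'
#' @inheritParams ci_wald
#' @param skew logical; set `FALSE` to force the skewness coefficient to zero
#'   (then the result equals [ci_mn()]).  Mainly for testing.
#' @return An object of class `rd_ci`.
#' @export
ci_scas <- function(x1, n1, x2, n2, level = 0.95, skew = TRUE) {
  .check_table(x1, n1, x2, n2); .check_level(level)
  statfun <- if (skew) .scas_stat else .mn_z
  lim <- .invert_score(x1, n1, x2, n2, level, statfun)
  .new_rd_ci("scas", x1 / n1 - x2 / n2, lim[1, 1], lim[1, 2], level)
}

# Vectorised limits for one method over many tables; used by the pipeline and
# the coverage engine.  Returns a 2-column matrix.
.limits_for <- function(method, x1, n1, x2, n2, level) {
  switch(method,
    wald = .wald_limits(x1, n1, x2, n2, level),
    agresti_caffo = .ac_limits(x1, n1, x2, n2, level),
    newcombe = .newcombe_limits(x1, n1, x2, n2, level),
    miettinen_nurminen = .invert_score(x1, n1, x2, n2, level, .mn_z),
    scas = .invert_score(x1, n1, x2, n2, level, .scas_stat),
    stop("unknown method: ", method))
}

#' All five risk-difference intervals for one 2x2 table
#'
#' @inheritParams ci_wald
#' @return A data frame with one row per method: `method`, `estimate`,
#'   `lower`, `upper`, `width`, `level`.
#' @examples
#' ci_all(8, 10, 6, 10)
#' @export
ci_all <- function(x1, n1, x2, n2, level = 0.95) {
  .check_table(x1, n1, x2, n2); .check_level(level)
  rows <- lapply(RD_METHODS, function(m) {
    lim <- .limits_for(m, x1, n1, x2, n2, level)
    data.frame(method = m, estimate = x1 / n1 - x2 / n2,
               lower = lim[1, 1], upper = lim[1, 2],
               width = lim[1, 2] - lim[1, 1], level = level,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
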