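# Independent brute-force oracles.  These deliberately share no code with the
# package internals: the constrained MLE is found by likelihood grid search
# (not the cubic), and score-interval limits by locating sign changes of the
# statistic on a d grid refined to 1e-5.

z_of <- function(level) qnorm(1 - (1 - level) / 2)

oracle_wald <- function(x1, n1, x2, n2, level = 0.95) {
  p1 <- x1 / n1; p2 <- x2 / n2
  half <- z_of(level) * sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  c(max(p1 - p2 - half, -1), min(p1 - p2 + half, 1))
}

oracle_wilson <- function(x, n, level = 0.95) {
  # roots of (phat - p)^2 = z^2 p (1-p) / n via the quadratic formula
  z2 <- z_of(level)^2
  p <- x / n
  a <- 1 + z2 / n
  b <- -(2 * p + z2 / n)
  cc <- p^2
  disc <- sqrt(b^2 - 4 * a * cc)
  c((-b - disc) / (2 * a), (-b + disc) / (2 * a))
}

oracle_newcombe <- function(x1, n1, x2, n2, level = 0.95) {
  p1 <- x1 / n1; p2 <- x2 / n2
  w1 <- oracle_wilson(x1, n1, level); w2 <- oracle_wilson(x2, n2, level)
  c(p1 - p2 - sqrt((p1 - w1[1])^2 + (w2[2] - p2)^2),
    p1 - p2 + sqrt((w1[2] - p1)^2 + (p2 - w2[1])^2))
}

# log-likelihood of the two-binomial model, safe at the boundaries
oracle_ll <- function(x, n, p) {
  out <- numeric(length(p))
  inb <- p > 0 & p < 1
  out[inb] <- x * log(p[inb]) + (n - x) * log1p(-p[inb])
  out[!inb & p <= 0] <- if (x == 0) 0 else -Inf
  out[!inb & p >= 1] <- if (x == n) 0 else -Inf
  out
}

# constrained MLE of p2 under p1 - p2 = d by two-stage grid search
oracle_rmle_p2 <- function(x1, n1, x2, n2, d, coarse = 1e-3, fine = 1e-6) {
  lo <- max(0, -d); hi <- min(1, 1 - d)
  if (hi - lo < fine) return(lo)
  g <- seq(lo, hi, by = coarse)
  f <- oracle_ll(x1, n1, g + d) + oracle_ll(x2, n2, g)
  best <- g[which.max(f)]
  g2 <- seq(max(lo, best - 2 * coarse), min(hi, best + 2 * coarse), by = fine)
  f2 <- oracle_ll(x1, n1, g2 + d) + oracle_ll(x2, n2, g2)
  g2[which.max(f2)]
}

oracle_stat <- function(x1, n1, x2, n2, d, skew = FALSE) {
  p2 <- oracle_rmle_p2(x1, n1, x2, n2, d)
  p1 <- p2 + d
  N <- n1 + n2
  V <- (p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2) * N / (N - 1)
  dh <- x1 / n1 - x2 / n2
  if (V <= 0) return(if (dh == d) 0 else sign(dh - d) * Inf)
  z <- (dh - d) / sqrt(V)
  if (!skew) return(z)
  mu3 <- p1 * (1 - p1) * (1 - 2 * p1) / n1^2 - p2 * (1 - p2) * (1 - 2 * p2) / n2^2
  z - mu3 / (6 * V^1.5) * (z^2 - 1)
}

# score-interval limit on one side: walk outward from the point estimate on a
# coarse d grid until the statistic first crosses -/+ crit (the crossing
# nearest dhat), then locate the root on successively finer grids ending with
# step 1e-5 inside the bracket
oracle_score_limit <- function(x1, n1, x2, n2, level, side, skew = FALSE,
                               coarse = 1e-2) {
  crit <- z_of(level)
  dh <- x1 / n1 - x2 / n2
  sgn <- if (side == "lower") 1 else -1
  dir <- if (side == "lower") -1 else 1
  bnd <- dir * (1 - 1e-9)
  f_of <- function(d) oracle_stat(x1, n1, x2, n2, d, skew) - sgn * crit
  prev_d <- min(max(dh, -1 + 1e-9), 1 - 1e-9)
  prev_f <- f_of(prev_d)
  found <- FALSE
  d <- prev_d
  while (dir * (bnd - d) > 0) {
    d <- if (dir > 0) min(d + coarse, bnd) else max(d - coarse, bnd)
    f <- f_of(d)
    if (is.finite(f) && is.finite(prev_f) && sign(f) != sign(prev_f)) {
      found <- TRUE
      break
    }
    prev_d <- d; prev_f <- f
  }
  if (!found) return(dir)
  a <- min(prev_d, d); b <- max(prev_d, d)
  for (step in c(5e-4, 1e-5)) {
    g <- seq(a, b, by = step)
    f <- vapply(g, f_of, numeric(1))
    ch <- which(sign(f[-1]) != sign(f[-length(f)]))
    if (!length(ch)) break
    a <- g[ch[1]]; b <- g[ch[1] + 1]
  }
  (a + b) / 2
}

oracle_score_ci <- function(x1, n1, x2, n2, level = 0.95, skew = FALSE) {
  c(oracle_score_limit(x1, n1, x2, n2, level, "lower", skew),
    oracle_score_limit(x1, n1, x2, n2, level, "upper", skew))
}

# random small 2x2 tables under a fixed seed
random_tables <- function(n_tables, nmax = 60, seed = 1234) {
  set.seed(seed)
  n1 <- sample(2:nmax, n_tables, replace = TRUE)
  n2 <- sample(2:nmax, n_tables, replace = TRUE)
  x1 <- rbinom(n_tables, n1, runif(n_tables))
  x2 <- rbinom(n_tables, n2, runif(n_tables))
  data.frame(x1 = x1, n1 = n1, x2 = x2, n2 = n2)
}

# sort-based quantile oracle (linear interpolation between order statistics)
oracle_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# per-gridpoint tricube-weighted quadratic least squares, the naive local
# regression oracle matching span/degree-2 loess with direct surface
oracle_loess <- function(x, y, span, grid) {
  n <- length(x)
  q <- floor(span * n)
  vapply(grid, function(x0) {
    dist <- abs(x - x0)
    h <- sort(dist)[q]
    w <- pmax(1 - (dist / h)^3, 0)^3
    keep <- w > 0
    X <- cbind(1, x[keep] - x0, (x[keep] - x0)^2)
    beta <- solve(t(X) %*% (w[keep] * X), t(X) %*% (w[keep] * y[keep]))
    beta[1]
  }, numeric(1))
}
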