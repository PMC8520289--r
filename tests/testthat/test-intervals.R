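# expected values below were frozen from the closed-form hand evaluations in
# helper-oracles.R before the main implementation was written

test_that("worked micro-example (8/10 vs 6/10) matches hand evaluation", {
  expect_equal(round(unlist(ci_wald(8, 10, 6, 10)[c("lower", "upper")]), 3),
               c(lower = -0.192, upper = 0.592))
  expect_equal(round(unlist(ci_agresti_caffo(8, 10, 6, 10)[c("lower", "upper")]), 3),
               c(lower = -0.205, upper = 0.538))
  expect_equal(round(unlist(ci_newcombe(8, 10, 6, 10)[c("lower", "upper")]), 3),
               c(lower = -0.187, upper = 0.521))
  expect_equal(round(unlist(ci_wilson(8, 10)[c("lower", "upper")]), 3),
               c(lower = 0.490, upper = 0.943))
})

test_that("closed-form methods agree with independent oracles on random tables", {
  tabs <- random_tables(60, seed = 11)
  for (i in seq_len(nrow(tabs))) {
    t <- tabs[i, ]
    expect_equal(unlist(ci_wald(t$x1, t$n1, t$x2, t$n2)[c("lower", "upper")]),
                 c(lower = oracle_wald(t$x1, t$n1, t$x2, t$n2)[1],
                   upper = oracle_wald(t$x1, t$n1, t$x2, t$n2)[2]),
                 tolerance = 1e-10)
    expect_equal(unlist(ci_newcombe(t$x1, t$n1, t$x2, t$n2)[c("lower", "upper")]),
                 c(lower = oracle_newcombe(t$x1, t$n1, t$x2, t$n2)[1],
                   upper = oracle_newcombe(t$x1, t$n1, t$x2, t$n2)[2]),
                 tolerance = 1e-10)
  }
})

test_that("Agresti-Caffo equals Wald on augmented counts exactly", {
  tabs <- random_tables(50, seed = 7)
  for (i in seq_len(nrow(tabs))) {
    t <- tabs[i, ]
    ac <- ci_agresti_caffo(t$x1, t$n1, t$x2, t$n2)
    w <- ci_wald(t$x1 + 1, t$n1 + 2, t$x2 + 1, t$n2 + 2)
    expect_identical(c(ac$lower, ac$upper), c(w$lower, w$upper))
  }
})

test_that("SCAS with skewness coefficient forced to zero equals MN", {
  tabs <- random_tables(25, seed = 5)
  for (i in seq_len(nrow(tabs))) {
    t <- tabs[i, ]
    s0 <- ci_scas(t$x1, t$n1, t$x2, t$n2, skew = FALSE)
    mn <- ci_mn(t$x1, t$n1, t$x2, t$n2)
    expect_equal(c(s0$lower, s0$upper), c(mn$lower, mn$upper), tolerance = 1e-12)
  }
})

test_that("arm-swap antisymmetry holds for all five methods", {
  tabs <- random_tables(40, seed = 3)
  for (i in seq_len(nrow(tabs))) {
    t <- tabs[i, ]
    a <- ci_all(t$x1, t$n1, t$x2, t$n2)
    b <- ci_all(t$x2, t$n2, t$x1, t$n1)
    expect_equal(a$lower, -b$upper, tolerance = 1e-7)
    expect_equal(a$upper, -b$lower, tolerance = 1e-7)
  }
})

test_that("width is monotone in confidence level", {
  tabs <- random_tables(15, seed = 21)
  for (i in seq_len(nrow(tabs))) {
    t <- tabs[i, ]
    for (m in list(ci_wald, ci_agresti_caffo, ci_newcombe, ci_mn, ci_scas)) {
      w <- vapply(c(0.90, 0.95, 0.99),
                  function(l) m(t$x1, t$n1, t$x2, t$n2, level = l)$width,
                  numeric(1))
      expect_true(all(diff(w) >= -1e-12))
    }
  }
})

test_that("Wald width scales as 1/sqrt(n) for interior tables", {
  w1 <- ci_wald(30, 40, 22, 36)$width
  w4 <- ci_wald(120, 160, 88, 144)$width
  expect_equal(w4, w1 / 2, tolerance = 1e-12)
})

test_that("degenerate and boundary tables behave per contract", {
  all5 <- ci_all(50, 50, 50, 50)
  expect_equal(all5$width[all5$method == "wald"], 0)
  expect_true(all(all5$width[all5$method != "wald"] > 0))
  expect_true(all(abs(all5$lower) <= 1 & abs(all5$upper) <= 1))
  # augmentation removes the zero-variance degeneracy at 0/n too
  z <- ci_agresti_caffo(0, 10, 0, 10)
  expect_gt(z$width, 0)
  expect_equal(z$lower, -z$upper, tolerance = 1e-12)
  # score upper limit attains the boundary exactly when dhat = 1
  expect_identical(ci_mn(10, 10, 0, 10)$upper, 1)
  expect_identical(ci_scas(10, 10, 0, 10)$upper, 1)
  # near-boundary restricted MLE must not error (arccos clamping)
  expect_silent(restricted_mle(0, 10, 10, 10, d = -0.999999))
  # Wilson boundary cases
  expect_equal(ci_wilson(0, 17)$lower, 0)
  expect_equal(ci_wilson(17, 17)$upper, 1)
})

test_that("Wilson complement symmetry", {
  for (x in c(0, 3, 9, 14)) {
    a <- ci_wilson(x, 14)
    b <- ci_wilson(14 - x, 14)
    expect_equal(c(a$lower, a$upper), c(1 - b$upper, 1 - b$lower),
                 tolerance = 1e-12)
  }
})

test_that("restricted MLE maximises the constrained likelihood (grid oracle)", {
  set.seed(42)
  for (k in 1:25) {
    n1 <- sample(5:50, 1); n2 <- sample(5:50, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    d <- runif(1, -0.9, 0.9)
    fit <- restricted_mle(x1, n1, x2, n2, d)
    expect_equal(unname(fit["p1"] - fit["p2"]), d, tolerance = 1e-10)
    p2grid <- seq(max(0, -d), min(1, 1 - d), length.out = 2001)
    llgrid <- oracle_ll(x1, n1, p2grid + d) + oracle_ll(x2, n2, p2grid)
    llfit <- oracle_ll(x1, n1, fit["p1"]) + oracle_ll(x2, n2, fit["p2"])
    expect_gte(llfit + 1e-9, max(llgrid))
  }
  # unconstrained MLE satisfies the constraint at d = dhat
  fit <- restricted_mle(8, 10, 6, 10, d = 0.2)
  expect_equal(unname(fit), c(0.8, 0.6), tolerance = 1e-9)
})

test_that("MN score statistic: zero at dhat, sign and monotonicity", {
  tabs <- random_tables(20, seed = 13)
  tabs <- tabs[tabs$x1 > 0 & tabs$x1 < tabs$n1 & tabs$x2 > 0 & tabs$x2 < tabs$n2, ]
  for (i in seq_len(nrow(tabs))) {
    t <- tabs[i, ]
    dh <- t$x1 / t$n1 - t$x2 / t$n2
    expect_equal(mn_score(t$x1, t$n1, t$x2, t$n2, dh), 0, tolerance = 1e-8)
    ds <- sort(runif(8, max(-0.99, dh - 0.5), min(0.99, dh + 0.5)))
    zs <- vapply(ds, function(d) mn_score(t$x1, t$n1, t$x2, t$n2, d), numeric(1))
    expect_true(all(diff(zs) < 0))
    expect_true(all(zs[ds < dh] > 0) && all(zs[ds > dh] < 0))
  }
})

test_that("MN score statistic matches the grid-oracle recomputation", {
  cases <- list(c(8, 10, 6, 10, 0.1), c(3, 25, 20, 30, -0.3),
                c(40, 45, 35, 50, 0.05), c(1, 12, 0, 15, 0.2))
  for (cs in cases) {
    expect_equal(mn_score(cs[1], cs[2], cs[3], cs[4], cs[5]),
                 oracle_stat(cs[1], cs[2], cs[3], cs[4], cs[5]),
                 tolerance = 1e-6)
  }
})

test_that("score-equation residual at MN and SCAS limits is below 1e-6", {
  tabs <- random_tables(30, seed = 17)
  crit <- z_of(0.95)
  for (i in seq_len(nrow(tabs))) {
    t <- tabs[i, ]
    mn <- ci_mn(t$x1, t$n1, t$x2, t$n2)
    for (lim in c(mn$lower, mn$upper)) {
      if (abs(lim) < 1 - 1e-9)
        expect_lt(abs(abs(mn_score(t$x1, t$n1, t$x2, t$n2, lim)) - crit), 1e-6)
    }
    sc <- ci_scas(t$x1, t$n1, t$x2, t$n2)
    for (lim in c(sc$lower, sc$upper)) {
      if (abs(lim) < 1 - 1e-9)
        expect_lt(abs(abs(rdci:::.scas_stat(t$x1, t$n1, t$x2, t$n2, lim)) - crit),
                  1e-6)
    }
  }
})

test_that("ci_all returns the five methods with consistent rows", {
  out <- ci_all(8, 10, 6, 10)
  expect_setequal(out$method, c("wald", "agresti_caffo", "newcombe",
                                "miettinen_nurminen", "scas"))
  expect_true(all(out$lower <= out$upper))
  expect_true(all(out$lower >= -1 & out$upper <= 1))
  expect_equal(out$width, out$upper - out$lower)
})

test_that("invalid tables and levels are rejected", {
  expect_error(ci_wald(11, 10, 5, 10), "invalid")
  expect_error(ci_wald(-1, 10, 5, 10), "invalid")
  expect_error(ci_wald(2.5, 10, 5, 10), "invalid")
  expect_error(ci_wald(5, 10, 5, 10, level = 1))
  expect_error(mn_score(5, 10, 5, 10, d = 1))
})
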