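# Exact 2x2 inference, trend and t tests

test_that("fisher_2x2 reproduces published sparse-table conventions", {
  # a 1-vs-1 exposed table: the conditional MLE differs visibly from the
  # sample cross-product ratio (213.57)
  r <- fisher_2x2(1, 365, 1, 77952)
  expect_equal(round(r$or_cmle, 2), 212.33)
  expect_equal(round(r$ci_low, 2), 2.71)
  expect_equal(round(r$ci_high, 2), 14121.54)
  # zero exposed cases: OR 0 with a finite upper bound
  r0 <- fisher_2x2(0, 298, 990, 72833)
  expect_identical(r0$or_cmle, 0)
  expect_identical(r0$ci_low, 0)
  expect_equal(round(r0$ci_high, 2), 0.92)
  # zero exposed controls with an exposed case: infinite OR, finite lower
  rI <- fisher_2x2(1, 297, 0, 73823)
  expect_identical(rI$or_cmle, Inf)
  expect_identical(rI$ci_high, Inf)
  expect_equal(round(rI$ci_low, 2), 6.35)
})

test_that("fisher_2x2 agrees with stats::fisher.test across random tables", {
  set.seed(101)
  for (i in 1:300) {
    x <- matrix(rpois(4, sample(c(2, 8, 40), 1)), 2)
    if (any(rowSums(x) == 0) || any(colSums(x) == 0)) next
    ft <- stats::fisher.test(x)
    mine <- fisher_2x2(x[1, 1], x[1, 2], x[2, 1], x[2, 2])
    expect_equal(mine$p, ft$p.value, tolerance = 1e-12)
    expect_equal(mine$or_cmle, unname(ft$estimate), tolerance = 1e-8)
    expect_equal(mine$ci_low, ft$conf.int[1], tolerance = 1e-8)
    expect_equal(mine$ci_high, ft$conf.int[2], tolerance = 1e-8)
  }
})

test_that("fisher_2x2 invariances: symmetry, monotonicity, degenerate input", {
  # simultaneous row and column swap leaves p unchanged
  set.seed(7)
  for (i in 1:50) {
    t <- rpois(4, 10) + 1
    p1 <- fisher_2x2(t[1], t[2], t[3], t[4])$p
    p2 <- fisher_2x2(t[4], t[3], t[2], t[1])$p
    expect_equal(p1, p2, tolerance = 1e-12)
  }
  # or_cmle strictly increasing in a at fixed margins
  m <- 12; n <- 40; k <- 15
  ors <- vapply(1:11, function(a) {
    fisher_2x2(a, k - a, m - a, n - (k - a))$or_cmle
  }, 0)
  expect_true(all(diff(ors) > 0))
  # symmetric table: OR 1, p 1
  rs <- fisher_2x2(5, 10, 5, 10)
  expect_equal(rs$or_cmle, 1, tolerance = 1e-6)
  expect_equal(rs$p, 1)
  # zero margin is undefined
  expect_error(fisher_2x2(0, 0, 3, 4), "margin")
})

test_that("exact CI covers the null in >= 93% of null simulations", {
  # true odds ratio 1, 200 per arm, exposure prevalence 0.1
  set.seed(2024)
  n <- 200; cover <- 0; runs <- 2000
  for (i in seq_len(runs)) {
    a <- rbinom(1, n, 0.1); c <- rbinom(1, n, 0.1)
    if (a + c == 0) { cover <- cover + 1; next } # no information: CI is (0, Inf)
    r <- fisher_2x2(a, n - a, c, n - c)
    cover <- cover + (r$ci_low <= 1 && r$ci_high >= 1)
  }
  expect_gte(cover / runs, 0.93)
})

test_that("welch_t matches the direct formula and handles identity", {
  # 3-value toy, summary stats of x = (1,2,3) vs y = (2,4,9)
  x <- c(1, 2, 3); y <- c(2, 4, 9)
  r <- welch_t(3, mean(x), sd(x), 3, mean(y), sd(y))
  tt <- t.test(x, y)
  expect_equal(r$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r$df, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(r$p, tt$p.value, tolerance = 1e-10)
  # identical summaries
  r0 <- welch_t(10, 5, 2, 12, 5, 2)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # the published demographic contrast is significant
  expect_lt(welch_t(366, 211.50, 48.33, 77953, 222.20, 35.94)$p, 0.001)
})

test_that("cochran_armitage matches a hand-computed toy and null case", {
  # k = 3 toy, computed from the closed form directly
  ex <- c(2, 5, 9); tot <- c(20, 20, 20); s <- 1:3
  pbar <- sum(ex) / sum(tot)
  num <- sum(s * (ex - tot * pbar))^2
  den <- pbar * (1 - pbar) * (sum(tot * s^2) - sum(tot * s)^2 / sum(tot))
  r <- cochran_armitage(ex, tot)
  expect_equal(r$chi2, num / den, tolerance = 1e-12)
  # equal proportions: chi2 = 0, p = 1
  r0 <- cochran_armitage(c(5, 10, 15), c(50, 100, 150))
  expect_equal(r0$chi2, 0, tolerance = 1e-20)
  expect_equal(r0$p, 1)
  # published income trend is significant at the printed level
  rA <- cochran_armitage(c(25, 48, 107, 107, 79),
                         c(8246, 12601, 20674, 24153, 12645))
  expect_equal(round(rA$p, 3), 0.002)
  rB <- cochran_armitage(c(20, 41, 84, 90, 63),
                         c(7665, 11668, 19549, 23155, 12084))
  expect_equal(round(rB$p, 3), 0.010)
  expect_error(cochran_armitage(c(1, 2, 3), c(10, 0, 10)), "positive")
})

test_that("fisher_rxc_mc is seeded, consistent with 2x2, and calibrated", {
  tab <- matrix(c(7, 3, 5, 15), 2)
  r1 <- fisher_rxc_mc(tab, n_mc = 2e4, seed = 5)
  r2 <- fisher_rxc_mc(tab, n_mc = 2e4, seed = 5)
  expect_identical(r1$p, r2$p)
  exact <- fisher_2x2(7, 3, 5, 15)$p
  expect_lt(abs(r1$p - exact), 3 * r1$se + 1e-4)
  # near-independent table: p near 1
  u <- matrix(c(50, 100, 52, 99, 48, 101), 2)
  expect_gt(fisher_rxc_mc(u, n_mc = 1e4, seed = 3)$p, 0.5)
  expect_error(fisher_rxc_mc(matrix(c(0, 0, 3, 4), 2), seed = 1), "margin")
  expect_error(fisher_rxc_mc(tab, n_mc = 100, seed = 1), "10\\^4")
})

test_that("published multi-level income contrast reproduces by Monte Carlo", {
  tab <- rbind(c(25, 48, 107, 107, 79),
               c(8221, 12553, 20567, 24046, 12566))
  r <- fisher_rxc_mc(tab, n_mc = 4e4, seed = 11)
  expect_lt(abs(r$p - 0.005), 3 * r$se + 2e-3)
})
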