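test_that("the subsampling grid has 300 years and the stated structure", {
  g <- subsample_grid()
  expect_length(g, 300)
  expect_true(all(1:100 %in% g))
  expect_true(all(seq(100, 2000, 19) %in% g))
  expect_true(all(seq(2000, 15000, 130) %in% g))
  expect_false(anyDuplicated(g) > 0)
})

test_that("subsampling reads the trajectory as a step function", {
  traj <- data.frame(t_years = c(0, 1000, 5000),
                     ne_median = c(100, 1000, 10000))
  s <- subsample_years(traj)
  expect_equal(s$y[s$t < 1000], rep(log(100), sum(s$t < 1000)))
  expect_equal(s$y[s$t >= 1000 & s$t < 5000][1], log(1000))
  expect_equal(s$y[s$t >= 5000][1], log(10000))
  ## constant trajectory
  s2 <- subsample_years(data.frame(t_years = 0, ne_median = 1000))
  expect_equal(unique(s2$y), log(1000))
  ## short coverage truncates with a warning
  short <- data.frame(t_years = c(0, 500), ne_median = c(50, 60))
  attr(short, "coverage_years") <- 2000
  expect_warning(s3 <- subsample_years(short), "truncated")
  expect_lt(nrow(s3), 300)
  expect_lte(max(s3$t), 2000)
})

## noiseless series generated from per-period growth rates (backward time)
eq2_series <- function(psi, rates, y0 = 9) {
  g <- subsample_grid()
  b <- log(1 + rates)        # slope per period of ln(Ne) vs backward years
  knots <- c(0, psi, max(g))
  y <- numeric(length(g))
  base <- y0
  for (k in seq_along(b)) {
    sel <- g > knots[k] & g <= knots[k + 1]
    y[sel] <- base + b[k] * (g[sel] - knots[k])
    base <- base + b[k] * (knots[k + 1] - knots[k])
  }
  data.frame(t = g, y = y)
}

test_that("noiseless series from known rates are recovered exactly", {
  s <- eq2_series(psi = c(700, 4000), rates = c(0.001, -0.0004, 0.002))
  fit <- suppressWarnings(fit_piecewise(s, k_breakpoints = 2))
  expect_true(fit$converged)
  expect_lt(abs(fit$psi[1] - 700), 19)
  expect_lt(abs(fit$psi[2] - 4000), 130)
  b_true <- log(1 + c(0.001, -0.0004, 0.002))
  expect_equal(fit$segments$b, b_true, tolerance = 1e-4 / max(abs(b_true)))
  ## Eq-4 rates with the reverted sign
  expect_equal(fit$segments$r, -(exp(fit$segments$b) - 1), tolerance = 1e-12)
})

test_that("breakpoint recovery stays within 2 grid steps under noise", {
  set.seed(55)
  bias1 <- bias2 <- c()
  for (i in 1:60) {
    s <- eq2_series(psi = c(700, 4000), rates = c(0.001, -0.0004, 0.002))
    s$y <- s$y + rnorm(nrow(s), sd = 0.05)
    fit <- suppressWarnings(fit_piecewise(s, k_breakpoints = 2,
                                          init = c(500, 3000)))
    if (length(fit$psi) == 2) {
      bias1 <- c(bias1, fit$psi[1] - 700)
      bias2 <- c(bias2, fit$psi[2] - 4000)
    }
  }
  expect_gt(length(bias1), 40)
  expect_lt(abs(mean(bias1)), 2 * 19)
  expect_lt(abs(mean(bias2)), 2 * 130)
})

test_that("a perfectly linear series degenerates to the 0-breakpoint fit", {
  g <- subsample_grid()
  s <- data.frame(t = g, y = 2 + 0.0005 * g)
  fit <- suppressWarnings(fit_piecewise(s, k_breakpoints = 3))
  expect_length(fit$psi, 0)
  expect_equal(fit$rss, fit$rss0, tolerance = 1e-12)
  expect_equal(fit$segments$b, 0.0005, tolerance = 1e-10)
})

test_that("fits are invariant to shuffling the input order", {
  set.seed(66)
  s <- eq2_series(psi = 900, rates = c(0.002, -0.001))
  s$y <- s$y + rnorm(nrow(s), sd = 0.02)
  f1 <- suppressWarnings(fit_piecewise(s, k_breakpoints = 1))
  f2 <- suppressWarnings(fit_piecewise(s[sample(nrow(s)), ],
                                       k_breakpoints = 1))
  expect_equal(f1$psi, f2$psi, tolerance = 1e-10)
  expect_equal(f1$segments$b, f2$segments$b, tolerance = 1e-10)
})

test_that("RSS does not increase with more breakpoints", {
  set.seed(91)
  s <- eq2_series(psi = c(500, 5000), rates = c(0, 0.002, -0.0005))
  s$y <- s$y + rnorm(nrow(s), sd = 0.03)
  rss <- vapply(0:3, function(k) {
    if (k == 0) {
      sum(resid(lm(y ~ t, s))^2)
    } else suppressWarnings(fit_piecewise(s, k_breakpoints = k))$rss
  }, 0)
  expect_true(all(diff(rss) <= 1e-8))
})

test_that("rate transformation is the exact algebraic inverse", {
  s <- eq2_series(psi = 900, rates = c(0.002, -0.001))
  fit <- suppressWarnings(fit_piecewise(s, k_breakpoints = 1))
  ## b = 0 -> r = 0 exactly
  m <- fit
  m$segments$b <- c(0, log(1.05))
  m$segments$b_lo <- m$segments$b - 0.01
  m$segments$b_hi <- m$segments$b + 0.01
  m <- slopes_to_rates(m)
  expect_identical(m$segments$r[1], 0)
  expect_equal(m$segments$r[2], -0.05, tolerance = 1e-12)
  ## CI endpoints swap under the decreasing transform
  expect_equal(m$segments$r_lo, -(exp(m$segments$b_hi) - 1))
  expect_equal(m$segments$r_hi, -(exp(m$segments$b_lo) - 1))
  ## round trip across a grid of rates
  for (r in seq(-0.45, 0.45, by = 0.1)) {
    b <- log(1 + r)
    expect_equal(-(exp(b) - 1), -r, tolerance = 1e-12)
  }
})

test_that("model methods are coherent", {
  s <- eq2_series(psi = c(700, 4000), rates = c(0.001, -0.0004, 0.002))
  set.seed(2); s$y <- s$y + rnorm(nrow(s), sd = 0.01)
  fit <- suppressWarnings(fit_piecewise(s, k_breakpoints = 2))
  expect_equal(predict(fit), unname(fit$fitted), tolerance = 1e-10)
  expect_equal(unname(residuals(fit)), s$y - predict(fit), tolerance = 1e-10)
  cf <- coef(fit)
  expect_length(cf$psi, 2)
  expect_length(cf$slopes, 3)
  expect_output(print(fit), "breakpoint")
  expect_output(summary(fit), "Periods")
})
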