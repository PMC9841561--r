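test_that("sign subpopulations split, summarise and handle edge cases", {
  sp <- split_subpopulations(c(-5, -3, 4))
  gs <- attr(sp, "group_stats")
  expect_equal(gs$mean[gs$label == "negative"], -4)
  expect_equal(gs$mean[gs$label == "positive"], 4)
  expect_equal(gs$n, c(2L, 1L))

  allneg <- split_subpopulations(c(-1, -2, -3))
  expect_true(all(allneg$label == "negative"))

  sym <- split_subpopulations(c(-2, 2, -7, 7))
  expect_equal(mean(sym$value), 0)

  expect_message(zeros <- split_subpopulations(c(0, -1)), "zero value")
  expect_equal(zeros$label, c("positive", "negative"))
  expect_error(split_subpopulations(numeric(0)), "at least one")
})

test_that("EM mixture fitting recovers parameters and stays monotone", {
  set.seed(101)
  x <- c(rnorm(250, -50, 15), rnorm(250, 50, 15))
  fit <- fit_gaussian_mixture(x, seed = 2)
  expect_true(fit$converged)
  expect_equal(fit$means, c(-50, 50), tolerance = 3 / 50)    # +-3 au
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 0.07 / 0.5)
  expect_true(fit$means[1] <= fit$means[2])
  expect_equal(sum(fit$weights), 1, tolerance = 1e-12)
  # EM log-likelihood never decreases
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))

  td <- tidy(fit)
  expect_equal(td$mean, fit$means)
  expect_equal(glance(fit)$converged, TRUE)
})

test_that("symmetric two-point data give means near +-1, weights near 1/2", {
  set.seed(5)
  x <- c(-1, -1, 1, 1) + rnorm(4, sd = 1e-3)
  fit <- fit_gaussian_mixture(x, seed = 1)
  expect_equal(fit$means, c(-1, 1), tolerance = 0.01)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 0.01)
})

test_that("single-Gaussian data yield the documented degenerate outcome", {
  set.seed(8)
  x <- rnorm(500, 0, 10)
  fit <- fit_gaussian_mixture(x, seed = 3)
  # the two components may share the variance budget, but the fitted
  # density must stay close to the single-Gaussian MLE: the extra component
  # buys essentially nothing
  grid <- seq(-60, 60, length.out = 4001)
  f_mix <- mixture_density(fit, grid)
  f_one <- dnorm(grid, mean(x), sqrt(mean((x - mean(x))^2)))
  l1 <- sum(abs(f_mix - f_one)) * diff(grid[1:2])
  expect_lt(l1, 0.05)
  # and the folded shape collapses onto a single central mode
  expect_equal(attr(folded_abs_distribution(fit), "modality"), "unimodal")
})

test_that("degenerate samples are rejected", {
  expect_error(fit_gaussian_mixture(c(1, 2, 3)), "degenerate")
  expect_error(fit_gaussian_mixture(rep(2, 10)), "degenerate")
})

test_that("negating samples mirrors the mixture and preserves W^2", {
  set.seed(33)
  x <- c(rnorm(100, -20, 5), rnorm(150, 35, 8))
  f1 <- fit_gaussian_mixture(x, seed = 4)
  f2 <- fit_gaussian_mixture(-x, seed = 4)
  expect_equal(f2$means, -rev(f1$means), tolerance = 1e-4)
  expect_equal(f2$weights, rev(f1$weights), tolerance = 1e-4)
  expect_equal(f2$sigmas, rev(f1$sigmas), tolerance = 1e-4)
  w1 <- cvm_statistic(x, function(q) mixture_cdf(f1, q))
  w2 <- cvm_statistic(-x, function(q) mixture_cdf(f2, q))
  expect_equal(w2, w1, tolerance = 1e-6)
})

test_that("CvM statistic matches closed forms and the naive oracle", {
  # n = 1 with F(x1) = 0.5: W^2 = 1/12
  expect_equal(cvm_statistic(0, function(q) rep(0.5, length(q))), 1 / 12,
               tolerance = 1e-12)
  # n = 2 at the exact quantiles {0.25, 0.75}: W^2 = 1/24
  expect_equal(cvm_statistic(c(-1, 1), function(q) ifelse(q < 0, 0.25, 0.75)),
               1 / 24, tolerance = 1e-12)
  # the quantile minimiser attains 1/(12n)
  for (n in c(3, 10, 57)) {
    x <- qnorm((2 * seq_len(n) - 1) / (2 * n))
    expect_equal(cvm_statistic(x, pnorm), 1 / (12 * n), tolerance = 1e-12)
  }
  # random fixtures against the direct-sum oracle
  set.seed(12)
  for (r in 1:100) {
    x <- rnorm(sample(2:40, 1), sd = runif(1, 0.5, 3))
    cdf <- function(q) pnorm(q, sd = 2)
    expect_equal(cvm_statistic(x, cdf), oracle_cvm(x, cdf), tolerance = 1e-12)
  }
  expect_error(cvm_statistic(c(1, 2), function(q) rev(pnorm(q))), "monotone")
})

test_that("asymptotic CvM tail matches published critical points", {
  # limiting null distribution of W^2: 10/5/1 percent points
  expect_equal(cvm_p_asymptotic(0.34730), 0.10, tolerance = 2e-3)
  expect_equal(cvm_p_asymptotic(0.46136), 0.05, tolerance = 1e-3)
  expect_equal(cvm_p_asymptotic(0.74346), 0.01, tolerance = 5e-4)
  expect_equal(cvm_p_asymptotic(0), 1)
})

test_that("parametric bootstrap p-value is computable and bounded", {
  set.seed(55)
  x <- c(rnorm(40, -30, 10), rnorm(40, 30, 10))
  fit <- fit_gaussian_mixture(x, seed = 6)
  pv <- cvm_pvalue(fit, n_boot = 99, seed = 7, n_starts = 2)
  expect_true(pv$p_value > 0 && pv$p_value <= 1)
  expect_true(pv$cvm_stat > 0)
  expect_equal(pv$n_boot, 99)
  # data drawn from the fitted model itself should not be rejected strongly
  expect_gt(pv$p_value, 0.01)
  expect_error(cvm_pvalue(fit, n_boot = 50), "n_boot")
})

test_that("folded |Lz| densities classify modality and conserve mass", {
  sym <- gaussian_mixture(c(0.5, 0.5), c(-50, 50), c(15, 15))
  grid <- seq(0, 120, length.out = 2048)
  g1 <- folded_abs_distribution(sym, grid)
  expect_equal(attr(g1, "modality"), "unimodal")
  expect_equal(g1$x[which.max(g1$density)], 50, tolerance = 1)
  # folding conserves probability
  expect_equal(sum((g1$density[-1] + g1$density[-nrow(g1)]) / 2 * diff(g1$x)),
               1, tolerance = 1e-3)

  ctr <- gaussian_mixture(c(0.5, 0.5), c(-1e-9, 0), c(10, 10))
  g2 <- folded_abs_distribution(ctr, seq(0, 60, length.out = 1024))
  expect_equal(attr(g2, "modality"), "unimodal")
  expect_equal(g2$x[which.max(g2$density)], 0)
  expect_equal(g2$density[1], 2 * mixture_density(ctr, 0), tolerance = 1e-6)

  asym <- gaussian_mixture(c(0.45, 0.55), c(-20, 70), c(12, 15))
  g3 <- folded_abs_distribution(asym, seq(0, 140, length.out = 2048))
  expect_equal(attr(g3, "modality"), "bimodal")

  expect_error(folded_abs_distribution(sym, c(-1, 0, 1)), ">= 0")
})

test_that("mixture constructor validates and orders components", {
  gm <- gaussian_mixture(c(0.3, 0.7), c(5, -5), c(1, 2))
  expect_equal(gm$means, c(-5, 5))
  expect_equal(gm$weights, c(0.7, 0.3))
  expect_error(gaussian_mixture(c(0.5, 0.6), c(0, 1), c(1, 1)), "sum")
})
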