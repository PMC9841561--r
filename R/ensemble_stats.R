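#' Split trajectories into sign subpopulations of Lz
#'
#' Labels each value `"positive"` or `"negative"` by the sign of its
#' classification statistic (zero counts as positive by convention and is
#' reported).  One empty group is valid: an ensemble with a robust single
#' rotational sense puts every trajectory on one side.
#'
#' @param lz_values numeric vector of per-trajectory Lz statistics (au),
#'   e.g. from [traj_lz_statistic()].
#' @return a tibble with columns `value`, `label`; attributes
#'   `"group_stats"` (per-group n/mean/sd tibble) and `"n_zero"`.
#' @export
split_subpopulations <- function(lz_values) {
  lz_values <- as.numeric(lz_values)
  if (!length(lz_values)) stop("need at least one value", call. = FALSE)
  n_zero <- sum(lz_values == 0)
  if (n_zero) message(n_zero, " zero value(s) assigned to the positive group")
  label <- ifelse(lz_values >= 0, "positive", "negative")
  out <- tibble::tibble(value = lz_values, label = label)
  gs <- dplyr::summarise(
    dplyr::group_by(out, .data$label),
    n = dplyr::n(), mean = mean(.data$value),
    sd = if (dplyr::n() > 1) stats::sd(.data$value) else NA_real_,
    .groups = "drop"
  )
  attr(out, "group_stats") <- gs
  attr(out, "n_zero") <- n_zero
  out
}

#' Two-component Gaussian mixture by expectation-maximisation
#'
#' Maximum-likelihood fit of
#' \eqn{f(x) = w_1 N(\mu_1, \sigma_1^2) + w_2 N(\mu_2, \sigma_2^2)} with
#' multi-start EM: quantile-based and seeded random initialisations,
#' keeping the best final log-likelihood.  A variance floor
#' (`sigma_floor`, default 1e-3 of the sample range) prevents component
#' collapse onto a single point.  Components are reported in ascending-mean
#' order.  Convergence requires the log-likelihood change to stay below
#' `tol` for 5 consecutive iterations; EM guarantees the log-likelihood is
#' non-decreasing, and the per-iteration trace is kept so that can be
#' audited.
#'
#' @param x numeric samples (>= 4 distinct values).
#' @param k number of components; only 2 is supported.
#' @param seed integer seed for the random restarts.
#' @param n_starts number of initialisations (first two are quantile-based).
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter iteration cap per start.
#' @param sigma_floor lower bound on component standard deviations;
#'   default `1e-3 * diff(range(x))`.
#' @return object of class `gaussian_mixture_fit`: `weights`, `means`,
#'   `sigmas`, `loglik`, `converged`, `n_iter`, `loglik_trace`, `data`,
#'   `seed`, `sigma_floor`.
#' @export
fit_gaussian_mixture <- function(x, k = 2, seed = 1, n_starts = 10,
                                 tol = 1e-9, max_iter = 1000,
                                 sigma_floor = NULL) {
  x <- as.numeric(x)
  if (k != 2) stop("only k = 2 mixtures are supported", call. = FALSE)
  if (length(x) < 4 || length(unique(x)) < 2) {
    stop("degenerate input: need >= 4 samples with at least 2 distinct values",
         call. = FALSE)
  }
  if (is.null(sigma_floor)) sigma_floor <- 1e-3 * diff(range(x))
  n <- length(x)

  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  starts <- list(
    list(w = c(0.5, 0.5), mu = stats::quantile(x, c(0.25, 0.75), names = FALSE),
         s = rep(max(stats::sd(x) / 2, sigma_floor), 2)),
    list(w = c(0.5, 0.5), mu = stats::quantile(x, c(0.1, 0.9), names = FALSE),
         s = rep(max(stats::sd(x) / 2, sigma_floor), 2))
  )
  while (length(starts) < n_starts) {
    starts[[length(starts) + 1]] <- list(
      w = c(0.5, 0.5), mu = sample(x, 2),
      s = rep(max(stats::sd(x) * stats::runif(1, 0.3, 1.5), sigma_floor), 2)
    )
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  best <- NULL
  for (st in starts) {
    fit <- em_2gauss(x, st$w, st$mu, st$s, tol, max_iter, sigma_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$means)
  structure(
    list(weights = best$weights[ord], means = best$means[ord],
         sigmas = best$sigmas[ord], loglik = best$loglik,
         converged = best$converged, n_iter = best$n_iter,
         loglik_trace = best$trace, data = x, seed = as.integer(seed),
         sigma_floor = sigma_floor, n = n),
    class = "gaussian_mixture_fit"
  )
}

#' Specify a two-component Gaussian mixture directly
#'
#' Builds the same object [fit_gaussian_mixture()] returns, without fitting;
#' useful for evaluating [folded_abs_distribution()], [mixture_density()] or
#' [cvm_statistic()] against a hypothesised mixture.
#'
#' @param weights,means,sigmas length-2 numeric vectors; weights must sum
#'   to 1 and sigmas be positive.  Components are stored in ascending-mean
#'   order.
#' @return a `gaussian_mixture_fit` (with `converged = TRUE` and no data).
#' @export
gaussian_mixture <- function(weights, means, sigmas) {
  stopifnot(length(weights) == 2, length(means) == 2, length(sigmas) == 2,
            abs(sum(weights) - 1) < 1e-12, all(sigmas > 0))
  ord <- order(means)
  structure(
    list(weights = weights[ord], means = means[ord], sigmas = sigmas[ord],
         loglik = NA_real_, converged = TRUE, n_iter = 0L,
         loglik_trace = numeric(0), data = numeric(0), seed = NA_integer_,
         sigma_floor = 0, n = 0L),
    class = "gaussian_mixture_fit"
  )
}

# one EM run; trace records the log-likelihood after every M step
em_2gauss <- function(x, w, mu, s, tol, max_iter, sigma_floor) {
  n <- length(x)
  ll_old <- -Inf
  trace <- numeric(0)
  stable <- 0L
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    d1 <- w[1] * stats::dnorm(x, mu[1], s[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r1 <- d1 / tot
    # M step
    n1 <- sum(r1); n2 <- n - n1
    w <- c(n1, n2) / n
    mu <- c(sum(r1 * x) / n1, sum((1 - r1) * x) / n2)
    s <- sqrt(c(sum(r1 * (x - mu[1])^2) / n1,
                sum((1 - r1) * (x - mu[2])^2) / n2))
    s <- pmax(s, sigma_floor)
    ll <- sum(log(w[1] * stats::dnorm(x, mu[1], s[1]) +
                    w[2] * stats::dnorm(x, mu[2], s[2])))
    trace <- c(trace, ll)
    if (is.finite(ll) && abs(ll - ll_old) < tol) stable <- stable + 1L else stable <- 0L
    if (stable >= 5L) { converged <- TRUE; break }
    if (it >= max_iter) break
    ll_old <- ll
  }
  list(weights = w, means = mu, sigmas = s, loglik = ll,
       converged = converged, n_iter = it, trace = trace)
}

#' @export
print.gaussian_mixture_fit <- function(x, ...) {
  cat("<gaussian_mixture_fit> k = 2, n =", x$n, "\n")
  for (j in 1:2) {
    cat(sprintf("  component %d: w = %.3f, mu = %.3f, sigma = %.3f\n",
                j, x$weights[j], x$means[j], x$sigmas[j]))
  }
  cat(sprintf("  loglik %.4f after %d iterations (%s)\n", x$loglik, x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Mixture density and CDF
#'
#' @param fit a [fit_gaussian_mixture()] result.
#' @param x evaluation points.
#' @return numeric vector of density / CDF values.
#' @export
mixture_density <- function(fit, x) {
  fit$weights[1] * stats::dnorm(x, fit$means[1], fit$sigmas[1]) +
    fit$weights[2] * stats::dnorm(x, fit$means[2], fit$sigmas[2])
}

#' @rdname mixture_density
#' @export
mixture_cdf <- function(fit, x) {
  fit$weights[1] * stats::pnorm(x, fit$means[1], fit$sigmas[1]) +
    fit$weights[2] * stats::pnorm(x, fit$means[2], fit$sigmas[2])
}

# seeded draw from a fitted mixture
mixture_rand <- function(fit, n) {
  comp <- 1L + (stats::runif(n) > fit$weights[1])
  stats::rnorm(n, fit$means[comp], fit$sigmas[comp])
}

#' Cramér-von Mises statistic
#'
#' \deqn{W^2 = \frac{1}{12n} + \sum_{i=1}^{n}
#'   \left(F(x_{(i)}) - \frac{2i - 1}{2n}\right)^2}
#' on the sorted samples, for a fully specified continuous CDF `cdf`.
#'
#' @param x numeric samples.
#' @param cdf vectorised distribution function, monotone on the sample
#'   range.
#' @return the statistic \eqn{W^2}.
#' @export
cvm_statistic <- function(x, cdf) {
  x <- sort(as.numeric(x))
  n <- length(x)
  if (n < 1) stop("need at least one sample", call. = FALSE)
  Fx <- cdf(x)
  if (any(diff(Fx) < -1e-12)) stop("cdf is not monotone on the sample range",
                                   call. = FALSE)
  1 / (12 * n) + sum((Fx - (2 * seq_len(n) - 1) / (2 * n))^2)
}

#' Goodness of fit of a mixture by parametric-bootstrap Cramér-von Mises
#'
#' The observed \eqn{W^2} compares the sample to the fitted mixture CDF.
#' Because the mixture parameters were estimated from the same sample, the
#' standard null tables do not apply; the p-value is obtained by parametric
#' bootstrap: draw `n_boot` synthetic samples of size n from the fitted
#' mixture, refit each, recompute \eqn{W^2}, and report
#' \eqn{p = (1 + \#\{W^2_\mathrm{boot} \ge W^2_\mathrm{obs}\})/(n_\mathrm{boot}+1)}.
#' The asymptotic-table p-value (which ignores parameter estimation and is
#' anti-conservative here) is reported alongside for reference.
#'
#' @param fit a converged [fit_gaussian_mixture()].
#' @param x the samples the fit was made on; defaults to `fit$data`.
#' @param n_boot bootstrap replicates (>= 99).
#' @param seed integer seed.
#' @param n_starts,max_iter EM settings for the bootstrap refits (kept small
#'   for speed).
#' @return a one-row tibble: `cvm_stat`, `p_value`, `p_asymptotic`,
#'   `n_boot`, `n_refit_failed`, `seed`.
#' @export
cvm_pvalue <- function(fit, x = fit$data, n_boot = 199, seed = 1,
                       n_starts = 2, max_iter = 300) {
  stopifnot(inherits(fit, "gaussian_mixture_fit"))
  if (!fit$converged) stop("mixture fit did not converge", call. = FALSE)
  if (n_boot < 99) stop("n_boot must be >= 99", call. = FALSE)
  n <- length(x)
  w2_obs <- cvm_statistic(x, function(q) mixture_cdf(fit, q))

  old <- get0(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  w2_boot <- rep(NA_real_, n_boot)
  failed <- 0L
  for (b in seq_len(n_boot)) {
    xb <- mixture_rand(fit, n)
    fb <- tryCatch(
      fit_gaussian_mixture(xb, seed = sample.int(2^30, 1), n_starts = n_starts,
                           max_iter = max_iter, tol = 1e-8),
      error = function(e) NULL
    )
    if (is.null(fb)) { failed <- failed + 1L; next }
    w2_boot[b] <- cvm_statistic(xb, function(q) mixture_cdf(fb, q))
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  if (failed > 0.1 * n_boot) {
    stop("unreliable p-value: ", failed, " of ", n_boot, " refits failed",
         call. = FALSE)
  }
  ok <- !is.na(w2_boot)
  tibble::tibble(
    cvm_stat = w2_obs,
    p_value = (1 + sum(w2_boot[ok] >= w2_obs)) / (sum(ok) + 1),
    p_asymptotic = cvm_p_asymptotic(w2_obs),
    n_boot = n_boot, n_refit_failed = failed, seed = as.integer(seed)
  )
}

#' Asymptotic upper tail of the Cramér-von Mises null distribution
#'
#' Limiting distribution of \eqn{W^2} for a fully specified null,
#' evaluated from the classical Bessel-function series
#' \deqn{F(x) = \frac{1}{\pi\sqrt{x}} \sum_{j\ge 0} (-1)^j \binom{-1/2}{j}
#'   \sqrt{4j+1}\; e^{-(4j+1)^2/(16x)}\, K_{1/4}\!\big((4j+1)^2/(16x)\big).}
#' Valid only when the hypothesised CDF is not estimated from the data.
#'
#' @param w2 observed statistic.
#' @param n_terms series terms (the series converges very fast).
#' @return upper-tail probability `1 - F(w2)`.
#' @export
cvm_p_asymptotic <- function(w2, n_terms = 6) {
  if (w2 <= 0) return(1)
  j <- 0:(n_terms - 1)
  coef <- (-1)^j * choose(-1/2, j) * sqrt(4 * j + 1)
  arg <- (4 * j + 1)^2 / (16 * w2)
  cdf <- sum(coef * exp(-arg) * besselK(arg, 0.25)) / (pi * sqrt(w2))
  min(max(1 - cdf, 0), 1)
}

#' Folded |Lz| distribution of a fitted mixture
#'
#' Density of the absolute value, \eqn{g(x) = f(x) + f(-x)} for
#' \eqn{x \ge 0}, where f is the fitted mixture density (the signed fits
#' summed over positive and negative arguments).  The folded shape is
#' classified as `"unimodal"` or `"bimodal"` by counting the interior local
#' maxima of g on the grid (sign changes of the discrete derivative,
#' counting a maximum at the origin): a well-separated symmetric mixture
#' folds onto a single peak, while an asymmetric mixture keeps two.
#'
#' @param fit a [fit_gaussian_mixture()] result.
#' @param grid non-negative evaluation grid (au); default 512 points
#'   covering the fitted range.
#' @return a tibble with columns `x`, `density`; attributes `"modality"`
#'   (`"unimodal"`/`"bimodal"`/`"multimodal"`) and `"n_modes"`.
#' @export
folded_abs_distribution <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "gaussian_mixture_fit"))
  if (is.null(grid)) {
    hi <- max(abs(fit$means)) + 4 * max(fit$sigmas)
    grid <- seq(0, hi, length.out = 512)
  }
  if (any(grid < 0)) stop("grid values must be >= 0", call. = FALSE)
  grid <- sort(grid)
  g <- mixture_density(fit, grid) + mixture_density(fit, -grid)
  n_modes <- count_modes(g)
  out <- tibble::tibble(x = grid, density = g)
  attr(out, "modality") <- c("unimodal", "bimodal")[min(n_modes, 2)]
  if (n_modes > 2) attr(out, "modality") <- "multimodal"
  attr(out, "n_modes") <- n_modes
  out
}

# local maxima of a sampled curve, counting a maximum at the left edge
count_modes <- function(g) {
  d <- sign(diff(g))
  d <- d[d != 0]
  n <- sum(d[-1] < 0 & d[-length(d)] > 0)   # interior up-then-down
  if (length(d) && d[1] < 0) n <- n + 1L    # falling from the origin
  n
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Broom-style accessors for mixture fits
#'
#' @param x a `gaussian_mixture_fit`.
#' @param ... unused.
#' @return `tidy()`: one row per component (`component`, `weight`, `mean`,
#'   `sigma`); `glance()`: one row of fit-level summaries.
#' @export
tidy.gaussian_mixture_fit <- function(x, ...) {
  tibble::tibble(component = 1:2, weight = x$weights, mean = x$means,
                 sigma = x$sigmas)
}

#' @rdname tidy.gaussian_mixture_fit
#' @export
glance.gaussian_mixture_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n = x$n, n_iter = x$n_iter,
                 converged = x$converged, sigma_floor = x$sigma_floor,
                 seed = x$seed)
}
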