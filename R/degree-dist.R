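## Degree-distribution machinery: empirical cumulative distribution,
## power-law and Poisson fits, and AIC model comparison.  Two estimation
## frameworks coexist deliberately: the exponent gamma' reported in the
## panel comes from an ordinary least-squares fit of the log10 cumulative
## distribution (that is what the reported R2 describes), while AIC and
## log-likelihood come from the proper discrete maximum-likelihood fits on
## the degree sample.

#' Empirical degree distribution
#'
#' Builds the histogram, the relative-frequency pmf and the inclusive
#' cumulative distribution `P(K >= k)` on the observed support, unbinned.
#' Degree-0 vertices are excluded from the support: an isolated word type
#' carries no information about the tail of syntactic connectivity.
#'
#' @param degrees Integer degrees (e.g. `degree_stats(net)$k`), or a
#'   `syntactic_network` whose degrees are taken.
#' @return A `degree_distribution` list with `k` (sorted support),
#'   `count`, `pmf`, `cumulative` and `n` (sample size).
#' @export
degree_distribution <- function(degrees) {
  if (inherits(degrees, "syntactic_network"))
    degrees <- degree_vector(degrees)
  degrees <- degrees[degrees >= 1]
  if (!length(degrees)) stop_validation("all degrees are zero")
  tab <- table(degrees)
  k <- as.numeric(names(tab))
  count <- as.numeric(tab)
  degree_distribution_from_counts(k, count)
}

#' Degree distribution from (degree, count) pairs
#'
#' Counts may be non-integer weights; this is the constructor used by the
#' fitting code and by tests that need an exactly specified cumulative.
#'
#' @param k Strictly increasing positive degrees.
#' @param count Positive weights per degree.
#' @return A `degree_distribution`.
#' @export
degree_distribution_from_counts <- function(k, count) {
  stopifnot(length(k) == length(count), all(diff(k) > 0), all(k >= 1),
            all(count > 0))
  n <- sum(count)
  pmf <- count / n
  cumulative <- rev(cumsum(rev(pmf)))
  structure(list(k = k, count = count, pmf = pmf, cumulative = cumulative,
                 n = n),
            class = "degree_distribution")
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf("<degree_distribution> support %g..%g, n = %g\n",
              min(x$k), max(x$k), x$n))
  invisible(x)
}

## Discrete power-law log-likelihood: P(k) = k^-g / zeta(g, k_min).
powerlaw_loglik <- function(g, k, count, k_min) {
  n <- sum(count)
  -n * log(hurwitz_zeta(g, k_min)) - g * sum(count * log(k))
}

#' Fit a power law to the cumulative degree distribution
#'
#' The panel exponent gamma' is the negated slope of the OLS regression of
#' `log10 P(K >= k)` on `log10 k` over the fit range (`k >= k_min`), with
#' its R2; `gamma = gamma' + 1` by the cumulative/Zipf relation.  The AIC
#' and log-likelihood come from the discrete maximum-likelihood power law
#' on the degree sample, normalized by the Hurwitz zeta over
#' `k >= k_min` (the MLE exponent is reported as `gamma_mle`).
#'
#' @param dist A `degree_distribution`.
#' @param k_min Lower cut-off of the fit range (default 1).
#' @return A `powerlaw_fit` list: `gamma_prime`, `gamma`, `R2`,
#'   `gamma_mle`, `loglik`, `aic`, `fit_range`, `n`.
#' @export
fit_power_law <- function(dist, k_min = 1) {
  sel <- dist$k >= k_min
  k <- dist$k[sel]
  if (length(k) < 3) stop_validation("insufficient support: %d point(s) at k >= %g",
                                     length(k), k_min)
  ## renormalize the cumulative on the fit range so its first point is 1
  cum <- dist$cumulative[sel] / sum(dist$pmf[sel])
  lx <- log10(k)
  ly <- log10(cum)
  fit <- ols_simple(lx, ly)
  gamma_prime <- -fit$slope
  cnt <- dist$count[sel]
  mle <- optimize(function(g) -powerlaw_loglik(g, k, cnt, k_min),
                  interval = c(1.0001, 20))
  ll <- -mle$objective
  structure(list(gamma_prime = gamma_prime, gamma = gamma_prime + 1,
                 R2 = fit$R2, intercept = fit$intercept,
                 gamma_mle = mle$minimum, loglik = ll, aic = 2 - 2 * ll,
                 fit_range = c(k_min, max(k)), n = sum(cnt)),
            class = "powerlaw_fit")
}

#' Fit a Poisson model to a degree distribution
#'
#' The rate is the maximum-likelihood estimate (sample mean of the degree
#' sample).  R2 is computed on the same log10 cumulative domain used by
#' [fit_power_law()]: observed `log10 P(K >= k)` against the model's
#' cumulative conditioned on the support floor (`K >= min k`), so a
#' heavy-tailed sample yields a strongly negative R2.  AIC uses the
#' unconditioned Poisson log-likelihood of the sample.
#'
#' @param dist A `degree_distribution`.
#' @param k_min Lower cut-off for the R2 domain (default 1, matching
#'   [fit_power_law()]).
#' @return A `poisson_fit` list: `lambda`, `R2`, `loglik`, `aic`, `n`.
#' @export
fit_poisson <- function(dist, k_min = 1) {
  sel <- dist$k >= k_min
  k <- dist$k[sel]
  cnt <- dist$count[sel]
  lambda <- sum(dist$k * dist$count) / dist$n
  ll <- sum(dist$count * dpois(dist$k, lambda, log = TRUE))
  ## model cumulative P(K >= k | K >= k0) on the observed support
  k0 <- min(dist$k)
  tail_model <- ppois(k - 1, lambda, lower.tail = FALSE) /
    ppois(k0 - 1, lambda, lower.tail = FALSE)
  obs <- dist$cumulative[sel] / sum(dist$pmf[sel])
  ly <- log10(obs)
  pred <- log10(pmax(tail_model, .Machine$double.xmin))
  ss_res <- sum((ly - pred)^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(lambda = lambda, R2 = r2, loglik = ll, aic = 2 - 2 * ll,
                 n = dist$n),
            class = "poisson_fit")
}

#' Compare power-law and Poisson fits by AIC
#'
#' @param power A `powerlaw_fit`.
#' @param pois A `poisson_fit` on the same degree sample.
#' @return List with both fits, `delta_aic = AIC_poisson - AIC_powerlaw`
#'   and `preferred` (`"poisson"` on an exact tie: fewer assumptions).
#' @export
compare_models <- function(power, pois) {
  stopifnot(inherits(power, "powerlaw_fit"), inherits(pois, "poisson_fit"))
  if (!isTRUE(all.equal(power$n, pois$n)))
    stop_validation("fits come from different samples (n = %g vs %g)",
                    power$n, pois$n)
  delta <- pois$aic - power$aic
  preferred <- if (delta > 0) "power_law" else "poisson"
  list(power_law = power, poisson = pois, delta_aic = delta,
       preferred = preferred)
}

#' Sample from a discrete power law
#'
#' Draws from `P(k) proportional to k^-gamma` on `k = k_min, ..., k_cap`.
#' The cap (default 1e5) truncates an astronomically small tail mass for
#' the exponents in realistic use (gamma > 1.5).
#'
#' @param n Sample size.
#' @param gamma Exponent (> 1).
#' @param k_min Support floor.
#' @param k_cap Upper truncation.
#' @param seed Optional RNG seed (restores the caller's RNG state).
#' @return Integer vector of length `n`.
#' @export
rpowerlaw <- function(n, gamma, k_min = 1, k_cap = 1e5, seed = NULL) {
  stopifnot(gamma > 1)
  ks <- seq.int(k_min, k_cap)
  w <- ks^(-gamma)
  with_seed(seed, sample(ks, n, replace = TRUE, prob = w))
}
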