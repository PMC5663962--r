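#' Expected interaction count under the process model
#'
#' The process model is log-linear with a per-focal random intercept and a
#' log-exposure offset: `log(lambda) = alpha_j + x'beta + log(gamma)`, so the
#' expected count is `gamma * exp(alpha_j + x'beta)`. Doubling the exposure
#' doubles the expectation.
#'
#' @param alpha_j Random intercept(s) of the focal(s), recycled over dyads.
#' @param beta Coefficient vector.
#' @param x Covariate matrix (one row per dyad) or vector (single dyad).
#' @param gamma_minutes Positive exposure(s) in focal minutes.
#' @return The expected count(s) `lambda`, strictly positive.
#' @export
linear_predictor <- function(alpha_j, beta, x, gamma_minutes) {
  if (any(gamma_minutes <= 0)) abort("gamma_minutes must be positive")
  x <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  lam <- gamma_minutes * exp(alpha_j + drop(x %*% beta))
  if (any(!is.finite(lam))) abort("non-finite expected count (numeric overflow)")
  lam
}

#' Negative-binomial log PMF in the mean parameterization
#'
#' The sampling distribution of dyad counts: NB with success probability
#' `p = r / (r + lambda)` so that the mean is `lambda` and the variance is
#' `lambda * (1 + lambda / r)`; the dispersion `r` is continuous, so the PMF
#' is evaluated with log-gamma functions.
#'
#' @param y Non-negative integer count(s).
#' @param lambda Positive mean(s).
#' @param r Positive dispersion.
#' @return Log probability mass, vectorized over `y`/`lambda`.
#' @export
nb_log_pmf <- function(y, lambda, r) {
  if (any(y < 0) || any(y != floor(y))) abort("y must be non-negative integer")
  if (any(lambda <= 0) || any(r <= 0)) abort("lambda and r must be positive")
  lgamma(y + r) - lgamma(r) - lgamma(y + 1) +
    r * (log(r) - log(r + lambda)) + y * (log(lambda) - log(r + lambda))
}

# Prior precision shared by the coefficient and mu_alpha priors
# (normal(0, 0.1) read as mean/precision, i.e. variance 10).
PRIOR_PRECISION <- 0.1
TAU_SUPPORT <- c(0.001, 100)
R_SUPPORT <- c(0, 100)

#' Log posterior density of the hierarchical NB model
#'
#' Sum of the NB log-likelihood over dyads and the log-priors: coefficients
#' and `mu_alpha` are normal with mean 0 and precision 0.1 (variance 10),
#' random intercepts are normal with mean `mu_alpha` and precision
#' `tau_alpha`, and `tau_alpha` and `r` are uniform on (0.001, 100) and
#' (0, 100). Outside the uniform supports the density is `-Inf` (a valid
#' return, not an error). With zero dyads the log-prior alone is returned.
#'
#' @param beta Coefficient vector.
#' @param alpha Vector of per-focal intercepts.
#' @param mu_alpha,tau_alpha Mean and precision of the intercept distribution.
#' @param r NB dispersion.
#' @param y,x,gamma_minutes,focal Dyad data: counts, covariate matrix,
#'   exposures, and for each dyad the index (into `alpha`) of its focal.
#' @return The unnormalized log posterior density.
#' @export
log_posterior <- function(beta, alpha, mu_alpha, tau_alpha, r,
                          y, x, gamma_minutes, focal) {
  if (tau_alpha <= TAU_SUPPORT[1] || tau_alpha >= TAU_SUPPORT[2]) return(-Inf)
  if (r <= R_SUPPORT[1] || r >= R_SUPPORT[2]) return(-Inf)
  lp <- sum(-0.5 * PRIOR_PRECISION * beta^2 +
              0.5 * log(PRIOR_PRECISION / (2 * pi)))
  lp <- lp - 0.5 * PRIOR_PRECISION * mu_alpha^2 +
    0.5 * log(PRIOR_PRECISION / (2 * pi))
  lp <- lp + sum(-0.5 * tau_alpha * (alpha - mu_alpha)^2 +
                   0.5 * log(tau_alpha / (2 * pi)))
  lp <- lp - log(diff(TAU_SUPPORT)) - log(diff(R_SUPPORT))
  if (length(y) > 0) {
    lam <- linear_predictor(alpha[focal], beta, x, gamma_minutes)
    lp <- lp + sum(nb_log_pmf(y, lam, r))
  }
  lp
}

#' Gelman-Rubin potential scale reduction factor
#'
#' For m chains of equal length n, with within-chain variance W (mean of the
#' chain variances) and between-chain variance B (n times the variance of
#' the chain means): `Rhat = sqrt(((n-1)/n * W + B/n) / W)`. Identical
#' chains give exactly 1; values below 1.1 are conventionally taken as
#' converged. Zero within-chain variance leaves the diagnostic undefined
#' (`NA` with a message attribute).
#'
#' @param chains A list of numeric vectors, one per chain, equal lengths
#'   (at least 10 post-burn-in draws each).
#' @return The scalar Rhat, or `NA` if undefined.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2) {
    abort("need at least 2 chains")
  }
  n <- unique(lengths(chains))
  if (length(n) != 1) abort("chains must have equal length")
  if (n < 10) abort("chains must have at least 10 draws")
  means <- vapply(chains, mean, numeric(1))
  vars <- vapply(chains, stats::var, numeric(1))
  w <- mean(vars)
  b_over_n <- stats::var(means)   # = B / n
  if (w == 0) {
    out <- NA_real_
    attr(out, "note") <- "zero within-chain variance; Rhat undefined"
    return(out)
  }
  sqrt(((n - 1) / n * w + b_over_n) / w)
}
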