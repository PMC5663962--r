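#' MCMC configuration
#'
#' Sampler settings: number of parallel chains, iterations per chain,
#' burn-in fraction discarded from the front of each chain, thinning, and
#' the RNG seed. Defaults follow the analysis protocol: three chains of
#' 100,000 iterations with the first 10% discarded and no thinning. At
#' least two chains are required for the convergence diagnostic.
#'
#' @param n_chains Integer >= 2.
#' @param n_iter Iterations per chain.
#' @param burn_in_fraction In [0, 1).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param seed Integer RNG seed.
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 3, n_iter = 100000,
                        burn_in_fraction = 0.10, thin = 1, seed = 1) {
  stopifnot(n_chains >= 2, n_iter >= 10,
            burn_in_fraction >= 0, burn_in_fraction < 1, thin >= 1)
  structure(
    list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
         burn_in_fraction = burn_in_fraction, thin = as.integer(thin),
         seed = as.integer(seed)),
    class = "mcmc_config"
  )
}

#' Model design matrix from a dyad table
#'
#' Extracts the stratum's covariates from a dyad table in the fixed model
#' order, z-scoring the continuous covariates (age, and age orphaned in the
#' orphan stratum) across the table's rows.
#'
#' @param dyads A single-stratum, single-activity dyad table.
#' @return Numeric matrix with a `scaling` attribute.
#' @export
dyad_model_matrix <- function(dyads) {
  stratum <- unique(dyads$stratum)
  if (length(stratum) != 1) abort("dyad table must hold exactly one stratum")
  status <- tibble::tibble(
    focal_id = unique(dyads$focal_id)
  )
  i <- match(status$focal_id, dyads$focal_id)
  status$is_orphan <- stratum == "orphan"
  status$mean_age <- dyads$age[i]
  status$age_orphaned <- dyads$age_orphaned[i]
  covariate_matrix(status, dyads, stratum)
}

#' Fit the hierarchical Bayesian negative-binomial affiliation model
#'
#' Fits one of the four study models (stratum x activity) to a dyad table:
#' NB counts with mean `gamma * exp(alpha_j + x'beta)`, per-focal random
#' intercepts `alpha_j ~ N(mu_alpha, precision tau_alpha)`, coefficient and
#' `mu_alpha` priors normal(0, precision 0.1), `tau_alpha` uniform on
#' (0.001, 100) and the dispersion uniform on (0, 100). Sampling is
#' adaptive Metropolis-within-Gibbs
#' (componentwise Gaussian random walks; bounded parameters on logit
#' transforms; proposal scales adapted toward 0.44 acceptance during burn-in
#' only). Chains are initialised from the priors and run sequentially, so
#' the fit is deterministic given the seed.
#'
#' @param dyads A single-stratum, single-activity dyad table from
#'   [build_dyad_table()].
#' @param config An [mcmc_config()].
#' @param check_collinearity Refuse to fit when any covariate pair has
#'   |r| > 0.7 (default TRUE).
#' @return An object of class `affil_nb` with elements `chains` (list of
#'   draw matrices, post-burn-in), `spec`, `config`, `data`, `acceptance`,
#'   `scaling`.
#' @export
fit_affiliation_model <- function(dyads, config = mcmc_config(),
                                  check_collinearity = TRUE) {
  stratum <- unique(dyads$stratum)
  activity <- unique(dyads$activity)
  if (length(stratum) != 1 || length(activity) != 1) {
    abort("dyad table must hold exactly one stratum and one activity")
  }
  if (nrow(dyads) == 0L) abort("dyad table is empty")
  x <- dyad_model_matrix(dyads)
  scr <- collinearity_screen(x)
  if (check_collinearity && !scr$pass) {
    bad <- scr$pairs[scr$pairs$flagged, ]
    abort(paste0("collinearity screen failed (|r| > 0.7): ",
                 paste(paste(bad$var_a, bad$var_b, sep = "~"), collapse = ", ")))
  }
  all_zero <- colnames(x)[colSums(dyads$y * (x != 0)) == 0 &
                            apply(x != 0, 2, any)]
  if (length(all_zero) > 0) {
    warn(paste0("no interactions observed for covariate(s) ",
                paste(all_zero, collapse = ", "),
                "; weakly identified"))
  }
  fit_nb_raw(
    y = dyads$y, x = x, gamma_minutes = dyads$gamma_minutes,
    focal_id = dyads$focal_id, config = config,
    spec = list(stratum = stratum, activity = activity,
                covariate_order = colnames(x)),
    screen = scr
  )
}

# Core fitting routine shared by the public fitter and prior-only fits.
fit_nb_raw <- function(y, x, gamma_minutes, focal_id, config, spec,
                       screen = NULL) {
  focal_levels <- unique(focal_id)
  j <- length(focal_levels)
  p <- ncol(x)
  burn <- floor(config$n_iter * config$burn_in_fraction)
  set.seed(config$seed)
  chains <- vector("list", config$n_chains)
  acceptance <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    # overdispersed initials drawn from the priors
    tau0 <- runif(1, TAU_SUPPORT[1] + 1e-6, TAU_SUPPORT[2] - 1e-6)
    r0 <- runif(1, 0.01, R_SUPPORT[2] - 1e-6)
    mu0 <- rnorm(1, 0, sqrt(1 / PRIOR_PRECISION))
    beta0 <- rnorm(p, 0, sqrt(1 / PRIOR_PRECISION))
    alpha0 <- rnorm(j, mu0, sqrt(1 / tau0))
    res <- .nb_mcmc_chain(
      y = as.integer(y), log_gamma = log(gamma_minutes), X = x,
      focal = match(focal_id, focal_levels) - 1L, n_focals = j,
      n_iter = config$n_iter, burn_in = burn, thin = config$thin,
      init_beta = beta0, init_alpha = alpha0, init_mu = mu0,
      init_tau = tau0, init_r = r0
    )
    pn <- c(spec$covariate_order,
            paste0("alpha[", focal_levels, "]", recycle0 = TRUE),
            "mu_alpha", "tau_alpha", "r")
    colnames(res$samples) <- pn
    chains[[ch]] <- res$samples
    acceptance[[ch]] <- setNames(res$acceptance, pn)
  }
  acc <- colMeans(do.call(rbind, acceptance))
  out_of_range <- acc[acc < 0.05 | acc > 0.95]
  if (length(out_of_range) > 0) {
    warn(paste0("acceptance rate outside [0.05, 0.95] after adaptation for: ",
                paste(names(out_of_range), collapse = ", ")))
  }
  structure(
    list(chains = chains, spec = spec, config = config,
         data = list(y = y, x = x, gamma_minutes = gamma_minutes,
                     focal_id = focal_id, focal_levels = focal_levels),
         acceptance = acc, screen = screen,
         scaling = attr(x, "scaling")),
    class = "affil_nb"
  )
}

#' Posterior summary of a fitted model
#'
#' Pools the post-burn-in draws of all chains and reports, per parameter,
#' the median, the equal-tailed 95% credible interval, and the Gelman-Rubin
#' diagnostic computed across chains. Coefficients come first, in the
#' model's covariate order.
#'
#' @param fit An `affil_nb` object.
#' @return A tibble with `term`, `median`, `ci_2.5`, `ci_97.5`, `rhat`.
#' @export
summarize_posterior <- function(fit) {
  stopifnot(inherits(fit, "affil_nb"))
  pooled <- do.call(rbind, fit$chains)
  terms <- colnames(pooled)
  qs <- apply(pooled, 2, quantile, probs = c(0.5, 0.025, 0.975), names = FALSE)
  rhat <- vapply(terms, function(tm) {
    as.numeric(gelman_rubin(lapply(fit$chains, function(m) m[, tm])))
  }, numeric(1))
  tibble::tibble(
    term = terms, median = qs[1, ], ci_2.5 = qs[2, ], ci_97.5 = qs[3, ],
    rhat = rhat
  )
}

#' @export
print.affil_nb <- function(x, ...) {
  cat("Hierarchical Bayesian NB affiliation model\n")
  cat("  stratum:", x$spec$stratum, " activity:", x$spec$activity, "\n")
  cat("  dyads:", length(x$data$y), " focals:", length(x$data$focal_levels), "\n")
  cat("  chains:", length(x$chains), "x", nrow(x$chains[[1]]),
      "post-burn-in draws\n")
  s <- summarize_posterior(x)
  s <- s[s$term %in% x$spec$covariate_order, ]
  print(as.data.frame(s), digits = 3, row.names = FALSE)
  invisible(x)
}

#' Tidy coefficient summary (broom-style)
#'
#' @param x An `affil_nb` fit.
#' @param ... Unused.
#' @return A tibble with one row per regression coefficient: `term`,
#'   `estimate` (posterior median), `conf.low`, `conf.high` (95% credible
#'   interval), `rhat`.
#' @export
tidy.affil_nb <- function(x, ...) {
  s <- summarize_posterior(x)
  s <- s[match(x$spec$covariate_order, s$term), ]
  tibble::tibble(
    term = s$term, estimate = s$median,
    conf.low = s$ci_2.5, conf.high = s$ci_97.5, rhat = s$rhat
  )
}

#' One-row model overview (broom-style)
#'
#' @param x An `affil_nb` fit.
#' @param ... Unused.
#' @return A one-row tibble: stratum, activity, dyads, focals, chains,
#'   iterations, max Rhat over monitored parameters, convergence flag.
#' @export
glance.affil_nb <- function(x, ...) {
  s <- summarize_posterior(x)
  tibble::tibble(
    stratum = x$spec$stratum, activity = x$spec$activity,
    n_dyads = length(x$data$y), n_focals = length(x$data$focal_levels),
    n_chains = length(x$chains),
    n_iter = x$config$n_iter,
    max_rhat = max(s$rhat, na.rm = TRUE),
    converged = all(s$rhat < 1.1, na.rm = TRUE)
  )
}

#' Forest plot of posterior coefficient estimates
#'
#' @param object An `affil_nb` fit.
#' @param ... Unused.
#' @return A ggplot: posterior medians with 95% credible intervals per
#'   covariate.
#' @export
autoplot.affil_nb <- function(object, ...) {
  td <- tidy(object)
  td$term <- factor(td$term, levels = rev(td$term))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(
      x = "Posterior median (95% CrI)", y = NULL,
      title = paste0(object$spec$stratum, " (", object$spec$activity, ")")
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
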