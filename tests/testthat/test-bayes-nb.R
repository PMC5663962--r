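test_that("linear predictor implements the offset process model", {
  # beta = 0, alpha = 0 -> expectation equals the exposure
  expect_equal(linear_predictor(0, c(0, 0), c(1, 2), 45), 45)
  # alpha = ln 2, beta.x = 0, gamma = 10 -> lambda = 20
  expect_equal(linear_predictor(log(2), 0, 0, 10), 20)
  # doubling the exposure doubles the expectation
  l1 <- linear_predictor(0.3, c(0.5, -0.2), c(1, 1), 60)
  l2 <- linear_predictor(0.3, c(0.5, -0.2), c(1, 1), 120)
  expect_equal(l2, 2 * l1)
  expect_error(linear_predictor(0, 0, 0, 0), "positive")
  expect_error(linear_predictor(5000, 0, 0, 10), "overflow")
})

test_that("NB pmf is normalized, mean-parameterized, with Poisson limit", {
  # brute-force normalization: probabilities over y = 0..large sum to 1
  y <- 0:2000
  expect_equal(sum(exp(nb_log_pmf(y, lambda = 3, r = 1.5))), 1,
               tolerance = 1e-10)
  # mean identity under p = r/(r+lambda): E[Y] = lambda by direct summation
  expect_equal(sum(y * exp(nb_log_pmf(y, lambda = 5, r = 2))), 5,
               tolerance = 1e-8)
  # variance identity: lambda (1 + lambda/r)
  expect_equal(sum(y^2 * exp(nb_log_pmf(y, 5, 2))) - 25, 5 * (1 + 5 / 2),
               tolerance = 1e-6)
  # r -> infinity limit reproduces the Poisson log pmf
  expect_equal(nb_log_pmf(0:15, lambda = 4, r = 1e6),
               dpois(0:15, 4, log = TRUE), tolerance = 1e-4)
  expect_error(nb_log_pmf(-1, 1, 1), "non-negative")
  expect_error(nb_log_pmf(1, -2, 1), "positive")
})

test_that("log posterior matches a brute-force oracle to 1e-10", {
  toy <- toy_dyads()
  set.seed(5)
  for (i in 1:20) {
    beta <- rnorm(4, 0, 1)
    alpha <- rnorm(3, -1, 1)
    mu <- rnorm(1)
    tau <- runif(1, 0.01, 50)
    r <- runif(1, 0.2, 20)
    got <- log_posterior(beta, alpha, mu, tau, r,
                         toy$y, toy$x, toy$gamma, toy$focal)
    want <- oracle_log_posterior(beta, alpha, mu, tau, r,
                                 toy$y, toy$x, toy$gamma, toy$focal)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("log posterior respects the uniform prior supports", {
  toy <- toy_dyads()
  base <- list(beta = rep(0, 4), alpha = rep(0, 3), mu = 0)
  expect_equal(log_posterior(base$beta, base$alpha, base$mu, 200, 1,
                             toy$y, toy$x, toy$gamma, toy$focal), -Inf)
  expect_equal(log_posterior(base$beta, base$alpha, base$mu, 1e-4, 1,
                             toy$y, toy$x, toy$gamma, toy$focal), -Inf)
  expect_equal(log_posterior(base$beta, base$alpha, base$mu, 1, 150,
                             toy$y, toy$x, toy$gamma, toy$focal), -Inf)
  # zero dyads: the log-prior alone
  got <- log_posterior(base$beta, base$alpha, base$mu, 1, 1,
                       integer(0), matrix(0, 0, 4), numeric(0), integer(0))
  want <- oracle_log_posterior(base$beta, base$alpha, base$mu, 1, 1,
                               integer(0), matrix(0, 0, 4), numeric(0),
                               integer(0))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("Gelman-Rubin diagnostic behaves at its limits", {
  x <- rnorm(1e4)
  # identical chains: B = 0, Rhat = 1 (up to the (n-1)/n factor)
  expect_equal(gelman_rubin(list(x, x, x)), 1, tolerance = 1e-4)
  # well-separated chains
  set.seed(8)
  far <- gelman_rubin(list(rnorm(1000, 0), rnorm(1000, 10)))
  expect_gt(far, 5)
  # chains from one stationary distribution
  set.seed(9)
  near <- gelman_rubin(list(rnorm(1e4), rnorm(1e4), rnorm(1e4)))
  expect_lt(near, 1.01)
  # degenerate chains: undefined, reported as NA
  expect_true(is.na(gelman_rubin(list(rep(1, 100), rep(1, 100)))))
  expect_error(gelman_rubin(list(rnorm(10))), "at least 2")
  expect_error(gelman_rubin(list(rnorm(10), rnorm(12))), "equal length")
})

test_that("Gelman-Rubin agrees with the coda reference implementation", {
  set.seed(12)
  chains <- list(rnorm(2000, 0), rnorm(2000, 0.05), rnorm(2000, -0.05, 1.1))
  got <- gelman_rubin(chains)
  ref <- coda::gelman.diag(coda::mcmc.list(lapply(chains, coda::mcmc)),
                           autoburnin = FALSE)$psrf[1, 1]
  # coda applies a df adjustment and an (m+1)/m factor on B; near
  # convergence the two estimators coincide closely
  expect_equal(got, unname(ref), tolerance = 0.01)
  # and both classify clearly divergent chains as unconverged
  far <- list(rnorm(500, 0), rnorm(500, 3))
  ref_far <- coda::gelman.diag(coda::mcmc.list(lapply(far, coda::mcmc)),
                               autoburnin = FALSE)$psrf[1, 1]
  expect_gt(gelman_rubin(far), 1.1)
  expect_gt(ref_far, 1.1)
})

test_that("the sampler is deterministic given the seed", {
  reg <- tiny_registry()
  dy <- build_dyad_table(tiny_follows(), tiny_interactions(), reg,
                         "feeding", "non_orphan", tiny_window())
  cfg <- mcmc_config(n_chains = 2, n_iter = 500, seed = 42)
  f1 <- suppressWarnings(fit_affiliation_model(dy, cfg))
  f2 <- suppressWarnings(fit_affiliation_model(dy, cfg))
  expect_identical(f1$chains, f2$chains)
  cfg2 <- mcmc_config(n_chains = 2, n_iter = 500, seed = 43)
  f3 <- suppressWarnings(fit_affiliation_model(dy, cfg2))
  expect_false(identical(f1$chains[[1]], f3$chains[[1]]))
})

test_that("prior-only sampling reproduces the declared priors", {
  # no dyads: the posterior is the prior; beta_k ~ N(0, precision 0.1)
  fit <- orphanbonds:::fit_nb_raw(
    y = integer(0), x = matrix(numeric(0), 0, 2,
                               dimnames = list(NULL, c("b1", "b2"))),
    gamma_minutes = numeric(0), focal_id = character(0),
    config = mcmc_config(n_chains = 3, n_iter = 20000, seed = 31),
    spec = list(stratum = "orphan", activity = "feeding",
                covariate_order = c("b1", "b2"))
  )
  pooled <- do.call(rbind, fit$chains)
  expect_equal(sd(pooled[, "b1"]), sqrt(10), tolerance = 0.1)
  expect_equal(mean(pooled[, "b2"]), 0, tolerance = 0.15)
  # r remains uniform on (0, 100)
  expect_equal(mean(pooled[, "r"]), 50, tolerance = 3)
  expect_gt(min(pooled[, "tau_alpha"]), 0.001)
  expect_lt(max(pooled[, "tau_alpha"]), 100)
})

test_that("posterior summaries order terms and bracket the median", {
  tr <- recovery_truth(seed = 3)
  sim <- simulate_study(tr)
  dy <- build_dyad_table(sim$follows, sim$interactions, sim$registry,
                         "feeding", "orphan", tr$window, status = sim$status)
  fit <- fit_affiliation_model(dy, mcmc_config(n_chains = 2, n_iter = 2000,
                                               seed = 14))
  s <- summarize_posterior(fit)
  expect_true(all(s$ci_2.5 <= s$median & s$median <= s$ci_97.5))
  td <- tidy(fit)
  expect_identical(td$term, covariate_names("orphan"))
  g <- glance(fit)
  expect_equal(g$n_dyads, nrow(dy))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("fit refuses collinear designs and flags unidentified covariates", {
  reg <- tiny_registry()
  dy <- build_dyad_table(tiny_follows(), tiny_interactions(), reg,
                         "feeding", "non_orphan", tiny_window())
  dup <- dy
  dup$aunt <- dup$sister   # force a perfectly collinear flag pair
  expect_error(fit_affiliation_model(dup, mcmc_config(n_iter = 100)),
               "collinearity")
  # all-zero counts for an active covariate column draw a warning
  none <- dy
  none$y <- 0L
  expect_warning(
    fit_affiliation_model(none, mcmc_config(n_chains = 2, n_iter = 200,
                                            seed = 2)),
    "weakly identified"
  )
})
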