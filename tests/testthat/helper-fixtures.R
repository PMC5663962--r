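# Hand-built miniature population used across tests. Window 2010-2014
# (midpoint 2012). Group G1 holds a dead grandmother, a living matriarch
# (also an aunt of the focals), two mothers, a focal sister pair, a calf, a
# dispersed bull and a natal young male; G2 holds an orphaned focal whose
# mother died in 2011; G3 holds a mother who is the oldest living female of
# her group (matriarch to outsiders, mother to her own daughter).
tiny_window <- function() study_window(2010, 2014)

tiny_registry <- function() {
  validate_registry(tibble::tribble(
    ~id,    ~sex, ~birth_year, ~mother_id, ~core_group_id, ~death_year, ~dispersed_from_natal,
    "GM1",  "F",  1960,        NA,         "G1",           2005,        FALSE,
    "MAT1", "F",  1970,        "GM1",      "G1",           NA,          FALSE,
    "M1",   "F",  1985,        "GM1",      "G1",           NA,          FALSE,
    "M2",   "F",  1988,        "GM1",      "G1",           NA,          FALSE,
    "F1",   "F",  2002,        "M1",       "G1",           NA,          FALSE,
    "F2",   "F",  2004,        "M1",       "G1",           NA,          FALSE,
    "F3",   "F",  2003,        "M2",       "G1",           NA,          FALSE,
    "C1",   "F",  2013.5,      "M2",       "G1",           NA,          FALSE,
    "B1",   "M",  1990,        NA,         "G1",           NA,          TRUE,
    "YM1",  "M",  2004,        NA,         "G1",           NA,          FALSE,
    "MAT2", "F",  1972,        NA,         "G2",           NA,          FALSE,
    "M3",   "F",  1990,        "MAT2",     "G2",           2011,        FALSE,
    "F4",   "F",  2003,        "M3",       "G2",           NA,          FALSE,
    "B2",   "M",  1995,        NA,         "G2",           NA,          TRUE,
    "M4",   "F",  1980,        NA,         "G3",           NA,          FALSE,
    "F5",   "F",  2004,        "M4",       "G3",           NA,          FALSE
  ))
}

tiny_follows <- function() {
  validate_follows(tibble::tibble(
    follow_id = c("FL1", "FL2", "FL3", "FL4"),
    focal_id = c("F1", "F1", "F1", "F4"),
    date = as.Date(c("2012-06-01", "2012-06-02", "2012-06-01", "2012-06-03")),
    activity = c("feeding", "feeding", "resting", "feeding"),
    duration_minutes = c(30, 30, 20, 15),
    present_ids = list(c("F2", "B1", "M1"), c("F2", "M1", "M2", "YM1"),
                       "F2", c("B2", "MAT2"))
  ))
}

tiny_interactions <- function() {
  validate_interactions(tibble::tibble(
    follow_id = c("FL1", "FL1", "FL1", "FL2", "FL2", "FL4"),
    partner_id = c("F2", "B1", "M1", "F2", "F2", "MAT2"),
    itype = c("greeting", "play", "greeting", "trunk_touch", "other",
              "bodily_contact")
  ), tiny_follows())
}

# Independently coded direct-summation log posterior used as the oracle for
# the packaged log_posterior and (indirectly) the sampler target.
oracle_log_posterior <- function(beta, alpha, mu_alpha, tau_alpha, r,
                                 y, x, gamma, focal) {
  if (tau_alpha <= 0.001 || tau_alpha >= 100 || r <= 0 || r >= 100) {
    return(-Inf)
  }
  lp <- 0
  for (k in seq_along(beta)) {
    lp <- lp + stats::dnorm(beta[k], 0, sqrt(1 / 0.1), log = TRUE)
  }
  lp <- lp + stats::dnorm(mu_alpha, 0, sqrt(1 / 0.1), log = TRUE)
  for (j in seq_along(alpha)) {
    lp <- lp + stats::dnorm(alpha[j], mu_alpha, sqrt(1 / tau_alpha), log = TRUE)
  }
  lp <- lp + stats::dunif(tau_alpha, 0.001, 100, log = TRUE)
  lp <- lp + stats::dunif(r, 0, 100, log = TRUE)
  for (i in seq_along(y)) {
    lam <- gamma[i] * exp(alpha[focal[i]] + sum(x[i, ] * beta))
    lp <- lp + stats::dnbinom(y[i], size = r, mu = lam, log = TRUE)
  }
  lp
}

# A reproducible 10-dyad toy problem spanning 3 focals and 4 covariates.
toy_dyads <- function(seed = 99) {
  set.seed(seed)
  n <- 10
  list(
    y = c(0L, 3L, 1L, 0L, 7L, 2L, 0L, 1L, 4L, 0L),
    x = matrix(round(rnorm(n * 4), 2), n, 4,
               dimnames = list(NULL, paste0("x", 1:4))),
    gamma = round(runif(n, 5, 120), 1),
    focal = c(1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L)
  )
}
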