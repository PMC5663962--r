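# orphanbonds

Dyadic affiliation analysis for orphaned and non-orphaned female elephants.

Maternal loss forces young female elephants to rebuild their social networks
in a society organised around mothers and maternal kin. This package
implements, as a tested and reusable pipeline, the comparison of affiliative
social partners between orphaned and non-orphaned focal females observed by
focal-follow sampling, in two behavioural contexts with different resource
competition (feeding vs resting). It is aimed at behavioural ecologists
working with focal-follow interaction data and co-occurrence-based exposure.

## What it computes

The unit of analysis is the dyad (focal *j*, partner *i*) within one
activity: the affiliative interaction count *y<sub>ij</sub>* and the exposure
*γ<sub>ij</sub>* — total focal minutes of *j* during which *i* was present in
the same aggregation and therefore available to interact. The core model is
a hierarchical Bayesian negative-binomial regression with a log-exposure
offset and per-focal random intercepts:

    ln(λ_ij) = α_j + β·x_ij + ln(γ_ij)
    y_ij ~ NB(p_ij, r),   p_ij = r / (r + λ_ij)      (mean λ, variance λ(1+λ/r))
    β_k ~ N(0, 0.1)   μ_α ~ N(0, 0.1)                (mean, precision)
    α_j ~ N(μ_α, τ_α)   τ_α ~ U(0.001, 100)   r ~ U(0, 100)

fitted separately for orphans/non-orphans × feeding/resting with an
in-package adaptive Metropolis-within-Gibbs sampler (C++ core; three chains
of 100,000 iterations, 10% burn-in by default) and Gelman–Rubin convergence
diagnostics (R̂ < 1.1). Covariates are partner categories (age mate, aunt,
bull, calf, matriarch, mother, maternal sister) plus focal age and — for
orphans — age at orphaning.

Around the model the package provides: validated CSV I/O for registries,
focal follows and interaction events; dyad-table assembly with zero-exposure
exclusion; per-category median (IQR) interaction-rate tables; Kruskal–Wallis
rank sum tests (tie-corrected, with an exact permutation option) for
partner counts per time followed and focal–partner age differences; a
collinearity screen (|r| > 0.7 blocks fitting); a synthetic-data generator
with known ground truth; and a parameter-recovery harness. See the
`affiliation-analysis` vignette for the model's assumptions, the generator's
design and its limits.

## Worked example

Simulate a study with known ground truth, build the orphan/feeding dyad
table, run the rank-test battery and fit one model:

```r
library(orphanbonds)

truth <- synthetic_truth(seed = 7)     # ~48 focals, 8 core groups, 60% orphans
sim <- simulate_study(truth)

dyads <- build_dyad_table(sim$follows, sim$interactions, sim$registry,
                          activity = "feeding", stratum = "orphan",
                          window = truth$window, status = sim$status)
dyads[1:3, c("focal_id", "partner_id", "y", "gamma_minutes")]
#>   focal_id partner_id     y gamma_minutes
#> 1 G01_F01  G01_A01        1         267.
#> 2 G01_F01  G01_A02        0         254.
#> 3 G01_F01  G01_B01        1          58.8
```

Each row is one dyad: partner `G01_A01` was co-present for 267 focal
minutes and interacted affiliatively once. Orphan vs non-orphan rank tests:

```r
kw_partner_tests(sim$follows, sim$interactions, sim$registry,
                 truth$window, sim$status)
#>                test activity partner_filter statistic p_value
#> 1 partners_per_time  feeding   all_partners     0.245  0.6203
#> 2    age_difference  feeding   all_partners     5.232  0.0222
#> ...
```

The statistic is the tie-corrected Kruskal–Wallis chi-square on 1 df;
here partner *numbers* do not differ between orphans and non-orphans
(p = 0.62) but partner *age differences* do while feeding (p = 0.022).
Fit the orphan/feeding model and summarise the posterior:

```r
fit <- fit_affiliation_model(dyads, mcmc_config(n_chains = 3, n_iter = 20000,
                                                seed = 7))
tidy(fit)
#>   term         estimate conf.low conf.high  rhat
#> 1 age            -0.592  -0.758     -0.432  1.00
#> 2 age_orphaned    0.229   0.0638     0.400  1.00
#> 3 age_mate        0.435   0.310      0.560  1.00
#> 4 aunt           -0.439  -0.704     -0.171  1.00
#> 5 bull            0.651   0.531      0.773  1.00
#> 6 calf            0.740   0.564      0.921  1.00
#> 7 matriarch      -0.352  -0.596     -0.117  1.00
#> 8 sister         -0.202  -0.559      0.176  1.00
```

Estimates are posterior medians with equal-tailed 95% credible intervals on
z-scored continuous covariates and 0/1 category flags: positive values mean
more affiliation with that partner category than the focal's baseline rate.
All R̂ ≈ 1.00, and the medians recover this simulation's true coefficients
(e.g. bull 0.7, calf 0.9, matriarch −0.45) within posterior uncertainty.
`glance(fit)` gives a one-row convergence overview, `autoplot(fit)` a forest
plot, and `run_study()` orchestrates all four models plus descriptives and
report CSVs in one call.

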