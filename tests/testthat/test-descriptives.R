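test_that("interaction rates are per-dyad y/gamma medians by category", {
  reg <- tiny_registry()
  dy <- dplyr::bind_rows(
    build_dyad_table(tiny_follows(), tiny_interactions(), reg, "feeding",
                     "non_orphan", tiny_window()),
    build_dyad_table(tiny_follows(), tiny_interactions(), reg, "feeding",
                     "orphan", tiny_window())
  )
  rates <- interaction_rates(dy)
  sister <- rates[rates$category == "sister" & rates$stratum == "non_orphan", ]
  expect_equal(sister$rate_median, 2 / 60)   # F1-F2: y=2 over 60 minutes

  # a dyad with matching flag but no interactions contributes rate 0
  aunt <- rates[rates$category == "aunt" & rates$stratum == "non_orphan", ]
  expect_equal(aunt$rate_median, 0)          # F1-M2 never interacted

  # empty cells are absent, not zero
  expect_false("mother" %in% rates$category[rates$stratum == "orphan"])

  # scaling: multiplying every exposure by c divides every rate by c
  dy2 <- dy
  dy2$gamma_minutes <- dy2$gamma_minutes * 10
  r2 <- interaction_rates(dy2)
  expect_equal(r2$rate_median, rates$rate_median / 10)
  expect_equal(r2$rate_q3, rates$rate_q3 / 10)

  # and the medians do not depend on dyad ordering
  set.seed(2)
  r3 <- interaction_rates(dy[sample(nrow(dy)), ])
  expect_equal(r3, rates)
})

test_that("partners per time counts distinct affiliative partners", {
  ppt <- partners_per_time(tiny_follows(), tiny_interactions(), "feeding")
  f1 <- ppt[ppt$focal_id == "F1", ]
  # F2 (twice, counted once), B1, M1 -> 3 partners over 60 minutes
  expect_equal(f1$n_partners, 3L)
  expect_equal(f1$partners_per_minute, 0.05)
  # a focal with follows but no interactions scores 0
  ppt_rest <- partners_per_time(tiny_follows(), tiny_interactions(), "resting")
  expect_equal(ppt_rest$n_partners[ppt_rest$focal_id == "F1"], 0L)
  # focals with no minutes in the activity are excluded
  expect_false("F4" %in% ppt_rest$focal_id)
})

test_that("age differences are per-focal means under the chosen filter", {
  reg <- tiny_registry()
  w <- tiny_window()
  # evaluate focal and partner ages at the same date (the window midpoint)
  st <- orphan_status(reg, c("F1", "F4"), w$mid)
  ad_all <- age_differences(tiny_follows(), tiny_interactions(), reg,
                            "feeding", w, st, partner_filter = "all_partners")
  # F1 (age 10 at 2012): partners F2 (-2), B1 (+12), M1 (+17)
  f1 <- ad_all[ad_all$focal_id == "F1", ]
  expect_equal(f1$n_partners, 3L)
  expect_equal(f1$mean_age_diff, mean(c(-2, 12, 17)))

  # restricted filter: only older female partners -> drops F2 and bull B1
  ad_f <- age_differences(tiny_follows(), tiny_interactions(), reg,
                          "feeding", w, st, partner_filter = "older_females")
  f1f <- ad_f[ad_f$focal_id == "F1", ]
  expect_equal(f1f$n_partners, 1L)
  expect_equal(f1f$mean_age_diff, 17)

  # a focal whose only partners are excluded disappears from the table
  ev_bull <- tibble::tibble(follow_id = "FL4", partner_id = "B2",
                            itype = "play")
  ad_b <- age_differences(tiny_follows(), ev_bull, reg, "feeding", w, st,
                          partner_filter = "older_females")
  expect_false("F4" %in% ad_b$focal_id)
})

test_that("Kruskal-Wallis statistic matches hand-derived and reference values", {
  # rank-sum formula evaluated by hand: H({1,2,3},{4,5,6}) = 27/7 = 3.857
  kw <- kruskal_wallis(c(1, 2, 3), c(4, 5, 6))
  expect_equal(kw$statistic, 27 / 7, tolerance = 1e-12)
  expect_equal(round(kw$statistic, 3), 3.857)
  expect_equal(kw$df, 1L)

  # two identical groups -> H = 0 by symmetry
  expect_equal(kruskal_wallis(c(2, 5, 9), c(2, 5, 9))$statistic, 0,
               tolerance = 1e-12)

  # all pooled values identical -> guarded tie correction, H defined as 0
  kw0 <- kruskal_wallis(rep(3, 4), rep(3, 5))
  expect_equal(kw0$statistic, 0)
  expect_equal(kw0$p_value, 1)

  # agreement with the independent reference implementation, with ties
  set.seed(101)
  for (i in 1:100) {
    a <- sample(0:8, sample(3:12, 1), replace = TRUE)
    b <- sample(0:8, sample(3:12, 1), replace = TRUE)
    if (length(unique(c(a, b))) < 2) next
    ref <- stats::kruskal.test(list(a, b))
    kw <- kruskal_wallis(a, b)
    expect_equal(kw$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(kw$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Kruskal-Wallis is rank-based and properly bounded", {
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(6)
    b <- rnorm(8)
    h <- kruskal_wallis(a, b)
    # invariant under strictly monotone transforms of the pooled values
    h2 <- kruskal_wallis(exp(a), exp(b))
    expect_equal(h$statistic, h2$statistic, tolerance = 1e-12)
    expect_gte(h$statistic, 0)
    expect_gt(h$p_value, 0)
    expect_lte(h$p_value, 1)
  }
})

test_that("exact permutation p-value agrees with enumeration expectations", {
  # complete separation of 3 vs 3: the most extreme of choose(6,3) splits,
  # counted on both tails of the statistic -> p = 2/20
  kw <- kruskal_wallis(c(1, 2, 3), c(4, 5, 6), method = "permutation")
  expect_equal(kw$p_value, 2 / 20)
  # permutation p for a null configuration is large
  kw0 <- kruskal_wallis(c(1, 4, 6), c(2, 3, 5), method = "permutation")
  expect_gt(kw0$p_value, 0.5)
})

test_that("collinearity screen flags strictly above |r| = 0.7", {
  x <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4) * 2, c = c(4, 1, 3, 2))
  scr <- collinearity_screen(x)
  expect_false(scr$pass)
  expect_equal(scr$max_abs_r, 1)
  flagged <- scr$pairs[scr$pairs$flagged, ]
  expect_equal(nrow(flagged), 1L)
  expect_setequal(c(flagged$var_a, flagged$var_b), c("a", "b"))

  # exactly |r| = 0.7 is not flagged (strictly greater triggers)
  set.seed(3)
  u <- rnorm(200)
  v <- rnorm(200)
  u <- (u - mean(u)) / sd(u)
  v <- residuals(lm(v ~ u))
  v <- v / sd(v)
  w <- 0.7 * u + sqrt(1 - 0.49) * v      # correlation exactly 0.7
  scr2 <- collinearity_screen(cbind(p = u, q = w))
  expect_equal(scr2$max_abs_r, 0.7, tolerance = 1e-10)
  expect_true(scr2$pass)

  # zero-variance covariate is reported degenerate and excluded
  scr3 <- collinearity_screen(cbind(a = c(1, 2, 3), b = c(5, 5, 5),
                                    c = c(2, 1, 3)))
  expect_equal(scr3$degenerate, "b")
  expect_false(any(grepl("b", c(scr3$pairs$var_a, scr3$pairs$var_b))))
})

test_that("rank-test battery compares orphans with non-orphans tidily", {
  tr <- synthetic_truth(n_core_groups = 4, focals_per_group = 4,
                        orphan_fraction = 0.5, seed = 21)
  sim <- simulate_study(tr)
  kw <- kw_partner_tests(sim$follows, sim$interactions, sim$registry,
                         tr$window, sim$status)
  expect_true(all(c("partners_per_time", "age_difference") %in% kw$test))
  expect_true(all(kw$statistic >= 0))
  expect_true(all(kw$p_value > 0 & kw$p_value <= 1))
  expect_true(all(kw$n_orphan > 0) && all(kw$n_non_orphan > 0))
})
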