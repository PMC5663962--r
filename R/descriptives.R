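#' Median interaction rates by partner category
#'
#' The per-dyad interaction rate is the number of affiliative interactions
#' divided by the focal-follow minutes during which both partners were
#' observed in the same aggregation (`y / gamma_minutes`). A dyad contributes
#' to every category whose flag is true (categories are not exclusive).
#' Empty cells yield no row rather than a zero.
#'
#' @param dyads A dyad tibble from [build_dyad_table()], or several row-bound
#'   together (the `activity`/`stratum` columns keep them apart).
#' @return A tibble with `activity`, `stratum`, `category`, `n_dyads`,
#'   `rate_median`, `rate_q1`, `rate_q3`.
#' @export
interaction_rates <- function(dyads) {
  cats <- c("age_mate", "aunt", "bull", "calf", "matriarch", "mother", "sister")
  dyads$rate <- dyads$y / dyads$gamma_minutes
  long <- tidyr::pivot_longer(
    dyads[, c("activity", "stratum", "rate", cats)],
    cols = dplyr::all_of(cats), names_to = "category", values_to = "flag"
  )
  long |>
    dplyr::filter(.data$flag) |>
    dplyr::group_by(.data$activity, .data$stratum, .data$category) |>
    dplyr::summarise(
      n_dyads = dplyr::n(),
      rate_median = median(.data$rate),
      rate_q1 = quantile(.data$rate, 0.25, names = FALSE),
      rate_q3 = quantile(.data$rate, 0.75, names = FALSE),
      .groups = "drop"
    )
}

#' Affiliative partners per minute followed
#'
#' For each focal with follow time in the activity: the number of distinct
#' partners with at least one affiliative interaction, divided by the focal's
#' total follow minutes in that activity. Focals with zero minutes in the
#' activity are excluded.
#'
#' @param follows,interactions Validated tables.
#' @param activity `"feeding"` or `"resting"`.
#' @return A tibble with `focal_id`, `n_partners`, `minutes`,
#'   `partners_per_minute`.
#' @export
partners_per_time <- function(follows, interactions, activity) {
  activity <- match.arg(activity, ACTIVITIES)
  fl <- follows[follows$activity == activity, ]
  if (nrow(fl) == 0L) {
    return(tibble::tibble(focal_id = character(0), n_partners = integer(0),
                          minutes = numeric(0),
                          partners_per_minute = numeric(0)))
  }
  ev <- interactions[interactions$follow_id %in% fl$follow_id &
                       interactions$itype %in% AFFILIATIVE_TYPES, ]
  ev$focal_id <- fl$focal_id[match(ev$follow_id, fl$follow_id)]
  minutes <- tapply(fl$duration_minutes, fl$focal_id, sum)
  n_partners <- vapply(names(minutes), function(f) {
    length(unique(ev$partner_id[ev$focal_id == f]))
  }, integer(1))
  tibble::tibble(
    focal_id = names(minutes),
    n_partners = as.integer(n_partners),
    minutes = as.numeric(minutes),
    partners_per_minute = n_partners / as.numeric(minutes)
  )
}

#' Mean age difference between focals and their affiliative partners
#'
#' Per affiliative partner the difference is partner age minus focal age;
#' the per-focal statistic is the mean over retained (unique) partners, so
#' focals are the independent replicates in downstream rank tests. The
#' restricted filter keeps only female partners strictly older than the
#' focal (excluding bulls by construction); focals with no retained partner
#' are excluded.
#'
#' @param follows,interactions Validated tables.
#' @param registry A validated registry.
#' @param activity `"feeding"` or `"resting"`.
#' @param window A [study_window()]; partner ages are taken at its midpoint.
#' @param status [orphan_status()] table supplying each focal's mean age.
#' @param partner_filter `"all_partners"` or `"older_females"`.
#' @return A tibble with `focal_id`, `n_partners`, `mean_age_diff`.
#' @export
age_differences <- function(follows, interactions, registry, activity, window,
                            status,
                            partner_filter = c("all_partners", "older_females")) {
  activity <- match.arg(activity, ACTIVITIES)
  partner_filter <- match.arg(partner_filter)
  fl <- follows[follows$activity == activity, ]
  ev <- interactions[interactions$follow_id %in% fl$follow_id &
                       interactions$itype %in% AFFILIATIVE_TYPES, ]
  ev$focal_id <- fl$focal_id[match(ev$follow_id, fl$follow_id)]
  pairs <- unique(ev[, c("focal_id", "partner_id")])
  if (nrow(pairs) == 0L) {
    return(tibble::tibble(focal_id = character(0), n_partners = integer(0),
                          mean_age_diff = numeric(0)))
  }
  pairs$focal_age <- status$mean_age[match(pairs$focal_id, status$focal_id)]
  pi <- match(pairs$partner_id, registry$id)
  pairs$partner_age <- window$mid - registry$birth_year[pi]
  pairs$partner_sex <- registry$sex[pi]
  pairs$diff <- pairs$partner_age - pairs$focal_age
  if (partner_filter == "older_females") {
    pairs <- pairs[pairs$partner_sex == "F" & pairs$diff > 0, ]
  }
  pairs |>
    dplyr::group_by(.data$focal_id) |>
    dplyr::summarise(n_partners = dplyr::n(),
                     mean_age_diff = mean(.data$diff), .groups = "drop")
}

#' Kruskal-Wallis rank sum test with tie correction
#'
#' Computes the rank-sum statistic
#' \eqn{H = \frac{12}{N(N+1)} \sum_k R_k^2 / n_k - 3(N+1)} using mid-ranks
#' for ties, divides by the tie-correction factor
#' \eqn{1 - \sum_t (t^3 - t)/(N^3 - N)}, and refers the corrected statistic
#' to a chi-square distribution with (groups - 1) degrees of freedom. When
#' every pooled value is identical the statistic is defined as 0. A small-
#' sample exact permutation p-value (full enumeration, two groups only) is
#' available as an alternative to the chi-square approximation.
#'
#' @param group_a,group_b Numeric vectors of observations, both non-empty.
#' @param method `"chisq"` (default) or `"permutation"`.
#' @return A tibble with `statistic` (tie-corrected H), `df`, `p_value`, `n`.
#' @examples
#' kruskal_wallis(c(1, 2, 3), c(4, 5, 6))
#' @export
kruskal_wallis <- function(group_a, group_b, method = c("chisq", "permutation")) {
  method <- match.arg(method)
  if (length(group_a) == 0L || length(group_b) == 0L) {
    abort("both groups must be non-empty")
  }
  x <- c(group_a, group_b)
  g <- rep(1:2, c(length(group_a), length(group_b)))
  h <- kw_statistic(x, g)
  p <- if (method == "chisq") {
    if (h == 0) 1 else pchisq(h, df = 1, lower.tail = FALSE)
  } else {
    kw_permutation_p(x, length(group_a))
  }
  tibble::tibble(statistic = h, df = 1L, p_value = p, n = length(x))
}

# Tie-corrected H for arbitrary group labels.
kw_statistic <- function(x, g) {
  n <- length(x)
  r <- rank(x)  # mid-ranks for ties
  rk <- tapply(r, g, sum)
  nk <- tapply(r, g, length)
  h <- 12 / (n * (n + 1)) * sum(rk^2 / nk) - 3 * (n + 1)
  ties <- table(x)
  denom <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (denom <= 0) return(0)  # all pooled values identical
  h / denom
}

# Exact permutation p-value for the two-group case: enumerate every
# assignment of n_a of the pooled values to group A.
kw_permutation_p <- function(x, n_a) {
  n <- length(x)
  obs <- kw_statistic(x, rep(1:2, c(n_a, n - n_a)))
  picks <- utils::combn(n, n_a)
  stats <- apply(picks, 2, function(idx) {
    g <- rep(2L, n)
    g[idx] <- 1L
    kw_statistic(x, g)
  })
  mean(stats >= obs - 1e-12)
}

#' Orphan vs non-orphan rank-test battery
#'
#' Runs the Kruskal-Wallis comparisons between orphan and non-orphan focals:
#' affiliative partners per minute followed (per activity), and per-focal
#' mean age difference to affiliative partners (per activity, for all
#' partners and for older female partners only).
#'
#' @inheritParams age_differences
#' @return A tidy tibble with `test`, `activity`, `partner_filter`,
#'   `statistic`, `df`, `p_value`, `n_orphan`, `n_non_orphan`.
#' @export
kw_partner_tests <- function(follows, interactions, registry, window, status) {
  orphans <- status$focal_id[status$is_orphan]
  res <- list()
  for (act in ACTIVITIES) {
    ppt <- partners_per_time(follows, interactions, act)
    a <- ppt$partners_per_minute[ppt$focal_id %in% orphans]
    b <- ppt$partners_per_minute[!ppt$focal_id %in% orphans]
    if (length(a) > 0 && length(b) > 0) {
      kw <- kruskal_wallis(a, b)
      res[[length(res) + 1]] <- tibble::tibble(
        test = "partners_per_time", activity = act, partner_filter = "all_partners",
        statistic = kw$statistic, df = kw$df, p_value = kw$p_value,
        n_orphan = length(a), n_non_orphan = length(b)
      )
    }
    for (filt in c("all_partners", "older_females")) {
      ad <- age_differences(follows, interactions, registry, act, window,
                            status, partner_filter = filt)
      a <- ad$mean_age_diff[ad$focal_id %in% orphans]
      b <- ad$mean_age_diff[!ad$focal_id %in% orphans]
      if (length(a) > 0 && length(b) > 0) {
        kw <- kruskal_wallis(a, b)
        res[[length(res) + 1]] <- tibble::tibble(
          test = "age_difference", activity = act, partner_filter = filt,
          statistic = kw$statistic, df = kw$df, p_value = kw$p_value,
          n_orphan = length(a), n_non_orphan = length(b)
        )
      }
    }
  }
  dplyr::bind_rows(res)
}

#' Pairwise collinearity screen for model covariates
#'
#' All pairwise Pearson correlations between covariate columns; a pair is
#' flagged when |r| strictly exceeds the threshold (0.7 by default, the
#' conventional bound below which covariates may share a model).
#' Zero-variance columns are reported as degenerate and excluded from the
#' correlation computation.
#'
#' @param x A numeric matrix or data frame of covariate columns (at least 2).
#' @param threshold Flagging bound on |r|.
#' @return A list with `pairs` (tibble `var_a`, `var_b`, `r`, `flagged`),
#'   `max_abs_r`, `degenerate` (column names), and `pass`.
#' @export
collinearity_screen <- function(x, threshold = 0.7) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (ncol(x) < 2) abort("need at least 2 covariates to screen")
  v <- apply(x, 2, stats::var)
  degenerate <- colnames(x)[v == 0 | is.na(v)]
  keep <- setdiff(colnames(x), degenerate)
  if (length(keep) < 2) {
    return(list(pairs = tibble::tibble(var_a = character(0), var_b = character(0),
                                       r = numeric(0), flagged = logical(0)),
                max_abs_r = NA_real_, degenerate = degenerate, pass = TRUE))
  }
  cm <- cor(x[, keep, drop = FALSE])
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  pairs <- tibble::tibble(
    var_a = rownames(cm)[idx[, 1]],
    var_b = colnames(cm)[idx[, 2]],
    r = cm[idx]
  )
  pairs$flagged <- abs(pairs$r) > threshold
  list(pairs = pairs, max_abs_r = max(abs(pairs$r)),
       degenerate = degenerate, pass = !any(pairs$flagged))
}
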