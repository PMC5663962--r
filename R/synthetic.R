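#' Ground truth for the synthetic study generator
#'
#' Bundles every parameter of the generative model: population layout (core
#' groups, focals per group, orphan fraction), the true regression
#' coefficients per stratum/activity model, the random-intercept
#' distribution (`mu_alpha`, precision `tau_alpha`), the NB dispersion `r`,
#' the sampling design (follows per focal per activity, follow duration
#' range), fission-fusion presence probabilities, and the seed. Defaults
#' emulate the field study's scale: ~48 focal-aged females across 8 core
#' groups with 60% orphans, roughly 15 feeding and 3 resting follows per
#' focal of 10-30 minutes, coefficient magnitudes below 1.3, a baseline
#' affiliation rate of about exp(-4.5) interactions per co-present minute,
#' and moderate overdispersion.
#'
#' @param n_core_groups Number of multi-generation core groups.
#' @param focals_per_group Focal-aged (6-17 y) females per group.
#' @param orphan_fraction Fraction of focals whose mothers die before the
#'   study ends (between 0 and 1).
#' @param true_beta Named list `orphan_feeding`, `non_orphan_feeding`,
#'   `orphan_resting`, `non_orphan_resting`; each a named vector over that
#'   stratum's [covariate_names()].
#' @param mu_alpha,tau_alpha Mean and precision of the per-focal intercepts.
#' @param r NB dispersion (must lie in the prior support (0, 100)).
#' @param follows_per_focal Named vector `c(feeding = , resting = )`.
#' @param follow_minutes Length-2 vector: duration range in minutes (max 30).
#' @param presence_probability Named vector: `same_group` (per-member
#'   presence when a group is in the aggregation), `other_group` (chance a
#'   non-natal core group joins a follow's aggregation), `bull` (independent
#'   per-bull presence).
#' @param bulls_per_group Dispersed adult males per natal group.
#' @param sister_pairs_per_group Focal pairs per group sharing a mother
#'   (maternal sisters); must be below `focals_per_group`.
#' @param window A [study_window()].
#' @param seed RNG seed recorded in the truth (mandatory for reproducibility).
#' @return A list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(
    n_core_groups = 8,
    focals_per_group = 6,
    orphan_fraction = 0.6,
    true_beta = default_true_beta(),
    mu_alpha = -4.5,
    tau_alpha = 4,
    r = 1.5,
    follows_per_focal = c(feeding = 15, resting = 3),
    follow_minutes = c(10, 30),
    presence_probability = c(same_group = 0.85, other_group = 0.12, bull = 0.25),
    bulls_per_group = 2,
    sister_pairs_per_group = 1,
    window = study_window(2012.33, 2015.33),
    seed = 1) {
  if (orphan_fraction < 0 || orphan_fraction > 1) {
    abort("orphan_fraction must lie in [0, 1]")
  }
  if (tau_alpha <= TAU_SUPPORT[1] || tau_alpha >= TAU_SUPPORT[2] ||
      r <= R_SUPPORT[1] || r >= R_SUPPORT[2]) {
    abort("tau_alpha and r must lie inside their prior supports")
  }
  if (any(presence_probability < 0) || any(presence_probability > 1)) {
    abort("presence probabilities must lie in [0, 1]")
  }
  if (follow_minutes[2] > 30 || follow_minutes[1] <= 0) {
    abort("follow durations must lie in (0, 30] minutes")
  }
  if (sister_pairs_per_group >= focals_per_group) {
    abort("sister_pairs_per_group must be smaller than focals_per_group")
  }
  for (m in names(true_beta)) {
    stratum <- if (startsWith(m, "non_orphan")) "non_orphan" else "orphan"
    want <- covariate_names(stratum)
    if (!identical(sort(names(true_beta[[m]])), sort(want))) {
      abort(paste0("true_beta$", m, " must be named over: ",
                   paste(want, collapse = ", ")))
    }
    true_beta[[m]] <- true_beta[[m]][want]
  }
  structure(
    list(n_core_groups = n_core_groups, focals_per_group = focals_per_group,
         orphan_fraction = orphan_fraction, true_beta = true_beta,
         mu_alpha = mu_alpha, tau_alpha = tau_alpha, r = r,
         follows_per_focal = follows_per_focal,
         follow_minutes = follow_minutes,
         presence_probability = presence_probability,
         bulls_per_group = bulls_per_group,
         sister_pairs_per_group = sister_pairs_per_group,
         window = window, seed = seed),
    class = "synthetic_truth"
  )
}

#' Default true coefficients for the four synthetic models
#'
#' Magnitudes chosen to stress realistic signal sizes (|beta| <= 1.3), with
#' strong positive calf/bull effects while feeding, a strong sister effect
#' for resting orphans, and mild age effects.
#'
#' @return Named list of named coefficient vectors.
#' @export
default_true_beta <- function() {
  list(
    orphan_feeding = c(age = -0.45, age_orphaned = 0.15, age_mate = 0.4,
                       aunt = -0.5, bull = 0.7, calf = 0.9,
                       matriarch = -0.45, sister = -0.4),
    non_orphan_feeding = c(age = 0.07, age_mate = 0.75, aunt = -0.7,
                           bull = 0.95, calf = 1.3, matriarch = 0,
                           mother = 0.6, sister = 0.35),
    orphan_resting = c(age = -0.05, age_orphaned = -0.25, age_mate = 0.5,
                       aunt = 0, bull = 1.2, calf = 0.1,
                       matriarch = -0.3, sister = 1.0),
    non_orphan_resting = c(age = 0.03, age_mate = 0.4, aunt = 0.9,
                           bull = 0.35, calf = 0.3, matriarch = 0.25,
                           mother = 0.5, sister = -0.4)
  )
}

#' Generate a multi-generation registry from ground truth
#'
#' Each core group holds a (dead) grandmother anchoring the maternal
#' pedigree; her adult daughters — the mothers of the focal-aged females
#' (hence mutual aunts) plus two without focal offspring (aunts of every
#' focal in the group); a matriarch whose ancestry predates the records;
#' the focal-aged females themselves (6-17 y, with the configured number of
#' maternal sister pairs, plus earlier-born adult sisters for most
#' mothers); calves born during the study; dispersed bulls; and one
#' non-dispersed young male. The requested fraction of focals is orphaned
#' by assigning their mothers a death year drawn over the daughters'
#' early-to-mid childhood. Consumes RNG state; call under a seed (see
#' [simulate_study()]).
#'
#' @param truth A [synthetic_truth()].
#' @return A validated registry tibble.
#' @export
generate_registry <- function(truth) {
  w <- truth$window
  rows <- list()
  add <- function(id, sex, birth, mother = NA_character_, group,
                  death = NA_real_, dispersed = FALSE) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      id = id, sex = sex, birth_year = birth, mother_id = mother,
      core_group_id = group, death_year = death,
      dispersed_from_natal = dispersed
    )
  }
  focal_mothers <- character(0)   # mother id per focal, for orphaning
  focal_ids <- character(0)

  for (g in seq_len(truth$n_core_groups)) {
    gid <- sprintf("G%02d", g)
    gm <- paste0(gid, "_GM")
    add(gm, "F", w$mid - 58, group = gid, death = w$start - 1)
    # the matriarch predates the long-term records: her ancestry is unknown,
    # so she is nobody's registered maternal aunt
    mat <- paste0(gid, "_MAT")
    add(mat, "F", w$mid - 45, group = gid)
    n_focals <- truth$focals_per_group
    sp <- truth$sister_pairs_per_group
    # each sister pair shares a mother, so pairs reduce the mother count
    n_mothers <- n_focals - sp
    mother_ids <- sprintf("%s_M%02d", gid, seq_len(n_mothers))
    for (k in seq_len(n_mothers)) {
      add(mother_ids[k], "F", w$mid - runif(1, 26, 38), mother = gm, group = gid)
    }
    assigned <- c(rep(mother_ids[seq_len(sp)], each = 2),
                  mother_ids[setdiff(seq_len(n_mothers), seq_len(sp))])
    for (k in seq_len(n_focals)) {
      fid <- sprintf("%s_F%02d", gid, k)
      add(fid, "F", w$mid - runif(1, 7, 16), mother = assigned[k], group = gid)
      focal_ids <- c(focal_ids, fid)
      focal_mothers <- c(focal_mothers, assigned[k])
    }
    # most mothers also have an earlier-born (adult) daughter: a maternal
    # sister of the focal class, old enough never to be a focal herself
    for (k in seq_len(n_mothers)) {
      if (runif(1) < 0.7) {
        add(sprintf("%s_S%02d", gid, k), "F", w$mid - runif(1, 18, 22),
            mother = mother_ids[k], group = gid)
      }
    }
    # two grandmother-line adult daughters without focal offspring: adult
    # maternal aunts of every focal in the group (and alive regardless of
    # how many focal mothers the orphaning step removes)
    for (k in 1:2) {
      add(sprintf("%s_A%02d", gid, k), "F", w$mid - runif(1, 20, 32),
          mother = gm, group = gid)
    }
    for (b in seq_len(truth$bulls_per_group)) {
      add(sprintf("%s_B%02d", gid, b), "M", w$mid - runif(1, 18, 35),
          group = gid, dispersed = TRUE)
    }
    add(paste0(gid, "_YM"), "M", w$mid - runif(1, 7, 12), group = gid)
  }
  reg <- dplyr::bind_rows(rows)

  # orphan the requested fraction of focals by killing their mothers during
  # the study (mothers are shared within sister pairs, so greedily accumulate)
  n_target <- round(truth$orphan_fraction * length(focal_ids))
  dead_mothers <- character(0)
  n_orphaned <- 0
  for (m in unique(focal_mothers)) {
    if (n_orphaned >= n_target) break
    dead_mothers <- c(dead_mothers, m)
    n_orphaned <- n_orphaned + sum(focal_mothers == m)
  }
  # heightened adult mortality precedes the study, so a mother may die at
  # any point of her daughters' lives: draw the daughter's age at orphaning
  # uniformly over most of her lifespan (anchored on the youngest daughter),
  # which keeps age-orphaned only mildly correlated with age itself
  for (m in dead_mothers) {
    daughters <- reg$birth_year[!is.na(reg$mother_id) & reg$mother_id == m]
    # anchor on the focal-class daughters; adult daughters are born well
    # before any admissible death year
    daughters <- daughters[daughters >= w$mid - 17]
    base <- mean(daughters)
    hi <- min(9, w$end - 1 - base)   # orphaned during early-to-mid childhood
    reg$death_year[reg$id == m] <-
      max(base + runif(1, 0.3, hi), max(daughters) + 0.3)
  }

  # calves born during the study (to mothers and matriarchs, 70% each; a
  # mother that dies during the study can only have a calf born before her
  # death, so calves exist even when every focal is orphaned)
  adult_females <- c(unique(focal_mothers),
                     reg$id[grepl("_MAT$", reg$id)])
  calves <- list()
  for (m in adult_females) {
    if (runif(1) >= 0.7) next
    mrow <- reg[reg$id == m, ]
    hi <- if (is.na(mrow$death_year)) w$end - 0.3 else mrow$death_year - 0.3
    lo <- w$start + 0.1
    if (hi <= lo) next
    calves[[length(calves) + 1]] <- tibble::tibble(
      id = paste0(m, "_C"), sex = sample(c("F", "M"), 1),
      birth_year = runif(1, lo, hi),
      mother_id = m, core_group_id = mrow$core_group_id,
      death_year = NA_real_, dispersed_from_natal = FALSE
    )
  }
  validate_registry(dplyr::bind_rows(reg, calves))
}

empty_interactions <- function() {
  tibble::tibble(follow_id = character(0), partner_id = character(0),
                 itype = character(0))
}

#' Generate follows and interaction events from a registry and ground truth
#'
#' Per focal and activity, draws follow dates (at most one per day),
#' durations, and aggregation membership under a fission-fusion scheme: the
#' focal's own core group is in the aggregation (each member present with
#' probability `same_group`), every other core group joins with probability
#' `other_group` (members then present with probability `same_group`), and
#' each dispersed bull is independently present with probability `bull`.
#' Dyad interaction totals are then drawn from the NB model — mean
#' `gamma_ij * exp(alpha_j + x'beta)` with `alpha_j ~ N(mu_alpha,
#' 1/tau_alpha)` — and scattered multinomially across the focal's follows in
#' which the partner was present (weights proportional to duration), with
#' affiliative types assigned uniformly. Consumes RNG state; call under a
#' seed (see [simulate_study()]).
#'
#' @param registry A registry from [generate_registry()].
#' @param truth The [synthetic_truth()] used to build it.
#' @return A list: `follows`, `interactions`, `status`, and `effects` (the
#'   realized `alpha_j` per model, for recovery checks).
#' @export
generate_observations <- function(registry, truth) {
  w <- truth$window
  focals <- eligible_focals(registry, w)
  groups <- split(registry$id, registry$core_group_id)
  bulls <- registry$id[registry$sex == "M" & registry$dispersed_from_natal]
  pp <- truth$presence_probability
  all_days <- seq(as.Date("2012-05-01"), as.Date("2015-04-30"), by = "day")

  follows <- list()
  fid <- 0
  for (f in focals) {
    f_group <- registry$core_group_id[match(f, registry$id)]
    for (act in ACTIVITIES) {
      n_follow <- truth$follows_per_focal[[act]]
      days <- sort(sample(all_days, n_follow))
      for (d in seq_len(n_follow)) {
        fid <- fid + 1
        yr <- date_to_year(days[d])
        own <- setdiff(groups[[f_group]], c(f, bulls))
        own <- own[alive_at(registry, own, yr)]
        present <- own[runif(length(own)) < pp[["same_group"]]]
        for (og in setdiff(names(groups), f_group)) {
          if (runif(1) < pp[["other_group"]]) {
            mem <- setdiff(groups[[og]], bulls)
            mem <- mem[alive_at(registry, mem, yr)]
            present <- c(present, mem[runif(length(mem)) < pp[["same_group"]]])
          }
        }
        b_here <- bulls[alive_at(registry, bulls, yr) & runif(length(bulls)) < pp[["bull"]]]
        present <- unique(c(present, b_here))
        follows[[fid]] <- tibble::tibble(
          follow_id = sprintf("FL%05d", fid), focal_id = f, date = days[d],
          activity = act,
          duration_minutes = round(runif(1, truth$follow_minutes[1],
                                         truth$follow_minutes[2]), 2),
          present_ids = list(present)
        )
      }
    }
  }
  follows <- validate_follows(dplyr::bind_rows(follows))
  status <- orphan_status(registry, focals, w$end, follows = follows)

  events <- list()
  effects <- list()
  for (stratum in STRATA) {
    for (act in ACTIVITIES) {
      dy <- build_dyad_table(follows, empty_interactions(), registry, act,
                             stratum, w, status = status)
      if (nrow(dy) == 0L) next
      x <- dyad_model_matrix(dy)
      model <- paste(stratum, act, sep = "_")
      beta <- truth$true_beta[[model]]
      fl <- unique(dy$focal_id)
      alpha <- rnorm(length(fl), truth$mu_alpha, 1 / sqrt(truth$tau_alpha))
      names(alpha) <- fl
      lam <- linear_predictor(alpha[dy$focal_id], beta, x, dy$gamma_minutes)
      yv <- rnbinom(length(lam), size = truth$r, mu = lam)
      effects[[model]] <- tibble::tibble(model = model, focal_id = fl,
                                         alpha = unname(alpha))
      # scatter dyad totals across the follows where the partner was present
      fsub <- follows[follows$activity == act, ]
      co_rows <- split(
        rep(seq_len(nrow(fsub)), lengths(fsub$present_ids)),
        paste(rep(fsub$focal_id, lengths(fsub$present_ids)),
              unlist(fsub$present_ids))
      )
      for (i in which(yv > 0)) {
        rows <- co_rows[[paste(dy$focal_id[i], dy$partner_id[i])]]
        counts <- as.vector(rmultinom(1, yv[i], fsub$duration_minutes[rows]))
        for (q in which(counts > 0)) {
          events[[length(events) + 1]] <- tibble::tibble(
            follow_id = fsub$follow_id[rows[q]],
            partner_id = dy$partner_id[i],
            itype = sample(AFFILIATIVE_TYPES, counts[q], replace = TRUE)
          )
        }
      }
    }
  }
  interactions <- if (length(events) > 0) {
    dplyr::bind_rows(events)
  } else {
    empty_interactions()
  }
  list(follows = follows,
       interactions = validate_interactions(interactions, follows),
       status = status,
       effects = dplyr::bind_rows(effects))
}

#' Simulate a complete synthetic study
#'
#' Seeds the RNG from the truth's `seed`, generates the registry and the
#' observation tables, and returns everything needed to run the full
#' pipeline plus the ground truth for verification. Deterministic given the
#' seed.
#'
#' @param truth A [synthetic_truth()].
#' @return A list: `registry`, `follows`, `interactions`, `status`,
#'   `effects`, `truth`.
#' @export
simulate_study <- function(truth = synthetic_truth()) {
  set.seed(truth$seed)
  registry <- generate_registry(truth)
  obs <- generate_observations(registry, truth)
  c(list(registry = registry), obs, list(truth = truth))
}

#' Write a simulated study to CSV files
#'
#' Emits `registry.csv`, `follows.csv`, `interactions.csv` and a plain-text
#' truth manifest (including the seed) into a directory.
#'
#' @param sim Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reg <- sim$registry
  reg$dispersed_from_natal <- ifelse(reg$dispersed_from_natal, "true", "false")
  utils::write.csv(reg, file.path(dir, "registry.csv"), row.names = FALSE,
                   na = "")
  fl <- sim$follows
  fl$present_ids <- vapply(fl$present_ids, paste, character(1), collapse = ";")
  utils::write.csv(fl, file.path(dir, "follows.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(sim$interactions, file.path(dir, "interactions.csv"),
                   row.names = FALSE, na = "")
  manifest <- c(
    paste0("seed: ", sim$truth$seed),
    paste0("mu_alpha: ", sim$truth$mu_alpha),
    paste0("tau_alpha: ", sim$truth$tau_alpha),
    paste0("r: ", sim$truth$r),
    vapply(names(sim$truth$true_beta), function(m) {
      paste0("beta_", m, ": ",
             paste(sprintf("%s=%g", names(sim$truth$true_beta[[m]]),
                           sim$truth$true_beta[[m]]), collapse = ", "))
    }, character(1))
  )
  writeLines(manifest, file.path(dir, "truth_manifest.txt"))
  invisible(dir)
}
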