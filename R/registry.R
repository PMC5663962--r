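#' Define a study window
#'
#' The study window bounds the field sampling period in (fractional) calendar
#' years. Its midpoint is the reference date at which partner ages, matriarch
#' status and orphan status are evaluated, and the full span is the window
#' used for the calf category (an animal at most six months old at any point
#' during the study).
#'
#' @param start_year,end_year Fractional calendar years, `end_year > start_year`.
#' @return A list with elements `start`, `end`, `mid`.
#' @examples
#' study_window(2012.33, 2015.33)
#' @export
study_window <- function(start_year, end_year) {
  stopifnot(is.numeric(start_year), is.numeric(end_year), end_year > start_year)
  list(start = start_year, end = end_year, mid = (start_year + end_year) / 2)
}

#' Read and validate an individual registry
#'
#' The registry is the long-term record of the population: one row per
#' elephant carrying identity, sex, birth year, maternal link, core social
#' group membership, death year (if dead) and, for males, whether they have
#' dispersed from their natal group. Empty strings are read as missing.
#'
#' @param path Path to a CSV with columns `id`, `sex`, `birth_year`,
#'   `mother_id`, `core_group_id`, `death_year`, `dispersed_from_natal`.
#' @return A validated registry tibble.
#' @seealso [validate_registry()]
#' @export
read_registry <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", na.strings = "")
  need <- c("id", "sex", "birth_year", "mother_id", "core_group_id",
            "death_year", "dispersed_from_natal")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("registry file is missing columns: ", paste(miss, collapse = ", ")))
  }
  reg <- tibble::tibble(
    id = df$id,
    sex = df$sex,
    birth_year = as.numeric(df$birth_year),
    mother_id = df$mother_id,
    core_group_id = df$core_group_id,
    death_year = as.numeric(df$death_year),
    dispersed_from_natal = tolower(df$dispersed_from_natal) %in% c("true", "t", "1", "yes")
  )
  reg$dispersed_from_natal[is.na(df$dispersed_from_natal)] <- FALSE
  validate_registry(reg)
}

#' Validate a registry tibble
#'
#' Checks referential and biological integrity: unique ids, sexes in `F`/`M`,
#' maternal links resolving to female records, and `death_year >= birth_year`.
#'
#' @param registry A registry data frame (see [read_registry()] for columns).
#' @return The registry as a tibble, invisibly unchanged, or an error.
#' @export
validate_registry <- function(registry) {
  registry <- tibble::as_tibble(registry)
  if (anyDuplicated(registry$id)) {
    abort("registry ids must be unique")
  }
  if (!all(registry$sex %in% c("F", "M"))) {
    abort("registry sex must be 'F' or 'M'")
  }
  if (anyNA(registry$birth_year)) {
    abort("registry birth_year must be present for every individual")
  }
  if (anyNA(registry$core_group_id)) {
    abort("every individual must belong to exactly one core group")
  }
  linked <- !is.na(registry$mother_id)
  if (any(linked)) {
    m <- match(registry$mother_id[linked], registry$id)
    if (anyNA(m)) {
      bad <- registry$mother_id[linked][is.na(m)]
      abort(paste0("mother_id refers to absent record(s): ",
                   paste(unique(bad), collapse = ", ")))
    }
    if (any(registry$sex[m] != "F")) {
      abort("mother_id must refer to a female record")
    }
  }
  both <- !is.na(registry$death_year)
  if (any(registry$death_year[both] < registry$birth_year[both])) {
    abort("death_year must not precede birth_year")
  }
  registry
}

age_at <- function(registry, ids, year) {
  year - registry$birth_year[match(ids, registry$id)]
}

alive_at <- function(registry, ids, year) {
  i <- match(ids, registry$id)
  registry$birth_year[i] <= year &
    (is.na(registry$death_year[i]) | registry$death_year[i] > year)
}

#' Identify eligible focal animals
#'
#' Focal animals are non-parous females aged 6-17 years at the study
#' midpoint. Parity is inferred from the registry: a female with any
#' registered offspring is parous.
#'
#' @param registry A validated registry.
#' @param window A [study_window()].
#' @return Character vector of focal ids.
#' @export
eligible_focals <- function(registry, window) {
  age <- window$mid - registry$birth_year
  parous <- registry$id %in% registry$mother_id[!is.na(registry$mother_id)]
  ok <- registry$sex == "F" & age >= 6 & age <= 17 & !parous &
    alive_at(registry, registry$id, window$mid)
  registry$id[ok]
}

#' Determine orphan status of focal animals
#'
#' A focal is an orphan if her mother died on or before the reference date;
#' the age orphaned is the focal's age (in years) at the mother's death.
#' Mean focal age is the average age across that focal's follows when follows
#' are supplied, otherwise the age at the reference date.
#'
#' @param registry A validated registry.
#' @param focal_ids Character vector of focal ids (females).
#' @param reference_year Fractional calendar year at which status is assessed.
#' @param follows Optional validated follow table used to compute the mean
#'   age across follows.
#' @return A tibble with columns `focal_id`, `is_orphan`, `age_orphaned`
#'   (NA for non-orphans), `mean_age`.
#' @export
orphan_status <- function(registry, focal_ids, reference_year, follows = NULL) {
  i <- match(focal_ids, registry$id)
  if (anyNA(i)) {
    abort(paste0("focal id(s) absent from registry: ",
                 paste(focal_ids[is.na(i)], collapse = ", ")))
  }
  if (any(registry$sex[i] != "F")) {
    abort("focal animals must be female")
  }
  mid <- registry$mother_id[i]
  mi <- match(mid, registry$id)
  if (any(!is.na(mid) & is.na(mi))) {
    abort("mother_id set but mother record absent: data-integrity error")
  }
  mother_death <- registry$death_year[mi]
  is_orphan <- !is.na(mid) & !is.na(mother_death) & mother_death <= reference_year
  age_orphaned <- ifelse(is_orphan, mother_death - registry$birth_year[i], NA_real_)
  mean_age <- reference_year - registry$birth_year[i]
  if (!is.null(follows)) {
    yr <- date_to_year(follows$date)
    by_focal <- tapply(yr, follows$focal_id, mean)
    got <- focal_ids %in% names(by_focal)
    mean_age[got] <- as.numeric(by_focal[focal_ids[got]]) -
      registry$birth_year[i][got]
  }
  tibble::tibble(
    focal_id = focal_ids,
    is_orphan = is_orphan,
    age_orphaned = age_orphaned,
    mean_age = mean_age
  )
}

#' Categorise the social partners of a focal animal
#'
#' Assigns the (non-exclusive) partner-category flags used as model
#' covariates: age mate (within +/- 2 years of the focal's age), adult
#' maternal aunt, bull (male dispersed from his natal group), calf (at most
#' six months old at some point in the study window), matriarch (oldest
#' living female of the partner's core group at the study midpoint that is
#' not the focal's mother), mother, and maternal sister. Mother and matriarch
#' are mutually exclusive by definition; all other combinations may co-occur.
#' Missing maternal ancestry yields `FALSE` for the kin flags.
#'
#' @param registry A validated registry.
#' @param focal_id A single focal id.
#' @param window A [study_window()]; ages and matriarch status are evaluated
#'   at its midpoint, the calf definition over its full span.
#' @param partner_ids Partners to categorise; defaults to everyone except the
#'   focal.
#' @return A tibble with `partner_id` and logical columns `age_mate`, `aunt`,
#'   `bull`, `calf`, `matriarch`, `mother`, `sister`.
#' @export
categorize_partners <- function(registry, focal_id, window,
                                partner_ids = setdiff(registry$id, focal_id)) {
  if (length(focal_id) != 1L || !focal_id %in% registry$id) {
    abort("focal_id must be a single id present in the registry")
  }
  if (focal_id %in% partner_ids) {
    abort("a focal cannot be its own partner")
  }
  pi <- match(partner_ids, registry$id)
  if (anyNA(pi)) {
    abort("partner id(s) absent from registry")
  }
  fi <- match(focal_id, registry$id)

  f_age <- window$mid - registry$birth_year[fi]
  p_age <- window$mid - registry$birth_year[pi]
  p_sex <- registry$sex[pi]
  f_mother <- registry$mother_id[fi]
  p_mother <- registry$mother_id[pi]

  if (is.na(f_mother) && getOption("orphanbonds.verbose", FALSE)) {
    rlang::inform(paste0("focal ", focal_id,
                         " has no registered mother; kin flags set to FALSE"))
  }

  # grandmother = mother of focal's mother; needed for the aunt flag
  f_grandmother <- if (!is.na(f_mother)) {
    registry$mother_id[match(f_mother, registry$id)]
  } else {
    NA_character_
  }

  age_mate <- abs(p_age - f_age) <= 2
  mother <- !is.na(f_mother) & partner_ids == f_mother
  sister <- p_sex == "F" & !is.na(f_mother) & !is.na(p_mother) &
    p_mother == f_mother
  aunt <- p_sex == "F" & p_age >= 18 & !is.na(f_grandmother) &
    !is.na(p_mother) & p_mother == f_grandmother & !mother
  bull <- p_sex == "M" & registry$dispersed_from_natal[pi]
  calf <- registry$birth_year[pi] + 0.5 >= window$start &
    registry$birth_year[pi] <= window$end

  matriarch_ids <- group_matriarchs(registry, window$mid, exclude = f_mother)
  matriarch <- partner_ids %in% matriarch_ids

  tibble::tibble(
    partner_id = partner_ids,
    age_mate = age_mate, aunt = aunt, bull = bull, calf = calf,
    matriarch = matriarch & !mother, mother = mother, sister = sister
  )
}

# Oldest living female per core group at `year`, optionally excluding one id
# (the focal's mother, per the matriarch definition). Ties broken by id order.
group_matriarchs <- function(registry, year, exclude = NA_character_) {
  cand <- registry$sex == "F" & alive_at(registry, registry$id, year)
  if (!is.na(exclude)) cand <- cand & registry$id != exclude
  sub <- registry[cand, ]
  if (nrow(sub) == 0L) return(character(0))
  sub <- sub[order(sub$core_group_id, sub$birth_year, sub$id), ]
  sub$id[!duplicated(sub$core_group_id)]
}

#' Covariate set for a model stratum
#'
#' The orphan-stratum models include the focal's mean age, her age when
#' orphaned, and every partner-category flag except mother (an orphan's
#' mother is dead); the non-orphan models include mean age, the mother flag,
#' and every category flag except age orphaned. Order is fixed.
#'
#' @param stratum `"orphan"` or `"non_orphan"`.
#' @return Character vector of covariate names in model order.
#' @export
covariate_names <- function(stratum) {
  stratum <- match.arg(stratum, STRATA)
  if (stratum == "orphan") {
    c("age", "age_orphaned", "age_mate", "aunt", "bull", "calf",
      "matriarch", "sister")
  } else {
    c("age", "age_mate", "aunt", "bull", "calf", "matriarch",
      "mother", "sister")
  }
}

#' Assemble the model covariate matrix for one stratum
#'
#' Joins focal-level covariates (mean age, age orphaned) with the partner
#' category flags and returns them in the fixed stratum order. Continuous
#' covariates (age, age orphaned) are z-scored across the rows of the table
#' (within stratum); flags enter as 0/1.
#'
#' @param status Tibble from [orphan_status()] restricted to the stratum's
#'   focals.
#' @param flags Tibble with `focal_id`, `partner_id` and category flag
#'   columns, one row per dyad.
#' @param stratum `"orphan"` or `"non_orphan"`.
#' @return A numeric matrix with one row per row of `flags`, columns in
#'   [covariate_names()] order. Attribute `scaling` records the centre/scale
#'   used for the continuous covariates.
#' @export
covariate_matrix <- function(status, flags, stratum) {
  stratum <- match.arg(stratum, STRATA)
  if (stratum == "orphan" && !all(status$is_orphan)) {
    abort("orphan stratum requested for non-orphan focal(s)")
  }
  if (stratum == "non_orphan" && any(status$is_orphan)) {
    abort("non_orphan stratum requested for orphan focal(s)")
  }
  i <- match(flags$focal_id, status$focal_id)
  if (anyNA(i)) abort("flags contain focals absent from status")
  cols <- covariate_names(stratum)
  raw <- cbind(
    age = status$mean_age[i],
    if (stratum == "orphan") cbind(age_orphaned = status$age_orphaned[i]),
    age_mate = as.numeric(flags$age_mate),
    aunt = as.numeric(flags$aunt),
    bull = as.numeric(flags$bull),
    calf = as.numeric(flags$calf),
    matriarch = as.numeric(flags$matriarch),
    if (stratum == "non_orphan") cbind(mother = as.numeric(flags$mother)),
    sister = as.numeric(flags$sister)
  )
  raw <- raw[, cols, drop = FALSE]
  continuous <- intersect(c("age", "age_orphaned"), cols)
  centre <- setNames(rep(0, length(cols)), cols)
  scale_ <- setNames(rep(1, length(cols)), cols)
  for (cc in continuous) {
    mu <- mean(raw[, cc])
    sdv <- sd(raw[, cc])
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    raw[, cc] <- (raw[, cc] - mu) / sdv
    centre[cc] <- mu
    scale_[cc] <- sdv
  }
  attr(raw, "scaling") <- list(centre = centre, scale = scale_)
  raw
}
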