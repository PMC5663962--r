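# Fractional calendar year of a date (used for ages at follow time).
date_to_year <- function(date) {
  lt <- as.POSIXlt(as.Date(date))
  1900 + lt$year + lt$yday / 365.25
}

#' Read and validate focal-follow records
#'
#' One row per timed focal follow: a continuous observation bout (at most 30
#' minutes) of one focal animal in one activity, recording every conspecific
#' present in the aggregation and therefore available to interact. At most
#' one follow per focal per activity per day is permitted.
#'
#' @param path CSV with columns `follow_id`, `focal_id`, `date` (ISO-8601),
#'   `activity` (`feeding` or `resting`), `duration_minutes`, `present_ids`
#'   (semicolon-separated).
#' @return A validated tibble with `present_ids` as a list-column.
#' @export
read_follows <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", na.strings = "")
  need <- c("follow_id", "focal_id", "date", "activity", "duration_minutes",
            "present_ids")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("follows file is missing columns: ", paste(miss, collapse = ", ")))
  }
  present <- lapply(df$present_ids, function(s) {
    if (is.na(s) || s == "") character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
  })
  fl <- tibble::tibble(
    follow_id = df$follow_id,
    focal_id = df$focal_id,
    date = as.Date(df$date),
    activity = df$activity,
    duration_minutes = as.numeric(df$duration_minutes),
    present_ids = present
  )
  validate_follows(fl)
}

#' Validate a follow table
#'
#' Enforces the sampling-design invariants: activity in `feeding`/`resting`,
#' duration in (0, 30] minutes, no duplicate follow per focal, activity and
#' day (the behavioural-autocorrelation control), and the focal absent from
#' its own aggregation list. Violations are reported with row numbers.
#'
#' @param follows A follow tibble (see [read_follows()]).
#' @return The validated tibble.
#' @export
validate_follows <- function(follows) {
  follows <- tibble::as_tibble(follows)
  problems <- character(0)
  row_msg <- function(rows, what) {
    if (length(rows) > 0) {
      problems <<- c(problems, paste0(what, " (row ",
                                      paste(rows, collapse = ", "), ")"))
    }
  }
  row_msg(which(!follows$activity %in% ACTIVITIES), "unknown activity")
  row_msg(which(is.na(follows$duration_minutes) |
                  follows$duration_minutes <= 0 |
                  follows$duration_minutes > 30),
          "duration_minutes outside (0, 30]")
  row_msg(which(is.na(follows$date)), "unparseable date")
  row_msg(which(anyDuplicated(follows$follow_id) > 0 &
                  duplicated(follows$follow_id)), "duplicate follow_id")
  key <- paste(follows$focal_id, follows$activity, follows$date)
  row_msg(which(duplicated(key)),
          "more than one follow per focal per activity per day")
  self_present <- vapply(seq_len(nrow(follows)), function(i) {
    follows$focal_id[i] %in% follows$present_ids[[i]]
  }, logical(1))
  row_msg(which(self_present), "focal_id listed in its own present_ids")
  if (length(problems) > 0) {
    abort(paste0("invalid follow records:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  follows
}

#' Read and validate interaction events
#'
#' One row per interaction initiated during a focal follow. Only the six
#' affiliative types (bodily contact, trunk touch, greeting, allomothering,
#' play, trunk-to-mouth) count toward the analysis; rows typed `other` are
#' retained but filtered out downstream.
#'
#' @param path CSV with columns `follow_id`, `partner_id`, `itype`.
#' @param follows The validated follow table the events refer to.
#' @return A validated tibble of events.
#' @export
read_interactions <- function(path, follows) {
  df <- utils::read.csv(path, colClasses = "character", na.strings = "")
  need <- c("follow_id", "partner_id", "itype")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    abort(paste0("interactions file is missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  ev <- tibble::as_tibble(df[need])
  validate_interactions(ev, follows)
}

#' Validate an interaction-event table against its follows
#'
#' Checks referential integrity: every event's `follow_id` resolves to a
#' follow, its `partner_id` was present in that follow's aggregation, and its
#' type is recognised.
#'
#' @param interactions Event tibble (`follow_id`, `partner_id`, `itype`).
#' @param follows Validated follow tibble.
#' @return The validated event tibble.
#' @export
validate_interactions <- function(interactions, follows) {
  interactions <- tibble::as_tibble(interactions)
  problems <- character(0)
  known <- c(AFFILIATIVE_TYPES, "other")
  fi <- match(interactions$follow_id, follows$follow_id)
  bad <- which(is.na(fi))
  if (length(bad) > 0) {
    problems <- c(problems, paste0("dangling follow_id (row ",
                                   paste(bad, collapse = ", "), ")"))
  }
  bad <- which(!interactions$itype %in% known)
  if (length(bad) > 0) {
    problems <- c(problems, paste0("unknown interaction type (row ",
                                   paste(bad, collapse = ", "), ")"))
  }
  ok <- !is.na(fi)
  present <- mapply(function(i, p) p %in% follows$present_ids[[i]],
                    fi[ok], interactions$partner_id[ok])
  if (length(present) > 0 && !all(present)) {
    bad <- which(ok)[!present]
    problems <- c(problems,
                  paste0("partner not present in referenced follow (row ",
                         paste(bad, collapse = ", "), ")"))
  }
  if (length(problems) > 0) {
    abort(paste0("invalid interaction records:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  interactions
}

#' Assemble the dyadic observation table
#'
#' The unit of analysis: for each (focal j, partner i) pair within one
#' activity and one stratum, the affiliative interaction count `y` and the
#' exposure `gamma_minutes` — the total focal minutes of j in that activity
#' during which i was observed in the same aggregation and therefore
#' available to interact. Pairs with zero exposure are excluded, not
#' zero-filled. Partners of every age/sex class co-present enter as candidate
#' dyads; partners fitting no category carry all-false flags.
#'
#' @param follows,interactions Validated tables.
#' @param registry A validated registry.
#' @param activity `"feeding"` or `"resting"`.
#' @param stratum `"orphan"` or `"non_orphan"`.
#' @param window A [study_window()].
#' @param status Optional precomputed [orphan_status()] table for the focals
#'   in `follows`; computed from the registry at `window$end` if omitted.
#' @return A tibble with one row per dyad: ids, `activity`, `stratum`, `y`,
#'   `gamma_minutes`, the category flags, and focal covariates `age` and
#'   `age_orphaned` (raw years; scaling happens at fit time).
#' @export
build_dyad_table <- function(follows, interactions, registry, activity,
                             stratum, window, status = NULL) {
  activity <- match.arg(activity, ACTIVITIES)
  stratum <- match.arg(stratum, STRATA)
  if (is.null(status)) {
    status <- orphan_status(registry, unique(follows$focal_id), window$end,
                            follows = follows)
  }
  keep_focals <- status$focal_id[status$is_orphan == (stratum == "orphan")]
  fl <- follows[follows$activity == activity &
                  follows$focal_id %in% keep_focals, ]
  if (nrow(fl) == 0L) {
    return(empty_dyad_table(activity, stratum))
  }
  ev <- interactions[interactions$follow_id %in% fl$follow_id &
                       interactions$itype %in% AFFILIATIVE_TYPES, ]

  per_focal <- lapply(split(seq_len(nrow(fl)), fl$focal_id), function(rows) {
    focal <- fl$focal_id[rows[1]]
    # exposure: each follow contributes its full duration to every partner
    # present at any time during it (membership is per-follow and binary)
    gamma <- tapply(
      rep(fl$duration_minutes[rows], lengths(fl$present_ids[rows])),
      unlist(fl$present_ids[rows]), sum
    )
    partner_ids <- names(gamma)
    evf <- ev[ev$follow_id %in% fl$follow_id[rows], ]
    y <- table(factor(evf$partner_id, levels = partner_ids))
    tibble::tibble(
      focal_id = focal,
      partner_id = partner_ids,
      y = as.integer(y),
      gamma_minutes = as.numeric(gamma)
    )
  })
  dy <- dplyr::bind_rows(per_focal)
  dy <- dy[dy$gamma_minutes > 0, ]

  flags <- purrr::map_dfr(unique(dy$focal_id), function(f) {
    p <- unique(dy$partner_id[dy$focal_id == f])
    cf <- categorize_partners(registry, f, window, partner_ids = p)
    cf$focal_id <- f
    cf
  })
  dy <- dplyr::left_join(dy, flags, by = c("focal_id", "partner_id"))
  si <- match(dy$focal_id, status$focal_id)
  dy$age <- status$mean_age[si]
  dy$age_orphaned <- status$age_orphaned[si]
  dy$activity <- activity
  dy$stratum <- stratum
  dy <- dy[order(dy$focal_id, dy$partner_id), ]
  dplyr::relocate(dy, "focal_id", "partner_id", "activity", "stratum",
                  "y", "gamma_minutes")
}

empty_dyad_table <- function(activity, stratum) {
  tibble::tibble(
    focal_id = character(0), partner_id = character(0),
    activity = character(0), stratum = character(0),
    y = integer(0), gamma_minutes = numeric(0),
    age_mate = logical(0), aunt = logical(0), bull = logical(0),
    calf = logical(0), matriarch = logical(0), mother = logical(0),
    sister = logical(0), age = numeric(0), age_orphaned = numeric(0)
  )
}

#' Write a dyad table to CSV for audit
#'
#' @param dyads A dyad tibble from [build_dyad_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dyad_table <- function(dyads, path) {
  utils::write.csv(dyads, path, row.names = FALSE)
  invisible(path)
}

#' Summarise sampling effort
#'
#' Per activity and stratum: number of focals, total sampling hours, and the
#' median (with interquartile range) of per-focal follow minutes and follow
#' counts — the format in which focal-follow effort is conventionally
#' reported.
#'
#' @param follows Validated follow table.
#' @param status [orphan_status()] table covering the focals in `follows`.
#' @return A tibble with one row per (activity, stratum).
#' @export
sampling_summary <- function(follows, status) {
  if (nrow(follows) == 0L) {
    return(tibble::tibble(
      activity = character(0), stratum = character(0), n_focals = integer(0),
      total_hours = numeric(0), minutes_median = numeric(0),
      minutes_q1 = numeric(0), minutes_q3 = numeric(0),
      follows_median = numeric(0), follows_q1 = numeric(0),
      follows_q3 = numeric(0)
    ))
  }
  si <- match(follows$focal_id, status$focal_id)
  follows$stratum <- ifelse(status$is_orphan[si], "orphan", "non_orphan")
  follows |>
    dplyr::group_by(.data$activity, .data$stratum, .data$focal_id) |>
    dplyr::summarise(
      minutes = sum(.data$duration_minutes),
      n_follows = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::group_by(.data$activity, .data$stratum) |>
    dplyr::summarise(
      n_focals = dplyr::n(),
      total_hours = sum(.data$minutes) / 60,
      minutes_median = median(.data$minutes),
      minutes_q1 = quantile(.data$minutes, 0.25, names = FALSE),
      minutes_q3 = quantile(.data$minutes, 0.75, names = FALSE),
      follows_median = median(.data$n_follows),
      follows_q1 = quantile(.data$n_follows, 0.25, names = FALSE),
      follows_q3 = quantile(.data$n_follows, 0.75, names = FALSE),
      .groups = "drop"
    )
}
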