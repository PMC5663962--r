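test_that("follow and interaction files round-trip through validation", {
  dir <- withr::local_tempdir()
  fl <- tiny_follows()
  out <- fl
  out$present_ids <- vapply(out$present_ids, paste, character(1),
                            collapse = ";")
  write.csv(out, file.path(dir, "follows.csv"), row.names = FALSE)
  write.csv(tiny_interactions(), file.path(dir, "interactions.csv"),
            row.names = FALSE)

  got <- read_follows(file.path(dir, "follows.csv"))
  expect_equal(got$follow_id, fl$follow_id)
  expect_equal(got$present_ids, fl$present_ids)
  ev <- read_interactions(file.path(dir, "interactions.csv"), got)
  expect_equal(nrow(ev), nrow(tiny_interactions()))

  # empty file with header -> empty table
  write.csv(out[0, ], file.path(dir, "empty.csv"), row.names = FALSE)
  expect_equal(nrow(read_follows(file.path(dir, "empty.csv"))), 0L)
})

test_that("follow validation rejects malformed records with row numbers", {
  fl <- tiny_follows()

  bad <- fl
  bad$duration_minutes[2] <- 31    # follows are at most 30 minutes
  expect_error(validate_follows(bad), "\\(0, 30\\].*row 2")

  bad <- fl
  bad$duration_minutes[1] <- 0
  expect_error(validate_follows(bad), "row 1")

  bad <- fl
  bad$activity[3] <- "sleeping"
  expect_error(validate_follows(bad), "unknown activity")

  # one follow per focal per activity per day
  bad <- fl
  bad$date[2] <- bad$date[1]
  expect_error(validate_follows(bad), "per focal per activity per day")

  bad <- fl
  bad$present_ids[[1]] <- c("F2", "F1")
  expect_error(validate_follows(bad), "own present_ids")
})

test_that("interaction validation enforces referential integrity", {
  fl <- tiny_follows()
  ev <- tibble::tibble(follow_id = "FL9", partner_id = "F2",
                       itype = "greeting")
  expect_error(validate_interactions(ev, fl), "dangling follow_id")

  ev <- tibble::tibble(follow_id = "FL1", partner_id = "MAT2",
                       itype = "greeting")
  expect_error(validate_interactions(ev, fl), "not present")

  ev <- tibble::tibble(follow_id = "FL1", partner_id = "F2",
                       itype = "headbutt")
  expect_error(validate_interactions(ev, fl), "unknown interaction type")
})

test_that("dyad table sums exposure and counts only affiliative events", {
  reg <- tiny_registry()
  dy <- build_dyad_table(tiny_follows(), tiny_interactions(), reg,
                         "feeding", "non_orphan", tiny_window())
  row <- function(p) dy[dy$partner_id == p & dy$focal_id == "F1", ]

  # partner present in two 30-min follows, one greeting -> y = 1, gamma = 60
  expect_equal(row("M1")$y, 1L)
  expect_equal(row("M1")$gamma_minutes, 60)

  # two affiliative + one non-affiliative event -> y = 2
  expect_equal(row("F2")$y, 2L)
  expect_equal(row("F2")$gamma_minutes, 60)

  # present in one follow only
  expect_equal(row("B1")$y, 1L)
  expect_equal(row("B1")$gamma_minutes, 30)

  # co-present but never interacting -> y = 0 row retained
  expect_equal(row("M2")$y, 0L)

  # never co-present -> no row (zero exposure excluded, not zero-filled)
  expect_false("C1" %in% dy$partner_id)
  expect_true(all(dy$gamma_minutes > 0))

  # stratum selection: F4 is an orphan, absent from the non-orphan table
  expect_false("F4" %in% dy$focal_id)
  dyo <- build_dyad_table(tiny_follows(), tiny_interactions(), reg,
                          "feeding", "orphan", tiny_window())
  expect_setequal(unique(dyo$focal_id), "F4")
  expect_equal(dyo$y[dyo$partner_id == "MAT2"], 1L)
})

test_that("dyad counts reconcile with the event log and exposure bounds", {
  reg <- tiny_registry()
  fl <- tiny_follows()
  ev <- tiny_interactions()
  for (stratum in c("orphan", "non_orphan")) {
    dy <- build_dyad_table(fl, ev, reg, "feeding", stratum, tiny_window())
    for (f in unique(dy$focal_id)) {
      fids <- fl$follow_id[fl$focal_id == f & fl$activity == "feeding"]
      n_events <- sum(ev$follow_id %in% fids &
                        ev$itype %in% orphanbonds:::AFFILIATIVE_TYPES)
      expect_equal(sum(dy$y[dy$focal_id == f]), n_events)
      total_min <- sum(fl$duration_minutes[fl$focal_id == f &
                                             fl$activity == "feeding"])
      expect_true(all(dy$gamma_minutes[dy$focal_id == f] <= total_min + 1e-9))
    }
  }
})

test_that("dyad table is invariant to input row order", {
  reg <- tiny_registry()
  fl <- tiny_follows()
  ev <- tiny_interactions()
  dy1 <- build_dyad_table(fl, ev, reg, "feeding", "non_orphan", tiny_window())
  set.seed(4)
  dy2 <- build_dyad_table(fl[sample(nrow(fl)), ], ev[sample(nrow(ev)), ],
                          reg[sample(nrow(reg)), ], "feeding", "non_orphan",
                          tiny_window())
  expect_equal(dy1, dy2)
})

test_that("sampling summary reports totals and per-focal medians with IQR", {
  fl <- tiny_follows()
  st <- orphan_status(tiny_registry(), unique(fl$focal_id), 2014)
  ss <- sampling_summary(fl, st)
  feeding_no <- ss[ss$activity == "feeding" & ss$stratum == "non_orphan", ]
  expect_equal(feeding_no$total_hours, 1)       # two 30-minute follows
  expect_equal(feeding_no$n_focals, 1L)
  expect_equal(feeding_no$minutes_median, 60)
  expect_equal(feeding_no$follows_median, 2)
  resting <- ss[ss$activity == "resting", ]
  expect_equal(resting$total_hours, 20 / 60)
  # no follows -> empty summary, not zeros for absent strata
  expect_equal(nrow(sampling_summary(fl[0, ], st)), 0L)
})

test_that("dyad tables written for audit can be read back", {
  dir <- withr::local_tempdir()
  dy <- build_dyad_table(tiny_follows(), tiny_interactions(), tiny_registry(),
                         "feeding", "non_orphan", tiny_window())
  path <- write_dyad_table(dy, file.path(dir, "dyads.csv"))
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(dy))
  expect_equal(back$y, dy$y)
})
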