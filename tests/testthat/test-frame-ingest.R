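test_that("frame logs round-trip losslessly through the CSV dialect", {
  sim <- small_sim(seed = 41)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_frame_log(sim$frames, f1)
  rt <- read_frame_log(f1)
  write_frame_log(rt, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(names(rt), gazewm:::FRAME_LOG_COLUMNS)
})

test_that("schema and integrity violations are reported with their location", {
  sim <- small_sim(seed = 42, runs = 4L, displays = 1L)
  fr <- data.table::as.data.table(sim$frames)

  f <- tempfile(fileext = ".csv")
  data.table::fwrite(fr[, !"aoi"], f)
  expect_error(read_frame_log(f), "schema error.*aoi")

  # a PICKUP while already holding an object
  bad <- data.table::copy(fr[participant == 1 & run == 1 & display == 1])
  i <- which(bad$controller_event == "PICKUP")[2]
  bad$held_object[i - 1L] <- 99L
  expect_error(validate_frame_log(bad), "PICKUP while already holding")

  # a RELEASE with empty hands
  bad2 <- data.table::copy(fr[participant == 1 & run == 1 & display == 1])
  j <- which(bad2$controller_event == "RELEASE")[1]
  bad2$held_object[j] <- NA_integer_
  expect_error(validate_frame_log(bad2), "RELEASE while holding nothing")

  # non-monotone time
  bad3 <- data.table::copy(fr[participant == 1 & run == 1 & display == 1])
  bad3$time_s[5] <- bad3$time_s[4]
  expect_error(validate_frame_log(bad3), "non-monotone time")

  # empty file: zero-row log with a warning
  fe <- tempfile(fileext = ".csv")
  writeLines(paste(gazewm:::FRAME_LOG_COLUMNS, collapse = ","), fe)
  expect_warning(z <- read_frame_log(fe), "empty")
  expect_equal(nrow(z), 0)
})

test_that("visit compression is an exact run-length encoding", {
  fr <- make_frames(list(list(aoi = "MODEL", n = 2), list(aoi = "RESOURCE", n = 1),
                         list(aoi = "MODEL", n = 1)))
  v <- compress_visits(fr)
  expect_equal(v$aoi, c("MODEL", "RESOURCE", "MODEL"))
  expect_equal(v$n_frames, c(2L, 1L, 1L))
  # durations tile the display span exactly
  expect_equal(sum(v$n_frames) / 90, nrow(fr) / 90)

  # all-model display: a single visit
  fr1 <- make_frames(list(list(aoi = "MODEL", n = 10)))
  expect_equal(nrow(compress_visits(fr1)), 1)

  # alternating every frame: one visit per frame
  fr2 <- make_frames(lapply(1:6, function(i)
    list(aoi = if (i %% 2) "MODEL" else "RESOURCE", n = 1)))
  expect_equal(nrow(compress_visits(fr2)), 6)
})

test_that("event derivation maps pickups and placements and flags corrections", {
  fr <- make_frames(list(
    list(aoi = "MODEL", n = 3),
    list(aoi = "RESOURCE", n = 2, event = "PICKUP", object = 3L),
    list(aoi = "WORKSPACE", n = 2, event = "RELEASE", object = 3L,
         cell = 5L, correct = TRUE, held = 3L),
    list(aoi = "MODEL", n = 2)))
  ev <- derive_events(fr)
  expect_equal(ev$kind, c("PICKUP", "PLACE"))
  expect_equal(ev$object_id, c(3L, 3L))
  expect_equal(ev$placement_cell[2], 5L)
  expect_false(any(ev$is_corrective))

  # a release with no cell is a dropped object: no PLACE event
  fr2 <- make_frames(list(
    list(aoi = "MODEL", n = 2),
    list(aoi = "RESOURCE", n = 2, event = "PICKUP", object = 4L),
    list(aoi = "WORKSPACE", n = 2, event = "RELEASE", object = 4L),
    list(aoi = "MODEL", n = 2)))
  ev2 <- derive_events(fr2)
  expect_equal(ev2$kind, "PICKUP")

  # wrong placement, corrective re-pickup (REMOVE), corrective re-place
  fr3 <- make_frames(list(
    list(aoi = "MODEL", n = 2),
    list(aoi = "RESOURCE", n = 2, event = "PICKUP", object = 6L),
    list(aoi = "WORKSPACE", n = 2, event = "RELEASE", object = 6L,
         cell = 2L, correct = FALSE, held = 6L),
    list(aoi = "WORKSPACE", n = 1, event = "PICKUP", object = 6L),
    list(aoi = "WORKSPACE", n = 2, event = "RELEASE", object = 6L,
         cell = 1L, correct = TRUE, held = 6L),
    list(aoi = "MODEL", n = 2)))
  ev3 <- derive_events(fr3)
  expect_equal(ev3$kind, c("PICKUP", "PLACE", "REMOVE", "PLACE"))
  expect_equal(ev3$is_corrective, c(FALSE, FALSE, TRUE, TRUE))

  # idempotent and order-preserving
  expect_identical(derive_events(fr3), ev3)
})
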