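test_that("write/read round-trips the canonical form byte-identically", {
  rec <- simulate_participant(routine_params(), days = 4, seed = 11, participant_id = "rt1")
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- write_recording(rec, d1)
  rec2 <- read_recording(p1[["pir"]], p1[["doors"]], p1[["bed"]],
    participant_id = "rt1", timezone = "UTC"
  )
  p2 <- write_recording(rec2, d2)
  for (k in names(p1)) {
    expect_identical(readBin(p1[[k]], "raw", file.size(p1[[k]])),
      readBin(p2[[k]], "raw", file.size(p2[[k]])),
      label = sprintf("bytes of %s", k)
    )
  }
  expect_equal(nrow(rec2$nights), nrow(rec$nights))
  expect_equal(nrow(rec2$doors), nrow(rec$doors))
})

test_that("well-formed fixture reads into the expected structure", {
  rec <- scripted_recording()
  dir <- withr::local_tempdir()
  paths <- write_recording(rec, dir)
  got <- read_recording(paths[["pir"]], paths[["doors"]], paths[["bed"]],
    participant_id = "t1", timezone = "UTC"
  )
  expect_s3_class(got, "home_recording")
  expect_setequal(unique(got$pir$room), room_labels())
  expect_equal(nrow(got$doors), 6)
  expect_equal(nrow(got$nights), 3)
})

test_that("schema violations are rejected with file/row/field context", {
  dir <- withr::local_tempdir()
  pir_path <- file.path(dir, "x_pir.csv")
  writeLines(c(
    "participant_id,room,timestamp,state",
    "x,garage,2021-03-01T00:00:00Z,1"
  ), pir_path)
  expect_error(read_recording(pir_path, participant_id = "x"), "garage")

  writeLines(c(
    "participant_id,room,timestamp,state",
    "x,kitchen,2021-03-01T00:00:00Z,7"
  ), pir_path)
  expect_error(read_recording(pir_path, participant_id = "x"), "state")

  writeLines(c(
    "participant_id,room,timestamp,state",
    "x,kitchen,2021-03-01T00:00:02Z,1",
    "x,kitchen,2021-03-01T00:00:00Z,1"
  ), pir_path)
  expect_error(read_recording(pir_path, participant_id = "x"), "non-monotone")

  door_path <- file.path(dir, "x_doors.csv")
  writeLines(c(
    "participant_id,door,timestamp,event",
    "x,window,2021-03-01T10:00:00Z,open"
  ), door_path)
  expect_error(read_recording(door_path = door_path, participant_id = "x"), "window")
})

test_that("per-epoch and run-length PIR variants parse identically", {
  dir <- withr::local_tempdir()
  ep <- file.path(dir, "a_pir.csv")
  writeLines(c(
    "participant_id,room,timestamp,state",
    "a,kitchen,2021-03-01T10:00:00Z,1",
    "a,kitchen,2021-03-01T10:00:02Z,1",
    "a,kitchen,2021-03-01T10:00:04Z,0",
    "a,kitchen,2021-03-01T10:00:06Z,0"
  ), ep)
  rl <- file.path(dir, "b_pir.csv")
  writeLines(c(
    "participant_id,room,timestamp_start,timestamp_end,state",
    "b,kitchen,2021-03-01T10:00:00Z,2021-03-01T10:00:04Z,1",
    "b,kitchen,2021-03-01T10:00:04Z,2021-03-01T10:00:08Z,0"
  ), rl)
  ra <- read_recording(ep, participant_id = "a")
  rb <- read_recording(rl, participant_id = "b")
  expect_equal(ra$pir[, c("room", "start", "end", "state")],
    rb$pir[, c("room", "start", "end", "state")],
    ignore_attr = TRUE
  )
})

test_that("repeated door states get a synthetic complement at the midpoint", {
  doors <- tibble::tibble(
    door = "entrance",
    time = ts_utc(c("2021-03-01 10:00:00", "2021-03-01 10:10:00")),
    state = c("open", "open")
  )
  expect_warning(norm <- normalize_door_events(doors), "synthetic")
  expect_equal(nrow(norm), 3)
  expect_equal(norm$state, c("open", "close", "open"))
  expect_equal(norm$time[2], ts_utc("2021-03-01 10:05:00"))
})

test_that("stream invariants are enforced by the validator", {
  expect_error(
    home_recording("z", pir = pir_run("kitchen", "2021-03-01 00:00:00", "2021-03-01 00:00:03", 1)),
    "2-s"
  )
  overlapping <- dplyr::bind_rows(
    make_night("2021-03-01 22:00:00", "2021-03-02 06:00:00"),
    make_night("2021-03-02 05:00:00", "2021-03-02 09:00:00")
  )
  expect_error(home_recording("z", nights = overlapping), "overlap")
  bad_hr <- make_night("2021-03-01 22:00:00", "2021-03-01 23:00:00", hr = -5)
  expect_error(home_recording("z", nights = bad_hr), "hr")
})
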