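test_that("write then read round-trips a recording exactly", {
  recs <- list(
    generate_fall("F02", seed = 11),
    generate_adl("D04", seed = 12)
  )
  for (rec in recs) {
    dir <- withr::local_tempdir()
    write_recording(rec, dir)
    back <- read_recording(dir)
    expect_identical(back$activity, rec$activity)
    expect_identical(back$cohort, rec$cohort)
    expect_identical(as.character(back$user_id), as.character(rec$user_id))
    expect_equal(back$actual_fall, rec$actual_fall)
    for (s in names(rec$traces)) {
      expect_equal(as.data.frame(back$traces[[s]]), as.data.frame(rec$traces[[s]]),
        tolerance = 0
      )
      expect_equal(trace_rate(back$traces[[s]]), trace_rate(rec$traces[[s]]))
    }
  }
})

test_that("a 16.5 s accelerometer file at 50 Hz reads back as 825 samples", {
  rec <- synthetic_recording(duration = 16.5, rate = 50, fall = c(7, 10))
  expect_identical(nrow(rec$traces$accelerometer), 825L)
  dir <- withr::local_tempdir()
  write_recording(rec, dir)
  back <- read_recording(dir)
  expect_identical(nrow(back$traces$accelerometer), 825L)
  expect_equal(trace_duration(back$traces$accelerometer), 16.5)
})

test_that("a non-numeric cell raises a parse error naming the line", {
  dir <- withr::local_tempdir()
  writeLines(
    c("t,x,y,z", "0,1,2,3", "0.02,oops,2,3"),
    file.path(dir, "accelerometer.csv")
  )
  writeLines(
    c("user_id: U1", "cohort: YP", "activity: D01", "trial: 1"),
    file.path(dir, "meta.txt")
  )
  expect_error(read_recording(dir), "line 2")
})

test_that("a missing sensor file yields a structured marker, not a failure", {
  rec <- generate_adl("D01", seed = 3)
  dir <- withr::local_tempdir()
  write_recording(rec, dir)
  unlink(file.path(dir, "gyroscope.csv"))
  back <- read_recording(dir)
  expect_identical(attr(back, "missing_sensors"), "gyroscope")
  expect_null(back$traces$gyroscope)
  expect_false(is.null(back$traces$accelerometer))
})

test_that("an empty trace writes a header-only CSV and reads back empty", {
  tr <- sensor_trace("accelerometer",
    data.frame(t = numeric(0), x = numeric(0), y = numeric(0), z = numeric(0)),
    rate_hz = 50
  )
  rec <- recording("U1", "YP", "D11", 1, traces = list(accelerometer = tr))
  dir <- withr::local_tempdir()
  write_recording(rec, dir)
  expect_identical(readLines(file.path(dir, "accelerometer.csv")), "t,x,y,z")
  back <- read_recording(dir)
  expect_identical(nrow(back$traces$accelerometer), 0L)
})

test_that("the actual-fall interval is persisted in the sidecar and recovered", {
  rec <- synthetic_recording(duration = 12, fall = c(3.25, 6.5))
  dir <- withr::local_tempdir()
  write_recording(rec, dir)
  meta <- readLines(file.path(dir, "meta.txt"))
  expect_true(any(grepl("actual_fall_start", meta)))
  expect_equal(read_recording(dir)$actual_fall, c(3.25, 6.5))
})

test_that("the young-participant protocol totals 350 falls and 462 ADLs", {
  counts <- expected_signal_counts(yp_protocol())
  expect_identical(counts$falls, 350L)
  expect_identical(counts$adls, 462L)
})

test_that("signal counts: empty protocol, direct products, additivity", {
  expect_identical(expected_signal_counts(yp_protocol(0))$falls, 0L)
  expect_identical(expected_signal_counts(yp_protocol(0))$adls, 0L)

  two_user_f01 <- protocol(data.frame(
    user_id = c("A", "B"), cohort = "YP", activity = "F01", reps = 3L
  ))
  expect_identical(expected_signal_counts(two_user_f01)$falls, 6L)

  # additive over disjoint participant sets
  full <- yp_protocol(5)
  part1 <- protocol(full[full$user_id %in% c("U1", "U2"), ])
  part2 <- protocol(full[!full$user_id %in% c("U1", "U2"), ])
  expect_identical(
    expected_signal_counts(full)$falls,
    expected_signal_counts(part1)$falls + expected_signal_counts(part2)$falls
  )
  expect_identical(
    expected_signal_counts(full)$adls,
    expected_signal_counts(part1)$adls + expected_signal_counts(part2)$adls
  )
})

test_that("unknown activity codes are rejected", {
  expect_error(
    protocol(data.frame(user_id = "A", cohort = "YP", activity = "F99", reps = 1L)),
    "unknown activity"
  )
})

test_that("fall recordings require an actual-fall interval and ADLs forbid one", {
  tr <- sensor_trace("accelerometer",
    data.frame(t = (0:499) / 50, x = 0, y = 0, z = GRAVITY),
    rate_hz = 50
  )
  expect_error(
    recording("U1", "YP", "F01", 1, list(accelerometer = tr)),
    "actual_fall"
  )
  expect_error(
    recording("U1", "YP", "D01", 1, list(accelerometer = tr), actual_fall = c(1, 2)),
    "must not carry"
  )
  expect_error(
    recording("U1", "YP", "F01", 1, list(accelerometer = tr), actual_fall = c(5, 20)),
    "duration"
  )
})
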