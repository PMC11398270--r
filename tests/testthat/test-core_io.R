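test_that("well-formed trace files parse with file-level sampling metadata", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "time_s,pressure,acc_x,acc_y,acc_z",
    "0.0,-0.5,0.01,0.3,0.5",
    "0.1,-0.2,0.01,0.3,0.5",
    "0.2,0.3,0.02,0.3,0.5",
    "0.3,0.5,0.01,0.3,0.5",
    "0.4,0.1,0.01,0.3,0.5"
  ), path)
  tr <- read_trace(path)
  expect_s3_class(tr, "sensor_trace")
  expect_equal(trace_length(tr), 5)
  expect_equal(tr$sampling_rate, 10)
})

test_that("non-monotone time and malformed rows are rejected with location", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "time_s,pressure,acc_x,acc_y,acc_z",
    "0.0,0,0,0,0.5",
    "0.2,0,0,0,0.5",
    "0.1,0,0,0,0.5"
  ), path)
  expect_error(read_trace(path), "non-monotone time")
  writeLines(c(
    "time_s,pressure,acc_x,acc_y,acc_z",
    "0.0,zero,0,0,0.5"
  ), path)
  expect_error(read_trace(path), "malformed")
})

test_that("out-of-range acceleration is rejected or flagged per config", {
  z <- rep(0.5, 4)
  expect_error(sensor_trace("c", 10, z, rep(0.4, 4), z, z), "range")
  expect_warning(
    sensor_trace("c", 10, z, rep(0.4, 4), z, z, on_range = "warn"),
    "range"
  )
  expect_silent(sensor_trace("c", 10, z, rep(0.2, 4), z, z))
})

test_that("simulated traces round-trip through write/read bit-identically", {
  trial <- simulate_trial(sim_config(seed = 7, duration_s = 120,
                                     gap_loss_prob = 0.4))
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(trial$trace, path)
  back <- read_trace(path)
  expect_identical(back$pressure, trial$trace$pressure)
  expect_identical(back$acc_x, trial$trace$acc_x)
  expect_identical(back$acc_y, trial$trace$acc_y)
  expect_identical(back$acc_z, trial$trace$acc_z)
  expect_identical(back$sampling_rate, trial$trace$sampling_rate)
  expect_equal(back$gaps$start_s, trial$trace$gaps$start_s)
  expect_equal(back$gaps$end_s, trial$trace$gaps$end_s)
  # and writing again reproduces the same file
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_trace(back, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("event logs convert h:m:s stamps to seconds from period start", {
  period <- observation_period("p1", "c1", 0, 600, "ruminating", "video")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "cow_id,period_id,source,time",
    "c1,p1,visual,00:02:01",
    "c1,p1,visual,00:01:00"
  ), path)
  log <- read_event_log(path, period)
  expect_equal(log$events, c(60, 121)) # unsorted input comes back sorted
  expect_equal(log$source, "visual")

  # non-zero wall-clock period start shifts the origin
  period2 <- observation_period("p1", "c1", 3600, 4200, "ruminating", "video")
  writeLines(c("cow_id,period_id,source,time", "c1,p1,visual,01:01:00"), path)
  expect_equal(read_event_log(path, period2)$events, 60)
})

test_that("event logs validate bounds and duplicates", {
  period <- observation_period("p1", "c1", 0, 100, "ruminating", "video")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cow_id,period_id,source,time", "c1,p1,visual,150"), path)
  expect_error(read_event_log(path, period), "bounds")
  writeLines(c("cow_id,period_id,source,time",
               "c1,p1,visual,50", "c1,p1,visual,50"), path)
  expect_error(read_event_log(path, period), "duplicate")
  expect_equal(read_event_log(path, period, dedupe = TRUE)$events, 50)
  # empty file -> empty log
  writeLines("cow_id,period_id,source,time", path)
  expect_length(read_event_log(path, period)$events, 0)
})

test_that("gap masking removes exactly the gapped samples and is idempotent", {
  tr <- sensor_trace("c", 10, rep(0.1, 600), rep(0, 600), rep(0, 600),
                     rep(0.5, 600))
  g <- gap_set(10, 20)
  masked <- mask_gaps(tr, g)
  expect_equal(sum(is.na(masked$pressure)), 100) # 10 s at 10 Hz
  expect_identical(mask_gaps(masked, g), masked)
  # empty gap set is the identity
  expect_identical(mask_gaps(tr, gap_set()), tr)
  # gap beyond the trace is a validation error
  expect_error(mask_gaps(tr, gap_set(50, 70)), "exceeds")
})

test_that("overlapping gaps merge to canonical form (interval-union oracle)", {
  set.seed(41)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    s <- runif(n, 0, 50)
    e <- s + runif(n, 1, 15)
    g <- gap_set(s, e)
    expect_true(all(diff(g$start_s) > 0))
    expect_true(all(g$end_s[-nrow(g)] < g$start_s[-1]))
    grid <- seq(0, 70, by = 0.25)
    expect_equal(in_gaps(grid, g), union_member(grid, s, e))
    # total masked duration equals summed interval lengths
    tr <- sensor_trace("c", 10, rep(0, 700), rep(0, 700), rep(0, 700),
                       rep(0.5, 700))
    masked <- mask_gaps(tr, g)
    expect_equal(sum(is.na(masked$pressure)) / 10, gap_total(g),
                 tolerance = 0.2)
  }
})

test_that("period tables round-trip", {
  periods <- list(
    observation_period("p1", "c1", 0, 600, "ruminating", "direct", "2022"),
    observation_period("p2", "c2", 0, 600, "negative_control", "video", "2018")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_period_table(periods, path)
  back <- read_period_table(path)
  expect_equal(back$p1$behavior, "ruminating")
  expect_equal(back$p2$method, "video")
  expect_equal(period_duration(back$p1), 600)
})
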