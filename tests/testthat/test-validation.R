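test_that("tolerance-window matching handles the hand-checked cases", {
  m <- match_events(make_log(c(10, 70, 130)),
                    make_log(c(12, 68, 200), "sensor"))
  expect_equal(nrow(m$matched_pairs), 2)
  expect_equal(m$unmatched_visual, 130)
  expect_equal(m$unmatched_sensor, 200)

  m0 <- match_events(make_log(numeric(0)), make_log(numeric(0), "sensor"))
  expect_equal(nrow(m0$matched_pairs), 0)
  expect_length(m0$unmatched_visual, 0)
  expect_length(m0$unmatched_sensor, 0)

  # two sensor events near one reference: one TP, the surplus is an FP
  m1 <- match_events(make_log(100), make_log(c(95, 105), "sensor"))
  expect_equal(nrow(m1$matched_pairs), 1)
  expect_length(m1$unmatched_sensor, 1)

  # the tolerance is inclusive
  m2 <- match_events(make_log(100), make_log(105, "sensor"))
  expect_equal(nrow(m2$matched_pairs), 1)
  m3 <- match_events(make_log(100), make_log(105.01, "sensor"))
  expect_equal(nrow(m3$matched_pairs), 0)

  expect_error(
    match_events(make_log(10, period = "a"), make_log(10, "sensor", period = "b")),
    "different periods"
  )
})

test_that("greedy matching equals the exhaustive optimum on realistic logs", {
  set.seed(99)
  for (i in 1:200) {
    inst <- random_match_instance()
    m <- match_events(make_log(inst$ref), make_log(inst$sensor, "sensor"))
    opt <- oracle_match(inst$ref, inst$sensor, 5)
    expect_equal(nrow(m$matched_pairs), opt$pairs)
    if (opt$pairs > 0) {
      expect_equal(sum(abs(m$matched_pairs$visual_s - m$matched_pairs$sensor_s)),
                   opt$total, tolerance = 1e-9)
    }
    # partition invariants
    expect_equal(nrow(m$matched_pairs) + length(m$unmatched_visual),
                 length(inst$ref))
    expect_equal(nrow(m$matched_pairs) + length(m$unmatched_sensor),
                 length(inst$sensor))
  }
})

test_that("matching is invariant to a common time shift", {
  set.seed(17)
  inst <- random_match_instance()
  m <- match_events(make_log(inst$ref), make_log(inst$sensor, "sensor"))
  ms <- match_events(make_log(inst$ref + 1000),
                     make_log(inst$sensor + 1000, "sensor"))
  expect_equal(nrow(ms$matched_pairs), nrow(m$matched_pairs))
  expect_equal(ms$unmatched_sensor, m$unmatched_sensor + 1000)
})

test_that("negative-control minutes are counted from period start", {
  p <- observation_period("n1", "c1", 0, 3600, "negative_control", "video")
  # 3 events in 3 distinct minutes of a 60-min control
  nc <- count_negative_control(p, make_log(c(100, 700, 1300), "sensor",
                                           period = "n1"))
  expect_equal(nc$tn, 57)
  expect_equal(nc$fp, 3)
  # 10 min, no events
  p10 <- observation_period("n2", "c1", 0, 600, "negative_control", "direct")
  nc10 <- count_negative_control(p10, make_log(numeric(0), "sensor",
                                               period = "n2"))
  expect_equal(nc10$tn, 10)
  expect_equal(nc10$fp, 0)
  # two events in the same minute spoil only that minute
  nc2 <- count_negative_control(p, make_log(c(100, 110), "sensor",
                                            period = "n1"))
  expect_equal(nc2$tn, 59)
  expect_equal(nc2$fp, 2)
  # gap minutes are reported for later correction
  ncg <- count_negative_control(p10, make_log(numeric(0), "sensor",
                                              period = "n2"),
                                gaps = gap_set(c(30, 200), c(45, 210)))
  expect_equal(ncg$gap_minutes, 2)
  expect_error(
    count_negative_control(observation_period("r", "c", 0, 600,
                                              "ruminating", "direct"),
                           make_log(numeric(0), "sensor")),
    "negative-control"
  )
})

test_that("gap correction removes gap casualties and nothing else", {
  raw <- confusion_counts(tp = 227, fn = 151, tn = 55, fp = 5)
  corr <- correct_for_gaps(raw, gap_events = 149, gap_minutes = 19)
  expect_equal(corr$fn, 2)
  expect_equal(corr$tn, 36)
  expect_equal(corr$tp, raw$tp)
  expect_equal(corr$fp, raw$fp)
  # empty gaps: identity
  expect_identical(correct_for_gaps(raw), raw)
  # reference-log route counts gap-covered events
  ref <- make_log(c(10, 50, 200))
  g <- gap_set(40, 60)
  c2 <- correct_for_gaps(confusion_counts(tp = 0, fn = 3), ref, g)
  expect_equal(c2$fn, 2)
  # over-correction is an error
  expect_error(correct_for_gaps(confusion_counts(fn = 1), gap_events = 2),
               "negative")
})

test_that("the four metrics follow their defining ratios with half-up rounding", {
  r18 <- performance(confusion_counts(tp = 201, fn = 0, tn = 57, fp = 3))
  expect_equal(c(r18$Se, r18$Sp, r18$PPV, r18$NPV), c(100.0, 95.0, 98.5, 100.0))
  r22 <- performance(confusion_counts(tp = 227, fn = 151, tn = 55, fp = 5))
  expect_equal(c(r22$Se, r22$Sp, r22$PPV, r22$NPV), c(60.1, 91.7, 97.8, 26.7))
  # undefined ratios stay missing, never 0
  r0 <- performance(confusion_counts(tp = 0, fn = 0, tn = 10, fp = 0))
  expect_true(is.na(r0$Se))
  expect_equal(r0$Sp, 100.0)
  expect_equal(r0$NPV, 100.0)
  expect_true(is.na(r0$PPV))
})

test_that("end-to-end evaluation satisfies the partition invariants", {
  trial <- simulate_trial(sim_config(seed = 23))
  det <- detect_regurgitations(trial$trace, period_id = trial$truth$period_id)
  res <- evaluate_detection(trial$truth, det, trial$period, trial$gaps)
  expect_equal(res$counts_raw$tp + res$counts_raw$fn,
               length(trial$truth$events))
  expect_equal(res$counts_raw$tp + res$counts_raw$fp, length(det$events))
})
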