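#' Match sensor events against reference events
#'
#' One-to-one matching of sensor-detected regurgitations against visually
#' observed ones with an inclusive tolerance window (a sensor event at the
#' same time point +/- `tolerance_s` is a true positive). Pairs are formed
#' greedily in order of increasing absolute time difference, ties broken by
#' earlier reference time, then earlier sensor time. Unmatched reference
#' events are false negatives; unmatched sensor events are false positives.
#'
#' @param reference the visual [event_log()].
#' @param sensor the sensor [event_log()].
#' @param tolerance_s inclusive matching tolerance in seconds.
#' @return an object of class `match_result`: list with `matched_pairs`
#'   (data.frame `visual_s`, `sensor_s`), `unmatched_visual`,
#'   `unmatched_sensor` (numeric vectors) and `tolerance_s`.
#' @export
match_events <- function(reference, sensor, tolerance_s = 5) {
  if (reference$period_id != sensor$period_id) {
    stop("reference and sensor logs belong to different periods")
  }
  rv <- reference$events
  sv <- sensor$events
  pairs <- expand.grid(ri = seq_along(rv), si = seq_along(sv))
  if (nrow(pairs) > 0) {
    pairs$dt <- abs(rv[pairs$ri] - sv[pairs$si])
    pairs <- pairs[pairs$dt <= tolerance_s, , drop = FALSE]
    pairs <- pairs[order(pairs$dt, rv[pairs$ri], sv[pairs$si]), , drop = FALSE]
  }
  used_r <- logical(length(rv))
  used_s <- logical(length(sv))
  mi <- integer(0)
  ms <- integer(0)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$ri[k]
    j <- pairs$si[k]
    if (used_r[i] || used_s[j]) next
    used_r[i] <- TRUE
    used_s[j] <- TRUE
    mi <- c(mi, i)
    ms <- c(ms, j)
  }
  o <- order(rv[mi])
  structure(
    list(
      matched_pairs = data.frame(visual_s = rv[mi][o], sensor_s = sv[ms][o]),
      unmatched_visual = rv[!used_r],
      unmatched_sensor = sv[!used_s],
      tolerance_s = tolerance_s
    ),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> TP %d, FN %d, FP %d (tolerance +/- %g s)\n",
    nrow(x$matched_pairs), length(x$unmatched_visual),
    length(x$unmatched_sensor), x$tolerance_s
  ))
  invisible(x)
}

#' Confusion counts
#'
#' Binary-classification counts for regurgitation detection. True negatives
#' are counted in event-free negative-control minutes, so the TN unit is one
#' minute, while TP/FN/FP are event counts.
#'
#' @param tp,fn,tn,fp non-negative integers.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0, fn = 0, tn = 0, fp = 0) {
  v <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(v < 0) || any(v != round(v))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d  FN %d  TN %d  FP %d\n",
              x$tp, x$fn, x$tn, x$fp))
  invisible(x)
}

#' Add confusion counts
#' @param e1,e2 [confusion_counts()] objects.
#' @export
"+.confusion_counts" <- function(e1, e2) {
  confusion_counts(e1$tp + e2$tp, e1$fn + e2$fn, e1$tn + e2$tn, e1$fp + e2$fp)
}

#' Confusion counts from a match result
#'
#' For a ruminating period: TP = matched pairs, FN = unmatched reference
#' events, FP = unmatched sensor events, TN = 0 (true negatives come only
#' from negative-control periods).
#'
#' @param match a [match_events()] result.
#' @return a [confusion_counts()].
#' @export
counts_from_match <- function(match) {
  confusion_counts(
    tp = nrow(match$matched_pairs),
    fn = length(match$unmatched_visual),
    fp = length(match$unmatched_sensor)
  )
}

#' Count true negatives on a negative-control period
#'
#' The period is divided into whole minutes from its start; a minute with no
#' sensor event counts as one true negative, every sensor event is a false
#' positive. Minutes overlapping streaming gaps are still counted here but
#' reported so they can be removed by [correct_for_gaps()].
#'
#' @param period an [observation_period()] with
#'   `behavior = "negative_control"`.
#' @param sensor the sensor [event_log()] for the period.
#' @param gaps a [gap_set()] (empty by default).
#' @return a list with `tn` (minutes), `fp` (event count) and `gap_minutes`
#'   (gap-affected minutes).
#' @export
count_negative_control <- function(period, sensor, gaps = gap_set()) {
  if (period$behavior != "negative_control") {
    stop("true-negative minutes are only counted on negative-control periods")
  }
  dur <- period_duration(period)
  n_min <- floor(dur / 60 + 1e-9)
  ev_min <- unique(floor(sensor$events / 60))
  ev_min <- ev_min[ev_min < n_min]
  list(
    tn = n_min - length(ev_min),
    fp = length(sensor$events),
    gap_minutes = gap_minutes(gaps, dur)
  )
}

#' Correct confusion counts for streaming gaps
#'
#' Events the sensor could not record because of a transmission gap are not
#' detection failures: the correction removes from FN the unmatched
#' reference events whose time lies inside a gap, and removes the
#' gap-affected minutes from TN. TP and FP are never changed.
#'
#' @param counts uncorrected [confusion_counts()].
#' @param reference optional [event_log()] of the *unmatched* reference
#'   events; with `gaps`, used to count gap-covered misses when
#'   `gap_events` is not given. Passing the full reference log is only
#'   correct when no gap-covered event could have been matched.
#' @param gaps optional [gap_set()].
#' @param gap_minutes number of gap-affected negative-control minutes to
#'   remove from TN.
#' @param gap_events number of gap-covered (hence unmatched) reference
#'   events to remove from FN; computed from `reference` and `gaps` when
#'   `NULL`.
#' @return corrected [confusion_counts()]. Driving FN or TN negative is an
#'   error.
#' @export
correct_for_gaps <- function(counts, reference = NULL, gaps = NULL,
                             gap_minutes = 0, gap_events = NULL) {
  if (is.null(gap_events)) {
    gap_events <- if (!is.null(reference) && !is.null(gaps)) {
      sum(in_gaps(reference$events, gaps))
    } else {
      0
    }
  }
  fn <- counts$fn - gap_events
  tn <- counts$tn - gap_minutes
  if (fn < 0 || tn < 0) {
    stop("gap correction would drive FN or TN negative")
  }
  confusion_counts(counts$tp, fn, tn, counts$fp)
}

# half-up rounding to one decimal (matches how the reported percentages
# were rounded; base round() rounds half to even)
round_half_up1 <- function(x) floor(x * 10 + 0.5) / 10

#' Classification performance
#'
#' Sensitivity, specificity, positive and negative predictive value, in
#' percent:
#' Se = 100 TP/(TP+FN), Sp = 100 TN/(TN+FP), PPV = 100 TP/(TP+FP),
#' NPV = 100 TN/(FN+TN). A zero denominator leaves that metric missing
#' (`NA`), never 0. Reported values are rounded half-up to one decimal; the
#' raw ratios are retained.
#'
#' @param counts a [confusion_counts()].
#' @return an object of class `performance_report`: list with `Se`, `Sp`,
#'   `PPV`, `NPV` (rounded percentages), `raw` (unrounded) and `counts`.
#' @export
performance <- function(counts) {
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  raw <- c(
    Se = ratio(counts$tp, counts$tp + counts$fn),
    Sp = ratio(counts$tn, counts$tn + counts$fp),
    PPV = ratio(counts$tp, counts$tp + counts$fp),
    NPV = ratio(counts$tn, counts$fn + counts$tn)
  )
  rounded <- round_half_up1(raw)
  structure(
    list(Se = rounded[["Se"]], Sp = rounded[["Sp"]], PPV = rounded[["PPV"]],
         NPV = rounded[["NPV"]], raw = raw, counts = counts),
    class = "performance_report"
  )
}

#' @export
print.performance_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "  --" else sprintf("%5.1f", v)
  cat(sprintf("<performance_report> Se %s  Sp %s  PPV %s  NPV %s  (%%)\n",
              fmt(x$Se), fmt(x$Sp), fmt(x$PPV), fmt(x$NPV)))
  invisible(x)
}

#' Evaluate a detector log against a reference log
#'
#' Convenience composition for one period: matching (ruminating) or
#' minute-based TN counting (negative control), raw counts, gap-corrected
#' counts, and both performance reports.
#'
#' @param reference visual [event_log()] (ignored for negative controls).
#' @param sensor sensor [event_log()].
#' @param period the [observation_period()].
#' @param gaps a [gap_set()].
#' @param tolerance_s matching tolerance in seconds.
#' @param correct apply the gap correction?
#' @return a list with `counts_raw`, `counts_corrected`, `report_raw`,
#'   `report_corrected`, and `match` (ruminating periods only).
#' @export
evaluate_detection <- function(reference, sensor, period, gaps = gap_set(),
                               tolerance_s = 5, correct = TRUE) {
  if (period$behavior == "ruminating") {
    m <- match_events(reference, sensor, tolerance_s)
    raw <- counts_from_match(m)
    corr <- if (correct) {
      # only unmatched reference events can be gap casualties
      correct_for_gaps(raw, gap_events = sum(in_gaps(m$unmatched_visual, gaps)))
    } else {
      raw
    }
    list(counts_raw = raw, counts_corrected = corr,
         report_raw = performance(raw), report_corrected = performance(corr),
         match = m)
  } else {
    nc <- count_negative_control(period, sensor, gaps)
    raw <- confusion_counts(tn = nc$tn, fp = nc$fp)
    corr <- if (correct) {
      correct_for_gaps(raw, gap_minutes = nc$gap_minutes)
    } else {
      raw
    }
    list(counts_raw = raw, counts_corrected = corr,
         report_raw = performance(raw), report_corrected = performance(corr),
         match = NULL)
  }
}
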