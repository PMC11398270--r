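#' Detector configuration
#'
#' Thresholds operationalizing the regurgitation signature: the z-orientation
#' stays in a narrow band around `z_center` for at least `min_plateau_s`
#' (but not longer than `max_plateau_s` -- sustained stillness is not a
#' regurgitation), corroborated by a breath interval exceeding
#' `pause_factor` times the rolling median breath period beginning inside
#' the plateau or within `pause_window_s` after it.
#'
#' @param z_center expected plateau level in g (default 0; configurable
#'   because mounting orientation varies).
#' @param z_band half-width of the near-zero band in g.
#' @param min_plateau_s,max_plateau_s admissible plateau lengths in seconds.
#' @param pause_factor prolonged-breath threshold, multiple of the rolling
#'   median breath interval.
#' @param require_pause if `TRUE` (default) a plateau without a corroborating
#'   prolonged breath is rejected.
#' @param pause_window_s seconds after plateau end in which the prolonged
#'   breath must begin.
#' @param refractory_s minimum separation of accepted events (must stay
#'   below the 35-s physiological minimum cycle length).
#' @param smoothing_window_s moving-average window applied to pressure and z
#'   before thresholding.
#' @return a validated list of class `detector_config`.
#' @export
detector_config <- function(z_center = 0, z_band = 0.05,
                            min_plateau_s = 2, max_plateau_s = 8,
                            pause_factor = 1.5, require_pause = TRUE,
                            pause_window_s = 10, refractory_s = 20,
                            smoothing_window_s = 0.3) {
  if (!(min_plateau_s > 0 && min_plateau_s < max_plateau_s)) {
    stop("need 0 < min_plateau_s < max_plateau_s")
  }
  if (z_band <= 0) stop("z_band must be positive")
  if (refractory_s >= 35) stop("refractory_s must stay below the 35-s minimum cycle")
  structure(
    list(z_center = z_center, z_band = z_band, min_plateau_s = min_plateau_s,
         max_plateau_s = max_plateau_s, pause_factor = pause_factor,
         require_pause = require_pause, pause_window_s = pause_window_s,
         refractory_s = refractory_s, smoothing_window_s = smoothing_window_s),
    class = "detector_config"
  )
}

# centered moving average; NAs propagate so gap samples never contribute
smooth_ma <- function(x, fs, window_s) {
  k <- max(1L, round(window_s * fs))
  if (k %% 2 == 0) k <- k + 1L
  if (k == 1L) return(x)
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
}

#' Segment breaths from the pressure channel
#'
#' Breath onsets are the exhalation-to-inhalation transitions of the smoothed
#' pressure signal: downward zero crossings, taken with a hysteresis deadband
#' so that noise around zero does not produce spurious onsets. Onsets inside
#' gaps are impossible (masked samples), and intervals spanning a gap are
#' discarded.
#'
#' @param trace a [sensor_trace()] with gaps already masked.
#' @param config a [detector_config()].
#' @return an object of class `breath_series`: list with `breath_times`
#'   (sorted onset times in seconds) and `intervals` (successive
#'   differences, gap-spanning ones dropped; `NA`-free).
#' @export
segment_breaths <- function(trace, config = detector_config()) {
  fs <- trace$sampling_rate
  p <- smooth_ma(trace$pressure, fs, config$smoothing_window_s)
  if (all(is.na(p))) {
    return(structure(list(breath_times = numeric(0), intervals = numeric(0)),
                     class = "breath_series"))
  }
  h <- 0.25 * stats::median(abs(p), na.rm = TRUE)
  tt <- trace_times(trace)
  onsets <- numeric(0)
  state <- 0L # +1 above +h, -1 below -h, 0 unknown (start / after gap)
  for (i in seq_along(p)) {
    v <- p[i]
    if (is.na(v)) {
      state <- 0L
      next
    }
    if (v > h) {
      state <- 1L
    } else if (v < -h) {
      if (state == 1L) onsets <- c(onsets, tt[i])
      state <- -1L
    }
  }
  intervals <- diff(onsets)
  if (length(intervals) > 0 && nrow(trace$gaps) > 0) {
    # drop intervals whose span touches a gap
    spans_gap <- vapply(seq_along(intervals), function(i) {
      a <- onsets[i]
      b <- onsets[i + 1]
      any(trace$gaps$start_s < b & trace$gaps$end_s > a)
    }, logical(1))
    intervals[spans_gap] <- NA_real_
  }
  structure(list(breath_times = onsets, intervals = intervals),
            class = "breath_series")
}

#' @export
print.breath_series <- function(x, ...) {
  cat(sprintf("<breath_series> %d onset(s), median interval %.2f s\n",
              length(x$breath_times),
              stats::median(x$intervals, na.rm = TRUE)))
  invisible(x)
}

#' Find near-zero z-orientation plateaus
#'
#' Locates maximal runs where the smoothed z channel stays within
#' `z_band` of `z_center`. Because a centered moving average of width w
#' erodes a step plateau by about 0.8 w, the measured run length is
#' compensated by adding `smoothing_window_s` before the
#' `[min_plateau_s, max_plateau_s]` rule is applied. Runs touching a gap are
#' dropped.
#'
#' @param trace a [sensor_trace()].
#' @param config a [detector_config()].
#' @return a data.frame with columns `start_s`, `end_s`, `length_s`
#'   (compensated length), one row per candidate plateau.
#' @export
find_z_plateaus <- function(trace, config = detector_config()) {
  fs <- trace$sampling_rate
  z <- smooth_ma(trace$acc_z, fs, config$smoothing_window_s)
  inband <- !is.na(z) & abs(z - config$z_center) <= config$z_band
  r <- rle(inband)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  out <- data.frame(start_s = numeric(0), end_s = numeric(0), length_s = numeric(0))
  tt <- trace_times(trace)
  for (k in keep) {
    i0 <- starts[k]
    i1 <- ends[k]
    a <- tt[i0]
    b <- tt[i1] + 1 / fs
    len <- (i1 - i0 + 1) / fs + config$smoothing_window_s
    if (len < config$min_plateau_s || len > config$max_plateau_s) next
    if (nrow(trace$gaps) > 0) {
      # a run bordered by masked samples may be a truncated plateau: drop it
      near_gap <- any(trace$gaps$start_s < b + 1 / fs & trace$gaps$end_s > a - 1 / fs)
      if (near_gap) next
    }
    out <- rbind(out, data.frame(start_s = a, end_s = b, length_s = len))
  }
  out
}

# rolling median of breath intervals, robust to respiration-rate drift
rolling_median_intervals <- function(intervals, k = 9L) {
  vals <- intervals[!is.na(intervals)]
  if (length(vals) == 0) return(rep(NA_real_, length(intervals)))
  overall <- stats::median(vals)
  if (length(vals) < k) return(rep(overall, length(intervals)))
  out <- rep(overall, length(intervals))
  half <- (k - 1L) / 2L
  for (i in seq_along(intervals)) {
    lo <- max(1L, i - half)
    hi <- min(length(intervals), i + half)
    w <- intervals[lo:hi]
    w <- w[!is.na(w)]
    if (length(w) > 0) out[i] <- stats::median(w)
  }
  out
}

#' Detect regurgitation events
#'
#' Full signature detector: candidate z plateaus from [find_z_plateaus()]
#' become events (timestamped at plateau start) when corroborated by a
#' prolonged breath -- an interval exceeding `pause_factor` times the rolling
#' median that begins inside the plateau or within `pause_window_s` after
#' it. Events closer than `refractory_s` to the previously accepted event
#' are suppressed (the earlier event wins), and no event is ever emitted
#' inside a gap.
#'
#' @param trace a [sensor_trace()].
#' @param config a [detector_config()].
#' @param cow_id,period_id identifiers for the output log.
#' @return an [event_log()] with `source = "sensor"`.
#' @export
detect_regurgitations <- function(trace, config = detector_config(),
                                  cow_id = trace$cow_id, period_id = "trace") {
  plateaus <- find_z_plateaus(trace, config)
  if (nrow(plateaus) == 0) {
    return(event_log(cow_id, period_id, "sensor", numeric(0)))
  }
  pauses <- numeric(0)
  if (config$require_pause) {
    br <- segment_breaths(trace, config)
    if (length(br$intervals) > 0) {
      med <- rolling_median_intervals(br$intervals)
      is_pause <- !is.na(br$intervals) & !is.na(med) &
        br$intervals > config$pause_factor * med
      pauses <- br$breath_times[which(is_pause)]
    }
  }
  events <- numeric(0)
  for (i in seq_len(nrow(plateaus))) {
    a <- plateaus$start_s[i]
    b <- plateaus$end_s[i]
    if (config$require_pause) {
      hit <- any(pauses >= a & pauses <= b + config$pause_window_s)
      if (!hit) next
    }
    if (length(events) > 0 && a - events[length(events)] < config$refractory_s) next
    if (nrow(trace$gaps) > 0 && in_gaps(a, trace$gaps)) next
    events <- c(events, a)
  }
  event_log(cow_id, period_id, "sensor", events)
}
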