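#' Regurgitation event logs
#'
#' An `event_log` stores the timestamps of regurgitations for one cow and one
#' observation period, in seconds from the period start, from either visual
#' observation (the reference method) or the sensor-based detector.
#'
#' @param cow_id,period_id identifiers (character scalars).
#' @param source `"visual"` or `"sensor"`.
#' @param events numeric vector of event times in seconds from period start;
#'   sorted on construction, duplicates rejected.
#' @return an object of class `event_log`.
#' @export
event_log <- function(cow_id, period_id, source = c("visual", "sensor"),
                      events = numeric(0)) {
  source <- match.arg(source)
  events <- sort(as.numeric(events))
  if (anyNA(events)) stop("event times must not be missing")
  if (any(events < 0)) stop("event times must be non-negative")
  if (length(events) > 1 && any(diff(events) == 0)) {
    stop("duplicate event timestamps")
  }
  structure(
    list(cow_id = as.character(cow_id), period_id = as.character(period_id),
         source = source, events = events),
    class = "event_log"
  )
}

#' @export
print.event_log <- function(x, ...) {
  cat(sprintf("<event_log> cow %s, period %s, source %s: %d event(s)\n",
              x$cow_id, x$period_id, x$source, length(x$events)))
  invisible(x)
}

#' Observation periods
#'
#' A bounded observation interval for one cow, labelled with the behavior
#' shown (`ruminating` or `negative_control` -- dozing, feeding, standing or
#' lying without rumination) and the observation method (`video` or `direct`).
#'
#' @param period_id,cow_id identifiers.
#' @param start_s,end_s period bounds in seconds (`end_s > start_s`).
#' @param behavior `"ruminating"` or `"negative_control"`.
#' @param method `"video"` or `"direct"`.
#' @param year_label free-text trial label.
#' @return an object of class `observation_period`.
#' @export
observation_period <- function(period_id, cow_id, start_s, end_s,
                               behavior = c("ruminating", "negative_control"),
                               method = c("video", "direct"),
                               year_label = "") {
  behavior <- match.arg(behavior)
  method <- match.arg(method)
  if (!is.numeric(start_s) || !is.numeric(end_s) || end_s <= start_s) {
    stop("observation period must satisfy end_s > start_s")
  }
  structure(
    list(period_id = as.character(period_id), cow_id = as.character(cow_id),
         start_s = start_s, end_s = end_s, behavior = behavior,
         method = method, year_label = year_label),
    class = "observation_period"
  )
}

#' @export
print.observation_period <- function(x, ...) {
  cat(sprintf("<observation_period> %s (cow %s): [%.0f, %.0f) s, %s, %s\n",
              x$period_id, x$cow_id, x$start_s, x$end_s, x$behavior, x$method))
  invisible(x)
}

#' Period duration in seconds
#' @param period an [observation_period()].
#' @export
period_duration <- function(period) period$end_s - period$start_s

#' Parse an h:m:s timestamp to seconds
#'
#' Accepts `"hh:mm:ss"` (the format field observers use on paper forms) or a
#' plain decimal number of seconds.
#'
#' @param x character or numeric vector.
#' @return numeric vector of seconds.
#' @export
parse_hms <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  vapply(x, function(s) {
    if (grepl(":", s, fixed = TRUE)) {
      p <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
      if (length(p) != 3 || anyNA(p)) stop("cannot parse timestamp: ", s)
      p[1] * 3600 + p[2] * 60 + p[3]
    } else {
      v <- suppressWarnings(as.numeric(s))
      if (is.na(v)) stop("cannot parse timestamp: ", s)
      v
    }
  }, numeric(1), USE.NAMES = FALSE)
}

#' Read a regurgitation event log
#'
#' Reads a comma-separated file with columns `cow_id,period_id,source,time`.
#' Times may be `h:m:s` wall-clock stamps (converted to seconds from the
#' period start, taken as `period$start_s` seconds past the same clock
#' origin) or decimal seconds from period start. Events are sorted; events
#' outside the period bounds are a validation error.
#'
#' @param path file path.
#' @param period the owning [observation_period()].
#' @param dedupe if `TRUE`, silently drop duplicate timestamps instead of
#'   rejecting them.
#' @return an [event_log()].
#' @export
read_event_log <- function(path, period, dedupe = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("cow_id", "period_id", "source", "time")
  if (!all(need %in% names(df))) {
    stop("event log must have columns ", paste(need, collapse = ","))
  }
  if (nrow(df) == 0) {
    return(event_log(period$cow_id, period$period_id, "visual", numeric(0)))
  }
  raw <- parse_hms(df$time)
  # h:m:s stamps are wall clock: shift to the period's own zero
  is_clock <- grepl(":", df$time, fixed = TRUE)
  ev <- ifelse(is_clock, raw - period$start_s, raw)
  if (dedupe) ev <- unique(ev)
  dur <- period_duration(period)
  if (any(ev < 0 | ev > dur)) {
    stop("event outside period bounds [0, ", dur, "] s")
  }
  src <- unique(df$source)
  if (length(src) != 1 || !src %in% c("visual", "sensor")) {
    stop("event log source must be uniformly 'visual' or 'sensor'")
  }
  event_log(df$cow_id[1], df$period_id[1], src, ev)
}

#' @rdname read_event_log
#' @param log an [event_log()] to write (times as decimal seconds).
#' @export
write_event_log <- function(log, path) {
  df <- data.frame(
    cow_id = rep(log$cow_id, length(log$events)),
    period_id = rep(log$period_id, length(log$events)),
    source = rep(log$source, length(log$events)),
    time = fmt_num(log$events)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write observation-period tables
#'
#' Comma-separated files with columns
#' `period_id,cow_id,start,end,behavior,method,year_label`; `start`/`end`
#' accept `h:m:s` or decimal seconds.
#'
#' @param path file path.
#' @return `read_period_table` returns a list of [observation_period()]
#'   objects, named by `period_id`.
#' @export
read_period_table <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("period_id", "cow_id", "start", "end", "behavior", "method")
  if (!all(need %in% names(df))) {
    stop("period table must have columns ", paste(need, collapse = ","))
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    observation_period(
      df$period_id[i], df$cow_id[i],
      parse_hms(df$start[i]), parse_hms(df$end[i]),
      behavior = df$behavior[i], method = df$method[i],
      year_label = if ("year_label" %in% names(df)) df$year_label[i] else ""
    )
  })
  names(out) <- df$period_id
  out
}

#' @rdname read_period_table
#' @param periods a list of [observation_period()] objects.
#' @export
write_period_table <- function(periods, path) {
  if (inherits(periods, "observation_period")) periods <- list(periods)
  df <- do.call(rbind, lapply(periods, function(p) {
    data.frame(period_id = p$period_id, cow_id = p$cow_id,
               start = fmt_num(p$start_s), end = fmt_num(p$end_s),
               behavior = p$behavior, method = p$method,
               year_label = p$year_label)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
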