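#' Sensor traces from the nose-clip respiration sensor
#'
#' A `sensor_trace` holds a uniformly sampled recording of nasal differential
#' pressure (dimensionless sensor units; inhalation negative, exhalation
#' positive) and triaxial acceleration (in g) for one cow, together with the
#' set of streaming gaps. Samples inside a gap are explicitly missing (`NA`),
#' never interpolated.
#'
#' The accelerometer range is +/-1 g on every axis; the x axis is mounted so
#' that its measured value stays within +/-0.25 g.
#'
#' @param cow_id cow identifier (character scalar).
#' @param sampling_rate samples per second, > 0.
#' @param pressure,acc_x,acc_y,acc_z numeric vectors of equal length.
#' @param gaps a [gap_set()] of intervals already masked in the signals.
#' @param start_time optional wall-clock start (character, kept verbatim).
#' @param on_range what to do with out-of-range acceleration samples:
#'   `"error"` rejects the trace, `"warn"` flags and keeps them.
#' @return an object of class `sensor_trace`.
#' @export
sensor_trace <- function(cow_id, sampling_rate, pressure, acc_x, acc_y, acc_z,
                         gaps = gap_set(), start_time = NULL,
                         on_range = c("error", "warn")) {
  on_range <- match.arg(on_range)
  n <- length(pressure)
  if (length(acc_x) != n || length(acc_y) != n || length(acc_z) != n) {
    stop("all four signal sequences must have equal length")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 || sampling_rate <= 0) {
    stop("sampling_rate must be a positive scalar")
  }
  rng_bad <- function(x, lim) any(abs(x) > lim, na.rm = TRUE)
  if (rng_bad(acc_x, 0.25) || rng_bad(acc_y, 1) || rng_bad(acc_z, 1)) {
    msg <- "acceleration samples outside sensor range (|x| <= 0.25 g, |y|,|z| <= 1 g)"
    if (on_range == "error") stop(msg) else warning(msg)
  }
  if (!inherits(gaps, "gap_set")) stop("gaps must be a gap_set")
  x <- list(
    cow_id = as.character(cow_id),
    start_time = start_time,
    sampling_rate = sampling_rate,
    pressure = as.numeric(pressure),
    acc_x = as.numeric(acc_x),
    acc_y = as.numeric(acc_y),
    acc_z = as.numeric(acc_z),
    gaps = gaps
  )
  class(x) <- "sensor_trace"
  x
}

#' @export
print.sensor_trace <- function(x, ...) {
  cat(sprintf(
    "<sensor_trace> cow %s: %d samples @ %g Hz (%.1f s), %d gap(s) (%.1f s missing)\n",
    x$cow_id, trace_length(x), x$sampling_rate, trace_duration(x),
    nrow(x$gaps), gap_total(x$gaps)
  ))
  invisible(x)
}

#' Trace geometry helpers
#' @param trace a [sensor_trace()].
#' @return `trace_length`: number of samples; `trace_duration`: duration in
#'   seconds; `trace_times`: sample times in seconds from trace start.
#' @export
trace_length <- function(trace) length(trace$pressure)

#' @rdname trace_length
#' @export
trace_duration <- function(trace) trace_length(trace) / trace$sampling_rate

#' @rdname trace_length
#' @export
trace_times <- function(trace) {
  (seq_len(trace_length(trace)) - 1) / trace$sampling_rate
}

#' Mask streaming gaps in a trace
#'
#' Sets every sample whose time falls inside a gap interval to `NA` in all
#' four channels and merges the intervals into the trace's gap bookkeeping.
#' Masking is idempotent; overlapping input intervals are merged to canonical
#' form first.
#'
#' @param trace a [sensor_trace()].
#' @param gaps a [gap_set()] of intervals to mask, in seconds from trace start.
#' @return the masked `sensor_trace`.
#' @export
mask_gaps <- function(trace, gaps) {
  if (nrow(gaps) > 0 && max(gaps$end_s) > trace_duration(trace) + 1e-9) {
    stop("gap interval exceeds trace duration")
  }
  idx <- in_gaps(trace_times(trace), gaps)
  for (ch in c("pressure", "acc_x", "acc_y", "acc_z")) {
    trace[[ch]][idx] <- NA_real_
  }
  trace$gaps <- gap_merge(trace$gaps, gaps)
  trace
}

#' Read and write sensor trace files
#'
#' Traces are stored as comma-separated text with a `#`-prefixed metadata
#' line (`cow_id`, `sampling_rate`, `start_time`, and the gap intervals) and
#' fixed column names `time_s,pressure,acc_x,acc_y,acc_z`. The sampling rate
#' is file-level metadata, never inferred per row; if the metadata line is
#' absent the dialect default applies.
#'
#' @param path file path.
#' @param dialect a list of options: `sampling_rate` (default 10, used when
#'   the file carries no metadata line) and `on_range` (`"error"` or
#'   `"warn"`, see [sensor_trace()]).
#' @return `read_trace` returns a validated [sensor_trace()];
#'   `write_trace` returns `path` invisibly. Numeric values round-trip
#'   exactly.
#' @export
read_trace <- function(path, dialect = list()) {
  if (!file.exists(path)) stop("no such file: ", path)
  fs_default <- dialect$sampling_rate %||% 10
  on_range <- dialect$on_range %||% "error"
  first <- readLines(path, n = 1)
  meta <- list()
  skip <- 0
  if (startsWith(first, "#")) {
    meta <- parse_meta_line(first)
    skip <- 1
  }
  df <- tryCatch(
    utils::read.csv(path, skip = skip, colClasses = "numeric"),
    error = function(e) stop("malformed trace file ", path, ": ", conditionMessage(e))
  )
  need <- c("time_s", "pressure", "acc_x", "acc_y", "acc_z")
  if (!all(need %in% names(df))) {
    stop("trace file must have columns ", paste(need, collapse = ","))
  }
  bad <- which(diff(df$time_s) <= 0)
  if (length(bad) > 0) {
    stop("non-monotone time at data row ", bad[1] + 1, " of ", path)
  }
  fs <- as.numeric(meta$sampling_rate %||% fs_default)
  if (nrow(df) > 1) {
    step <- diff(df$time_s)
    if (max(abs(step - 1 / fs)) > 1e-6 / fs) {
      stop("time column of ", path, " is not uniform at the stated sampling rate")
    }
  }
  gaps <- if (!is.null(meta$gaps) && nzchar(meta$gaps)) {
    iv <- do.call(rbind, lapply(strsplit(meta$gaps, ";")[[1]], function(s) {
      as.numeric(strsplit(s, ":")[[1]])
    }))
    gap_set(iv[, 1], iv[, 2])
  } else {
    gap_set()
  }
  sensor_trace(
    cow_id = meta$cow_id %||% "unknown",
    sampling_rate = fs,
    pressure = df$pressure, acc_x = df$acc_x,
    acc_y = df$acc_y, acc_z = df$acc_z,
    gaps = gaps,
    start_time = if (nzchar(meta$start_time %||% "")) meta$start_time else NULL,
    on_range = on_range
  )
}

#' @rdname read_trace
#' @param trace a [sensor_trace()] to write.
#' @export
write_trace <- function(trace, path) {
  gaps_str <- if (nrow(trace$gaps) > 0) {
    paste(sprintf("%s:%s", fmt_num(trace$gaps$start_s), fmt_num(trace$gaps$end_s)),
          collapse = ";")
  } else ""
  meta <- sprintf(
    "# cow_id=%s sampling_rate=%s start_time=%s gaps=%s",
    trace$cow_id, fmt_num(trace$sampling_rate), trace$start_time %||% "", gaps_str
  )
  df <- data.frame(
    time_s = fmt_num(trace_times(trace)),
    pressure = fmt_num(trace$pressure),
    acc_x = fmt_num(trace$acc_x),
    acc_y = fmt_num(trace$acc_y),
    acc_z = fmt_num(trace$acc_z)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_meta_line <- function(line) {
  line <- sub("^#\\s*", "", line)
  parts <- strsplit(line, "\\s+")[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) >= 1) out[[p[1]]] <- if (length(p) > 1) p[2] else ""
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
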