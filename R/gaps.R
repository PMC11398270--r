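#' Streaming-gap interval sets
#'
#' A `gap_set` records the half-open intervals `[start_s, end_s)`, in seconds
#' from the start of an observation period, during which the sensor stored no
#' samples (typically because data were uploaded every 30 s without on-device
#' buffering). Intervals are kept in canonical form: sorted, non-overlapping,
#' positive length.
#'
#' @param start_s,end_s numeric vectors of equal length; interval bounds in
#'   seconds. Overlapping or abutting intervals are merged.
#' @return an object of class `gap_set`: a data.frame with columns `start_s`
#'   and `end_s`.
#' @examples
#' g <- gap_set(c(10, 15), c(20, 25))  # merged to [10, 25)
#' gap_total(g)
#' @export
gap_set <- function(start_s = numeric(0), end_s = numeric(0)) {
  if (length(start_s) != length(end_s)) {
    stop("start_s and end_s must have equal length")
  }
  if (any(!is.finite(start_s)) || any(!is.finite(end_s))) {
    stop("gap bounds must be finite")
  }
  if (any(start_s < 0)) stop("gap start times must be non-negative")
  if (any(end_s < start_s)) stop("gap intervals must have non-negative length")
  keep <- end_s > start_s
  start_s <- start_s[keep]
  end_s <- end_s[keep]
  if (length(start_s) > 1) {
    o <- order(start_s, end_s)
    start_s <- start_s[o]
    end_s <- end_s[o]
    # union of intervals
    ms <- start_s[1]
    me <- end_s[1]
    outs <- numeric(0)
    oute <- numeric(0)
    for (i in seq_along(start_s)[-1]) {
      if (start_s[i] <= me) {
        me <- max(me, end_s[i])
      } else {
        outs <- c(outs, ms)
        oute <- c(oute, me)
        ms <- start_s[i]
        me <- end_s[i]
      }
    }
    start_s <- c(outs, ms)
    end_s <- c(oute, me)
  }
  structure(
    data.frame(start_s = start_s, end_s = end_s),
    class = c("gap_set", "data.frame")
  )
}

#' @export
print.gap_set <- function(x, ...) {
  cat(sprintf("<gap_set> %d interval(s), %.1f s total\n", nrow(x), gap_total(x)))
  if (nrow(x) > 0) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Total gap duration in seconds
#' @param gaps a [gap_set()].
#' @return numeric scalar, the summed length of all gap intervals.
#' @export
gap_total <- function(gaps) {
  if (nrow(gaps) == 0) return(0)
  sum(gaps$end_s - gaps$start_s)
}

#' Which times fall inside a gap?
#'
#' Membership uses the half-open convention `[start_s, end_s)`.
#'
#' @param times numeric vector of times in seconds from period start.
#' @param gaps a [gap_set()].
#' @return logical vector parallel to `times`.
#' @export
in_gaps <- function(times, gaps) {
  res <- rep(FALSE, length(times))
  for (i in seq_len(nrow(gaps))) {
    res <- res | (times >= gaps$start_s[i] & times < gaps$end_s[i])
  }
  res
}

#' Merge two gap sets
#' @param a,b [gap_set()] objects.
#' @return their interval union as a `gap_set`.
#' @export
gap_merge <- function(a, b) {
  gap_set(c(a$start_s, b$start_s), c(a$end_s, b$end_s))
}

#' Count whole minutes overlapped by gaps
#'
#' Minutes are counted from time 0 in the period's own clock; minute `k`
#' covers `[60k, 60(k+1))`. A minute is gap-affected if any part of a gap
#' interval intersects it.
#'
#' @param gaps a [gap_set()].
#' @param duration_s period duration in seconds.
#' @return integer count of gap-affected minutes.
#' @export
gap_minutes <- function(gaps, duration_s) {
  n_min <- ceiling(duration_s / 60)
  if (n_min == 0 || nrow(gaps) == 0) return(0L)
  affected <- logical(n_min)
  for (i in seq_len(nrow(gaps))) {
    lo <- floor(gaps$start_s[i] / 60) + 1
    hi <- ceiling(gaps$end_s[i] / 60)
    hi <- min(hi, n_min)
    if (lo <= hi) affected[lo:hi] <- TRUE
  }
  sum(affected)
}

#' Read / write gap interval files
#'
#' Plain comma-separated files with columns `start_s,end_s`.
#'
#' @param path file path.
#' @return `read_gap_set` returns a [gap_set()]; `write_gap_set` returns
#'   `path` invisibly.
#' @export
read_gap_set <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!all(c("start_s", "end_s") %in% names(df))) {
    stop("gap file must have columns start_s,end_s")
  }
  gap_set(df$start_s, df$end_s)
}

#' @rdname read_gap_set
#' @param gaps a [gap_set()] to write.
#' @export
write_gap_set <- function(gaps, path) {
  df <- data.frame(start_s = fmt_num(gaps$start_s), end_s = fmt_num(gaps$end_s))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# full-precision decimal formatting so that write/read round-trips exactly
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}
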