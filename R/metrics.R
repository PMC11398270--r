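#' Rumination-cycle durations
#'
#' The duration of a rumination cycle is the difference between two
#' successive regurgitations. Differences are taken within one observation
#' period only, never across periods, and never across a streaming gap that
#' interrupts the log (two events separated by unobserved time are not one
#' cycle).
#'
#' @param logs a list of [event_log()] objects (one per period).
#' @param periods a list of [observation_period()] objects named by
#'   `period_id`, covering every log.
#' @param gaps optional list of [gap_set()] objects named by `period_id`;
#'   differences straddling a gap are dropped.
#' @return a named list, one numeric vector of durations (seconds) per
#'   cow id. Logs with fewer than two events contribute nothing.
#' @export
cycle_durations <- function(logs, periods, gaps = NULL) {
  if (inherits(logs, "event_log")) logs <- list(logs)
  out <- list()
  for (log in logs) {
    if (is.null(periods[[log$period_id]])) {
      stop("no observation period for period_id ", log$period_id)
    }
    ev <- log$events
    if (length(ev) < 2) next
    d <- diff(ev)
    g <- gaps[[log$period_id]]
    if (!is.null(g) && nrow(g) > 0) {
      straddles <- vapply(seq_along(d), function(i) {
        any(g$start_s < ev[i + 1] & g$end_s > ev[i])
      }, logical(1))
      d <- d[!straddles]
    }
    out[[log$cow_id]] <- c(out[[log$cow_id]], d)
  }
  out
}

#' Summarize cycle durations
#'
#' Pooled and per-cow summaries of rumination-cycle durations. The SD of a
#' single duration is undefined and reported as `NA`. A Shapiro-Wilk
#' normality p-value is attached descriptively (the pooled distribution is
#' typically non-normal until outlier cows are removed); it drives no
#' decision.
#'
#' @param durations a named per-cow list of duration vectors, as returned by
#'   [cycle_durations()].
#' @return an object of class `cycle_stats`: list with `n_cycles`, `mean_s`,
#'   `sd_s`, `median_s`, `min_s`, `max_s`, `normality_p`, and a `per_cow`
#'   data.frame (`cow_id`, `n`, `mean_s`, `sd_s`).
#' @export
summarize_cycles <- function(durations) {
  pooled <- unlist(durations, use.names = FALSE)
  if (length(pooled) == 0) stop("no cycle durations to summarize")
  per_cow <- do.call(rbind, lapply(names(durations), function(cw) {
    d <- durations[[cw]]
    data.frame(cow_id = cw, n = length(d), mean_s = mean(d),
               sd_s = if (length(d) > 1) stats::sd(d) else NA_real_)
  }))
  norm_p <- if (length(pooled) >= 3 && length(pooled) <= 5000 &&
                stats::sd(pooled) > 0) {
    stats::shapiro.test(pooled)$p.value
  } else {
    NA_real_
  }
  structure(
    list(n_cycles = length(pooled), mean_s = mean(pooled),
         sd_s = if (length(pooled) > 1) stats::sd(pooled) else NA_real_,
         median_s = stats::median(pooled), min_s = min(pooled),
         max_s = max(pooled), normality_p = norm_p, per_cow = per_cow),
    class = "cycle_stats"
  )
}

#' @export
print.cycle_stats <- function(x, ...) {
  cat(sprintf(
    "<cycle_stats> n = %d cycles: mean %.2f +/- %.2f s, median %.1f s, range [%.1f, %.1f] s\n",
    x$n_cycles, x$mean_s, x$sd_s, x$median_s, x$min_s, x$max_s
  ))
  if (!is.na(x$normality_p)) {
    cat(sprintf("  Shapiro-Wilk normality p = %.3g (descriptive)\n", x$normality_p))
  }
  cat(sprintf("  %d cow(s)\n", nrow(x$per_cow)))
  invisible(x)
}

#' Flag cows with nonphysiological mean cycle durations
#'
#' A cow whose mean cycle duration falls outside the physiological range is
#' flagged (e.g. a cow averaging about two minutes per cycle). Flags are
#' advisory: recomputation excluding flagged cows is an explicit second call
#' to [summarize_cycles()].
#'
#' @param per_cow the `per_cow` data.frame from a [summarize_cycles()]
#'   result (or a compatible data.frame with `cow_id` and `mean_s`).
#' @param physiological_range length-2 numeric, seconds.
#' @return the `per_cow` data.frame with an added logical column `flagged`.
#' @export
flag_outlier_cows <- function(per_cow, physiological_range = c(35, 90)) {
  if (inherits(per_cow, "cycle_stats")) per_cow <- per_cow$per_cow
  per_cow$flagged <- per_cow$mean_s < physiological_range[1] |
    per_cow$mean_s > physiological_range[2]
  per_cow
}

#' Rumination time from an event log
#'
#' Events are partitioned into bouts wherever the inter-event interval
#' exceeds `bout_gap_s`; within each bout the rumination time is the span
#' from first to last event plus an end-of-bout allowance for the final
#' cycle (one mean cycle length by default).
#'
#' @param log an [event_log()].
#' @param bout_gap_s bout-splitting threshold in seconds.
#' @param allowance_s seconds credited for the final cycle of each bout.
#' @return total rumination time in seconds (0 for an empty log).
#' @export
rumination_time <- function(log, bout_gap_s = 180, allowance_s = 59.27) {
  ev <- log$events
  if (length(ev) == 0) return(0)
  breaks <- which(diff(ev) > bout_gap_s)
  bout_start <- c(1, breaks + 1)
  bout_end <- c(breaks, length(ev))
  sum(ev[bout_end] - ev[bout_start]) + length(bout_start) * allowance_s
}

#' Write a cycle-statistics report
#'
#' Emits the per-cow table as comma-separated text and the pooled summary as
#' a short human-readable block.
#'
#' @param stats a [summarize_cycles()] result.
#' @param path base file path; `<path>.csv` and `<path>.txt` are written.
#' @return invisibly, the two paths written.
#' @export
write_cycle_report <- function(stats, path) {
  csv <- paste0(path, ".csv")
  txt <- paste0(path, ".txt")
  utils::write.csv(stats$per_cow, csv, row.names = FALSE, quote = FALSE)
  lines <- c(
    sprintf("cycles: %d", stats$n_cycles),
    sprintf("mean_s: %.2f", stats$mean_s),
    sprintf("sd_s: %.2f", stats$sd_s),
    sprintf("median_s: %.2f", stats$median_s),
    sprintf("min_s: %.2f", stats$min_s),
    sprintf("max_s: %.2f", stats$max_s)
  )
  writeLines(lines, txt)
  invisible(c(csv, txt))
}
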