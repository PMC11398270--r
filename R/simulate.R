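#' Simulation configuration
#'
#' Parameters of the seeded trace simulator. The defaults encode the study
#' conditions the analysis assumes: a resting respiration rate of about 30
#' breaths/min, rumination cycles drawn from a truncated normal with mean
#' 59.27 s, SD 9.01 s and minimum 35 s, a near-zero z-orientation plateau of
#' 2-4 s at each regurgitation followed by a prolonged breath, and optional
#' streaming gaps aligned to 30-s upload windows.
#'
#' @param seed integer seed; mandatory, drives every random draw.
#' @param duration_s trace duration in seconds.
#' @param sampling_rate samples per second.
#' @param respiration_rate breaths per minute.
#' @param breath_amplitude pressure amplitude, arbitrary sensor units.
#' @param amplitude_jitter per-breath amplitude CV (fraction).
#' @param period_jitter per-breath period CV (fraction).
#' @param pressure_noise_sd additive pressure noise SD (sensor units).
#' @param cycle_mean_s,cycle_sd_s,cycle_min_s rumination-cycle renewal
#'   parameters in seconds (normal mean/SD, truncated below at the minimum).
#' @param plateau_range_s length-2 interval; regurgitation z-plateau length
#'   is uniform over it (seconds).
#' @param pause_factor factor by which the post-regurgitation breath is
#'   widened (multiple of its nominal period).
#' @param pause_prob probability that the widened breath is present.
#' @param z_baseline resting z-orientation (g) away from the near-zero band.
#' @param z_noise_sd accelerometer noise SD (g).
#' @param plateau_noise_sd z noise SD during the plateau (g).
#' @param distractor_rate distractor motions per minute.
#' @param gap_loss_prob per-upload-window probability of a streaming loss.
#' @param gap_loss_length_s length of each lost sub-interval (seconds,
#'   capped at the window length).
#' @param upload_interval_s upload window length (seconds).
#' @param behavior `"ruminating"` or `"negative_control"`.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       duration_s = 600,
                       sampling_rate = 10,
                       respiration_rate = 30,
                       breath_amplitude = 1,
                       amplitude_jitter = 0.1,
                       period_jitter = 0.1,
                       pressure_noise_sd = 0.05,
                       cycle_mean_s = 59.27,
                       cycle_sd_s = 9.01,
                       cycle_min_s = 35,
                       plateau_range_s = c(2, 4),
                       pause_factor = 2,
                       pause_prob = 1,
                       z_baseline = 0.5,
                       z_noise_sd = 0.02,
                       plateau_noise_sd = 0.01,
                       distractor_rate = 1,
                       gap_loss_prob = 0,
                       gap_loss_length_s = 30,
                       upload_interval_s = 30,
                       behavior = c("ruminating", "negative_control")) {
  behavior <- match.arg(behavior)
  if (missing(seed) || is.null(seed) || is.na(seed)) stop("seed is mandatory")
  if (length(plateau_range_s) != 2 || plateau_range_s[1] > plateau_range_s[2] ||
      plateau_range_s[1] <= 0) {
    stop("plateau_range_s must be an increasing positive interval")
  }
  if (!(cycle_mean_s > cycle_min_s && cycle_min_s > plateau_range_s[2])) {
    stop("need cycle_mean_s > cycle_min_s > upper plateau bound")
  }
  for (nm in c("duration_s", "sampling_rate", "respiration_rate", "breath_amplitude")) {
    if (get(nm) <= 0) stop(nm, " must be positive")
  }
  if (gap_loss_prob < 0 || gap_loss_prob > 1) stop("gap_loss_prob must be in [0, 1]")
  cfg <- list(
    seed = as.integer(seed), duration_s = duration_s, sampling_rate = sampling_rate,
    respiration_rate = respiration_rate, breath_amplitude = breath_amplitude,
    amplitude_jitter = amplitude_jitter, period_jitter = period_jitter,
    pressure_noise_sd = pressure_noise_sd, cycle_mean_s = cycle_mean_s,
    cycle_sd_s = cycle_sd_s, cycle_min_s = cycle_min_s,
    plateau_range_s = plateau_range_s, pause_factor = pause_factor,
    pause_prob = pause_prob, z_baseline = z_baseline, z_noise_sd = z_noise_sd,
    plateau_noise_sd = plateau_noise_sd, distractor_rate = distractor_rate,
    gap_loss_prob = gap_loss_prob, gap_loss_length_s = gap_loss_length_s,
    upload_interval_s = upload_interval_s, behavior = behavior
  )
  class(cfg) <- "sim_config"
  cfg
}

# truncated-normal renewal draw (resample until >= lo)
rtnorm1 <- function(mean, sd, lo) {
  if (sd == 0) {
    if (mean < lo) stop("degenerate cycle distribution below the minimum")
    return(mean)
  }
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo) return(x)
  }
}

# render the biphasic pressure waveform from a breath table
# (onset/inhal_s/exhal_s/amp per breath; inhalation negative, exhalation
# positive). Returns a vector of n samples at fs.
render_pressure <- function(breaths, n, fs) {
  p <- numeric(n)
  t <- (seq_len(n) - 1) / fs
  onset <- cumsum(c(0, breaths$inhal_s + breaths$exhal_s))[seq_len(nrow(breaths))]
  for (i in seq_len(nrow(breaths))) {
    o <- onset[i]
    Ti <- breaths$inhal_s[i]
    Te <- breaths$exhal_s[i]
    if (o >= n / fs) break
    k0 <- max(1L, ceiling(o * fs + 1 - 1e-9))
    k1 <- min(n, ceiling((o + Ti + Te) * fs - 1e-9))
    if (k0 > k1) next
    tt <- t[k0:k1] - o
    seg <- ifelse(tt < Ti,
                  -breaths$amp[i] * sin(pi * tt / Ti),
                  breaths$amp[i] * sin(pi * (tt - Ti) / Te))
    p[k0:k1] <- seg
  }
  p
}

breath_onsets_from_table <- function(breaths) {
  cumsum(c(0, breaths$inhal_s + breaths$exhal_s))[seq_len(nrow(breaths))]
}

#' Simulate quasi-periodic breathing
#'
#' Generates a biphasic pressure waveform (inhalation negative, exhalation
#' positive) at the configured respiration rate, with per-breath period and
#' amplitude jitter plus additive noise, and accelerometer channels at their
#' baselines with noise. The returned trace carries the breath table as an
#' attribute so that later injection steps can reshape individual breaths.
#'
#' @param config a [sim_config()].
#' @return a [sensor_trace()].
#' @export
simulate_breathing <- function(config) {
  set.seed(config$seed)
  fs <- config$sampling_rate
  dur <- config$duration_s
  T0 <- 60 / config$respiration_rate
  if (dur < T0) stop("duration shorter than one breath period")
  n <- round(dur * fs)
  # enough breaths to cover the trace even after pause widenings
  n_breaths <- ceiling((dur + 120) / T0 * (1 + 4 * config$period_jitter))
  periods <- T0 * pmax(0.3, 1 + config$period_jitter * stats::rnorm(n_breaths))
  amps <- config$breath_amplitude *
    pmax(0.1, 1 + config$amplitude_jitter * stats::rnorm(n_breaths))
  breaths <- data.frame(inhal_s = periods / 2, exhal_s = periods / 2, amp = amps)
  noise <- stats::rnorm(n, 0, config$pressure_noise_sd)
  pressure <- render_pressure(breaths, n, fs) + noise
  acc_x <- pmin(0.25, pmax(-0.25, 0.05 + stats::rnorm(n, 0, config$z_noise_sd / 2)))
  acc_y <- pmin(1, pmax(-1, 0.3 + stats::rnorm(n, 0, config$z_noise_sd)))
  acc_z <- pmin(1, pmax(-1, config$z_baseline + stats::rnorm(n, 0, config$z_noise_sd)))
  tr <- sensor_trace("sim", fs, pressure, acc_x, acc_y, acc_z)
  attr(tr, "breaths") <- breaths
  attr(tr, "pressure_noise") <- noise
  tr
}

#' Inject regurgitation signatures
#'
#' Draws regurgitation times as a renewal process with inter-event intervals
#' from Normal(`cycle_mean_s`, `cycle_sd_s`) truncated below at
#' `cycle_min_s`. At each event the z channel is driven into the near-zero
#' band for a plateau of length uniform in `plateau_range_s`, and (with
#' probability `pause_prob`) the first breath starting after the plateau is
#' widened by `pause_factor`, with the extra time put on its exhalation or
#' inhalation at random.
#'
#' @param trace a trace from [simulate_breathing()].
#' @param config a [sim_config()] with `behavior = "ruminating"`.
#' @return a list with elements `trace` (modified [sensor_trace()]) and
#'   `truth` (ground-truth [event_log()], source `"visual"`; event time =
#'   plateau start).
#' @export
inject_regurgitations <- function(trace, config) {
  if (config$behavior != "ruminating") {
    stop("regurgitations are only injected into ruminating trials")
  }
  set.seed(config$seed + 1L)
  fs <- trace$sampling_rate
  n <- trace_length(trace)
  dur <- trace_duration(trace)
  margin <- config$plateau_range_s[2] + 12
  events <- numeric(0)
  t <- stats::runif(1, 5, 5 + config$cycle_mean_s)
  while (t < dur - margin) {
    events <- c(events, t)
    t <- t + rtnorm1(config$cycle_mean_s, config$cycle_sd_s, config$cycle_min_s)
  }
  if (length(events) == 0) {
    warning("duration too short for a single rumination cycle")
    return(list(trace = trace,
                truth = event_log(trace$cow_id, "sim", "visual", numeric(0))))
  }
  breaths <- attr(trace, "breaths")
  if (is.null(breaths)) stop("trace carries no breath table; simulate_breathing first")
  tt <- trace_times(trace)
  for (e in events) {
    L <- stats::runif(1, config$plateau_range_s[1], config$plateau_range_s[2])
    idx <- tt >= e & tt < e + L
    z <- stats::rnorm(sum(idx), 0, config$plateau_noise_sd)
    trace$acc_z[idx] <- pmin(0.03, pmax(-0.03, z))
    if (stats::runif(1) < config$pause_prob) {
      onsets <- breath_onsets_from_table(breaths)
      k <- which(onsets >= e + L)[1]
      if (!is.na(k)) {
        # pause length is set by the regurgitation, not by the breath that
        # happens to follow: stretch to pause_factor x the nominal period
        target <- config$pause_factor * 60 / config$respiration_rate
        extra <- max(0, target - (breaths$inhal_s[k] + breaths$exhal_s[k]))
        if (stats::runif(1) < 0.5) {
          breaths$exhal_s[k] <- breaths$exhal_s[k] + extra
        } else {
          breaths$inhal_s[k] <- breaths$inhal_s[k] + extra
        }
      }
    }
  }
  trace$pressure <- render_pressure(breaths, n, fs) + attr(trace, "pressure_noise")
  attr(trace, "breaths") <- breaths
  attr(trace, "truth_events") <- events
  list(trace = trace, truth = event_log(trace$cow_id, "sim", "visual", events))
}

#' Inject distractor motion
#'
#' Adds the kinds of head motion seen while a cow dozes, feeds, stands or
#' lies without ruminating: brief z excursions into the near-zero band
#' (shorter than the 2-s signature minimum), longer excursions that stop
#' short of the band, and isolated pressure irregularities. None satisfies
#' the full regurgitation signature. In ruminating trials distractors avoid
#' the neighbourhood of true events so the injected signatures stay intact.
#'
#' @param trace a [sensor_trace()].
#' @param config a [sim_config()].
#' @return the modified [sensor_trace()].
#' @export
inject_distractors <- function(trace, config) {
  if (config$distractor_rate <= 0) return(trace)
  set.seed(config$seed + 2L)
  dur <- trace_duration(trace)
  tt <- trace_times(trace)
  n_d <- stats::rpois(1, config$distractor_rate * dur / 60)
  if (n_d == 0) return(trace)
  truth <- attr(trace, "truth_events") %||% numeric(0)
  placed <- numeric(0)
  for (i in seq_len(n_d)) {
    for (try in 1:50) {
      pos <- stats::runif(1, 2, dur - 8)
      ok <- all(abs(pos - truth) > 10) && all(abs(pos - placed) > 8)
      if (ok) break
    }
    if (!ok) next
    placed <- c(placed, pos)
    if (stats::runif(1) < 0.5) {
      # short dip into the near-zero band: below the signature minimum
      d <- stats::runif(1, 0.5, 1.5)
      idx <- tt >= pos & tt < pos + d
      trace$acc_z[idx] <- stats::rnorm(sum(idx), 0, config$plateau_noise_sd)
    } else {
      # longer excursion that does not reach the band
      d <- stats::runif(1, 2, 5)
      idx <- tt >= pos & tt < pos + d
      trace$acc_z[idx] <- 0.2 + stats::rnorm(sum(idx), 0, config$z_noise_sd)
    }
    # pressure irregularity: a half-second bump
    idb <- tt >= pos & tt < pos + 0.5
    trace$acc_y[idb] <- pmin(1, pmax(-1, trace$acc_y[idb] + 0.2))
    trace$pressure[idb] <- trace$pressure[idb] +
      stats::runif(1, 0.3, 0.6) * config$breath_amplitude
  }
  trace$acc_z <- pmin(1, pmax(-1, trace$acc_z))
  trace
}

#' Apply streaming gaps
#'
#' Emulates the 30-s upload regime in which the sensor cannot buffer: for
#' each upload window, with probability `gap_loss_prob` a sub-interval of
#' length `gap_loss_length_s` is lost. With loss probability 0 (continuous
#' streaming) the trace is returned unchanged with an empty gap set.
#'
#' @param trace a [sensor_trace()].
#' @param config a [sim_config()].
#' @return a list with elements `trace` (masked) and `gaps` (a [gap_set()]).
#' @export
apply_streaming_gaps <- function(trace, config) {
  set.seed(config$seed + 3L)
  dur <- trace_duration(trace)
  if (config$gap_loss_prob <= 0) {
    return(list(trace = trace, gaps = gap_set()))
  }
  w <- config$upload_interval_s
  starts <- seq(0, dur - 1e-9, by = w)
  gs <- numeric(0)
  ge <- numeric(0)
  for (s in starts) {
    wlen <- min(w, dur - s)
    if (stats::runif(1) < config$gap_loss_prob) {
      len <- min(config$gap_loss_length_s, wlen)
      off <- if (wlen - len > 0) stats::runif(1, 0, wlen - len) else 0
      gs <- c(gs, s + off)
      ge <- c(ge, s + off + len)
    }
  }
  gaps <- gap_set(gs, ge)
  list(trace = mask_gaps(trace, gaps), gaps = gaps)
}

#' Simulate a full observation trial
#'
#' Composes breathing, regurgitation injection (ruminating trials only),
#' distractors and streaming gaps into one reproducible trial with period
#' metadata and a ground-truth event log.
#'
#' @param config a [sim_config()].
#' @return an object of class `simulated_trial`: a list with elements
#'   `trace`, `truth` (an [event_log()], empty for negative controls),
#'   `gaps` (a [gap_set()]) and `period` (an [observation_period()]).
#' @export
simulate_trial <- function(config) {
  trace <- simulate_breathing(config)
  if (config$behavior == "ruminating") {
    inj <- inject_regurgitations(trace, config)
    trace <- inj$trace
    truth <- inj$truth
  } else {
    truth <- event_log(trace$cow_id, "sim", "visual", numeric(0))
  }
  trace <- inject_distractors(trace, config)
  g <- apply_streaming_gaps(trace, config)
  period <- observation_period(
    period_id = paste0("sim", config$seed), cow_id = trace$cow_id,
    start_s = 0, end_s = trace_duration(trace),
    behavior = config$behavior, method = "direct",
    year_label = if (config$gap_loss_prob > 0) "streamed-30s" else "continuous"
  )
  truth$period_id <- period$period_id
  structure(
    list(trace = g$trace, truth = truth, gaps = g$gaps, period = period),
    class = "simulated_trial"
  )
}

#' @export
print.simulated_trial <- function(x, ...) {
  cat(sprintf(
    "<simulated_trial> %s: %.0f s, %s, %d truth event(s), %.0f s of gaps\n",
    x$period$period_id, period_duration(x$period), x$period$behavior,
    length(x$truth$events), gap_total(x$gaps)
  ))
  invisible(x)
}
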