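# Independent oracles used by the tests. These deliberately re-derive
# quantities by brute force / direct scanning, independent of the package's
# own code paths.

# exhaustive one-to-one matching: maximum number of pairs, then minimum
# total |dt|; feasible for logs with <= 6 events
oracle_match <- function(rv, sv, tol) {
  best <- list(pairs = -1L, total = Inf)
  used <- logical(length(sv))
  rec <- function(i, pairs, total) {
    if (i > length(rv)) {
      if (pairs > best$pairs ||
          (pairs == best$pairs && total < best$total)) {
        best <<- list(pairs = pairs, total = total)
      }
      return(invisible())
    }
    rec(i + 1L, pairs, total)
    for (j in seq_along(sv)) {
      d <- abs(rv[i] - sv[j])
      if (!used[j] && d <= tol) {
        used[j] <<- TRUE
        rec(i + 1L, pairs + 1L, total + d)
        used[j] <<- FALSE
      }
    }
  }
  rec(1L, 0L, 0)
  best
}

# domain-realistic random matching instance: reference events are a renewal
# process with >= 35 s spacing; sensor events are jittered copies with
# drops plus a few spurious events
random_match_instance <- function() {
  n_ref <- sample(0:6, 1)
  ref <- if (n_ref > 0) 10 + cumsum(stats::runif(n_ref, 35, 90)) else numeric(0)
  sens <- numeric(0)
  for (r in ref) {
    if (stats::runif(1) < 0.75) sens <- c(sens, r + stats::runif(1, -8, 8))
  }
  n_spur <- sample(0:2, 1)
  if (n_spur > 0) {
    sens <- c(sens, stats::runif(n_spur, 0, max(c(ref, 60)) + 30))
  }
  sens <- sort(unique(pmax(0, sens)))
  if (length(sens) > 6) sens <- sens[seq_len(6)]
  list(ref = ref, sensor = sens)
}

# threshold scan on a raw z channel: maximal runs inside the band
band_runs <- function(z, fs, center = 0, band = 0.05) {
  inb <- !is.na(z) & abs(z - center) <= band
  r <- rle(inb)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  data.frame(start_s = (starts[keep] - 1) / fs, len_s = r$lengths[keep] / fs)
}

# pointwise interval-union membership
union_member <- function(t, starts, ends) {
  vapply(t, function(x) any(x >= starts & x < ends), logical(1))
}

make_log <- function(events, source = "visual", period = "p1", cow = "c1") {
  event_log(cow, period, source, events)
}
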