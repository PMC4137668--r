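# Fixture builders used across test files. All fixtures are generated in
# code; nothing is read from disk.

# Epoch on the standard 30 s / 25 Hz grid (time relative to cue onset at
# 12 s after the marker).
make_epoch <- function(left, right, fs = 25, trial_index = 1L,
                       epoch_start_s = 0, cue_offset_s = 12) {
  n <- length(left)
  time <- epoch_start_s - cue_offset_s + (seq_len(n) - 1L) / fs
  ftcdlat:::new_epoch(trial_index, time, left, right)
}

# Raised-cosine pulsatile envelope around a given level.
pulsatile_series <- function(n, fs = 25, hr_hz = 1.5, level = 100,
                             amp = 20, phase = 0) {
  t <- (seq_len(n) - 1) / fs
  level + amp * 0.5 * (1 - cos(2 * pi * hr_hz * t + phase))
}

make_pulsatile_epoch <- function(n = 750, fs = 25, hr_hz = 1.5, level = 100,
                                 amp = 20) {
  make_epoch(pulsatile_series(n, fs, hr_hz, level, amp),
             pulsatile_series(n, fs, hr_hz, level, amp, phase = 0.3), fs = fs)
}

# Quiet simulation parameter sets.
quiet_params <- function(...) {
  defaults <- list(noise_sd = 0, drift_sd = 0, shared_drift_sd = 0,
                   amp_jitter_sd = 0, heart_rate_sd_bpm = 0,
                   p_dropout_trial = 0, p_spike_trial = 0)
  do.call(simulation_params, utils::modifyList(defaults, list(...)))
}

# Fast low-rate variant: simulate directly at the 25 Hz analysis rate so
# that injected artifacts are not smeared by the anti-alias filter.
quiet_params_25 <- function(...) quiet_params(fs_raw = 25, ...)

# Independent exhaustive-loop implementation of the LI computation:
# plain-loop averaging, peak scan over every POI sample (max |diff|,
# earliest tie), plain-loop window means. Used as the oracle route.
oracle_li <- function(epochs, spec = epoch_spec()) {
  acc <- Filter(function(e) e$status %in% c("accepted", "corrected"), epochs)
  stopifnot(length(acc) >= 1)
  nt <- length(acc[[1]]$time)
  d <- numeric(nt)
  for (i in seq_len(nt)) {
    s <- 0
    for (e in acc) s <- s + (e$left[i] - e$right[i])
    d[i] <- s / length(acc)
  }
  time <- acc[[1]]$time
  best <- -Inf; peak <- NA_real_
  for (i in seq_len(nt)) {
    if (time[i] >= spec$poi_s[1] - 1e-9 && time[i] <= spec$poi_s[2] + 1e-9) {
      if (abs(d[i]) > best) { best <- abs(d[i]); peak <- time[i] }
    }
  }
  half <- spec$li_window_s / 2
  lo <- max(peak - half, time[1]); hi <- min(peak + half, time[nt])
  per <- numeric(length(acc))
  for (j in seq_along(acc)) {
    e <- acc[[j]]; s <- 0; k <- 0
    for (i in seq_len(nt)) {
      if (time[i] >= lo - 1e-9 && time[i] <= hi + 1e-9) {
        s <- s + (e$left[i] - e$right[i]); k <- k + 1
      }
    }
    per[j] <- s / k
  }
  list(peak = peak, per_epoch = per, li = mean(per))
}

# Swap the hemispheres of a recording.
swap_channels <- function(rec) {
  tmp <- rec$left; rec$left <- rec$right; rec$right <- tmp
  rec
}
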