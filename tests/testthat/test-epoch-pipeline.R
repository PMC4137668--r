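test_that("epoch_spec validates the paradigm geometry", {
  s <- epoch_spec()
  expect_equal(s$cue_offset_s, 12)
  expect_equal(s$poi_s, c(4, 14))
  expect_error(epoch_spec(baseline_interval_s = c(2, 13)), "baseline")
  expect_error(epoch_spec(poi_s = c(4, 20)), "period of interest")
  expect_error(epoch_spec(min_trials = 0), "min_trials")
})

test_that("extract_epochs emits one epoch per marker with annotation and bounds handling", {
  sim <- simulate_session(quiet_params_25(n_trials = 24, seed = 3))
  eps <- extract_epochs(sim$recording, epoch_spec())
  expect_length(eps, 24)
  expect_true(all(vapply(eps, function(e) e$status == "accepted", logical(1))))
  # cue-relative time axis: 0 is marker + 12 s
  expect_equal(eps[[1]]$time[1], -12)

  ann <- trial_annotations(2L, "talked during baseline")
  eps2 <- extract_epochs(sim$recording, epoch_spec(), ann)
  expect_equal(eps2[[2]]$status, "rejected")
  expect_equal(eps2[[2]]$rejection_reason, "annotated_invalid")

  # last marker only 10 s before the end of the record
  rec <- sim$recording
  short <- ftcd_recording(left = rec$left[1:(rec$markers[2] + 250)],
                          right = rec$right[1:(rec$markers[2] + 250)],
                          fs = 25, markers = rec$markers[1:2])
  eps3 <- extract_epochs(short, epoch_spec())
  expect_equal(eps3[[2]]$rejection_reason, "out_of_bounds")

  rec_nomark <- ftcd_recording(left = rec$left, right = rec$right, fs = 25)
  expect_error(extract_epochs(rec_nomark, epoch_spec()), "no trials")
})

test_that("screening repairs single points and rejects multi-point artifacts", {
  e <- make_pulsatile_epoch()
  expect_equal(screen_epoch(e)$status, "accepted")

  # one dropped sample -> corrected by the channel mean
  e1 <- e
  e1$left[100] <- 0
  m_before <- mean(e1$left)
  out <- screen_epoch(e1)
  expect_equal(out$status, "corrected")
  expect_equal(out$left[100], m_before)
  expect_equal(out$corrected_points$sample, 100L)

  # two samples far above the spiking bound recomputed on the data
  e2 <- e
  m <- mean(e2$right); s <- sd(e2$right)
  e2$right[c(200, 400)] <- m + 6 * s
  m2 <- mean(e2$right); s2 <- sd(e2$right)
  expect_true(all(e2$right[c(200, 400)] > m2 + 4 * s2))
  out2 <- screen_epoch(e2)
  expect_equal(out2$status, "rejected")
  expect_equal(out2$rejection_reason, "spiking")

  # mixed dropout + spike reports dropout
  e3 <- e
  e3$left[c(50, 300)] <- c(0, mean(e3$left) + 8 * sd(e3$left))
  expect_equal(screen_epoch(e3)$rejection_reason, "dropout")
})

test_that("screening is idempotent", {
  set.seed(11)
  for (i in 1:5) {
    e <- make_pulsatile_epoch(amp = 15 + 5 * i)
    if (i %% 2 == 0) e$left[7 * i] <- 0  # some runs get a repairable point
    once <- screen_epoch(e)
    twice <- screen_epoch(once)
    expect_equal(twice$left, once$left)
    expect_equal(twice$right, once$right)
    expect_equal(twice$status, once$status)
  }
})

test_that("detect_beats counts pulses like a direct scan oracle", {
  fs <- 25
  x <- pulsatile_series(30 * fs, fs = fs, hr_hz = 1.2, amp = 25)
  beats <- detect_beats(x, fs)
  # oracle: every local maximum of the noise-free train is a beat
  oracle <- sum(x[2:(length(x) - 1)] > x[1:(length(x) - 2)] &
                x[2:(length(x) - 1)] >= x[3:length(x)])
  expect_lte(abs(length(beats) - oracle), 1)
  expect_true(length(beats) %in% 35:37)  # 1.2 Hz over 30 s

  expect_length(detect_beats(rep(5, 100), fs), 0)

  # a weak high harmonic must not add beats
  t <- (seq_len(30 * fs) - 1) / fs
  x2 <- x + 0.5 * sin(2 * pi * 6 * t)
  expect_equal(length(detect_beats(x2, fs)), length(beats))
})

test_that("heart-cycle integration conserves per-beat means and flattens pulsation", {
  # constant channels unchanged
  e0 <- make_epoch(rep(100, 200), rep(100, 200))
  out0 <- integrate_heart_cycles(e0, beats = c(10L, 60L, 110L, 160L))
  expect_equal(out0$left, rep(100, 200))

  fs <- 25
  e <- make_pulsatile_epoch(n = 750, fs = fs, hr_hz = 1.5, amp = 20)
  beats <- detect_beats((e$left + e$right) / 2, fs)
  out <- integrate_heart_cycles(e, beats)

  # per-beat conservation to 1e-9 on every interval (including edges)
  bounds <- unique(c(1L, beats, 751L))
  for (k in seq_len(length(bounds) - 1)) {
    seg <- bounds[k]:(bounds[k + 1] - 1L)
    expect_lt(abs(mean(out$left[seg]) - mean(e$left[seg])), 1e-9)
    expect_lt(abs(mean(out$right[seg]) - mean(e$right[seg])), 1e-9)
  }

  # flat to within ~1 unit of the mean away from the epoch edges
  interior <- 50:700
  expect_lt(max(abs(out$left[interior] - mean(e$left))), 1.5)

  # cardiac-band power reduced by at least 95%
  band_power <- function(x, hr = 1.5) {
    sp <- stats::spec.pgram(ts(x, frequency = fs), plot = FALSE, taper = 0,
                            detrend = TRUE)
    sel <- sp$freq > hr - 0.3 & sp$freq < hr + 0.3
    sum(sp$spec[sel])
  }
  expect_lt(band_power(out$left) / band_power(e$left), 0.05)

  expect_error(integrate_heart_cycles(e, beats = 5L), "insufficient beats")
})

test_that("normalization scales each channel to mean exactly 100", {
  e <- make_epoch(rep(50, 100), rep(120, 100) * runif(100, 0.9, 1.1))
  out <- normalize_epoch(e)
  expect_equal(out$left, rep(100, 100))
  expect_lt(abs(mean(out$right) - 100), 1e-9)

  e2 <- make_epoch(c(80, 80), c(120, 120))
  out2 <- normalize_epoch(e2)
  expect_equal(out2$left, c(100, 100))  # factor 1.25
  expect_equal(out2$right, c(100, 100)) # factor 100/120

  expect_error(normalize_epoch(make_epoch(c(-1, 1), c(1, 1))),
               "cannot normalize")
})

test_that("extreme-value rejection uses a closed acceptance interval", {
  base <- rep(100, 50)
  expect_equal(reject_extremes(make_epoch(base + 10, base - 10))$status,
               "accepted")
  e_hi <- make_epoch(base, base); e_hi$left[10] <- 141
  expect_equal(reject_extremes(e_hi)$rejection_reason, "extreme_values")
  e_edge <- make_epoch(base, base); e_edge$left[10] <- 140
  expect_equal(reject_extremes(e_edge)$status, "accepted")
})

test_that("baseline correction zeroes the baseline mean of both channels", {
  spec <- epoch_spec()
  fs <- 25; n <- 750
  e <- make_epoch(rep(100, n), rep(100, n), fs = fs)
  out <- baseline_correct(e, spec)
  expect_equal(out$left, rep(0, n))

  # step of +4 (left) and +1 (right) after the cue -> difference is +3
  t <- e$time
  e2 <- make_epoch(100 + 4 * (t >= 0), 100 + 1 * (t >= 0), fs = fs)
  out2 <- baseline_correct(e2, spec)
  expect_lt(max(abs(out2$left[t >= -10 & t < 0])), 1e-9)
  expect_equal(unique(out2$left[t >= 0] - out2$right[t >= 0]), 3)

  # property: random epochs end with baseline mean 0
  set.seed(21)
  for (i in 1:5) {
    er <- make_epoch(rnorm(n, 100, 5), rnorm(n, 100, 5), fs = fs)
    outr <- baseline_correct(er, spec)
    bl <- outr$time >= -10 & outr$time < 0
    expect_lt(abs(mean(outr$left[bl])), 1e-9)
    expect_lt(abs(mean(outr$right[bl])), 1e-9)
  }
})

test_that("pipeline processes a clean session fully and rejects injected artifacts", {
  spec <- epoch_spec()
  sim <- simulate_session(quiet_params(n_trials = 24, seed = 4))
  eps <- run_epoch_pipeline(sim$recording, spec)
  expect_length(eps, 24)
  expect_true(all(vapply(eps, ftcdlat:::is_accepted, logical(1))))
  # accepted epochs: baseline mean 0 on both channels
  for (e in eps[1:3]) {
    bl <- e$time >= -10 & e$time < 0
    expect_lt(abs(mean(e$left[bl])), 1e-9)
  }

  # two-point dropouts in trials 3, 7, 11 -> exactly those rejected
  sim25 <- simulate_session(quiet_params_25(n_trials = 12, seed = 5))
  rec <- sim25$recording
  for (tr in c(3L, 7L, 11L))
    rec <- inject_artifact(rec, tr, "dropout", n_points = 2)
  eps2 <- run_epoch_pipeline(rec, spec)
  status <- vapply(eps2, function(e) e$status, character(1))
  expect_equal(which(status == "rejected"), c(3L, 7L, 11L))
  expect_true(all(vapply(eps2[c(3, 7, 11)],
                         function(e) e$rejection_reason == "dropout",
                         logical(1))))

  # all trials annotated invalid -> nothing accepted, result insufficient
  ann <- trial_annotations(1:12, "observer exclusion")
  eps3 <- run_epoch_pipeline(rec, spec, ann)
  res <- compute_li(eps3, spec)
  expect_equal(res$n_accepted, 0L)
  expect_equal(res$category, "insufficient")
})

test_that("accepted + corrected + rejected equals the marker count", {
  sim <- simulate_session(simulation_params(n_trials = 20, seed = 6,
                                            p_dropout_trial = 0.2,
                                            p_spike_trial = 0.1))
  eps <- run_epoch_pipeline(sim$recording, epoch_spec())
  status <- vapply(eps, function(e) e$status, character(1))
  expect_equal(length(status), length(sim$recording$markers))
  expect_equal(sum(status %in% c("accepted", "corrected", "rejected")),
               length(status))
})

test_that("stage order is normalize before baseline-correct (gain cancellation)", {
  # identical waveforms with different hardware gains must yield a null
  # difference curve under the correct stage order
  sim <- simulate_session(quiet_params_25(n_trials = 12, seed = 7,
                                          true_li = 0, response_amp = 3))
  rec <- sim$recording
  rec$left <- rec$right * 1.8  # pure gain difference
  res <- analyze_session(rec)
  expect_lt(max(abs(res$diff_curve$diff)), 1e-9)
  expect_lt(abs(res$li), 1e-9)

  # doing baseline correction before normalization would not cancel the
  # gain: the baseline-corrected response still differs by the gain factor
  e <- run_epoch_pipeline(rec, epoch_spec())[[1]]
  raw <- extract_epochs(downsample(rec, 25), epoch_spec())[[1]]
  wrong <- baseline_correct(raw, epoch_spec())
  expect_gt(max(abs(wrong$left - wrong$right)), 0.5)
})
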