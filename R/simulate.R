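#' Simulation parameters for a synthetic fTCD session
#'
#' The generative model per channel is
#' `baseline_velocity * (1 + pulsatility * cardiac(t)) + response(t, channel)
#'  + slow drift + white noise`,
#' where `cardiac(t)` is a raised-cosine systolic pulse with exponential
#' diastolic decay at a slowly varying heart rate, and the task response is
#' zero while the child watches, rises after the cue to speak to a peak at
#' `response_latency_s`, and returns to zero during rest. The left/right
#' response asymmetry is calibrated so that the noise-free analysis
#' pipeline recovers exactly `true_li` (ground truth is defined
#' operationally as the quantity the pipeline estimates).
#'
#' Slow drift is an Ornstein-Uhlenbeck (vasomotion-like) process per
#' channel plus a shared systemic component. Its default SD (1.8
#' normalized units, timescale 4 s) is derived from the dispersion the
#' method shows on real data -- per-subject LI standard errors near 0.6--0.8
#' at ~24 trials imply a per-epoch LI SD around 3 normalized units, which
#' white noise alone cannot produce once heart-cycle integration has
#' smoothed it.
#'
#' @param n_trials Trials per session (default 24; paradigm maximum 30).
#' @param fs_raw Acquisition sampling rate in Hz (default 100).
#' @param watch_s,talk_s,rest_s Phase durations in seconds (12, 10, 8).
#' @param baseline_velocity Mean envelope level (default 100).
#' @param heart_rate_bpm,heart_rate_sd_bpm Mean heart rate and beat-to-beat
#'   SD (defaults 95 and 5; child range).
#' @param pulsatility Cardiac waveform amplitude as a fraction of baseline
#'   (default 0.25).
#' @param response_amp Bilateral task-evoked amplitude in normalized units
#'   (default 3).
#' @param true_li Target laterality index (left minus right, normalized
#'   units) the noise-free pipeline should recover (default 2).
#' @param response_latency_s Time from cue to response peak (default 9).
#' @param noise_sd White measurement noise SD per channel (default 0.8).
#' @param drift_sd,drift_tau_s Per-channel independent slow-drift SD and
#'   timescale (defaults 1.8 units, 4 s).
#' @param shared_drift_sd Shared (systemic) slow-drift SD (default 2); it
#'   cancels in the left-right difference.
#' @param amp_jitter_sd Lognormal SD of the per-trial response amplitude
#'   multiplier (default 0.2).
#' @param p_dropout_trial,p_spike_trial Per-trial artifact probabilities
#'   (defaults 0.05 each; their sum must not exceed 1).
#' @param artifact_run_length Artifact run length in samples at the 25 Hz
#'   analysis rate (default 2; scaled to `fs_raw` on injection).
#' @param lead_in_s,lead_out_s Recording padding (defaults 2 s each).
#' @param seed Optional integer seed.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(n_trials = 24, fs_raw = 100, watch_s = 12,
                              talk_s = 10, rest_s = 8,
                              baseline_velocity = 100, heart_rate_bpm = 95,
                              heart_rate_sd_bpm = 5, pulsatility = 0.25,
                              response_amp = 3, true_li = 2,
                              response_latency_s = 9, noise_sd = 0.8,
                              drift_sd = 1.8, drift_tau_s = 4,
                              shared_drift_sd = 2, amp_jitter_sd = 0.2,
                              p_dropout_trial = 0.05, p_spike_trial = 0.05,
                              artifact_run_length = 2, lead_in_s = 2,
                              lead_out_s = 2, seed = NULL) {
  p <- structure(as.list(environment()), class = "simulation_params")
  validate_simulation_params(p)
  p
}

validate_simulation_params <- function(p) {
  stopifnot(p$n_trials >= 1, p$watch_s > 0, p$talk_s > 0, p$rest_s > 0,
            p$fs_raw > 0, p$baseline_velocity > 0, p$heart_rate_bpm > 0,
            p$heart_rate_sd_bpm >= 0, p$pulsatility >= 0, p$noise_sd >= 0,
            p$drift_sd >= 0, p$drift_tau_s > 0, p$shared_drift_sd >= 0,
            p$amp_jitter_sd >= 0, p$artifact_run_length >= 1,
            p$response_latency_s > 0,
            p$response_latency_s <= p$talk_s + p$rest_s)
  if (p$p_dropout_trial < 0 || p$p_spike_trial < 0 ||
      p$p_dropout_trial + p$p_spike_trial > 1)
    stop("artifact probabilities must be in [0, 1] and sum to at most 1")
  if (p$fs_raw < 4 * p$heart_rate_bpm / 60)
    stop("fs_raw must be at least 4x the cardiac frequency")
  invisible(p)
}

trial_duration <- function(p) p$watch_s + p$talk_s + p$rest_s

# Raised-cosine systolic upstroke to the peak, exponential diastolic decay;
# phase in [0, 1) within the beat. Long-run mean is removed session-wide so
# the cardiac term is (approximately) zero-mean.
cardiac_waveform <- function(phase, systole_frac = 0.3, decay_frac = 0.25) {
  rise <- phase < systole_frac / 2
  w <- numeric(length(phase))
  w[rise] <- 0.5 * (1 - cos(2 * pi * phase[rise] / systole_frac))
  w[!rise] <- exp(-(phase[!rise] - systole_frac / 2) / decay_frac)
  w
}

# Task-response template on the cue-relative time axis: raised-cosine rise
# over [0, latency], raised-cosine fall back to zero by the end of rest.
response_template <- function(t_rel_cue, latency, t_end) {
  s <- numeric(length(t_rel_cue))
  up <- t_rel_cue >= 0 & t_rel_cue <= latency
  dn <- t_rel_cue > latency & t_rel_cue <= t_end
  s[up] <- 0.5 * (1 - cos(pi * t_rel_cue[up] / latency))
  s[dn] <- 0.5 * (1 + cos(pi * (t_rel_cue[dn] - latency) / (t_end - latency)))
  s
}

# Core generator: builds the session for a given left-right asymmetry
# amplitude `asym` (in template units). Draws from the RNG only for
# components whose parameter is non-zero, so a fully deterministic
# parameterization consumes no random numbers.
sim_core <- function(p, asym) {
  fs <- p$fs_raw
  tdur <- trial_duration(p)
  total_s <- p$lead_in_s + p$n_trials * tdur + p$lead_out_s
  n <- round(total_s * fs)
  t <- (seq_len(n) - 1L) / fs
  markers <- as.integer(round((p$lead_in_s + (seq_len(p$n_trials) - 1L) *
                               tdur) * fs)) + 1L

  # cardiac beat train over the whole session
  mean_ibi <- 60 / p$heart_rate_bpm
  beat_times <- numeric(0)
  tcur <- -mean_ibi * stats::runif(1) * (p$heart_rate_sd_bpm > 0)
  while (tcur < total_s) {
    beat_times <- c(beat_times, tcur)
    hr <- p$heart_rate_bpm
    if (p$heart_rate_sd_bpm > 0)
      hr <- max(stats::rnorm(1, hr, p$heart_rate_sd_bpm), 40)
    tcur <- tcur + 60 / hr
  }
  beat_times <- c(beat_times, tcur)
  k <- findInterval(t, beat_times)
  phase <- (t - beat_times[k]) / (beat_times[k + 1L] - beat_times[k])
  cardiac <- cardiac_waveform(phase)
  cardiac <- cardiac - mean(cardiac)

  # task response, lateralized
  trial_of <- pmin(pmax(floor((t - p$lead_in_s) / tdur) + 1, 1), p$n_trials)
  t_rel_cue <- t - (p$lead_in_s + (trial_of - 1) * tdur + p$watch_s)
  s <- response_template(t_rel_cue, p$response_latency_s, p$talk_s + p$rest_s)
  amp_jit <- rep(1, p$n_trials)
  if (p$amp_jitter_sd > 0)
    amp_jit <- stats::rlnorm(p$n_trials, -p$amp_jitter_sd^2 / 2,
                             p$amp_jitter_sd)
  sj <- s * amp_jit[trial_of]
  resp_left <- (p$response_amp + asym / 2) * sj
  resp_right <- (p$response_amp - asym / 2) * sj

  # stationary OU process: first innovation drawn from the stationary law
  ou_stat <- function(sd, tau) {
    if (sd <= 0) return(numeric(n))
    a <- exp(-1 / (tau * fs))
    innov <- stats::rnorm(n, 0, sd * sqrt(1 - a^2))
    innov[1] <- stats::rnorm(1, 0, sd)
    as.numeric(stats::filter(innov, a, method = "recursive", init = 0))
  }
  shared <- ou_stat(p$shared_drift_sd, p$drift_tau_s)
  dl <- ou_stat(p$drift_sd, p$drift_tau_s)
  dr <- ou_stat(p$drift_sd, p$drift_tau_s)
  nl <- if (p$noise_sd > 0) stats::rnorm(n, 0, p$noise_sd) else numeric(n)
  nr <- if (p$noise_sd > 0) stats::rnorm(n, 0, p$noise_sd) else numeric(n)

  base <- p$baseline_velocity * (1 + p$pulsatility * cardiac)
  left <- base + resp_left + shared + dl + nl
  right <- base + resp_right + shared + dr + nr

  # per-trial artifact injection
  artifacts <- data.frame(trial = integer(), kind = character(),
                          channel = character(), first_sample = integer(),
                          n_points_raw = integer(), stringsAsFactors = FALSE)
  if (p$p_dropout_trial + p$p_spike_trial > 0) {
    run_raw <- max(1L, as.integer(round(p$artifact_run_length * fs / 25)))
    for (tr in seq_len(p$n_trials)) {
      u <- stats::runif(1)
      kind <- if (u < p$p_dropout_trial) "dropout"
              else if (u < p$p_dropout_trial + p$p_spike_trial) "spike"
              else next
      pos_s <- stats::runif(1, 1, tdur - 1)
      i0 <- markers[tr] + as.integer(round(pos_s * fs))
      idx <- i0:(i0 + run_raw - 1L)
      idx <- idx[idx <= n]
      ch <- if (stats::runif(1) < 0.5) "left" else "right"
      if (kind == "dropout") {
        if (ch == "left") left[idx] <- 0 else right[idx] <- 0
      } else {
        v <- 2.5 * p$baseline_velocity
        if (ch == "left") left[idx] <- v else right[idx] <- v
      }
      artifacts <- rbind(artifacts,
                         data.frame(trial = tr, kind = kind, channel = ch,
                                    first_sample = i0,
                                    n_points_raw = length(idx),
                                    stringsAsFactors = FALSE))
    }
  }

  rec <- ftcd_recording(left = left, right = right, fs = fs,
                        markers = markers, subject_id = "sim",
                        meta = list(simulated = TRUE))
  gt <- list(true_li = p$true_li, asym = asym, beat_times = beat_times,
             trial_amp = amp_jit, artifacts = artifacts)
  list(recording = rec, ground_truth = gt)
}

# The asymmetry amplitude that makes the noise-free pipeline recover an LI
# of exactly 1 depends only on the deterministic parameters, so it is
# computed once per parameter set (3-trial noise-free run through the real
# pipeline) and cached.
.calib_cache <- new.env(parent = emptyenv())

calibrate_asymmetry <- function(p, spec) {
  key <- paste(p$fs_raw, p$watch_s, p$talk_s, p$rest_s, p$baseline_velocity,
               p$heart_rate_bpm, p$pulsatility, p$response_amp,
               p$response_latency_s, spec$analysis_fs, spec$cue_offset_s,
               paste(spec$poi_s, collapse = ","), spec$li_window_s,
               paste(spec$baseline_interval_s, collapse = ","), sep = "|")
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(hit)
  pc <- p
  pc$n_trials <- 3; pc$noise_sd <- 0; pc$drift_sd <- 0
  pc$shared_drift_sd <- 0; pc$amp_jitter_sd <- 0; pc$heart_rate_sd_bpm <- 0
  pc$p_dropout_trial <- 0; pc$p_spike_trial <- 0
  sim <- sim_core(pc, asym = 1)
  epochs <- run_epoch_pipeline(sim$recording, spec)
  res <- compute_li(epochs, spec)
  k <- res$li
  if (!is.finite(k) || k <= 0) stop("asymmetry calibration failed")
  .calib_cache[[key]] <- k
  k
}

#' Simulate a complete fTCD session with known ground truth
#'
#' See [simulation_params()] for the generative model. The asymmetry
#' amplitude is calibrated so the noise-free pipeline output equals
#' `params$true_li`; the calibration run is deterministic and consumes no
#' random numbers.
#'
#' @param params A [simulation_params()].
#' @param spec The [epoch_spec()] the session is calibrated against.
#' @return List with elements `recording` (an [ftcd_recording()]) and
#'   `ground_truth` (true LI, asymmetry amplitude, beat times, per-trial
#'   amplitude multipliers, artifact log).
#' @export
simulate_session <- function(params = simulation_params(),
                             spec = epoch_spec()) {
  validate_simulation_params(params)
  if (!is.null(params$seed)) set.seed(params$seed)
  k <- calibrate_asymmetry(params, spec)
  sim_core(params, asym = params$true_li / k)
}

#' Inject a dropout or spike artifact into a recording
#'
#' Dropout writes zeros; a spike writes values far above the local mean
#' (guaranteed past the 4-SD screening bound). `n_points` is interpreted at
#' the recording's own sampling rate. The injection is appended to
#' `rec$meta$injections`.
#'
#' @param rec An [ftcd_recording()].
#' @param trial 1-based trial (marker) index.
#' @param kind `"dropout"` or `"spike"`.
#' @param n_points Number of consecutive samples to overwrite (0 = no-op).
#' @param channel `"left"` or `"right"`.
#' @param at_s Offset of the artifact from the trial start in seconds
#'   (default 15, mid-trial).
#' @return The modified recording.
#' @export
inject_artifact <- function(rec, trial, kind = c("dropout", "spike"),
                            n_points = 1, channel = c("left", "right"),
                            at_s = 15) {
  kind <- match.arg(kind)
  channel <- match.arg(channel)
  if (trial < 1 || trial > length(rec$markers)) stop("invalid trial index")
  if (n_points == 0) return(rec)
  i0 <- rec$markers[trial] + as.integer(round(at_s * rec$fs))
  idx <- i0:(i0 + n_points - 1L)
  if (any(idx < 1L) || any(idx > n_samples(rec)))
    stop("artifact extends outside the recording")
  x <- rec[[channel]]
  if (kind == "dropout") {
    x[idx] <- 0
  } else {
    seg <- rec$markers[trial]:min(rec$markers[trial] + round(30 * rec$fs),
                                  n_samples(rec))
    x[idx] <- mean(x[seg]) + 12 * stats::sd(x[seg])
  }
  rec[[channel]] <- x
  rec$meta$injections <- rbind(
    rec$meta$injections,
    data.frame(trial = trial, kind = kind, channel = channel,
               first_sample = i0, n_points = n_points,
               stringsAsFactors = FALSE))
  rec
}

#' Simulate a cohort of subjects with subgroup structure
#'
#' Subjects are assigned to the four developmental subgroups by
#' largest-remainder rounding of `subgroup_mix`; each subject's true LI is
#' drawn from the subgroup's distribution, language z-scores are drawn
#' consistent with the subgroup's impairment status under
#' [classify_language_status()], and handedness records are generated with
#' right-biased item and reach probabilities.
#'
#' @param n_subjects Number of subjects.
#' @param subgroup_mix Named proportions over
#'   `typical`, `late_bloomer`, `plateau`, `persistent_sli` (default
#'   36/10/6/5 out of 57).
#' @param li_distributions Named list of `c(mean, sd)` per subgroup;
#'   defaults use the typical-language LI distribution (2.2, 3.95) for the
#'   non-impaired subgroups and the impaired-group distribution
#'   (-0.2, 3.31) for the impaired ones.
#' @param params A [simulation_params()] template for the sessions.
#' @param spec An [epoch_spec()].
#' @param seed Integer seed (required for reproducibility; default 1).
#' @param generate_signals If `FALSE`, skip signal synthesis and return
#'   only outcomes and ground truths (fast path for statistic-level
#'   simulations).
#' @return List with `recordings` (list, `NULL`s when
#'   `generate_signals = FALSE`), `outcomes` (data frame), and
#'   `ground_truths` (list).
#' @export
simulate_cohort <- function(n_subjects,
                            subgroup_mix = c(typical = 36, late_bloomer = 10,
                                             plateau = 6, persistent_sli = 5) / 57,
                            li_distributions = list(
                              typical = c(mean = 2.2, sd = 3.95),
                              late_bloomer = c(mean = 2.2, sd = 3.95),
                              plateau = c(mean = -0.2, sd = 3.31),
                              persistent_sli = c(mean = -0.2, sd = 3.31)),
                            params = simulation_params(), spec = epoch_spec(),
                            seed = 1, generate_signals = TRUE) {
  stopifnot(n_subjects >= 1)
  if (any(subgroup_mix < 0)) stop("impossible mix: negative proportions")
  subgroup_mix <- subgroup_mix / sum(subgroup_mix)
  lv <- c("typical", "late_bloomer", "plateau", "persistent_sli")
  if (!all(lv %in% names(subgroup_mix))) stop("subgroup_mix must name all four subgroups")
  counts <- largest_remainder(subgroup_mix[lv] * n_subjects)
  labels <- rep(lv, counts)

  set.seed(seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_subjects)
  outcomes <- vector("list", n_subjects)
  recordings <- vector("list", n_subjects)
  gts <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sg <- labels[i]
    late <- sg %in% c("late_bloomer", "persistent_sli")
    imp <- sg %in% c("plateau", "persistent_sli")
    d <- li_distributions[[sg]]
    true_li <- stats::rnorm(1, d[["mean"]], d[["sd"]])
    z <- draw_zscores(imp)
    ehi_r <- stats::rbinom(1, 9, 0.87)
    hand <- handedness_record(ehi_r, 9 - ehi_r,
                              stats::rbinom(1, 21, 0.78), 21)
    outcomes[[i]] <- data.frame(
      subject_id = sprintf("S%03d", i), subgroup = sg,
      late_talker_20m = late, impaired_4y = imp, true_li = true_li,
      t(stats::setNames(z, paste0("z", seq_along(z)))),
      ehi_right_items = hand$ehi_right_items,
      ehi_left_items = hand$ehi_left_items,
      qhp_right_reaches = hand$qhp_right_reaches,
      qhp_total_reaches = hand$qhp_total_reaches,
      stringsAsFactors = FALSE)
    if (generate_signals) {
      ps <- params
      ps$true_li <- true_li
      ps$seed <- subj_seeds[i]
      sim <- simulate_session(ps, spec)
      sim$recording$subject_id <- sprintf("S%03d", i)
      recordings[[i]] <- sim$recording
      gts[[i]] <- sim$ground_truth
    }
  }
  list(recordings = recordings, outcomes = do.call(rbind, outcomes),
       ground_truths = gts)
}

largest_remainder <- function(x) {
  fl <- floor(x)
  rem <- sum(round(sum(x))) - sum(fl)
  if (rem > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

# z-scores on 6 measures consistent with the impairment label under the
# "more than 1 SD below on 2+ measures" rule (rejection sampling).
draw_zscores <- function(impaired, n_measures = 6) {
  for (it in seq_len(1000)) {
    z <- if (impaired) stats::rnorm(n_measures, -1.3, 0.8)
         else stats::rnorm(n_measures, 0.2, 0.9)
    if (classify_language_status(z) == impaired) return(z)
  }
  stop("could not draw z-scores consistent with label")
}
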