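#' Epoching and screening parameters
#'
#' All timing constants of the animation-description paradigm and the
#' thresholds of the artifact-screening stages, in seconds unless noted.
#' The defaults encode a 30 s trial: 12 s silent watching (baseline),
#' a cue to speak, 10 s talking, 8 s rest. The period of interest (POI)
#' for the laterality index is 4--14 s after the cue.
#'
#' @param epoch_start_s,epoch_end_s Epoch bounds relative to the trial
#'   marker (defaults 0 and 30).
#' @param cue_offset_s Time from marker to speak-cue onset (default 12).
#' @param baseline_interval_s Length-2 numeric, baseline window relative to
#'   the marker (default `c(2, 12)`).
#' @param poi_s Length-2 numeric, period of interest relative to cue onset
#'   (default `c(4, 14)`).
#' @param li_window_s Width of the LI summation window centred on the peak
#'   (default 2).
#' @param dropout_sd,spike_sd Screening thresholds in channel SD units
#'   (defaults 3 and 4): dropout = amplitude at or below zero or more than
#'   `dropout_sd` SD below the channel mean; spiking = more than `spike_sd`
#'   SD above it.
#' @param extreme_limits Length-2 numeric, closed acceptance interval for
#'   normalized samples (default `c(60, 140)`).
#' @param min_trials Minimum accepted trials for a laterality index
#'   (default 12).
#' @param analysis_fs Analysis sampling rate in Hz (default 25).
#' @param screening_scope `"epoch"` (default) or `"session"`: scope over
#'   which the screening mean/SD per channel are computed.
#' @param peak_mode `"abs"` (default) or `"signed"` peak search.
#' @param ci_method `"t"` (default) or `"z"` confidence interval.
#' @return An object of class `epoch_spec`.
#' @export
epoch_spec <- function(epoch_start_s = 0, epoch_end_s = 30, cue_offset_s = 12,
                       baseline_interval_s = c(2, 12), poi_s = c(4, 14),
                       li_window_s = 2, dropout_sd = 3, spike_sd = 4,
                       extreme_limits = c(60, 140), min_trials = 12,
                       analysis_fs = 25, screening_scope = c("epoch", "session"),
                       peak_mode = c("abs", "signed"), ci_method = c("t", "z")) {
  spec <- structure(list(
    epoch_start_s = epoch_start_s, epoch_end_s = epoch_end_s,
    cue_offset_s = cue_offset_s,
    baseline_interval_s = as.numeric(baseline_interval_s),
    poi_s = as.numeric(poi_s), li_window_s = li_window_s,
    dropout_sd = dropout_sd, spike_sd = spike_sd,
    extreme_limits = as.numeric(extreme_limits), min_trials = min_trials,
    analysis_fs = analysis_fs,
    screening_scope = match.arg(screening_scope),
    peak_mode = match.arg(peak_mode), ci_method = match.arg(ci_method)),
    class = "epoch_spec")
  validate_epoch_spec(spec)
  spec
}

validate_epoch_spec <- function(s) {
  stopifnot(s$epoch_start_s < s$epoch_end_s,
            length(s$baseline_interval_s) == 2L,
            length(s$poi_s) == 2L, length(s$extreme_limits) == 2L)
  b <- s$baseline_interval_s
  if (!(b[1] >= s$epoch_start_s && b[2] <= s$cue_offset_s && b[1] < b[2]))
    stop("baseline interval must lie within [epoch start, cue offset]")
  poi_abs <- s$poi_s + s$cue_offset_s
  if (!(poi_abs[1] >= s$epoch_start_s && poi_abs[2] <= s$epoch_end_s))
    stop("period of interest must lie within the epoch")
  if (s$li_window_s <= 0) stop("li_window_s must be > 0")
  if (s$dropout_sd <= 0 || s$spike_sd <= 0) stop("thresholds must be > 0")
  if (s$min_trials < 1) stop("min_trials must be >= 1")
  if (s$extreme_limits[1] >= s$extreme_limits[2])
    stop("extreme_limits must be increasing")
  invisible(s)
}

new_epoch <- function(trial_index, time, left, right,
                      status = "accepted", rejection_reason = "none",
                      corrected_points = NULL) {
  structure(list(trial_index = trial_index, time = time,
                 left = left, right = right, status = status,
                 rejection_reason = rejection_reason,
                 corrected_points = corrected_points),
            class = "ftcd_epoch")
}

#' @export
print.ftcd_epoch <- function(x, ...) {
  cat(sprintf("fTCD epoch (trial %d): %d samples, status %s%s\n",
              x$trial_index, length(x$left), x$status,
              if (x$rejection_reason != "none")
                paste0(" (", x$rejection_reason, ")") else ""))
  invisible(x)
}

is_accepted <- function(e) e$status %in% c("accepted", "corrected")

#' Cut marker-locked epochs from a recording
#'
#' One epoch per trial marker, on a time axis where 0 is the cue onset
#' (marker time + `cue_offset_s`). Trials flagged in the annotations are
#' emitted with status `rejected`, reason `annotated_invalid`; epochs
#' extending past the record are rejected with reason `out_of_bounds`.
#'
#' @param rec An [ftcd_recording()] at the analysis rate.
#' @param spec An [epoch_spec()].
#' @param ann A [trial_annotations()] (default: none excluded).
#' @return List of `ftcd_epoch` objects, one per marker, in session order.
#' @export
extract_epochs <- function(rec, spec = epoch_spec(), ann = trial_annotations()) {
  validate_recording(rec)
  if (!length(rec$markers)) stop("no trials: recording has no markers")
  fs <- rec$fs
  n <- n_samples(rec)
  n_ep <- round((spec$epoch_end_s - spec$epoch_start_s) * fs)
  rel_time <- spec$epoch_start_s - spec$cue_offset_s + (seq_len(n_ep) - 1L) / fs
  lapply(seq_along(rec$markers), function(k) {
    i0 <- rec$markers[k] + round(spec$epoch_start_s * fs)
    idx <- i0 + seq_len(n_ep) - 1L
    if (k %in% ann$excluded_trials) {
      ok <- idx >= 1L & idx <= n
      return(new_epoch(k, rel_time[ok], rec$left[idx[ok]], rec$right[idx[ok]],
                       status = "rejected",
                       rejection_reason = "annotated_invalid"))
    }
    if (idx[1] < 1L || idx[n_ep] > n) {
      ok <- idx >= 1L & idx <= n
      return(new_epoch(k, rel_time[ok], rec$left[idx[ok]], rec$right[idx[ok]],
                       status = "rejected", rejection_reason = "out_of_bounds"))
    }
    new_epoch(k, rel_time, rec$left[idx], rec$right[idx])
  })
}

#' Screen an epoch for signal dropout and spiking
#'
#' Per channel, samples at or below zero or more than `dropout_sd` SD below
#' the channel mean are dropout; samples more than `spike_sd` SD above it
#' are spikes. A channel with exactly one flagged sample is repaired by
#' substituting the channel mean (status `corrected`); any channel with two
#' or more flagged samples rejects the epoch, with reason `dropout` if any
#' flagged sample anywhere is a dropout, else `spiking`.
#'
#' @param e An `ftcd_epoch` (not already rejected).
#' @param spec An [epoch_spec()].
#' @param session_stats Optional list with elements `left` and `right`,
#'   each `c(mean, sd)`, used when `spec$screening_scope == "session"`.
#' @return The epoch with updated status / repaired samples.
#' @export
screen_epoch <- function(e, spec = epoch_spec(), session_stats = NULL) {
  if (e$status == "rejected") return(e)
  flags <- lapply(c("left", "right"), function(ch) {
    x <- e[[ch]]
    if (identical(spec$screening_scope, "session") && !is.null(session_stats)) {
      m <- session_stats[[ch]][1]; s <- session_stats[[ch]][2]
    } else {
      m <- mean(x); s <- stats::sd(x)
    }
    drop <- x <= 0 | x < m - spec$dropout_sd * s
    spike <- x > m + spec$spike_sd * s
    list(ch = ch, mean = m, drop = which(drop), spike = which(spike),
         flagged = which(drop | spike))
  })
  n_flagged <- vapply(flags, function(f) length(f$flagged), integer(1))
  if (any(n_flagged >= 2L)) {
    any_drop <- any(vapply(flags, function(f) length(f$drop) > 0, logical(1)))
    e$status <- "rejected"
    e$rejection_reason <- if (any_drop) "dropout" else "spiking"
    return(e)
  }
  corrected <- e$corrected_points
  for (f in flags) {
    if (length(f$flagged) == 1L) {
      e[[f$ch]][f$flagged] <- f$mean
      corrected <- rbind(corrected,
                         data.frame(channel = f$ch, sample = f$flagged))
    }
  }
  if (!is.null(corrected) && nrow(corrected)) {
    e$corrected_points <- corrected
    e$status <- "corrected"
  }
  e
}

#' Detect cardiac beats in a velocity envelope
#'
#' Local maxima with prominence at least 25% of the series' interquartile
#' range, separated by at least `min_ibi_s` seconds. A constant series has
#' no cardiac structure and returns an empty vector.
#'
#' @param series Numeric vector (finite).
#' @param fs Sampling rate in Hz.
#' @param min_ibi_s Minimum inter-beat interval in seconds (default 0.35,
#'   about a 170 bpm ceiling).
#' @return Integer vector of 1-based beat (systolic peak) sample indices.
#' @export
detect_beats <- function(series, fs, min_ibi_s = 0.35) {
  stopifnot(all(is.finite(series)), min_ibi_s > 0)
  n <- length(series)
  if (n < 3L) return(integer())
  iqr <- stats::IQR(series)
  if (iqr == 0) return(integer())
  # strict rise, non-strict fall: first sample of a plateau counts
  cand <- which(series[2:(n - 1L)] > series[1:(n - 2L)] &
                series[2:(n - 1L)] >= series[3:n]) + 1L
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(i) peak_prominence(series, i), numeric(1))
  cand <- cand[prom >= 0.25 * iqr]
  if (!length(cand)) return(integer())
  # enforce minimum separation, keeping higher peaks first
  min_gap <- min_ibi_s * fs
  ord <- cand[order(-series[cand], cand)]
  kept <- integer()
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  sort(kept)
}

# prominence of peak i: height above the higher of the two bases, where a
# base is the minimum between the peak and the nearest strictly higher
# sample on that side (or the series edge).
peak_prominence <- function(x, i) {
  h <- x[i]
  left_min <- h
  for (j in seq(i - 1L, 1L)) {
    if (x[j] > h) break
    if (x[j] < left_min) left_min <- x[j]
  }
  right_min <- h
  n <- length(x)
  if (i < n) for (j in seq(i + 1L, n)) {
    if (x[j] > h) break
    if (x[j] < right_min) right_min <- x[j]
  }
  h - max(left_min, right_min)
}

#' Heart-cycle integration
#'
#' Removes the pulsatile cardiac component: within each inter-beat
#' interval both channels are replaced by the interval mean, the
#' piecewise-constant result is smoothed by linear interpolation between
#' interval midpoints, and each interval is then re-centred so its mean
#' equals the raw interval mean exactly (conservation).
#'
#' @param e An `ftcd_epoch`.
#' @param beats Strictly increasing 1-based sample indices of systolic
#'   peaks within the epoch; at least 2.
#' @return The epoch with smoothed channels.
#' @export
integrate_heart_cycles <- function(e, beats) {
  n <- length(e$left)
  beats <- as.integer(beats)
  if (length(beats) < 2L) stop("insufficient beats")
  if (any(diff(beats) <= 0L) || beats[1] < 1L || beats[length(beats)] > n)
    stop("beats must be strictly increasing and within the epoch")
  bounds <- unique(c(1L, beats, n + 1L))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1] - 1L
  mids <- (starts + ends) / 2
  for (ch in c("left", "right")) {
    x <- e[[ch]]
    mu <- vapply(seq_along(starts),
                 function(k) mean(x[starts[k]:ends[k]]), numeric(1))
    y <- stats::approx(mids, mu, xout = seq_len(n), rule = 2)$y
    for (k in seq_along(starts)) {
      seg <- starts[k]:ends[k]
      y[seg] <- y[seg] + (mu[k] - mean(y[seg]))
    }
    e[[ch]] <- y
  }
  e
}

#' Normalize both channels of an epoch to a mean of 100
#'
#' @param e An `ftcd_epoch` with positive channel means.
#' @return The epoch, each channel scaled so its mean is exactly 100.
#' @export
normalize_epoch <- function(e) {
  for (ch in c("left", "right")) {
    m <- mean(e[[ch]])
    if (!is.finite(m) || m <= 0)
      stop("cannot normalize: non-positive ", ch, " channel mean")
    e[[ch]] <- e[[ch]] * (100 / m)
  }
  e
}

#' Reject epochs with extreme normalized values
#'
#' @param e A normalized `ftcd_epoch`.
#' @param spec An [epoch_spec()]; the closed interval `spec$extreme_limits`
#'   is the acceptance range.
#' @return The epoch, rejected with reason `extreme_values` if any sample
#'   of either channel falls strictly outside the limits.
#' @export
reject_extremes <- function(e, spec = epoch_spec()) {
  if (e$status == "rejected") return(e)
  lo <- spec$extreme_limits[1]; hi <- spec$extreme_limits[2]
  if (any(e$left < lo | e$left > hi) || any(e$right < lo | e$right > hi)) {
    e$status <- "rejected"
    e$rejection_reason <- "extreme_values"
  }
  e
}

#' Baseline-correct an epoch
#'
#' Subtracts each channel's mean over the baseline interval (relative to
#' the trial marker, default 2--12 s, i.e. the silent-watching phase), so
#' both channels -- and hence their difference -- have baseline mean zero.
#'
#' @param e An `ftcd_epoch`.
#' @param spec An [epoch_spec()].
#' @return The baseline-corrected epoch.
#' @export
baseline_correct <- function(e, spec = epoch_spec()) {
  b <- spec$baseline_interval_s - spec$cue_offset_s  # relative to cue onset
  sel <- e$time >= b[1] - 1e-9 & e$time < b[2] - 1e-9
  if (!any(sel)) stop("baseline interval empty after clipping")
  for (ch in c("left", "right")) e[[ch]] <- e[[ch]] - mean(e[[ch]][sel])
  e
}

#' Run the full epoch-processing pipeline
#'
#' Stages, in order: downsample to the analysis rate (if needed), extract
#' marker-locked epochs, screen for dropout/spiking (single-point repair),
#' normalize each channel to mean 100, heart-cycle integrate, reject
#' extreme values, baseline-correct. Rejected epochs are preserved with
#' their reasons. Epochs in which fewer than two beats are detectable
#' (no cardiac structure) skip the integration stage.
#'
#' @param rec An [ftcd_recording()] (any rate at or above the analysis rate).
#' @param spec An [epoch_spec()].
#' @param ann A [trial_annotations()].
#' @return List of `ftcd_epoch` objects with final statuses.
#' @export
run_epoch_pipeline <- function(rec, spec = epoch_spec(),
                               ann = trial_annotations()) {
  if (rec$fs != spec$analysis_fs) rec <- downsample(rec, spec$analysis_fs)
  epochs <- extract_epochs(rec, spec, ann)
  session_stats <- NULL
  if (identical(spec$screening_scope, "session"))
    session_stats <- list(left = c(mean(rec$left), stats::sd(rec$left)),
                          right = c(mean(rec$right), stats::sd(rec$right)))
  lapply(epochs, function(e) {
    if (e$status == "rejected") return(e)
    e <- screen_epoch(e, spec, session_stats)
    if (e$status == "rejected") return(e)
    e <- normalize_epoch(e)
    beats <- detect_beats((e$left + e$right) / 2, spec$analysis_fs)
    if (length(beats) >= 2L) e <- integrate_heart_cycles(e, beats)
    e <- reject_extremes(e, spec)
    if (e$status == "rejected") return(e)
    baseline_correct(e, spec)
  })
}
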