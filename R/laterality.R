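#' Grand-average left-minus-right difference curve
#'
#' Pointwise mean of (left - right) across accepted (including corrected)
#' epochs on their common time axis.
#'
#' @param epochs List of `ftcd_epoch` objects; only accepted/corrected ones
#'   contribute.
#' @return A data frame with columns `time` (s relative to cue onset) and
#'   `diff` (normalized velocity units).
#' @export
average_difference <- function(epochs) {
  acc <- Filter(is_accepted, epochs)
  if (!length(acc)) stop("zero accepted epochs")
  time <- acc[[1]]$time
  for (e in acc) {
    if (length(e$time) != length(time) || max(abs(e$time - time)) > 1e-9)
      stop("accepted epochs must share a common time axis")
  }
  d <- rowMeans(vapply(acc, function(e) e$left - e$right,
                       numeric(length(time))))
  data.frame(time = time, diff = d)
}

#' Locate the peak difference within the period of interest
#'
#' By default the peak is the maximum of the absolute difference (sign
#' retained by the curve), so a consistently right-lateralized response is
#' found at its own peak; `spec$peak_mode = "signed"` takes the maximum of
#' the signed curve instead. Ties break to the earliest latency.
#'
#' @param diff_curve Data frame from [average_difference()].
#' @param spec An [epoch_spec()]; the POI is `spec$poi_s` seconds after cue
#'   onset.
#' @return Peak latency in seconds after cue onset.
#' @export
find_peak <- function(diff_curve, spec = epoch_spec()) {
  sel <- diff_curve$time >= spec$poi_s[1] - 1e-9 &
         diff_curve$time <= spec$poi_s[2] + 1e-9
  if (!any(sel)) stop("period of interest is empty")
  d <- diff_curve$diff[sel]
  if (all(is.na(d))) stop("all-NA period of interest")
  crit <- if (identical(spec$peak_mode, "signed")) d else abs(d)
  diff_curve$time[sel][which.max(crit)]
}

#' Compute the laterality index and classification for a session
#'
#' The LI is the mean left-minus-right velocity difference in a
#' `li_window_s`-wide window centred on the grand-average peak within the
#' POI (window clipped to the epoch support). It is computed per accepted
#' epoch; the session LI is their mean, with SE and a 95% confidence
#' interval (Student t by default) used for left/bilateral/right
#' classification. Odd/even split LIs share the overall peak latency.
#'
#' @param epochs List of `ftcd_epoch` objects (output of
#'   [run_epoch_pipeline()]).
#' @param spec An [epoch_spec()].
#' @param subject_id Carried into the result for reporting.
#' @return An object of class `laterality_result`: list with `li`,
#'   `per_epoch_li`, `se`, `ci95`, `peak_latency_s`, `n_accepted`,
#'   `category`, `li_odd`, `li_even`, `diff_curve`, `subject_id`.
#' @export
compute_li <- function(epochs, spec = epoch_spec(), subject_id = NA_character_) {
  acc <- Filter(is_accepted, epochs)
  n_acc <- length(acc)
  if (n_acc == 0L) {
    return(structure(list(subject_id = subject_id, li = NA_real_,
                          per_epoch_li = numeric(), se = NA_real_,
                          ci95 = c(NA_real_, NA_real_),
                          peak_latency_s = NA_real_, n_accepted = 0L,
                          category = "insufficient",
                          li_odd = NA_real_, li_even = NA_real_,
                          diff_curve = NULL),
                     class = "laterality_result"))
  }
  diff_curve <- average_difference(epochs)
  peak <- find_peak(diff_curve, spec)
  win <- li_window(peak, spec, range(diff_curve$time))
  per_epoch <- vapply(acc, function(e) epoch_window_mean(e, win), numeric(1))
  li <- mean(per_epoch)
  se <- if (n_acc > 1L) stats::sd(per_epoch) / sqrt(n_acc) else NA_real_
  ci <- li_ci(li, se, n_acc, spec$ci_method)
  parity <- seq_len(n_acc) %% 2L
  li_odd <- mean(per_epoch[parity == 1L])
  li_even <- if (any(parity == 0L)) mean(per_epoch[parity == 0L]) else NA_real_
  res <- structure(list(subject_id = subject_id, li = li,
                        per_epoch_li = per_epoch, se = se, ci95 = ci,
                        peak_latency_s = peak, n_accepted = n_acc,
                        category = NA_character_, li_odd = li_odd,
                        li_even = li_even, diff_curve = diff_curve),
                   class = "laterality_result")
  res$category <- classify_laterality(res, spec)
  res
}

# 2 s window centred on the peak, clipped to the epoch support (it may
# extend past the POI but not past the epoch).
li_window <- function(peak, spec, support) {
  half <- spec$li_window_s / 2
  c(max(peak - half, support[1]), min(peak + half, support[2]))
}

epoch_window_mean <- function(e, win) {
  sel <- e$time >= win[1] - 1e-9 & e$time <= win[2] + 1e-9
  mean(e$left[sel] - e$right[sel])
}

li_ci <- function(li, se, n, method = "t") {
  if (is.na(se)) return(c(NA_real_, NA_real_))
  q <- if (identical(method, "z")) stats::qnorm(0.975)
       else stats::qt(0.975, df = n - 1L)
  c(li - q * se, li + q * se)
}

#' Classify language laterality from a result
#'
#' `insufficient` below the accepted-trial minimum; otherwise `left` if the
#' 95% CI lies above zero, `right` if below, `bilateral` if it spans zero.
#' A degenerate CI (SE = 0, identical epochs) is classified by the sign of
#' the LI, with a warning; LI = 0 with SE = 0 is bilateral.
#'
#' @param result A `laterality_result`.
#' @param spec An [epoch_spec()] supplying `min_trials`.
#' @return One of `"left"`, `"right"`, `"bilateral"`, `"insufficient"`.
#' @export
classify_laterality <- function(result, spec = epoch_spec()) {
  if (result$n_accepted < spec$min_trials) return("insufficient")
  ci <- result$ci95
  if (anyNA(ci)) return("insufficient")
  if (!is.na(result$se) && result$se == 0) {
    if (result$li == 0) return("bilateral")
    warning("degenerate zero-width confidence interval; ",
            "classifying by the sign of the LI")
    return(if (result$li > 0) "left" else "right")
  }
  if (ci[1] > 0) "left" else if (ci[2] < 0) "right" else "bilateral"
}

#' Odd/even split-half laterality indices
#'
#' Accepted epochs are partitioned by the parity of their position in the
#' accepted sequence (1st, 3rd, ... = odd); each half's LI is the mean of
#' its per-epoch window means at the shared peak latency.
#'
#' @param epochs List of `ftcd_epoch` objects.
#' @param peak_latency_s Peak latency from the overall mean LI (seconds
#'   after cue onset).
#' @param spec An [epoch_spec()].
#' @return Named numeric vector `c(li_odd = , li_even = )`.
#' @export
split_half <- function(epochs, peak_latency_s, spec = epoch_spec()) {
  acc <- Filter(is_accepted, epochs)
  n <- length(acc)
  if (n < 2L) stop("both halves need at least one accepted epoch")
  win <- li_window(peak_latency_s, spec, range(acc[[1]]$time))
  per_epoch <- vapply(acc, function(e) epoch_window_mean(e, win), numeric(1))
  parity <- seq_len(n) %% 2L
  c(li_odd = mean(per_epoch[parity == 1L]),
    li_even = mean(per_epoch[parity == 0L]))
}

#' Analyze a session end to end
#'
#' Convenience wrapper: [run_epoch_pipeline()] then [compute_li()].
#'
#' @param rec An [ftcd_recording()].
#' @param spec An [epoch_spec()].
#' @param ann A [trial_annotations()].
#' @return A `laterality_result`.
#' @export
analyze_session <- function(rec, spec = epoch_spec(),
                            ann = trial_annotations()) {
  epochs <- run_epoch_pipeline(rec, spec, ann)
  compute_li(epochs, spec, subject_id = rec$subject_id)
}

#' @export
print.laterality_result <- function(x, ...) {
  cat(sprintf("Laterality result%s\n",
              if (!is.na(x$subject_id)) paste0(" for ", x$subject_id) else ""))
  cat(sprintf("  accepted trials: %d\n", x$n_accepted))
  if (x$n_accepted > 0L) {
    cat(sprintf("  LI = %.2f (SE %.3f), 95%% CI [%.2f, %.2f]\n",
                x$li, x$se, x$ci95[1], x$ci95[2]))
    cat(sprintf("  peak latency: %.2f s after cue onset\n", x$peak_latency_s))
    cat(sprintf("  odd/even split LIs: %.2f / %.2f\n", x$li_odd, x$li_even))
  }
  cat(sprintf("  category: %s\n", x$category))
  invisible(x)
}

#' One-row summary of a laterality result
#'
#' @param result A `laterality_result`.
#' @return A one-row data frame with columns `subject_id`, `n_accepted`,
#'   `li`, `se`, `ci_low`, `ci_high`, `peak_latency_s`, `category`,
#'   `li_odd`, `li_even`.
#' @export
laterality_summary_row <- function(result) {
  data.frame(subject_id = result$subject_id, n_accepted = result$n_accepted,
             li = result$li, se = result$se, ci_low = result$ci95[1],
             ci_high = result$ci95[2], peak_latency_s = result$peak_latency_s,
             category = result$category, li_odd = result$li_odd,
             li_even = result$li_even, stringsAsFactors = FALSE)
}

#' Export a laterality result as JSON
#'
#' @param result A `laterality_result`.
#' @param path Output path.
#' @param include_curve Include the grand-average difference curve.
#' @return Invisibly, `path`.
#' @export
write_laterality_json <- function(result, path, include_curve = TRUE) {
  out <- unclass(result)
  if (!include_curve) out$diff_curve <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}
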