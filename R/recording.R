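#' Two-channel fTCD recording
#'
#' Container for a functional transcranial Doppler session: synchronized
#' left and right middle-cerebral-artery envelope velocity channels sampled
#' at `fs` Hz, plus trial-start marker events. Velocity is in arbitrary
#' (normalized downstream) units.
#'
#' @param left,right Numeric vectors of equal length, finite values.
#' @param fs Sampling rate in Hz (finite, > 0).
#' @param markers Integer vector of 1-based sample indices of trial starts,
#'   strictly increasing, each in `[1, N]`.
#' @param subject_id Subject identifier (single string).
#' @param t0 Time of the first sample in seconds (default 0).
#' @param meta Named list of free-form annotations.
#'
#' @return An object of class `ftcd_recording`: a list with elements
#'   `subject_id`, `fs`, `t0`, `left`, `right`, `markers`, `meta`.
#' @export
#' @examples
#' rec <- ftcd_recording(left = rnorm(100, 100), right = rnorm(100, 100),
#'                       fs = 25, markers = c(1, 51))
#' n_samples(rec)
ftcd_recording <- function(left, right, fs, markers = integer(),
                           subject_id = "anon", t0 = 0, meta = list()) {
  rec <- structure(
    list(subject_id = as.character(subject_id)[1], fs = as.numeric(fs)[1],
         t0 = as.numeric(t0)[1], left = as.numeric(left),
         right = as.numeric(right), markers = as.integer(markers),
         meta = meta),
    class = "ftcd_recording")
  validate_recording(rec)
  rec
}

#' @rdname ftcd_recording
#' @param rec An `ftcd_recording`.
#' @export
n_samples <- function(rec) length(rec$left)

validate_recording <- function(rec) {
  n <- length(rec$left)
  if (n < 1L) stop("recording must contain at least one sample")
  if (length(rec$right) != n)
    stop("left and right channels differ in length (", n, " vs ",
         length(rec$right), ")")
  if (!is.finite(rec$fs) || rec$fs <= 0) stop("fs must be finite and > 0")
  if (!all(is.finite(rec$left)) || !all(is.finite(rec$right)))
    stop("velocity samples must all be finite")
  m <- rec$markers
  if (length(m)) {
    if (any(m < 1L) || any(m > n)) stop("marker out of range")
    if (any(diff(m) <= 0L)) stop("marker indices must be strictly increasing")
  }
  invisible(rec)
}

#' @export
print.ftcd_recording <- function(x, ...) {
  cat(sprintf("fTCD recording '%s': %d samples @ %g Hz (%.1f s), %d markers\n",
              x$subject_id, n_samples(x), x$fs, n_samples(x) / x$fs,
              length(x$markers)))
  invisible(x)
}

#' Per-trial validity annotations
#'
#' Trials flagged by an observer as invalid (e.g. the child talked during
#' the baseline period, or was silent during the activation period). Every
#' excluded trial carries a reason.
#'
#' @param excluded_trials Integer vector of 1-based trial indices.
#' @param reasons Character vector of the same length as `excluded_trials`
#'   (recycled if length 1), or a named character vector / list mapping
#'   trial index to reason.
#' @return An object of class `trial_annotations`.
#' @export
trial_annotations <- function(excluded_trials = integer(), reasons = character()) {
  excluded_trials <- as.integer(excluded_trials)
  if (length(excluded_trials) && any(excluded_trials < 1L))
    stop("trial indices must be positive")
  if (anyDuplicated(excluded_trials)) stop("duplicate excluded trial index")
  if (length(excluded_trials)) {
    if (!length(reasons)) stop("every excluded trial needs a reason")
    if (!is.null(names(reasons))) {
      reasons <- unlist(reasons)[as.character(excluded_trials)]
      if (anyNA(reasons)) stop("every excluded trial needs a reason")
    } else if (length(reasons) == 1L) {
      reasons <- rep(as.character(reasons), length(excluded_trials))
    } else if (length(reasons) != length(excluded_trials)) {
      stop("reasons must match excluded_trials in length")
    }
    reasons <- as.character(reasons)
  } else reasons <- character()
  structure(list(excluded_trials = excluded_trials,
                 reasons = stats::setNames(reasons, excluded_trials)),
            class = "trial_annotations")
}

# ---------------------------------------------------------------------------
# File dialect `.ftcd.tsv`: one header line `#fs=<Hz> subject=<id>`, then
# tab-separated columns time_s, left, right, marker (0/1). UTF-8, LF.
# A missing marker column means "no markers".

#' Read an fTCD recording from the `.ftcd.tsv` text dialect
#'
#' The dialect is one comment header `#fs=<Hz> subject=<id>` followed by
#' tab-separated columns `time_s  left  right  marker`, where `marker` is 0
#' or 1 (1 = trial start at that sample). A file without the marker column
#' is read as having no markers.
#'
#' @param path Path to the file.
#' @param dialect Format name; only `"ftcd.tsv"` is supported.
#' @return An [ftcd_recording()].
#' @export
read_recording <- function(path, dialect = "ftcd.tsv") {
  if (!identical(dialect, "ftcd.tsv"))
    stop("unknown dialect: ", dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("line 1: empty file")
  hdr <- lines[[1]]
  if (!startsWith(hdr, "#"))
    stop("line 1: malformed header (expected '#fs=<Hz> subject=<id>')")
  fs_m <- regmatches(hdr, regexec("fs=([0-9eE.+-]+)", hdr))[[1]]
  if (length(fs_m) < 2L) stop("line 1: malformed header: missing fs")
  fs <- suppressWarnings(as.numeric(fs_m[2]))
  if (!is.finite(fs) || fs <= 0) stop("line 1: malformed header: bad fs value")
  sid_m <- regmatches(hdr, regexec("subject=([^[:space:]]+)", hdr))[[1]]
  subject <- if (length(sid_m) >= 2L) sid_m[2] else "anon"

  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body)) stop("line 2: no samples")
  fields <- strsplit(body, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    bad <- which(ncol < 3L)[1]
    stop("line ", bad + 1L, ": expected at least 3 tab-separated columns")
  }
  has_marker <- ncol[1] >= 4L
  parse_col <- function(k, what) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", k)))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("line ", bad + 1L, ": non-numeric ", what, " value")
    }
    v
  }
  time_s <- parse_col(1L, "time")
  left   <- parse_col(2L, "left")
  right  <- parse_col(3L, "right")
  if (length(time_s) > 1L && any(diff(time_s) <= 0)) {
    bad <- which(diff(time_s) <= 0)[1] + 1L
    stop("line ", bad + 1L, ": non-monotone time column")
  }
  markers <- integer()
  if (has_marker) {
    mk <- parse_col(4L, "marker")
    if (any(!mk %in% c(0, 1))) {
      bad <- which(!mk %in% c(0, 1))[1]
      stop("line ", bad + 1L, ": marker flag must be 0 or 1")
    }
    markers <- which(mk == 1)
  }
  ftcd_recording(left = left, right = right, fs = fs, markers = markers,
                 subject_id = subject, t0 = time_s[1])
}

#' Write an fTCD recording in the `.ftcd.tsv` text dialect
#'
#' @param rec An [ftcd_recording()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  n <- n_samples(rec)
  time_s <- rec$t0 + (seq_len(n) - 1L) / rec$fs
  mk <- integer(n)
  mk[rec$markers] <- 1L
  hdr <- sprintf("#fs=%s subject=%s", format(rec$fs, digits = 17),
                 rec$subject_id)
  rows <- paste(sprintf("%.17g", time_s), sprintf("%.17g", rec$left),
                sprintf("%.17g", rec$right), mk, sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Downsampling

# Symmetric windowed-sinc (Hamming) low-pass FIR; applied centred, so the
# filter is zero-phase by construction. Edges handled by reflection padding.
fir_lowpass <- function(x, fs, cutoff_hz, n_taps = NULL) {
  if (cutoff_hz >= fs / 2) return(x)
  if (is.null(n_taps)) {
    n_taps <- ceiling(4 * fs / cutoff_hz)
    if (n_taps %% 2 == 0) n_taps <- n_taps + 1L
  }
  m <- (n_taps - 1L) / 2L
  k <- seq(-m, m)
  fc <- cutoff_hz / fs
  h <- 2 * fc * sinc(2 * fc * k) * (0.54 + 0.46 * cos(pi * k / m))
  h <- h / sum(h)
  n <- length(x)
  pad_n <- min(m, n - 1L)
  xp <- c(rev(x[seq_len(pad_n) + 1L]), x, x[n - seq_len(pad_n)])
  y <- stats::filter(xp, h, method = "convolution", sides = 2)
  as.numeric(y[pad_n + seq_len(n)])
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Nearest output sample for a 1-based input index, ties rounding down.
remap_marker <- function(idx, ratio, n_out) {
  pos <- (idx - 1) * ratio          # 0-based output position
  new0 <- ceiling(pos - 0.5)        # round half down
  pmin(pmax(new0 + 1L, 1L), n_out)
}

#' Downsample a recording to the analysis rate
#'
#' Applies a zero-phase anti-alias low-pass (cutoff `0.4 * target_fs`)
#' before rate reduction. Integer rate ratios take a decimation path;
#' non-integer ratios are linearly interpolated onto the target grid after
#' filtering. Marker indices are remapped to the nearest output sample
#' (ties round down).
#'
#' @param rec An [ftcd_recording()].
#' @param target_fs Target sampling rate in Hz; must satisfy
#'   `0 < target_fs <= rec$fs`.
#' @return An [ftcd_recording()] at `target_fs`.
#' @export
downsample <- function(rec, target_fs) {
  validate_recording(rec)
  if (!is.finite(target_fs) || target_fs <= 0) stop("target_fs must be > 0")
  if (target_fs > rec$fs) stop("target_fs exceeds recording rate")
  if (target_fs == rec$fs) return(rec)
  ratio <- target_fs / rec$fs
  n <- n_samples(rec)
  left <- fir_lowpass(rec$left, rec$fs, 0.4 * target_fs)
  right <- fir_lowpass(rec$right, rec$fs, 0.4 * target_fs)
  q <- rec$fs / target_fs
  if (abs(q - round(q)) < 1e-9) {
    q <- as.integer(round(q))
    keep <- seq(1L, n, by = q)
    left <- left[keep]; right <- right[keep]
    n_out <- length(keep)
  } else {
    n_out <- floor(n * ratio)
    t_in <- (seq_len(n) - 1L) / rec$fs
    t_out <- (seq_len(n_out) - 1L) / target_fs
    left <- stats::approx(t_in, left, xout = t_out, rule = 2)$y
    right <- stats::approx(t_in, right, xout = t_out, rule = 2)$y
  }
  markers <- if (length(rec$markers))
    remap_marker(rec$markers, ratio, n_out) else integer()
  ftcd_recording(left = left, right = right, fs = target_fs,
                 markers = markers, subject_id = rec$subject_id,
                 t0 = rec$t0, meta = rec$meta)
}
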