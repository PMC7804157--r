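## Preprocessing of raw keypoint trajectories.
##
## Stage order follows the analysis pipeline: segment around the beep events,
## Fourier duration-normalization, temporal smoothing, outlier interpolation,
## then restriction to the temporal range of interest (ROI). Every operation
## acts per keypoint column, so outputs are invariant to keypoint ordering.

#' Preprocessing parameters
#'
#' @param pre_pad Frames kept before initiation-beep onset (default 30).
#' @param post_pad Frames kept after termination-beep onset (default 90).
#' @param smooth_window Moving-average width in frames (default 6 = 100 ms
#'   at 60 Hz).
#' @param outlier_threshold Minimum pixel deviation from the previous
#'   retained frame that marks a sample as an outlier (default 100).
#' @param target_durations Optional named seconds per duration class the
#'   trials are normalized to; `NULL` means each trial's nominal duration.
#' @return Object of class `preproc_params`.
#' @export
preproc_params <- function(pre_pad = 30L, post_pad = 90L, smooth_window = 6L,
                           outlier_threshold = 100,
                           target_durations = NULL) {
  stopifnot(pre_pad >= 0, post_pad >= 0, smooth_window >= 1,
            outlier_threshold > 0)
  structure(list(pre_pad = as.integer(pre_pad),
                 post_pad = as.integer(post_pad),
                 smooth_window = as.integer(smooth_window),
                 outlier_threshold = outlier_threshold,
                 target_durations = target_durations),
            class = "preproc_params")
}

#' Segment a trajectory around the beep events
#'
#' Keeps frames from `pre_pad` before initiation-beep onset to `post_pad`
#' after termination-beep onset (inclusive), re-indexing events so the
#' initiation onset lands on frame `pre_pad` (0-based).
#'
#' @param traj A `keypoint_trajectory`.
#' @param p A [preproc_params()].
#' @return The segmented `keypoint_trajectory`.
#' @export
segment_trial <- function(traj, p = preproc_params()) {
  validate_trajectory(traj)
  init <- traj$events$initiation_frame
  term <- traj$events$termination_frame
  n <- n_frames(traj)
  lo <- init - p$pre_pad
  hi <- term + p$post_pad
  if (lo < 0)
    stop(sprintf("insufficient pre-initiation frames: %d available, %d required",
                 init, p$pre_pad))
  if (hi > n - 1L)
    stop(sprintf("insufficient post-termination frames: %d available, %d required",
                 n - 1L - term, p$post_pad))
  rows <- (lo:hi) + 1L
  out <- traj
  out$y <- traj$y[rows, , drop = FALSE]
  if (!is.null(traj$x)) out$x <- traj$x[rows, , drop = FALSE]
  out$events$initiation_frame <- p$pre_pad
  out$events$termination_frame <- p$pre_pad + (term - init)
  out
}

#' Fourier-interpolated resampling of a series
#'
#' Resamples a series to `target_len` samples on the same interval by
#' truncating or zero-padding its discrete Fourier spectrum (the classical
#' `interpft` construction), so energy at representable frequencies is
#' preserved proportionally and band-limited inputs round-trip exactly.
#'
#' @param y Numeric series (length >= 2, finite).
#' @param target_len Desired length (>= 2).
#' @return Numeric series of length `target_len`.
#' @export
normalize_duration <- function(y, target_len) {
  n <- length(y)
  if (n < 2) stop("series too short to resample")
  if (target_len < 2) stop("target_len must be at least 2")
  if (anyNA(y)) stop("series contains missing values; interpolate first")
  m <- as.integer(target_len)
  if (m == n) return(y)
  a <- stats::fft(y) / n
  b <- rep(0 + 0i, m)
  kmax <- floor((min(n, m) - 1) / 2)
  b[1] <- a[1]
  if (kmax >= 1) {
    b[2:(kmax + 1)] <- a[2:(kmax + 1)]
    b[(m - kmax + 1):m] <- a[(n - kmax + 1):n]
  }
  if (min(n, m) %% 2 == 0) {
    kn <- min(n, m) / 2
    if (m > n) {          # split the source Nyquist bin
      b[kn + 1] <- a[kn + 1] / 2
      b[m - kn + 1] <- a[kn + 1] / 2
    } else {              # fold source +/- kn onto the new Nyquist bin
      b[kn + 1] <- a[kn + 1] + a[n - kn + 1]
    }
  }
  Re(stats::fft(b, inverse = TRUE))
}

#' Duration-normalize a segmented trajectory
#'
#' Rescales the time axis so the initiation-to-termination duration equals
#' the target duration for the trial's class (each keypoint series is
#' Fourier-resampled; events are re-indexed by the same factor).
#'
#' @param traj A segmented `keypoint_trajectory`.
#' @param p A [preproc_params()]; `p$target_durations` may name the target
#'   seconds per class, defaulting to the trial's nominal duration.
#' @return The normalized trajectory.
#' @export
normalize_trial <- function(traj, p = preproc_params()) {
  ev <- traj$events
  fs <- traj$sampling_rate
  d_actual <- (ev$termination_frame - ev$initiation_frame) / fs
  d_target <- if (is.null(p$target_durations)) ev$nominal_duration
  else p$target_durations[[traj$duration_class]]
  r <- (round(d_target * fs)) / (ev$termination_frame - ev$initiation_frame)
  n <- n_frames(traj)
  m <- max(2L, as.integer(round(n * r)))
  out <- traj
  out$y <- apply(traj$y, 2, normalize_duration, target_len = m)
  colnames(out$y) <- traj$keypoints
  if (!is.null(traj$x)) {
    out$x <- apply(traj$x, 2, normalize_duration, target_len = m)
    colnames(out$x) <- traj$keypoints
  }
  out$events$initiation_frame <- as.integer(round(ev$initiation_frame * r))
  out$events$termination_frame <- out$events$initiation_frame +
    as.integer(round(d_target * fs))
  if (out$events$termination_frame > m - 1L)
    out$events$termination_frame <- m - 1L
  out
}

#' Centered moving-average smoothing
#'
#' Width-`window` centered moving average; at the edges the window shrinks
#' (no padding), so constant series are preserved exactly end to end. For
#' even widths the window extends one frame further forward than backward.
#' Missing samples are ignored within each window.
#'
#' @param y Numeric series.
#' @param window Width in frames (>= 1, <= length of the series).
#' @return Smoothed series of the same length.
#' @export
smooth_series <- function(y, window = 6L) {
  n <- length(y)
  if (window < 1) stop("window must be at least 1")
  if (window > n) stop("window exceeds series length")
  if (window == 1) return(y)
  lo <- floor((window - 1) / 2)
  hi <- ceiling((window - 1) / 2)
  yc <- ifelse(is.na(y), 0, y)
  cs <- cumsum(yc)
  cn <- cumsum(!is.na(y))
  i <- seq_len(n)
  a <- pmax(i - lo, 1L)
  b <- pmin(i + hi, n)
  tot <- cs[b] - c(0, cs)[a]
  cnt <- cn[b] - c(0, cn)[a]
  out <- tot / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Flag and interpolate outlier samples
#'
#' A sample is an outlier when its absolute deviation from the previous
#' *retained* (non-outlier, non-missing) sample is at least `threshold`
#' pixels, so runs of consecutive spikes are fully flagged. Flagged and
#' originally missing samples are filled by piecewise-linear interpolation
#' against the frame index (end values held constant).
#'
#' @param y Numeric series, possibly with missing samples.
#' @param threshold Pixel threshold (> 0).
#' @return List with `y` (filled series) and `mask` (logical, `TRUE` where
#'   a sample was flagged as an outlier; originally missing samples are not
#'   part of the mask).
#' @export
interpolate_outliers <- function(y, threshold = 100) {
  n <- length(y)
  mask <- logical(n)
  last <- NA_real_
  for (i in seq_len(n)) {
    v <- y[i]
    if (is.na(v)) next
    if (!is.na(last) && abs(v - last) >= threshold) mask[i] <- TRUE
    else last <- v
  }
  keep <- !mask & !is.na(y)
  if (!any(keep)) stop("all samples flagged or missing; nothing to interpolate from")
  if (all(keep)) return(list(y = y, mask = mask))
  filled <- stats::approx(which(keep), y[keep], xout = seq_len(n),
                          rule = 2)$y
  list(y = filled, mask = mask)
}

#' Temporal range-of-interest indices
#'
#' The analyzed epoch runs from 1000 ms after initiation-beep onset to the
#' termination-beep onset: 0-based frames `i` with
#' `fs <= i <= round(d * fs)`, where `d` is the normalized trial duration in
#' seconds. At 60 Hz this yields 344 frames for 6.71 s trials and 609 for
#' 11.14 s trials.
#'
#' @param d Normalized duration in seconds.
#' @param fs Sampling rate in Hz.
#' @return Integer vector of 0-based frame offsets from initiation onset.
#' @export
roi_indices <- function(d, fs = 60) {
  hi <- round(d * fs)
  if (hi < fs) stop("trial too short for a range of interest (d*fs < fs)")
  seq.int(fs, hi)
}

#' Restrict a preprocessed trajectory to the range of interest
#'
#' @param traj A segmented (and typically normalized/smoothed) trajectory.
#' @return Matrix of ROI frames x keypoints of vertical coordinates, with
#'   attribute `"frames"` giving the 0-based frame offsets from initiation.
#' @export
range_of_interest <- function(traj) {
  ev <- traj$events
  fs <- traj$sampling_rate
  d <- (ev$termination_frame - ev$initiation_frame) / fs
  idx <- roi_indices(d, fs)
  rows <- ev$initiation_frame + idx + 1L
  if (max(rows) > n_frames(traj))
    stop("range of interest extends beyond the trajectory")
  out <- traj$y[rows, , drop = FALSE]
  attr(out, "frames") <- idx
  out
}

#' Run the full preprocessing chain on one trial
#'
#' segment -> duration-normalize -> smooth -> outlier-interpolate -> ROI.
#'
#' @param traj Raw `keypoint_trajectory`.
#' @param p A [preproc_params()].
#' @return List of class `preprocessed_trial`: `traj` (processed, full
#'   segmented length), `roi` (ROI frames x keypoints matrix of vertical
#'   series), `outlier_counts` (per keypoint), and the trial metadata
#'   carried over (`condition`, `duration_class`, ids).
#' @export
preprocess_trial <- function(traj, p = preproc_params()) {
  tr <- segment_trial(traj, p)
  tr <- normalize_trial(tr, p)
  ocount <- integer(length(tr$keypoints))
  names(ocount) <- tr$keypoints
  for (k in tr$keypoints) {
    s <- smooth_series(tr$y[, k], p$smooth_window)
    io <- interpolate_outliers(s, p$outlier_threshold)
    tr$y[, k] <- io$y
    ocount[k] <- sum(io$mask)
  }
  structure(list(
    traj = tr,
    roi = range_of_interest(tr),
    outlier_counts = ocount,
    participant_id = tr$participant_id, trial_id = tr$trial_id,
    condition = tr$condition, duration_class = tr$duration_class
  ), class = "preprocessed_trial")
}

#' Preprocess a list of trials
#'
#' Convenience wrapper: when `p$target_durations` is `NULL`, the trials are
#' normalized to the per-class mean of their actual initiation-termination
#' durations (the per-participant normalization target).
#'
#' @param trials List of raw `keypoint_trajectory` objects.
#' @param p A [preproc_params()].
#' @return List of `preprocessed_trial` objects.
#' @export
preprocess_trials <- function(trials, p = preproc_params()) {
  if (is.null(p$target_durations)) {
    dur <- vapply(trials, function(tr)
      (tr$events$termination_frame - tr$events$initiation_frame) /
        tr$sampling_rate, numeric(1))
    cls <- vapply(trials, function(tr) tr$duration_class, character(1))
    p$target_durations <- tapply(dur, cls, mean)
  }
  lapply(trials, preprocess_trial, p = p)
}
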