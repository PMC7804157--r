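## Automaticity metrics: tapping rate and FWHM band from pooled inter-trial
## coherence; inter-finger and inter-trial coherence summaries; Hilbert-
## envelope tapping amplitude and the attentional modulation index.

#' Frequency band of interest
#'
#' @param tapping_rate Peak frequency of the pooled coherence spectrum (Hz).
#' @param f_low,f_high FWHM band edges (Hz), `f_low < tapping_rate < f_high`.
#' @return Object of class `band_of_interest`.
#' @export
band_of_interest <- function(tapping_rate, f_low, f_high) {
  if (!(f_low < tapping_rate && tapping_rate < f_high))
    stop("band must satisfy f_low < tapping_rate < f_high")
  structure(list(tapping_rate = tapping_rate, f_low = f_low, f_high = f_high),
            class = "band_of_interest")
}

#' @export
print.band_of_interest <- function(x, ...) {
  cat(sprintf("<band_of_interest> tapping rate %.3f Hz, FWHM band [%.3f, %.3f] Hz\n",
              x$tapping_rate, x$f_low, x$f_high))
  invisible(x)
}

#' Mean coherence spectrum over a set of WTC maps
#'
#' Per frequency, averages coherence over COI-valid points in the temporal
#' range of interest within each map, then across maps. Frequencies with no
#' valid point anywhere are reported as `NA` and excluded from peak search.
#'
#' @param maps List of `wtc_map` objects sharing one frequency grid.
#' @param roi Optional integer vector of time rows to average over
#'   (default: all rows).
#' @return Numeric vector of per-frequency mean coherence with attribute
#'   `freqs`.
#' @export
mean_coherence_spectrum <- function(maps, roi = NULL) {
  if (length(maps) < 1) stop("need at least one map")
  freqs <- maps[[1]]$freqs
  per_map <- sapply(maps, function(m) {
    if (!isTRUE(all.equal(m$freqs, freqs)))
      stop("maps do not share one frequency grid")
    rows <- roi %||% seq_len(nrow(m$coherence))
    co <- m$coherence[rows, , drop = FALSE]
    valid <- m$coi_mask[rows, , drop = FALSE]
    co[!valid] <- NA
    colMeans(co, na.rm = TRUE)
  })
  spec <- rowMeans(per_map, na.rm = TRUE)
  spec[!is.finite(spec)] <- NA
  attr(spec, "freqs") <- freqs
  spec
}

#' Tapping rate and FWHM band from a coherence spectrum
#'
#' The tapping rate is the frequency of the spectrum's global peak; the band
#' is the maximal contiguous interval around the peak where the spectrum
#' stays at or above half the peak value, with the half-maximum crossings
#' linearly interpolated between grid points (clamped to the grid span when
#' the spectrum never falls below half maximum on one side).
#'
#' @param spectrum Per-frequency coherence (with attribute `freqs`, or pass
#'   `freqs` explicitly). `NA` entries are excluded from the peak search.
#' @param freqs Frequency grid in Hz.
#' @return A [band_of_interest()].
#' @export
estimate_band <- function(spectrum, freqs = attr(spectrum, "freqs")) {
  if (is.null(freqs)) stop("frequency grid required")
  s <- as.numeric(spectrum)
  ok <- which(is.finite(s))
  if (length(ok) < 3) stop("too few valid frequencies for a peak")
  pk_val <- max(s[ok])
  pk_cand <- ok[s[ok] == pk_val]
  if (length(pk_cand) > 1)
    warning("plateau peak; using the leftmost maximum")
  pk <- pk_cand[1]
  if (pk == ok[1] || pk == ok[length(ok)])
    stop("spectrum peak at grid boundary; extend the frequency grid")
  half <- pk_val / 2

  cross <- function(i0, i1) {  # linear interpolation of the half crossing
    freqs[i0] + (half - s[i0]) / (s[i1] - s[i0]) * (freqs[i1] - freqs[i0])
  }
  f_low <- freqs[ok[1]]
  for (i in pk:(ok[1] + 1)) {
    if (is.finite(s[i - 1]) && s[i - 1] < half) { f_low <- cross(i - 1, i); break }
  }
  f_high <- freqs[ok[length(ok)]]
  for (i in pk:(ok[length(ok)] - 1)) {
    if (is.finite(s[i + 1]) && s[i + 1] < half) { f_high <- cross(i + 1, i); break }
  }
  band_of_interest(freqs[pk], f_low, f_high)
}

band_rows <- function(band, freqs) {
  idx <- which(freqs >= band$f_low & freqs <= band$f_high)
  if (!length(idx)) idx <- which.min(abs(freqs - band$tapping_rate))
  idx
}

## mean coherence over COI-valid points restricted to band columns
masked_band_mean <- function(map, band) {
  cols <- band_rows(band, map$freqs)
  co <- map$coherence[, cols, drop = FALSE]
  valid <- map$coi_mask[, cols, drop = FALSE]
  if (!any(valid)) return(NA_real_)
  mean(co[valid])
}

#' Inter-trial coherence of one fingertip
#'
#' WTC between the ROI series of the same fingertip on every unordered pair
#' of trials; coherence averaged over COI-valid points in the FWHM band,
#' then over pairs (n trials give `n*(n-1)/2` pairs).
#'
#' @param series List of equal-length ROI series (one per trial).
#' @param band A [band_of_interest()].
#' @param p A [wavelet_params()].
#' @return Mean coherence in \[0, 1\] with attribute `n_pairs`.
#' @export
inter_trial_coherence <- function(series, band, p = wavelet_params()) {
  m <- length(series)
  if (m < 2) stop("need at least 2 trials for inter-trial coherence")
  lens <- lengths(series)
  if (length(unique(lens)) != 1)
    stop("trials must share one normalized length")
  pairs <- utils::combn(m, 2)
  vals <- apply(pairs, 2, function(ij)
    masked_band_mean(wtc(series[[ij[1]]], series[[ij[2]]], p), band))
  structure(mean(vals, na.rm = TRUE), n_pairs = ncol(pairs))
}

#' Inter-finger coherence within one trial
#'
#' WTC between every unordered pair of the four tapping fingertips' ROI
#' series (6 pairs), averaged over COI-valid points in the FWHM band and
#' over pairs. Coherence is invariant to fixed phase lags between fingers,
#' so sequential tapping with stable lags yields values near 1.
#'
#' @param Y ROI frames x fingertips matrix (4 named columns).
#' @param band A [band_of_interest()].
#' @param p A [wavelet_params()].
#' @return Mean coherence in \[0, 1\] with attribute `n_pairs`.
#' @export
inter_finger_coherence <- function(Y, band, p = wavelet_params()) {
  want <- fingertip_keypoints()
  missing_kp <- setdiff(want, colnames(Y))
  if (length(missing_kp))
    stop("missing fingertip series: ", paste(missing_kp, collapse = ", "))
  Y <- Y[, want, drop = FALSE]
  pairs <- t(utils::combn(4, 2))
  co <- wtc_pairs_coherence(Y, p, pairs)
  coi <- attr(co, "coi")
  cols <- band_rows(band, p$freqs)
  vals <- apply(co, 3, function(m) {
    v <- m[, cols, drop = FALSE]; k <- coi[, cols, drop = FALSE]
    if (!any(k)) NA_real_ else mean(v[k])
  })
  structure(mean(vals, na.rm = TRUE), n_pairs = nrow(pairs))
}

#' Estimate a participant's tapping band from preprocessed trials
#'
#' Pools inter-trial WTC maps of the four fingertips across all conditions
#' and duration classes (pairs formed within condition and duration class so
#' lengths match), averages them into one coherence spectrum, and extracts
#' the tapping rate and FWHM band.
#'
#' @param ptrials List of `preprocessed_trial` objects for one participant.
#' @param p A [wavelet_params()].
#' @param fingertips Keypoints to use (default the four fingertips).
#' @return A [band_of_interest()] with attribute `spectrum`.
#' @export
participant_band <- function(ptrials, p = wavelet_params(),
                             fingertips = fingertip_keypoints()) {
  groups <- split(ptrials, interaction(
    vapply(ptrials, `[[`, "", "condition"),
    vapply(ptrials, `[[`, "", "duration_class"), drop = TRUE))
  maps <- list()
  for (g in groups) {
    if (length(g) < 2) next
    pairs <- utils::combn(length(g), 2)
    for (tip in fingertips) for (q in seq_len(ncol(pairs))) {
      maps[[length(maps) + 1]] <-
        wtc(g[[pairs[1, q]]]$roi[, tip], g[[pairs[2, q]]]$roi[, tip], p)
    }
  }
  if (!length(maps))
    stop("fewer than 2 trials in every condition: cannot pool inter-trial maps")
  spec <- mean_coherence_spectrum(maps)
  band <- estimate_band(spec)
  attr(band, "spectrum") <- spec
  band
}

#' Per-condition coherence summary
#'
#' Mean inter-finger and inter-trial coherence per condition (inter-trial
#' values averaged over the four fingertips; trial pairs formed within
#' duration class), with the pair counts entering each average.
#'
#' @param ptrials List of `preprocessed_trial` objects for one participant.
#' @param band A [band_of_interest()].
#' @param p A [wavelet_params()].
#' @param fingertips Fingertip keypoints used.
#' @return Data frame: condition, inter_finger, inter_trial, n_finger_pairs,
#'   n_trial_pairs.
#' @export
coherence_summary <- function(ptrials, band, p = wavelet_params(),
                              fingertips = fingertip_keypoints()) {
  conds <- unique(vapply(ptrials, `[[`, "", "condition"))
  rows <- lapply(conds, function(cn) {
    sel <- ptrials[vapply(ptrials, `[[`, "", "condition") == cn]
    if (length(sel) < 2)
      stop("fewer than 2 trials for condition ", cn)
    if_vals <- vapply(sel, function(tr)
      as.numeric(inter_finger_coherence(tr$roi[, fingertips], band, p)),
      numeric(1))
    it_vals <- c(); it_pairs <- 0L
    for (dc in unique(vapply(sel, `[[`, "", "duration_class"))) {
      sub <- sel[vapply(sel, `[[`, "", "duration_class") == dc]
      if (length(sub) < 2) next
      for (tip in fingertips) {
        v <- inter_trial_coherence(lapply(sub, function(tr) tr$roi[, tip]),
                                   band, p)
        it_vals <- c(it_vals, as.numeric(v))
        it_pairs <- it_pairs + attr(v, "n_pairs")
      }
    }
    data.frame(condition = cn,
               inter_finger = mean(if_vals),
               inter_trial = if (length(it_vals)) mean(it_vals) else NA_real_,
               n_finger_pairs = 6L * length(sel),
               n_trial_pairs = it_pairs,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## analytic signal via FFT (no installed package provides it)
analytic_signal <- function(y) {
  n <- length(y)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(y) * h, inverse = TRUE) / n
}

#' Hilbert-envelope tapping amplitude
#'
#' Band-passes the ROI series into the FWHM band (zero-phase forward-
#' backward 4th-order Butterworth by default; a causal single-pass mode is
#' available for comparison), takes the analytic-signal magnitude, and
#' averages it over the ROI excluding one settling length (one period of
#' `f_low`) at each edge.
#'
#' @param y ROI vertical series (demeaned internally).
#' @param band A [band_of_interest()].
#' @param fs Sampling rate in Hz.
#' @param causal If `TRUE`, apply the filter causally (single pass).
#' @return Amplitude `A` in pixels (mean envelope).
#' @export
envelope_amplitude <- function(y, band, fs = 60, causal = FALSE) {
  ny <- fs / 2
  if (band$f_high >= ny || band$f_low <= 0)
    stop("band outside (0, Nyquist)")
  n <- length(y)
  n_edge <- ceiling(fs / band$f_low)
  if (n <= 3 * n_edge)
    stop("ROI series shorter than 3 filter settling lengths")
  bf <- signal::butter(4, c(band$f_low, band$f_high) / ny, type = "pass")
  yc <- y - mean(y)
  filt <- if (causal) signal::filter(bf, yc) else signal::filtfilt(bf, yc)
  env <- Mod(analytic_signal(as.numeric(filt)))
  mean(env[(n_edge + 1):(n - n_edge)])
}

#' Attentional modulation index
#'
#' `I_A = A_attention / A_reference - 1`: positive values indicate
#' facilitation (larger tapping amplitude than under the reference
#' condition), negative values inhibition. The reference condition maps to
#' exactly 0.
#'
#' @param A_attention,A_reference Amplitudes in pixels (`A_reference > 0`).
#' @return Dimensionless modulation index (> -1).
#' @export
modulation_index <- function(A_attention, A_reference) {
  if (any(A_reference <= 0)) stop("reference amplitude must be positive")
  A_attention / A_reference - 1
}

#' Per finger x condition amplitude table
#'
#' Mean envelope amplitude of each fingertip per condition, and the
#' modulation index against the reference condition.
#'
#' @param ptrials List of `preprocessed_trial` objects for one participant.
#' @param band A [band_of_interest()].
#' @param fs Sampling rate in Hz.
#' @param reference Reference condition label.
#' @return Data frame: finger, condition, A (pixels), I_A.
#' @export
amplitude_table <- function(ptrials, band, fs = 60, reference = "reference") {
  conds <- unique(vapply(ptrials, `[[`, "", "condition"))
  if (!reference %in% conds)
    stop("no trials for the reference condition: ", reference)
  tips <- fingertip_keypoints()
  fingers <- sub("_tip$", "", tips)
  A <- matrix(NA_real_, length(tips), length(conds),
              dimnames = list(fingers, conds))
  for (cn in conds) {
    sel <- ptrials[vapply(ptrials, `[[`, "", "condition") == cn]
    for (i in seq_along(tips)) {
      A[i, cn] <- mean(vapply(sel, function(tr)
        envelope_amplitude(tr$roi[, tips[i]], band, fs), numeric(1)))
    }
  }
  out <- expand.grid(finger = fingers, condition = conds,
                     stringsAsFactors = FALSE)
  out$A <- A[cbind(out$finger, out$condition)]
  out$I_A <- modulation_index(out$A, A[out$finger, reference])
  out$I_A[out$condition == reference] <- 0
  out
}
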