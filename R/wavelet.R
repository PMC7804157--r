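## Morlet continuous wavelet transform and wavelet-transform coherence (WTC).
##
## Conventions follow the Torrence & Compo CWT normalization with the
## Torrence & Webster smoothing used by the standard cross-wavelet/WTC
## toolbox: Gaussian smoothing in time with width proportional to scale,
## boxcar smoothing across scales over a fixed decorrelation length.
## Transforms are computed by zero-padding to the next power of two and
## truncating; the cone of influence (COI) marks where edge effects are
## negligible and all downstream averages exclude COI-invalid points.

#' Wavelet analysis parameters
#'
#' @param omega0 Morlet nondimensional frequency (>= 5 for practical
#'   admissibility; default 6).
#' @param freqs Strictly increasing analysis frequencies in Hz; default 40
#'   logarithmically spaced points on \[0.5, 15\] Hz, bracketing observed
#'   tapping rates (3.07-8.43 Hz) with margin for harmonics.
#' @param dt Sampling interval in seconds (default 1/60).
#' @param scale_smooth Decorrelation length of the boxcar smoothing across
#'   scales, in octaves (default 0.6).
#' @param time_smooth Width of the Gaussian time smoothing as a multiple of
#'   scale (default 1, the conventional choice).
#' @return Object of class `wavelet_params` with derived fields: `scales`,
#'   `fourier_factor`, `dj` (mean log2 frequency spacing).
#' @export
wavelet_params <- function(omega0 = 6,
                           freqs = exp(seq(log(0.5), log(15), length.out = 40)),
                           dt = 1 / 60, scale_smooth = 0.6,
                           time_smooth = 1) {
  if (omega0 < 5) stop("omega0 must be at least 5")
  if (any(diff(freqs) <= 0)) stop("freqs must be strictly increasing")
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  structure(list(
    omega0 = omega0, freqs = freqs, dt = dt, scale_smooth = scale_smooth,
    time_smooth = time_smooth,
    fourier_factor = ff, scales = 1 / (ff * freqs),
    dj = mean(diff(log2(freqs)))
  ), class = "wavelet_params")
}

next_pow2 <- function(n) 2^ceiling(log2(n))

## angular FFT frequencies of a length-N grid at sampling interval dt
fft_omega <- function(N, dt) {
  k <- c(0:floor(N / 2), -(ceiling(N / 2) - 1):-1)
  2 * pi * k / (N * dt)
}

## Precomputed machinery for repeated transforms of equal-length series:
## Morlet daughters, time-smoothing Gaussians, scale-smoothing operator and
## COI mask for a fixed series length.
wtc_plan <- function(n, p) {
  stopifnot(inherits(p, "wavelet_params"), n >= 2)
  npad <- next_pow2(n)
  omega <- fft_omega(npad, p$dt)
  pos <- omega > 0
  nf <- length(p$freqs)
  daughters <- matrix(0, npad, nf)
  for (j in seq_len(nf)) {
    s <- p$scales[j]
    daughters[pos, j] <- sqrt(2 * pi * s / p$dt) * pi^(-0.25) *
      exp(-0.5 * (s * omega[pos] - p$omega0)^2)
  }
  tsmooth <- exp(-0.5 * outer(omega^2, (p$time_smooth * p$scales)^2))
  w <- max(1L, as.integer(round(p$scale_smooth / p$dj)))
  lo <- floor((w - 1) / 2); hi <- ceiling((w - 1) / 2)
  M <- matrix(0, nf, nf)
  for (k in seq_len(nf)) {
    idx <- max(1, k - lo):min(nf, k + hi)
    M[idx, k] <- 1 / length(idx)
  }
  list(n = n, npad = npad, nf = nf, p = p, daughters = daughters,
       tsmooth = tsmooth, scale_op = M,
       coi = cone_of_influence(n, p))
}

## The series mean is removed before transforming: the Morlet wavelet has
## (numerically) zero mean, but zero-padding a series with a large offset
## creates a step edge whose leakage would dominate low-frequency
## coefficients identically in every trial.
cwt_with_plan <- function(y, plan) {
  y <- y - mean(y)
  yh <- stats::fft(c(y, rep(0, plan$npad - plan$n)))
  W <- stats::mvfft(plan$daughters * yh, inverse = TRUE) / plan$npad
  W[seq_len(plan$n), , drop = FALSE]
}

## Torrence-Webster smoothing of a (possibly complex) time x scale field that
## has already been divided by scale: Gaussian in time (width = scale),
## boxcar across scales.
smooth_with_plan <- function(A, plan) {
  Ap <- rbind(A, matrix(0, plan$npad - plan$n, plan$nf))
  sm <- stats::mvfft(stats::mvfft(Ap) * plan$tsmooth, inverse = TRUE) /
    plan$npad
  sm <- sm[seq_len(plan$n), , drop = FALSE]
  sm %*% plan$scale_op
}

#' Morlet continuous wavelet transform
#'
#' Computes the CWT of a series at the scales corresponding to the analysis
#' frequency grid, via FFT with zero-padding to the next power of two
#' (results truncated to the input length). The transform is linear in its
#' input.
#'
#' @param y Finite numeric series, at least two samples per period of the
#'   longest analyzed period.
#' @param p A [wavelet_params()].
#' @return Complex matrix, time x frequency, with attributes `freqs`,
#'   `scales` and `times`.
#' @export
cwt_morlet <- function(y, p = wavelet_params()) {
  n <- length(y)
  if (n < 2) stop("series too short")
  if (!all(is.finite(y))) stop("series contains non-finite values; preprocess first")
  plan <- wtc_plan(n, p)
  W <- cwt_with_plan(y, plan)
  attr(W, "freqs") <- p$freqs
  attr(W, "scales") <- p$scales
  attr(W, "times") <- (seq_len(n) - 1) * p$dt
  W
}

#' Cone of influence mask
#'
#' A time-frequency point is valid (inside the cone) when its distance to
#' the nearer series edge exceeds the Morlet e-folding time `sqrt(2) * s` of
#' its scale.
#'
#' @param n_frames Series length (>= 2).
#' @param p A [wavelet_params()].
#' @return Logical time x frequency matrix; `TRUE` = valid.
#' @export
cone_of_influence <- function(n_frames, p = wavelet_params()) {
  if (n_frames < 2) stop("need at least 2 frames")
  i <- 0:(n_frames - 1)
  edge_dist <- pmin(i, n_frames - 1 - i) * p$dt
  outer(edge_dist, sqrt(2) * p$scales, ">")
}

#' Wavelet transform coherence between two series
#'
#' Squared coherence
#' \deqn{R^2(t,s) = |S(W_{xy}/s)|^2 / ( S(|W_x|^2/s) \cdot S(|W_y|^2/s) )}
#' with `S` the time-then-scale smoothing operator, together with the phase
#' of the smoothed cross-spectrum and the COI mask. Coherence lies in
#' \[0, 1\]; 1 means locally perfect phase-locked correlation. Coherence is
#' symmetric in its arguments; phase is antisymmetric.
#'
#' @param x,y Equal-length finite numeric series at one sampling rate.
#' @param p A [wavelet_params()].
#' @return Object of class `wtc_map`: list with `coherence`, `phase`
#'   (time x frequency), `coi_mask` (`TRUE` = valid), `freqs`, `times`.
#' @export
wtc <- function(x, y, p = wavelet_params()) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("series contain non-finite values; preprocess first")
  if (stats::sd(x) == 0) stop("x is constant: coherence undefined")
  if (stats::sd(y) == 0) stop("y is constant: coherence undefined")
  plan <- wtc_plan(length(x), p)
  Wx <- cwt_with_plan(x, plan)
  Wy <- cwt_with_plan(y, plan)
  inv_s <- matrix(1 / p$scales, plan$n, plan$nf, byrow = TRUE)
  SX <- Re(smooth_with_plan(abs(Wx)^2 * inv_s, plan))
  SY <- Re(smooth_with_plan(abs(Wy)^2 * inv_s, plan))
  Sxy <- smooth_with_plan(Wx * Conj(Wy) * inv_s, plan)
  R2 <- Mod(Sxy)^2 / pmax(SX * SY, .Machine$double.xmin)
  R2 <- pmin(pmax(R2, 0), 1)
  structure(list(
    coherence = R2, phase = Arg(Sxy), coi_mask = plan$coi,
    freqs = p$freqs, times = (seq_len(plan$n) - 1) * p$dt
  ), class = "wtc_map")
}

#' @export
print.wtc_map <- function(x, ...) {
  cat(sprintf(
    "<wtc_map> %d frames x %d frequencies (%.3g-%.3g Hz)\n  mean COI-valid coherence: %.3f\n",
    nrow(x$coherence), length(x$freqs), min(x$freqs), max(x$freqs),
    mean(x$coherence[x$coi_mask])))
  invisible(x)
}

## Batched pairwise coherence for one trial: Y is a time x keypoint matrix;
## CWTs and smoothed auto-spectra are computed once per keypoint and reused
## across all pairs. Returns a time x frequency x pair array; `pairs` is a
## 2-column index matrix.
wtc_pairs_coherence <- function(Y, p, pairs, plan = NULL) {
  n <- nrow(Y); K <- ncol(Y)
  if (is.null(plan)) plan <- wtc_plan(n, p)
  inv_s <- matrix(1 / p$scales, n, plan$nf, byrow = TRUE)
  W <- vector("list", K)
  SA <- vector("list", K)
  for (k in seq_len(K)) {
    if (stats::sd(Y[, k]) == 0)
      stop("constant series for keypoint ", colnames(Y)[k] %||% k)
    W[[k]] <- cwt_with_plan(Y[, k], plan)
    SA[[k]] <- Re(smooth_with_plan(abs(W[[k]])^2 * inv_s, plan))
  }
  out <- array(NA_real_, c(n, plan$nf, nrow(pairs)))
  for (q in seq_len(nrow(pairs))) {
    a <- pairs[q, 1]; b <- pairs[q, 2]
    Sxy <- smooth_with_plan(W[[a]] * Conj(W[[b]]) * inv_s, plan)
    R2 <- Mod(Sxy)^2 / pmax(SA[[a]] * SA[[b]], .Machine$double.xmin)
    out[, , q] <- pmin(pmax(R2, 0), 1)
  }
  attr(out, "coi") <- plan$coi
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
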