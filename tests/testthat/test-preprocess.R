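test_that("segmentation keeps the padded window and re-indexes events", {
  # index arithmetic oracle: [init - 30, term + 90] inclusive
  # = (500 - 100 + 1) + 30 + 90 = 521 frames
  y <- matrix(rnorm(1000 * 2), 1000, 2,
              dimnames = list(NULL, c("index_tip", "thumb_anchor")))
  tr <- keypoint_trajectory("p", "t", "reference", "short", y = y,
                            events = list(initiation_frame = 100,
                                          termination_frame = 500,
                                          nominal_duration = 6.71))
  seg <- segment_trial(tr, preproc_params(pre_pad = 30, post_pad = 90))
  expect_equal(n_frames(seg), 521)
  expect_equal(seg$events$initiation_frame, 30)
  expect_equal(seg$events$termination_frame, 430)
  expect_equal(seg$y[31, "index_tip"], y[101, "index_tip"])

  seg0 <- segment_trial(tr, preproc_params(pre_pad = 0, post_pad = 0))
  expect_equal(n_frames(seg0), 401)

  early <- tr; early$events$initiation_frame <- 10
  expect_error(segment_trial(early, preproc_params(pre_pad = 30)),
               "10 available, 30 required")
})

test_that("Fourier resampling rescales a tone's frequency by the length ratio", {
  # FFT oracle: an exactly periodic tone (33 cycles in 400 samples) resampled
  # to 403 samples equals the same 33 cycles on the stretched axis, so its
  # per-sample frequency scales by exactly 400/403
  y <- sin(2 * pi * 33 * (0:399) / 400)
  z <- normalize_duration(y, 403)
  expect_length(z, 403)
  expect_equal(z, sin(2 * pi * 33 * (0:402) / 403), tolerance = 1e-10)
  expect_equal(which.max(Mod(fft(z))[2:200]), 33)

  expect_equal(normalize_duration(y, 400), y, tolerance = 1e-12)
  expect_equal(normalize_duration(rep(2.5, 50), 71), rep(2.5, 71))
  expect_error(normalize_duration(y, 1), "target_len")
})

test_that("resampling round-trips band-limited inputs", {
  set.seed(1)
  y <- as.numeric(stats::filter(rnorm(256), rep(1 / 8, 8), circular = TRUE))
  back <- normalize_duration(normalize_duration(y, 300), 256)
  expect_lt(max(abs(back - y)) / sd(y), 1e-6)
})

test_that("moving-average smoothing matches the convolution oracle", {
  expect_equal(smooth_series(rep(3, 40), 6), rep(3, 40))
  expect_equal(smooth_series(1:10, 1), 1:10)
  expect_error(smooth_series(1:5, 7), "exceeds")

  imp <- rep(0, 30); imp[15] <- 1
  sm <- smooth_series(imp, 6)
  expect_equal(sum(sm > 0), 6)
  expect_equal(sm[sm > 0], rep(1 / 6, 6))
  # centered with the forward-leaning convention for even windows
  expect_equal(which(sm > 0), 12:17)
})

test_that("outlier interpolation flags runs against the last retained sample", {
  r <- interpolate_outliers(c(0, 0, 150, 0, 0), 100)
  expect_equal(r$y, rep(0, 5))
  expect_equal(which(r$mask), 3L)

  ramp <- seq(0, 100, by = 5)
  r2 <- interpolate_outliers(ramp, 100)
  expect_equal(r2$y, ramp)
  expect_false(any(r2$mask))

  # hand-computed fill: both consecutive spikes flagged, one line segment
  r3 <- interpolate_outliers(c(10, 10, 150, 160, 10, 10), 100)
  expect_equal(which(r3$mask), c(3L, 4L))
  expect_equal(r3$y, rep(10, 6))

  # second pass flags nothing (idempotence)
  set.seed(2)
  y <- cumsum(rnorm(200, 0, 4)); y[c(50, 51, 120)] <- y[c(50, 51, 120)] + 130
  once <- interpolate_outliers(y, 100)
  twice <- interpolate_outliers(once$y, 100)
  expect_false(any(twice$mask))
  expect_equal(twice$y, once$y)

  # originally-missing samples are filled but not flagged as outliers
  r4 <- interpolate_outliers(c(1, NA, 3), 100)
  expect_equal(r4$y, c(1, 2, 3))
  expect_false(any(r4$mask))

  expect_error(interpolate_outliers(c(NA_real_, NA_real_), 100), "nothing")
})

test_that("range of interest reproduces the printed frame counts", {
  expect_length(roi_indices(6.71, 60), 344)
  expect_length(roi_indices(11.14, 60), 609)
  expect_equal(roi_indices(1.0, 60), 60L)   # boundary: one frame
  expect_error(roi_indices(0.9, 60), "too short")
})

test_that("the full chain yields ROI matrices of the nominal lengths", {
  cfg <- sim_config(seed = 6, trial_counts = quick_counts(1))
  ses <- generate_session(cfg, "p")
  pt <- preprocess_trial(ses$trials[[1]])
  expect_equal(nrow(pt$roi), 344)
  expect_equal(ncol(pt$roi), 17)
  expect_true(all(is.finite(pt$roi)))

  long_tr <- generate_trial(cfg, "reference", "long", seed = 8)
  expect_equal(nrow(preprocess_trial(long_tr)$roi), 609)
})

test_that("preprocessing is invariant to keypoint ordering", {
  cfg <- sim_config(seed = 13, trial_counts = quick_counts(1))
  tr <- generate_trial(cfg, "reference", "short", seed = 31)
  perm <- rev(seq_along(tr$keypoints))
  tr2 <- tr
  tr2$y <- tr$y[, perm]; tr2$x <- tr$x[, perm]
  tr2$keypoints <- tr$keypoints[perm]
  a <- preprocess_trial(tr)
  b <- preprocess_trial(tr2)
  expect_equal(b$roi[, tr$keypoints], a$roi[, tr$keypoints])
})

test_that("trials are normalized to the per-class mean duration", {
  cfg <- sim_config(seed = 2, trial_counts = quick_counts(2))
  pt <- preprocess_trials(generate_session(cfg, "p")$trials)
  expect_true(all(vapply(pt, function(x) nrow(x$roi), numeric(1)) == 344))
})
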