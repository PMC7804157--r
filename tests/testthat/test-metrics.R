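# fabricate a wtc_map with constant coherence for averaging tests
flat_map <- function(value, n = 50, freqs = 1:10) {
  structure(list(
    coherence = matrix(value, n, length(freqs)),
    phase = matrix(0, n, length(freqs)),
    coi_mask = matrix(TRUE, n, length(freqs)),
    freqs = freqs, times = seq_len(n) / 60
  ), class = "wtc_map")
}

test_that("coherence spectra average over maps and respect the COI", {
  s1 <- mean_coherence_spectrum(list(flat_map(0.7)))
  expect_equal(as.numeric(s1), rep(0.7, 10))
  s2 <- mean_coherence_spectrum(list(flat_map(0.2), flat_map(0.8)))
  expect_equal(as.numeric(s2), rep(0.5, 10))

  # a frequency with no valid point anywhere is reported missing
  m <- flat_map(0.9)
  m$coi_mask[, 4] <- FALSE
  s3 <- mean_coherence_spectrum(list(m))
  expect_true(is.na(s3[4]))
  expect_equal(as.numeric(s3[-4]), rep(0.9, 9))
})

test_that("band estimation reproduces FWHM geometry", {
  freqs <- 1:9
  spec <- c(0.1, 0.15, 0.2, 0.4, 0.8, 0.4, 0.2, 0.15, 0.1)  # triangle at 5
  b <- estimate_band(spec, freqs)
  expect_equal(b$tapping_rate, 5)
  expect_equal(b$f_low, 4)
  expect_equal(b$f_high, 6)

  suppressWarnings(
    expect_error(estimate_band(rep(0.5, 9), freqs), "boundary"))
  expect_error(estimate_band(c(0.9, 0.5, 0.3, 0.2, 0.1, 0.1, 0.1, 0.1, 0.1),
                             freqs), "boundary")
  expect_warning(estimate_band(c(0.1, 0.3, 0.8, 0.8, 0.3, 0.1, 0.1, 0.1, 0.1),
                               freqs), "plateau")
  # band clamps to the grid span when never dropping below half on one side
  b2 <- estimate_band(c(0.5, 0.6, 0.9, 0.6, 0.5, 0.5, 0.5, 0.5, 0.5), freqs)
  expect_equal(b2$f_high, 9)
})

test_that("band invariants are enforced", {
  expect_error(band_of_interest(5, 6, 7), "f_low")
  b <- band_of_interest(5, 4, 6)
  expect_s3_class(b, "band_of_interest")
})

test_that("inter-trial coherence averages all unordered pairs", {
  wp <- quick_wp()
  set.seed(7)
  base <- sin(2 * pi * 5 * (0:343) / 60)
  trials <- lapply(1:4, function(i) base + rnorm(344, 0, 0.2))
  band <- band_of_interest(5, 4, 6.5)
  v <- inter_trial_coherence(trials, band, wp)
  expect_equal(attr(v, "n_pairs"), 6L)          # 4 trials -> 6 pairs
  expect_gt(as.numeric(v), 0.8)

  dup <- inter_trial_coherence(list(base + 0.01 * rnorm(344),
                                    base + 0.01 * rnorm(344)), band, wp)
  expect_gt(as.numeric(dup), 0.99)
  expect_error(inter_trial_coherence(trials[1], band, wp), "at least 2")
  expect_error(inter_trial_coherence(list(base, base[-1]), band, wp),
               "length")
})

test_that("inter-finger coherence is invariant to fixed phase lags", {
  wp <- quick_wp()
  t <- (0:343) / 60
  set.seed(8)
  Y <- sapply(c(0, pi / 2, pi, 3 * pi / 2),
              function(lag) sin(2 * pi * 5 * t + lag) + rnorm(344, 0, 0.05))
  colnames(Y) <- fingertip_keypoints()
  band <- band_of_interest(5, 4, 6.5)
  v <- inter_finger_coherence(Y, band, wp)
  expect_equal(attr(v, "n_pairs"), 6L)
  expect_gt(as.numeric(v), 0.97)

  # one desynchronized finger drags the mean down
  Y2 <- Y
  set.seed(9)
  jolt <- cumsum(rnorm(344, 0, 0.25))
  Y2[, "ring_tip"] <- sin(2 * pi * 5 * t + jolt) + rnorm(344, 0, 0.05)
  expect_lt(as.numeric(inter_finger_coherence(Y2, band, wp)), as.numeric(v))

  expect_error(inter_finger_coherence(Y[, 1:3], band, wp), "little_tip")
})

test_that("envelope amplitude recovers tone amplitudes and scales linearly", {
  band <- band_of_interest(5, 4, 6.5)
  t <- (0:699) / 60
  y <- 20 * sin(2 * pi * 5 * t)
  A <- envelope_amplitude(y, band)
  expect_equal(A, 20, tolerance = 0.02)
  expect_equal(envelope_amplitude(2 * y, band), 2 * A, tolerance = 1e-9)
  expect_error(envelope_amplitude(y, band_of_interest(20, 15, 35)), "Nyquist")
  expect_error(envelope_amplitude(y[1:30], band), "settling")
})

test_that("envelope amplitude ratios recover implanted gains on tap trains", {
  # generator oracle: raised-cosine trains differing only by gain g
  cfg1 <- noiseless_config(rate = 5)
  g <- default_condition_gain(); g["sequence_focused", ] <- 1.3
  cfg2 <- noiseless_config(rate = 5, condition_gain = g)
  r1 <- preprocess_trial(generate_trial(cfg1, "reference", "short", 3))
  r2 <- preprocess_trial(generate_trial(cfg2, "sequence_focused", "short", 3))
  band <- band_of_interest(5, 4, 6.5)
  a1 <- envelope_amplitude(r1$roi[, "index_tip"], band)
  a2 <- envelope_amplitude(r2$roi[, "index_tip"], band)
  expect_equal(a2 / a1, 1.3, tolerance = 0.02)
})

test_that("the modulation index is the amplitude ratio minus one", {
  expect_equal(modulation_index(10, 10), 0)
  expect_equal(modulation_index(15, 10), 0.5)
  expect_equal(modulation_index(5, 10), -0.5)
  expect_error(modulation_index(10, 0), "positive")
})

test_that("amplitude tables pin the reference condition to I_A = 0", {
  cfg <- sim_config(seed = 10, trial_counts = quick_counts(2))
  pt <- preprocess_trials(generate_session(cfg, "p")$trials)
  band <- participant_band(pt)
  tab <- amplitude_table(pt, band)
  expect_equal(nrow(tab), 16)            # 4 fingers x 4 conditions
  expect_true(all(tab$A > 0))
  expect_true(all(tab$I_A[tab$condition == "reference"] == 0))
  expect_true(all(tab$I_A > -1))
})

test_that("coherence summaries have the right combinatorics", {
  cfg <- sim_config(seed = 11, trial_counts = quick_counts(3))
  pt <- preprocess_trials(generate_session(cfg, "p")$trials)
  band <- participant_band(pt)
  cs <- coherence_summary(pt, band)
  expect_setequal(cs$condition, tap_conditions())
  expect_true(all(cs$inter_finger >= 0 & cs$inter_finger <= 1))
  expect_true(all(cs$inter_trial >= 0 & cs$inter_trial <= 1))
  expect_equal(cs$n_trial_pairs, rep(4L * choose(3, 2), 4))  # 4 fingertips
})
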