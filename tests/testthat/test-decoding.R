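# a compact labeled feature matrix with controllable class structure
toy_features <- function(n_per = 240, p = 12, sep = 0, seed = 1) {
  set.seed(seed)
  conds <- tap_conditions()
  X <- NULL; lab <- c()
  for (i in seq_along(conds)) {
    block <- matrix(rnorm(n_per * p), n_per, p)
    block[, i %% p + 1] <- block[, i %% p + 1] + sep
    X <- rbind(X, block); lab <- c(lab, rep(conds[i], n_per))
  }
  structure(list(X = X, condition = lab,
                 trial = rep("T", length(lab))), class = "feature_matrix")
}

test_that("14 keypoints produce 91 pair channels and 40 x 91 raw columns", {
  cfg <- sim_config(seed = 12, trial_counts = quick_counts(1))
  pt <- preprocess_trial(generate_session(cfg, "p")$trials[[1]])
  wp <- wavelet_params()
  F <- pairwise_wtc_features(pt$roi, wp)
  expect_equal(ncol(F), 40 * choose(14, 2))
  expect_equal(ncol(F), 3640)
  expect_equal(nrow(F), 344)
  expect_true(all(is.finite(F)))
  expect_true(all(F >= 0 & F <= 1))
  expect_error(pairwise_wtc_features(pt$roi[, 1:10], wp), "14 decoding")
})

test_that("a duplicated keypoint shows as a self-coherent pair channel", {
  cfg <- sim_config(seed = 14, trial_counts = quick_counts(1))
  pt <- preprocess_trial(generate_session(cfg, "p")$trials[[1]])
  wp <- quick_wp(nf = 8)
  Y <- pt$roi
  kp <- decoding_keypoints()
  Y[, kp[2]] <- Y[, kp[1]]          # duplicate channel
  F <- pairwise_wtc_features(Y, wp)
  # pair (1,2) occupies the first nf columns
  expect_true(all(F[, 1:8] > 0.999))
})

test_that("PCA keeps rank and orders variance", {
  # rank-5 data: 5 informative directions, the rest numerically zero
  set.seed(15)
  basis <- matrix(rnorm(60 * 5), 60, 5)
  feats <- structure(list(X = matrix(rnorm(500 * 5), 500, 5) %*% t(basis),
                          condition = rep(tap_conditions(), length.out = 500),
                          trial = rep("T", 500)), class = "feature_matrix")
  red <- reduce_dimensions(feats, decoder_params(n_components = 20))
  expect_equal(attr(red, "explained_variance"), 1, tolerance = 1e-9)
  v <- apply(red$X, 2, var)
  expect_lt(max(v[6:20]) / max(v), 1e-9)

  # explained variance grows monotonically with retained components
  noisy <- toy_features(n_per = 100, p = 30, sep = 0.5)
  ev <- vapply(c(2, 5, 10, 20), function(k)
    attr(suppressWarnings(
      reduce_dimensions(noisy, decoder_params(n_components = k))),
      "explained_variance"), numeric(1))
  expect_true(all(diff(ev) > 0))

  constant <- structure(list(X = matrix(1, 50, 4),
                             condition = rep("reference", 50),
                             trial = rep("T", 50)), class = "feature_matrix")
  expect_error(reduce_dimensions(constant, decoder_params(n_components = 2)),
               "constant")
})

test_that("dataset splitting is contiguous, balanced and disjoint", {
  dp <- decoder_params(n_datasets = 6, window_len = 60)
  f600 <- toy_features(n_per = 600, p = 4)
  s <- split_datasets(f600, dp)
  for (cn in tap_conditions()) {
    sizes <- table(s$dataset[s$condition == cn])
    expect_equal(unname(c(sizes)), rep(100L, 6))
    # contiguity: dataset index is non-decreasing along the condition rows
    expect_true(all(diff(s$dataset[s$condition == cn]) >= 0))
  }
  f601 <- toy_features(n_per = 601, p = 4)
  sizes <- table(split_datasets(f601, dp)$dataset[
    split_datasets(f601, dp)$condition == "reference"])
  expect_equal(sort(unname(c(sizes))), c(rep(100L, 5), 101L))

  expect_error(split_datasets(toy_features(n_per = 300, p = 4), dp),
               "reference")
})

test_that("window arithmetic follows floor((N - len)/step) + 1", {
  dp <- decoder_params(n_datasets = 2, window_len = 60, window_step = 4)
  mk <- function(N) {  # everything in one block: window counts are per block
    f <- toy_features(n_per = N, p = 3)
    f$dataset <- rep(1L, length(f$condition))
    f
  }
  w344 <- make_windows(mk(344), dp)
  expect_equal(sum(w344$label == "reference"), floor((344 - 60) / 4) + 1)
  expect_equal(sum(w344$label == "reference"), 72)
  w60 <- make_windows(mk(60), dp)
  expect_equal(sum(w60$label == "reference"), 1)
  # a single short block warns but the others still produce samples
  short_one <- mk(70)
  drop <- which(short_one$condition == "reference")[1:11]
  short_one$X <- short_one$X[-drop, , drop = FALSE]
  short_one$condition <- short_one$condition[-drop]
  short_one$trial <- short_one$trial[-drop]
  short_one$dataset <- short_one$dataset[-drop]
  expect_warning(w59 <- make_windows(short_one, dp), "0 samples")
  expect_equal(sum(w59$label == "reference"), 0)
  expect_gt(sum(w59$label == "index_focused"), 0)
  expect_equal(ncol(w60$S), 60 * 3)
})

test_that("cross-validated decoding recovers separable classes", {
  dp <- decoder_params(n_components = 12, window_len = 20, window_step = 10,
                       n_datasets = 3)
  f <- toy_features(n_per = 240, p = 12, sep = 1.5, seed = 16)
  win <- make_windows(split_datasets(f, dp), dp)
  res <- train_eval(win, dp)
  expect_gt(res$mean_accuracy, 0.8)
  expect_equal(unname(rowSums(res$confusion)), rep(1, 4), tolerance = 1e-9)
  expect_equal(res$chance_level, 0.25)
  expect_equal(res$mean_accuracy, mean(diag(res$confusion)))
})

test_that("kernlab and e1071 backends agree on the same model", {
  dp <- decoder_params(n_components = 10, window_len = 15, window_step = 15,
                       n_datasets = 2)
  f <- toy_features(n_per = 120, p = 10, sep = 1.2, seed = 17)
  win <- make_windows(split_datasets(f, dp), dp)
  a <- train_eval(win, dp, backend = "kernlab")
  b <- train_eval(win, dp, backend = "e1071")
  expect_equal(a$mean_accuracy, b$mean_accuracy, tolerance = 0.1)
  expect_gt(a$mean_accuracy, 0.6)
})

test_that("label shuffling collapses decoding to chance", {
  dp <- decoder_params(n_components = 12, window_len = 20, window_step = 10,
                       n_datasets = 3, seed = 2)
  f <- toy_features(n_per = 240, p = 12, sep = 1.5, seed = 18)
  set.seed(19)
  f$condition <- sample(f$condition)   # break the label-feature link
  win <- make_windows(split_datasets(f, dp), dp)
  res <- train_eval(win, dp)
  expect_lt(abs(res$mean_accuracy - 0.25), 0.15)
})

test_that("accuracy does not increase as class separation shrinks", {
  dp <- decoder_params(n_components = 12, window_len = 20, window_step = 10,
                       n_datasets = 3)
  accs <- vapply(c(1.5, 0.5, 0), function(sep) {
    f <- toy_features(n_per = 240, p = 12, sep = sep, seed = 20)
    train_eval(make_windows(split_datasets(f, dp), dp), dp)$mean_accuracy
  }, numeric(1))
  expect_true(all(diff(accs) <= 0.05))   # monotone up to Monte-Carlo error
  expect_gt(accs[1] - accs[3], 0.2)
})

test_that("a condition absent from a training fold is an error", {
  dp <- decoder_params(n_components = 4, window_len = 10, window_step = 10,
                       n_datasets = 2)
  f <- toy_features(n_per = 40, p = 4, seed = 21)
  s <- split_datasets(f, dp)
  s$dataset[s$condition == "reference"] <- 1L  # reference only in dataset 1
  win <- suppressWarnings(make_windows(s, dp))
  expect_error(train_eval(win, dp), "absent from training fold")
})

test_that("implanted condition-specific jitter patterns decode above chance", {
  # low noise, strong desynchronization contrast between conditions
  tc <- default_trial_counts(); tc[, "short"] <- 8L; tc[, "long"] <- 0L
  j <- zero_condition_matrix()
  j["reference", ] <- 0.1
  j["sequence_focused", ] <- 0.45
  j["index_focused", ] <- 0.2; j["index_focused", "index"] <- 0.7
  j["middle_focused", ] <- 0.2; j["middle_focused", "middle"] <- 0.7
  cfg <- sim_config(trial_counts = tc, seed = 311, phase_jitter_sd = j)
  pt <- preprocess_trials(generate_session(cfg, "eff")$trials)
  res <- suppressWarnings(decode_condition(pt))
  expect_gt(res$mean_accuracy, 0.4)
})

test_that("end-to-end decoding is deterministic and refuses missing conditions", {
  tc <- quick_counts(2)
  cfg <- sim_config(seed = 22, trial_counts = tc)
  pt <- preprocess_trials(generate_session(cfg, "p")$trials)
  wp <- quick_wp(nf = 10)
  dp <- quick_dp()
  r1 <- suppressWarnings(decode_condition(pt, wp, dp))
  r2 <- suppressWarnings(decode_condition(pt, wp, dp))
  expect_identical(r1$confusion, r2$confusion)

  no_mid <- pt[vapply(pt, `[[`, "", "condition") != "middle_focused"]
  expect_error(decode_condition(no_mid, wp, dp), "middle_focused")
})
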