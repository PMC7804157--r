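## Pattern decoding of attentional condition from pairwise-WTC features:
## 91 keypoint pairs x 40 frequencies per ROI time point, PCA to 80
## components, contiguous six-way dataset split, sliding-window sampling,
## RBF-SVM with six-fold cross-validation, row-normalized confusion matrix.

#' Decoder parameters
#'
#' @param n_components Retained PCA components (default 80).
#' @param variance_floor Warn when the retained components explain less than
#'   this fraction of total variance (default 0.80).
#' @param window_len Sliding-window length in time points (default 60).
#' @param window_step Step between windows (default 4).
#' @param n_datasets Number of contiguous datasets / CV folds (default 6).
#' @param kernel_gamma RBF kernel parameter (default 0.014).
#' @param cost SVM soft-margin cost (default 1).
#' @param svm_tol SMO convergence tolerance (default 0.05; looser than the
#'   libsvm default because at these sample sizes the tighter tolerance
#'   costs orders of magnitude more time without changing held-out
#'   predictions appreciably).
#' @param pca_per_fold Refit the PCA on each training fold only (leakage
#'   sensitivity analysis; default `FALSE`, one PCA per participant).
#' @param seed Seed for any stochastic stage.
#' @return Object of class `decoder_params`.
#' @export
decoder_params <- function(n_components = 80L, variance_floor = 0.80,
                           window_len = 60L, window_step = 4L,
                           n_datasets = 6L, kernel_gamma = 0.014,
                           cost = 1, svm_tol = 0.05, pca_per_fold = FALSE,
                           seed = 1L) {
  stopifnot(window_len >= window_step, window_step >= 1, n_datasets >= 2,
            n_components >= 1)
  structure(list(n_components = as.integer(n_components),
                 variance_floor = variance_floor,
                 window_len = as.integer(window_len),
                 window_step = as.integer(window_step),
                 n_datasets = as.integer(n_datasets),
                 kernel_gamma = kernel_gamma, cost = cost,
                 svm_tol = svm_tol,
                 pca_per_fold = isTRUE(pca_per_fold),
                 seed = as.integer(seed)),
            class = "decoder_params")
}

#' Pairwise WTC features for one trial
#'
#' Coherence between every unordered pair of the 14 decoding keypoints
#' (choose(14, 2) = 91 pairs) at every analysis frequency, per ROI time
#' point. COI-invalid entries are imputed with the per-pair per-frequency
#' mean over valid times, keeping the matrix complete without injecting
#' condition information.
#'
#' @param Y ROI frames x keypoints matrix containing the 14 decoding
#'   keypoints (columns selected and ordered by [decoding_keypoints()]).
#' @param p A [wavelet_params()].
#' @return Numeric matrix, ROI frames x (n_freqs * 91); columns ordered
#'   pair-major (all frequencies of pair 1, then pair 2, ...).
#' @export
pairwise_wtc_features <- function(Y, p = wavelet_params()) {
  want <- decoding_keypoints()
  missing_kp <- setdiff(want, colnames(Y))
  if (length(missing_kp))
    stop("expected the 14 decoding keypoints; missing: ",
         paste(missing_kp, collapse = ", "))
  Y <- Y[, want, drop = FALSE]
  pairs <- t(utils::combn(length(want), 2))
  co <- wtc_pairs_coherence(Y, p, pairs)
  coi <- attr(co, "coi")
  n <- nrow(Y); nf <- length(p$freqs); np <- nrow(pairs)
  out <- matrix(NA_real_, n, nf * np)
  for (q in seq_len(np)) {
    m <- co[, , q]
    for (j in seq_len(nf)) {
      v <- coi[, j]
      if (any(v)) {
        if (!all(v)) m[!v, j] <- mean(m[v, j])
      } else {
        m[, j] <- mean(m[coi], na.rm = TRUE)
      }
    }
    out[, (q - 1L) * nf + seq_len(nf)] <- m
  }
  out
}

#' Pooled feature matrix for one participant
#'
#' Stacks the per-trial pairwise-WTC feature blocks into the pooled
#' time x pooled frequency matrix, keeping trial order within condition,
#' with per-row condition and trial provenance.
#'
#' @param ptrials List of `preprocessed_trial` objects (one participant).
#' @param p A [wavelet_params()].
#' @return List of class `feature_matrix`: `X` (rows = pooled time points),
#'   `condition`, `trial` (per-row labels).
#' @export
participant_features <- function(ptrials, p = wavelet_params()) {
  conds <- vapply(ptrials, `[[`, "", "condition")
  ord <- order(match(conds, tap_conditions()), seq_along(ptrials))
  blocks <- vector("list", length(ptrials))
  lab <- tri <- vector("list", length(ptrials))
  for (i in seq_along(ord)) {
    tr <- ptrials[[ord[i]]]
    blocks[[i]] <- pairwise_wtc_features(tr$roi, p)
    lab[[i]] <- rep(tr$condition, nrow(blocks[[i]]))
    tri[[i]] <- rep(tr$trial_id, nrow(blocks[[i]]))
  }
  structure(list(X = do.call(rbind, blocks),
                 condition = unlist(lab), trial = unlist(tri)),
            class = "feature_matrix")
}

## PCA on the pooled frequency dimension via the covariance eigendecomposition
## (rows >> columns in this pipeline). Returns scores and rotation.
fit_pca <- function(X, n_components) {
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  C <- crossprod(Xc) / (nrow(X) - 1)
  tot <- sum(diag(C))
  if (tot <= .Machine$double.eps)
    stop("all feature columns are constant: PCA undefined")
  e <- eigen(C, symmetric = TRUE)
  k <- min(n_components, ncol(X))
  list(mu = mu, rotation = e$vectors[, seq_len(k), drop = FALSE],
       scores = Xc %*% e$vectors[, seq_len(k), drop = FALSE],
       explained = sum(pmax(e$values[seq_len(k)], 0)) / tot,
       values = e$values)
}

#' Reduce the pooled frequency dimension by PCA
#'
#' Projects the feature matrix onto its top variance-ordered principal
#' components, fitted on the participant's pooled matrix (all conditions
#' together). Warns when the retained components explain less variance than
#' `variance_floor`.
#'
#' @param features A `feature_matrix` from [participant_features()].
#' @param dp A [decoder_params()].
#' @return The `feature_matrix` with `X` replaced by component scores and
#'   attribute `explained_variance`.
#' @export
reduce_dimensions <- function(features, dp = decoder_params()) {
  if (nrow(features$X) < dp$n_components)
    stop("fewer rows than requested components")
  fit <- fit_pca(features$X, dp$n_components)
  if (fit$explained < dp$variance_floor)
    warning(sprintf("retained components explain %.1f%% < %.0f%% of variance",
                    100 * fit$explained, 100 * dp$variance_floor))
  features$X <- fit$scores
  attr(features, "explained_variance") <- fit$explained
  features
}

#' Split pooled time points into contiguous datasets
#'
#' Per condition, the trial-ordered time points are cut into `n_datasets`
#' contiguous near-equal blocks; block `k` of every condition forms dataset
#' `k`, and sliding windows never span dataset boundaries.
#'
#' When a condition contains at least `n_datasets` trials, the cuts are
#' placed at trial boundaries (each trial's time points stay in one
#' dataset, balancing point counts as evenly as the trial granularity
#' allows). This keeps the datasets independent: windows from one trial
#' never appear on both sides of a cross-validation fold, which would leak
#' trial identity into evaluation and inflate null decoding far above
#' chance. With fewer trials than datasets (or a single unlabeled block)
#' the cut is at the time-point level with sizes differing by at most one,
#' earlier blocks taking the remainder.
#'
#' @param features A (reduced) `feature_matrix`.
#' @param dp A [decoder_params()].
#' @return The `feature_matrix` with an added per-row `dataset` assignment.
#' @export
split_datasets <- function(features, dp = decoder_params()) {
  ds <- integer(length(features$condition))
  for (cn in unique(features$condition)) {
    rows <- which(features$condition == cn)
    N <- length(rows)
    if (N < dp$n_datasets * dp$window_len)
      stop(sprintf("condition %s has %d time points; need %d",
                   cn, N, dp$n_datasets * dp$window_len))
    trials <- features$trial[rows]
    trial_ids <- unique(trials)
    if (length(trial_ids) >= dp$n_datasets) {
      ## trial-aligned: assign each whole trial to the dataset whose share
      ## of the time axis contains the trial's midpoint
      counts <- as.vector(table(factor(trials, levels = trial_ids)))
      ends <- cumsum(counts)
      mids <- ends - counts / 2
      k <- pmin(dp$n_datasets, pmax(1L, ceiling(mids / N * dp$n_datasets)))
      k <- cummax(k)  # keep blocks contiguous
      ds[rows] <- rep(k, times = counts)
    } else {
      base <- N %/% dp$n_datasets
      sizes <- rep(base, dp$n_datasets)
      extra <- N %% dp$n_datasets
      if (extra > 0) sizes[seq_len(extra)] <- base + 1L
      ds[rows] <- rep(seq_len(dp$n_datasets), times = sizes)
    }
  }
  features$dataset <- ds
  features
}

#' Sliding-window samples from the dataset split
#'
#' Per condition-by-dataset block of length `N`, produces
#' `floor((N - window_len) / window_step) + 1` samples; each sample is the
#' flattened `window_len x n_components` block, labeled with its condition
#' and dataset. Blocks shorter than one window produce zero samples with a
#' warning.
#'
#' @param features A split `feature_matrix` (see [split_datasets()]).
#' @param dp A [decoder_params()].
#' @return List of class `window_samples`: `S` (samples x flattened
#'   features), `label` (condition factor), `dataset` (integer).
#' @export
make_windows <- function(features, dp = decoder_params()) {
  if (is.null(features$dataset)) stop("features not split; run split_datasets")
  len <- dp$window_len; step <- dp$window_step
  conds <- unique(features$condition)
  idx_list <- list(); lab <- list(); dsl <- list()
  for (cn in conds) for (k in sort(unique(features$dataset))) {
    rows <- which(features$condition == cn & features$dataset == k)
    N <- length(rows)
    if (N < len) {
      warning(sprintf("block (%s, dataset %d) has %d < %d points: 0 samples",
                      cn, k, N, len))
      next
    }
    starts <- seq.int(1L, N - len + 1L, by = step)
    for (s0 in starts) {
      idx_list[[length(idx_list) + 1L]] <- rows[s0:(s0 + len - 1L)]
      lab[[length(lab) + 1L]] <- cn
      dsl[[length(dsl) + 1L]] <- k
    }
  }
  if (!length(idx_list)) stop("no block long enough for a single window")
  S <- matrix(NA_real_, length(idx_list), len * ncol(features$X))
  for (i in seq_along(idx_list))
    S[i, ] <- as.vector(features$X[idx_list[[i]], , drop = FALSE])
  structure(list(S = S,
                 label = factor(unlist(lab),
                                levels = intersect(tap_conditions(), conds)),
                 dataset = unlist(dsl)),
            class = "window_samples")
}

rbf_gram <- function(A, B, gamma) {
  D <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(D, 0))
}

## train on rows where train_mask, predict the rest; standardization uses
## training-fold statistics only: columns are centered with training means
## and the whole matrix divided by one global scale (RMS column SD times
## sqrt(window_len)), so kernel distances average over the window's time
## points and gamma = 0.014 lives on the scale of the n_components space.
## Per-column z-scoring is deliberately avoided: it whitens the component
## spectrum, re-inflating low-variance noise directions and swamping the
## condition signal carried by the leading components.
svm_fold <- function(S, label, train_mask, dp, backend = "kernlab") {
  mu <- colMeans(S[train_mask, , drop = FALSE])
  sdv2 <- pmax(colMeans(S[train_mask, , drop = FALSE]^2) - mu^2, 0)
  s0 <- sqrt(mean(sdv2))
  if (s0 < 1e-12) s0 <- 1
  sc <- s0 * sqrt(dp$window_len)
  Xtr <- sweep(S[train_mask, , drop = FALSE], 2, mu) / sc
  Xte <- sweep(S[!train_mask, , drop = FALSE], 2, mu) / sc
  ytr <- droplevels(label[train_mask])
  if (backend == "kernlab") {
    K <- kernlab::as.kernelMatrix(rbf_gram(Xtr, Xtr, dp$kernel_gamma))
    m <- kernlab::ksvm(K, ytr, type = "C-svc", C = dp$cost, tol = dp$svm_tol)
    Kte <- kernlab::as.kernelMatrix(
      rbf_gram(Xte, Xtr, dp$kernel_gamma)[, kernlab::SVindex(m),
                                          drop = FALSE])
    as.character(kernlab::predict(m, Kte))
  } else {
    if (!requireNamespace("e1071", quietly = TRUE))
      stop("backend e1071 requires the e1071 package")
    m <- e1071::svm(Xtr, ytr, kernel = "radial", gamma = dp$kernel_gamma,
                    cost = dp$cost, tolerance = dp$svm_tol, scale = FALSE)
    as.character(predict(m, Xte))
  }
}

#' Cross-validated SVM training and evaluation
#'
#' One fold per dataset: the RBF-SVM (one-vs-one multi-class voting) is
#' trained on the flattened samples of the remaining datasets and evaluated
#' on the held-out one, so after all folds every dataset is tested exactly
#' once. Features are standardized with training-fold statistics only.
#' Confusion counts are aggregated over folds and row-normalized.
#'
#' @param win A `window_samples` object.
#' @param dp A [decoder_params()].
#' @param backend `"kernlab"` (precomputed RBF Gram matrix) or `"e1071"`
#'   (reference implementation of the identical model, used for
#'   cross-checking).
#' @return Object of class `decoding_result`: `confusion` (row-normalized),
#'   `counts`, `per_condition_accuracy`, `mean_accuracy`, `chance_level`,
#'   `n_per_dataset`.
#' @export
train_eval <- function(win, dp = decoder_params(),
                       backend = c("kernlab", "e1071")) {
  backend <- match.arg(backend)
  folds <- sort(unique(win$dataset))
  if (length(folds) < 2) stop("need at least 2 datasets")
  conds <- levels(win$label)
  counts <- matrix(0L, length(conds), length(conds),
                   dimnames = list(true = conds, predicted = conds))
  set.seed(dp$seed)
  for (k in folds) {
    tr <- win$dataset != k
    if (!all(conds %in% unique(as.character(win$label[tr]))))
      stop("condition absent from training fold ", k)
    pred <- svm_fold(win$S, win$label, tr, dp, backend)
    truth <- as.character(win$label[!tr])
    for (i in seq_along(truth))
      counts[truth[i], pred[i]] <- counts[truth[i], pred[i]] + 1L
  }
  confusion <- counts / rowSums(counts)
  structure(list(
    confusion = confusion, counts = counts,
    per_condition_accuracy = diag(confusion),
    mean_accuracy = mean(diag(confusion)),
    chance_level = 1 / length(conds),
    n_per_dataset = table(win$dataset)
  ), class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> mean accuracy %.3f (chance %.3f)\n",
              x$mean_accuracy, x$chance_level))
  print(round(x$confusion, 3))
  invisible(x)
}

#' Full condition-decoding pipeline for one participant
#'
#' pairwise WTC features -> PCA -> contiguous dataset split -> sliding
#' windows -> six-fold SVM evaluation.
#'
#' @param ptrials List of `preprocessed_trial` objects; all four conditions
#'   must be present.
#' @param p A [wavelet_params()].
#' @param dp A [decoder_params()].
#' @return A `decoding_result` with attribute `explained_variance`.
#' @export
decode_condition <- function(ptrials, p = wavelet_params(),
                             dp = decoder_params()) {
  conds <- unique(vapply(ptrials, `[[`, "", "condition"))
  missing_cond <- setdiff(tap_conditions(), conds)
  if (length(missing_cond))
    stop("decoding requires all conditions; missing: ",
         paste(missing_cond, collapse = ", "))
  feats <- participant_features(ptrials, p)
  if (!dp$pca_per_fold) {
    feats <- reduce_dimensions(feats, dp)
    win <- make_windows(split_datasets(feats, dp), dp)
    res <- train_eval(win, dp)
    attr(res, "explained_variance") <- attr(feats, "explained_variance")
    return(res)
  }
  ## leakage-sensitivity mode: PCA refitted on each training fold
  feats <- split_datasets(feats, dp)
  folds <- sort(unique(feats$dataset))
  conds_lv <- intersect(tap_conditions(), conds)
  counts <- matrix(0L, length(conds_lv), length(conds_lv),
                   dimnames = list(true = conds_lv, predicted = conds_lv))
  set.seed(dp$seed)
  for (k in folds) {
    fit <- fit_pca(feats$X[feats$dataset != k, , drop = FALSE],
                   dp$n_components)
    proj <- feats
    proj$X <- sweep(feats$X, 2, fit$mu) %*% fit$rotation
    win <- make_windows(proj, dp)
    pred <- svm_fold(win$S, win$label, win$dataset != k, dp)
    truth <- as.character(win$label[win$dataset == k])
    for (i in seq_along(truth))
      counts[truth[i], pred[i]] <- counts[truth[i], pred[i]] + 1L
  }
  confusion <- counts / rowSums(counts)
  structure(list(confusion = confusion, counts = counts,
                 per_condition_accuracy = diag(confusion),
                 mean_accuracy = mean(diag(confusion)),
                 chance_level = 1 / length(conds_lv),
                 n_per_dataset = table(feats$dataset)),
            class = "decoding_result")
}
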