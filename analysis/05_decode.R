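#!/usr/bin/env Rscript

# Sliding-window pattern decoding of attentional condition per participant:
# pairwise wavelet coherence of the 14 finger keypoints, PCA to 80
# components, trial-aligned six-way dataset split, 60/4 sliding windows,
# RBF-SVM with six-fold cross-validation. Group level: one-sample t-test of
# mean decoding accuracy against chance (0.25).

suppressMessages(library(autotap))

load_session <- function(sdir) {
  files <- setdiff(list.files(sdir, pattern = "\\.csv$", full.names = TRUE),
                   file.path(sdir, "ground_truth.csv"))
  preprocess_trials(lapply(files, read_trajectory))
}

sessions <- list.dirs("data/sessions", recursive = FALSE)
dir.create("results", showWarnings = FALSE)

accs <- c(); confusion_sum <- NULL
for (sdir in sessions) {
  id <- basename(sdir)
  res <- suppressWarnings(decode_condition(load_session(sdir)))
  accs[id] <- res$mean_accuracy
  confusion_sum <- if (is.null(confusion_sum)) res$confusion
  else confusion_sum + res$confusion
  message(sprintf("%s: mean decoding accuracy %.3f (chance %.3f)",
                  id, res$mean_accuracy, res$chance_level))
}
confusion_mean <- confusion_sum / length(sessions)
write.csv(as.data.frame(confusion_mean), "results/confusion_mean.csv")
write.csv(data.frame(participant = names(accs), mean_accuracy = accs),
          "results/decoding_accuracy.csv", row.names = FALSE)

tt <- t_tests(accs, 0.25, "one_sample")
message(sprintf("group: mean accuracy %.3f +/- %.3f SEM; vs chance t(%d) = %.2f, p = %.4g, d = %.2f",
                mean(accs), sd(accs) / sqrt(length(accs)), tt$df,
                tt$statistic, tt$p_value, tt$effect_size))
write.csv(data.frame(mean_accuracy = mean(accs), t = tt$statistic,
                     df = tt$df, p = tt$p_value, d = tt$effect_size),
          "results/decoding_vs_chance.csv", row.names = FALSE)
message("wrote results/decoding_accuracy.csv, confusion_mean.csv, decoding_vs_chance.csv")
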