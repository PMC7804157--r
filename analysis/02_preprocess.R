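#!/usr/bin/env Rscript

# Preprocess every simulated session: segment around the beeps (30/90-frame
# pads), normalize durations to the per-class mean, smooth (100 ms window),
# interpolate tracking outliers (100 px rule), and cut the range of
# interest (1 s after the initiation beep to the termination beep; 344
# frames for short trials). Writes a per-trial QC table.

suppressMessages(library(autotap))

sessions <- list.dirs("data/sessions", recursive = FALSE)
stopifnot(length(sessions) > 0)
dir.create("results", showWarnings = FALSE)

qc <- list()
for (sdir in sessions) {
  id <- basename(sdir)
  files <- setdiff(list.files(sdir, pattern = "\\.csv$", full.names = TRUE),
                   file.path(sdir, "ground_truth.csv"))
  trials <- lapply(files, read_trajectory)
  pt <- preprocess_trials(trials)
  qc[[id]] <- data.frame(
    participant = id,
    trial = vapply(pt, `[[`, "", "trial_id"),
    condition = vapply(pt, `[[`, "", "condition"),
    roi_frames = vapply(pt, function(x) nrow(x$roi), numeric(1)),
    outliers_interpolated = vapply(pt, function(x) sum(x$outlier_counts),
                                   numeric(1))
  )
  message(sprintf("%s: %d trials, ROI %d frames, %d outlier samples",
                  id, length(pt), nrow(pt[[1]]$roi),
                  sum(qc[[id]]$outliers_interpolated)))
}
write.csv(do.call(rbind, qc), "results/preprocessing_qc.csv",
          row.names = FALSE)
message("wrote results/preprocessing_qc.csv")
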