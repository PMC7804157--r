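## End-to-end orchestration: read a session directory of trajectory files,
## preprocess, estimate the tapping band, summarize coherence, compute the
## amplitude table, decode condition, and (with several participants) run
## the group statistics. Outputs are a pure function of (input files,
## config, seed).

#' Pipeline configuration
#'
#' Bundles every stage's tunable constants, all defaulting to the analysis
#' constants (30/90-frame segmentation pads, 6-frame smoothing, 100-px
#' outlier threshold, Morlet omega0 = 6 on a 40-point log grid, 80 PCA
#' components, 60/4 sliding windows, 6 datasets, RBF gamma 0.014).
#' Round-trips losslessly through JSON via [write_config()]/[read_config()].
#'
#' @param preproc A [preproc_params()].
#' @param wavelet A [wavelet_params()].
#' @param decoder A [decoder_params()].
#' @param seed Integer seed for stochastic stages.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(preproc = preproc_params(),
                            wavelet = wavelet_params(),
                            decoder = decoder_params(),
                            seed = 1L) {
  structure(list(preproc = preproc, wavelet = wavelet, decoder = decoder,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize a pipeline configuration
#' @param config A [pipeline_config()].
#' @param path Destination JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  ## doubles are written as %.17g strings so the round trip is bit-exact
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip)
    else if (is.double(x)) setNames(sprintf("%.17g", x), names(x))
    else x
  }
  payload <- strip(config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a pipeline configuration written by [write_config()]
#' @param path JSON path.
#' @return A [pipeline_config()] identical to the one written.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  wp <- raw$wavelet
  pp <- raw$preproc
  dp <- raw$decoder
  num <- function(v) if (is.null(v)) NULL else
    setNames(as.numeric(unlist(v)), names(v))
  pipeline_config(
    preproc = preproc_params(as.integer(pp$pre_pad), as.integer(pp$post_pad),
                             as.integer(pp$smooth_window),
                             num(pp$outlier_threshold),
                             target_durations = num(pp$target_durations)),
    wavelet = wavelet_params(num(wp$omega0), num(wp$freqs), num(wp$dt),
                             num(wp$scale_smooth), num(wp$time_smooth)),
    decoder = decoder_params(as.integer(dp$n_components),
                             num(dp$variance_floor),
                             as.integer(dp$window_len),
                             as.integer(dp$window_step),
                             as.integer(dp$n_datasets),
                             num(dp$kernel_gamma), num(dp$cost),
                             svm_tol = num(dp$svm_tol),
                             pca_per_fold = dp$pca_per_fold,
                             seed = as.integer(dp$seed)),
    seed = as.integer(raw$seed)
  )
}

#' Run the full analysis pipeline on a session directory
#'
#' Reads every trajectory file in `session_dir` (csv/yaml pairs in the
#' [write_trajectory()] dialect), groups trials by participant and, per
#' participant: preprocesses, estimates the tapping band, summarizes
#' inter-finger/inter-trial coherence, computes the amplitude table, and
#' decodes condition. Stages whose preconditions fail (fewer than 2 trials
#' per condition, or a missing condition for decoding) are skipped with a
#' logged reason rather than aborting the bundle. With at least 2
#' participants, group statistics (repeated-measures ANOVA on the coherence
#' summaries; one-sample t-tests of the modulation index against 0) are
#' added.
#'
#' @param session_dir Directory of trial files (>= 1 participant).
#' @param out_dir Output directory for the report bundle (created).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with per-participant results, the group
#'   statistics table (or `NULL`) and the log lines. The bundle contains
#'   per-participant delimited tables, a JSON summary each, the group
#'   `stats.csv`, the `config.json` used and `pipeline.log`.
#' @export
run_pipeline <- function(session_dir, out_dir, config = pipeline_config()) {
  files <- sort(list.files(session_dir, pattern = "\\.csv$",
                           full.names = TRUE))
  files <- files[basename(files) != "ground_truth.csv"]
  if (!length(files)) stop("no trajectory files in ", session_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  log_lines <- c(
    sprintf("pipeline start: %d trial files", length(files)),
    sprintf("config: pads %d/%d, smooth %d, outlier %g px, omega0 %g, %d freqs [%.3g, %.3g] Hz, pca %d, window %d/%d, datasets %d, gamma %g, seed %d",
            config$preproc$pre_pad, config$preproc$post_pad,
            config$preproc$smooth_window, config$preproc$outlier_threshold,
            config$wavelet$omega0, length(config$wavelet$freqs),
            min(config$wavelet$freqs), max(config$wavelet$freqs),
            config$decoder$n_components, config$decoder$window_len,
            config$decoder$window_step, config$decoder$n_datasets,
            config$decoder$kernel_gamma, config$seed))
  trials <- lapply(files, read_trajectory)
  pid <- vapply(trials, `[[`, "", "participant_id")
  results <- list()
  for (part in unique(pid)) {
    plog <- function(msg) log_lines <<- c(log_lines,
                                          sprintf("[%s] %s", part, msg))
    ptrials <- preprocess_trials(trials[pid == part], config$preproc)
    plog(sprintf("preprocessed %d trials; outliers interpolated: %d",
                 length(ptrials),
                 sum(vapply(ptrials, function(x) sum(x$outlier_counts), 0))))
    conds <- vapply(ptrials, `[[`, "", "condition")
    cond_n <- table(conds)

    band <- cohsum <- amp <- dec <- NULL
    if (any(cond_n >= 2)) {
      band <- participant_band(ptrials, config$wavelet)
      plog(sprintf("band: rate %.3f Hz, FWHM [%.3f, %.3f] Hz",
                   band$tapping_rate, band$f_low, band$f_high))
    } else plog("coherence stages skipped: fewer than 2 trials per condition")
    if (!is.null(band)) {
      if (all(cond_n >= 2)) {
        cohsum <- coherence_summary(ptrials, band, config$wavelet)
        amp <- amplitude_table(ptrials, band)
      } else plog("coherence summary skipped: a condition has < 2 trials")
      missing_cond <- setdiff(tap_conditions(), names(cond_n))
      if (!length(missing_cond)) {
        dec <- decode_condition(ptrials, config$wavelet, config$decoder)
        plog(sprintf("decoding: mean accuracy %.3f over %d samples",
                     dec$mean_accuracy, sum(dec$counts)))
      } else plog(paste("decoding skipped: missing condition",
                        paste(missing_cond, collapse = ", ")))
    }

    pdir <- file.path(out_dir, part)
    dir.create(pdir, showWarnings = FALSE)
    if (!is.null(band))
      utils::write.csv(data.frame(tapping_rate = band$tapping_rate,
                                  f_low = band$f_low, f_high = band$f_high),
                       file.path(pdir, "band.csv"), row.names = FALSE)
    if (!is.null(cohsum))
      utils::write.csv(cohsum, file.path(pdir, "coherence_summary.csv"),
                       row.names = FALSE)
    if (!is.null(amp))
      utils::write.csv(amp, file.path(pdir, "amplitude.csv"),
                       row.names = FALSE)
    if (!is.null(dec))
      utils::write.csv(as.data.frame(dec$confusion),
                       file.path(pdir, "confusion.csv"))
    summary_json <- list(
      participant = part, n_trials = length(ptrials),
      band = if (!is.null(band)) band[c("tapping_rate", "f_low", "f_high")],
      mean_accuracy = if (!is.null(dec)) dec$mean_accuracy,
      chance_level = if (!is.null(dec)) dec$chance_level
    )
    jsonlite::write_json(summary_json, file.path(pdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    results[[part]] <- list(band = band, coherence = cohsum,
                            amplitude = amp, decoding = dec)
  }

  stats_tab <- NULL
  with_coh <- Filter(function(r) !is.null(r$coherence), results)
  if (length(with_coh) >= 2) {
    conds <- tap_conditions()
    mk <- function(field) t(vapply(with_coh, function(r)
      setNames(r$coherence[[field]][match(conds, r$coherence$condition)],
               conds), numeric(4)))
    rows <- list()
    for (field in c("inter_finger", "inter_trial")) {
      a <- rm_anova_oneway(mk(field))
      rows[[field]] <- data.frame(
        effect = sprintf("attentional focus on %s coherence",
                         sub("_", "-", field)),
        statistic = a$statistic, df1 = a$df[1], df2 = a$df[2],
        p_value = a$p_value, effect_size = a$effect_size,
        stringsAsFactors = FALSE)
    }
    with_amp <- Filter(function(r) !is.null(r$amplitude), results)
    if (length(with_amp) >= 2) {
      amp0 <- with_amp[[1]]$amplitude
      for (i in which(amp0$condition != "reference")) {
        ia <- vapply(with_amp, function(r) r$amplitude$I_A[i], numeric(1))
        if (stats::sd(ia) > 0) {
          tt <- t_tests(ia, 0, "one_sample")
          rows[[paste0("ia", i)]] <- data.frame(
            effect = sprintf("I_A vs 0: %s finger, %s",
                             amp0$finger[i], amp0$condition[i]),
            statistic = tt$statistic, df1 = tt$df, df2 = NA,
            p_value = tt$p_value, effect_size = tt$effect_size,
            stringsAsFactors = FALSE)
        }
      }
    }
    stats_tab <- do.call(rbind, rows)
    utils::write.csv(stats_tab, file.path(out_dir, "stats.csv"),
                     row.names = FALSE)
  } else {
    log_lines <- c(log_lines, "group statistics skipped: < 2 participants")
  }

  write_config(config, file.path(out_dir, "config.json"))
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(list(participants = results, stats = stats_tab,
                 log = log_lines))
}
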