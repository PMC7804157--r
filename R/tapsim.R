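## Synthetic tapping-trajectory generator.
##
## Emulates the statistical structure the analysis pipeline assumes: each
## tapping finger oscillates quasi-periodically in the vertical (image-y)
## direction at a participant-specific rate, with fixed inter-finger phase
## lags (sequential tapping), condition-dependent per-finger amplitude gains
## (the ground truth for the modulation index), condition-dependent phase
## jitter (ground truth for coherence degradation), slow rate drift,
## additive pixel noise and occasional single-frame outlier spikes.

#' Simulation configuration
#'
#' All generator constants with their study-condition defaults. The default
#' tapping-rate range matches the observed range of spontaneous tapping
#' rates (3.07-8.43 Hz); trial durations, sampling rate and trial counts
#' mirror the experimental design (7 trials per condition and duration at
#' 60 Hz; 6.71 s / 11.14 s trials).
#'
#' @param tapping_rate Participant tapping rate in Hz, or `NULL` to draw one
#'   from a normal distribution with `rate_mean`/`rate_sd`, truncated to
#'   `rate_range`, when a session is generated (matching the observed
#'   population of spontaneous tapping rates).
#' @param rate_mean,rate_sd Moments of the participant-rate distribution
#'   (Hz); defaults 5.66 and 1.40.
#' @param rate_range Truncation range of the participant rate (Hz).
#' @param finger_phase_lags Named radians per finger; the default steps
#'   adjacent fingers by 2*pi/4 (index -> middle -> ring -> little).
#' @param base_amplitude Named pixels per joint type; fingertips move the
#'   most, MCP joints the least.
#' @param condition_gain Conditions x fingers matrix of multiplicative
#'   amplitude gains. The reference row is identically 1. The default
#'   emulates attentional facilitation of attended fingers (gain 1.2; 1.15
#'   for all fingers under sequence focus) and inhibition of unattended
#'   fingers (gain 0.9).
#' @param condition_lag_shift Conditions x fingers matrix of additive phase
#'   lag perturbations (radians); zero by default so amplitude and pattern
#'   effects are independently switchable.
#' @param phase_jitter_sd SD of per-cycle phase jitter in radians, drawn
#'   independently per finger and interpolated across each cycle. Either a
#'   single value, a named per-condition vector, or a conditions x fingers
#'   matrix. Larger values degrade inter-trial and inter-finger coherence.
#'   The default implements attentional desynchronization: jitter is lowest
#'   under the reference condition, elevated for all fingers under sequence
#'   focus, and highest for the attended finger under single-finger focus —
#'   which also gives each condition a distinct coherence pattern for the
#'   decoding stage.
#' @param rate_drift_sd Random-walk scale of the instantaneous rate,
#'   Hz per sqrt(second).
#' @param tremor_sd RMS pixels of the band-limited high-frequency movement
#'   component added to every keypoint (physiological tremor plus the extra
#'   tracking jitter that fast movement induces), independent per keypoint
#'   and trial.
#' @param tremor_band Frequency band of the tremor component in Hz.
#' @param baseline_drift_sd Random-walk scale of slow postural drift of the
#'   resting position, pixels per sqrt(second); drawn independently per
#'   finger (shared by its joints) and per trial, as hand posture relaxes
#'   differently on every trial.
#' @param reaction_time Seconds between a beep's onset and the movement
#'   change it triggers: tapping starts this long after the initiation beep
#'   and stops this long after the termination beep, so the analyzed epoch
#'   contains steady tapping only.
#' @param noise_sd Additive white pixel noise SD.
#' @param outlier_rate Per-frame probability of a tracking spike (one
#'   keypoint displaced by at least 100 px for a single frame).
#' @param outlier_size Range of spike magnitudes in pixels.
#' @param coupling Inter-finger mechanical-coupling (enslaving) coefficient;
#'   0 by default.
#' @param trial_counts Conditions x duration-class matrix of trial counts.
#' @param waveform `"raised_cosine"` (brief down-stroke, mostly up; has
#'   harmonics so band selection is non-trivial) or `"sine"` (analytic
#'   single-tone mode for tests).
#' @param waveform_power Sharpness exponent of the raised-cosine pulse.
#' @param pre_pad_frames,post_pad_frames Recorded frames before the
#'   initiation beep and after the termination beep (must exceed the
#'   preprocessing pads of 30/90).
#' @param sampling_rate Frames per second.
#' @param frame_size Video frame size in pixels (width, height).
#' @param seed Root seed; per-trial child seeds are drawn from it once, so
#'   any single trial is reproducible in isolation from its child seed.
#'
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(tapping_rate = NULL,
                       rate_mean = 5.66, rate_sd = 1.40,
                       rate_range = c(3.07, 8.43),
                       finger_phase_lags = c(index = 0, middle = pi / 2,
                                             ring = pi, little = 3 * pi / 2),
                       base_amplitude = c(tip = 40, dip = 28, pip = 16, mcp = 6),
                       condition_gain = default_condition_gain(),
                       condition_lag_shift = zero_condition_matrix(),
                       phase_jitter_sd = default_phase_jitter(),
                       rate_drift_sd = 0.02,
                       tremor_sd = 8,
                       tremor_band = c(7, 12),
                       baseline_drift_sd = 1.5,
                       reaction_time = 0.3,
                       noise_sd = 4.65,
                       outlier_rate = 0.005,
                       outlier_size = c(110, 160),
                       coupling = 0,
                       trial_counts = default_trial_counts(),
                       waveform = c("raised_cosine", "sine"),
                       waveform_power = 3,
                       pre_pad_frames = 60,
                       post_pad_frames = 120,
                       sampling_rate = 60,
                       frame_size = c(1920, 1080),
                       seed = 1L) {
  waveform <- match.arg(waveform)
  phase_jitter_sd <- as_jitter_matrix(phase_jitter_sd)
  cfg <- structure(list(
    tapping_rate = tapping_rate, rate_mean = rate_mean, rate_sd = rate_sd,
    rate_range = rate_range,
    finger_phase_lags = finger_phase_lags,
    base_amplitude = base_amplitude,
    condition_gain = condition_gain,
    condition_lag_shift = condition_lag_shift,
    phase_jitter_sd = phase_jitter_sd,
    rate_drift_sd = rate_drift_sd, tremor_sd = tremor_sd,
    tremor_band = tremor_band, baseline_drift_sd = baseline_drift_sd,
    reaction_time = reaction_time, noise_sd = noise_sd,
    outlier_rate = outlier_rate, outlier_size = outlier_size,
    coupling = coupling, trial_counts = trial_counts,
    waveform = waveform, waveform_power = waveform_power,
    pre_pad_frames = pre_pad_frames, post_pad_frames = post_pad_frames,
    sampling_rate = sampling_rate, frame_size = frame_size,
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Default condition-by-finger phase-jitter matrix (radians per cycle)
#'
#' Attentional desynchronization: 0.2 rad everywhere under the reference
#' condition, 0.32 for all fingers under sequence focus, and 0.40 for the
#' attended finger (0.24 for the others) under index/middle focus.
#'
#' @return 4x4 matrix, conditions x fingers.
#' @export
default_phase_jitter <- function() {
  j <- zero_condition_matrix()
  j["reference", ] <- 0.20
  j["sequence_focused", ] <- 0.32
  j["index_focused", ] <- 0.24
  j["index_focused", "index"] <- 0.40
  j["middle_focused", ] <- 0.24
  j["middle_focused", "middle"] <- 0.40
  j
}

## accept scalar, per-condition vector, or conditions x fingers matrix
as_jitter_matrix <- function(x) {
  fingers <- c("index", "middle", "ring", "little")
  if (is.matrix(x)) {
    stopifnot(identical(rownames(x), tap_conditions()))
    colnames(x) <- fingers
    return(x)
  }
  m <- zero_condition_matrix()
  if (length(x) == 1L) m[] <- x
  else {
    stopifnot(!is.null(names(x)))
    m[names(x), ] <- x
  }
  m
}

#' Default condition-by-finger amplitude gain matrix
#' @return 4x4 matrix, conditions in rows (reference row all 1).
#' @export
default_condition_gain <- function() {
  fingers <- c("index", "middle", "ring", "little")
  g <- matrix(1, 4, 4, dimnames = list(tap_conditions(), fingers))
  g["sequence_focused", ] <- 1.15
  g["index_focused", ] <- 0.9
  g["index_focused", "index"] <- 1.2
  g["middle_focused", ] <- 0.9
  g["middle_focused", "middle"] <- 1.2
  g
}

#' All-zero conditions x fingers matrix (lag-shift default)
#' @return 4x4 zero matrix with condition/finger dimnames.
#' @export
zero_condition_matrix <- function() {
  matrix(0, 4, 4, dimnames = list(tap_conditions(),
                                  c("index", "middle", "ring", "little")))
}

#' Default trial-count design (7 per condition and duration)
#' @return 4x2 integer matrix, conditions x duration classes.
#' @export
default_trial_counts <- function() {
  matrix(7L, 4, 2, dimnames = list(tap_conditions(), names(tap_durations())))
}

#' Null-session configuration
#'
#' A configuration in which all four conditions are generated with identical
#' parameters: unit gains, no lag shifts, and one common phase-jitter SD.
#' Used for chance-level decoding checks.
#'
#' @param seed Root seed.
#' @param trial_counts Trial-count matrix (default 8 short trials per
#'   condition, no long trials).
#' @param phase_jitter_sd Common jitter SD (radians).
#' @param ... Further arguments passed to [sim_config()].
#' @return A `sim_config`.
#' @export
null_sim_config <- function(seed = 1L,
                            trial_counts = {
                              tc <- default_trial_counts()
                              tc[, "short"] <- 8L; tc[, "long"] <- 0L; tc
                            },
                            phase_jitter_sd = 0.2, ...) {
  g <- default_condition_gain(); g[] <- 1
  sim_config(condition_gain = g,
             condition_lag_shift = zero_condition_matrix(),
             phase_jitter_sd = phase_jitter_sd,
             trial_counts = trial_counts, seed = seed, ...)
}

validate_sim_config <- function(cfg) {
  if (!all(cfg$condition_gain["reference", ] == 1))
    stop("condition_gain must be identically 1 for the reference condition")
  sds <- c(as.vector(cfg$phase_jitter_sd), cfg$rate_drift_sd, cfg$noise_sd,
           cfg$outlier_rate, cfg$tremor_sd, cfg$baseline_drift_sd)
  if (any(sds < 0)) stop("SDs and rates must be non-negative")
  if (!is.null(cfg$tapping_rate) &&
      (cfg$tapping_rate < 0.5 || cfg$tapping_rate > 15))
    stop("tapping_rate outside the analyzed frequency range")
  if (cfg$pre_pad_frames < 30 || cfg$post_pad_frames < 90)
    stop("recording pads must cover the preprocessing segmentation pads")
  if (any(cfg$outlier_size < 100))
    stop("outlier spikes must be at least 100 px to match the outlier rule")
  invisible(cfg)
}

## truncated-normal participant rate draw (rejection sampling)
draw_rate <- function(cfg) {
  repeat {
    r <- rnorm(1, cfg$rate_mean, cfg$rate_sd)
    if (r >= cfg$rate_range[1] && r <= cfg$rate_range[2]) return(r)
  }
}

## resting pixel geometry of the 17 keypoints (image convention: y down)
keypoint_baselines <- function() {
  fingers <- c(index = 950, middle = 1020, ring = 1090, little = 1160)
  joints <- c(tip = 600, dip = 625, pip = 655, mcp = 690)
  kp <- tap_keypoints()
  y0 <- x0 <- setNames(numeric(length(kp)), kp)
  for (f in names(fingers)) for (j in names(joints)) {
    k <- paste(f, j, sep = "_")
    x0[k] <- fingers[[f]] + (joints[[j]] - 600) * 0.15
    y0[k] <- joints[[j]]
  }
  x0["thumb_anchor"] <- 860
  y0["thumb_anchor"] <- 740
  list(x = x0, y = y0)
}

tap_waveform <- function(phase, waveform, power) {
  if (waveform == "sine") {
    (1 + cos(phase)) / 2          # single tone, for analytic tests
  } else {
    ((1 + cos(phase)) / 2)^power  # brief down-stroke, mostly up
  }
}

#' Generate one synthetic tapping trial
#'
#' Simulates the vertical trajectory of all 17 keypoints for one trial:
#' pre-initiation rest, a tapping epoch between the initiation and
#' termination beeps (with short onset/offset ramps, since starting and
#' stopping are not instantaneous), and post-termination rest. The
#' down-stroke of each tapping finger increases image-y by
#' `gain * base_amplitude * waveform(phase)`; joints of one finger share its
#' phase and jitter; the thumb anchor is static up to noise.
#'
#' @param cfg A [sim_config()].
#' @param condition One of [tap_conditions()].
#' @param duration_class `"short"` or `"long"`.
#' @param seed Trial seed (integer). Also drives the participant rate when
#'   `cfg$tapping_rate` is `NULL`.
#' @param participant_id,trial_id Identifiers stored in the trajectory.
#'
#' @return A `keypoint_trajectory` with attribute `"ground_truth"`: a list
#'   with the realized `rate`, per-finger `gain`, `jitter_sd`, and a data
#'   frame `outliers` of injected spike frames (0-based) and keypoints.
#' @export
generate_trial <- function(cfg, condition, duration_class, seed,
                           participant_id = "sim", trial_id = "T001") {
  if (!condition %in% tap_conditions())
    stop("unknown condition label: ", condition)
  if (!duration_class %in% names(tap_durations()))
    stop("unknown duration_class: ", duration_class)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(as.integer(seed))

  fs <- cfg$sampling_rate
  dt <- 1 / fs
  d_nom <- tap_durations()[[duration_class]]
  n_move <- round(d_nom * fs)
  init <- cfg$pre_pad_frames               # 0-based event frames
  term <- init + n_move
  n <- cfg$pre_pad_frames + n_move + cfg$post_pad_frames + 1L

  f0 <- if (is.null(cfg$tapping_rate)) draw_rate(cfg) else cfg$tapping_rate
  drift <- cumsum(rnorm(n, 0, cfg$rate_drift_sd * sqrt(dt)))
  f_t <- pmax(f0 + drift, 0.2)
  phase <- 2 * pi * cumsum(f_t) * dt

  ## tapping envelope: movement follows each beep by the reaction time, with
  ## 0.25 s ramps, so the range of interest sees steady tapping only
  tfr <- 0:(n - 1L)
  ramp <- 0.25 * fs
  react <- round(cfg$reaction_time * fs)
  env <- pmin(1, pmax(0, (tfr - init - react) / ramp)) *
    pmin(1, pmax(0, (term + react + ramp - tfr) / ramp))

  fingers <- c("index", "middle", "ring", "little")
  gains <- cfg$condition_gain[condition, fingers]
  lagsh <- cfg$condition_lag_shift[condition, fingers]
  jsd <- cfg$phase_jitter_sd[condition, fingers]

  ## per-finger smooth per-cycle phase jitter
  n_cycles <- ceiling(max(phase) / (2 * pi)) + 2L
  cycle_of <- floor(phase / (2 * pi)) + 1L
  frac <- phase / (2 * pi) - (cycle_of - 1L)
  jitter <- sapply(fingers, function(f) {
    off <- rnorm(n_cycles, 0, jsd[[f]])
    (1 - frac) * off[cycle_of] + frac * off[pmin(cycle_of + 1L, n_cycles)]
  })

  base <- keypoint_baselines()
  kp <- tap_keypoints()
  y <- matrix(0, n, length(kp), dimnames = list(NULL, kp))
  pulses <- matrix(0, n, 4, dimnames = list(NULL, fingers))
  for (fi in seq_along(fingers)) {
    f <- fingers[fi]
    ph <- phase + cfg$finger_phase_lags[[f]] + lagsh[[f]] + jitter[, f]
    pulses[, f] <- tap_waveform(ph, cfg$waveform, cfg$waveform_power) * env
  }
  if (cfg$coupling > 0) {
    coupled <- pulses %*% (diag(4) * (1 - cfg$coupling) +
                             cfg$coupling / 3 * (1 - diag(4)))
    dimnames(coupled) <- dimnames(pulses)
    pulses <- coupled
  }
  for (f in fingers) for (j in names(cfg$base_amplitude)) {
    k <- paste(f, j, sep = "_")
    y[, k] <- base$y[[k]] + gains[[f]] * cfg$base_amplitude[[j]] * pulses[, f]
  }
  y[, "thumb_anchor"] <- base$y[["thumb_anchor"]]
  ## slow postural drift, independent per finger, shared by its joints
  if (cfg$baseline_drift_sd > 0) {
    for (f in c(fingers, "thumb")) {
      bd <- cumsum(rnorm(n, 0, cfg$baseline_drift_sd * sqrt(dt)))
      cols <- if (f == "thumb") "thumb_anchor"
      else paste(f, names(cfg$base_amplitude), sep = "_")
      y[, cols] <- y[, cols] + bd
    }
  }
  if (cfg$tremor_sd > 0) {
    bf <- signal::butter(2, cfg$tremor_band / (fs / 2), type = "pass")
    for (k in seq_len(ncol(y))) {
      tn <- as.numeric(signal::filtfilt(bf, rnorm(n)))
      y[, k] <- y[, k] + tn / stats::sd(tn) * cfg$tremor_sd
    }
  }
  y <- y + matrix(rnorm(n * ncol(y), 0, cfg$noise_sd), n)
  x <- matrix(rep(base$x[kp], each = n), n, length(kp),
              dimnames = list(NULL, kp)) +
    matrix(rnorm(n * length(kp), 0, cfg$noise_sd), n)

  ## single-frame tracking spikes: per-frame Bernoulli, one keypoint hit
  spike <- which(runif(n) < cfg$outlier_rate)
  out_kp <- character(0)
  if (length(spike)) {
    out_kp <- sample(kp, length(spike), replace = TRUE)
    mag <- runif(length(spike), cfg$outlier_size[1], cfg$outlier_size[2]) *
      sample(c(-1, 1), length(spike), replace = TRUE)
    y[cbind(spike, match(out_kp, kp))] <-
      y[cbind(spike, match(out_kp, kp))] + mag
  }

  traj <- keypoint_trajectory(
    participant_id = participant_id, trial_id = trial_id,
    condition = condition, duration_class = duration_class,
    y = y, x = x, keypoints = kp,
    events = list(initiation_frame = init, termination_frame = term,
                  nominal_duration = d_nom),
    sampling_rate = fs
  )
  attr(traj, "ground_truth") <- list(
    rate = f0, gain = gains, jitter_sd = jsd, seed = as.integer(seed),
    outliers = data.frame(frame = spike - 1L, keypoint = out_kp,
                          stringsAsFactors = FALSE)
  )
  traj
}

#' Generate a full synthetic session
#'
#' Produces a balanced set of trials per condition and duration class for one
#' simulated participant, with a ground-truth table of everything implanted.
#' One root seed deterministically yields the participant's tapping rate and
#' one child seed per trial, so sessions are exactly reproducible and any
#' single trial can be regenerated in isolation.
#'
#' @param cfg A [sim_config()].
#' @param participant_id Identifier for the simulated participant.
#' @return List with `trials` (list of `keypoint_trajectory`),
#'   `ground_truth` (one row per trial: ids, condition, duration class, child
#'   seed, rate, jitter SD and per-finger gains) and `config`.
#' @export
generate_session <- function(cfg, participant_id = "sim01") {
  validate_sim_config(cfg)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)
  rate <- if (is.null(cfg$tapping_rate)) draw_rate(cfg) else cfg$tapping_rate
  cfg_fixed <- cfg
  cfg_fixed$tapping_rate <- rate

  design <- expand.grid(condition = rownames(cfg$trial_counts),
                        duration_class = colnames(cfg$trial_counts),
                        stringsAsFactors = FALSE)
  design <- design[rep(seq_len(nrow(design)),
                       cfg$trial_counts[cbind(design$condition,
                                              design$duration_class)]), ]
  if (nrow(design) == 0L) stop("trial_counts request zero trials")
  used <- rownames(cfg$trial_counts)[rowSums(cfg$trial_counts) > 0]
  if (length(used) < length(tap_conditions()))
    warning("some conditions have zero trials: ",
            paste(setdiff(tap_conditions(), used), collapse = ", "))
  seeds <- sample.int(.Machine$integer.max - 1L, nrow(design))

  trials <- vector("list", nrow(design))
  gt <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    id <- sprintf("T%03d", i)
    trials[[i]] <- generate_trial(cfg_fixed, design$condition[i],
                                  design$duration_class[i], seeds[i],
                                  participant_id = participant_id,
                                  trial_id = id)
    g <- attr(trials[[i]], "ground_truth")
    gt[[i]] <- data.frame(
      participant_id = participant_id, trial_id = id,
      condition = design$condition[i],
      duration_class = design$duration_class[i],
      seed = seeds[i], rate = g$rate,
      jitter_index = g$jitter_sd[["index"]],
      jitter_middle = g$jitter_sd[["middle"]],
      jitter_ring = g$jitter_sd[["ring"]],
      jitter_little = g$jitter_sd[["little"]],
      gain_index = g$gain[["index"]], gain_middle = g$gain[["middle"]],
      gain_ring = g$gain[["ring"]], gain_little = g$gain[["little"]],
      n_outliers = nrow(g$outliers), stringsAsFactors = FALSE
    )
  }
  list(trials = trials, ground_truth = do.call(rbind, gt), config = cfg)
}

#' Write a session to a directory in the trajectory file dialect
#'
#' @param session Result of [generate_session()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly. Writes one csv/yaml pair per trial plus
#'   `ground_truth.csv`.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (tr in session$trials) {
    stem <- sprintf("%s_%s.csv", tr$participant_id, tr$trial_id)
    write_trajectory(tr, file.path(dir, stem))
  }
  utils::write.csv(session$ground_truth,
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  invisible(dir)
}
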