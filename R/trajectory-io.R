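## Closed vocabularies of the experimental design ------------------------------

#' Attentional-focus condition labels
#'
#' The four conditions of the tapping experiments: a reference condition in
#' which attention is directed away from the tapping fingers, and three
#' movement-focused conditions (whole sequence, index finger, middle finger).
#'
#' @return Character vector of the four condition labels, reference first.
#' @export
tap_conditions <- function() {
  c("reference", "sequence_focused", "index_focused", "middle_focused")
}

#' Trial duration classes
#'
#' Trials come in two nominal durations, 6.71 s ("short") and 11.14 s
#' ("long"), so participants cannot predict trial termination.
#'
#' @return Named numeric vector of nominal durations in seconds.
#' @export
tap_durations <- function() {
  c(short = 6.71, long = 11.14)
}

#' Hand keypoint labels
#'
#' The 17 tracked keypoints: four joints (tip, DIP, PIP, MCP) on each of the
#' four tapping fingers (index, middle, ring, little), plus one static thumb
#' anchor. The thumb rests on an anchor patch and does not tap.
#'
#' @param fingers_only If `TRUE`, return only the 16 tapping-finger points
#'   (thumb anchor dropped). The 14-point subset used for pattern decoding is
#'   given by [decoding_keypoints()].
#'
#' @return Character vector of keypoint labels (length 17 or 16).
#' @export
tap_keypoints <- function(fingers_only = FALSE) {
  fingers <- c("index", "middle", "ring", "little")
  joints <- c("tip", "dip", "pip", "mcp")
  kp <- as.vector(t(outer(fingers, joints, paste, sep = "_")))
  if (fingers_only) kp else c(kp, "thumb_anchor")
}

#' Keypoints used for pattern decoding
#'
#' The decoding stage operates on the trajectory of all keypoints of the
#' tapping fingers excluding the thumb anchor, a total of 14 points, giving
#' choose(14, 2) = 91 unordered keypoint pairs. With 16 finger joints tracked,
#' the two least mobile points (ring and little MCP, which barely move during
#' sequential tapping) are excluded to arrive at the 14-point set.
#'
#' @return Character vector of 14 keypoint labels.
#' @export
decoding_keypoints <- function() {
  setdiff(tap_keypoints(fingers_only = TRUE), c("ring_mcp", "little_mcp"))
}

#' Fingertip keypoints
#' @return The four fingertip labels used for coherence and amplitude.
#' @export
fingertip_keypoints <- function() {
  paste0(c("index", "middle", "ring", "little"), "_tip")
}

## KeypointTrajectory ----------------------------------------------------------

#' Construct a keypoint trajectory
#'
#' Container for one trial's video-derived keypoint coordinates at a fixed
#' sampling rate, together with trial metadata and the initiation/termination
#' beep events. Frames are 0-based: frame 0 is the first recorded frame and
#' event frames index that axis. Coordinates follow the image convention
#' (y increases downward); all analyses use the vertical axis only.
#'
#' @param participant_id,trial_id Identifiers (scalars, coerced to character).
#' @param condition One of [tap_conditions()].
#' @param duration_class `"short"` or `"long"`.
#' @param y Numeric matrix, frames x keypoints, vertical pixel coordinate.
#'   Column names must match `keypoints`. May contain `NA` (missing samples)
#'   before preprocessing.
#' @param x Optional matrix of horizontal coordinates with the same shape.
#' @param keypoints Ordered character vector of keypoint names.
#' @param events List with `initiation_frame`, `termination_frame` (0-based
#'   frame indices) and `nominal_duration` (seconds).
#' @param sampling_rate Frames per second (default 60).
#'
#' @return Object of class `keypoint_trajectory`.
#' @export
keypoint_trajectory <- function(participant_id, trial_id, condition,
                                duration_class, y, x = NULL,
                                keypoints = colnames(y),
                                events, sampling_rate = 60) {
  y <- as.matrix(y)
  if (is.null(keypoints)) stop("keypoint names are required")
  colnames(y) <- keypoints
  if (!is.null(x)) {
    x <- as.matrix(x)
    colnames(x) <- keypoints
  }
  for (f in c("initiation_frame", "termination_frame"))
    if (!is.null(events[[f]])) events[[f]] <- as.integer(events[[f]])
  traj <- structure(
    list(
      participant_id = as.character(participant_id)[1],
      trial_id = as.character(trial_id)[1],
      condition = as.character(condition)[1],
      duration_class = as.character(duration_class)[1],
      sampling_rate = as.numeric(sampling_rate)[1],
      keypoints = as.character(keypoints),
      y = y, x = x,
      events = events
    ),
    class = "keypoint_trajectory"
  )
  validate_trajectory(traj)
  traj
}

#' Validate a keypoint trajectory
#'
#' Checks the structural invariants: closed condition/duration vocabularies,
#' consistent frame counts across keypoint series, ordered events, and a
#' positive sampling rate. Raw trajectories may contain missing samples;
#' preprocessed ones must be finite.
#'
#' @param traj A `keypoint_trajectory`.
#' @return `traj`, invisibly. Errors describe the offending field.
#' @export
validate_trajectory <- function(traj) {
  stopifnot(inherits(traj, "keypoint_trajectory"))
  if (!traj$condition %in% tap_conditions())
    stop("unknown condition label: ", traj$condition)
  if (!traj$duration_class %in% names(tap_durations()))
    stop("unknown duration_class: ", traj$duration_class)
  if (length(traj$keypoints) < 1L) stop("empty keypoint list")
  if (anyDuplicated(traj$keypoints)) stop("duplicated keypoint labels")
  if (!is.matrix(traj$y) || ncol(traj$y) != length(traj$keypoints))
    stop("y must be a frames x keypoints matrix matching keypoint names")
  if (!identical(colnames(traj$y), traj$keypoints))
    stop("column names of y do not match keypoint list")
  if (!is.null(traj$x) && !identical(dim(traj$x), dim(traj$y)))
    stop("x and y series must share one frame count")
  if (!is.numeric(traj$sampling_rate) || traj$sampling_rate <= 0)
    stop("sampling_rate must be positive")
  ev <- traj$events
  for (f in c("initiation_frame", "termination_frame", "nominal_duration"))
    if (is.null(ev[[f]]) || !is.finite(ev[[f]]))
      stop("events field missing or non-finite: ", f)
  if (ev$initiation_frame >= ev$termination_frame)
    stop("initiation_frame must precede termination_frame")
  if (ev$termination_frame > nrow(traj$y) - 1L)
    stop("termination_frame beyond recorded frames")
  invisible(traj)
}

#' @export
print.keypoint_trajectory <- function(x, ...) {
  cat(sprintf(
    "<keypoint_trajectory> participant %s, trial %s\n  condition: %s (%s), %d frames x %d keypoints @ %g Hz\n  events: init %d, term %d (nominal %.2f s)\n",
    x$participant_id, x$trial_id, x$condition, x$duration_class,
    nrow(x$y), length(x$keypoints), x$sampling_rate,
    x$events$initiation_frame, x$events$termination_frame,
    x$events$nominal_duration))
  nmiss <- sum(is.na(x$y))
  if (nmiss > 0) cat(sprintf("  missing samples: %d\n", nmiss))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `keypoint_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$y)

## File dialect ----------------------------------------------------------------
##
## One trial = a long-format delimited file (frame, keypoint, x, y) plus a
## YAML sidecar with the same stem carrying metadata and events. Coordinates
## are written with 17 significant digits so the round trip is bit-exact.

sidecar_path <- function(path) sub("\\.[^.]+$", ".yaml", path)

fmt_num <- function(v) ifelse(is.na(v), "", sprintf("%.17g", v))

#' Write a keypoint trajectory to disk
#'
#' Writes the long-format coordinate table (`frame,keypoint,x,y`) and a YAML
#' metadata sidecar next to it. Missing samples are written as empty cells
#' and survive the round trip; coordinates round-trip bit-for-bit.
#'
#' @param traj A valid `keypoint_trajectory`.
#' @param path Destination `.csv` path; the sidecar replaces the extension
#'   with `.yaml`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  validate_trajectory(traj)
  n <- n_frames(traj)
  K <- length(traj$keypoints)
  xs <- if (is.null(traj$x)) matrix(NA_real_, n, K) else traj$x
  df <- data.frame(
    frame = rep(0:(n - 1L), times = K),
    keypoint = rep(traj$keypoints, each = n),
    x = fmt_num(as.vector(xs)),
    y = fmt_num(as.vector(traj$y)),
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write trajectory file: ",
                              conditionMessage(e)))
  meta <- list(
    participant_id = traj$participant_id,
    trial_id = traj$trial_id,
    condition = traj$condition,
    duration_class = traj$duration_class,
    sampling_rate = traj$sampling_rate,
    keypoints = as.list(traj$keypoints),
    events = list(
      initiation_frame = as.integer(traj$events$initiation_frame),
      termination_frame = as.integer(traj$events$termination_frame),
      nominal_duration = traj$events$nominal_duration
    )
  )
  yaml::write_yaml(meta, sidecar_path(path), precision = 17)
  invisible(path)
}

#' Read a keypoint trajectory from disk
#'
#' Inverse of [write_trajectory()]. Validates the header, frame indices and
#' keypoint labels against the sidecar metadata; blank coordinate cells
#' become missing samples (`NA`), never zero.
#'
#' @param path Path to the `.csv` coordinate table (sidecar must exist).
#' @return A validated `keypoint_trajectory`.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such trajectory file: ", path)
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing metadata sidecar: ", sp)
  meta <- yaml::read_yaml(sp)
  for (f in c("participant_id", "trial_id", "condition", "duration_class",
              "sampling_rate", "keypoints", "events"))
    if (is.null(meta[[f]])) stop("sidecar missing field: ", f)
  for (f in c("initiation_frame", "termination_frame", "nominal_duration"))
    if (is.null(meta$events[[f]])) stop("sidecar events missing field: ", f)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("integer", "character",
                                       "numeric", "numeric"))
  if (!identical(names(df), c("frame", "keypoint", "x", "y")))
    stop("malformed header: expected frame,keypoint,x,y, got: ",
         paste(names(df), collapse = ","))
  kp <- unlist(meta$keypoints)
  bad <- setdiff(unique(df$keypoint), kp)
  if (length(bad))
    stop("unknown keypoint label in row ",
         which(df$keypoint == bad[1])[1], ": ", bad[1])
  n <- max(df$frame) + 1L
  y <- matrix(NA_real_, n, length(kp), dimnames = list(NULL, kp))
  xm <- y
  for (k in kp) {
    rows <- df[df$keypoint == k, ]
    if (anyDuplicated(rows$frame)) {
      d <- rows$frame[duplicated(rows$frame)][1]
      stop("duplicate frame index ", d, " for keypoint ", k)
    }
    y[rows$frame + 1L, k] <- rows$y
    xm[rows$frame + 1L, k] <- rows$x
  }
  if (all(is.na(xm))) xm <- NULL
  keypoint_trajectory(
    participant_id = meta$participant_id, trial_id = meta$trial_id,
    condition = meta$condition, duration_class = meta$duration_class,
    y = y, x = xm, keypoints = kp,
    events = meta$events, sampling_rate = meta$sampling_rate
  )
}
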