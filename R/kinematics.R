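#' A 2-D sway trajectory (pitch, roll) in either the angle or velocity domain
#'
#' @param pitch,roll equal-length finite numeric vectors; deg (angle) or deg/s
#'   (velocity).
#' @param kind `"angle"` or `"velocity"`.
#' @export
sway_trajectory <- function(pitch, roll, kind = c("angle", "velocity")) {
  kind <- match.arg(kind)
  if (length(pitch) != length(roll))
    stop_domain("pitch and roll differ in length")
  if (length(pitch) < 1) stop_domain("empty trajectory")
  if (!all(is.finite(pitch)) || !all(is.finite(roll)))
    stop_domain("non-finite trajectory sample")
  structure(list(pitch = as.numeric(pitch), roll = as.numeric(roll),
                 kind = kind), class = "sway_trajectory")
}

detrend_linear <- function(x) {
  n <- length(x)
  t <- seq_len(n)
  tc <- t - mean(t)
  x - mean(x) - tc * (sum(tc * x) / sum(tc * tc))
}

#' Reconstruct sway angle from angular velocity
#'
#' Only angular velocity is stored by the sensor, but position and velocity
#' encode different information, so the angle trajectory is reconstructed by
#' cumulative trapezoidal integration at the recording's sample period. A
#' best-fit linear trend is removed per channel afterwards to suppress
#' integration drift (the simplest defensible drift correction for otherwise
#' unpreprocessed signals).
#'
#' @param rec a [sway_recording()] with at least 2 samples.
#' @return a [sway_trajectory()] of kind `"angle"` (degrees), same length as
#'   the input.
#' @export
integrate_angle <- function(rec) {
  n <- length(rec$pitch_velocity)
  if (n < 2) stop_domain("integration needs at least 2 samples")
  dt <- 1 / rec$sample_rate
  cumtrapz <- function(v) c(0, cumsum((v[-n] + v[-1]) / 2 * dt))
  sway_trajectory(detrend_linear(cumtrapz(rec$pitch_velocity)),
                  detrend_linear(cumtrapz(rec$roll_velocity)),
                  kind = "angle")
}

#' Velocity trajectory of a recording
#' @param rec a [sway_recording()].
#' @export
velocity_trajectory <- function(rec) {
  sway_trajectory(rec$pitch_velocity, rec$roll_velocity, kind = "velocity")
}

#' Root-mean-square of a signal
#' @param values non-empty numeric vector.
#' @return `sqrt(mean(values^2))`.
#' @export
rms <- function(values) {
  if (!length(values)) stop_domain("rms of an empty vector is undefined")
  sqrt(mean(values^2))
}

#' RMS of the resultant (per-sample Euclidean) sway magnitude
#'
#' Equals `sqrt(rms(pitch)^2 + rms(roll)^2)` and is invariant under joint
#' rotation of the two axes — the "sway in all directions" summary.
#'
#' @param pitch,roll equal-length non-empty numeric vectors.
#' @export
resultant_rms <- function(pitch, roll) {
  if (length(pitch) != length(roll)) stop_domain("channel length mismatch")
  rms(sqrt(pitch^2 + roll^2))
}

#' Path length of a 2-D sway trajectory
#'
#' Cumulative Euclidean distance traveled across consecutive samples,
#' `sum_i sqrt(dpitch_i^2 + droll_i^2)`. A single point has path length 0.
#'
#' @param traj a [sway_trajectory()].
#' @export
path_length <- function(traj) {
  if (length(traj$pitch) < 2) return(0)
  sum(sqrt(diff(traj$pitch)^2 + diff(traj$roll)^2))
}

#' Confidence-ellipse area of a 2-D sway trajectory
#'
#' Area of the `coverage`-level ellipse of the sample covariance:
#' `pi * q * sqrt(lambda1 * lambda2)` where `lambda` are the covariance
#' eigenvalues and `q = qchisq(coverage, df = 2)`. The standard posturography
#' sway-magnitude summary (default 95% coverage). A degenerate (rank < 2)
#' covariance yields 0 with a warning.
#'
#' @param traj a [sway_trajectory()] with at least 3 samples.
#' @param coverage ellipse coverage probability (default 0.95).
#' @export
ellipse_area <- function(traj, coverage = 0.95) {
  if (length(traj$pitch) < 3) stop_domain("ellipse_area needs >= 3 samples")
  S <- stats::cov(cbind(traj$pitch, traj$roll))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= .Machine$double.eps * max(ev, 1)) {
    warning("degenerate sway covariance; ellipse area set to 0", call. = FALSE)
    return(0)
  }
  pi * stats::qchisq(coverage, df = 2) * sqrt(ev[1] * ev[2])
}

#' Names of the 11 kinematic sway features, in order
#' @export
feature_names <- function() {
  c("rms_pitch_angle", "rms_roll_angle", "rms_resultant_angle",
    "rms_pitch_velocity", "rms_roll_velocity", "rms_resultant_velocity",
    "path_length_angle", "path_length_velocity",
    "ellipse_area_angle", "ellipse_area_velocity",
    "rms_resultant_combined")
}

#' The 11 hand-engineered kinematic sway descriptors of one repetition
#'
#' Spans the three classical descriptor families — RMS sway in all directions,
#' sway-path length, and elliptical fit area — in both the reconstructed angle
#' domain (deg) and the measured angular-velocity domain (deg/s): per-axis and
#' resultant RMS for each domain, path length for each domain, 95%
#' confidence-ellipse area for each domain, plus a combined resultant RMS over
#' the concatenation of the two domains' per-sample magnitude series,
#' `sqrt((rms_resultant_angle^2 + rms_resultant_velocity^2) / 2)`. All entries
#' are non-negative and deterministic; RMS and path length scale linearly and
#' ellipse areas quadratically under uniform signal scaling.
#'
#' @param rec a valid, complete [sway_recording()].
#' @param coverage ellipse coverage (default 0.95).
#' @return named numeric vector of length 11 (see [feature_names()]).
#' @export
feature_vector <- function(rec, coverage = 0.95) {
  ang <- integrate_angle(rec)
  vel <- velocity_trajectory(rec)
  rra <- resultant_rms(ang$pitch, ang$roll)
  rrv <- resultant_rms(vel$pitch, vel$roll)
  out <- c(
    rms_pitch_angle = rms(ang$pitch),
    rms_roll_angle = rms(ang$roll),
    rms_resultant_angle = rra,
    rms_pitch_velocity = rms(vel$pitch),
    rms_roll_velocity = rms(vel$roll),
    rms_resultant_velocity = rrv,
    path_length_angle = path_length(ang),
    path_length_velocity = path_length(vel),
    ellipse_area_angle = suppressWarnings(ellipse_area(ang, coverage)),
    ellipse_area_velocity = suppressWarnings(ellipse_area(vel, coverage)),
    rms_resultant_combined = sqrt((rra^2 + rrv^2) / 2)
  )
  stopifnot(all(is.finite(out)), all(out >= 0))
  out
}

#' Feature table for a whole dataset
#'
#' @param ds a `sway_dataset`.
#' @param coverage ellipse coverage (default 0.95).
#' @return data.frame with `repetition_id`, `participant_id` and the 11
#'   feature columns, one row per repetition.
#' @export
featurize_dataset <- function(ds, coverage = 0.95) {
  rows <- lapply(ds$recordings, function(rec) {
    data.frame(repetition_id = rec$repetition_id,
               participant_id = rec$participant_id,
               as.list(feature_vector(rec, coverage)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
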