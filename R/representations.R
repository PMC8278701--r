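#' Channel configuration for the time-series representation
#'
#' The default uses four channels in two groups — reconstructed pitch/roll
#' angle and measured pitch/roll angular velocity — matching the depth-wise
#' convolution design in which position-like and velocity-like channels get
#' separate filters. A literal two-channel velocity-only mode is available
#' for ablation.
#'
#' @param mode `"angle_velocity"` (4 channels, 2 groups; default) or
#'   `"velocity"` (2 channels, 1 group).
#' @return list with `channels` (names) and `groups` (named list of channel
#'   index vectors partitioning the channels).
#' @export
channel_config <- function(mode = c("angle_velocity", "velocity")) {
  mode <- match.arg(mode)
  if (mode == "angle_velocity") {
    list(mode = mode,
         channels = c("pitch_angle", "roll_angle",
                      "pitch_velocity", "roll_velocity"),
         groups = list(angle = 1:2, velocity = 3:4))
  } else {
    list(mode = mode,
         channels = c("pitch_velocity", "roll_velocity"),
         groups = list(velocity = 1:2))
  }
}

raw_channels <- function(rec, config) {
  out <- matrix(0, length(config$channels), length(rec$pitch_velocity))
  rownames(out) <- config$channels
  if ("pitch_angle" %in% config$channels) {
    ang <- integrate_angle(rec)
    out["pitch_angle", ] <- ang$pitch
    out["roll_angle", ] <- ang$roll
  }
  out["pitch_velocity", ] <- rec$pitch_velocity
  out["roll_velocity", ] <- rec$roll_velocity
  out
}

#' Fit per-channel standardization statistics on training data only
#'
#' @param train_recs list of training [sway_recording()]s.
#' @param config a [channel_config()].
#' @return list with per-channel `mean` and `sd` (floored at a tiny epsilon),
#'   to be passed to [to_timeseries()] for every split.
#' @export
fit_standardizer <- function(train_recs, config = channel_config()) {
  if (!length(train_recs)) stop_domain("empty training collection")
  mats <- lapply(train_recs, raw_channels, config = config)
  all <- do.call(cbind, mats)
  m <- rowMeans(all)
  s <- sqrt(rowMeans((all - m)^2))
  list(mean = m, sd = pmax(s, 1e-12), config = config)
}

#' Build the standardized multichannel time-series input for one repetition
#'
#' Channels are standardized with training-set statistics (subtract channel
#' mean, divide by channel SD) and brought to the fixed nominal length
#' `T = duration * sample_rate` by symmetric zero-padding or truncation.
#'
#' @param rec a [sway_recording()].
#' @param standardizer output of [fit_standardizer()].
#' @param length_out fixed output length (default the recording's nominal
#'   3000 for 30 s at 100 Hz).
#' @return matrix `channels x length_out` with attributes `groups`, `channels`.
#' @export
to_timeseries <- function(rec, standardizer,
                          length_out = round(30 * rec$sample_rate)) {
  config <- standardizer$config
  x <- (raw_channels(rec, config) - standardizer$mean) / standardizer$sd
  n <- ncol(x)
  if (n > length_out) {
    lead <- (n - length_out) %/% 2
    x <- x[, (lead + 1):(lead + length_out), drop = FALSE]
  } else if (n < length_out) {
    pad <- length_out - n
    x <- cbind(matrix(0, nrow(x), pad %/% 2), x,
               matrix(0, nrow(x), pad - pad %/% 2))
  }
  attr(x, "groups") <- config$groups
  attr(x, "channels") <- config$channels
  x
}

#' Raster bounds for the trajectory-image representation
#'
#' The plot's axis half-widths, fitted on training data only and serialized
#' with any trained model (test data never influence them).
#'
#' @param trajs non-empty list of [sway_trajectory()]s (one domain).
#' @param policy `"max_abs"` (default) or `"percentile"`.
#' @param p percentile in (0, 100] when `policy = "percentile"`.
#' @return list of class `raster_bounds` with positive `pitch_halfwidth` and
#'   `roll_halfwidth`.
#' @export
fit_bounds <- function(trajs, policy = c("max_abs", "percentile"), p = 99) {
  policy <- match.arg(policy)
  if (!length(trajs)) stop_domain("empty training collection")
  all_p <- abs(unlist(lapply(trajs, `[[`, "pitch")))
  all_r <- abs(unlist(lapply(trajs, `[[`, "roll")))
  hw <- function(v) {
    x <- if (policy == "max_abs") max(v)
         else unname(stats::quantile(v, p / 100, type = 7))
    max(x, 1e-9)
  }
  structure(list(pitch_halfwidth = hw(all_p), roll_halfwidth = hw(all_r),
                 policy = policy, p = p), class = "raster_bounds")
}

# map coordinates in [-hw, hw] to pixel indices 1..npix (clamped)
coord_to_pixel <- function(v, hw, npix) {
  pmin(pmax(1L + floor((v + hw) / (2 * hw) * npix), 1L), npix)
}

bresenham <- function(x0, y0, x1, y1) {
  dx <- abs(x1 - x0); dy <- abs(y1 - y0)
  sx <- sign(x1 - x0); sy <- sign(y1 - y0)
  n <- max(dx, dy) + 1L
  xs <- integer(n); ys <- integer(n)
  err <- dx - dy
  x <- x0; y <- y0
  for (i in seq_len(n)) {
    xs[i] <- x; ys[i] <- y
    if (x == x1 && y == y1) { xs <- xs[1:i]; ys <- ys[1:i]; break }
    e2 <- 2L * err
    if (e2 > -dy) { err <- err - dy; x <- x + sx }
    if (e2 < dx) { err <- err + dx; y <- y + sy }
  }
  cbind(xs, ys)
}

#' Rasterize a sway trajectory onto a binary 60x60 image
#'
#' Pitch maps to the x-axis (columns), roll to the y-axis with row 1 at +roll
#' (the plotting convention). Consecutive samples are connected by Bresenham
#' line segments so the image depicts the drawn trajectory rather than a
#' scatter; out-of-bounds samples clamp to the border pixels. Lit pixels are 1.
#'
#' @param traj a [sway_trajectory()].
#' @param bounds a [fit_bounds()] result for the trajectory's domain.
#' @param npix image side (default 60).
#' @return `npix x npix` binary matrix (rows = roll from +hw down, columns =
#'   pitch from -hw up).
#' @export
rasterize <- function(traj, bounds, npix = 60L) {
  col <- coord_to_pixel(traj$pitch, bounds$pitch_halfwidth, npix)
  row <- coord_to_pixel(-traj$roll, bounds$roll_halfwidth, npix)
  img <- matrix(0L, npix, npix)
  img[cbind(row, col)] <- 1L
  n <- length(col)
  if (n > 1) {
    jump <- which(pmax(abs(diff(col)), abs(diff(row))) > 1L)
    for (i in jump) {
      # draw from the lexicographically smaller endpoint so the image is
      # invariant under sample-order reversal of the trajectory
      a <- c(col[i], row[i]); b <- c(col[i + 1L], row[i + 1L])
      if (b[1] < a[1] || (b[1] == a[1] && b[2] < a[2])) { tmp <- a; a <- b; b <- tmp }
      px <- bresenham(a[1], a[2], b[1], b[2])
      img[cbind(px[, 2], px[, 1])] <- 1L
    }
  }
  img
}

#' Build the two-channel image input (angle and velocity) for one repetition
#'
#' @param rec a [sway_recording()].
#' @param angle_bounds,velocity_bounds per-domain [fit_bounds()] results
#'   fitted on training trajectories.
#' @param npix image side (default 60).
#' @param rotation optional rotation (degrees) applied to the (pitch, roll)
#'   coordinates of both domains before rasterization (used by augmentation).
#' @return list of class `image_input` with `angle` and `velocity` binary
#'   `npix x npix` matrices and the bounds used.
#' @export
make_image_input <- function(rec, angle_bounds, velocity_bounds, npix = 60L,
                             rotation = 0) {
  rot <- function(traj, deg) {
    if (deg == 0) return(traj)
    a <- deg * pi / 180
    sway_trajectory(cos(a) * traj$pitch - sin(a) * traj$roll,
                    sin(a) * traj$pitch + cos(a) * traj$roll,
                    kind = traj$kind)
  }
  ang <- rot(integrate_angle(rec), rotation)
  vel <- rot(velocity_trajectory(rec), rotation)
  structure(list(angle = rasterize(ang, angle_bounds, npix),
                 velocity = rasterize(vel, velocity_bounds, npix),
                 bounds = list(angle = angle_bounds,
                               velocity = velocity_bounds),
                 rotation = rotation),
            class = "image_input")
}

#' The rotation-angle set used for training-image augmentation (degrees)
#' @export
rotation_angle_set <- function() c(30, 60, 120, 150, 210, 240, 300, 330)

#' Rotation-augment one training repetition's image input
#'
#' Draws `n_copies` angles uniformly with replacement from `angle_set` and
#' rotates the underlying (pitch, roll) coordinates before rasterization —
#' exact and interpolation-free, realizing the same augmentation intent as
#' rotating the rendered image. Applied to training data only; the label
#' travels with each copy.
#'
#' @param rec a training-set [sway_recording()].
#' @param angle_bounds,velocity_bounds training-fitted [fit_bounds()].
#' @param n_copies number of augmented copies (default 3, so the augmented
#'   training set is 4x the original).
#' @param angle_set candidate rotations, degrees (default
#'   [rotation_angle_set()]).
#' @param seed integer seed controlling the angle draws.
#' @param npix image side (default 60).
#' @return list of `n_copies` `image_input` objects.
#' @export
augment_rotations <- function(rec, angle_bounds, velocity_bounds,
                              n_copies = 3L, angle_set = rotation_angle_set(),
                              seed = 1L, npix = 60L) {
  if (!length(angle_set)) stop_domain("angle_set must be non-empty")
  angles <- with_seed(seed,
                      angle_set[sample.int(length(angle_set), n_copies,
                                           replace = TRUE)])
  lapply(angles, function(a)
    make_image_input(rec, angle_bounds, velocity_bounds, npix, rotation = a))
}
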