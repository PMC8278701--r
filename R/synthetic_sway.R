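#' Configuration of the synthetic posturography generator
#'
#' The generator emulates the statistical structure the downstream method
#' assumes: band-limited stochastic trunk sway whose magnitude grows with a
#' latent severity in [0, 1], pitch/roll anisotropy, occasional step-out
#' transients at high severity, a panel of 1-8 noisy ordinal raters, and a
#' downward-biased self-assessment.
#'
#' @param n_participants number of participants (default 10).
#' @param n_exercises_per_participant exercises per participant (default 15).
#' @param n_repetitions repetitions per exercise (default 3).
#' @param duration repetition length, seconds (default 30).
#' @param sample_rate sampling rate, samples/s (default 100).
#' @param sway_band passband of the sway spectrum, Hz (default 0.1-3.0, the
#'   conventional postural-sway bandwidth).
#' @param base_rms resultant angular-velocity RMS at severity 0, deg/s
#'   (default 0.5).
#' @param rms_gain additional resultant RMS per unit severity, deg/s
#'   (default 6).
#' @param anisotropy pitch:roll RMS ratio (default 1.4; anterior-posterior
#'   sway usually exceeds medial-lateral sway in stance).
#' @param stepout_rate expected step-out transients per repetition at
#'   severity 1 (default 2).
#' @param n_raters_mean expected PT panel size (default 4.28).
#' @param rater_noise_sd SD of per-rater perception noise, severity units
#'   (default 0.12).
#' @param self_bias severity units subtracted before self-assessment binning
#'   (default 0.15), producing systematic underestimation.
#' @param rating_thresholds four increasing cut points on severity mapping it
#'   to the ordinal 1-5 scale (default 0.2, 0.4, 0.6, 0.8).
#' @param severity_noise_sd SD of the repetition-level severity jitter around
#'   ability + difficulty (default 0.05).
#' @param seed master seed; every repetition and rater panel derives its own
#'   sub-seed from it, so datasets are reproducible under partial regeneration.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 10,
                       n_exercises_per_participant = 15,
                       n_repetitions = 3,
                       duration = 30,
                       sample_rate = 100,
                       sway_band = c(0.1, 3.0),
                       base_rms = 0.5,
                       rms_gain = 6.0,
                       anisotropy = 1.4,
                       stepout_rate = 2.0,
                       n_raters_mean = 4.28,
                       rater_noise_sd = 0.12,
                       self_bias = 0.15,
                       rating_thresholds = c(0.2, 0.4, 0.6, 0.8),
                       severity_noise_sd = 0.05,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (length(rating_thresholds) != 4 || any(diff(rating_thresholds) <= 0) ||
      any(rating_thresholds <= 0) || any(rating_thresholds >= 1))
    stop_domain("rating_thresholds must be 4 strictly increasing values in (0,1)")
  pos <- c("duration", "sample_rate", "base_rms", "rms_gain", "anisotropy",
           "n_raters_mean")
  for (p in pos) if (cfg[[p]] <= 0) stop_domain("%s must be positive", p)
  if (stepout_rate < 0 || rater_noise_sd < 0 || severity_noise_sd < 0)
    stop_domain("rates and noise SDs must be non-negative")
  if (length(sway_band) != 2 || sway_band[1] <= 0 ||
      sway_band[2] <= sway_band[1] || sway_band[2] > sample_rate / 2)
    stop_domain("sway_band must be an increasing Hz interval below Nyquist")
  structure(cfg, class = "sim_config")
}

# Band-limited Gaussian noise: white noise filtered in the frequency domain to
# a flat spectrum inside `band`, rescaled so the *expected* RMS equals target.
bandlimited_noise <- function(n, sample_rate, band, target_rms) {
  x <- stats::rnorm(n)
  f <- (seq_len(n) - 1) / n * sample_rate
  f <- pmin(f, sample_rate - f)  # two-sided frequency axis
  keep <- f >= band[1] & f <= band[2]
  X <- stats::fft(x)
  X[!keep] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  # masking keeps a fraction `mean(keep)` of the white-noise variance
  y * target_rms / sqrt(mean(keep))
}

#' Simulate one repetition's sway recording at a given severity
#'
#' Pitch and roll angular velocity are independent band-limited Gaussian
#' processes with resultant RMS `base_rms + rms_gain * severity`, split
#' between the axes by the configured anisotropy. With a Poisson-distributed
#' count of mean `stepout_rate * severity`, half-sine transient excursions
#' (0.5-1.5 s, amplitude 3-5 times the stationary RMS, random direction) are
#' added, mimicking corrective steps; the injected count is recorded as
#' metadata. Deterministic given (severity, cfg, seed).
#'
#' @param severity latent severity in [0, 1].
#' @param cfg a [sim_config()].
#' @param seed integer seed for this repetition.
#' @param repetition_id,participant_id,exercise_id identifiers to attach.
#' @return a [sway_recording()].
#' @export
simulate_repetition <- function(severity, cfg, seed,
                                repetition_id = "rep", participant_id = "p1",
                                exercise_id = "ex1") {
  if (!is.finite(severity) || severity < 0 || severity > 1)
    stop_domain("severity must lie in [0, 1], got %s", format(severity))
  n <- round(cfg$duration * cfg$sample_rate)
  with_seed(seed, {
    target <- cfg$base_rms + cfg$rms_gain * severity
    # resultant^2 = pitch^2 + roll^2 with pitch = anisotropy * roll
    roll_rms <- target / sqrt(1 + cfg$anisotropy^2)
    pitch_rms <- cfg$anisotropy * roll_rms
    pitch <- bandlimited_noise(n, cfg$sample_rate, cfg$sway_band, pitch_rms)
    roll <- bandlimited_noise(n, cfg$sample_rate, cfg$sway_band, roll_rms)
    n_steps <- stats::rpois(1, cfg$stepout_rate * severity)
    for (k in seq_len(n_steps)) {
      dur <- stats::runif(1, 0.5, 1.5)
      amp <- stats::runif(1, 3, 5) * target * sample(c(-1, 1), 1)
      theta <- stats::runif(1, 0, 2 * pi)
      len <- min(max(2L, round(dur * cfg$sample_rate)), n)
      start <- sample.int(n - len + 1L, 1)
      pulse <- amp * sin(pi * seq(0, 1, length.out = len))
      span <- start:(start + len - 1L)
      pitch[span] <- pitch[span] + cos(theta) * pulse
      roll[span] <- roll[span] + sin(theta) * pulse
    }
    sway_recording(repetition_id, participant_id, exercise_id,
                   cfg$sample_rate, pitch, roll, step_out_count = n_steps)
  })
}

severity_to_rating <- function(x, thresholds) {
  1L + vapply(x, function(v) sum(v > thresholds), 0L)
}

#' Simulate a PT rating panel (and self-assessment) for one repetition
#'
#' Panel size is 1 + Binomial(7, (n_raters_mean - 1)/7), giving support 1..8
#' with the configured mean. Each PT's rating bins (severity + Gaussian
#' perception noise) against the rating thresholds; the self-assessment bins
#' (severity - self_bias + noise), yielding systematic underestimation.
#'
#' @param severity latent severity in [0, 1].
#' @param cfg a [sim_config()].
#' @param seed integer seed for this panel.
#' @return a [rating_set()] with rater IDs drawn from the pool pt1..pt8.
#' @export
simulate_raters <- function(severity, cfg, seed) {
  if (!is.finite(severity) || severity < 0 || severity > 1)
    stop_domain("severity must lie in [0, 1]")
  with_seed(seed, {
    n_raters <- 1L + stats::rbinom(1, 7, (cfg$n_raters_mean - 1) / 7)
    raters <- sort(sample.int(8, n_raters))
    perceived <- severity + stats::rnorm(n_raters, 0, cfg$rater_noise_sd)
    pt <- severity_to_rating(perceived, cfg$rating_thresholds)
    own <- severity - cfg$self_bias + stats::rnorm(1, 0, cfg$rater_noise_sd)
    rating_set(stats::setNames(pt, paste0("pt", raters)),
               self_rating = severity_to_rating(own, cfg$rating_thresholds))
  })
}

# Catalogue of exercise definitions spanning the surface / stance / vision /
# head-movement conditions used in standing-balance progressions.
exercise_catalogue <- function() {
  grid <- expand.grid(surface = c("firm", "foam"),
                      stance = c("feet_apart", "feet_together",
                                 "partial_heel_toe", "heel_toe", "single_leg"),
                      vision = c("open", "closed"),
                      head = c("none", "pitch", "yaw"),
                      stringsAsFactors = FALSE)
  ids <- sprintf("ex%02d", seq_len(nrow(grid)))
  stats::setNames(split(grid, seq_len(nrow(grid))), ids)
}

#' Simulate a full labeled dataset
#'
#' Participant abilities and exercise difficulties are drawn uniformly on
#' [0, 1]; a repetition's severity is
#' `clamp(ability + difficulty - 0.5 + noise, 0, 1)`, so difficult exercises
#' performed by low-ability participants saturate at severity 1 (rating 5)
#' and easy ones at 0 (rating 1), concentrating labels at the scale ends as
#' observed in balance-exercise panels. Every repetition and rater panel uses
#' an independent sub-seed derived from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return a `sway_dataset` with
#'   `n_participants * n_exercises_per_participant * n_repetitions`
#'   repetitions; the latent severities are attached as attribute
#'   `"severities"` for parameter-recovery studies.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  catalogue <- exercise_catalogue()
  base <- with_seed(derive_seed(cfg$seed, "latents"), {
    ability <- stats::runif(cfg$n_participants)
    ex_ids <- lapply(seq_len(cfg$n_participants), function(i)
      sample(names(catalogue), cfg$n_exercises_per_participant,
             replace = cfg$n_exercises_per_participant > length(catalogue)))
    difficulty <- lapply(seq_len(cfg$n_participants), function(i)
      stats::runif(cfg$n_exercises_per_participant))
    list(ability = ability, ex_ids = ex_ids, difficulty = difficulty)
  })
  recs <- list(); rats <- list(); sev_out <- numeric()
  counter <- 0L
  for (p in seq_len(cfg$n_participants)) {
    pid <- sprintf("p%02d", p)
    for (e in seq_len(cfg$n_exercises_per_participant)) {
      for (r in seq_len(cfg$n_repetitions)) {
        counter <- counter + 1L
        rid <- sprintf("%s_e%02d_r%d", pid, e, r)
        sev <- with_seed(derive_seed(cfg$seed, "sev", counter), {
          min(max(base$ability[p] + base$difficulty[[p]][e] - 0.5 +
                    stats::rnorm(1, 0, cfg$severity_noise_sd), 0), 1)
        })
        recs[[rid]] <- simulate_repetition(
          sev, cfg, derive_seed(cfg$seed, "rep", counter),
          repetition_id = rid, participant_id = pid,
          exercise_id = base$ex_ids[[p]][e])
        rats[[rid]] <- simulate_raters(sev, cfg,
                                       derive_seed(cfg$seed, "rater", counter))
        sev_out[rid] <- sev
      }
    }
  }
  ds <- sway_dataset(recs, rats, catalogue)
  attr(ds, "severities") <- sev_out
  ds
}
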