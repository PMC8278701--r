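#' A single balance-exercise repetition recorded by a trunk-worn IMU
#'
#' Two channels of angular velocity (pitch = anterior-posterior lean, roll =
#' medial-lateral lean) sampled at a fixed rate, nominally 100 Hz for 30 s.
#' Angles are in degrees throughout the package (deg/s here), the conventional
#' unit for trunk-sway reporting.
#'
#' @param repetition_id,participant_id,exercise_id character identifiers.
#' @param sample_rate samples per second (> 0).
#' @param pitch_velocity,roll_velocity numeric vectors of equal length, deg/s.
#' @param step_out_count optional count of step-outs observed (metadata only).
#' @return an object of class `sway_recording`.
#' @export
sway_recording <- function(repetition_id, participant_id, exercise_id,
                           sample_rate, pitch_velocity, roll_velocity,
                           step_out_count = NA_integer_) {
  if (length(pitch_velocity) != length(roll_velocity))
    stop_domain("pitch and roll channels differ in length (%d vs %d)",
                length(pitch_velocity), length(roll_velocity))
  if (length(pitch_velocity) < 1) stop_domain("recording is empty")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0)
    stop_domain("sample_rate must be a single positive number")
  bad <- which(!is.finite(pitch_velocity) | !is.finite(roll_velocity))
  if (length(bad))
    stop_domain("non-finite sample at row %d of recording '%s'",
                bad[1], repetition_id)
  structure(list(
    repetition_id = as.character(repetition_id),
    participant_id = as.character(participant_id),
    exercise_id = as.character(exercise_id),
    sample_rate = as.numeric(sample_rate),
    pitch_velocity = as.numeric(pitch_velocity),
    roll_velocity = as.numeric(roll_velocity),
    duration = length(pitch_velocity) / sample_rate,
    step_out_count = as.integer(step_out_count)
  ), class = "sway_recording")
}

#' @export
print.sway_recording <- function(x, ...) {
  cat(sprintf("<sway_recording %s: participant %s, exercise %s, %d samples @ %g Hz (%.2f s)>\n",
              x$repetition_id, x$participant_id, x$exercise_id,
              length(x$pitch_velocity), x$sample_rate, x$duration))
  invisible(x)
}

#' The rating panel for one repetition
#'
#' One to eight physical therapists (PTs) each assign an ordinal score in
#' 1 (independent, limited sway) .. 5 (unable to maintain position even with
#' assistance); the participant may also self-rate on the same scale.
#'
#' @param pt_ratings named integer vector, values in 1..5, names are unique
#'   rater IDs. May be empty (a missing label, removed by [filter_valid()]).
#' @param self_rating integer in 1..5 or `NA`.
#' @return an object of class `rating_set`.
#' @export
rating_set <- function(pt_ratings = integer(), self_rating = NA_integer_) {
  pt_ratings <- stats::setNames(as.integer(pt_ratings), names(pt_ratings))
  if (length(pt_ratings)) {
    if (is.null(names(pt_ratings)) || anyDuplicated(names(pt_ratings)))
      stop_domain("pt_ratings must carry unique rater IDs as names")
    if (any(pt_ratings < 1L | pt_ratings > 5L))
      stop_domain("PT ratings must lie in 1..5")
  }
  if (!is.na(self_rating) && (self_rating < 1 || self_rating > 5))
    stop_domain("self_rating must lie in 1..5 or be NA")
  structure(list(pt_ratings = pt_ratings,
                 self_rating = as.integer(self_rating)),
            class = "rating_set")
}

#' Assemble a dataset of recordings and ratings
#'
#' @param recordings list of [sway_recording()] objects.
#' @param ratings named list of [rating_set()] keyed by repetition_id; every
#'   key must resolve to a recording.
#' @param exercise_metadata optional named list keyed by exercise_id, each
#'   entry a list with fields surface, stance, vision, head.
#' @return an object of class `sway_dataset`.
#' @export
sway_dataset <- function(recordings, ratings = list(), exercise_metadata = list()) {
  names(recordings) <- vapply(recordings, `[[`, "", "repetition_id")
  if (anyDuplicated(names(recordings)))
    stop_domain("duplicated repetition_id in recordings")
  orphan <- setdiff(names(ratings), names(recordings))
  if (length(orphan))
    stop_domain("rating for unknown repetition '%s'", orphan[1])
  structure(list(recordings = recordings, ratings = ratings,
                 exercise_metadata = exercise_metadata),
            class = "sway_dataset")
}

#' @export
print.sway_dataset <- function(x, ...) {
  cat(sprintf("<sway_dataset: %d repetitions, %d participants, %d rated>\n",
              length(x$recordings), length(dataset_participants(x)),
              length(x$ratings)))
  invisible(x)
}

#' Participant IDs present in a dataset
#' @param ds a `sway_dataset`.
#' @export
dataset_participants <- function(ds) {
  unique(vapply(ds$recordings, `[[`, "", "participant_id"))
}

#' Subset a dataset to a set of repetition IDs
#' @param ds a `sway_dataset`.
#' @param rep_ids character vector of repetition IDs to keep.
#' @export
dataset_subset <- function(ds, rep_ids) {
  rep_ids <- intersect(names(ds$recordings), rep_ids)
  sway_dataset(ds$recordings[rep_ids],
               ds$ratings[intersect(names(ds$ratings), rep_ids)],
               ds$exercise_metadata)
}

# ---- on-disk formats -------------------------------------------------------

fmt_full <- function(x) sprintf("%.17g", x)

#' Write one repetition's signal to a CSV file
#'
#' Columns: `time_s, pitch_velocity_dps, roll_velocity_dps`. Samples are
#' written with 17 significant digits so a load round-trips bit-exactly.
#'
#' @param rec a `sway_recording`.
#' @param path output file path.
#' @export
write_recording <- function(rec, path) {
  n <- length(rec$pitch_velocity)
  t <- (seq_len(n) - 1) / rec$sample_rate
  lines <- c("time_s,pitch_velocity_dps,roll_velocity_dps",
             paste(fmt_full(t), fmt_full(rec$pitch_velocity),
                   fmt_full(rec$roll_velocity), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Load one repetition's signal from a CSV file
#'
#' The sample rate is inferred from the time column; a non-uniform time grid
#' (beyond a 1e-6 s tolerance) or a non-finite sample is a format error naming
#' the offending data row.
#'
#' @param path signal CSV with header `time_s,pitch_velocity_dps,roll_velocity_dps`.
#' @param repetition_id,participant_id,exercise_id identifiers to attach
#'   (usually from the manifest).
#' @param step_out_count optional metadata.
#' @return a validated [sway_recording()].
#' @export
load_recording <- function(path, repetition_id = basename(path),
                           participant_id = NA_character_,
                           exercise_id = NA_character_,
                           step_out_count = NA_integer_) {
  df <- utils::read.csv(path, colClasses = "numeric")
  need <- c("time_s", "pitch_velocity_dps", "roll_velocity_dps")
  if (!all(need %in% names(df)))
    stop_domain("signal file '%s' lacks required columns (%s)", path,
                paste(setdiff(need, names(df)), collapse = ", "))
  if (nrow(df) < 2) stop_domain("signal file '%s' has fewer than 2 rows", path)
  bad <- which(!stats::complete.cases(df) |
                 !is.finite(df$pitch_velocity_dps) |
                 !is.finite(df$roll_velocity_dps) | !is.finite(df$time_s))
  if (length(bad))
    stop_domain("non-finite value at data row %d of '%s'", bad[1], path)
  dt <- diff(df$time_s)
  if (any(dt <= 0))
    stop_domain("non-increasing time step at data row %d of '%s'",
                which(dt <= 0)[1] + 1L, path)
  step <- stats::median(dt)
  off <- which(abs(dt - step) > 1e-6)
  if (length(off))
    stop_domain("non-uniform time step at data row %d of '%s'", off[1] + 1L, path)
  sway_recording(repetition_id, participant_id, exercise_id,
                 sample_rate = 1 / step,
                 pitch_velocity = df$pitch_velocity_dps,
                 roll_velocity = df$roll_velocity_dps,
                 step_out_count = step_out_count)
}

#' Write a dataset (manifest, signals, exercise metadata) to a directory
#'
#' Manifest columns: repetition_id, participant_id, exercise_id, signal_path,
#' pt_rating_1..pt_rating_8 (blank when that rater did not rate), self_rating,
#' step_out_count. Exercise metadata is stored as `exercises.json`.
#'
#' @param ds a `sway_dataset`.
#' @param dir output directory (created if missing).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(file.path(dir, "signals"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(ds$recordings, function(rec) {
    rel <- file.path("signals", paste0(rec$repetition_id, ".csv"))
    write_recording(rec, file.path(dir, rel))
    rs <- ds$ratings[[rec$repetition_id]]
    pt <- rep(NA_integer_, 8)
    if (!is.null(rs) && length(rs$pt_ratings)) {
      idx <- as.integer(sub("^pt", "", names(rs$pt_ratings)))
      pt[idx] <- rs$pt_ratings
    }
    c(list(repetition_id = rec$repetition_id,
           participant_id = rec$participant_id,
           exercise_id = rec$exercise_id,
           signal_path = rel),
      stats::setNames(as.list(pt), paste0("pt_rating_", 1:8)),
      list(self_rating = if (is.null(rs)) NA_integer_ else rs$self_rating,
           step_out_count = rec$step_out_count))
  })
  manifest <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE,
                   na = "")
  jsonlite::write_json(ds$exercise_metadata,
                       file.path(dir, "exercises.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' Load a dataset written by [write_dataset()]
#' @param dir dataset directory containing `manifest.csv`.
#' @return a `sway_dataset`.
#' @export
load_dataset <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              colClasses = c(repetition_id = "character",
                                             participant_id = "character",
                                             exercise_id = "character"))
  recs <- vector("list", nrow(manifest))
  rats <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    recs[[i]] <- load_recording(file.path(dir, m$signal_path),
                                repetition_id = m$repetition_id,
                                participant_id = m$participant_id,
                                exercise_id = m$exercise_id,
                                step_out_count = m$step_out_count)
    pt <- unlist(m[paste0("pt_rating_", 1:8)])
    keep <- !is.na(pt)
    if (any(keep) || !is.na(m$self_rating)) {
      rats[[m$repetition_id]] <- rating_set(
        stats::setNames(as.integer(pt[keep]), paste0("pt", which(keep))),
        self_rating = m$self_rating)
    }
  }
  meta_path <- file.path(dir, "exercises.json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  sway_dataset(recs, rats, meta)
}

# ---- validity filtering and splitting --------------------------------------

#' Drop unlabeled and prematurely terminated repetitions
#'
#' A repetition is excluded when it has no PT rating ("missing label") or when
#' it is shorter than the nominal duration minus one sample period
#' ("premature" termination of the recording).
#'
#' @param ds a `sway_dataset`.
#' @param nominal_duration nominal repetition length in seconds (default 30).
#' @return list with elements `dataset` (the retained repetitions) and
#'   `report` (named counts `missing_label` and `premature`).
#' @export
filter_valid <- function(ds, nominal_duration = 30) {
  ids <- names(ds$recordings)
  missing_label <- vapply(ids, function(id) {
    rs <- ds$ratings[[id]]
    is.null(rs) || length(rs$pt_ratings) == 0
  }, TRUE)
  premature <- vapply(ids, function(id) {
    rec <- ds$recordings[[id]]
    length(rec$pitch_velocity) < round(nominal_duration * rec$sample_rate) - 1
  }, TRUE)
  keep <- ids[!missing_label & !premature]
  list(dataset = dataset_subset(ds, keep),
       report = c(missing_label = sum(missing_label),
                  premature = sum(premature & !missing_label)))
}

#' Split a dataset by participant
#'
#' Every repetition of a participant lands in exactly one of train,
#' validation, test — the leakage-free protocol for within-person data.
#'
#' @param ds a `sway_dataset`.
#' @param assignment named character vector mapping each participant ID to one
#'   of `"train"`, `"validation"`, `"test"`.
#' @return list of three disjoint `sway_dataset`s named train/validation/test.
#' @export
split_by_participant <- function(ds, assignment) {
  parts <- c("train", "validation", "test")
  if (!all(assignment %in% parts))
    stop_domain("assignment values must be one of %s", paste(parts, collapse = "/"))
  pids <- dataset_participants(ds)
  unassigned <- setdiff(pids, names(assignment))
  if (length(unassigned))
    stop_domain("participant '%s' has no split assignment", unassigned[1])
  rec_part <- vapply(ds$recordings,
                     function(r) unname(assignment[r$participant_id]), "")
  stats::setNames(lapply(parts, function(p) {
    dataset_subset(ds, names(ds$recordings)[rec_part == p])
  }), parts)
}

#' The participant split used in the original evaluation protocol
#'
#' Participants 1-6 train, 7-8 validation, 9-10 test.
#'
#' @param participant_ids character vector in enrollment order.
#' @return named assignment vector for [split_by_participant()].
#' @export
default_assignment <- function(participant_ids) {
  n <- length(participant_ids)
  idx <- seq_len(n)
  part <- ifelse(idx <= ceiling(0.6 * n), "train",
                 ifelse(idx <= ceiling(0.8 * n), "validation", "test"))
  stats::setNames(part, participant_ids)
}
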