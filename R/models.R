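#' Specification of one classifier family
#'
#' @param family `"random_forest"` (11 sway features), `"cnn_1d"`
#'   (time-series input) or `"cnn_2d"` (60x60 trajectory-image input).
#' @param n_filters convolution filters per depth-wise group (default 8).
#' @param fc_hidden first fully-connected width (default 64 — the smallest
#'   round width that overfits the capacity fixture).
#' @param dropout dropout probability (default 0.5).
#' @param n_trees forest size (default 1000, the grid-search selection of the
#'   original protocol; see [tune_rf()]).
#' @param channel_mode time-series channel configuration (see
#'   [channel_config()]); the depth-wise default carries angle + velocity.
#' @param bounds_policy raster-bounds policy for images (see [fit_bounds()]).
#' @param n_copies rotation-augmentation copies per training image (default 3).
#' @param npix image side (default 60).
#' @param nominal_duration nominal repetition length in seconds fixing the
#'   time-series input length `T = nominal_duration * sample_rate`
#'   (default 30).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(family = c("random_forest", "cnn_1d", "cnn_2d"),
                       n_filters = 8L, fc_hidden = 64L, dropout = 0.5,
                       n_trees = 1000L,
                       channel_mode = "angle_velocity",
                       bounds_policy = "max_abs", n_copies = 3L, npix = 60L,
                       nominal_duration = 30) {
  family <- match.arg(family)
  structure(as.list(environment()), class = "model_spec")
}

#' Training configuration (Adam on cross-entropy)
#'
#' Defaults follow the original protocol: learning rate 1e-4, batch size 32,
#' a fixed budget of 2000 epochs with the best-validation-epoch snapshot
#' returned, and weight decay tuned on validation macro-AUROC over
#' `weight_decay_grid` when that grid has more than one entry.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size minibatch size.
#' @param max_epochs epoch budget.
#' @param weight_decay_grid candidate L2 coefficients (default
#'   `c(0, 1e-4, 1e-3, 1e-2)`); a single value skips tuning.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @export
training_config <- function(learning_rate = 1e-4, batch_size = 32L,
                            max_epochs = 2000L,
                            weight_decay_grid = c(0, 1e-4, 1e-3, 1e-2),
                            seed = 1L) {
  if (learning_rate <= 0 || batch_size < 1 || max_epochs < 1)
    stop_domain("rates and sizes must be positive")
  structure(as.list(environment()), class = "training_config")
}

labels_of <- function(ds) mode_labels(ds)

ts_array <- function(recs, standardizer, length_out) {
  n <- length(recs)
  C <- length(standardizer$config$channels)
  X <- array(0, c(C, length_out, 1L, n))
  for (i in seq_len(n))
    X[, , 1L, i] <- to_timeseries(recs[[i]], standardizer, length_out)
  X
}

image_array <- function(images) {
  n <- length(images)
  npix <- nrow(images[[1]]$angle)
  X <- array(0, c(2L, npix, npix, n))
  for (i in seq_len(n)) {
    X[1L, , , i] <- images[[i]]$angle
    X[2L, , , i] <- images[[i]]$velocity
  }
  X
}

#' Train one classifier on a participant-disjoint train/validation split
#'
#' All fitted preprocessing state (channel standardization, raster bounds)
#' derives from the training split only; rotation augmentation is applied to
#' training images only. CNNs optimize cross-entropy with Adam and return the
#' best-validation-macro-AUROC epoch snapshot; when `weight_decay_grid` has
#' several entries, each is trained and the best validation metric wins. The
#' random forest is fitted single-shot with `spec$n_trees` trees (tree-count
#' selection lives in [tune_rf()]).
#'
#' @param spec a [model_spec()].
#' @param train_ds,val_ds labeled, participant-disjoint `sway_dataset`s.
#' @param cfg a [training_config()].
#' @return object of class `sway_model` holding the spec, fitted parameters,
#'   fitted preprocessing state, and the training log.
#' @export
train_balance_model <- function(spec, train_ds, val_ds, cfg = training_config()) {
  if (!length(train_ds$recordings)) stop_domain("empty training set")
  y_train <- labels_of(train_ds)
  y_val <- labels_of(val_ds)
  model <- list(spec = spec, family = spec$family)

  if (spec$family == "random_forest") {
    ftr <- featurize_dataset(train_ds)
    Xtr <- as.matrix(ftr[, feature_names()])
    model$forest <- rf_fit(Xtr, y_train, n_trees = spec$n_trees,
                           seed = cfg$seed)
    model$log <- NULL
  } else {
    train_recs <- train_ds$recordings
    val_recs <- val_ds$recordings
    wd_grid <- cfg$weight_decay_grid
    if (spec$family == "cnn_1d") {
      config <- channel_config(spec$channel_mode)
      std <- fit_standardizer(train_recs, config)
      len <- round(spec$nominal_duration * train_recs[[1]]$sample_rate)
      Xtr <- ts_array(train_recs, std, len)
      Xval <- ts_array(val_recs, std, len)
      ytr <- y_train
      model$standardizer <- std
      model$length_out <- len
      build <- function(seed) nn_build(
        c(length(config$channels), len, 1L), config$groups,
        kernel = c(3L, 1L), pool = c(2L, 1L), n_filters = spec$n_filters,
        fc_hidden = spec$fc_hidden, dropout = spec$dropout, seed = seed)
    } else {
      ang_tr <- lapply(train_recs, integrate_angle)
      vel_tr <- lapply(train_recs, velocity_trajectory)
      ab <- fit_bounds(ang_tr, spec$bounds_policy)
      vb <- fit_bounds(vel_tr, spec$bounds_policy)
      imgs <- lapply(train_recs, make_image_input, angle_bounds = ab,
                     velocity_bounds = vb, npix = spec$npix)
      ytr <- y_train
      if (spec$n_copies > 0) {
        for (i in seq_along(train_recs)) {
          aug <- augment_rotations(train_recs[[i]], ab, vb,
                                   n_copies = spec$n_copies,
                                   seed = derive_seed(cfg$seed, "aug", i),
                                   npix = spec$npix)
          imgs <- c(imgs, aug)
          ytr <- c(ytr, rep(y_train[i], spec$n_copies))
        }
      }
      Xtr <- image_array(imgs)
      Xval <- image_array(lapply(val_recs, make_image_input, angle_bounds = ab,
                                 velocity_bounds = vb, npix = spec$npix))
      model$bounds <- list(angle = ab, velocity = vb)
      build <- function(seed) nn_build(
        c(2L, spec$npix, spec$npix), list(angle = 1L, velocity = 2L),
        kernel = c(3L, 3L), pool = c(2L, 2L), n_filters = spec$n_filters,
        fc_hidden = spec$fc_hidden, dropout = spec$dropout, seed = seed)
    }
    fits <- lapply(wd_grid, function(wd) {
      nn_train(build(derive_seed(cfg$seed, "init")), Xtr, ytr, Xval, y_val,
               learning_rate = cfg$learning_rate, batch_size = cfg$batch_size,
               max_epochs = cfg$max_epochs, weight_decay = wd,
               seed = derive_seed(cfg$seed, "sgd"))
    })
    best <- which.max(vapply(fits, function(f) max(f$log$val_metric), 0))
    model$net <- fits[[best]]
    model$weight_decay <- wd_grid[best]
    model$log <- fits[[best]]$log
  }
  model$cfg <- cfg
  structure(model, class = "sway_model")
}

#' Class scores for every repetition of a dataset
#'
#' Deterministic: dropout disabled, batch norm in inference mode.
#'
#' @param model a trained `sway_model`.
#' @param ds a `sway_dataset` whose recordings match the model's
#'   representation.
#' @return matrix `n x 5` of class probabilities (rows sum to 1), rownames =
#'   repetition IDs.
#' @export
predict_balance <- function(model, ds) {
  recs <- ds$recordings
  scores <- switch(model$family,
    random_forest = {
      ftr <- featurize_dataset(ds)
      rf_predict(model$forest, as.matrix(ftr[, feature_names()]))
    },
    cnn_1d = nn_predict(model$net,
                        ts_array(recs, model$standardizer, model$length_out)),
    cnn_2d = nn_predict(model$net, image_array(
      lapply(recs, make_image_input, angle_bounds = model$bounds$angle,
             velocity_bounds = model$bounds$velocity,
             npix = model$spec$npix))),
    stop_domain("unknown model family '%s'", model$family))
  rownames(scores) <- names(recs)
  colnames(scores) <- 1:5
  scores
}

#' Serialize a trained model to a directory
#'
#' Parameters, preprocessing state and training log round-trip bit-exactly
#' (predictions after [load_model()] equal predictions before saving).
#'
#' @param model a `sway_model`.
#' @param dir output directory (created if missing).
#' @export
save_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(dir, "model.rds"))
  jsonlite::write_json(list(family = model$family,
                            spec = model$spec[names(model$spec) != "family"],
                            cfg = unclass(model$cfg)),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  if (!is.null(model$log))
    utils::write.csv(model$log, file.path(dir, "training_log.csv"),
                     row.names = FALSE)
  invisible(dir)
}

#' Load a model saved by [save_model()]
#' @param dir model directory.
#' @export
load_model <- function(dir) readRDS(file.path(dir, "model.rds"))
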