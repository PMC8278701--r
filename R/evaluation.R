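#' Summarize a PT rating panel into the ground-truth mode label
#'
#' The most frequent rating in the panel. Ties are broken toward the rating
#' closest to the panel mean; a remaining tie goes to the higher (more severe)
#' rating — the conservative choice for balance training, where overestimating
#' difficulty is safer than underestimating it.
#'
#' @param rs a [rating_set()] with at least one PT rating.
#' @return integer label in 1..5.
#' @export
mode_label <- function(rs) {
  r <- rs$pt_ratings
  if (!length(r)) stop_domain("missing label: empty PT panel")
  tab <- tabulate(r, 5L)
  cand <- which(tab == max(tab))
  if (length(cand) > 1) {
    d <- abs(cand - mean(r))
    cand <- cand[d == min(d)]
  }
  max(cand)
}

mode_labels <- function(ds) {
  vapply(ds$ratings[names(ds$recordings)], mode_label, 0L)
}

#' Classification accuracy
#' @param predictions,truth equal-length label vectors.
#' @return fraction of exact matches.
#' @export
accuracy <- function(predictions, truth) {
  if (length(predictions) != length(truth) || !length(truth))
    stop_domain("predictions and truth must be non-empty and equal length")
  mean(predictions == truth)
}

auroc_binary <- function(score, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged one-vs-rest AUROC
#'
#' The unweighted mean of per-class AUROC values (rank-based; score ties
#' contribute 0.5), computed over the classes present in the truth — classes
#' absent from the truth are excluded from the average, which changes the
#' class weighting on small test sets and is therefore documented behavior.
#'
#' @param scores matrix `n x 5` of class scores (columns = labels 1..5).
#' @param truth integer labels 1..5 with at least two distinct values.
#' @return macro AUROC in [0, 1].
#' @export
macro_auroc <- function(scores, truth) {
  scores <- as.matrix(scores)
  if (nrow(scores) != length(truth)) stop_domain("scores/truth length mismatch")
  classes <- sort(unique(truth))
  if (length(classes) < 2)
    stop_domain("macro AUROC undefined: single-class truth")
  mean(vapply(classes, function(cl)
    auroc_binary(scores[, cl], truth == cl), 0))
}

#' Confusion matrix and per-class recall
#'
#' @param predictions,truth equal-length integer label vectors in 1..5.
#' @return list with `confusion` (5x5 count matrix, rows = truth) and
#'   `per_class_accuracy` (recall per label; `NA` for labels absent from the
#'   truth, whose confusion rows are all zero).
#' @export
confusion_and_per_class <- function(predictions, truth) {
  if (length(predictions) != length(truth)) stop_domain("length mismatch")
  if (any(!predictions %in% 1:5) || any(!truth %in% 1:5))
    stop_domain("labels must lie in 1..5")
  cm <- matrix(0L, 5, 5, dimnames = list(truth = 1:5, predicted = 1:5))
  for (i in seq_along(truth))
    cm[truth[i], predictions[i]] <- cm[truth[i], predictions[i]] + 1L
  rs <- rowSums(cm)
  recall <- ifelse(rs > 0, diag(cm) / rs, NA_real_)
  list(confusion = cm, per_class_accuracy = stats::setNames(recall, 1:5))
}

one_hot_scores <- function(labels, n_classes = 5L) {
  m <- matrix(0, length(labels), n_classes)
  m[cbind(seq_along(labels), labels)] <- 1
  m
}

#' Random-PT baseline: accuracy/AUROC of a randomly selected rater
#'
#' Per resample, one PT rating is drawn uniformly per repetition and treated
#' as a hard prediction (one-hot scores for AUROC) against the mode labels.
#' This estimates the agreement an "average PT" achieves with the panel
#' consensus — the practical upper bound for a model trained on mode labels.
#'
#' @param ratings named list of [rating_set()], each with >= 1 PT rating.
#' @param truth integer mode labels, same order as `ratings`.
#' @param n_resamples number of resampling repeats (default 1000).
#' @param seed integer seed.
#' @return list with mean/sd of accuracy and macro AUROC across resamples.
#' @export
random_rater_baseline <- function(ratings, truth, n_resamples = 1000L,
                                  seed = 1L) {
  acc <- numeric(n_resamples); auc <- numeric(n_resamples)
  with_seed(seed, {
    for (k in seq_len(n_resamples)) {
      pred <- vapply(ratings, function(rs) {
        r <- rs$pt_ratings
        r[sample.int(length(r), 1)]
      }, 0L)
      acc[k] <- accuracy(pred, truth)
      auc[k] <- macro_auroc(one_hot_scores(pred), truth)
    }
  })
  list(accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
       auroc_mean = mean(auc), auroc_sd = stats::sd(auc))
}

#' Krippendorff's alpha for a repetition-by-rater matrix
#'
#' Chance-corrected agreement supporting any number of raters and missing
#' entries, computed from the coincidence matrix:
#' `alpha = 1 - D_observed / D_expected`. The nominal difference function is
#' the default (the conventional choice for this coefficient); the ordinal
#' difference function of the same framework is available for the 1-5 scale.
#'
#' @param mat numeric matrix, rows = repetitions (units), columns = raters,
#'   `NA` for missing ratings. Units with fewer than 2 ratings are ignored.
#' @param metric `"nominal"` or `"ordinal"`.
#' @return alpha (<= 1).
#' @export
krippendorff_alpha <- function(mat, metric = c("nominal", "ordinal")) {
  metric <- match.arg(metric)
  mat <- as.matrix(mat)
  vals <- sort(unique(stats::na.omit(as.vector(mat))))
  k <- length(vals)
  co <- matrix(0, k, k)
  for (u in seq_len(nrow(mat))) {
    obs <- match(stats::na.omit(mat[u, ]), vals)
    m <- length(obs)
    if (m < 2) next
    for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
      co[obs[i], obs[j]] <- co[obs[i], obs[j]] + 1 / (m - 1)
  }
  n_tot <- sum(co)
  if (n_tot <= 1 || k < 1)
    stop_domain("insufficient pairable values for Krippendorff's alpha")
  nc <- rowSums(co)
  if (metric == "nominal") {
    delta <- 1 - diag(k)
  } else {
    delta <- matrix(0, k, k)
    for (a in seq_len(k)) for (b in seq_len(k)) if (a != b) {
      lo <- min(a, b); hi <- max(a, b)
      delta[a, b] <- (sum(nc[lo:hi]) - (nc[a] + nc[b]) / 2)^2
    }
  }
  d_obs <- sum(co * delta) / n_tot
  d_exp <- sum(outer(nc, nc) * delta) / (n_tot * (n_tot - 1))
  if (d_exp == 0) return(1)
  1 - d_obs / d_exp
}

#' Rating matrix (repetitions x raters) of a dataset
#' @param ds a `sway_dataset`.
#' @param rater_pool rater IDs defining the columns (default pt1..pt8).
#' @export
rating_matrix <- function(ds, rater_pool = paste0("pt", 1:8)) {
  m <- matrix(NA_real_, length(ds$ratings), length(rater_pool),
              dimnames = list(names(ds$ratings), rater_pool))
  for (id in names(ds$ratings)) {
    r <- ds$ratings[[id]]$pt_ratings
    m[id, names(r)] <- r
  }
  m
}

#' Paired comparison of two models' per-run metric values
#'
#' Two-sided paired t-test across runs matched by seed (the models are
#' evaluated on the same test examples, so runs are related). Degenerate
#' difference vectors are resolved analytically: identical per-run values
#' give a zero statistic (not significant); a constant nonzero difference is
#' the t -> infinity limit (significant).
#'
#' @param a,b equal-length numeric vectors of per-run metric values.
#' @param alpha significance level (default 0.05).
#' @return list with `statistic`, `p_value`, `significant`, `mean_diff`.
#' @export
compare_models <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop_domain("unequal run counts")
  d <- a - b
  if (stats::sd(d) == 0 || length(d) < 2) {
    if (mean(d) == 0)
      return(list(statistic = 0, p_value = 1, significant = FALSE,
                  mean_diff = 0, alpha = alpha))
    return(list(statistic = sign(mean(d)) * Inf, p_value = 0,
                significant = TRUE, mean_diff = mean(d), alpha = alpha))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value < alpha, mean_diff = mean(d), alpha = alpha)
}

#' Train/evaluate every representation across repeated restarts
#'
#' For each model family, trains `n_seeds` models with different random
#' initializations on the training split, evaluates accuracy and macro AUROC
#' on the fixed test split, and reports mean and SD per family alongside two
#' baselines: the majority classifier (constant prediction of the training
#' mode label — the leak-free variant) and the participants' self-assessments.
#' Pairwise paired t-tests (per-run values matched by seed) against the
#' majority classifier and between families are included.
#'
#' @param ds a labeled `sway_dataset` (already validity-filtered).
#' @param assignment participant split assignment (see
#'   [split_by_participant()]); default [default_assignment()].
#' @param families model families to run (default all three).
#' @param n_seeds number of restarts (30 in the original protocol).
#' @param training a [training_config()].
#' @param spec_overrides named list of [model_spec()] arguments per family.
#' @param base_seed master seed; each restart derives its own sub-seed.
#' @return list with `table` (one row per method: accuracy/AUROC mean and sd),
#'   `per_run` (per-family metric vectors), `comparisons`, `confusion`
#'   (per family, summed over runs), and the split sizes.
#' @export
run_experiment <- function(ds,
                           assignment = default_assignment(dataset_participants(ds)),
                           families = c("random_forest", "cnn_1d", "cnn_2d"),
                           n_seeds = 30L,
                           training = training_config(),
                           spec_overrides = list(),
                           base_seed = 1L) {
  split <- split_by_participant(ds, assignment)
  y_test <- mode_labels(split$test)
  y_train <- mode_labels(split$train)
  test_ids <- names(split$test$recordings)

  results <- list(); per_run <- list(); confusions <- list()
  add_row <- function(name, acc, auc) {
    results[[name]] <<- data.frame(
      representation = name,
      accuracy_mean = mean(acc),
      accuracy_sd = if (length(acc) > 1) stats::sd(acc) else 0,
      auroc_mean = mean(auc),
      auroc_sd = if (length(auc) > 1) stats::sd(auc) else 0,
      n_runs = length(acc))
    per_run[[name]] <<- list(accuracy = acc, auroc = auc)
  }

  # majority classifier: constant training-mode prediction, identical scores
  maj_label <- mode_label(rating_set(stats::setNames(y_train,
                                                     paste0("pt", seq_along(y_train)))))
  maj_scores <- matrix(1 / 5, length(y_test), 5)
  add_row("majority", accuracy(rep(maj_label, length(y_test)), y_test),
          macro_auroc(maj_scores, y_test))

  self <- vapply(split$test$ratings[test_ids], `[[`, 0L, "self_rating")
  if (!anyNA(self))
    add_row("self_assessment", accuracy(self, y_test),
            macro_auroc(one_hot_scores(self), y_test))

  family_label <- c(random_forest = "features", cnn_1d = "timeseries",
                    cnn_2d = "image")
  for (fam in families) {
    accs <- numeric(n_seeds); aucs <- numeric(n_seeds)
    cm <- matrix(0L, 5, 5)
    for (s in seq_len(n_seeds)) {
      spec <- do.call(model_spec,
                      c(list(family = fam), spec_overrides[[fam]]))
      cfg <- training
      cfg$seed <- derive_seed(base_seed, fam, s)
      model <- train_balance_model(spec, split$train, split$validation, cfg)
      scores <- predict_balance(model, split$test)
      pred <- max.col(scores, ties.method = "first")
      accs[s] <- accuracy(pred, y_test)
      aucs[s] <- macro_auroc(scores, y_test)
      cm <- cm + confusion_and_per_class(pred, y_test)$confusion
    }
    add_row(family_label[[fam]], accs, aucs)
    confusions[[family_label[[fam]]]] <- cm
  }

  expand_runs <- function(v, n) if (length(v) == 1) rep(v, n) else v
  comparisons <- list()
  methods <- names(per_run)
  ml <- intersect(unname(family_label[families]), methods)
  for (m in ml) {
    for (base in intersect(c("majority", "self_assessment"), methods)) {
      n <- length(per_run[[m]]$auroc)
      comparisons[[paste(m, "vs", base)]] <- list(
        auroc = compare_models(per_run[[m]]$auroc,
                               expand_runs(per_run[[base]]$auroc, n)),
        accuracy = compare_models(per_run[[m]]$accuracy,
                                  expand_runs(per_run[[base]]$accuracy, n)))
    }
  }
  if (length(ml) > 1) {
    for (i in seq_len(length(ml) - 1)) for (j in (i + 1):length(ml)) {
      comparisons[[paste(ml[i], "vs", ml[j])]] <- list(
        auroc = compare_models(per_run[[ml[i]]]$auroc, per_run[[ml[j]]]$auroc),
        accuracy = compare_models(per_run[[ml[i]]]$accuracy,
                                  per_run[[ml[j]]]$accuracy))
    }
  }
  table <- do.call(rbind, results)
  rownames(table) <- NULL
  list(table = table, per_run = per_run, comparisons = comparisons,
       confusion = confusions,
       split_sizes = vapply(split, function(d) length(d$recordings), 0L))
}
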