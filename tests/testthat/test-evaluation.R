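rs_of <- function(...) {
  v <- c(...)
  rating_set(setNames(as.integer(v), paste0("pt", seq_along(v))))
}

test_that("mode_label applies the majority / closest-to-mean / severity tie rules", {
  expect_equal(mode_label(rs_of(2, 2, 5)), 2L)
  expect_equal(mode_label(rs_of(4)), 4L)
  # tie between 1 and 5, both equidistant from mean 3 -> higher wins
  expect_equal(mode_label(rs_of(1, 1, 5, 5)), 5L)
  # tie between 1 and 2, mean 2.2 -> 2 is closer
  expect_equal(mode_label(rs_of(1, 1, 2, 2, 5)), 2L)
  # tie between 2 and 3, mean 2.5 equidistant -> 3
  expect_equal(mode_label(rs_of(2, 2, 3, 3)), 3L)
  expect_error(mode_label(rating_set()), "missing label")
})

test_that("accuracy matches a brute-force count", {
  expect_equal(accuracy(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(accuracy(c(1, 2), c(2, 1)), 0.0)
  set.seed(21)
  a <- sample(1:5, 100, TRUE); b <- sample(1:5, 100, TRUE)
  expect_equal(accuracy(a, b), sum(a == b) / 100)
  expect_error(accuracy(1:3, 1:4), "length")
})

test_that("macro AUROC matches the all-pairs concordance oracle", {
  brute_macro_auroc <- function(scores, truth) {
    classes <- sort(unique(truth))
    mean(vapply(classes, function(cl) {
      pos <- which(truth == cl); neg <- which(truth != cl)
      s <- 0
      for (i in pos) for (j in neg) {
        s <- s + (scores[i, cl] > scores[j, cl]) +
          0.5 * (scores[i, cl] == scores[j, cl])
      }
      s / (length(pos) * length(neg))
    }, 0))
  }
  set.seed(22)
  for (k in 1:5) {
    n <- 25
    truth <- sample(1:3, n, TRUE)
    scores <- matrix(runif(n * 5), n, 5)
    scores[sample(n, 5), 2] <- 0.5   # inject score ties
    expect_equal(macro_auroc(scores, truth), brute_macro_auroc(scores, truth),
                 tolerance = 1e-12)
  }
  # identical scores for every example: 0.5 (the majority-classifier value)
  expect_equal(macro_auroc(matrix(0.2, 10, 5), rep(c(1, 2), 5)), 0.5)
  # perfect separation on a 2-class set
  truth <- c(1, 1, 4, 4)
  sc <- matrix(0, 4, 5); sc[1:2, 1] <- 1; sc[3:4, 4] <- 1
  expect_equal(macro_auroc(sc, truth), 1.0)
  expect_error(macro_auroc(matrix(0.2, 4, 5), rep(3, 4)), "single-class")
})

test_that("macro AUROC is invariant under per-class monotone score transforms", {
  set.seed(23)
  n <- 40
  truth <- sample(1:5, n, TRUE)
  scores <- matrix(runif(n * 5), n, 5)
  base <- macro_auroc(scores, truth)
  warped <- scores
  warped[, 1] <- exp(3 * warped[, 1])
  warped[, 3] <- warped[, 3]^5
  warped[, 5] <- log(warped[, 5] + 1)
  expect_equal(macro_auroc(warped, truth), base, tolerance = 1e-12)
  expect_true(base >= 0 && base <= 1)
})

test_that("confusion matrix and per-class recall match brute force", {
  pred <- c(1, 2, 2, 5, 5, 3)
  truth <- c(1, 2, 3, 5, 2, 3)
  out <- confusion_and_per_class(pred, truth)
  expect_equal(sum(out$confusion), length(truth))
  for (cl in 1:5) {
    idx <- truth == cl
    if (any(idx))
      expect_equal(unname(out$per_class_accuracy[cl]),
                   mean(pred[idx] == cl))
    else {
      expect_true(is.na(out$per_class_accuracy[cl]))
      expect_true(all(out$confusion[cl, ] == 0))
    }
  }
  perfect <- confusion_and_per_class(truth, truth)
  expect_true(all(perfect$confusion[upper.tri(perfect$confusion)] == 0))
  expect_true(all(perfect$confusion[lower.tri(perfect$confusion)] == 0))
  expect_error(confusion_and_per_class(c(0, 1), c(1, 1)), "1..5")
})

test_that("random rater baseline reproduces degenerate and enumerable panels", {
  unanimous <- list(a = rs_of(2, 2, 2), b = rs_of(4, 4), c = rs_of(1, 1, 1))
  truth <- c(2L, 4L, 1L)
  out <- random_rater_baseline(unanimous, truth, n_resamples = 50, seed = 24)
  expect_equal(out$accuracy_mean, 1.0)
  expect_equal(out$accuracy_sd, 0.0)
  expect_equal(out$auroc_mean, 1.0)
  expect_equal(out$auroc_sd, 0.0)

  single <- list(a = rs_of(3), b = rs_of(5), c = rs_of(3))
  out1 <- random_rater_baseline(single, c(3L, 5L, 3L), n_resamples = 20,
                                seed = 25)
  expect_equal(out1$accuracy_sd, 0.0)

  # enumeration oracle for the expected accuracy with disagreeing two-rater
  # panels: each panel matches its mode with probability (#matching)/2
  panels <- list(a = rs_of(1, 2), b = rs_of(2, 2), c = rs_of(5, 4),
                 d = rs_of(5, 5))
  tr <- vapply(panels, mode_label, 0L)
  exact <- mean(vapply(panels, function(rs)
    mean(rs$pt_ratings == mode_label(rs)), 0))
  mc <- random_rater_baseline(panels, tr, n_resamples = 4000, seed = 26)
  expect_lt(abs(mc$accuracy_mean - exact), 0.02)
})

test_that("Krippendorff's alpha matches an independent pair-enumeration oracle", {
  brute_alpha <- function(mat, metric = "nominal") {
    vals <- sort(unique(na.omit(as.vector(mat))))
    pairs <- NULL
    for (u in seq_len(nrow(mat))) {
      obs <- na.omit(mat[u, ]); m <- length(obs)
      if (m < 2) next
      for (i in seq_len(m)) for (j in seq_len(m)) if (i != j)
        pairs <- rbind(pairs, c(obs[i], obs[j], 1 / (m - 1)))
    }
    n_ck <- vapply(vals, function(v) sum(pairs[, 3][pairs[, 1] == v]), 0)
    n_tot <- sum(pairs[, 3])
    dfun <- function(a, b) {
      if (metric == "nominal") return(as.numeric(a != b))
      ia <- match(a, vals); ib <- match(b, vals)
      lo <- min(ia, ib); hi <- max(ia, ib)
      (sum(n_ck[lo:hi]) - (n_ck[ia] + n_ck[ib]) / 2)^2
    }
    d_o <- sum(apply(pairs, 1, function(p) p[3] * dfun(p[1], p[2]))) / n_tot
    d_e <- 0
    for (a in vals) for (b in vals)
      d_e <- d_e + n_ck[match(a, vals)] * n_ck[match(b, vals)] * dfun(a, b)
    d_e <- d_e / (n_tot * (n_tot - 1))
    1 - d_o / d_e
  }
  set.seed(27)
  mat <- matrix(sample(c(1:5, NA), 12 * 6, TRUE, prob = c(rep(0.15, 5), 0.25)),
                12, 6)
  mat[1, ] <- c(1, 1, NA, NA, NA, NA)  # ensure at least one pairable unit
  expect_equal(krippendorff_alpha(mat, "nominal"), brute_alpha(mat, "nominal"),
               tolerance = 1e-10)
  expect_equal(krippendorff_alpha(mat, "ordinal"), brute_alpha(mat, "ordinal"),
               tolerance = 1e-10)

  perfect <- matrix(rep(c(1, 3, 5, 2), each = 4), 4, 4, byrow = TRUE)
  expect_equal(krippendorff_alpha(perfect), 1.0)

  lonely <- matrix(c(1, NA, NA, 2, NA, NA), 2, 3)
  expect_error(krippendorff_alpha(lonely), "insufficient")
})

test_that("paired comparisons match the closed-form t-test", {
  same <- compare_models(rep(0.8, 10), rep(0.8, 10))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)

  set.seed(28)
  b <- runif(10, 0.5, 0.6)
  shifted <- compare_models(b + 0.1 + rnorm(10, sd = 1e-4), b)
  expect_true(shifted$significant)

  # textbook closed form on a 5-pair worked example
  a <- c(0.81, 0.77, 0.90, 0.66, 0.84)
  bb <- c(0.70, 0.72, 0.80, 0.68, 0.75)
  d <- a - bb
  t_stat <- mean(d) / (sd(d) / sqrt(5))
  p_ref <- 2 * pt(-abs(t_stat), df = 4)
  out <- compare_models(a, bb)
  expect_equal(out$statistic, t_stat, tolerance = 1e-10)
  expect_equal(out$p_value, p_ref, tolerance = 1e-10)

  const <- compare_models(rep(0.9, 5), rep(0.5, 5))
  expect_true(const$significant)
  expect_equal(const$p_value, 0)
  expect_error(compare_models(1:3, 1:4), "unequal")
})

test_that("rating_matrix lays out panels by rater ID", {
  ds <- quick_dataset(n = 3)
  m <- rating_matrix(ds)
  expect_identical(dim(m), c(3L, 8L))
  expect_equal(unname(m["r01", "pt2"]),
               unname(ds$ratings[["r01"]]$pt_ratings["pt2"]))
})
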