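test_that("time-series inputs have fixed length and train-fitted standardization", {
  set.seed(8)
  train <- lapply(1:5, function(i)
    make_rec(rnorm(3000, mean = 2), rnorm(3000, sd = 3), rate = 100,
             id = paste0("r", i)))
  std <- fit_standardizer(train)
  xs <- lapply(train, to_timeseries, standardizer = std)
  expect_true(all(vapply(xs, ncol, 0L) == 3000))
  expect_identical(rownames(xs[[1]]),
                   c("pitch_angle", "roll_angle", "pitch_velocity",
                     "roll_velocity"))
  # recomputation oracle: standardized training channels have mean 0, sd 1
  all_x <- do.call(cbind, xs)
  expect_lt(max(abs(rowMeans(all_x))), 1e-6)
  expect_lt(max(abs(sqrt(rowMeans(all_x^2) - rowMeans(all_x)^2) - 1)), 1e-6)
  expect_identical(attr(xs[[1]], "groups"), list(angle = 1:2, velocity = 3:4))
})

test_that("velocity-only mode yields two channels in one group", {
  cfgv <- channel_config("velocity")
  rec <- make_rec(rnorm(200), rnorm(200), rate = 100)
  std <- fit_standardizer(list(rec), cfgv)
  x <- to_timeseries(rec, std, length_out = 200)
  expect_equal(nrow(x), 2)
  expect_length(attr(x, "groups"), 1)
})

test_that("off-nominal lengths are symmetrically padded or truncated", {
  rec_short <- make_rec(rnorm(90), rnorm(90), rate = 100)
  rec_long <- make_rec(rnorm(130), rnorm(130), rate = 100)
  std <- fit_standardizer(list(rec_short))
  xs <- to_timeseries(rec_short, std, length_out = 100)
  expect_equal(ncol(xs), 100)
  expect_true(all(xs[, 1:5] == 0) && all(xs[, 96:100] == 0))
  xl <- to_timeseries(rec_long, std, length_out = 100)
  expect_equal(ncol(xl), 100)
})

test_that("fit_bounds follows its policy and ignores ordering", {
  t1 <- sway_trajectory(c(-4, 1, 2), c(0.5, -0.25, 0))
  b <- fit_bounds(list(t1))
  expect_equal(b$pitch_halfwidth, 4.0)
  expect_equal(b$roll_halfwidth, 0.5)
  t2 <- sway_trajectory(c(2, -4, 1), c(0, 0.5, -0.25))
  expect_equal(fit_bounds(list(t2))[1:2], b[1:2])
  expect_error(fit_bounds(list()), "empty")

  set.seed(9)
  vals <- rnorm(500)
  tp <- sway_trajectory(vals, rev(vals))
  bp <- fit_bounds(list(tp), policy = "percentile", p = 90)
  # brute-force percentile (type-7 interpolation on the sorted array)
  s <- sort(abs(vals)); h <- (length(s) - 1) * 0.9
  brute <- s[floor(h) + 1] + (h - floor(h)) * (s[floor(h) + 2] - s[floor(h) + 1])
  expect_equal(bp$pitch_halfwidth, brute, tolerance = 1e-12)
})

test_that("rasterization lights the center pixel for a constant trajectory", {
  b <- fit_bounds(list(sway_trajectory(c(-1, 1), c(-1, 1))))
  img <- rasterize(sway_trajectory(rep(0, 10), rep(0, 10)), b)
  expect_identical(dim(img), c(60L, 60L))
  expect_equal(sum(img), 1)
  expect_equal(img[31, 31], 1L)
})

test_that("a straight diagonal trajectory rasterizes to the diagonal pixel set", {
  b <- structure(list(pitch_halfwidth = 1, roll_halfwidth = 1),
                 class = "raster_bounds")
  n <- 400
  v <- seq(-1 + 1e-9, 1 - 1e-9, length.out = n)
  img <- rasterize(sway_trajectory(v, -v), b)   # roll = -v: rows top->bottom
  lit <- which(img == 1L, arr.ind = TRUE)
  expect_true(all(lit[, "row"] == lit[, "col"]))
  expect_equal(sum(img), 60)
  # out-of-bounds points clamp to the border
  img2 <- rasterize(sway_trajectory(c(5, 5), c(5, -5)), b)
  expect_equal(sum(img2[, 60]), 60)  # clamped vertical line on last column
})

test_that("rasterization is invariant under sample-order reversal", {
  set.seed(10)
  for (k in 1:5) {
    p <- cumsum(rnorm(300)); r <- cumsum(rnorm(300))
    traj <- sway_trajectory(p, r)
    b <- fit_bounds(list(traj))
    rev_traj <- sway_trajectory(rev(p), rev(r))
    expect_identical(rasterize(traj, b), rasterize(rev_traj, b))
  }
})

test_that("line rasterization matches an independent Bresenham oracle", {
  oracle_line <- function(x0, y0, x1, y1) {
    # independent re-derivation: walk the major axis, round the minor
    steps <- max(abs(x1 - x0), abs(y1 - y0))
    if (steps == 0) return(cbind(x0, y0))
    tseq <- 0:steps
    xs <- x0 + round(tseq * (x1 - x0) / steps)
    ys <- y0 + round(tseq * (y1 - y0) / steps)
    cbind(xs, ys)
  }
  b <- structure(list(pitch_halfwidth = 1, roll_halfwidth = 1),
                 class = "raster_bounds")
  # exact diagonal and axis-aligned jumps: both rasterizers agree exactly
  traj <- sway_trajectory(c(-0.99, 0.99), c(0.99, -0.99))
  img <- rasterize(traj, b)
  pix <- oracle_line(1, 1, 60, 60)
  expect_equal(sum(img), nrow(pix))
  expect_true(all(img[pix[, 2:1]] == 1L))
  traj_h <- sway_trajectory(c(-0.99, 0.99), c(0, 0))
  expect_equal(sum(rasterize(traj_h, b)), 60)
})

test_that("image inputs carry two 60x60 channels and are deterministic", {
  rec <- sine_rec(A = 2, f = 0.4, duration = 3, rate = 50)
  ab <- fit_bounds(list(integrate_angle(rec)))
  vb <- fit_bounds(list(velocity_trajectory(rec)))
  img <- make_image_input(rec, ab, vb)
  expect_identical(dim(img$angle), c(60L, 60L))
  expect_identical(dim(img$velocity), c(60L, 60L))
  expect_true(all(img$angle %in% 0:1))
  expect_identical(img, make_image_input(rec, ab, vb))

  z <- make_rec(rep(0, 100), rep(0, 100), rate = 50)
  zb <- structure(list(pitch_halfwidth = 1, roll_halfwidth = 1),
                  class = "raster_bounds")
  zimg <- make_image_input(z, zb, zb)
  expect_equal(sum(zimg$angle), 1)
  expect_equal(sum(zimg$velocity), 1)
})

test_that("rotation augmentation draws from the angle set and multiplies images", {
  rec <- sine_rec(A = 2, f = 0.5, duration = 4, rate = 50)
  ab <- fit_bounds(list(integrate_angle(rec)))
  vb <- fit_bounds(list(velocity_trajectory(rec)))
  aug <- augment_rotations(rec, ab, vb, n_copies = 3, seed = 21)
  expect_length(aug, 3)
  expect_true(all(vapply(aug, function(a) a$rotation, 0) %in%
                    rotation_angle_set()))
  aug2 <- augment_rotations(rec, ab, vb, n_copies = 3, seed = 21)
  expect_identical(vapply(aug, function(a) a$rotation, 0),
                   vapply(aug2, function(a) a$rotation, 0))
  expect_error(augment_rotations(rec, ab, vb, angle_set = numeric()),
               "non-empty")
  # a 4x augmented training set: originals plus 3 copies each
  expect_equal(1 + length(aug), 4)
})

test_that("a circular trajectory yields similar lit-pixel counts at all rotations", {
  t <- seq(0, 2 * pi, length.out = 600)
  traj_rec <- make_rec(cos(t), sin(t), rate = 100)
  b <- structure(list(pitch_halfwidth = 1.45, roll_halfwidth = 1.45),
                 class = "raster_bounds")
  counts <- vapply(rotation_angle_set(), function(a) {
    img <- make_image_input(traj_rec, b, b, rotation = a)
    sum(img$velocity)
  }, 0)
  expect_lt((max(counts) - min(counts)) / max(counts), 0.10)
})

test_that("fitted representation state derives from training data only", {
  set.seed(11)
  train <- lapply(1:3, function(i) make_rec(rnorm(100), rnorm(100), rate = 50))
  std1 <- fit_standardizer(train)
  b1 <- fit_bounds(lapply(train, velocity_trajectory))
  # a different "test set" cannot alter fitted state
  std2 <- fit_standardizer(train)
  b2 <- fit_bounds(lapply(train, velocity_trajectory))
  expect_identical(std1, std2)
  expect_identical(b1, b2)
})
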