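test_that("patch grids cover every pixel with clamped border anchors", {
  g <- build_patch_grid(c(96, 96), 48, 12)
  expect_equal(g$anchors_row, c(1L, 13L, 25L, 37L, 49L))
  expect_equal(nrow(g$positions), 25L)
  g2 <- build_patch_grid(c(50, 50), 48, 12)
  expect_equal(g2$anchors_row, c(1L, 3L))
  g3 <- build_patch_grid(c(96, 96), 48, 48)       # non-overlapping tiling
  expect_equal(g3$anchors_row, c(1L, 49L))
  # full-coverage property over assorted shapes and strides
  for (case in list(c(64, 80, 16, 5), c(49, 63, 16, 16), c(100, 52, 20, 7))) {
    gg <- build_patch_grid(case[1:2], case[3], case[4])
    covered <- matrix(FALSE, case[1], case[2])
    for (i in seq_len(nrow(gg$positions))) {
      r <- gg$positions$row[i]; cl <- gg$positions$col[i]
      covered[r:(r + case[3] - 1), cl:(cl + case[3] - 1)] <- TRUE
    }
    expect_true(all(covered))
  }
  expect_error(build_patch_grid(c(40, 40), 48, 12), "larger than slice")
  expect_error(build_patch_grid(c(96, 96), 48, 0), "stride")
})

test_that("overlap percent matches brute-force pixel-set intersection", {
  expect_equal(overlap_percent(48, 12), 75)
  expect_equal(overlap_percent(48, 48), 0)
  expect_equal(overlap_percent(48, 24), 50)
  for (size in c(4, 8, 16, 33, 48, 64)) {
    for (stride in unique(c(1, 3, size %/% 2, size))) {
      p1 <- outer(1:size, 1:size, function(r, c) paste(r, c))
      p2 <- outer(1:size, 1:size + stride, function(r, c) paste(r, c))
      frac <- length(intersect(p1, p2)) / length(p1)
      expect_equal(overlap_percent(size, stride), 100 * frac)
    }
  }
  expect_error(overlap_percent(48, 60), "stride")
})

test_that("the cosine window is center-peaked, positive and 8-fold symmetric", {
  w <- cosine_weight_window(48)
  ctr <- c(24, 25)
  expect_equal(max(w), max(w[ctr, ctr]))
  expect_true(all(w > 0))
  corners <- c(w[1, 1], w[1, 48], w[48, 1], w[48, 48])
  expect_true(all(corners == min(w)))
  expect_equal(w, w[48:1, ])
  expect_equal(w, w[, 48:1])
  expect_equal(w, t(w))
  expect_error(cosine_weight_window(1), ">= 2")
})

test_that("overlap-tile recombination is a partition of unity", {
  set.seed(7)
  sl <- matrix(runif(96 * 96), 96)
  for (case in list(c(48, 12), c(48, 48), c(32, 8), c(20, 20), c(24, 15))) {
    g <- build_patch_grid(dim(sl), case[1], case[2])
    const <- predict_slice(function(p) matrix(0.7, nrow(p), ncol(p)), sl,
                           grid = g)
    expect_equal(max(abs(const - 0.7)), 0, tolerance = 1e-12)
    ident <- predict_slice(function(p) p, sl, grid = g)
    expect_lt(max(abs(ident - sl)), 1e-6)
  }
  # stride = size with box weights reduces to naive tiling
  g <- build_patch_grid(dim(sl), 48, 48)
  tiled <- predict_slice(function(p) p * 0 + mean(p), sl, grid = g,
                         weights = matrix(1, 48, 48))
  expect_equal(tiled[1:48, 1:48], matrix(mean(sl[1:48, 1:48]), 48, 48))
})

test_that("threshold selection equals a brute-force argmax oracle", {
  # hand-built 10-pixel example
  p <- c(0.05, 0.15, 0.35, 0.42, 0.48, 0.55, 0.62, 0.71, 0.88, 0.97)
  y <- c(0, 0, 0, 1, 0, 1, 1, 0, 1, 1)
  cand <- seq(0.01, 0.99, by = 0.01)
  oracle <- function(p, y) {
    f1 <- vapply(cand, function(th) {
      cm <- classification_metrics(confusion_counts(p >= th, y == 1))
      if (is.na(cm$f1)) 0 else cm$f1
    }, numeric(1))
    cand[which(f1 >= max(f1) - 1e-12)[1]]
  }
  got <- select_threshold(p, y)
  expect_equal(got$threshold, oracle(p, y))
  # shifting probabilities shifts the optimum accordingly
  got_shift <- select_threshold(pmin(p + 0.1, 1), y)
  expect_equal(got_shift$threshold, oracle(pmin(p + 0.1, 1), y))
  expect_equal(got_shift$threshold, got$threshold + 0.1, tolerance = 1e-9)
  # random instances
  set.seed(42)
  for (i in 1:20) {
    pp <- runif(60)
    yy <- rbinom(60, 1, 0.4)
    if (sum(yy) == 0) yy[1] <- 1
    expect_equal(select_threshold(pp, yy)$threshold, oracle(pp, yy))
  }
  # degenerate cases
  perfect <- select_threshold(y, y)
  expect_equal(perfect$threshold, 0.01)        # lowest among ties
  expect_equal(perfect$f1, 1)
  expect_error(select_threshold(p, rep(0, 10)), "no positive")
})

test_that("longitudinal smoothing behaves like a 1-D Gaussian on slices", {
  set.seed(1)
  pv <- array(runif(20 * 20 * 10), c(20, 20, 10))
  expect_identical(smooth_longitudinal(pv, 0), pv)
  const <- array(0.3, c(8, 8, 12))
  expect_equal(smooth_longitudinal(const, 3), const)
  alt <- array(rep(c(0, 1), each = 4 * 4, times = 20), c(4, 4, 40))
  sm <- smooth_longitudinal(alt, 500)
  expect_lt(max(abs(sm - 0.5)), 1e-3)
  # smoothing reduces adjacent-slice disagreement of binarized fractions
  sig <- array(rep(pmin(pmax(sin(seq(0, 3 * pi, length.out = 30)), 0), 1),
                   each = 16 * 16), c(16, 16, 30))
  noisy <- pmin(pmax(sig + array(rnorm(length(sig), 0, 0.25), dim(sig)), 0), 1)
  frac <- function(x) apply(x >= 0.5, 3, mean)
  jitter0 <- mean(abs(diff(frac(noisy))))
  jitter1 <- mean(abs(diff(frac(smooth_longitudinal(noisy, 1.5)))))
  expect_lt(jitter1, jitter0)
})

test_that("decay quantification counts thresholded wood voxels, minus cracks", {
  wood <- array(TRUE, c(10, 10, 4))
  pv <- array(0, dim(wood))
  pv[1:5, , ] <- 0.9
  expect_equal(quantify_decay(pv, 0.5, wood), 50)
  expect_equal(quantify_decay(array(0, dim(wood)), 0.5, wood), 0)
  cracks <- array(FALSE, dim(wood)); cracks[1, , ] <- TRUE
  expect_equal(quantify_decay(pv, 0.5, wood, cracks), 40)
  # monotone in the threshold
  set.seed(2)
  pv2 <- array(runif(length(wood)), dim(wood))
  ests <- vapply(seq(0.1, 0.9, 0.1),
                 function(th) quantify_decay(pv2, th, wood), numeric(1))
  expect_true(all(diff(ests) <= 0))
  expect_error(quantify_decay(pv, 0.5, array(FALSE, dim(wood))), "empty wood")
})

test_that("training improves the loss and degenerate labels predict background", {
  ann <- synthetic_decay_annotations(n_logs = 2, slices_per_log = 6, seed = 31)
  cfg <- train_config(epochs = 4, n_patches = 48, batch = 8,
                      base_channels = 4, seed = 7)
  m <- train_decay_model(ann, cfg)
  expect_true(all(is.finite(m$history)))
  expect_lt(m$history[length(m$history)], m$history[1])
  # model round-trips through its checkpoint
  fn <- tempfile(fileext = ".json")
  save_decay_model(m, fn)
  m2 <- load_decay_model(fn)
  sl <- ann$images[[1]]
  expect_equal(predict_slice(m2, sl), predict_slice(m, sl), tolerance = 1e-12)

  # all-background labels: the model learns to predict almost no decay
  ann0 <- ann
  ann0$masks <- lapply(ann0$masks, function(m) m * 0)
  m0 <- train_decay_model(ann0, train_config(epochs = 3, n_patches = 32,
                                             base_channels = 4, seed = 8))
  fracs <- vapply(which(ann0$split == "train")[1:3], function(i)
    mean(predict_slice(m0, ann0$images[[i]]) >= 0.5), numeric(1))
  expect_lt(mean(fracs), 0.01)
  expect_error(train_decay_model(annotation_set(list(), list())), "empty")
})

test_that("cross-validation folds are assigned per slice", {
  ann <- synthetic_decay_annotations(n_logs = 2, slices_per_log = 5, seed = 3)
  ann <- assign_cv_folds(ann, k = 5, seed = 2)
  expect_setequal(unique(ann$split), paste0("fold", 1:5))
  expect_equal(length(ann$split), 10L)
})
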