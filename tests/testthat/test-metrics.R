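test_that("confusion counts match enumeration, with region restriction", {
  pred <- c(1, 1, 0, 0) == 1
  truth <- c(1, 0, 1, 0) == 1
  cc <- confusion_counts(pred, truth)
  expect_equal(unclass(cc)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  same <- confusion_counts(truth, truth)
  expect_equal(same$fp + same$fn, 0L)
  inv <- confusion_counts(!truth, truth)
  expect_equal(inv$tp + inv$tn, 0L)
  reg <- c(TRUE, TRUE, FALSE, FALSE)
  cc2 <- confusion_counts(pred, truth, region = reg)
  expect_equal(cc2$tp + cc2$fp + cc2$fn + cc2$tn, 2L)
  expect_error(confusion_counts(pred, truth[1:3]), "differ")
})

test_that("classification metrics match direct arithmetic and flag undefined", {
  perfect <- classification_metrics(confusion_counts(c(TRUE, FALSE),
                                                     c(TRUE, FALSE)))
  expect_equal(unlist(perfect[c("precision", "sensitivity", "specificity",
                                "accuracy", "f1")]),
               c(precision = 1, sensitivity = 1, specificity = 1,
                 accuracy = 1, f1 = 1))
  cc <- structure(list(tp = 7L, fp = 3L, fn = 3L, tn = 87L),
                  class = "confusion_counts")
  m <- classification_metrics(cc)
  expect_equal(m$precision, 0.7)
  expect_equal(m$sensitivity, 0.7)
  expect_equal(m$accuracy, 0.94)
  expect_equal(m$f1, 0.7)
  # harmonic-mean identity: precision 0.5, sensitivity 1 -> F1 = 2/3
  cc2 <- structure(list(tp = 5L, fp = 5L, fn = 0L, tn = 0L),
                   class = "confusion_counts")
  expect_equal(classification_metrics(cc2)$f1, 2 / 3)
  # zero denominators are NA, not 0 or 1
  none <- structure(list(tp = 0L, fp = 0L, fn = 2L, tn = 8L),
                    class = "confusion_counts")
  m0 <- classification_metrics(none)
  expect_true(is.na(m0$precision))
  expect_equal(m0$sensitivity, 0)
})

test_that("metrics agree with an exhaustive per-pixel oracle on random masks", {
  set.seed(11)
  for (i in 1:10) {
    pred <- matrix(runif(64) > 0.5, 8)
    truth <- matrix(runif(64) > 0.6, 8)
    m <- classification_metrics(confusion_counts(pred, truth))
    tp <- fp <- fn <- tn <- 0
    for (j in seq_along(pred)) {
      if (pred[j] && truth[j]) tp <- tp + 1
      else if (pred[j]) fp <- fp + 1
      else if (truth[j]) fn <- fn + 1
      else tn <- tn + 1
    }
    expect_equal(m$accuracy, (tp + tn) / 64)
    if (tp + fp > 0) expect_equal(m$precision, tp / (tp + fp))
    if (!is.na(m$f1) && !is.na(m$precision) && m$precision + m$sensitivity > 0)
      expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                     (m$precision + m$sensitivity))
  }
})

test_that("spearman matches Pearson-on-ranks and handles monotone invariance", {
  expect_equal(spearman_test(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_test(1:8, -(1:8))$rho, -1)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 5)
  r <- spearman_test(x, y)
  # brute-force Pearson on ranks
  rx <- rank(x); ry <- rank(y)
  brute <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(r$rho, brute)
  set.seed(6)
  a <- rnorm(15); b <- rnorm(15) + a
  expect_equal(spearman_test(exp(a), b)$rho, spearman_test(a, b)$rho)
  expect_equal(spearman_test(a, 2 * b + 5)$rho, spearman_test(a, b)$rho)
  expect_error(spearman_test(rep(1, 5), 1:5), "constant")
  expect_error(spearman_test(1:2, 1:2), "at least 3")
})

test_that("spearman p-values track the reference implementation", {
  set.seed(9)
  # small n: exact permutation enumeration
  x <- c(3.1, 1.2, 5.4, 2.2, 4.4, 0.4, 2.9)
  y <- c(2.0, 1.1, 4.9, 3.0, 3.7, 1.5, 0.3)
  ours <- spearman_test(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(ours$rho, unname(ref$estimate))
  expect_lt(abs(ours$p_value - ref$p.value), 0.03)
  # large n: t-approximation
  a <- rnorm(40); b <- a + rnorm(40, 0, 2)
  ours2 <- spearman_test(a, b)
  ref2 <- suppressWarnings(cor.test(a, b, method = "spearman", exact = FALSE))
  expect_equal(ours2$rho, unname(ref2$estimate))
  expect_lt(abs(ours2$p_value - ref2$p.value), 1e-6)
})

test_that("the disc-based dry-mass estimator applies the printed formula", {
  expect_equal(estimate_log_dry_mass(1000, 100, 50), 500)
  expect_equal(estimate_log_dry_mass(80, 80, 42), 42)   # disc == log
  expect_error(estimate_log_dry_mass(100, 0, 10), "positive")
  expect_equal(relative_mass_loss(100, 90), 10)
  expect_equal(relative_mass_loss(100, 100), 0)
  expect_equal(relative_mass_loss(100, 105), -5)
  expect_error(relative_mass_loss(0, 10), "positive")
})

test_that("the simulated experiment reproduces the field-data signatures", {
  sim <- simulate_experiment(seed = 14)
  logs <- sim$logs[sim$logs$batch == 1, ]          # first harvest, n = 61
  m0_hat <- estimate_log_dry_mass(logs$fresh_mass_log, logs$fresh_mass_disc,
                                  logs$dry_mass_disc)
  loss <- relative_mass_loss(m0_hat, logs$dry_mass_final)
  # disc subsampling error produces some negative apparent mass loss
  expect_gt(sum(loss < 0), 0)
  # tunnel volume correlates positively with mass loss
  ct <- spearman_test(logs$true_tunnel_fraction, loss)
  expect_equal(ct$n, 61L)
  expect_gt(ct$rho, 0)
  expect_lt(ct$p_value, 0.05)
})
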