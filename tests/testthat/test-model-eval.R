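test_that("the hand-computed 2x2 table yields the closed-form metrics", {
  # confusion at threshold 0.5: TP=2, TN=1, FP=1, FN=0
  y <- c(1, 1, 0, 0)
  s <- c(0.9, 0.8, 0.7, 0.2)
  m <- compute_metrics(y, s, threshold = 0.5)
  expect_equal(m$counts, c(tp = 2L, tn = 1L, fp = 1L, fn = 0L))
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 2 / 3)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$mcc, 2 / sqrt(3 * 2 * 2 * 1), tolerance = 1e-12)
})

test_that("perfect and degenerate classifiers hit the metric anchors", {
  y <- rep(c(1, 0), each = 50)
  s <- rep(c(0.9, 0.1), each = 50)
  m <- compute_metrics(y, s, 0.5)
  expect_equal(unlist(m[c("sensitivity", "specificity", "precision",
                          "accuracy", "mcc", "auc")]),
               c(sensitivity = 1, specificity = 1, precision = 1,
                 accuracy = 1, mcc = 1, auc = 1))
  tied <- compute_metrics(y, rep(0.5, 100), 0.6)
  expect_equal(tied$auc, 0.5)
  expect_equal(tied$mcc, 0)   # zero-denominator convention
  expect_error(compute_metrics(rep(1, 4), runif(4)), "both classes")
  expect_error(compute_metrics(integer(0), numeric(0)), "empty")
})

test_that("MCC equals the Pearson correlation on exhaustive small tables", {
  for (n in 4:6) {
    grid <- expand.grid(rep(list(0:1), 2 * n))
    for (k in seq_len(nrow(grid))) {
      y <- as.integer(grid[k, 1:n])
      pred <- as.integer(grid[k, (n + 1):(2 * n)])
      if (length(unique(y)) < 2) next
      m <- compute_metrics(y, pred, threshold = 1)  # call = (pred == 1)
      if (length(unique(pred)) < 2) {
        expect_equal(m$mcc, 0)
      } else {
        expect_equal(m$mcc, cor(pred, y), tolerance = 1e-12)
      }
    }
  }
})

test_that("rank AUC equals trapezoidal ROC integration and the pROC oracle", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (k in 1:25) {
    n <- sample(10:60, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    s <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    m <- compute_metrics(y, s, 0.5)
    trap <- sum(diff(m$roc$fpr) * (utils::head(m$roc$tpr, -1) +
                                     utils::tail(m$roc$tpr, -1)) / 2)
    expect_equal(m$auc, trap, tolerance = 1e-9)
    expect_equal(m$auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-9)
  }
})

test_that("ROC curves are anchored and monotone; threshold sweeps behave", {
  set.seed(8)
  y <- rbinom(50, 1, 0.5); y[1:2] <- c(0, 1)
  s <- runif(50)
  m <- compute_metrics(y, s, 0.5)
  expect_equal(m$roc$fpr[1], 0); expect_equal(m$roc$tpr[1], 0)
  expect_equal(utils::tail(m$roc$fpr, 1), 1)
  expect_equal(utils::tail(m$roc$tpr, 1), 1)
  expect_true(all(diff(m$roc$fpr) >= 0))
  expect_true(all(diff(m$roc$tpr) >= 0))
  ths <- seq(0, 1, by = 0.05)
  sn <- vapply(ths, function(t) compute_metrics(y, s, t)$sensitivity, 1)
  sp <- vapply(ths, function(t) compute_metrics(y, s, t)$specificity, 1)
  expect_true(all(diff(sn) <= 1e-12))
  expect_true(all(diff(sp) >= -1e-12))
})

test_that("random-forest training is seeded, separable, and name-strict", {
  set.seed(2)
  n <- 80
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(a = y * 2 + rnorm(n, 0, 0.1), b = rnorm(n))
  m1 <- train_rf(x, y, seed = 7)
  m2 <- train_rf(x, y, seed = 7)
  s1 <- predict_scores(m1, x)
  s2 <- predict_scores(m2, x)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  expect_equal(auc_rank(y, s1), 1)
  xr <- x[, c("b", "a")]
  expect_error(predict_scores(m1, xr[, "b", drop = FALSE]), "feature names")
  colnames(xr) <- c("c", "d")
  expect_error(predict_scores(m1, xr), "feature names")
  expect_error(train_rf(x, rep(0, n)), "both classes")
})

test_that("threshold calibration finds the minimal threshold at target specificity", {
  neg <- seq(0, 0.99, by = 0.01)
  th <- threshold_at_specificity(neg, 0.99)
  expect_equal(th$threshold, 0.99)
  expect_gte(th$specificity, 0.99)
  # one step below fails the target, so 0.99 is minimal
  expect_lt(mean(neg < 0.98), 0.99)
  expect_equal(threshold_at_specificity(neg, 0)$threshold, 0)
  z <- threshold_at_specificity(rep(0, 10), 0.99)
  expect_gt(z$threshold, 0)
  expect_equal(z$specificity, 1)
  expect_error(threshold_at_specificity(numeric(0)), "no negative")
})

test_that("cross-validation recovers signal, nulls out on permuted labels, and reproduces", {
  set.seed(12)
  n <- 300
  y <- rep(c(0, 1), each = n / 2)
  x <- cbind(a = y * 1.5 + rnorm(n, 0, 0.6), b = y + rnorm(n, 0, 0.9),
             c = rnorm(n))
  cv <- cross_validate(x, y, folds = 5, rounds = 5, num.trees = 150, seed = 3)
  expect_gt(cv$mean["auc"], 0.85)
  cv2 <- cross_validate(x, y, folds = 5, rounds = 5, num.trees = 150, seed = 3)
  expect_identical(cv$mean, cv2$mean)
  # a single fixed permutation keeps its realized label-feature correlation
  # across folds, so the null is checked as a mean over permutations
  null_auc <- vapply(1:5, function(k) {
    yp <- sample(y)
    unname(cross_validate(x, yp, folds = 5, rounds = 2, num.trees = 150,
                          seed = 4 + k)$mean["auc"])
  }, numeric(1))
  expect_lt(abs(mean(null_auc) - 0.5), 0.05)
})

test_that("screening calls sites above the threshold and counts per protein", {
  sp <- small_planted()
  fm <- sp$fm
  ok <- !is.na(fm$y)
  model <- train_rf(fm$x[ok, ], fm$y[ok], num.trees = 200, seed = 1)
  out <- screen(model, sp$feats, threshold = 0.5, sites = sp$ds$sites)
  expect_equal(nrow(out$sites), nrow(sp$feats))
  expect_true(all(out$sites$call == (out$sites$score >= 0.5)))
  expect_equal(sum(out$proteins$n_called), sum(out$sites$call))
  expect_true(all(out$sites$author == sp$ds$sites$author))
  empty <- screen(model, sp$feats[0, ], threshold = 0.5)
  expect_equal(nrow(empty$sites), 0)
})
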