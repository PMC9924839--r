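test_that("node entropy has the textbook endpoints, symmetry, and range", {
  expect_identical(node_entropy(1), 0)
  expect_identical(node_entropy(0), 0)
  expect_equal(node_entropy(0.5), 1)
  expect_equal(node_entropy(0.25), -(0.25 * log2(0.25) + 0.75 * log2(0.75)))
  p <- seq(0, 1, by = 0.01)
  expect_equal(node_entropy(p), node_entropy(1 - p))
  expect_true(all(node_entropy(p) >= 0 & node_entropy(p) <= 1))
  expect_error(node_entropy(1.2), "\\[0, 1\\]")
  expect_error(node_entropy(-0.1), "\\[0, 1\\]")
})

test_that("model_report computes the four metrics and reports undefined ratios as NA", {
  r <- model_report(tp = 29, fn = 1, tn = 28, fp = 2)
  expect_equal(r$sensitivity, 29 / 30)
  expect_equal(r$specificity, 28 / 30)
  expect_equal(r$precision, 29 / 31)
  expect_equal(r$accuracy, 57 / 60)
  perfect <- model_report(tp = 10, fp = 0, tn = 10, fn = 0)
  expect_equal(unlist(perfect[c("accuracy", "precision", "sensitivity",
                                "specificity")]),
               c(accuracy = 1, precision = 1, sensitivity = 1,
                 specificity = 1))
  # all-positive predictor on balanced labels
  allpos <- model_report_from(rep(TRUE, 20), rep(c(TRUE, FALSE), 10))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  expect_equal(allpos$accuracy, 0.5)
  # zero denominator -> NA, never 0
  none <- model_report(tp = 0, fp = 0, tn = 5, fn = 0)
  expect_true(is.na(none$precision))
  expect_true(is.na(none$sensitivity))
})

test_that("balanced_cohort keeps all minority cases plus a seeded equal-size sample", {
  set.seed(1)
  labels <- rep(c(TRUE, FALSE), c(17, 79))
  idx <- balanced_cohort(labels, seed = 5)
  expect_length(idx, 34)
  expect_equal(sum(labels[idx]), 17)
  expect_true(all(which(labels) %in% idx))
  expect_identical(idx, balanced_cohort(labels, seed = 5))   # determinism
  expect_false(identical(idx, balanced_cohort(labels, seed = 6)))
  balanced <- rep(c(TRUE, FALSE), 10)
  expect_setequal(balanced_cohort(balanced, seed = 1), seq_along(balanced))
  expect_error(balanced_cohort(rep(TRUE, 5), seed = 1), "both classes")
})

test_that("grouped train/test splits never let a subject span train and test", {
  group <- rep(sprintf("s%02d", 1:20), each = 8)
  sp <- train_test_split(length(group), split_plan(seed = 3), group = group)
  expect_length(intersect(unique(group[sp$train]), unique(group[sp$test])), 0)
  expect_equal(length(unique(group[sp$train])), 14)   # 0.7 of 20 groups
  # ungrouped: row-level 7:3
  sp2 <- train_test_split(100, split_plan(seed = 3))
  expect_length(sp2$train, 70)
  expect_length(intersect(sp2$train, sp2$test), 0)
})

test_that("decision tree selects a sensible depth by tenfold CV", {
  # 1-D separable: depth 1 suffices and wins the parsimony tie-break
  x <- data.frame(RI = c(seq(0, 0.9, length.out = 30),
                         seq(1.1, 2, length.out = 30)))
  y <- rep(c(FALSE, TRUE), each = 30)
  fit <- lvh_model(x, y, method = "tree", seed = 1, depth_range = 1:10)
  expect_equal(fit$depth, 1)
  expect_equal(unname(fit$cv_accuracy["1"]), 1)
  expect_equal(predict(fit, x), y)
  # XOR needs depth >= 2
  set.seed(2)
  a <- runif(200) > 0.5; b <- runif(200) > 0.5
  xx <- data.frame(f1 = as.numeric(a) + rnorm(200, 0, 0.05),
                   f2 = as.numeric(b) + rnorm(200, 0, 0.05))
  yy <- xor(a, b)
  fitx <- lvh_model(xx, yy, method = "tree", seed = 1, depth_range = 1:6)
  expect_gte(fitx$depth, 2)
  expect_gt(mean(predict(fitx, xx) == yy), 0.95)
  # pure-noise labels: CV accuracy within binomial noise of 0.5
  set.seed(3)
  xn <- data.frame(matrix(rnorm(200 * 4), 200))
  yn <- rep(c(TRUE, FALSE), 100)
  fitn <- lvh_model(xn, yn, method = "tree", seed = 1, depth_range = 1:8)
  expect_lt(abs(max(fitn$cv_accuracy) - 0.5), 0.2)
  expect_error(lvh_model(xn, rep(TRUE, 200), method = "tree"),
               "single class")
})

test_that("k-means++ classifier separates blobs and degrades to priors on noise", {
  set.seed(4)
  n <- 60
  x <- rbind(matrix(rnorm(n * 2, 0), ncol = 2),
             matrix(rnorm(n * 2, 6), ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c(FALSE, TRUE), each = n)
  fit <- lvh_model(x, y, method = "kmeans", seed = 1)
  expect_equal(mean(predict(fit, x) == y), 1)
  expect_identical(predict(fit, x),
                   predict(lvh_model(x, y, method = "kmeans", seed = 1), x))
  # labels independent of cluster structure: accuracy ~ max class prior
  yr <- rep(c(TRUE, FALSE), n)
  fitr <- lvh_model(x, yr, method = "kmeans", seed = 1)
  expect_lt(mean(predict(fitr, x) == yr), 0.75)
  # k = 1: every prediction is the majority label
  fit1 <- lvh_model(x, c(rep(TRUE, 70), rep(FALSE, 50)), method = "kmeans",
                    k = 1, seed = 1)
  expect_true(all(predict(fit1, x)))
  expect_error(lvh_model(x[1:3, ], y[1:3], method = "kmeans", k = 5),
               "exceeds")
})

test_that("BPN learns a separable table, agrees with an independent MLP, and is seeded", {
  tab <- synth_feature_table(150, effect_size = 3, seed = 6)
  sp <- train_test_split(300, split_plan(seed = 6))
  fit <- lvh_model(tab$x[sp$train, ], tab$y[sp$train], method = "bpn",
                   seed = 6, cv_folds = 0, epochs = 150)
  rep <- evaluate_model(fit, tab$x[sp$test, ], tab$y[sp$test])
  expect_gte(rep$accuracy, 0.9)
  # bit-identical refit under the same seed
  fit2 <- lvh_model(tab$x[sp$train, ], tab$y[sp$train], method = "bpn",
                    seed = 6, cv_folds = 0, epochs = 150)
  expect_identical(fit$weights, fit2$weights)
  # independent single-hidden-layer MLP (nnet) reaches the same regime
  skip_if_not_installed("nnet")
  nn <- nnet::nnet(x = scale(tab$x[sp$train, ]), y = tab$y[sp$train],
                   size = 8, maxit = 200, trace = FALSE, decay = 1e-3)
  pred_nn <- predict(nn, scale(tab$x[sp$test, ],
                               center = colMeans(tab$x[sp$train, ]),
                               scale = apply(tab$x[sp$train, ], 2, sd))) > 0.5
  expect_gte(mean(pred_nn == tab$y[sp$test]), 0.9)
})

test_that("BPN cross-validation accuracy is reported and zero-epoch nets sit at chance", {
  tab <- synth_feature_table(30, effect_size = 3, seed = 7)
  fit <- lvh_model(tab$x, tab$y, method = "bpn", seed = 7, cv_folds = 5,
                   epochs = 100)
  expect_gte(fit$cv_accuracy, 0.75)
  fit0 <- lvh_model(tab$x, tab$y, method = "bpn", seed = 7, cv_folds = 0,
                    epochs = 0)
  acc0 <- mean(predict(fit0, tab$x) == tab$y)
  expect_lt(abs(acc0 - 0.5), 0.25)   # untrained: chance-level
})
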