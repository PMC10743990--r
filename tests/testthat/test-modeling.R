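# Metrics, grids, training contracts, CV protocols, y-randomization.

test_that("confusion-matrix metrics match the stated formulas", {
  ev <- evaluateBinary(
    c(rep("active", 4), rep("inactive", 4)),
    c("active", "active", "active", "inactive",
      "inactive", "inactive", "active", "active"))
  expect_equal(ev$TP, 3); expect_equal(ev$FP, 1)
  expect_equal(ev$TN, 2); expect_equal(ev$FN, 2)
  expect_equal(ev$accuracy, 0.625)
  expect_equal(ev$precision, 0.75)
  expect_equal(ev$recall, 0.6)

  perfect <- evaluateBinary(c("active", "inactive"), c("active", "inactive"))
  expect_equal(c(perfect$accuracy, perfect$precision, perfect$recall),
               c(1, 1, 1))

  expect_warning(
    ev0 <- evaluateBinary(rep("inactive", 3),
                          c("active", "inactive", "inactive")),
    "no positive predictions")
  expect_equal(ev0$precision, 0)
  expect_equal(ev0$recall, 0)
  expect_error(evaluateBinary("active", c("active", "active")), "mismatch")
})

test_that("metrics agree with a brute-force counter on random vectors", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    pred <- sample(c("active", "inactive"), n, replace = TRUE)
    truth <- sample(c("active", "inactive"), n, replace = TRUE)
    ev <- suppressWarnings(evaluateBinary(pred, truth))
    # independent oracle: literal element-by-element counting
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (j in seq_len(n)) {
      if (pred[j] == "active" && truth[j] == "active") tp <- tp + 1
      if (pred[j] == "inactive" && truth[j] == "inactive") tn <- tn + 1
      if (pred[j] == "active" && truth[j] == "inactive") fp <- fp + 1
      if (pred[j] == "inactive" && truth[j] == "active") fn <- fn + 1
    }
    expect_equal(c(ev$TP, ev$TN, ev$FP, ev$FN), c(tp, tn, fp, fn))
    expect_equal(ev$accuracy, (tp + tn) / n)
    if (tp + fp > 0) expect_equal(ev$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(ev$recall, tp / (tp + fn))
  }
})

test_that("default grids enumerate the printed combination counts", {
  expect_length(consensusVS:::gridPoints(defaultGrid("RF")), 6L)    # 3 x 2
  expect_length(consensusVS:::gridPoints(defaultGrid("SVM")), 10L)  # 5 x 2
  expect_length(consensusVS:::gridPoints(defaultGrid("KNN")), 60L)  # 30 x 2
  expect_length(consensusVS:::gridPoints(defaultGrid("MLP")), 144L) # 3x3x4x4
  # deterministic order: first point is the first value of every list
  p1 <- consensusVS:::gridPoints(defaultGrid("SVM"))[[1]]
  expect_equal(p1$C, 0.01); expect_equal(p1$kernel, "linear")
})

test_that("the Tanimoto kernel is a valid similarity kernel", {
  for (seed in 1:3) {
    X <- randomBits(25, 64, seed)
    K <- tanimotoMatrix(X)
    expect_equal(K, t(K))
    expect_equal(unname(diag(K)), rep(1, 25))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
  # zero-vector conventions
  Z <- rbind(rep(0L, 8), c(1L, rep(0L, 7)))
  KZ <- tanimotoMatrix(Z)
  expect_equal(KZ[1, 1], 1)   # both empty -> identical
  expect_equal(KZ[1, 2], 0)   # one empty -> dissimilar
})

test_that("every family emits PS in [0,1] and labels = PS >= 0.5", {
  fx <- fixSmall()
  sub <- c(1:25, 61:85)  # 25 actives + 25 inactives, keeps fits quick
  X <- fx$X[sub, ]; y <- fx$y[sub]
  hps <- list(
    RF = list(max_features = "sqrt", n_estimators = 100L),
    SVM = list(C = 1, kernel = "tanimoto"),
    KNN = list(n_neighbors = 3L, weight = "distance"),
    MLP = list(hidden_layer_size = 100L, solver = "adam",
               activation = "relu", learning_rate_init = 0.001))
  for (alg in names(hps)) {
    m <- trainClassifier(alg, X, y, hps[[alg]], "morgan", 5L)
    ps <- predictPS(m, fx$X)
    expect_true(all(ps >= 0 & ps <= 1))
    expect_identical(predictLabel(m, fx$X),
                     ifelse(ps >= 0.5, "active", "inactive"))
    # training a second time with the same seed is deterministic
    m2 <- trainClassifier(alg, X, y, hps[[alg]], "morgan", 5L)
    expect_equal(predictPS(m2, fx$X), ps, tolerance = 1e-12)
  }
})

test_that("training separable data reaches >= 0.95 training accuracy", {
  fx <- fixSmall()
  for (alg in c("RF", "KNN")) {
    m <- trainClassifier(alg, fx$X, fx$y, NULL, "morgan", 5L)
    acc <- mean(predictLabel(m, fx$X) == as.character(fx$y))
    expect_gte(acc, 0.95)
  }
})

test_that("KNN with one neighbor returns PS 1 for a training active", {
  fx <- fixSmall()
  m <- trainClassifier("KNN", fx$X, fx$y,
                       list(n_neighbors = 1L, weight = "uniform"), "morgan")
  i <- which(fx$y == "active")[1]
  expect_equal(predictPS(m, fx$X[i, , drop = FALSE]), 1)
  j <- which(fx$y == "inactive")[1]
  expect_equal(predictPS(m, fx$X[j, , drop = FALSE]), 0)
})

test_that("the Tanimoto kernel refuses non-binary input", {
  fx <- fixSmall()
  d <- featurizeDataset(fx$dataset, "descriptors")
  expect_error(
    trainClassifier("SVM", featureData(d), fx$y,
                    list(C = 1, kernel = "tanimoto"), "descriptors"),
    "binary representation")
})

test_that("grid search returns a deterministic, row-order-invariant argmax", {
  fx <- fixSmall()
  sub <- c(1:20, 61:80)
  X <- fx$X[sub, ]; y <- fx$y[sub]
  grid <- list(n_neighbors = c(1L, 5L, 15L), weight = c("uniform", "distance"))
  gs1 <- gridSearch(X, y, "KNN", "morgan", grid, seed = 4L)
  expect_length(consensusVS:::gridPoints(grid), 6L)
  expect_equal(nrow(gs1$table), 6L)
  gs2 <- gridSearch(X, y, "KNN", "morgan", grid, seed = 4L)
  expect_identical(gs1$best, gs2$best)
  # shuffling dataset rows does not change the selected hyperparameters
  set.seed(8); perm <- sample(length(y))
  gs3 <- gridSearch(X[perm, ], y[perm], "KNN", "morgan", grid, seed = 4L)
  expect_identical(gs1$best, gs3$best)
  # single-class data is rejected
  expect_error(gridSearch(X[y == "active", ], y[y == "active"], "KNN",
                          "morgan", grid), "both classes")
})

test_that("repeated 70/30 validation is stratified and deterministic", {
  fx <- fixSmall()
  cv1 <- repeatedSplitCV("KNN", fx$X, fx$y,
    list(n_neighbors = 5L, weight = "uniform"), "morgan",
    n_repeats = 4L, seed = 6L)
  cv2 <- repeatedSplitCV("KNN", fx$X, fx$y,
    list(n_neighbors = 5L, weight = "uniform"), "morgan",
    n_repeats = 4L, seed = 6L)
  expect_identical(cv1$reports, cv2$reports)
  expect_length(cv1$reports, 4L)
  expect_gte(cv1$mean_accuracy, 0.95)   # planted signal is separable
  expect_equal(cv1$mean_accuracy, mean(cv1$accuracies))
  expect_equal(cv1$sd_accuracy, sd(cv1$accuracies))
  expect_error(repeatedSplitCV("KNN", fx$X, fx$y, n_repeats = 0L), "n_repeats")
})

test_that("label permutation drives accuracy to chance, same seed same result", {
  fx <- fixSmall()
  yr1 <- yRandomization("KNN", fx$X, fx$y,
    list(n_neighbors = 5L, weight = "uniform"), "morgan",
    n_repeats = 5L, n_splits = 5L, seed = 11L)
  expect_length(yr1, 5L)
  expect_lt(abs(mean(yr1) - 0.5), 0.1)
  yr2 <- yRandomization("KNN", fx$X, fx$y,
    list(n_neighbors = 5L, weight = "uniform"), "morgan",
    n_repeats = 5L, n_splits = 5L, seed = 11L)
  expect_identical(yr1, yr2)
})

test_that("descriptor inputs are z-scored with training statistics only", {
  fx <- fixSmall()
  d <- featurizeDataset(fx$dataset, "descriptors")
  X <- featureData(d)
  m <- trainClassifier("KNN", X[1:80, ], fx$y[1:80],
                       list(n_neighbors = 3L, weight = "uniform"),
                       "descriptors")
  expect_false(is.null(m@fit$scaler))
  expect_equal(m@fit$scaler$center, colMeans(X[1:80, ]))
  ps <- predictPS(m, X)   # prediction on wider data still in range
  expect_true(all(ps >= 0 & ps <= 1))
})
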