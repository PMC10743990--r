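# Classifier training, hyperparameter grids, grid-search CV, repeated
# 70/30 validation, metrics and the y-randomization control.
#
# Four algorithm families are supported. Random Forest is delegated to
# randomForest; SVM optimization to kernlab (always through a precomputed
# kernel matrix, linear or Tanimoto) with in-package cross-validated
# sigmoid (Platt) calibration to obtain probability scores; KNN and MLP
# are implemented in-package. Every model emits a probability score
# PS in [0, 1] for the active class.

#' Default hyperparameter grid of an algorithm family
#'
#' The grids reproduce the published search space: RF over
#' \code{max_features} \{sqrt, log2, all\} x \code{n_estimators}
#' \{100, 500\}; SVM over \code{C} \{0.01, 0.1, 1, 10, 100\} x
#' \code{kernel} \{linear, tanimoto\}; KNN over \code{n_neighbors} 1..30 x
#' \code{weight} \{uniform, distance\}; MLP over \code{hidden_layer_size}
#' \{(50,50,50), (50,100,50), (100)\} x \code{solver} \{lbfgs, adam, sgd\}
#' x \code{activation} \{identity, logistic, tanh, relu\} x
#' \code{learning_rate_init} \{1e-2, 1e-3, 1e-4, 1e-5\}.
#'
#' @param algorithm one of "RF", "SVM", "KNN", "MLP".
#' @return named list of candidate value lists, in deterministic order.
#' @export
defaultGrid <- function(algorithm = c("RF", "SVM", "KNN", "MLP")) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    RF = list(max_features = c("sqrt", "log2", "all"),
              n_estimators = c(100L, 500L)),
    SVM = list(C = c(0.01, 0.1, 1, 10, 100),
               kernel = c("linear", "tanimoto")),
    KNN = list(n_neighbors = 1:30,
               weight = c("uniform", "distance")),
    MLP = list(hidden_layer_size = list(c(50L, 50L, 50L), c(50L, 100L, 50L),
                                        100L),
               solver = c("lbfgs", "adam", "sgd"),
               activation = c("identity", "logistic", "tanh", "relu"),
               learning_rate_init = c(0.01, 0.001, 0.0001, 0.00001)))
}

# enumerate grid points in deterministic order (last parameter fastest)
gridPoints <- function(grid) {
  lens <- vapply(grid, length, 0L)
  idx <- expand.grid(rev(lapply(lens, seq_len)), KEEP.OUT.ATTRS = FALSE)
  idx <- idx[, rev(seq_along(grid)), drop = FALSE]
  names(idx) <- names(grid)
  lapply(seq_len(nrow(idx)), function(r) {
    hp <- list()
    for (p in names(grid)) hp[[p]] <- grid[[p]][[idx[r, p]]]
    hp
  })
}

# ---- evaluation -------------------------------------------------------

#' Confusion-matrix evaluation of binary predictions
#'
#' Active is the positive class. precision = TP/(TP+FP), recall =
#' TP/(TP+FN), accuracy = (TP+TN)/n. An empty denominator yields 0 with a
#' warning.
#'
#' @param predicted,truth character/factor vectors of "active"/"inactive".
#' @return list with TP, TN, FP, FN, accuracy, precision, recall.
#' @examples
#' evaluateBinary(rep(c("active","inactive"), c(4,4)),
#'                rep(c("active","inactive"), each = 4))
#' @export
evaluateBinary <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("prediction/truth length mismatch")
  predicted <- as.character(predicted); truth <- as.character(truth)
  stopifnot(all(predicted %in% c("active", "inactive")),
            all(truth %in% c("active", "inactive")))
  TP <- sum(predicted == "active" & truth == "active")
  TN <- sum(predicted == "inactive" & truth == "inactive")
  FP <- sum(predicted == "active" & truth == "inactive")
  FN <- sum(predicted == "inactive" & truth == "active")
  precision <- if (TP + FP == 0) { warning("no positive predictions; precision set to 0"); 0 } else TP / (TP + FP)
  recall <- if (TP + FN == 0) { warning("no positive truths; recall set to 0"); 0 } else TP / (TP + FN)
  accuracy <- if (TP + TN + FP + FN == 0) 0 else (TP + TN) / (TP + TN + FP + FN)
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       accuracy = accuracy, precision = precision, recall = recall)
}

# ---- training ---------------------------------------------------------

.needsScaling <- function(algorithm, kind)
  kind == "descriptors" && algorithm %in% c("SVM", "KNN", "MLP")

#' Train one classifier
#'
#' @param algorithm "RF", "SVM", "KNN" or "MLP".
#' @param X numeric feature matrix (rows = compounds).
#' @param y factor with levels active/inactive.
#' @param hyperparameters named list from the algorithm's grid domain
#'   (defaults to the first point of the default grid).
#' @param kind the representation kind of X (controls scaling and kernel
#'   admissibility: the Tanimoto kernel requires a binary representation).
#' @param seed integer seed.
#' @param calibrate for SVM, fit the cross-validated sigmoid (Platt)
#'   calibration of decision values (default TRUE). Grid search turns
#'   this off: selection is label-based and the uncalibrated sigmoid
#'   thresholds at the same decision boundary.
#' @return a \linkS4class{TrainedClassifier}.
#' @export
trainClassifier <- function(algorithm, X, y, hyperparameters = NULL,
                            kind = "morgan", seed = 1L, calibrate = TRUE) {
  algorithm <- match.arg(algorithm, c("RF", "SVM", "KNN", "MLP"))
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- factor(as.character(y), levels = c("active", "inactive"))
  if (any(is.na(y))) stop("labels must be active/inactive")
  hp <- hyperparameters %||% gridPoints(defaultGrid(algorithm))[[1]]

  scaler <- NULL
  if (.needsScaling(algorithm, kind)) {
    ctr <- colMeans(X); scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
    scaler <- list(center = ctr, scale = scl)
  }

  fit <- switch(algorithm,
    RF = {
      mtry <- switch(hp$max_features,
        sqrt = max(1L, floor(sqrt(ncol(X)))),
        log2 = max(1L, floor(log2(ncol(X)))),
        all = ncol(X),
        stop("unknown max_features: ", hp$max_features))
      rf <- withSeed(seed, randomForest::randomForest(
        x = X, y = y, ntree = hp$n_estimators, mtry = min(mtry, ncol(X))))
      list(model = rf)
    },
    SVM = .svmFit(X, y, hp, kind, seed, calibrate),
    KNN = list(X = X, y = y, k = hp$n_neighbors, weight = hp$weight),
    MLP = {
      m <- withSeed(seed, suppressMessages(mlpFit(X, as.numeric(y == "active"),
        hidden = as.integer(hp$hidden_layer_size), activation = hp$activation,
        solver = hp$solver, learning_rate_init = hp$learning_rate_init,
        seed = seed)))
      list(model = m)
    })
  fit$scaler <- scaler

  new("TrainedClassifier", algorithm = algorithm, kind = kind,
      hyperparameters = hp, seed = as.integer(seed), fit = fit,
      manifest = list(dataset = datasetChecksum(X, y), n = nrow(X),
                      date = format(Sys.Date())))
}

datasetChecksum <- function(X, y) {
  sprintf("n%d-p%d-a%d-s%.6g", nrow(X), ncol(X), sum(y == "active"),
          sum(X[1, ]) + sum(X[nrow(X), ]))
}

.svmFit <- function(X, y, hp, kind, seed, calibrate = TRUE) {
  if (hp$kernel == "tanimoto") {
    if (kind == "descriptors" || any(!X %in% c(0, 1)))
      stop("the Tanimoto kernel requires a binary representation")
  }
  Kfun <- if (hp$kernel == "tanimoto") tanimotoMatrix else function(A, B = A) A %*% t(B)
  K <- Kfun(X, X)
  fitOne <- function(Ktr, ytr) {
    kernlab::ksvm(kernlab::as.kernelMatrix(Ktr), ytr, type = "C-svc",
                  C = hp$C, scaled = FALSE)
  }
  model <- fitOne(K, y)
  sv0 <- kernlab::SVindex(model)
  dec_tr <- kernlab::predict(model,
    kernlab::as.kernelMatrix(K[, sv0, drop = FALSE]), type = "decision")[, 1]
  # decision sign convention: make positive correspond to "active"
  sgn <- if (mean(dec_tr[y == "active"]) >= mean(dec_tr[y == "inactive"]))
    1 else -1
  if (!calibrate) {
    # uncalibrated PS = sigmoid of the signed decision value; thresholds
    # at the decision boundary, which is all label-based selection needs
    return(list(model = model, Xtrain = X, kernel = hp$kernel,
                platt = NULL, sgn = sgn))
  }
  # cross-validated decision values -> sigmoid (Platt) calibration
  dec_cv <- rep(NA_real_, length(y))
  folds <- stratifiedFolds(y, 3L, childSeed(seed, "platt"))
  for (f in 1:3) {
    tr <- which(folds != f); te <- which(folds == f)
    mf <- tryCatch(fitOne(K[tr, tr, drop = FALSE], y[tr]),
                   error = function(e) NULL)
    if (is.null(mf)) next
    sv <- kernlab::SVindex(mf)
    dec_cv[te] <- kernlab::predict(mf,
      kernlab::as.kernelMatrix(K[te, tr, drop = FALSE][, sv, drop = FALSE]),
      type = "decision")[, 1]
  }
  use <- is.finite(dec_cv)
  platt <- if (sum(use) >= 4 && length(unique(y[use])) == 2) {
    df <- data.frame(d = sgn * dec_cv[use], yy = y[use] == "active")
    suppressWarnings(stats::glm(yy ~ d, family = stats::binomial(), data = df))
  } else NULL
  list(model = model, Xtrain = X, kernel = hp$kernel, platt = platt,
       sgn = sgn)
}

#' Probability score of the active class
#'
#' @param classifier a \linkS4class{TrainedClassifier}.
#' @param X feature matrix in the classifier's representation.
#' @return numeric vector of PS in [0, 1].
#' @export
predictPS <- function(classifier, X) {
  stopifnot(is(classifier, "TrainedClassifier"), is.matrix(X))
  fit <- classifier@fit
  if (!is.null(fit$scaler))
    X <- sweep(sweep(X, 2, fit$scaler$center), 2, fit$scaler$scale, "/")
  ps <- switch(classifier@algorithm,
    RF = as.numeric(stats::predict(fit$model, X, type = "prob")[, "active"]),
    SVM = {
      Kfun <- if (fit$kernel == "tanimoto") tanimotoMatrix
              else function(A, B = A) A %*% t(B)
      Kte <- Kfun(X, fit$Xtrain)
      sv <- kernlab::SVindex(fit$model)
      dec <- kernlab::predict(fit$model,
        kernlab::as.kernelMatrix(Kte[, sv, drop = FALSE]),
        type = "decision")[, 1]
      if (is.null(fit$platt)) {
        1 / (1 + exp(-fit$sgn * dec))
      } else {
        as.numeric(stats::predict(fit$platt,
          newdata = data.frame(d = fit$sgn * dec), type = "response"))
      }
    },
    KNN = .knnPS(fit, X),
    MLP = mlpPredict(fit$model, X))
  pmin(pmax(ps, 0), 1)
}

.knnPS <- function(fit, X) {
  # squared Euclidean distances via the expansion |a-b|^2 = a.a + b.b - 2ab
  d2 <- outer(rowSums(X ^ 2), rowSums(fit$X ^ 2), "+") - 2 * X %*% t(fit$X)
  d2[d2 < 0] <- 0
  k <- min(fit$k, ncol(d2))
  act <- fit$y == "active"
  vapply(seq_len(nrow(X)), function(i) {
    d <- d2[i, ]
    nn <- order(d)[seq_len(k)]
    if (fit$weight == "uniform") {
      mean(act[nn])
    } else {
      dd <- sqrt(d[nn])
      if (any(dd == 0)) return(mean(act[nn][dd == 0]))
      w <- 1 / dd
      sum(w * act[nn]) / sum(w)
    }
  }, 0)
}

#' Predicted labels (PS thresholded at 0.5)
#'
#' @inheritParams predictPS
#' @return character vector "active"/"inactive".
#' @export
predictLabel <- function(classifier, X) {
  ifelse(predictPS(classifier, X) >= 0.5, "active", "inactive")
}

# ---- cross-validation protocols ---------------------------------------

#' Grid-search with 5-fold cross-validation
#'
#' Evaluates every grid point by 5-fold cross-validated accuracy and
#' returns the argmax (ties resolved by deterministic grid order) plus the
#' full ranked table.
#'
#' @param X,y features and labels (both classes required).
#' @param algorithm algorithm family.
#' @param kind representation kind of X.
#' @param grid hyperparameter grid (defaults to \code{defaultGrid}).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed controlling fold assignment and fits.
#' @return list with \code{best} (hyperparameter list), \code{best_index},
#'   and \code{table} (data.frame of grid points with mean CV accuracy).
#' @export
gridSearch <- function(X, y, algorithm, kind = "morgan",
                       grid = defaultGrid(algorithm), folds = 5L, seed = 1L) {
  y <- factor(as.character(y), levels = c("active", "inactive"))
  if (length(unique(y)) < 2) stop("grid search needs both classes")
  pts <- gridPoints(grid)
  if (!length(pts)) stop("empty grid")
  # canonicalize row order by a content hash so the selected
  # hyperparameters are invariant to how the caller ordered the dataset
  key <- hashRows(cbind(X, as.integer(y)))
  ord <- order(key)
  X <- X[ord, , drop = FALSE]; y <- y[ord]
  fold <- stratifiedFolds(y, folds, childSeed(seed, "gridcv"))
  acc <- numeric(length(pts))
  for (pi in seq_along(pts)) {
    hp <- pts[[pi]]
    fa <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold != f
      fitted <- tryCatch(
        trainClassifier(algorithm, X[tr, , drop = FALSE], y[tr],
                        hp, kind, childSeed(seed, paste0("fit", f)),
                        calibrate = FALSE),
        error = function(e) NULL)
      fa[f] <- if (is.null(fitted)) 0 else
        suppressWarnings(evaluateBinary(
          predictLabel(fitted, X[!tr, , drop = FALSE]), y[!tr])$accuracy)
    }
    acc[pi] <- mean(fa)
  }
  best <- which.max(acc)   # first max in deterministic grid order
  tab <- data.frame(index = seq_along(pts),
    hyperparameters = vapply(pts, digest_hp, ""), cv_accuracy = acc)
  tab <- tab[order(-tab$cv_accuracy, tab$index), ]
  list(best = pts[[best]], best_index = best, table = tab)
}

#' Repeated stratified 70/30 split validation
#'
#' The model is trained \code{n_repeats} times on a stratified random 70\%
#' of the data and evaluated on the held-out 30\%; reports per-repeat
#' confusion-matrix metrics and their mean and standard deviation.
#'
#' @param algorithm,kind,hyperparameters model spec.
#' @param X,y features and labels.
#' @param n_repeats number of random splits (default 10).
#' @param train_frac training fraction (default 0.7).
#' @param seed integer seed.
#' @return list with \code{reports} (per repeat), \code{mean_accuracy},
#'   \code{sd_accuracy}, and mean precision/recall.
#' @export
repeatedSplitCV <- function(algorithm, X, y, hyperparameters = NULL,
                            kind = "morgan", n_repeats = 10L,
                            train_frac = 0.7, seed = 1L) {
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  y <- factor(as.character(y), levels = c("active", "inactive"))
  if (length(unique(y)) < 2) stop("both classes required")
  reports <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    tr <- stratifiedSplit(y, train_frac, childSeed(seed, paste0("split", r)))
    te <- setdiff(seq_along(y), tr)
    fitted <- trainClassifier(algorithm, X[tr, , drop = FALSE], y[tr],
                              hyperparameters, kind,
                              childSeed(seed, paste0("rep", r)))
    reports[[r]] <- suppressWarnings(
      evaluateBinary(predictLabel(fitted, X[te, , drop = FALSE]), y[te]))
  }
  accs <- vapply(reports, `[[`, 0, "accuracy")
  list(reports = reports, accuracies = accs,
       mean_accuracy = mean(accs), sd_accuracy = stats::sd(accs),
       mean_precision = mean(vapply(reports, `[[`, 0, "precision")),
       mean_recall = mean(vapply(reports, `[[`, 0, "recall")))
}

#' y-randomization control
#'
#' Per repeat, the training labels are randomly permuted (seeded), the
#' model is refit with the given hyperparameters and evaluated by the same
#' repeated 70/30 protocol used for model selection. A real
#' structure-activity signal yields accuracies near 0.5 under permutation.
#'
#' @param algorithm,kind,hyperparameters model spec.
#' @param X,y features and labels.
#' @param n_repeats number of label permutations.
#' @param n_splits 70/30 splits evaluated per permutation (default 10).
#' @param seed integer seed.
#' @return numeric vector of mean held-out accuracy per permutation.
#' @export
yRandomization <- function(algorithm, X, y, hyperparameters = NULL,
                           kind = "morgan", n_repeats = 10L, n_splits = 10L,
                           seed = 1L) {
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  y <- factor(as.character(y), levels = c("active", "inactive"))
  vapply(seq_len(n_repeats), function(r) {
    yperm <- withSeed(childSeed(seed, paste0("perm", r)), sample(y))
    cv <- repeatedSplitCV(algorithm, X, yperm, hyperparameters, kind,
                          n_repeats = n_splits,
                          seed = childSeed(seed, paste0("ycv", r)))
    cv$mean_accuracy
  }, 0)
}
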