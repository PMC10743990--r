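# Shared fixtures, built in code and memoised so each is constructed at
# most once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# small balanced synthetic dataset (60 + 60), curated, with morgan matrix
fixSmall <- function() fixture("small", function() {
  cfg <- syntheticConfig(n_actives = 60L, n_inactives = 60L, seed = 7L)
  ds <- generateDataset(cfg)
  cur <- suppressWarnings(buildDataset(ds$records, "train"))
  fm <- featurizeDataset(cur, "morgan")
  list(cfg = cfg, records = ds$records, truth = ds$truth, dataset = cur,
       fm = fm, X = featureData(fm), y = activityLabels(cur))
})

# the study-scale dataset (200 + 200 = 400 compounds)
fixLarge <- function() fixture("large", function() {
  cfg <- syntheticConfig(n_actives = 200L, n_inactives = 200L, seed = 17L)
  ds <- generateDataset(cfg)
  cur <- suppressWarnings(buildDataset(ds$records, "train"))
  fm <- featurizeDataset(cur, "morgan")
  list(cfg = cfg, records = ds$records, truth = ds$truth, dataset = cur,
       fm = fm, X = featureData(fm), y = activityLabels(cur))
})

# a KNN + RF consensus trained on the small fixture
fixConsensus <- function() fixture("consensus", function() {
  fx <- fixSmall()
  knn <- trainClassifier("KNN", fx$X, fx$y,
    list(n_neighbors = 5L, weight = "uniform"), "morgan", 3L)
  rf <- trainClassifier("RF", fx$X, fx$y,
    list(max_features = "sqrt", n_estimators = 100L), "morgan", 3L)
  list(knn = knn, rf = rf, consensus = consensusModel(knn, rf))
})

# four distinct untrained classifier stubs (for enumeration tests)
stubModels <- function(n) {
  lapply(seq_len(n), function(i)
    new("TrainedClassifier", algorithm = "KNN", kind = "morgan",
        hyperparameters = list(n_neighbors = i, weight = "uniform"),
        seed = 1L, fit = list(), manifest = list(dataset = "stub")))
}

# classifier whose PS depends on exactly one input bit:
# PS = sigmoid(4 * x[bit] - 2), built on the in-package MLP forward pass
singleBitClassifier <- function(bit, nbits = 2048L) {
  net <- list(par = list(W = list(matrix(4, 1, 1)), b = list(-2)),
              keep = bit, activation = "identity")
  new("TrainedClassifier", algorithm = "MLP", kind = "morgan",
      hyperparameters = list(hidden_layer_size = integer(0), solver = "adam",
                             activation = "identity",
                             learning_rate_init = 0.001),
      seed = 1L, fit = list(model = net), manifest = list(dataset = "stub"))
}

# classifier with constant PS (KNN whose training labels are all active)
constantClassifier <- function(X) {
  yy <- factor(rep("active", nrow(X)), levels = c("active", "inactive"))
  new("TrainedClassifier", algorithm = "KNN", kind = "morgan",
      hyperparameters = list(n_neighbors = 3L, weight = "uniform"),
      seed = 1L, fit = list(X = X, y = yy, k = 3L, weight = "uniform"),
      manifest = list(dataset = "stub"))
}

# random binary matrix with a fixed seed
randomBits <- function(n, p, seed, density = 0.3) {
  set.seed(seed)
  matrix(rbinom(n * p, 1, density), n, p)
}
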