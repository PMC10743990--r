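# Permutation Shapley attribution, bit-to-atom retro-mapping, rendering.

test_that("a constant model receives zero attribution everywhere", {
  fx <- fixSmall()
  const <- constantClassifier(fx$X[1:10, ])
  x <- fx$X[12, ]
  att <- shapAttributions(const, x, fx$X[1:6, ], n_permutations = 2L, seed = 1L)
  expect_true(all(att$scores == 0))
  expect_equal(att$base, att$ps)
})

test_that("a single-feature model puts all attribution on that feature", {
  bit <- 17L
  m <- singleBitClassifier(bit)
  x <- integer(2048); x[bit] <- 1L
  bg <- matrix(0L, 4, 2048)
  bg[2, 40] <- 1L   # irrelevant background variation
  att <- shapAttributions(m, x, bg, n_permutations = 3L, seed = 2L)
  expect_gt(att$scores[bit], 0)
  expect_true(all(att$scores[-bit] == 0))
  expect_equal(att$base + sum(att$scores), att$ps, tolerance = 1e-12)
})

test_that("additivity holds within 1e-6 for real trained models", {
  fc <- fixConsensus(); fx <- fixSmall()
  bg <- fx$X[seq(1, 120, by = 10), ]
  x <- fx$X[3, ]
  for (m in list(fc$knn, fc$rf)) {
    att <- shapAttributions(m, x, bg, n_permutations = 3L, seed = 5L)
    expect_lt(abs(att$base + sum(att$scores) - att$ps), 1e-6)
    # determinism under the seed
    att2 <- shapAttributions(m, x, bg, n_permutations = 3L, seed = 5L)
    expect_identical(att$scores, att2$scores)
  }
  expect_error(shapAttributions(fc$knn, x, bg[0, , drop = FALSE]),
               "non-empty")
})

test_that("atom weight arithmetic follows fc / (n_Atoms * n_occ)", {
  # one bit, fc = 0.6, one environment of 3 atoms -> 0.2 per atom
  att <- list(list(scores = c(rep(0, 4), 0.6), base = 0, ps = 0.6))
  map <- list(`5` = list(n_occ = 1L, environments = list(c(1L, 2L, 3L))))
  aw <- atomWeights(att, map, 4L)
  expect_equal(aw$weights, c(0.2, 0.2, 0.2, 0))

  # one bit, fc = 0.4, two environments of 2 atoms each (n_occ = 2):
  # each environment membership contributes 0.4 / (2*2) = 0.1
  att2 <- list(list(scores = c(0.4, rep(0, 3)), base = 0, ps = 0.4))
  map2 <- list(`1` = list(n_occ = 2L,
                          environments = list(c(1L, 2L), c(2L, 3L))))
  aw2 <- atomWeights(att2, map2, 3L)
  expect_equal(aw2$weights, c(0.1, 0.2, 0.1))

  # an atom in two bits accumulates: 0.2/2 + 0.3/3 = 0.2
  att3 <- list(list(scores = c(0.2, 0.3), base = 0, ps = 0.5))
  map3 <- list(`1` = list(n_occ = 1L, environments = list(c(1L, 2L))),
               `2` = list(n_occ = 1L, environments = list(c(1L, 3L, 4L))))
  aw3 <- atomWeights(att3, map3, 4L)
  expect_equal(aw3$weights[1], 0.2)

  # a scored bit missing from the map warns and is excluded
  att4 <- list(list(scores = c(0.2, 0.7), base = 0, ps = 0.9))
  map4 <- list(`1` = list(n_occ = 1L, environments = list(c(1L, 2L))))
  expect_warning(aw4 <- atomWeights(att4, map4, 4L), "not present")
  expect_equal(aw4$weights, c(0.1, 0.1, 0, 0))
  expect_equal(aw4$mapped_score_sum, 0.2)
})

test_that("per-model conservation holds to 1e-9 end to end", {
  fc <- fixConsensus(); fx <- fixSmall()
  bg <- fx$X[seq(1, 120, by = 10), ]
  i <- which(fx$truth$class == "active")[2]
  sm <- fx$truth$smiles[i]
  ex <- suppressWarnings(explainCompound(fc$consensus, sm, bg,
                                         n_permutations = 3L, seed = 9L))
  for (mi in seq_along(members(fc$consensus)))
    expect_lt(abs(sum(ex$per_model[, mi]) - ex$mapped_score_sum[mi]), 1e-9)
  # averaging identical members reproduces a single member's weights
  m2 <- fc$knn; m2@hyperparameters$n_neighbors <- 99L  # distinct spec
  m2@fit <- fc$knn@fit                                 # same behavior
  twin <- consensusModel(fc$knn, m2)
  ex2 <- suppressWarnings(explainCompound(twin, sm, bg,
                                          n_permutations = 3L, seed = 9L))
  expect_equal(ex2$per_model[, 1], ex2$weights, tolerance = 1e-12)
})

test_that("planted scaffold atoms dominate the explanation of actives", {
  fc <- fixConsensus(); fx <- fixSmall()
  bg <- fx$X[seq(1, 120, by = 6), ]
  idx <- which(fx$truth$class == "active")[1:8]
  wins <- 0L; considered <- 0L
  for (i in idx) {
    sm <- fx$truth$smiles[i]
    x <- consensusVS:::morganFP(consensusVS:::molgraph(sm))$bits
    pred_cs <- mean(vapply(members(fc$consensus), function(m)
      predictPS(m, matrix(x, 1)), 0))
    if (pred_cs < 0.5) next   # only correctly predicted actives count
    considered <- considered + 1L
    ex <- suppressWarnings(explainCompound(fc$consensus, sm, bg,
                                           n_permutations = 3L, seed = 3L))
    planted <- fx$truth$planted_atoms[[i]]
    if (mean(ex$weights[planted]) > mean(ex$weights[-planted]))
      wins <- wins + 1L
  }
  expect_gte(considered, 5L)
  expect_gte(wins / considered, 0.8)
})

test_that("atom weight rendering writes an image file", {
  fx <- fixSmall()
  sm <- fx$truth$smiles[1]
  g <- consensusVS:::molgraph(sm)
  w <- numeric(g$n); w[1:3] <- c(0.5, -0.2, 0.1)
  path <- file.path(tempdir(), "weights.png")
  renderAtomWeights(sm, w, path)
  expect_true(file.exists(path))
  expect_gt(file.size(path), 1000)
  # all-zero weights still draw the bare skeleton
  path2 <- file.path(tempdir(), "zero.png")
  renderAtomWeights(sm, numeric(g$n), path2)
  expect_true(file.exists(path2))
  expect_error(renderAtomWeights(sm, w[-1], path), "one weight per atom")
  unlink(c(path, path2))
})
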