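# Screening funnel: CS cutoff, novelty filter, clustering, PAINS.

test_that("the CS cutoff is inclusive at the boundary", {
  # two single-bit stub members give exact, controllable CS values
  m1 <- singleBitClassifier(1L)
  m2 <- singleBitClassifier(1L)
  m2@hyperparameters$learning_rate_init <- 0.01   # distinct spec
  cm <- consensusModel(m1, m2)
  x_on <- matrix(0L, 2, 2048); x_on[1, 1] <- 1L
  fm <- new("FeatureMatrix", kind = "morgan", ids = c("on", "off"),
            data = x_on)
  pred <- predictConsensus(cm, fm)
  ps_on <- 1 / (1 + exp(-2)); ps_off <- 1 / (1 + exp(2))
  expect_equal(pred$cs, c(ps_on, ps_off))
  sw <- thresholdSweep(pred, c("active", "inactive"), thresholds = ps_on)
  expect_equal(sw$n_predicted_active, 1L)
})

test_that("screening retains exactly the compounds at or above the cutoff", {
  fc <- fixConsensus(); fx <- fixSmall()
  lib <- setNames(fx$dataset@smiles, fx$dataset@ids)
  hits_all <- screenLibrary(fc$consensus, lib, cs_cutoff = 0.5)
  # training actives re-screened at 0.5: essentially all recovered
  act_ids <- fx$dataset@ids[fx$y == "active"]
  expect_gte(mean(act_ids %in% hits_all$compound_id), 0.95)
  hits_hi <- screenLibrary(fc$consensus, lib, cs_cutoff = 0.8)
  # nested funnels: raising the cutoff never adds hits
  expect_true(all(hits_hi$compound_id %in% hits_all$compound_id))
  expect_true(all(hits_hi$cs >= 0.8))
  expect_equal(attr(hits_all, "n_screened"), length(lib))
  expect_error(screenLibrary(fc$consensus, lib, cs_cutoff = 0.3), "0.5")
  expect_warning(screenLibrary(fc$consensus, character(0)), "empty")
})

test_that("novelty filter removes similarity >= 0.40, keeps below", {
  fx <- fixSmall()
  # a hit identical to a training compound has similarity 1 -> removed
  hits <- data.frame(compound_id = c("dup", "far"),
    smiles = c(fx$dataset@smiles[1], "OCC(O)CO"),
    cs = c(0.9, 0.9), stringsAsFactors = FALSE)
  out <- noveltyFilter(hits, fx$dataset)
  expect_false("dup" %in% out$compound_id)
  expect_true("far" %in% out$compound_id)
  expect_true(all(out$max_train_similarity < 0.40))
  expect_error(noveltyFilter(hits, fx$dataset[0]), "empty")
})

test_that("clustering is deterministic sphere exclusion with CS reps", {
  # three dissimilar compounds -> three singleton clusters
  far <- data.frame(compound_id = c("a", "b", "c"),
    smiles = c("CCCCCCCC", "c1ccc2ccccc2c1", "OC(=O)CN"),
    cs = c(0.9, 0.8, 0.7), stringsAsFactors = FALSE)
  cl <- clusterHits(far)
  expect_equal(sort(unique(cl$cluster_id)), 1:3)
  expect_true(all(cl$is_cluster_representative))
  # duplicate structures cluster together; higher CS is representative
  dup <- data.frame(compound_id = c("low", "high"),
    smiles = rep("CC(=O)Nc1ccc(O)cc1", 2),
    cs = c(0.81, 0.93), stringsAsFactors = FALSE)
  cl2 <- clusterHits(dup)
  expect_equal(cl2$cluster_id, c(1L, 1L))
  expect_equal(cl2$compound_id[cl2$is_cluster_representative], "high")
  # CS tie -> lexicographically smallest id
  tie <- dup; tie$cs <- c(0.9, 0.9); tie$compound_id <- c("zz", "aa")
  cl3 <- clusterHits(tie)
  expect_equal(cl3$compound_id[cl3$is_cluster_representative], "aa")
  # determinism
  expect_identical(clusterHits(far), clusterHits(far))
})

test_that("PAINS annotation flags archetypes and passes clean molecules", {
  al <- painsAlerts(c("O=C1C=CC(=O)C=C1",     # para-quinone
                      "Oc1ccccc1O",           # catechol
                      "CCO",                  # ethanol: clean
                      "CC(=O)Nc1ccc(O)cc1"))  # paracetamol: clean here
  expect_true("quinone_A" %in% al[[1]])
  expect_true("catechol_A" %in% al[[2]])
  expect_length(al[[3]], 0L)
  hits <- data.frame(compound_id = c("q", "e"),
    smiles = c("O=C1C=CC(=O)C=C1", "CCO"), cs = c(0.9, 0.9),
    stringsAsFactors = FALSE)
  ann <- painsFilter(hits)
  expect_equal(ann$pains_pass, c(FALSE, TRUE))
  expect_equal(nrow(ann), 2L)    # annotated, not removed
  empty <- painsFilter(hits[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("the funnel is monotone and its counts reconcile", {
  fc <- fixConsensus(); fx <- fixSmall()
  lib <- generateScreeningLibrary(fx$cfg, n_library = 60, hit_fraction = 0.25)
  std <- standardizeLibrary(lib$smiles)
  res <- runFunnel(fc$consensus, std, fx$dataset)
  f <- res$funnel
  expect_true(f["library"] >= f["cs_pass"])
  expect_true(f["cs_pass"] >= f["novel"])
  expect_true(f["novel"] >= f["clusters"])
  expect_true(f["clusters"] >= f["selected"])
  expect_equal(unname(f["library"]), length(std))
  if (f["novel"] > 0) {
    expect_equal(unname(f["clusters"]), max(res$hits$cluster_id))
    expect_true(all(res$hits$cs >= 0.8))
    expect_true(all(res$hits$max_train_similarity < 0.40))
    # survivors are enriched in true planted-scaffold analogs
    is_analog <- lib$truth$is_analog[match(res$hits$compound_id,
                                           lib$truth$compound_id)]
    expect_gte(mean(is_analog), 0.8)
  }
  expect_true(all(res$selected$pains_pass))
})
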