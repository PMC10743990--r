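# Standardization, replicate aggregation, labeling and dataset building.

test_that("standardization strips salts, neutralizes and canonicalizes", {
  s <- standardizeSmiles("CC(=O)[O-].[Na+]")
  expect_true(s$ok)
  g <- consensusVS:::molgraph(s$smiles_std)
  expect_equal(sort(g$elem), c("C", "C", "O", "O"))   # one neutral fragment
  expect_true(all(g$charge == 0))

  ident <- standardizeSmiles("CCO")
  expect_true(ident$ok)
  expect_equal(consensusVS:::molgraph(ident$smiles_std)$elem, c("C", "C", "O"))

  # same structure under SMILES aliasing -> same structure key
  k1 <- standardizeSmiles("c1ccccc1O")$structure_key
  k2 <- standardizeSmiles("Oc1ccccc1")$structure_key
  expect_identical(k1, k2)
})

test_that("unparseable input yields a structured rejection, not an error", {
  r <- standardizeSmiles("C1CC")        # unclosed ring
  expect_false(r$ok)
  expect_identical(r$input, "C1CC")
  expect_false(standardizeSmiles("")$ok)
  expect_false(standardizeSmiles("[Na+]")$ok)   # zero organic heavy atoms
})

test_that("replicate aggregation follows the single-pass 25% rule", {
  expect_equal(aggregatePotency(0.2), 0.2)
  expect_equal(aggregatePotency(c(0.10, 0.20)), 0.15)
  # 0.16 deviates 33% from mean 0.12 and is removed
  expect_equal(aggregatePotency(c(0.10, 0.10, 0.16)), 0.10)
  # mean 0.4667: 0.10 (78.6%) and 0.90 (92.9%) are removed, 0.40 (14.3%)
  # survives, so the result is 0.40 - not a discard
  expect_equal(aggregatePotency(c(0.10, 0.40, 0.90)), 0.40)
  # all values > 25% off the mean -> discard
  expect_true(is.na(aggregatePotency(c(0.1, 1.0))) == FALSE)
  expect_true(is.na(aggregatePotency(c(0.01, 1, 100))))
  expect_error(aggregatePotency(c(0.1, -1)), "positive")
})

test_that("labeling respects the 0.1 / 0.5 uM thresholds inclusively", {
  expect_equal(assignLabel(c(0.05, 0.1, 0.100001, 0.3, 0.499, 0.5, 0.6)),
    c("active", "active", "excluded", "excluded", "excluded", "inactive",
      "inactive"))
  expect_error(assignLabel(0), "positive")
})

test_that("buildDataset composes the rules and keeps a reconciling audit", {
  rec <- data.frame(
    compound_id = c("a", "a", "a", "b", "c", "d", "e"),
    smiles = c("CCO", "OCC", "CCO", "c1ccccc1O", "CCN", "CCCC", "C1CC"),
    potency_um = c(0.10, 0.10, 0.16, 0.05, 5.0, 0.2, 1),
    potency_type = "IC50", relation = c(rep("=", 6), "="),
    stringsAsFactors = FALSE)
  ds <- suppressWarnings(buildDataset(rec, "train"))
  tab <- datasetTable(ds)
  # replicate group a: aggregated to 0.10, active
  expect_equal(tab$potency_um[tab$compound_id == "a"], 0.10)
  expect_equal(tab$label[tab$compound_id == "a"], "active")
  expect_equal(tab$n_used[tab$compound_id == "a"], 2L)
  expect_equal(tab$n_raw[tab$compound_id == "a"], 3L)
  # one active (b), one inactive (c); d excluded; e unparseable
  expect_setequal(tab$label, c("active", "active", "inactive"))
  expect_true(all(tab$potency_um <= 0.1 | tab$potency_um >= 0.5))
  # conservation: every input record is either in a retained group or audited
  expect_equal(nrow(rec), sum(tab$n_raw) + nrow(auditLog(ds)))
  expect_setequal(auditLog(ds)$reason,
    c("potency in excluded band (0.1-0.5 uM)", "unparseable SMILES"))
})

test_that("censored relations and mixed potency types are handled", {
  rec <- data.frame(compound_id = c("a", "b"), smiles = c("CCO", "CCN"),
    potency_um = c(0.05, 0.05), potency_type = "IC50",
    relation = c("=", ">"), stringsAsFactors = FALSE)
  ds <- buildDataset(rec, "train")
  expect_equal(length(ds), 1L)
  expect_equal(auditLog(ds)$reason, "censored relation")

  rec$relation <- "="
  rec$potency_type <- c("IC50", "Ki")
  expect_error(buildDataset(rec, "train"), "mixed potency types")

  one <- data.frame(compound_id = "x", smiles = "CCO", potency_um = 0.2,
                    potency_type = "IC50", relation = "=")
  expect_error(buildDataset(one, "train"), "empty dataset")
})

test_that("curation is idempotent and deterministic", {
  fx <- fixSmall()
  ds1 <- suppressWarnings(buildDataset(fx$records, "train"))
  ds2 <- suppressWarnings(buildDataset(fx$records, "train"))
  expect_identical(datasetTable(ds1), datasetTable(ds2))
  expect_identical(auditLog(ds1), auditLog(ds2))
  # re-curating the curated table reproduces it exactly
  tab <- datasetTable(ds1)
  rec2 <- data.frame(compound_id = tab$compound_id, smiles = tab$smiles,
    potency_um = tab$potency_um, potency_type = "IC50", relation = "=",
    stringsAsFactors = FALSE)
  ds3 <- buildDataset(rec2, "train")
  t3 <- datasetTable(ds3)
  expect_equal(t3$smiles, tab$smiles)
  expect_equal(t3$potency_um, tab$potency_um)
  expect_equal(t3$label, tab$label)
  expect_equal(nrow(auditLog(ds3)), 0L)
})

test_that("the excluded potency band is empty in every curated output", {
  fx <- fixSmall()
  p <- potencies(fx$dataset)
  expect_false(any(p > 0.1 & p < 0.5))
  expect_true(validObject(fx$dataset))
})
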