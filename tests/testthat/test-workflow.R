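# IO, configuration round-trips and the end-to-end pipeline driver.

test_that("activity CSV ingestion normalizes units to micromolar", {
  path <- file.path(tempdir(), "act.csv")
  write.csv(data.frame(
    compound_id = c("a", "b", "c", "d"),
    smiles = c("CCO", "CCN", "CCC", "CCS"),
    value = c(50, 0.05, 0.00005, 5e-8),
    units = c("nM", "uM", "mM", "M"),
    type = "IC50", relation = "="), path, row.names = FALSE)
  tab <- readActivityTable(path)
  expect_equal(tab$potency_um, rep(0.05, 4))
  write.csv(data.frame(compound_id = "a", smiles = "CCO", value = 1,
                       units = "furlongs", type = "IC50"), path,
             row.names = FALSE)
  expect_error(readActivityTable(path), "units")
  unlink(path)
})

test_that("SMILES files round-trip with ids", {
  path <- file.path(tempdir(), "lib.smi")
  sm <- c(m1 = "CCO", m2 = "c1ccccc1")
  writeSmilesFile(sm, path)
  back <- readSmilesFile(path)
  expect_identical(back, sm)
  unlink(path)
})

test_that("run configuration round-trips through YAML unchanged", {
  cfg <- runConfig(train_table = "x.csv", library = "y.smi",
                   cs_cutoff = 0.85, seed = 42L)
  path <- file.path(tempdir(), "cfg.yaml")
  writeRunConfig(cfg, path)
  cfg2 <- readRunConfig(path)
  expect_equal(cfg2$cs_cutoff, 0.85)
  expect_equal(cfg2$seed, 42L)
  expect_equal(cfg2$train_table, "x.csv")
  expect_equal(cfg2$algorithms, cfg$algorithms)
  # serialize -> parse -> serialize is identity on bytes
  path2 <- file.path(tempdir(), "cfg2.yaml")
  writeRunConfig(cfg2, path2)
  expect_identical(readLines(path), readLines(path2))
  expect_error(runConfig(cs_cutoff = 1.4), "out of range")
  expect_error(runConfig(nonsense = 1), "unknown config fields")
  unlink(c(path, path2))
})

test_that("the pipeline driver runs end to end with reconciling logs", {
  dir <- file.path(tempdir(), "cvs_run")
  unlink(dir, recursive = TRUE)
  cfg0 <- syntheticConfig(n_actives = 25L, n_inactives = 25L, seed = 13L)
  ds <- generateDataset(cfg0)
  tab <- ds$records
  tab$value <- tab$potency_um; tab$units <- "uM"; tab$type <- tab$potency_type
  act_path <- file.path(tempdir(), "pipeline_act.csv")
  write.csv(tab[c("compound_id", "smiles", "value", "units", "type",
                  "relation")], act_path, row.names = FALSE)
  lib <- generateScreeningLibrary(cfg0, 30, 0.2)
  lib_path <- file.path(tempdir(), "pipeline_lib.smi")
  writeSmilesFile(lib$smiles, lib_path)

  cfg <- runConfig(train_table = act_path, library = lib_path,
                   output_dir = dir, seed = 5L)
  res <- suppressWarnings(runPipeline(cfg, grid_search = FALSE))
  expect_true(file.exists(file.path(dir, "curated_train.csv")))
  expect_true(file.exists(file.path(dir, "hits.csv")))
  expect_true(file.exists(file.path(dir, "run_log.json")))
  log <- jsonlite::read_json(file.path(dir, "run_log.json"))
  expect_equal(log$n_records, nrow(tab))
  # conservation: input records = records consumed by curated compounds
  # plus audited drops
  cur <- read.csv(file.path(dir, "curated_train.csv"))
  expect_equal(sum(cur$n_raw) + log$n_dropped, log$n_records)
  expect_equal(log$funnel$library, length(lib$smiles))
  expect_true(log$funnel$cs_pass >= log$funnel$novel)

  # rerun with the same config + seed produces identical artifacts
  dir2 <- file.path(tempdir(), "cvs_run2")
  cfg2 <- runConfig(train_table = act_path, library = lib_path,
                    output_dir = dir2, seed = 5L)
  res2 <- suppressWarnings(runPipeline(cfg2, grid_search = FALSE))
  expect_identical(readLines(file.path(dir, "hits.csv")),
                   readLines(file.path(dir2, "hits.csv")))
  unlink(c(dir, dir2, act_path, lib_path), recursive = TRUE)
})
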