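# Readers/writers, run configuration and the end-to-end pipeline driver.

#' Read a raw activity table from CSV
#'
#' Expects columns compound_id, smiles, value, units, type and optionally
#' relation. Potencies are normalized to micromolar at ingest; recognized
#' units are nM, uM (or \enc{µ}{u}M), mM and M.
#'
#' @param path CSV file path.
#' @return data.frame with compound_id, smiles, potency_um, potency_type,
#'   relation.
#' @export
readActivityTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("compound_id", "smiles", "value", "units", "type")
  if (!all(req %in% names(df)))
    stop("activity CSV needs columns: ", paste(req, collapse = ", "))
  fac <- c(nM = 1e-3, uM = 1, "µM" = 1, mM = 1e3, M = 1e6)
  u <- df$units
  if (any(!u %in% names(fac))) stop("unrecognized units: ",
    paste(unique(u[!u %in% names(fac)]), collapse = ", "))
  data.frame(compound_id = as.character(df$compound_id), smiles = df$smiles,
    potency_um = df$value * unname(fac[u]), potency_type = df$type,
    relation = if ("relation" %in% names(df)) df$relation else "=",
    stringsAsFactors = FALSE)
}

#' Read a SMILES file (.smi): one record per line, SMILES then id
#'
#' @param path file path.
#' @return named character vector of SMILES.
#' @export
readSmilesFile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  sm <- vapply(parts, `[[`, "", 1)
  ids <- vapply(seq_along(parts), function(i)
    if (length(parts[[i]]) >= 2) parts[[i]][2] else sprintf("mol_%05d", i), "")
  stats::setNames(sm, ids)
}

#' Write a SMILES file
#' @param smiles named character vector.
#' @param path output path.
#' @export
writeSmilesFile <- function(smiles, path) {
  writeLines(paste(smiles, names(smiles) %||% seq_along(smiles)), path)
  invisible(path)
}

#' Read molecules from an SDF file
#'
#' @param path SDF (V2000) file path.
#' @return named character vector of SMILES (converted via OpenBabel).
#' @export
readSdfFile <- function(path) {
  sdfs <- ChemmineR::read.SDFset(path)
  sm <- ChemmineR::sdf2smiles(sdfs)
  out <- as.character(sm)
  nm <- ChemmineR::sdfid(sdfs)
  stats::setNames(trimws(sub("\\s.*$", "", out)), nm)
}

#' Standardize a screening library
#'
#' Applies the same standardization used during curation (largest organic
#' fragment, charge neutralization, canonical SMILES); failures are
#' dropped and reported in the \code{rejected} attribute.
#'
#' @param smiles named character vector of raw SMILES.
#' @return named character vector of standardized SMILES.
#' @export
standardizeLibrary <- function(smiles) {
  out <- character(0); rej <- list()
  for (i in seq_along(smiles)) {
    s <- standardizeSmiles(smiles[[i]])
    if (s$ok) out[names(smiles)[i] %||% as.character(i)] <- s$smiles_std
    else rej[[length(rej) + 1L]] <- list(id = names(smiles)[i],
                                         input = smiles[[i]],
                                         reason = s$reason)
  }
  structure(out, rejected = rej)
}

#' Run configuration with the published default settings
#'
#' Defaults reproduce the study settings: activity thresholds 0.1 / 0.5
#' uM, consensus-score screening cutoff 0.8, Tanimoto novelty cutoff
#' 0.40, clustering similarity cutoff 0.70, default hyperparameter grids.
#'
#' @param ... overrides for any field.
#' @return list of class \code{runConfig}.
#' @export
runConfig <- function(...) {
  cfg <- list(
    train_table = NULL, test_table = NULL, library = NULL, output_dir = ".",
    representations = "morgan", algorithms = c("KNN", "RF"),
    active_um = 0.1, inactive_um = 0.5,
    cs_cutoff = 0.8, novelty_cutoff = 0.40, cluster_cutoff = 0.70,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (cfg$cs_cutoff < 0.5 || cfg$cs_cutoff > 1 ||
      cfg$novelty_cutoff < 0 || cfg$novelty_cutoff > 1 ||
      cfg$cluster_cutoff < 0 || cfg$cluster_cutoff > 1)
    stop("thresholds out of range")
  structure(cfg, class = "runConfig")
}

#' Read / write a run configuration as YAML
#' @param path YAML file.
#' @return a \code{runConfig}.
#' @export
readRunConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}

#' @rdname readRunConfig
#' @param config a \code{runConfig} to serialize.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, TRUE)], path)
  invisible(path)
}

#' End-to-end pipeline: curate, tune, train, combine, screen
#'
#' Thin driver over the module functions; writes versioned artifacts
#' (curated tables, CV tables, hit tables, funnel summary and a run log
#' with seeds and stage counts) into the configured output directory.
#'
#' @param config a \code{\link{runConfig}} whose \code{train_table} and
#'   \code{library} point at existing files.
#' @param grid_search run hyperparameter grid search (default TRUE; FALSE
#'   uses each algorithm's first grid point).
#' @return list with dataset, models, consensus, funnel results and the
#'   run log, invisibly; artifacts on disk.
#' @export
runPipeline <- function(config, grid_search = TRUE) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(seed = config$seed, started = format(Sys.time()))

  records <- readActivityTable(config$train_table)
  dataset <- buildDataset(records, "train")
  log$n_records <- nrow(records)
  log$n_curated <- length(dataset)
  log$n_dropped <- nrow(auditLog(dataset))
  utils::write.csv(datasetTable(dataset),
    file.path(config$output_dir, "curated_train.csv"), row.names = FALSE)
  writeLines(apply(auditLog(dataset), 1, paste, collapse = "\t"),
    file.path(config$output_dir, "curation_audit.log"))

  kind <- config$representations[1]
  fm <- featurizeDataset(dataset, kind)
  y <- activityLabels(dataset)

  models <- list()
  for (alg in config$algorithms) {
    hp <- if (grid_search) {
      gs <- gridSearch(featureData(fm), y, alg, kind,
                       seed = childSeed(config$seed, paste0("gs", alg)))
      utils::write.csv(gs$table,
        file.path(config$output_dir, sprintf("cv_table_%s_%s.csv", alg, kind)),
        row.names = FALSE)
      gs$best
    } else NULL
    models[[paste0(alg, "_", kind)]] <- trainClassifier(alg, featureData(fm),
      y, hp, kind, childSeed(config$seed, paste0("fit", alg)))
  }
  log$models <- names(models)

  cons <- consensusModel(models)
  lib <- standardizeLibrary(readSmilesFile(config$library))
  log$n_library <- length(lib)
  log$n_library_rejected <- length(attr(lib, "rejected"))

  res <- runFunnel(cons, lib, dataset, config$cs_cutoff,
                   config$novelty_cutoff, config$cluster_cutoff)
  log$funnel <- as.list(res$funnel)
  utils::write.csv(res$hits, file.path(config$output_dir, "hits.csv"),
                   row.names = FALSE)
  jsonlite::write_json(log, file.path(config$output_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dataset = dataset, models = models, consensus = cons,
                 funnel = res, log = log))
}
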