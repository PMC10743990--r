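# Virtual-screening funnel: consensus cutoff, Tanimoto novelty filter,
# sphere-exclusion clustering and PAINS alert annotation.

#' Screen a compound library with a consensus model
#'
#' Standardizes nothing (the library must already be standardized, e.g.
#' through \code{\link{standardizeLibrary}}), featurizes per member
#' representation in chunks (bounded memory), computes CS and keeps
#' compounds with CS at or above the cutoff.
#'
#' @param consensus a \linkS4class{ConsensusModel}.
#' @param smiles character vector of standardized SMILES (named by id, or
#'   \code{ids} given separately).
#' @param cs_cutoff retain CS >= this value (default 0.8; must lie in
#'   [0.5, 1]).
#' @param ids compound identifiers.
#' @param chunk_size compounds featurized per chunk.
#' @return data.frame of hits (compound_id, smiles, member PS columns,
#'   cs), with attribute \code{n_screened}.
#' @export
screenLibrary <- function(consensus, smiles, cs_cutoff = 0.8, ids = NULL,
                          chunk_size = 500L) {
  stopifnot(is(consensus, "ConsensusModel"))
  if (cs_cutoff < 0.5 || cs_cutoff > 1)
    stop("cs_cutoff must lie in [0.5, 1]")
  if (!length(smiles)) {
    warning("empty screening library")
    return(structure(data.frame(), n_screened = 0L))
  }
  if (is.null(ids)) ids <- names(smiles) %||% sprintf("lib_%06d", seq_along(smiles))
  kinds <- unique(vapply(consensus@members, function(m) m@kind, ""))
  out <- list()
  for (s in seq(1, length(smiles), by = chunk_size)) {
    e <- min(s + chunk_size - 1, length(smiles))
    fms <- lapply(kinds, function(k) featurize(smiles[s:e], k, ids = ids[s:e]))
    names(fms) <- kinds
    pred <- predictConsensus(consensus, fms)
    pred$smiles <- smiles[s:e][match(pred$compound_id, ids[s:e])]
    out[[length(out) + 1L]] <- pred[pred$cs >= cs_cutoff, , drop = FALSE]
  }
  hits <- do.call(rbind, out)
  rownames(hits) <- NULL
  structure(hits, n_screened = length(smiles))
}

#' Remove screening hits similar to training compounds
#'
#' Computes the maximum Tanimoto similarity (circular fingerprint, 2048
#' bits) of each hit against all training compounds and removes hits with
#' a maximum at or above the cutoff; survivors carry their novelty score
#' in \code{max_train_similarity}.
#'
#' @param hits data.frame from \code{\link{screenLibrary}} (needs columns
#'   compound_id, smiles).
#' @param train a \linkS4class{LabeledDataset} (non-empty).
#' @param max_sim removal threshold (default 0.40: a hit with similarity
#'   >= 0.40 to any training compound is removed).
#' @return filtered hits with the novelty column added.
#' @export
noveltyFilter <- function(hits, train, max_sim = 0.40) {
  stopifnot(is(train, "LabeledDataset"))
  if (length(train) == 0) stop("empty training set")
  if (!nrow(hits)) return(cbind(hits, max_train_similarity = numeric(0)))
  fm_hits <- featurize(hits$smiles, "morgan", ids = hits$compound_id)
  fm_train <- featurize(train@smiles, "morgan", ids = train@ids)
  S <- tanimotoMatrix(fm_hits@data, fm_train@data)
  hits$max_train_similarity <- apply(S, 1, max)
  hits[hits$max_train_similarity < max_sim, , drop = FALSE]
}

#' Sphere-exclusion (Butina-style) clustering of hits
#'
#' Clusters hits on the subgraph-based fingerprint at a Tanimoto
#' similarity threshold: compounds are visited in decreasing order of
#' neighbor count (ties by input order), each unassigned visited compound
#' founds a cluster absorbing its unassigned neighbors. Within each
#' cluster the highest-CS member is flagged representative (CS ties break
#' to the lexicographically smallest compound_id). Deterministic and
#' seedless.
#'
#' @param hits data.frame with compound_id, smiles, cs.
#' @param sim_cutoff similarity threshold (default 0.70).
#' @param kind fingerprint kind used for clustering (default "rdkit").
#' @return hits with cluster_id and is_cluster_representative columns.
#' @export
clusterHits <- function(hits, sim_cutoff = 0.70, kind = "rdkit") {
  if (!nrow(hits)) {
    hits$cluster_id <- integer(0)
    hits$is_cluster_representative <- logical(0)
    return(hits)
  }
  fm <- featurize(hits$smiles, kind, ids = hits$compound_id)
  S <- tanimotoMatrix(fm@data)
  n <- nrow(hits)
  nb <- lapply(seq_len(n), function(i) which(S[i, ] >= sim_cutoff & seq_len(n) != i))
  ord <- order(-lengths(nb), seq_len(n))
  cluster <- rep(NA_integer_, n)
  cid <- 0L
  for (i in ord) {
    if (!is.na(cluster[i])) next
    cid <- cid + 1L
    cluster[i] <- cid
    for (j in nb[[i]]) if (is.na(cluster[j])) cluster[j] <- cid
  }
  hits$cluster_id <- cluster
  hits$is_cluster_representative <- FALSE
  for (c_ in seq_len(cid)) {
    idx <- which(cluster == c_)
    best <- idx[order(-hits$cs[idx], hits$compound_id[idx])][1]
    hits$is_cluster_representative[best] <- TRUE
  }
  hits
}

# Curated subset of the published pan-assay-interference (PAINS)
# substructure families, matched by SMARTS via OpenBabel. This is a
# representative subset of the open A/B/C catalogs, not the full list.
.PAINS_SMARTS <- c(
  quinone_A          = "O=C1C=CC(=O)C=C1",
  ortho_quinone_A    = "O=C1C(=O)C=CC=C1",
  catechol_A         = "Oc1ccccc1O",
  hydroquinone_A     = "Oc1ccc(O)cc1",
  azo_A              = "cN=Nc",
  ene_rhod_A         = "C=C1SC(=S)NC1=O",
  thiaz_ene_A        = "C=C1SC(=N)NC1=O",
  ene_five_het_A     = "C=C1C(=O)NC(=O)S1",
  alkylidene_barb_A  = "C=C1C(=O)NC(=O)NC1=O",
  hzone_phenol_A     = "Oc1ccccc1C=NN",
  hzone_acyl_A       = "O=CNN=Cc1ccccc1",
  anil_di_alk_ene_A  = "C(=Cc1ccccc1)C(=O)",
  mannich_A          = "Oc1ccccc1CN",
  imine_one_A        = "C(=O)C=Nc1ccccc1",
  thio_urea_B        = "NC(=S)Nc1ccccc1",
  nitroso_B          = "N=O",
  diazonium_B        = "[N+]#N",
  beta_keto_sulfone  = "O=S(=O)CC(=O)",
  acyl_hydrazide_B   = "C(=O)NNC(=O)",
  isothiocyanate_B   = "N=C=S",
  epoxide_C          = "C1OC1",
  aziridine_C        = "C1NC1",
  michael_nitrile_C  = "C=CC#N",
  anhydride_C        = "C(=O)OC(=O)")

#' Annotate screening hits with PAINS substructure alerts
#'
#' Matches every hit against a curated catalog of pan-assay interference
#' substructure patterns. All hits are returned annotated; compounds with
#' one or more alerts carry \code{pains_pass = FALSE} and are meant to be
#' excluded from the final selection.
#'
#' @param hits data.frame with a \code{smiles} column (may be empty).
#' @return hits with \code{pains_alerts} (semicolon-joined alert names,
#'   "" when clean) and \code{pains_pass} columns.
#' @export
painsFilter <- function(hits) {
  if (!nrow(hits)) {
    hits$pains_alerts <- character(0)
    hits$pains_pass <- logical(0)
    return(hits)
  }
  alerts <- painsAlerts(hits$smiles)
  hits$pains_alerts <- vapply(alerts, paste, "", collapse = ";")
  hits$pains_pass <- !nzchar(hits$pains_alerts)
  hits
}

#' PAINS alerts for a vector of SMILES
#'
#' @param smiles character vector.
#' @return list of character vectors of alert names (empty when clean).
#' @export
painsAlerts <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    stats::setNames(smiles, sprintf("p%d", seq_along(smiles)))))
  out <- rep(list(character(0)), length(smiles))
  for (nm in names(.PAINS_SMARTS)) {
    cnt <- tryCatch(suppressWarnings(
      ChemmineR::smartsSearchOB(sdf, .PAINS_SMARTS[[nm]], uniqueMatches = FALSE)),
      error = function(e) rep(0L, length(smiles)))
    hit <- which(cnt > 0)
    for (i in hit) out[[i]] <- c(out[[i]], nm)
  }
  out
}

#' Run the full screening funnel
#'
#' CS cutoff, then novelty filter, then clustering with representative
#' selection, then PAINS annotation. Stage counts are logged and returned
#' so they reconcile exactly (each stage's output is a subset of its
#' input).
#'
#' @param consensus a \linkS4class{ConsensusModel}.
#' @param smiles standardized library SMILES (named by id).
#' @param train the training \linkS4class{LabeledDataset}.
#' @param cs_cutoff,novelty_cutoff,cluster_cutoff funnel thresholds
#'   (defaults 0.8, 0.40, 0.70).
#' @return list with \code{hits} (annotated table), \code{selected}
#'   (cluster representatives passing all filters) and \code{funnel}
#'   (stage counts).
#' @export
runFunnel <- function(consensus, smiles, train, cs_cutoff = 0.8,
                      novelty_cutoff = 0.40, cluster_cutoff = 0.70) {
  hits <- screenLibrary(consensus, smiles, cs_cutoff)
  n0 <- attr(hits, "n_screened")
  n1 <- nrow(hits)
  hits <- noveltyFilter(hits, train, novelty_cutoff)
  n2 <- nrow(hits)
  hits <- clusterHits(hits, cluster_cutoff)
  hits <- painsFilter(hits)
  sel <- hits[hits$is_cluster_representative & hits$pains_pass, , drop = FALSE]
  list(hits = hits, selected = sel,
       funnel = c(library = n0, cs_pass = n1, novel = n2,
                  clusters = if (n2) max(hits$cluster_id) else 0L,
                  selected = nrow(sel)))
}
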