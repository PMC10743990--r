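# Synthetic activity tables and screening libraries with known ground
# truth. Actives are built by decorating a planted scaffold
# (benzofuran-2-carboxamide by default) with a fixed substituent
# vocabulary; inactives and decoys come from scaffold-free templates.
# Potencies are drawn from truncated log-normals on either side of the
# excluded 0.1-0.5 uM band, and a configurable fraction of compounds gets
# three replicate measurements including one >25% outlier, exercising the
# replicate-aggregation rule. Everything is deterministic under the seed.

# substitution vocabularies (kept chemically plain so every generated
# SMILES parses)
.SYN_R1 <- c("C", "CC", "CCC", "C(C)C", "CCO", "CCOC", "CCN(C)C",
             "Cc1ccccc1", "CCc1ccccc1", "CC(C)C", "CCCC", "CCCO",
             "CCCCC", "CCCCCC", "CC(C)CC", "CCOCC", "Cc1ccco1", "Cc1cccs1")
.SYN_R2 <- c("", "C", "F", "Cl", "Br", "OC", "CC", "N(C)C", "O", "C(F)(F)F",
             "CCl", "OCC", "I", "OC(C)C")

# active template: benzofuran-2-carboxamide core, N-substituent R1, ring
# substituent R2; scaffold atoms are the first 3 (O=C-N) plus the 9
# benzofuran ring atoms that follow R1
.synActive <- function(r1, r2) {
  if (nzchar(r2)) sprintf("O=C(N%s)c1cc2cc(%s)ccc2o1", r1, r2)
  else sprintf("O=C(N%s)c1cc2ccccc2o1", r1)
}

# atoms of the planted substructure in SMILES writing order:
# O(1) C(2) N(3) [r1 heavy atoms] c1 cc2 cc [r2 atoms] ccc2 o1
.synPlantedAtoms <- function(r1, r2) {
  n_r1 <- .heavyAtomCount(r1)
  n_r2 <- .heavyAtomCount(r2)
  head <- c(1L, 2L, 3L)
  ring1 <- 3L + n_r1 + 1:5          # c1 c c2 c c
  ring2 <- 3L + n_r1 + 5L + n_r2 + 1:4   # c c c2 o1
  c(head, ring1, ring2)
}

# scaffold-free decoy templates; {1} gets an R1-style, {2} an R2-style
# substituent
.SYN_DECOYS <- c(
  "O=C(N%s)c1ccncc1", "O=C(N%s)c1cccnc1", "O=S(=O)(N%s)c1ccc(%s)cc1",
  "O=C(N%s)C1CCCCC1", "O=C(N%s)c1ccc(%s)cc1", "%sOc1ccc(%s)cc1",
  "O=C(N%s)c1ccco1", "O=C(N%s)c1cccs1", "%sN1CCOCC1", "%sN1CCCCC1",
  "O=C(O%s)c1ccc(%s)cc1", "%sc1nc2ccccc2s1", "%sC1CCN(CC1)%s",
  "O=C(N%s)Cc1ccc(%s)cc1")

# prefix-position substituents (attachment via their *last* atom, so all
# end in carbon and are distinct as prefixes)
.SYN_R1_PREFIX <- c("C", "CC", "CCC", "CCCC", "CCCCC", "CCCCCC", "CC(C)C",
  "OCC", "OCCC", "COCC", "CN(C)CC", "CCN(C)CC", "c1ccccc1C", "c1ccccc1CC",
  "COCCC", "CCOCC", "OCC(C)C", "CCCOCC")

.synDecoy <- function(template, i1, i2) {
  r1 <- if (startsWith(template, "%s")) .SYN_R1_PREFIX[i1] else .SYN_R1[i1]
  r2 <- .SYN_R2[i2]
  k <- lengths(regmatches(template, gregexpr("%s", template)))
  if (k == 1) sprintf(template, r1) else sprintf(template, r1,
    if (nzchar(r2)) r2 else "C")
}

# truncated log-normal sampler (base-10 sigma), resampling until inside
# the allowed side of the excluded band
.synPotency <- function(n, median_um, sigma10, side) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- 10 ^ (log10(median_um) + stats::rnorm(1, 0, sigma10))
      if (side == "active" && v <= 0.1) break
      if (side == "inactive" && v >= 0.5) break
    }
    out[i] <- v
  }
  out
}

#' Configuration for the synthetic activity generator
#'
#' Defaults encode the study conditions the package is tested under: a
#' balanced table whose active potency median (0.02 uM) sits well inside
#' the active region and whose inactive median (5 uM) sits well inside
#' the inactive region, with 20\% of compounds carrying three replicate
#' measurements including one >25\% outlier.
#'
#' @param n_actives,n_inactives compound counts (>= 1).
#' @param seed integer seed; fully determines the output.
#' @param planted_smarts substructure defining true actives (SMARTS,
#'   used for verification; generation is template-based).
#' @param active_median_um,active_sigma10 log-normal location/spread of
#'   active potencies (uM / log10 units).
#' @param inactive_median_um,inactive_sigma10 same for inactives.
#' @param replicate_fraction fraction of compounds receiving 3 replicates
#'   with one injected >25\% outlier.
#' @return a list of class \code{syntheticConfig}.
#' @export
syntheticConfig <- function(n_actives = 200L, n_inactives = 200L, seed = 1L,
                            planted_smarts = "O=Cc1cc2ccccc2o1",
                            active_median_um = 0.02, active_sigma10 = 0.4,
                            inactive_median_um = 5, inactive_sigma10 = 0.5,
                            replicate_fraction = 0.2) {
  stopifnot(n_actives >= 1, n_inactives >= 1,
            active_median_um <= 0.1, inactive_median_um >= 0.5,
            replicate_fraction >= 0, replicate_fraction <= 1)
  structure(list(n_actives = as.integer(n_actives),
    n_inactives = as.integer(n_inactives), seed = as.integer(seed),
    planted_smarts = planted_smarts,
    active_median_um = active_median_um, active_sigma10 = active_sigma10,
    inactive_median_um = inactive_median_um,
    inactive_sigma10 = inactive_sigma10,
    replicate_fraction = replicate_fraction), class = "syntheticConfig")
}

# enumerate distinct molecules of one class deterministically; distinct
# means distinct *standardized structure key*, so curation recovers the
# generated counts exactly
.synEnumerate <- function(n, maker, seed, tag) {
  combos <- expand.grid(r1 = seq_along(.SYN_R1), r2 = seq_along(.SYN_R2),
                        t = seq_len(14L), KEEP.OUT.ATTRS = FALSE)
  ord <- withSeed(childSeed(seed, tag), sample(nrow(combos)))
  out <- list()
  keys <- character(0)
  for (i in ord) {
    cand <- maker(combos$r1[i], combos$r2[i], combos$t[i])
    if (is.null(cand)) next
    std <- standardizeSmiles(cand$smiles)
    if (!std$ok || std$structure_key %in% keys) next
    keys <- c(keys, std$structure_key)
    out[[length(out) + 1L]] <- cand
    if (length(out) == n) break
  }
  if (length(out) < n)
    stop("substituent vocabulary exhausted: can generate at most ",
         length(out), " distinct compounds of this class")
  out
}

#' Generate a synthetic activity table
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with \code{records} (data.frame shaped like a raw
#'   activity table: compound_id, smiles, potency_um, potency_type,
#'   relation) and \code{truth} (one row per compound: id, smiles, class,
#'   final potency, planted atom indices for actives).
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  .checkSmarts(config$planted_smarts)
  act <- .synEnumerate(config$n_actives, function(i1, i2, it) {
    r1 <- .SYN_R1[i1]; r2 <- .SYN_R2[i2]
    list(smiles = .synActive(r1, r2), planted = .synPlantedAtoms(r1, r2))
  }, config$seed, "act")
  ina <- .synEnumerate(config$n_inactives, function(i1, i2, it) {
    list(smiles = .synDecoy(.SYN_DECOYS[it], i1, i2),
         planted = integer(0))
  }, config$seed, "ina")

  withSeed(childSeed(config$seed, "potency"), {
    pa <- .synPotency(length(act), config$active_median_um,
                      config$active_sigma10, "active")
    pi_ <- .synPotency(length(ina), config$inactive_median_um,
                       config$inactive_sigma10, "inactive")
    all_sm <- c(vapply(act, `[[`, "", "smiles"), vapply(ina, `[[`, "", "smiles"))
    cls <- rep(c("active", "inactive"), c(length(act), length(ina)))
    pot <- c(pa, pi_)
    ids <- sprintf("SYN%04d", seq_along(all_sm))
    n_rep <- round(config$replicate_fraction * length(all_sm))
    rep_idx <- if (n_rep > 0) sample(seq_along(all_sm), n_rep) else integer(0)

    rec <- list()
    for (i in seq_along(all_sm)) {
      if (i %in% rep_idx) {
        # three replicates: two tightly bracketing the target potency
        # (their mean reproduces it; both inside the 25% band of the trio
        # mean) plus one outlier that the 25% rule removes
        eps <- stats::runif(1, 0.005, 0.02)
        v1 <- pot[i] * (1 + eps); v2 <- pot[i] * (1 - eps)
        v3 <- pot[i] * 1.9
        vals <- c(v1, v2, v3)
      } else vals <- pot[i]
      for (v in vals)
        rec[[length(rec) + 1L]] <- data.frame(compound_id = ids[i],
          smiles = all_sm[i], potency_um = v, potency_type = "IC50",
          relation = "=", stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rec)
    truth <- data.frame(compound_id = ids, smiles = all_sm, class = cls,
      potency_um = pot, stringsAsFactors = FALSE)
    truth$planted_atoms <- c(lapply(act, `[[`, "planted"),
                             lapply(ina, `[[`, "planted"))
    list(records = records, truth = truth)
  })
}

.checkSmarts <- function(smarts) {
  probe <- suppressWarnings(ChemmineR::smiles2sdf(c(p = "O=Cc1cc2ccccc2o1")))
  ok <- tryCatch({
    suppressWarnings(ChemmineR::smartsSearchOB(probe, smarts,
                                               uniqueMatches = FALSE))
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("invalid SMARTS pattern: ", smarts)
  invisible(TRUE)
}

# deeper-decorated analog template: scaffold retained, heavy decoration
# on both sides dilutes fingerprint overlap with the training actives
.SYN_ANALOG_R1 <- c("CCCN1CCN(CCO)CC1", "CCCN1CCOCC1C(=O)OCC",
  "CC(Cc1ccc(OCCN(CC)CC)cc1)C(=O)OC", "CCN(CCO)CCCNC(=O)CCc1ccccn1",
  "CCOC(=O)C1CCN(CCCOC)CC1", "CC(C)(C)OC(=O)N1CCN(CCCO)CC1")
.SYN_ANALOG_R2 <- c("CCN(CC)S(=O)(=O)C", "OCCOCCN(C)C", "CN1CCN(CCOC)CC1",
  "CCOC(=O)CSC", "CC(=O)N(CCO)CC", "COCCN(C)C(=O)CC")

#' Generate a synthetic screening library with ground truth
#'
#' A mixture of heavily decorated planted-scaffold analogs (distinct from
#' any training compound, decorated deeply enough to pass the novelty
#' filter) and scaffold-free decoys.
#'
#' @param config a \code{\link{syntheticConfig}} (for seed and scaffold).
#' @param n_library library size.
#' @param hit_fraction fraction of planted-scaffold analogs in [0, 1].
#' @return list with \code{smiles} (named vector) and \code{truth}
#'   (data.frame id, smiles, is_analog).
#' @export
generateScreeningLibrary <- function(config, n_library = 200L,
                                     hit_fraction = 0.1) {
  stopifnot(inherits(config, "syntheticConfig"),
            hit_fraction >= 0, hit_fraction <= 1)
  n_hit <- round(n_library * hit_fraction)
  n_dec <- n_library - n_hit
  hits <- if (n_hit > 0) .synEnumerate(n_hit, function(i1, i2, it) {
    r1 <- .SYN_ANALOG_R1[(i1 - 1L) %% length(.SYN_ANALOG_R1) + 1L]
    r2 <- .SYN_ANALOG_R2[(i2 - 1L) %% length(.SYN_ANALOG_R2) + 1L]
    list(smiles = .synActive(r1, r2))
  }, config$seed, "libhit") else list()
  decs <- if (n_dec > 0) .synEnumerate(n_dec, function(i1, i2, it) {
    list(smiles = .synDecoy(.SYN_DECOYS[it], i1, i2))
  }, childSeed(config$seed, "libdec"), "libdec") else list()
  sm <- c(vapply(hits, `[[`, "", "smiles"), vapply(decs, `[[`, "", "smiles"))
  ids <- sprintf("LIB%05d", seq_along(sm))
  names(sm) <- ids
  list(smiles = sm,
       truth = data.frame(compound_id = ids, smiles = unname(sm),
         is_analog = rep(c(TRUE, FALSE), c(length(hits), length(decs))),
         stringsAsFactors = FALSE))
}
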