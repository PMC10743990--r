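# Data curation: standardization, replicate aggregation, binary labeling.

#' Standardize a SMILES string
#'
#' Retains the largest organic fragment (salt/counter-ion removal),
#' neutralizes formal charges where a neutral protonation state exists,
#' and emits the canonical SMILES plus a structure key (InChI-based) used
#' for deduplication. Unparseable or zero-heavy-atom inputs yield a
#' structured rejection rather than an error, so a bad record never kills
#' a batch.
#'
#' @param smiles a single SMILES string.
#' @return a list with elements \code{ok} (logical), and on success
#'   \code{smiles_std}, \code{structure_key}; on failure \code{reason} and
#'   the offending \code{input}.
#' @examples
#' standardizeSmiles("CC(=O)[O-].[Na+]")$smiles_std  # neutral acetic acid
#' standardizeSmiles("C1CC")$ok                      # FALSE: unclosed ring
#' @export
standardizeSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || is.na(smiles) ||
      !nzchar(smiles))
    return(list(ok = FALSE, reason = "empty input", input = smiles))

  frag <- .largestOrganicFragment(smiles)
  if (is.null(frag))
    return(list(ok = FALSE, reason = "no organic fragment", input = smiles))
  frag <- .neutralizeSmiles(frag)

  can <- .toCanonical(frag)
  if (is.null(can))
    return(list(ok = FALSE, reason = "unparseable SMILES", input = smiles))
  if (.heavyAtomCount(can) == 0)
    return(list(ok = FALSE, reason = "zero heavy atoms", input = smiles))

  key <- .structureKey(can)
  list(ok = TRUE, smiles_std = can, structure_key = key)
}

# split on '.' outside brackets is safe because '.' never occurs inside []
.largestOrganicFragment <- function(smiles) {
  parts <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (!length(parts)) return(NULL)
  counts <- vapply(parts, .heavyAtomCount, 0L)
  has_c <- grepl("C|c", gsub("Cl|Ca|Cd|Cr|Co|Cu|Cs|Sc", "", parts))
  if (!any(has_c)) return(NULL)     # no organic (carbon-bearing) fragment
  keep <- which(has_c)
  best <- keep[order(-counts[keep], parts[keep])][1]
  parts[best]
}

# crude but deterministic heavy-atom count from a SMILES string
.heavyAtomCount <- function(s) {
  s2 <- gsub("\\[[0-9]*H[0-9+-]*\\]", "", s)        # explicit-H-only atoms
  s2 <- gsub("H[0-9]*", "", s2)                     # hydrogens inside brackets
  toks <- gregexpr("Cl|Br|Si|Se|Na|Li|[BCNOPSFIbcnops]", s2)[[1]]
  if (toks[1] == -1) 0L else length(toks)
}

# charged-group neutralization at the SMILES level: protonate/deprotonate
# atoms for which a neutral valence state exists; quaternary N ([N+] with
# four heavy neighbors, written without H) is left untouched.
.neutralizeSmiles <- function(s) {
  s <- gsub("[O-]", "O", s, fixed = TRUE)
  s <- gsub("[o-]", "o", s, fixed = TRUE)
  s <- gsub("[S-]", "S", s, fixed = TRUE)
  s <- gsub("[N-]", "N", s, fixed = TRUE)
  s <- gsub("[NH3+]", "N", s, fixed = TRUE)
  s <- gsub("[NH2+]", "N", s, fixed = TRUE)
  s <- gsub("[NH+]", "N", s, fixed = TRUE)
  s <- gsub("[nH+]", "[nH]", s, fixed = TRUE)
  s
}

.toCanonical <- function(s) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", s)),
    error = function(e) "")
  out <- sub("\\s.*$", "", trimws(out))
  if (!nzchar(out)) NULL else out
}

.structureKey <- function(canonical_smiles) {
  inchi <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "INCHI", canonical_smiles)),
    error = function(e) "")
  inchi <- trimws(inchi)
  if (nzchar(inchi)) inchi else paste0("SMI:", canonical_smiles)
}

#' Aggregate replicate potency measurements
#'
#' One value passes through; two values are averaged; with three or more,
#' every value deviating by more than 25\% from the mean of the full set is
#' removed in a single pass and the survivors are averaged. If no value
#' survives, the compound is discarded (\code{NA}).
#'
#' @param values numeric vector of positive potencies in micromolar.
#' @return the aggregated potency in micromolar, or \code{NA_real_} for a
#'   discard.
#' @examples
#' aggregatePotency(c(0.10, 0.20))        # 0.15
#' aggregatePotency(c(0.10, 0.10, 0.16))  # 0.10 (0.16 deviates > 25%)
#' @export
aggregatePotency <- function(values) {
  stopifnot(length(values) >= 1)
  if (any(!is.finite(values) | values <= 0))
    stop("potency values must be positive and finite")
  if (length(values) <= 2) return(mean(values))
  m <- mean(values)
  keep <- abs(values - m) / m <= 0.25
  if (!any(keep)) return(NA_real_)
  mean(values[keep])
}

#' Assign a binary activity label from potency
#'
#' Potency at or below 0.1 uM (pIC50 >= 7) is active; at or above 0.5 uM
#' is inactive; the band strictly in between is excluded.
#'
#' @param potency_um positive potency in micromolar (vectorized).
#' @return character vector in \{"active", "inactive", "excluded"\}.
#' @examples
#' assignLabel(c(0.05, 0.30, 0.60))  # active, excluded, inactive
#' @export
assignLabel <- function(potency_um) {
  if (any(!is.finite(potency_um) | potency_um <= 0))
    stop("potency must be positive and finite")
  ifelse(potency_um <= 0.1, "active",
         ifelse(potency_um >= 0.5, "inactive", "excluded"))
}

#' Build a curated, labeled dataset from raw activity records
#'
#' Standardizes each record, deduplicates by structure key, aggregates
#' replicate potencies with the 25\% outlier rule, assigns binary labels,
#' and drops excluded-band and discarded compounds. Every dropped record
#' appears in the audit log with a reason; input counts reconcile exactly
#' with output + audit counts.
#'
#' @param records data.frame with columns \code{compound_id},
#'   \code{smiles}, \code{potency_um} (positive, micromolar),
#'   \code{potency_type} (all \code{IC50} or all \code{Ki}) and optionally
#'   \code{relation} (records other than \code{"="} are censored and
#'   dropped with an audit reason).
#' @param role \code{"train"} or \code{"test"}.
#' @return a \linkS4class{LabeledDataset}.
#' @export
buildDataset <- function(records, role = c("train", "test")) {
  role <- match.arg(role)
  req <- c("compound_id", "smiles", "potency_um", "potency_type")
  if (!all(req %in% names(records)))
    stop("records must have columns: ", paste(req, collapse = ", "))
  if (length(unique(records$potency_type)) > 1)
    stop("mixed potency types in one dataset (need all IC50 or all Ki)")
  if (!"relation" %in% names(records)) records$relation <- "="

  audit <- data.frame(compound_id = character(0), smiles = character(0),
                      reason = character(0), stringsAsFactors = FALSE)
  drop <- function(i, reason) {
    audit <<- rbind(audit, data.frame(compound_id = records$compound_id[i],
      smiles = records$smiles[i], reason = reason, stringsAsFactors = FALSE))
  }

  n <- nrow(records)
  keys <- character(n); std <- character(n); ok <- logical(n)
  for (i in seq_len(n)) {
    if (!identical(records$relation[i], "=")) {
      drop(i, "censored relation"); next
    }
    if (!is.finite(records$potency_um[i]) || records$potency_um[i] <= 0) {
      drop(i, "non-positive potency"); next
    }
    s <- standardizeSmiles(records$smiles[i])
    if (!s$ok) { drop(i, s$reason); next }
    keys[i] <- s$structure_key; std[i] <- s$smiles_std; ok[i] <- TRUE
  }

  idx <- which(ok)
  groups <- split(idx, keys[idx])
  # deterministic output order: first appearance of each structure key
  groups <- groups[order(vapply(groups, min, 0L))]

  out <- list()
  for (g in groups) {
    vals <- records$potency_um[g]
    pot <- aggregatePotency(vals)
    n_used <- if (length(vals) <= 2) length(vals) else {
      m <- mean(vals); sum(abs(vals - m) / m <= 0.25)
    }
    if (is.na(pot)) {
      for (i in g) drop(i, "all replicates removed by 25% rule")
      next
    }
    lab <- assignLabel(pot)
    if (lab == "excluded") {
      for (i in g) drop(i, "potency in excluded band (0.1-0.5 uM)")
      next
    }
    first <- g[1]
    out[[length(out) + 1L]] <- list(id = records$compound_id[first],
      smiles = std[first], key = keys[first], label = lab, potency = pot,
      n_used = n_used, n_raw = length(g), members = g)
  }

  if (!length(out))
    stop("curation produced an empty dataset (all records dropped); ",
         "see the audit log")

  # records aggregated into a retained compound beyond the replicates
  # actually used still count as consumed (conservation holds by groups)
  new("LabeledDataset", role = role,
      ids = vapply(out, `[[`, "", "id"),
      smiles = vapply(out, `[[`, "", "smiles"),
      keys = vapply(out, `[[`, "", "key"),
      labels = factor(vapply(out, `[[`, "", "label"),
                      levels = c("active", "inactive")),
      potency = vapply(out, `[[`, 0, "potency"),
      pic50 = -log10(vapply(out, `[[`, 0, "potency") * 1e-6),
      nUsed = vapply(out, function(x) as.integer(x$n_used), 0L),
      nRaw = vapply(out, function(x) as.integer(x$n_raw), 0L),
      audit = audit)
}

#' Export a curated dataset as a data.frame
#'
#' @param dataset a \linkS4class{LabeledDataset}.
#' @return data.frame with one row per compound.
#' @export
datasetTable <- function(dataset) {
  stopifnot(is(dataset, "LabeledDataset"))
  data.frame(compound_id = dataset@ids, smiles = dataset@smiles,
    structure_key = dataset@keys, label = as.character(dataset@labels),
    potency_um = dataset@potency, pic50 = dataset@pic50,
    n_used = dataset@nUsed, n_raw = dataset@nRaw, stringsAsFactors = FALSE)
}
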