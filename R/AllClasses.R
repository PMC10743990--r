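#' @import methods
NULL

#' LabeledDataset: curated, binary-labeled compounds
#'
#' The unit all training and evaluation consumes. Compounds are
#' standardized (largest fragment, neutralized, canonical SMILES), unique
#' by structure key, and carry a binary activity label derived from the
#' potency thresholds: potency <= 0.1 uM is active, potency >= 0.5 uM is
#' inactive, and the band in between is excluded at curation time.
#'
#' @slot role character, "train" or "test".
#' @slot ids compound identifiers.
#' @slot smiles standardized canonical SMILES, parallel to \code{ids}.
#' @slot keys structure keys (InChI-based) used for deduplication.
#' @slot labels factor with levels \code{active}, \code{inactive}.
#' @slot potency aggregated potency in micromolar.
#' @slot pic50 -log10(potency in molar).
#' @slot nUsed,nRaw replicate counts retained / observed per compound.
#' @slot audit data.frame logging every dropped input record and reason.
#' @exportClass LabeledDataset
setClass("LabeledDataset",
  representation(role = "character", ids = "character", smiles = "character",
    keys = "character", labels = "factor", potency = "numeric",
    pic50 = "numeric", nUsed = "integer", nRaw = "integer",
    audit = "data.frame"))

setValidity("LabeledDataset", function(object) {
  msg <- character(0)
  n <- length(object@ids)
  if (!object@role %in% c("train", "test"))
    msg <- c(msg, "role must be 'train' or 'test'")
  if (length(object@smiles) != n || length(object@labels) != n ||
      length(object@potency) != n || length(object@keys) != n)
    msg <- c(msg, "parallel slots must have equal length")
  if (anyDuplicated(object@keys))
    msg <- c(msg, "structure keys must be unique within a dataset")
  if (!identical(levels(object@labels), c("active", "inactive")))
    msg <- c(msg, "labels must be a factor with levels active, inactive")
  if (any(is.na(object@labels)))
    msg <- c(msg, "no compound may be unlabeled")
  bad <- (object@labels == "active" & object@potency > 0.1) |
         (object@labels == "inactive" & object@potency < 0.5)
  if (any(bad))
    msg <- c(msg, "labels must respect the 0.1/0.5 uM thresholds")
  if (any(object@potency > 0.1 & object@potency < 0.5))
    msg <- c(msg, "no output compound may fall in the excluded potency band")
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: one molecular representation of a compound set
#'
#' @slot kind one of \code{morgan}, \code{rdkit}, \code{layered},
#'   \code{pattern}, \code{pharm2d}, \code{pubchem}, \code{descriptors}.
#' @slot ids compound identifiers, one per row.
#' @slot data numeric matrix, rows parallel to \code{ids}; binary for the
#'   fingerprint kinds, real-valued for \code{descriptors}.
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(kind = "character", ids = "character", data = "matrix"))

setValidity("FeatureMatrix", function(object) {
  msg <- character(0)
  if (!object@kind %in% REPRESENTATION_KINDS)
    msg <- c(msg, paste("unknown kind:", object@kind))
  if (nrow(object@data) != length(object@ids))
    msg <- c(msg, "row count must equal compound count")
  exp <- representationLength(object@kind)
  if (!is.na(exp) && ncol(object@data) != exp)
    msg <- c(msg, sprintf("kind '%s' must have %d columns", object@kind, exp))
  if (any(!is.finite(object@data)))
    msg <- c(msg, "all feature values must be finite")
  if (length(msg)) msg else TRUE
})

#' TrainedClassifier: one (algorithm, representation, hyperparameters) model
#'
#' Emits a probability score PS in [0, 1] per compound: the model's
#' confidence of the active class. Thresholding PS at 0.5 gives the label.
#'
#' @slot algorithm one of RF, SVM, KNN, MLP.
#' @slot kind the representation the model consumes.
#' @slot hyperparameters named list drawn from the algorithm's grid domain.
#' @slot seed integer seed used at fit time.
#' @slot fit opaque fitted state.
#' @slot manifest training manifest (dataset checksum, n, date).
#' @exportClass TrainedClassifier
setClass("TrainedClassifier",
  representation(algorithm = "character", kind = "character",
    hyperparameters = "list", seed = "integer", fit = "list",
    manifest = "list"))

setValidity("TrainedClassifier", function(object) {
  msg <- character(0)
  if (!object@algorithm %in% c("RF", "SVM", "KNN", "MLP"))
    msg <- c(msg, "algorithm must be RF, SVM, KNN or MLP")
  if (!object@kind %in% REPRESENTATION_KINDS)
    msg <- c(msg, "unknown representation kind")
  if (length(msg)) msg else TRUE
})

#' ConsensusModel: a set of classifiers combined by probability averaging
#'
#' The consensus score CS of a compound is the arithmetic mean of the
#' members' probability scores; CS >= 0.5 predicts active.
#'
#' @slot members list of at least two \linkS4class{TrainedClassifier}
#'   objects with distinct (algorithm, representation) specs, trained on
#'   the same dataset.
#' @exportClass ConsensusModel
setClass("ConsensusModel", representation(members = "list"))

setValidity("ConsensusModel", function(object) {
  msg <- character(0)
  if (length(object@members) < 2)
    msg <- c(msg, "a consensus needs at least 2 members")
  if (!all(vapply(object@members, is, TRUE, "TrainedClassifier")))
    msg <- c(msg, "members must be TrainedClassifier objects")
  specs <- vapply(object@members, function(m)
    paste(m@algorithm, m@kind, digest_hp(m@hyperparameters)), "")
  if (anyDuplicated(specs))
    msg <- c(msg, "member specs must be distinct")
  keys <- vapply(object@members, function(m) m@manifest$dataset %||% "", "")
  if (length(unique(keys)) > 1)
    msg <- c(msg, "members must be trained on the same dataset")
  if (length(msg)) msg else TRUE
})

digest_hp <- function(hp) {
  paste(names(hp), vapply(hp, function(v) paste(format(v), collapse = ","), ""),
        sep = "=", collapse = ";")
}

# ---- show methods -----------------------------------------------------

setMethod("show", "LabeledDataset", function(object) {
  tab <- table(object@labels)
  cat(sprintf("LabeledDataset (%s): %d compounds (%d active / %d inactive)\n",
      object@role, length(object@ids), tab[["active"]], tab[["inactive"]]))
  cat(sprintf("  potency range: %.4g - %.4g uM; %d records dropped in audit\n",
      min(object@potency), max(object@potency), nrow(object@audit)))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix '%s': %d compounds x %d features\n",
      object@kind, nrow(object@data), ncol(object@data)))
})

setMethod("show", "TrainedClassifier", function(object) {
  cat(sprintf("TrainedClassifier %s-%s (%s)\n", object@algorithm, object@kind,
      digest_hp(object@hyperparameters)))
})

setMethod("show", "ConsensusModel", function(object) {
  cat(sprintf("ConsensusModel with %d members:\n", length(object@members)))
  for (m in object@members)
    cat(sprintf("  %s-%s\n", m@algorithm, m@kind))
})

# ---- accessors --------------------------------------------------------

#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))
#' @describeIn LabeledDataset compound identifiers
#' @export
setMethod("compoundIds", "LabeledDataset", function(x) x@ids)
#' @describeIn FeatureMatrix compound identifiers (row order)
#' @export
setMethod("compoundIds", "FeatureMatrix", function(x) x@ids)

#' @export
setGeneric("compoundSmiles", function(x) standardGeneric("compoundSmiles"))
#' @describeIn LabeledDataset standardized SMILES
#' @export
setMethod("compoundSmiles", "LabeledDataset", function(x) x@smiles)

#' @export
setGeneric("activityLabels", function(x) standardGeneric("activityLabels"))
#' @describeIn LabeledDataset activity labels (factor active/inactive)
#' @export
setMethod("activityLabels", "LabeledDataset", function(x) x@labels)

#' @export
setGeneric("potencies", function(x) standardGeneric("potencies"))
#' @describeIn LabeledDataset aggregated potencies in micromolar
#' @export
setMethod("potencies", "LabeledDataset", function(x) x@potency)

#' @export
setGeneric("auditLog", function(x) standardGeneric("auditLog"))
#' @describeIn LabeledDataset audit log of dropped records
#' @export
setMethod("auditLog", "LabeledDataset", function(x) x@audit)

#' @export
setGeneric("fpKind", function(x) standardGeneric("fpKind"))
#' @describeIn FeatureMatrix representation kind
#' @export
setMethod("fpKind", "FeatureMatrix", function(x) x@kind)

#' @export
setGeneric("featureData", function(x) standardGeneric("featureData"))
#' @describeIn FeatureMatrix the numeric matrix
#' @export
setMethod("featureData", "FeatureMatrix", function(x) x@data)

#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @describeIn ConsensusModel the member classifiers
#' @export
setMethod("members", "ConsensusModel", function(x) x@members)

#' Number of compounds in a dataset
#' @param x a LabeledDataset
#' @export
setMethod("length", "LabeledDataset", function(x) length(x@ids))

#' Subset a LabeledDataset by index
#' @param x a LabeledDataset
#' @param i integer or logical index
#' @param j,drop,... ignored
#' @export
setMethod("[", "LabeledDataset", function(x, i, j, ..., drop = FALSE) {
  new("LabeledDataset", role = x@role, ids = x@ids[i], smiles = x@smiles[i],
      keys = x@keys[i], labels = droplevels2(x@labels[i]),
      potency = x@potency[i], pic50 = x@pic50[i],
      nUsed = x@nUsed[i], nRaw = x@nRaw[i], audit = x@audit)
})

# keep both levels even if a subset drops a class
droplevels2 <- function(f) factor(as.character(f), levels = c("active", "inactive"))
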