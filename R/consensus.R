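# Consensus scoring: probability-averaging over trained classifiers,
# combination enumeration and CS-threshold sweeps.

#' Build a consensus model from trained classifiers
#'
#' @param ... \linkS4class{TrainedClassifier} objects (or a single list of
#'   them); at least two, with distinct specs, trained on the same data.
#' @return a \linkS4class{ConsensusModel}.
#' @export
consensusModel <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) && !is(args[[1]], "TrainedClassifier"))
    args <- args[[1]]
  new("ConsensusModel", members = args)
}

#' Consensus score: arithmetic mean of member probability scores
#'
#' @param ps numeric vector (length >= 2) of member PS values in [0, 1].
#' @return the consensus score CS.
#' @examples
#' consensusScore(c(0.9, 0.7))  # 0.8
#' @export
consensusScore <- function(ps) {
  if (length(ps) < 2) stop("a consensus needs at least 2 probability scores")
  if (any(!is.finite(ps) | ps < 0 | ps > 1))
    stop("probability scores must lie in [0, 1]")
  mean(ps)
}

#' Consensus predictions for a compound set
#'
#' Each member predicts a PS per compound; the consensus score is their
#' mean, and CS >= 0.5 classifies a compound active.
#'
#' @param consensus a \linkS4class{ConsensusModel}.
#' @param features either a \linkS4class{FeatureMatrix} (when all members
#'   share one representation) or a named list of FeatureMatrix objects
#'   keyed by kind.
#' @return data.frame with compound_id, one PS column per member, cs and
#'   label.
#' @export
predictConsensus <- function(consensus, features) {
  stopifnot(is(consensus, "ConsensusModel"))
  if (is(features, "FeatureMatrix")) {
    features <- stats::setNames(list(features), features@kind)
  }
  ids <- NULL
  psm <- list()
  for (i in seq_along(consensus@members)) {
    m <- consensus@members[[i]]
    fm <- features[[m@kind]]
    if (is.null(fm))
      stop("no FeatureMatrix provided for representation '", m@kind, "'")
    if (is.null(ids)) ids <- fm@ids
    else if (!identical(ids, fm@ids))
      stop("feature matrices must cover the same compounds in order")
    psm[[paste0("ps_", m@algorithm, "_", m@kind, "_", i)]] <-
      predictPS(m, fm@data)
  }
  cs <- rowMeans(do.call(cbind, psm))
  out <- data.frame(compound_id = ids, psm, cs = cs,
    label = ifelse(cs >= 0.5, "active", "inactive"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Enumerate all consensus combinations of a model set
#'
#' All subsets of size >= 2 in deterministic order (by size, then
#' lexicographically by member index); n models yield 2^n - n - 1
#' combinations (11 for n = 4).
#'
#' @param models list of \linkS4class{TrainedClassifier} objects.
#' @return list of \linkS4class{ConsensusModel} objects; each carries an
#'   attribute \code{member_index} with the member positions.
#' @export
enumerateCombinations <- function(models) {
  n <- length(models)
  if (n < 2) stop("need at least 2 models to combine")
  out <- list()
  for (size in 2:n) {
    combs <- utils::combn(n, size, simplify = FALSE)
    for (cb in combs) {
      cm <- consensusModel(models[cb])
      attr(cm, "member_index") <- cb
      out[[length(out) + 1L]] <- cm
    }
  }
  out
}

#' Rank consensus combinations on held-out data
#'
#' Evaluates every combination with the confusion-matrix metrics and
#' ranks by accuracy, breaking ties by precision.
#'
#' @param models list of trained classifiers.
#' @param features FeatureMatrix or named list of them (see
#'   \code{\link{predictConsensus}}).
#' @param truth true labels, parallel to the feature rows.
#' @return data.frame, one row per combination, ranked best first.
#' @export
rankCombinations <- function(models, features, truth) {
  combos <- enumerateCombinations(models)
  rows <- lapply(seq_along(combos), function(i) {
    pred <- predictConsensus(combos[[i]], features)
    ev <- suppressWarnings(evaluateBinary(pred$label, truth))
    data.frame(combination = i,
      members = paste(attr(combos[[i]], "member_index"), collapse = "+"),
      accuracy = ev$accuracy, precision = ev$precision, recall = ev$recall)
  })
  tab <- do.call(rbind, rows)
  tab[order(-tab$accuracy, -tab$precision, tab$combination), ]
}

#' Precision/recall sweep over consensus-score thresholds
#'
#' Per threshold t, compounds with CS >= t are predicted active and the
#' confusion-matrix metrics are recomputed. Counts of predicted actives
#' and recall are non-increasing in t by construction.
#'
#' @param predictions data.frame from \code{\link{predictConsensus}}.
#' @param truth true labels parallel to the rows.
#' @param thresholds ascending CS thresholds in [0, 1]
#'   (default 0.5, 0.6, 0.7, 0.8, 0.9).
#' @return data.frame (threshold, precision, recall, accuracy,
#'   n_predicted_active).
#' @export
thresholdSweep <- function(predictions, truth,
                           thresholds = c(0.5, 0.6, 0.7, 0.8, 0.9)) {
  if (is.unsorted(thresholds, strictly = FALSE))
    stop("thresholds must be sorted ascending")
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]")
  rows <- lapply(thresholds, function(t) {
    lab <- ifelse(predictions$cs >= t, "active", "inactive")
    ev <- suppressWarnings(evaluateBinary(lab, truth))
    data.frame(threshold = t, precision = ev$precision, recall = ev$recall,
               accuracy = ev$accuracy, n_predicted_active = sum(lab == "active"))
  })
  do.call(rbind, rows)
}
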