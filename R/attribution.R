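# Atom-level explanation of consensus predictions.
#
# Per member model, Shapley values over fingerprint bits are estimated by
# the permutation method with antithetic (forward + reverse) orderings
# against a background set; additivity (base + sum of scores = PS of the
# explained compound) holds to machine precision by construction. Bit
# scores are then retro-mapped to atoms through the circular-fingerprint
# environment map and converted to atom weights
# fw_a = sum over features of fc / (n_Atoms * n_occ),
# finally averaged over the consensus members.

#' Permutation Shapley attribution of fingerprint bits
#'
#' For each background row, features where the compound and the
#' background agree contribute exactly zero and are skipped; the differing
#' features are flipped one by one along random permutations (forward and
#' reversed), accumulating prediction deltas. The result averages over
#' background rows and permutations.
#'
#' @param classifier a \linkS4class{TrainedClassifier} consuming the
#'   circular (morgan) representation.
#' @param x numeric feature vector of the compound to explain.
#' @param background matrix of background rows (same width as x).
#' @param n_permutations random permutations per background row
#'   (each also evaluated in reverse; default 10).
#' @param seed integer seed.
#' @param batch_rows model evaluations are batched to this many rows.
#' @return list with \code{scores} (signed per-bit vector; positive pushes
#'   toward active), \code{base} (mean background PS) and \code{ps} (PS of
#'   x). \code{base + sum(scores) == ps} within 1e-6.
#' @export
shapAttributions <- function(classifier, x, background, n_permutations = 10L,
                             seed = 1L, batch_rows = 4096L) {
  stopifnot(is(classifier, "TrainedClassifier"))
  if (classifier@kind != "morgan")
    stop("attribution is defined for the circular (morgan) representation")
  if (is.null(dim(background)) || nrow(background) < 1)
    stop("background must be a non-empty matrix")
  if (ncol(background) != length(x)) stop("background width mismatch")

  nB <- nrow(background)
  p <- length(x)

  # Build the full evaluation plan first, then predict in batches.
  plan <- withSeed(childSeed(seed, "shap"), {
    pl <- list()
    for (b in seq_len(nB)) {
      D <- which(x != background[b, ])
      if (!length(D)) next
      for (r in seq_len(n_permutations)) {
        ord <- if (length(D) == 1) D else sample(D)
        pl[[length(pl) + 1L]] <- list(b = b, ord = ord, dir = "fwd")
        pl[[length(pl) + 1L]] <- list(b = b, ord = rev(ord), dir = "rev")
      }
    }
    pl
  })

  # each pass contributes rows: background, then one flip at a time
  mkrows <- function(pass) {
    z <- background[pass$b, ]
    out <- matrix(0, length(pass$ord) + 1L, p)
    out[1, ] <- z
    for (j in seq_along(pass$ord)) {
      z[pass$ord[j]] <- x[pass$ord[j]]
      out[j + 1L, ] <- z
    }
    out
  }

  allrows <- lapply(plan, mkrows)
  nrows <- vapply(allrows, nrow, 0L)
  M <- do.call(rbind, allrows)
  f <- numeric(nrow(M))
  for (s in seq(1, nrow(M), by = batch_rows)) {
    e <- min(s + batch_rows - 1, nrow(M))
    f[s:e] <- predictPS(classifier, M[s:e, , drop = FALSE])
  }

  # per-background attribution: mean of the per-pass flip deltas; each
  # pass telescopes to f(x) - f(b), so every column of phiB sums to
  # f(x) - f(b) and the uniform average over backgrounds sums to
  # ps - base exactly (machine precision)
  phiB <- matrix(0, p, nB)
  npass <- integer(nB)
  off <- 0L
  for (i in seq_along(plan)) {
    pass <- plan[[i]]
    fv <- f[off + seq_len(nrows[i])]
    off <- off + nrows[i]
    phiB[pass$ord, pass$b] <- phiB[pass$ord, pass$b] + diff(fv)
    npass[pass$b] <- npass[pass$b] + 1L
  }
  for (b in which(npass > 0)) phiB[, b] <- phiB[, b] / npass[b]
  phi <- rowMeans(phiB)

  base <- mean(predictPS(classifier, background))
  ps <- predictPS(classifier, matrix(x, 1))
  list(scores = phi, base = base, ps = ps)
}

#' Atom weights from bit attributions (retro-mapping)
#'
#' Distributes each mapped on-bit's score over its generating atom
#' environments: every environment passes fc / (n_Atoms * n_occ) to each
#' of its atoms, so per model the atom weights sum exactly to the summed
#' scores of the mapped bits. Weights from several models (the consensus
#' members) are averaged per atom.
#'
#' @param attributions list of attribution results (one per model) from
#'   \code{\link{shapAttributions}}.
#' @param map bit-to-atom map from \code{\link{retroMapBits}}.
#' @param n_atoms number of atoms in the compound.
#' @return list with \code{weights} (mean per-atom weight vector),
#'   \code{per_model} (matrix n_atoms x n_models) and
#'   \code{mapped_score_sum} per model.
#' @export
atomWeights <- function(attributions, map, n_atoms) {
  if (!length(attributions)) stop("no attributions given")
  nm <- length(attributions)
  W <- matrix(0, n_atoms, nm)
  mapped_sum <- numeric(nm)
  mapped_bits <- as.integer(names(map))
  for (mi in seq_len(nm)) {
    fc <- attributions[[mi]]$scores
    unmapped <- which(fc != 0)
    unmapped <- unmapped[!unmapped %in% mapped_bits]
    if (length(unmapped))
      warning(length(unmapped), " scored bit(s) not present in the atom map",
              " (off-bits); excluded from the conservation sum")
    for (key in names(map)) {
      bit <- as.integer(key)
      score <- if (bit <= length(fc)) fc[bit] else 0
      if (is.na(score) || score == 0) next
      entry <- map[[key]]
      for (env in entry$environments) {
        W[env, mi] <- W[env, mi] + score / (length(env) * entry$n_occ)
      }
    }
    mapped_sum[mi] <- sum(fc[mapped_bits[mapped_bits <= length(fc)]])
  }
  list(weights = rowMeans(W), per_model = W, mapped_score_sum = mapped_sum)
}

#' Explain a consensus prediction at atom level
#'
#' Runs permutation Shapley attribution for every consensus member on the
#' compound's circular fingerprint, retro-maps bits to atoms and averages
#' the per-model atom weights.
#'
#' @param consensus a \linkS4class{ConsensusModel} whose members consume
#'   the morgan representation.
#' @param smiles standardized SMILES of the compound to explain.
#' @param background background FeatureMatrix (morgan) or plain matrix.
#' @param n_permutations,seed passed to \code{\link{shapAttributions}}.
#' @return list with \code{weights}, \code{per_model}, \code{table}
#'   (atom index, element, weight), \code{attributions} and \code{map}.
#' @export
explainCompound <- function(consensus, smiles, background,
                            n_permutations = 10L, seed = 1L) {
  stopifnot(is(consensus, "ConsensusModel"))
  if (is(background, "FeatureMatrix")) background <- background@data
  g <- molgraph(smiles)
  x <- morganFP(g)$bits
  map <- retroMapBits(smiles)
  # one seed shared by all members: identical members then receive
  # identical attributions, so consensus averaging is exactly idempotent
  atts <- lapply(consensus@members, function(m)
    shapAttributions(m, x, background, n_permutations = n_permutations,
                     seed = childSeed(seed, "shap")))
  aw <- atomWeights(atts, map, g$n)
  aw$table <- data.frame(atom = seq_len(g$n), element = g$elem,
                         weight = aw$weights)
  aw$attributions <- atts
  aw$map <- map
  aw
}

#' Render atom weights as a 2D depiction
#'
#' Draws the molecule (2D coordinates from the structure generator) with
#' atoms shaded by signed weight: warm (orange/red) for positive
#' contributions toward activity, blue for negative. Writes PNG or SVG by
#' file extension.
#'
#' @param smiles standardized SMILES.
#' @param weights per-atom weight vector.
#' @param path output file ending in .png or .svg.
#' @param scale circle size scale.
#' @return the path, invisibly.
#' @export
renderAtomWeights <- function(smiles, weights, path, scale = 1) {
  g <- molgraph(smiles)
  if (length(weights) != g$n) stop("one weight per atom required")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") grDevices::png(path, width = 900, height = 700, res = 150)
  else if (ext == "svg") grDevices::svg(path, width = 6, height = 5)
  else stop("unsupported extension: ", ext)
  on.exit(grDevices::dev.off(), add = TRUE)

  xy <- g$coords
  graphics::par(mar = c(0.5, 0.5, 0.5, 0.5))
  graphics::plot(xy, type = "n", axes = FALSE, xlab = "", ylab = "", asp = 1)
  wmax <- max(abs(weights), 1e-12)
  for (i in seq_len(g$n)) {
    w <- weights[i] / wmax
    if (abs(w) < 1e-9) next
    col <- if (w > 0) grDevices::rgb(1, 0.55 * (1 - w), 0, alpha = 0.55)
           else grDevices::rgb(0, 0.4 * (1 + w), 1, alpha = 0.55)
    graphics::symbols(xy[i, 1], xy[i, 2], circles = 0.32 * scale * sqrt(abs(w)),
                      inches = FALSE, add = TRUE, fg = NA, bg = col)
  }
  for (k in seq_len(nrow(g$bonds))) {
    a <- g$bonds$a[k]; b <- g$bonds$b[k]
    graphics::segments(xy[a, 1], xy[a, 2], xy[b, 1], xy[b, 2], lwd = 2)
    if (g$bonds$order[k] >= 2) {
      dx <- xy[b, 2] - xy[a, 2]; dy <- xy[a, 1] - xy[b, 1]
      nrm <- sqrt(dx ^ 2 + dy ^ 2); if (nrm == 0) nrm <- 1
      off <- 0.07
      graphics::segments(xy[a, 1] + off * dx / nrm, xy[a, 2] + off * dy / nrm,
                         xy[b, 1] + off * dx / nrm, xy[b, 2] + off * dy / nrm,
                         lwd = 1.4)
    }
  }
  show_lab <- g$elem != "C"
  if (any(show_lab))
    graphics::text(xy[show_lab, 1], xy[show_lab, 2], g$elem[show_lab],
                   cex = 0.8, font = 2)
  invisible(path)
}
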