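# 2D-pharmacophore fingerprint: chemical feature families combined with
# binned topological (bond-count) distances.
#
# Families: H-bond acceptor (A), H-bond donor (D), positive ionizable (P),
# negative ionizable (N), aromatic (R). Combinations of two and three
# features are encoded; topological distances are binned into 0-2, 3-5 and
# 6-8 bonds (pairs further apart are not encoded). The vector length is
# fixed by this scheme: 15 family pairs x 3 bins + 35 family triples x 10
# distance-bin multisets = 395.

.PHARM2D_FAMILIES <- c("A", "D", "P", "N", "R")
.PHARM2D_BINS <- 3L

.pharm2dPairIndex <- local({
  fams <- c("A", "D", "P", "N", "R")
  combs <- list(); k <- 0L
  for (i in 1:5) for (j in i:5) { k <- k + 1L
    combs[[paste(fams[i], fams[j])]] <- k }
  combs
})

.pharm2dTripleIndex <- local({
  fams <- c("A", "D", "P", "N", "R")
  combs <- list(); k <- 0L
  for (i in 1:5) for (j in i:5) for (l in j:5) { k <- k + 1L
    combs[[paste(fams[i], fams[j], fams[l])]] <- k }
  combs
})

.pharm2dBinTripleIndex <- local({
  combs <- list(); k <- 0L
  for (i in 1:3) for (j in i:3) for (l in j:3) { k <- k + 1L
    combs[[paste(i, j, l)]] <- k }
  combs
})

.PHARM2D_LEN <- 15L * 3L + 35L * 10L  # 395

# adjacent to a carbonyl / thiocarbonyl carbon (amide-like environment)
.adjCarbonyl <- function(g, a) {
  for (j in seq_along(g$adj[[a]])) {
    c_ <- g$adj[[a]][j]
    if (g$elem[c_] != "C") next
    ks <- g$bidx[[c_]]
    for (k in ks) {
      other <- if (g$bonds$a[k] == c_) g$bonds$b[k] else g$bonds$a[k]
      if (g$bonds$order[k] == 2 && g$elem[other] %in% c("O", "S")) return(TRUE)
    }
  }
  FALSE
}

# pharmacophore feature instances: list of (family, atoms)
pharmFeatures <- function(g) {
  feats <- list()
  add <- function(family, atoms)
    feats[[length(feats) + 1L]] <<- list(family = family, atoms = atoms)

  for (a in seq_len(g$n)) {
    el <- g$elem[a]
    if (el %in% c("N", "O")) {
      if (g$nH[a] >= 1 && g$charge[a] >= 0) add("D", a)
      pyrrole_like <- el == "N" && g$aromatic[a] &&
        (g$nH[a] >= 1 || mgDegree(g)[a] >= 3)
      if (g$charge[a] <= 0 && !pyrrole_like &&
          !(el == "N" && .adjCarbonyl(g, a)))
        add("A", a)
    }
    if (g$charge[a] > 0) add("P", a)
    if (g$charge[a] < 0) add("N", a)
    # neutral basic amine: non-aromatic N, all single bonds, no adjacent
    # carbonyl, at least one H or three heavy neighbors
    if (el == "N" && !g$aromatic[a] && g$charge[a] == 0 &&
        all(g$bonds$order[g$bidx[[a]]] == 1) && !.adjCarbonyl(g, a))
      add("P", a)
  }
  # acidic groups: carboxylic / sulfonic / phosphonic acid -> negative
  for (a in seq_len(g$n)) {
    if (!g$elem[a] %in% c("C", "S", "P")) next
    ks <- g$bidx[[a]]
    dbl_o <- integer(0); oh <- integer(0)
    for (k in ks) {
      other <- if (g$bonds$a[k] == a) g$bonds$b[k] else g$bonds$a[k]
      if (g$elem[other] == "O") {
        if (g$bonds$order[k] == 2) dbl_o <- c(dbl_o, other)
        else if (g$nH[other] >= 1) oh <- c(oh, other)
      }
    }
    if (length(dbl_o) >= 1 && length(oh) >= 1)
      add("N", c(a, dbl_o, oh))
  }
  # aromatic rings as ring-centered features
  for (i in seq_along(g$ringlist))
    if (g$aromring[i]) add("R", g$ringlist[[i]])
  feats
}

.pharmBin <- function(d) {
  if (d <= 2) 1L else if (d <= 5) 2L else if (d <= 8) 3L else NA_integer_
}

pharm2dFP <- function(g) {
  if (is.character(g)) g <- molgraph(g)
  feats <- pharmFeatures(g)
  bits <- integer(.PHARM2D_LEN)
  nf <- length(feats)
  if (nf < 2) return(bits)
  fam <- vapply(feats, `[[`, "", "family")
  # min topological distance between feature atom sets
  fdist <- matrix(0L, nf, nf)
  for (i in seq_len(nf - 1)) for (j in (i + 1):nf)
    fdist[i, j] <- fdist[j, i] <-
      as.integer(min(g$dist[feats[[i]]$atoms, feats[[j]]$atoms]))

  for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
    b <- .pharmBin(fdist[i, j])
    if (is.na(b)) next
    fp <- paste(sort(c(fam[i], fam[j])), collapse = " ")
    idx <- (.pharm2dPairIndex[[fp]] - 1L) * 3L + b
    bits[idx] <- 1L
  }
  if (nf >= 3) {
    for (i in seq_len(nf - 2)) for (j in (i + 1):(nf - 1)) for (l in (j + 1):nf) {
      bs <- c(.pharmBin(fdist[i, j]), .pharmBin(fdist[i, l]),
              .pharmBin(fdist[j, l]))
      if (any(is.na(bs))) next
      ft <- paste(sort(c(fam[i], fam[j], fam[l])), collapse = " ")
      bt <- paste(sort(bs), collapse = " ")
      idx <- 45L + (.pharm2dTripleIndex[[ft]] - 1L) * 10L +
             .pharm2dBinTripleIndex[[bt]]
      bits[idx] <- 1L
    }
  }
  bits
}
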