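# 128 physicochemical / topological descriptors computed on the internal
# molecular graph. The descriptor list is pinned in a versioned manifest
# (descriptorNames()) so the vector layout is stable across runs.

.ATOMIC_MASS <- c(H = 1.008, He = 4.003, Li = 6.94, Be = 9.012, B = 10.81,
  C = 12.011, N = 14.007, O = 15.999, F = 18.998, Na = 22.99, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, K = 39.098,
  Ca = 40.078, Fe = 55.845, Cu = 63.546, Zn = 65.38, Se = 78.971,
  Br = 79.904, Ag = 107.868, Sn = 118.71, I = 126.904, Pt = 195.084,
  Au = 196.967, Hg = 200.592)

.PAULING_EN <- c(H = 2.20, Li = 0.98, Be = 1.57, B = 2.04, C = 2.55,
  N = 3.04, O = 3.44, F = 3.98, Na = 0.93, Mg = 1.31, Al = 1.61, Si = 1.90,
  P = 2.19, S = 2.58, Cl = 3.16, K = 0.82, Ca = 1.00, Fe = 1.83, Cu = 1.90,
  Zn = 1.65, Se = 2.55, Br = 2.96, Sn = 1.96, I = 2.66, Pt = 2.28,
  Au = 2.54, Hg = 2.00)

# coarse covalent radii (pm / 100) for surface-area style sums
.COV_RADIUS <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
  F = 0.57, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20, I = 1.39)

# Crippen-style coarse atomic logP / molar refractivity contributions
.LOGP_CONTRIB <- function(elem, aromatic) {
  base <- c(C = 0.13, N = -0.60, O = -0.45, S = 0.25, F = 0.14, Cl = 0.65,
            Br = 0.86, I = 1.12, P = -0.40, B = -0.1, Si = 0.1)
  v <- unname(base[elem]); v[is.na(v)] <- -0.2
  v + ifelse(aromatic & elem == "C", 0.16, 0)
}

.MR_CONTRIB <- c(C = 2.75, N = 2.50, O = 1.60, S = 7.35, F = 0.90,
  Cl = 5.85, Br = 8.75, I = 13.95, P = 6.9, H = 1.03)

#' Names of the 128 molecular descriptors (versioned manifest)
#'
#' @return character vector of length 128.
#' @export
descriptorNames <- function() {
  c("HeavyAtomCount", "TotalHCount", "CCount", "NCount", "OCount", "SCount",
    "FCount", "ClCount", "BrCount", "ICount", "PCount", "BCount",
    "HalogenCount", "HeteroatomCount", "NetFormalCharge", "AbsFormalCharge",
    "MolWt", "AvgAtomicMass", "HBondDonorCount", "HBondAcceptorCount",
    "RotatableBondCount", "FractionCsp3", "BondCount", "MultipleBondCount",
    "RingCount", "AromaticRingCount", "SaturatedRingCount",
    "HeteroRingCount", "AromaticHeteroRingCount", "AromaticCarbocycleCount",
    "RingAtomFraction", "AromaticAtomFraction", "LargestRingSize",
    "SmallestRingSize", "Ring3Count", "Ring4Count", "Ring5Count",
    "Ring6Count", "Ring7Count", "Ring8Count",
    "Degree1Count", "Degree2Count", "Degree3Count", "Degree4Count",
    "Chi0", "Chi1", "Chi0v", "Chi1v", "Chi2v", "Chi3v", "Chi4v",
    "Kappa1", "Kappa2", "Kappa3",
    "WienerIndex", "Zagreb1", "Zagreb2", "BalabanJ",
    "TPSA", "ApproxSurfaceArea", "CrippenLogP", "CrippenMR",
    "EStateSum", "EStateMax", "EStateMin", "EStateMean",
    "EStateSumCaliph", "EStateSumCarom", "EStateSumN", "EStateSumO",
    paste0("ATS", rep(1:8, times = 6), rep(c("m", "e", "z", "d", "p", "c"),
                                           each = 8)),
    "BurdenMassMax", "BurdenMassMin", "BurdenENMax", "BurdenENMin",
    "GraphDiameter", "GraphRadius", "PetitjeanIndex", "BondAtomRatio",
    "MeanTopoDistance", "Path3Count")
}

# Ertl-style polar surface contributions for the common N/O environments
.tpsaContrib <- function(g, a) {
  el <- g$elem[a]
  if (!el %in% c("N", "O")) return(0)
  nH <- g$nH[a]
  ks <- g$bidx[[a]]
  ords <- g$bonds$order[ks]
  arom <- g$aromatic[a]
  if (el == "O") {
    if (arom) return(13.14)
    if (any(ords == 2)) return(17.07)
    if (nH >= 1) return(20.23)
    return(9.23)
  }
  # nitrogen
  if (arom) return(if (nH >= 1) 15.79 else 12.89)
  if (any(ords == 3)) return(23.79)
  if (any(ords == 2)) return(if (nH >= 1) 23.85 else 12.36)
  if (nH >= 2) return(26.02)
  if (nH == 1) return(12.03)
  3.24
}

.estate <- function(g) {
  # Kier-Hall intrinsic state I = ((2/L)^2 * dv + 1) / d with a simple
  # perturbation sum over topological distance
  deg <- mgDegree(g)
  dv <- pmax(1, g$Z - 2 - g$nH)            # crude valence-electron count
  I <- ((4 / pmax(g$Z, 1)) ^ 0 * dv + 1) / pmax(deg, 1)
  n <- g$n
  S <- I
  if (n > 1) for (a in seq_len(n)) {
    d <- g$dist[a, ]
    pert <- sum((I[a] - I[-a]) / (d[-a] + 1) ^ 2)
    S[a] <- I[a] + pert
  }
  S
}

descriptorVector <- function(g) {
  if (is.character(g)) g <- molgraph(g)
  n <- g$n; el <- g$elem; deg <- mgDegree(g)
  cnt <- function(e) sum(el == e)
  halogens <- sum(el %in% c("F", "Cl", "Br", "I"))
  nb <- nrow(g$bonds)
  rp <- .pcRingProps(g)
  nr <- if (is.null(rp)) 0L else nrow(rp)
  bcode <- if (nb) vapply(seq_len(nb), function(k) .bondCode(g, k), 0L) else integer(0)

  mass <- .ATOMIC_MASS[el]; mass[is.na(mass)] <- 12
  mw <- sum(mass) + 1.008 * sum(g$nH)

  # rotatable: single, acyclic, both atoms with heavy degree >= 2, not amide
  rot <- 0L
  if (nb) for (k in seq_len(nb)) {
    a <- g$bonds$a[k]; b <- g$bonds$b[k]
    if (g$bonds$order[k] != 1) next
    if (bcode[k] == 4) next
    inring_bond <- any(vapply(seq_along(g$ringlist), function(i)
      a %in% g$ringlist[[i]] && b %in% g$ringlist[[i]], TRUE))
    if (isTRUE(inring_bond)) next
    if (deg[a] >= 2 && deg[b] >= 2) rot <- rot + 1L
  }

  csp3 <- sum(el == "C" & !g$aromatic &
              vapply(seq_len(n), function(a)
                all(g$bonds$order[g$bidx[[a]]] == 1) || deg[a] == 0, TRUE))
  frac_csp3 <- if (cnt("C") > 0) csp3 / cnt("C") else 0

  hbd <- sum(el %in% c("N", "O") & g$nH >= 1)
  hba <- sum(el %in% c("N", "O") & g$charge <= 0)

  # connectivity indices
  chi0 <- sum(1 / sqrt(pmax(deg, 1)))
  chi1 <- if (nb) sum(1 / sqrt(deg[g$bonds$a] * deg[g$bonds$b])) else 0
  dv <- pmax(1, g$Z - 2 - g$nH)
  chi0v <- sum(1 / sqrt(dv))
  chi1v <- if (nb) sum(1 / sqrt(dv[g$bonds$a] * dv[g$bonds$b])) else 0
  chiNv <- function(len) {
    paths <- .enumeratePaths(g, maxlen = len)
    paths <- Filter(function(p) length(p$bonds) == len, paths)
    if (!length(paths)) return(0)
    sum(vapply(paths, function(p) 1 / sqrt(prod(dv[p$atoms])), 0))
  }
  chi2v <- chiNv(2L); chi3v <- chiNv(3L); chi4v <- chiNv(4L)

  # kappa shape indices
  p1 <- nb
  paths2 <- .enumeratePaths(g, maxlen = 2L)
  p2 <- sum(vapply(paths2, function(p) length(p$bonds) == 2L, TRUE))
  paths3 <- .enumeratePaths(g, maxlen = 3L)
  p3 <- sum(vapply(paths3, function(p) length(p$bonds) == 3L, TRUE))
  kappa1 <- if (p1 > 0) n * (n - 1) ^ 2 / p1 ^ 2 else 0
  kappa2 <- if (p2 > 0) (n - 1) * (n - 2) ^ 2 / p2 ^ 2 else 0
  kappa3 <- if (p3 > 0 && n >= 3) {
    if (n %% 2 == 1) (n - 1) * (n - 3) ^ 2 / p3 ^ 2
    else (n - 3) * (n - 2) ^ 2 / p3 ^ 2
  } else 0

  D <- g$dist; diag(D) <- 0
  finite <- D[upper.tri(D)]
  wiener <- sum(finite)
  zag1 <- sum(deg ^ 2)
  zag2 <- if (nb) sum(deg[g$bonds$a] * deg[g$bonds$b]) else 0
  dsum <- rowSums(D)
  mu <- nb - n + 1L   # cyclomatic number
  balaban <- if (nb > 0 && all(dsum > 0))
    nb / (mu + 1) * sum(if (nb) 1 / sqrt(dsum[g$bonds$a] * dsum[g$bonds$b]) else 0)
  else 0

  tpsa <- sum(vapply(seq_len(n), function(a) .tpsaContrib(g, a), 0))
  radius_ <- .COV_RADIUS[el]; radius_[is.na(radius_)] <- 1
  asa <- sum(4 * pi * (radius_ + 0.1 * g$nH) ^ 2)
  logp <- sum(.LOGP_CONTRIB(el, g$aromatic)) + 0.12 * sum(g$nH[el == "C"])
  mrc <- .MR_CONTRIB[el]; mrc[is.na(mrc)] <- 3
  mr <- sum(mrc) + 1.03 * sum(g$nH)

  S <- .estate(g)
  es <- c(sum(S), max(S), min(S), mean(S),
          sum(S[el == "C" & !g$aromatic]), sum(S[el == "C" & g$aromatic]),
          sum(S[el == "N"]), sum(S[el == "O"]))

  # Moreau-Broto autocorrelation over topological distance 1..8
  en <- .PAULING_EN[el]; en[is.na(en)] <- 2.2
  props <- list(m = mass, e = en, z = g$Z, d = deg,
                p = 0.5 * g$Z + en,          # polarizability proxy
                c = g$charge + g$nH * 0.1)
  ats <- numeric(48)
  k <- 0L
  for (pr in props) {
    for (d in 1:8) {
      k <- k + 1L
      sel <- which(D == d & upper.tri(D), arr.ind = TRUE)
      ats[k] <- if (nrow(sel)) sum(pr[sel[, 1]] * pr[sel[, 2]]) else 0
    }
  }
  # manifest orders lags within property blocks (m, e, z, d, p, c)
  ats <- ats

  burden <- function(w) {
    B <- matrix(0.001, n, n)
    if (nb) for (kk in seq_len(nb)) {
      v <- switch(as.character(g$bonds$order[kk]), "1" = 0.1, "2" = 0.2,
                  "3" = 0.3, 0.15)
      B[g$bonds$a[kk], g$bonds$b[kk]] <- v
      B[g$bonds$b[kk], g$bonds$a[kk]] <- v
    }
    diag(B) <- w
    ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
    c(max(ev), min(ev))
  }
  bm <- burden(mass / 12); be <- burden(en / 2.55)

  ecc <- apply(D, 1, max)
  diam <- max(ecc); rad <- min(ecc)
  petitjean <- if (rad > 0) (diam - rad) / rad else 0

  v <- c(n, sum(g$nH), cnt("C"), cnt("N"), cnt("O"), cnt("S"), cnt("F"),
    cnt("Cl"), cnt("Br"), cnt("I"), cnt("P"), cnt("B"), halogens,
    sum(!el %in% c("C", "H")), sum(g$charge), sum(abs(g$charge)),
    mw, mw / max(1, n + sum(g$nH)), hbd, hba, rot, frac_csp3, nb,
    if (nb) sum(g$bonds$order > 1 | bcode == 4) else 0,
    nr,
    if (nr) sum(rp$aromatic) else 0,
    if (nr) sum(rp$saturated) else 0,
    if (nr) sum(rp$hetero) else 0,
    if (nr) sum(rp$aromatic & rp$hetero) else 0,
    if (nr) sum(rp$aromatic & rp$carbon_only) else 0,
    sum(g$inring) / n, sum(g$aromatic) / n,
    if (nr) max(rp$size) else 0, if (nr) min(rp$size) else 0,
    if (nr) sum(rp$size == 3) else 0, if (nr) sum(rp$size == 4) else 0,
    if (nr) sum(rp$size == 5) else 0, if (nr) sum(rp$size == 6) else 0,
    if (nr) sum(rp$size == 7) else 0, if (nr) sum(rp$size == 8) else 0,
    sum(deg == 1), sum(deg == 2), sum(deg == 3), sum(deg >= 4),
    chi0, chi1, chi0v, chi1v, chi2v, chi3v, chi4v,
    kappa1, kappa2, kappa3,
    wiener, zag1, zag2, balaban,
    tpsa, asa, logp, mr, es, ats,
    bm[1], bm[2], be[1], be[2],
    diam, rad, petitjean, if (n > 0) nb / n else 0,
    if (n > 1) mean(finite) else 0, p3)
  v[!is.finite(v)] <- 0
  names(v) <- descriptorNames()
  v
}
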