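# 881-bit substructure-key fingerprint.
#
# Follows the public substructure-key layout: hierarchic element counts,
# ring counts by size and composition, bonded element pairs, atom
# neighborhoods (with and without bond orders), short linear fragments and
# aromatic-ring substitution patterns. Section spans match the published
# 881-bit layout; the key definitions inside each section are this
# package's own deterministic enumeration (documented in the vignette),
# so vectors are comparable within this package, not bit-compatible with
# other toolkits.

.pcElementKeys <- local({
  counted <- list(H = c(4, 8, 16, 32), Li = c(1, 2), Be = 1, B = c(1, 2, 4),
    C = c(2, 4, 8, 16, 32), N = c(1, 2, 4, 8), O = c(1, 2, 4, 8, 16),
    F = c(1, 2, 4), Na = c(1, 2), Mg = 1, Al = 1, Si = c(1, 2),
    P = c(1, 2, 4), S = c(1, 2, 4, 8), Cl = c(1, 2, 4, 8), K = c(1, 2),
    Ca = 1, Br = c(1, 2, 4), I = c(1, 2, 4))
  keys <- list()
  for (el in names(counted)) for (th in counted[[el]])
    keys[[length(keys) + 1L]] <- c(el, th)
  presence <- c("He", "Ne", "Ar", "Kr", "Xe", "Sc", "Ti", "V", "Cr", "Mn",
    "Fe", "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Rb", "Sr", "Y",
    "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn", "Sb",
    "Te", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Sm", "Gd", "Dy", "Er", "Yb", "Lu",
    "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi",
    "Th", "U", "Pu")
  for (el in presence) keys[[length(keys) + 1L]] <- c(el, 1)
  stopifnot(length(keys) == 115L)
  keys
})

# ring classification helpers on the minimal ring basis
.pcRingProps <- function(g) {
  rl <- g$ringlist
  if (!length(rl)) return(NULL)
  data.frame(
    size = lengths(rl),
    carbon_only = vapply(rl, function(r) all(g$elem[r] == "C"), TRUE),
    has_n = vapply(rl, function(r) any(g$elem[r] == "N"), TRUE),
    hetero = vapply(rl, function(r) any(g$elem[r] != "C"), TRUE),
    aromatic = g$aromring,
    saturated = vapply(seq_along(rl), function(i) {
      r <- rl[[i]]
      if (g$aromring[i]) return(FALSE)
      ks <- unique(unlist(g$bidx[r]))
      all(g$bonds$order[ks][g$bonds$a[ks] %in% r & g$bonds$b[ks] %in% r] == 1)
    }, TRUE))
}

.pcRingBits <- function(g) {
  bits <- integer(148)
  rp <- .pcRingProps(g)
  pos <- 0L
  for (s in 3:10) {
    sel <- if (is.null(rp)) rep(FALSE, 0) else rp$size == s
    cnts <- c(any = sum(sel),
      carbon = if (is.null(rp)) 0 else sum(sel & rp$carbon_only),
      nitro = if (is.null(rp)) 0 else sum(sel & rp$has_n),
      hetero = if (is.null(rp)) 0 else sum(sel & rp$hetero),
      sat = if (is.null(rp)) 0 else sum(sel & rp$saturated),
      unsat = if (is.null(rp)) 0 else sum(sel & !rp$saturated & !rp$aromatic),
      arom = if (is.null(rp)) 0 else sum(sel & rp$aromatic))
    for (cnt in cnts) for (th in c(1, 2)) {
      pos <- pos + 1L
      if (cnt >= th) bits[pos] <- 1L
    }
  }
  # global ring-census keys fill the remainder of the section
  glob <- c(
    total = if (is.null(rp)) 0 else nrow(rp),
    arom = if (is.null(rp)) 0 else sum(rp$aromatic),
    hetarom = if (is.null(rp)) 0 else sum(rp$aromatic & rp$hetero),
    carbarom = if (is.null(rp)) 0 else sum(rp$aromatic & rp$carbon_only),
    narom = if (is.null(rp)) 0 else sum(rp$aromatic & rp$has_n),
    sathet = if (is.null(rp)) 0 else sum(rp$saturated & rp$hetero),
    unsat = if (is.null(rp)) 0 else sum(!rp$saturated & !rp$aromatic))
  ths <- list(total = 1:8, arom = 1:4, hetarom = 1:4, carbarom = 1:4,
              narom = 1:4, sathet = 1:4, unsat = 1:4)
  for (nm in names(ths)) for (th in ths[[nm]]) {
    pos <- pos + 1L
    if (glob[[nm]] >= th) bits[pos] <- 1L
  }
  # fused systems: rings sharing at least one bond with another ring
  fused <- 0L
  if (!is.null(rp) && nrow(rp) >= 2) {
    rl <- g$ringlist
    for (i in seq_along(rl)) {
      for (j in seq_along(rl)) {
        if (i != j && length(intersect(rl[[i]], rl[[j]])) >= 2) {
          fused <- fused + 1L; break
        }
      }
    }
  }
  for (th in 1:4) { pos <- pos + 1L; if (fused >= th) bits[pos] <- 1L }
  stopifnot(pos == 148L)
  bits
}

.pcPairElems <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I")
.pcPairKeys <- local({
  keys <- list()
  for (i in seq_along(.pcPairElems)) for (j in i:length(.pcPairElems)) {
    keys[[length(keys) + 1L]] <- c(.pcPairElems[i], .pcPairElems[j])
    if (length(keys) == 64L) break
  }
  keys[seq_len(64L)]
})

.pcNeighborKeys <- local({
  centers <- c("C", "N", "O", "S", "P")
  nbrs <- c("C", "N", "O", "S", "X", "H")  # X = any halogen
  keys <- list()
  for (ce in centers) for (i in seq_along(nbrs)) for (j in i:length(nbrs)) {
    keys[[length(keys) + 1L]] <- list(center = ce, nb = c(nbrs[i], nbrs[j]))
  }
  keys[seq_len(89L)]
})

.pcDetailedKeys <- local({
  keys <- list()
  for (ce in c("C", "N")) for (db in c("C", "N", "O", "S"))
    for (sg in c("C", "N", "O", "S", "H", "X")) {
      keys[[length(keys) + 1L]] <- list(center = ce, double = db, single = sg)
    }
  # triple-bond keys complete the section
  for (pair in list(c("C", "C"), c("C", "N"), c("N", "N"), c("C", "O")))
    keys[[length(keys) + 1L]] <- list(center = pair[1], triple = pair[2])
  keys[seq_len(44L)]
})

.pcFragmentKeys <- local({
  # short linear fragments: element-bond-element(-bond-element)
  el <- c("C", "N", "O", "S")
  bo <- c(1L, 2L, 3L, 4L)       # single, double, triple, aromatic
  keys <- list()
  for (a in el) for (b1 in bo) for (b in el)
    keys[[length(keys) + 1L]] <- list(e = c(a, b), b = b1)
  for (a in el) for (b1 in bo) for (b in el) for (b2 in bo) for (cc in el) {
    if (length(keys) >= 253L) break
    keys[[length(keys) + 1L]] <- list(e = c(a, b, cc), b = c(b1, b2))
  }
  keys[seq_len(253L)]
})

.pcAromKeys <- local({
  # aromatic-ring substitution patterns
  subst <- c("C", "N", "O", "S", "F", "Cl", "Br")
  keys <- list()
  for (ring in c("carb6", "het6", "het5")) {
    for (s in subst)
      keys[[length(keys) + 1L]] <- list(ring = ring, sub = s)
    for (i in seq_along(subst)) for (j in i:length(subst)) {
      for (rel in if (ring == "het5") c(1, 2) else c(1, 2, 3)) {
        keys[[length(keys) + 1L]] <-
          list(ring = ring, sub = c(subst[i], subst[j]), rel = rel)
      }
    }
  }
  keys[seq_len(168L)]
})

.pcMatchHalogen <- function(el) el %in% c("F", "Cl", "Br", "I")

pubchemFP <- function(g) {
  if (is.character(g)) g <- molgraph(g)
  bits <- integer(881L)
  deg <- mgDegree(g)

  # --- element counts (115) ---
  counts <- table(g$elem)
  nh <- sum(g$nH)
  for (i in seq_along(.pcElementKeys)) {
    k <- .pcElementKeys[[i]]
    cnt <- if (k[1] == "H") nh else if (k[1] %in% names(counts)) counts[[k[1]]] else 0
    if (cnt >= as.numeric(k[2])) bits[i] <- 1L
  }

  # --- ring census (148) ---
  bits[116:263] <- .pcRingBits(g)

  # --- bonded element pairs (64) ---
  pairset <- character(0)
  for (k in seq_len(nrow(g$bonds))) {
    e1 <- g$elem[g$bonds$a[k]]; e2 <- g$elem[g$bonds$b[k]]
    pairset <- c(pairset, paste(sort(c(e1, e2)), collapse = "-"))
  }
  for (a in seq_len(g$n)) if (g$nH[a] > 0)
    pairset <- c(pairset, paste(sort(c("H", g$elem[a])), collapse = "-"))
  pairset <- unique(pairset)
  for (i in seq_along(.pcPairKeys)) {
    k <- sort(.pcPairKeys[[i]])
    if (paste(k, collapse = "-") %in% pairset) bits[263L + i] <- 1L
  }

  # --- simple neighborhoods (89) ---
  matchNb <- function(wanted, have_elems, have_h) {
    # multiset containment; "X" matches any halogen, "H" implicit hydrogens
    avail <- c(have_elems, rep("H", have_h))
    for (w in wanted) {
      hit <- if (w == "X") which(.pcMatchHalogen(avail))[1]
             else which(avail == w)[1]
      if (is.na(hit)) return(FALSE)
      avail <- avail[-hit]
    }
    TRUE
  }
  for (i in seq_along(.pcNeighborKeys)) {
    k <- .pcNeighborKeys[[i]]
    for (a in which(g$elem == k$center)) {
      if (matchNb(k$nb, g$elem[g$adj[[a]]], g$nH[a])) {
        bits[327L + i] <- 1L; break
      }
    }
  }

  # --- detailed neighborhoods with bond orders (44) ---
  for (i in seq_along(.pcDetailedKeys)) {
    k <- .pcDetailedKeys[[i]]
    for (a in which(g$elem == k$center)) {
      ks <- g$bidx[[a]]
      others <- ifelse(g$bonds$a[ks] == a, g$bonds$b[ks], g$bonds$a[ks])
      ords <- g$bonds$order[ks]
      if (!is.null(k$triple)) {
        if (any(ords == 3 & g$elem[others] == k$triple)) {
          bits[415L + i] <- 1L; break
        }
      } else {
        has_db <- any(ords == 2 & g$elem[others] == k$double)
        has_sg <- if (k$single == "H") g$nH[a] > 0
          else if (k$single == "X") any(ords == 1 & .pcMatchHalogen(g$elem[others]))
          else any(ords == 1 & g$elem[others] == k$single)
        if (has_db && has_sg) { bits[415L + i] <- 1L; break }
      }
    }
  }

  # --- short linear fragments (253) ---
  paths3 <- .enumeratePaths(g, maxlen = 2L)
  bcode <- vapply(seq_len(nrow(g$bonds)), function(k) .bondCode(g, k), 0L)
  fragset <- character(0)
  for (p in paths3) {
    el <- g$elem[p$atoms]; bo <- bcode[p$bonds]
    fwd <- paste(c(rbind(el, c(bo, "")))[-2 * length(el)], collapse = "")
    bwd <- paste(c(rbind(rev(el), c(rev(bo), "")))[-2 * length(el)], collapse = "")
    fragset <- c(fragset, min(fwd, bwd))
  }
  fragset <- unique(fragset)
  for (i in seq_along(.pcFragmentKeys)) {
    k <- .pcFragmentKeys[[i]]
    sig <- paste(c(rbind(k$e, c(k$b, "")))[-2 * length(k$e)], collapse = "")
    rsig <- paste(c(rbind(rev(k$e), c(rev(k$b), "")))[-2 * length(k$e)], collapse = "")
    if (min(sig, rsig) %in% fragset || max(sig, rsig) %in% fragset)
      bits[460L + i] <- 1L
  }

  # --- aromatic substitution patterns (168) ---
  ringClass <- function(i) {
    r <- g$ringlist[[i]]
    if (!g$aromring[i]) return(NA_character_)
    if (length(r) == 6 && all(g$elem[r] == "C")) "carb6"
    else if (length(r) == 6) "het6"
    else if (length(r) == 5) "het5"
    else NA_character_
  }
  subinfo <- list()
  for (i in seq_along(g$ringlist)) {
    cl <- ringClass(i)
    if (is.na(cl)) next
    r <- g$ringlist[[i]]
    subs <- list()
    for (pidx in seq_along(r)) {
      a <- r[pidx]
      ext <- setdiff(g$adj[[a]], r)
      for (e in ext) subs[[length(subs) + 1L]] <- c(pos = pidx, el = g$elem[e])
    }
    subinfo[[length(subinfo) + 1L]] <- list(class = cl, size = length(r),
                                            subs = subs)
  }
  for (i in seq_along(.pcAromKeys)) {
    k <- .pcAromKeys[[i]]
    for (ri in subinfo) {
      if (ri$class != k$ring) next
      els <- vapply(ri$subs, function(s) s[["el"]], "")
      if (length(k$sub) == 1) {
        if (k$sub %in% els) { bits[713L + i] <- 1L; break }
      } else {
        hit <- FALSE
        ns <- length(ri$subs)
        if (ns >= 2) for (x in seq_len(ns - 1)) for (y in (x + 1):ns) {
          p1 <- as.integer(ri$subs[[x]][["pos"]])
          p2 <- as.integer(ri$subs[[y]][["pos"]])
          d <- abs(p1 - p2); d <- min(d, ri$size - d)   # ring separation
          pair <- sort(c(ri$subs[[x]][["el"]], ri$subs[[y]][["el"]]))
          if (d == k$rel && identical(pair, sort(k$sub))) { hit <- TRUE; break }
        }
        if (hit) { bits[713L + i] <- 1L; break }
      }
    }
  }
  bits
}
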