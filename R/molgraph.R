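# Internal molecular graph built on ChemmineR/OpenBabel parsing.
#
# A molgraph is a plain list describing one connected, standardized
# molecule: elements, formal charges, implicit hydrogen counts, bonds with
# kekulized orders, ring membership, aromaticity flags and the topological
# distance matrix. Every representation in the package is computed from
# this structure, which keeps the bit -> atom retro-mapping exact.

.ELEMENTS <- c(H = 1, He = 2, Li = 3, Be = 4, B = 5, C = 6, N = 7, O = 8,
  F = 9, Ne = 10, Na = 11, Mg = 12, Al = 13, Si = 14, P = 15, S = 16,
  Cl = 17, Ar = 18, K = 19, Ca = 20, Sc = 21, Ti = 22, V = 23, Cr = 24,
  Mn = 25, Fe = 26, Co = 27, Ni = 28, Cu = 29, Zn = 30, Ga = 31, Ge = 32,
  As = 33, Se = 34, Br = 35, Kr = 36, Rb = 37, Sr = 38, Y = 39, Zr = 40,
  Ag = 47, Cd = 48, In = 49, Sn = 50, Sb = 51, Te = 52, I = 53, Xe = 54,
  Cs = 55, Ba = 56, Pt = 78, Au = 79, Hg = 80, Tl = 81, Pb = 82, Bi = 83)

# Default valences used to infer implicit hydrogens from kekulized bonds.
.VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
  S = 2, Cl = 1, Br = 1, I = 1, Se = 2, As = 3)

.mdlCharge <- function(code) {
  # MDL old-style charge codes: 1..3 => +3..+1, 4 => radical, 5..7 => -1..-3
  ifelse(code == 0 | code == 4, 0L, 4L - as.integer(code))
}

.molgraphCache <- new.env(parent = emptyenv())

#' Parse a standardized SMILES into an internal molecular graph
#'
#' Used by every featurizer. Results are memoised per SMILES string.
#'
#' @param smiles a single SMILES string (one connected fragment).
#' @return a list with atom, bond, ring and distance information.
#' @keywords internal
#' @noRd
molgraph <- function(smiles) {
  key <- smiles
  hit <- .molgraphCache[[key]]
  if (!is.null(hit)) return(hit)

  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))[[1]]),
    error = function(e) NULL)
  if (is.null(sdf)) stop("unparseable SMILES: ", smiles)

  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  n <- nrow(ab)
  if (n == 0) stop("zero-atom molecule: ", smiles)
  elem <- sub("_.*$", "", rownames(ab))
  chg_col <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n)
  charge <- .mdlCharge(chg_col)
  coords <- cbind(x = ab[, 1], y = ab[, 2])

  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- data.frame(a = integer(0), b = integer(0), order = integer(0))
  } else {
    bonds <- data.frame(a = as.integer(bb[, 1]), b = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
  }

  adj <- vector("list", n)
  bidx <- vector("list", n)   # incident bond ids per atom
  for (k in seq_len(nrow(bonds))) {
    a <- bonds$a[k]; b <- bonds$b[k]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    bidx[[a]] <- c(bidx[[a]], k); bidx[[b]] <- c(bidx[[b]], k)
  }

  # ring perception + aromaticity via ChemmineR, reduced to a minimal
  # (SSSR-sized) ring basis by greedy bond coverage over increasing size
  ringlist <- list(); aromring <- logical(0)
  n_sssr <- nrow(bonds) - n + 1L
  if (n_sssr > 0) {
    rr <- tryCatch(ChemmineR::rings(sdf, upper = 12, type = "all", arom = TRUE),
                   error = function(e) list(RINGS = list(), AROMATIC = logical(0)))
    rl <- rr$RINGS
    if (length(rl) > 0) {
      sizes <- lengths(rl)
      ord <- order(sizes)
      bondkey <- function(atoms) {
        m <- length(atoms)
        vapply(seq_len(m), function(i) {
          a <- atoms[i]; b <- atoms[if (i == m) 1L else i + 1L]
          paste(min(a, b), max(a, b))
        }, "")
      }
      covered <- character(0)
      for (i in ord) {
        atoms <- as.integer(sub("^.*_", "", rl[[i]]))
        bk <- bondkey(atoms)
        if (any(!bk %in% covered)) {
          ringlist[[length(ringlist) + 1L]] <- atoms
          aromring <- c(aromring, isTRUE(rr$AROMATIC[[i]]))
          covered <- union(covered, bk)
        }
        if (length(ringlist) >= n_sssr) break
      }
    }
  }

  inring <- logical(n); aromatic <- logical(n)
  for (i in seq_along(ringlist)) {
    inring[ringlist[[i]]] <- TRUE
    if (aromring[i]) aromatic[ringlist[[i]]] <- TRUE
  }

  # implicit hydrogens from default valence, adjusted for formal charge
  bosum <- numeric(n)
  for (k in seq_len(nrow(bonds))) {
    bosum[bonds$a[k]] <- bosum[bonds$a[k]] + bonds$order[k]
    bosum[bonds$b[k]] <- bosum[bonds$b[k]] + bonds$order[k]
  }
  val <- .VALENCE[elem]
  val[is.na(val)] <- 0
  chgadj <- ifelse(elem %in% c("N", "P"), charge,
            ifelse(elem %in% c("O", "S", "Se"), charge,
            ifelse(elem == "C", -abs(charge), 0)))
  nH <- pmax(0, round(val + chgadj - bosum))

  # all-pairs topological distances by BFS (molecules are small)
  dist <- matrix(n + 1L, n, n)
  for (s in seq_len(n)) {
    d <- rep.int(n + 1L, n); d[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (a in frontier) for (b in adj[[a]]) if (d[b] > d[a] + 1L) {
        d[b] <- d[a] + 1L; nxt <- c(nxt, b)
      }
      frontier <- nxt
    }
    dist[s, ] <- d
  }

  g <- list(smiles = smiles, n = n, elem = elem,
            Z = unname(.ELEMENTS[elem]), charge = charge, nH = nH,
            coords = coords, bonds = bonds, adj = adj, bidx = bidx,
            inring = inring, aromatic = aromatic,
            ringlist = ringlist, aromring = aromring, dist = dist)
  g$Z[is.na(g$Z)] <- 0L
  .molgraphCache[[key]] <- g
  g
}

# Heavy-atom degree per atom.
mgDegree <- function(g) lengths(g$adj)

# Clear the memoisation cache (exposed for tests of memory behaviour).
clearMolgraphCache <- function() {
  rm(list = ls(.molgraphCache), envir = .molgraphCache)
  invisible(NULL)
}
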