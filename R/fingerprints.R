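# Hashed binary fingerprints computed on the internal molecular graph.
#
# The circular (Morgan-style) fingerprint keeps full provenance: every bit
# records the atom environments (center, radius, atom set) that generated
# it, which the attribution module retro-maps back to atoms. The subgraph
# kinds (rdkit / layered / pattern) enumerate simple bond paths up to
# seven bonds and hash them under kind-specific atom and bond typing.

REPRESENTATION_KINDS <- c("morgan", "rdkit", "layered", "pattern",
                          "pharm2d", "pubchem", "descriptors")

#' Fixed vector length of a representation kind
#'
#' 2048 bits for the hashed fingerprints, 881 for the substructure-key
#' fingerprint, 395 for the 2D-pharmacophore fingerprint (5 feature
#' families, pairs and triples, 3 topological distance bins) and 128 for
#' the descriptor vector.
#'
#' @param kind a representation kind.
#' @return integer length.
#' @export
representationLength <- function(kind) {
  switch(kind,
    morgan = 2048L, rdkit = 2048L, layered = 2048L, pattern = 2048L,
    pubchem = 881L, pharm2d = .PHARM2D_LEN, descriptors = 128L,
    NA_integer_)
}

.FP_NBITS <- 2048L

# bond order code used in hashing; aromatic ring bonds get their own code
.bondCode <- function(g, k) {
  a <- g$bonds$a[k]; b <- g$bonds$b[k]
  if (g$aromatic[a] && g$aromatic[b] && g$inring[a] && g$inring[b]) 4L
  else g$bonds$order[k]
}

#' Circular fingerprint with atom-environment bookkeeping
#'
#' Radius-2, 2048-bit hashed circular fingerprint. Initial atom invariants
#' encode element, heavy degree, total hydrogen count, formal charge, ring
#' membership and aromaticity; each iteration hashes an atom's invariant
#' with the sorted (bond code, neighbor invariant) pairs. Environments
#' whose bond set duplicates an already-emitted environment are skipped,
#' mirroring circular-fingerprint deduplication.
#'
#' @param g internal molgraph (or a SMILES string).
#' @param radius maximum environment radius in bonds (default 2).
#' @param nbits vector length (default 2048).
#' @return list with \code{bits} (0/1 integer vector) and \code{envs}, a
#'   data-frame-like list per environment: bit, center, radius, atoms.
#' @keywords internal
#' @noRd
morganFP <- function(g, radius = 2L, nbits = .FP_NBITS) {
  if (is.character(g)) g <- molgraph(g)
  n <- g$n
  deg <- mgDegree(g)
  inv <- hashRows(cbind(g$Z, deg, g$nH, g$charge + 10L,
                        as.integer(g$inring), as.integer(g$aromatic)))
  bcode <- vapply(seq_len(nrow(g$bonds)), function(k) .bondCode(g, k), 0L)

  bits <- integer(nbits)
  envs <- list()
  seen <- character(0)   # canonical bond-set keys already emitted

  emit <- function(invariant, center, r, bondset) {
    key <- if (length(bondset)) paste(sort(bondset), collapse = ",")
           else paste0("a", center)
    if (key %in% seen) return(invisible(NULL))
    seen <<- c(seen, key)
    atoms <- if (length(bondset))
      sort(unique(c(g$bonds$a[bondset], g$bonds$b[bondset])))
    else center
    bit <- as.integer(invariant %% nbits) + 1L
    bits[bit] <<- 1L
    envs[[length(envs) + 1L]] <<- list(bit = bit, center = center,
                                       radius = r, atoms = atoms)
    invisible(NULL)
  }

  # radius 0
  for (a in seq_len(n)) emit(inv[a], a, 0L, integer(0))

  # bond sets within radius r of each atom, grown by BFS over bonds
  bondset <- lapply(seq_len(n), function(a) integer(0))
  frontier_atoms <- lapply(seq_len(n), function(a) a)
  cur <- inv
  if (radius >= 1L) for (r in seq_len(radius)) {
    nxt <- numeric(n)
    for (a in seq_len(n)) {
      nb <- g$adj[[a]]
      if (length(nb)) {
        bo <- vapply(g$bidx[[a]], function(k) bcode[k], 0L)
        o <- order(bo, cur[nb])
        pairs <- as.vector(rbind(bo[o], cur[nb][o]))
      } else pairs <- integer(0)
      nxt[a] <- hashInts(c(r, cur[a], pairs))
    }
    for (a in seq_len(n)) {
      newf <- integer(0)
      for (fa in frontier_atoms[[a]]) {
        ks <- g$bidx[[fa]]
        add <- ks[!ks %in% bondset[[a]]]
        bondset[[a]] <- c(bondset[[a]], add)
        newf <- c(newf, setdiff(g$adj[[fa]], c(a)))
      }
      frontier_atoms[[a]] <- unique(newf)
    }
    for (a in seq_len(n)) emit(nxt[a], a, r, bondset[[a]])
    cur <- nxt
  }

  list(bits = bits, envs = envs)
}

# ---- simple-path enumeration for the subgraph fingerprint kinds -------

# all simple bond paths of 1..maxlen bonds; each path is a bond id vector,
# canonical direction chosen lexicographically by the caller's coding
.enumeratePaths <- function(g, maxlen = 7L) {
  paths <- list()
  nb <- g$adj; bi <- g$bidx
  for (start in seq_len(g$n)) {
    stack <- list(list(atoms = start, bonds = integer(0)))
    while (length(stack)) {
      st <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      a <- st$atoms[length(st$atoms)]
      for (j in seq_along(nb[[a]])) {
        b <- nb[[a]][j]; k <- bi[[a]][j]
        if (b %in% st$atoms) next
        atoms2 <- c(st$atoms, b); bonds2 <- c(st$bonds, k)
        # emit each path once: only when the start endpoint is the
        # smaller atom index, or for symmetric reversal ties
        if (atoms2[1] <= atoms2[length(atoms2)])
          paths[[length(paths) + 1L]] <- list(atoms = atoms2, bonds = bonds2)
        if (length(bonds2) < maxlen)
          stack[[length(stack) + 1L]] <- list(atoms = atoms2, bonds = bonds2)
      }
    }
  }
  paths
}

# hash one path under a given atom/bond coding, canonicalized over direction
.pathHash <- function(acode, bcode2, layerid) {
  fwd <- c(layerid, as.vector(rbind(acode, c(bcode2, 0)))[-2 * length(acode)])
  racode <- rev(acode); rbcode <- rev(bcode2)
  bwd <- c(layerid, as.vector(rbind(racode, c(rbcode, 0)))[-2 * length(racode)])
  key <- if (paste(fwd, collapse = " ") <= paste(bwd, collapse = " ")) fwd else bwd
  hashInts(key)
}

.subgraphFP <- function(g, kind, nbits = .FP_NBITS, maxlen = 7L) {
  if (is.character(g)) g <- molgraph(g)
  paths <- .enumeratePaths(g, maxlen)
  bits <- integer(nbits)
  if (!length(paths) && g$n >= 1) {
    # single-atom molecules still set an atom-typed bit
    for (a in seq_len(g$n))
      bits[(hashInts(c(99L, g$Z[a])) %% nbits) + 1L] <- 1L
    return(bits)
  }
  bcode <- vapply(seq_len(nrow(g$bonds)), function(k) .bondCode(g, k), 0L)
  deg <- mgDegree(g)
  for (p in paths) {
    at <- p$atoms; bo <- bcode[p$bonds]
    if (kind == "rdkit") {
      ac <- hashRows(cbind(g$Z[at], as.integer(g$aromatic[at]), deg[at]))
      bits[(.pathHash(ac, bo, 1L) %% nbits) + 1L] <- 1L
    } else if (kind == "layered") {
      # several typing layers per subgraph, like layered substructure FPs
      l1 <- .pathHash(rep(1L, length(at)), bo, 11L)              # bonds only
      l2 <- .pathHash(g$Z[at], rep(1L, length(bo)), 12L)         # elements only
      l3 <- .pathHash(g$Z[at], bo, 13L)                          # elements+bonds
      l4 <- .pathHash(hashRows(cbind(g$Z[at],
              as.integer(g$aromatic[at]))), bo, 14L)             # +aromaticity
      l5 <- .pathHash(hashRows(cbind(g$Z[at],
              as.integer(g$inring[at]))), bo, 15L)               # +ring info
      for (h in c(l1, l2, l3, l4, l5)) bits[(h %% nbits) + 1L] <- 1L
    } else if (kind == "pattern") {
      # generic substructure-screening typing: ring membership and bond
      # codes only, so queries with unspecified atoms still collide
      ac <- hashRows(cbind(as.integer(g$inring[at]),
                           as.integer(g$aromatic[at])))
      bits[(.pathHash(ac, bo, 21L) %% nbits) + 1L] <- 1L
      ac2 <- hashRows(cbind(g$Z[at], as.integer(g$inring[at])))
      bits[(.pathHash(ac2, bo, 22L) %% nbits) + 1L] <- 1L
    }
  }
  # atom-only contributions keep single atoms visible to all kinds
  for (a in seq_len(g$n)) {
    h <- switch(kind,
      rdkit = hashInts(c(99L, g$Z[a], as.integer(g$aromatic[a]))),
      layered = hashInts(c(98L, g$Z[a])),
      pattern = hashInts(c(97L, g$Z[a])))
    bits[(h %% nbits) + 1L] <- 1L
  }
  bits
}

#' Tanimoto similarity between two binary fingerprints
#'
#' \code{|a AND b| / |a OR b|}; two all-zero vectors are defined as
#' identical (similarity 1).
#'
#' @param a,b binary vectors of equal length.
#' @return similarity in [0, 1].
#' @examples
#' tanimoto(c(1,1,0,0), c(1,0,1,0))  # 1/3
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint length mismatch")
  i <- sum(a & b); u <- sum(a | b)
  if (u == 0) 1 else i / u
}

#' Pairwise Tanimoto similarity matrix
#'
#' Vectorized over the rows of two binary matrices.
#'
#' @param A,B binary matrices with the same number of columns.
#' @return \code{nrow(A)} x \code{nrow(B)} similarity matrix.
#' @export
tanimotoMatrix <- function(A, B = A) {
  if (ncol(A) != ncol(B)) stop("fingerprint length mismatch")
  I <- A %*% t(B)
  U <- outer(rowSums(A), rowSums(B), "+") - I
  S <- ifelse(U == 0, 1, I / pmax(U, 1e-12))
  S
}
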