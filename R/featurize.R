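# Representation dispatcher: compounds -> FeatureMatrix.

#' Compute a molecular representation for a set of compounds
#'
#' Seven kinds are available: \code{morgan} (circular, radius 2, 2048
#' bits), \code{rdkit}, \code{layered} and \code{pattern} (subgraph-based,
#' 2048 bits), \code{pharm2d} (2D-pharmacophore pairs/triples with binned
#' topological distances), \code{pubchem} (881 substructure keys) and
#' \code{descriptors} (128 physicochemical/topological descriptors).
#' Deterministic for fixed inputs. Molecules that fail featurization are
#' dropped with a warning and recorded in the \code{rejected} attribute.
#'
#' @param smiles character vector of standardized SMILES.
#' @param kind representation kind.
#' @param ids compound identifiers (defaults to names or seq_along).
#' @return a \linkS4class{FeatureMatrix}; rejected inputs (if any) are in
#'   \code{attr(, "rejected")}.
#' @examples
#' fm <- featurize(c(eth = "CCO"), "morgan")
#' sum(featureData(fm))  # number of on-bits for ethanol
#' @export
featurize <- function(smiles, kind = REPRESENTATION_KINDS, ids = NULL) {
  kind <- match.arg(kind)
  if (is.null(ids)) ids <- names(smiles) %||% as.character(seq_along(smiles))
  m <- representationLength(kind)
  rows <- vector("list", length(smiles))
  ok <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    v <- tryCatch({
      g <- molgraph(smiles[i])
      switch(kind,
        morgan = morganFP(g)$bits,
        rdkit = .subgraphFP(g, "rdkit"),
        layered = .subgraphFP(g, "layered"),
        pattern = .subgraphFP(g, "pattern"),
        pharm2d = pharm2dFP(g),
        pubchem = pubchemFP(g),
        descriptors = descriptorVector(g))
    }, error = function(e) NULL)
    if (is.null(v)) next
    rows[[i]] <- v; ok[i] <- TRUE
  }
  if (!any(ok)) stop("no molecule could be featurized")
  if (any(!ok))
    warning(sum(!ok), " molecule(s) failed featurization and were dropped")
  data <- do.call(rbind, rows[ok])
  if (kind == "descriptors" && any(!is.finite(data))) {
    warning("non-finite descriptor values imputed to 0")
    data[!is.finite(data)] <- 0
  }
  rownames(data) <- ids[ok]
  fm <- new("FeatureMatrix", kind = kind, ids = ids[ok], data = data)
  attr(fm, "rejected") <- smiles[!ok]
  fm
}

#' Featurize a curated dataset
#'
#' @param dataset a \linkS4class{LabeledDataset}.
#' @param kind representation kind.
#' @return a \linkS4class{FeatureMatrix} row-parallel to the dataset.
#' @export
featurizeDataset <- function(dataset, kind) {
  stopifnot(is(dataset, "LabeledDataset"))
  fm <- featurize(dataset@smiles, kind, ids = dataset@ids)
  if (length(fm@ids) != length(dataset@ids))
    stop("featurization dropped curated compounds; dataset and matrix ",
         "would disagree")
  fm
}

#' Morgan bit -> atom environment map for one compound
#'
#' Re-computes the circular fingerprint with environment bookkeeping and
#' inverts it: for every on-bit, the list of generating atom environments
#' (center atom plus all atoms within the bit's radius). Hash collisions
#' put several environments under one bit; their number is \code{n_occ}.
#'
#' @param smiles one standardized SMILES.
#' @param radius,nbits fingerprint parameters (defaults 2 / 2048).
#' @return named list keyed by bit index (as character); each element has
#'   \code{n_occ} and \code{environments} (list of integer atom vectors).
#' @export
retroMapBits <- function(smiles, radius = 2L, nbits = 2048L) {
  fp <- morganFP(molgraph(smiles), radius = radius, nbits = nbits)
  map <- list()
  for (e in fp$envs) {
    key <- as.character(e$bit)
    if (is.null(map[[key]]))
      map[[key]] <- list(n_occ = 0L, environments = list())
    map[[key]]$n_occ <- map[[key]]$n_occ + 1L
    map[[key]]$environments[[map[[key]]$n_occ]] <- e$atoms
  }
  map
}
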