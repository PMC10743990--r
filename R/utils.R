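# Internal helpers: deterministic integer hashing and seed fan-out.
#
# All fingerprint hashing uses a polynomial rolling hash over non-negative
# integer codes, carried out in doubles below 2^53 so the arithmetic is
# exact on every platform. The modulus is the Mersenne prime 2^31 - 1.

.HASH_MOD <- 2147483647
.HASH_MUL <- 1000003

#' @keywords internal
#' @noRd
hashInts <- function(x, init = 17) {
  h <- init
  for (v in x) {
    h <- (h * .HASH_MUL + v + 1) %% .HASH_MOD
  }
  h
}

# Vectorised variant: hash each row of an integer matrix.
hashRows <- function(m, init = 17) {
  h <- rep(init, nrow(m))
  for (j in seq_len(ncol(m))) {
    h <- (h * .HASH_MUL + m[, j] + 1) %% .HASH_MOD
  }
  h
}

# Derive a child seed from a top-level seed and a stage tag, staying
# below 2^31 so it is a valid R integer.
childSeed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 7919 + hashInts(utf8ToInt(tag))) %% 2147483629)
}

# Run an expression under a local RNG state so library code never
# disturbs the caller's random stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Stratified fold assignment: per class, deal fold labels in shuffled order.
stratifiedFolds <- function(y, k, seed) {
  withSeed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    fold
  })
}

# Stratified train/test split; returns indices of the training portion.
stratifiedSplit <- function(y, train_frac, seed) {
  withSeed(seed, {
    train <- integer(0)
    for (cl in levels(y)) {
      idx <- which(y == cl)
      n_tr <- max(1L, round(train_frac * length(idx)))
      train <- c(train, sample(idx, n_tr))
    }
    sort(train)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
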