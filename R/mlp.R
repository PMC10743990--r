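# Minimal multi-layer perceptron for binary classification.
#
# Written in-package because the hyperparameter grid requires up to three
# hidden layers and the lbfgs/adam/sgd solvers, a combination no installed
# R backend provides. Feedforward net, sigmoid output, binary
# cross-entropy loss with a small L2 penalty; Glorot-uniform
# initialization under a fixed seed. Constant (zero-variance) input
# columns are dropped before fitting - they carry no information and the
# model class is unchanged - which keeps fingerprint inputs compact.

.mlpActivation <- function(name) {
  switch(name,
    identity = list(f = function(x) x, df = function(a) 1),
    logistic = list(f = function(x) 1 / (1 + exp(-x)), df = function(a) a * (1 - a)),
    tanh = list(f = tanh, df = function(a) 1 - a ^ 2),
    relu = list(f = function(x) pmax(x, 0), df = function(a) (a > 0) * 1),
    stop("unknown activation: ", name))
}

.mlpInit <- function(sizes, seed) {
  withSeed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(sizes) - 1)) {
      r <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1], -r, r),
                       sizes[l], sizes[l + 1])
      b[[l]] <- numeric(sizes[l + 1])
    }
    list(W = W, b = b)
  })
}

.mlpForward <- function(par, X, act) {
  L <- length(par$W)
  A <- list(X)
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    A[[l + 1]] <- if (l < L) act$f(Z) else 1 / (1 + exp(-Z))
  }
  A
}

.mlpLossGrad <- function(par, X, y, act, lambda = 1e-4) {
  n <- nrow(X); L <- length(par$W)
  A <- .mlpForward(par, X, act)
  p <- pmin(pmax(A[[L + 1]], 1e-12), 1 - 1e-12)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p)) +
    lambda / 2 * sum(vapply(par$W, function(w) sum(w ^ 2), 0)) / n
  delta <- (A[[L + 1]] - y) / n            # dL/dZ_out for sigmoid + BCE
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(A[[l]], delta) + lambda * par$W[[l]] / n
    gb[[l]] <- colSums(delta)
    if (l > 1) delta <- (delta %*% t(par$W[[l]])) * act$df(A[[l]])
  }
  list(loss = loss, gW = gW, gb = gb)
}

.mlpFlatten <- function(par) unlist(c(par$W, par$b), use.names = FALSE)

.mlpUnflatten <- function(theta, sizes) {
  W <- list(); b <- list(); off <- 0L
  for (l in seq_len(length(sizes) - 1)) {
    len <- sizes[l] * sizes[l + 1]
    W[[l]] <- matrix(theta[off + seq_len(len)], sizes[l], sizes[l + 1])
    off <- off + len
  }
  for (l in seq_len(length(sizes) - 1)) {
    len <- sizes[l + 1]
    b[[l]] <- theta[off + seq_len(len)]
    off <- off + len
  }
  list(W = W, b = b)
}

# Fit the net. X numeric matrix, y 0/1. Returns list with weights and
# the kept-column index. max_iter caps epochs (lbfgs: iterations);
# convergence declared when loss improves by < tol for 5 checks.
mlpFit <- function(X, y, hidden = c(100L), activation = "relu",
                   solver = "adam", learning_rate_init = 0.001,
                   max_iter = 200L, seed = 1L, tol = 1e-4) {
  keep <- which(apply(X, 2, function(v) any(v != v[1])))
  if (!length(keep)) keep <- 1L
  Xk <- X[, keep, drop = FALSE]
  act <- .mlpActivation(activation)
  sizes <- c(ncol(Xk), hidden, 1L)
  par <- .mlpInit(sizes, seed)

  if (solver == "lbfgs") {
    # optim() calls fn and gr at the same point back to back; cache the
    # single forward/backward pass they share
    cache <- new.env(parent = emptyenv())
    evalAt <- function(theta) {
      if (!is.null(cache$theta) && identical(cache$theta, theta))
        return(cache$val)
      val <- .mlpLossGrad(.mlpUnflatten(theta, sizes), Xk, y, act)
      cache$theta <- theta; cache$val <- val
      val
    }
    fn <- function(theta) evalAt(theta)$loss
    gr <- function(theta) {
      gg <- evalAt(theta)
      .mlpFlatten(list(W = gg$gW, b = gg$gb))
    }
    opt <- stats::optim(.mlpFlatten(par), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = max_iter, factr = 1e10))
    par <- .mlpUnflatten(opt$par, sizes)
    converged <- opt$convergence == 0
  } else {
    # adam / sgd-with-momentum over minibatches
    n <- nrow(Xk)
    batch <- min(200L, n)
    mW <- lapply(par$W, function(w) w * 0); vW <- mW
    mb <- lapply(par$b, function(bb) bb * 0); vb <- mb
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    t_ <- 0; best <- Inf; stall <- 0L; converged <- FALSE
    withSeed(childSeed(seed, "mlp-sgd"), {
      for (epoch in seq_len(max_iter)) {
        ord <- sample(n)
        ep_loss <- 0; nb_ <- 0
        for (s in seq(1, n, by = batch)) {
          idx <- ord[s:min(s + batch - 1, n)]
          gg <- .mlpLossGrad(par, Xk[idx, , drop = FALSE], y[idx], act)
          ep_loss <- ep_loss + gg$loss; nb_ <- nb_ + 1
          t_ <- t_ + 1
          for (l in seq_along(par$W)) {
            if (solver == "adam") {
              mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gg$gW[[l]]
              vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gg$gW[[l]] ^ 2
              mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gg$gb[[l]]
              vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gg$gb[[l]] ^ 2
              mhW <- mW[[l]] / (1 - beta1 ^ t_); vhW <- vW[[l]] / (1 - beta2 ^ t_)
              mhb <- mb[[l]] / (1 - beta1 ^ t_); vhb <- vb[[l]] / (1 - beta2 ^ t_)
              par$W[[l]] <- par$W[[l]] - learning_rate_init * mhW / (sqrt(vhW) + eps)
              par$b[[l]] <- par$b[[l]] - learning_rate_init * mhb / (sqrt(vhb) + eps)
            } else {  # sgd with momentum 0.9
              mW[[l]] <- 0.9 * mW[[l]] - learning_rate_init * gg$gW[[l]]
              mb[[l]] <- 0.9 * mb[[l]] - learning_rate_init * gg$gb[[l]]
              par$W[[l]] <- par$W[[l]] + mW[[l]]
              par$b[[l]] <- par$b[[l]] + mb[[l]]
            }
          }
        }
        ep_loss <- ep_loss / nb_
        if (best - ep_loss < tol) stall <- stall + 1L else stall <- 0L
        best <- min(best, ep_loss)
        if (stall >= 5L) { converged <- TRUE; break }
      }
    })
  }
  if (!converged)
    message("MLP did not converge within ", max_iter, " iterations")
  list(par = par, keep = keep, activation = activation)
}

mlpPredict <- function(fit, X) {
  act <- .mlpActivation(fit$activation)
  A <- .mlpForward(fit$par, X[, fit$keep, drop = FALSE], act)
  as.numeric(A[[length(A)]])
}
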