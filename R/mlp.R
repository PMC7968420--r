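# Internal multilayer-perceptron engine: two ReLU hidden layers, sigmoid
# output, binary cross-entropy with L2 weight penalty, full-batch Adam
# (momentum beta1 = 0.9, adaptive per-parameter learning rate) for a fixed
# iteration budget. Written out explicitly because no installed R package
# offers this architecture; small dense problems keep pure-R matrix algebra
# fast.

.mlpInit <- function(p, hidden, seed) {
  set.seed(seed)
  sizes <- c(p, hidden, 1L)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1L)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L]) *
                       sqrt(2 / sizes[l]), sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  list(W = W, b = b)
}

.mlpForward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% net$W[[l]], 2L, net$b[[l]], "+")
    A[[l + 1L]] <- if (l < L) pmax(Z, 0) else 1 / (1 + exp(-Z))
  }
  A
}

.mlpFit <- function(X, y, hidden = c(12L, 12L), maxIter = 800L, l2 = 1e-4,
                    learningRate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                    seed = 1L, Xval = NULL, yval = NULL, patience = 10L,
                    checkEvery = 20L) {
  X <- as.matrix(X); n <- nrow(X)
  net <- .mlpInit(ncol(X), hidden, seed)
  L <- length(net$W)
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(b) b * 0); vb <- mb
  eps <- 1e-8
  useVal <- !is.null(Xval) && length(yval)
  bestLoss <- Inf; bestNet <- net; bad <- 0L
  for (it in seq_len(maxIter)) {
    A <- .mlpForward(net, X)
    delta <- (A[[L + 1L]] - y) / n          # dLoss/dZ_out for BCE + sigmoid
    for (l in rev(seq_len(L))) {
      gW <- crossprod(A[[l]], delta) + (l2 / n) * net$W[[l]]
      gb <- colSums(delta)
      if (l > 1L)
        delta <- (delta %*% t(net$W[[l]])) * (A[[l]] > 0)
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      c1 <- 1 - beta1^it; c2 <- 1 - beta2^it
      net$W[[l]] <- net$W[[l]] -
        learningRate * (mW[[l]] / c1) / (sqrt(vW[[l]] / c2) + eps)
      net$b[[l]] <- net$b[[l]] -
        learningRate * (mb[[l]] / c1) / (sqrt(vb[[l]] / c2) + eps)
    }
    if (useVal && it %% checkEvery == 0L) {
      p <- .mlpPredict(net, Xval)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      loss <- -mean(yval * log(p) + (1 - yval) * log(1 - p))
      if (loss < bestLoss - 1e-6) {
        bestLoss <- loss; bestNet <- net; bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= patience) return(bestNet)
      }
    }
  }
  if (useVal && is.finite(bestLoss)) bestNet else net
}

.mlpPredict <- function(net, X) {
  A <- .mlpForward(net, as.matrix(X))
  as.numeric(A[[length(A)]])
}

# stratified train/test/validation indices; fractions applied per class
.stratifiedSplit <- function(group, fractions, seed) {
  set.seed(seed)
  idx <- list(train = integer(0), test = integer(0), validation = integer(0))
  for (g in unique(group)) {
    rows <- sample(which(group == g))
    n <- length(rows)
    ntr <- round(fractions[1] * n)
    nte <- round(fractions[2] * n)
    ntr <- min(ntr, n - 1L)  # keep at least one test case per class
    nte <- min(nte, n - ntr)
    idx$train <- c(idx$train, rows[seq_len(ntr)])
    idx$test <- c(idx$test, rows[ntr + seq_len(nte)])
    if (ntr + nte < n)
      idx$validation <- c(idx$validation, rows[(ntr + nte + 1L):n])
  }
  idx
}
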