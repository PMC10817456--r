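## Compact symmetric FastICA (logcosh contrast) used by the ICA cleaning
## stages. X is channels x samples, already centered. Returns the unmixed
## sources S (components x samples) and the mixing matrix A (channels x
## components) with X ~= A %*% S.
.fastICA <- function(X, n_comp = nrow(X), max_iter = 200, tol = 1e-4,
                     seed = 1) {
  nch <- nrow(X); n <- ncol(X)
  ## PCA whitening
  C <- tcrossprod(X) / n
  eg <- eigen(C, symmetric = TRUE)
  keep <- which(eg$values > max(eg$values) * 1e-10)[seq_len(min(n_comp, sum(eg$values > 0)))]
  D <- eg$values[keep]; E <- eg$vectors[, keep, drop = FALSE]
  K <- diag(1 / sqrt(D), length(D)) %*% t(E)     # whitening
  Kinv <- E %*% diag(sqrt(D), length(D))         # de-whitening
  Z <- K %*% X
  m <- nrow(Z)

  set.seed(seed)
  W <- matrix(stats::rnorm(m * m), m, m)
  W <- .symOrth(W)
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gp <- rowMeans(1 - G^2)
    W1 <- tcrossprod(G, Z) / n - diag(gp, m) %*% W
    W1 <- .symOrth(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Z
  A <- Kinv %*% t(W)    # W is orthogonal in whitened space
  list(S = S, A = A, W = W %*% K, iterations = it)
}

## Symmetric orthogonalization W <- (W W^T)^{-1/2} W.
.symOrth <- function(W) {
  sv <- eigen(tcrossprod(W), symmetric = TRUE)
  vals <- pmax(sv$values, .Machine$double.eps)
  sv$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(sv$vectors) %*% W
}
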