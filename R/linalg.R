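## Numerical primitives used by the feature extractors: a seeded randomized
## SVD (Halko-style range finder with power iterations) and a symmetric
## FastICA with the log-cosh contrast. Both are deliberately small,
## deterministic-under-seed implementations.

#' Randomized truncated SVD
#'
#' Approximate rank-`k` SVD of `A` via a Gaussian sketch with `p` oversampling
#' columns and `q` power iterations (QR-renormalized). Deterministic for a
#' given `seed`.
#'
#' @param A numeric matrix.
#' @param k target rank (truncated to `min(dim(A))`).
#' @param q power iterations (default 7).
#' @param p oversampling (default 10).
#' @param seed integer seed for the sketch.
#' @return list with `u`, `d`, `v` as in [svd()], rank `k`.
#' @export
randomized_svd <- function(A, k, q = 7, p = 10, seed = 1) {
  m <- nrow(A); n <- ncol(A)
  k <- min(k, m, n)
  l <- min(k + p, n)
  Omega <- with_seed(seed, matrix(rnorm(n * l), n, l))
  Y <- A %*% Omega
  Q <- qr.Q(qr(Y))
  for (i in seq_len(q)) {
    Z <- crossprod(A, Q)
    Z <- qr.Q(qr(Z))
    Y <- A %*% Z
    Q <- qr.Q(qr(Y))
  }
  B <- crossprod(Q, A)
  s <- svd(B, nu = k, nv = k)
  list(u = Q %*% s$u, d = s$d[seq_len(k)], v = s$v)
}

## run expr with a private RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## stable 32-bit-safe hash of a character key onto 0..2^31-2, used to fan a
## global seed out into stage-specific seeds
seed_for <- function(seed, key) {
  h <- 0
  for (c in utf8ToInt(paste0(key, ":", seed))) h <- (h * 31 + c) %% 2147483629
  as.integer(h)
}

#' Symmetric FastICA (log-cosh contrast)
#'
#' Extracts independent sources from whitened data by fixed-point iteration
#' with symmetric decorrelation. Rows of `Z` must be whitened signals
#' (zero mean, identity covariance across columns). Component sign is fixed so
#' each source's maximum-magnitude entry is positive.
#'
#' @param Z whitened `k x n` matrix (k components, n samples).
#' @param max_iter maximum fixed-point iterations (default 500).
#' @param tol convergence tolerance on the unmixing update (default 1e-7).
#' @param seed seed for the random orthogonal initialization.
#' @return list with `S` (`k x n` estimated sources, unit variance), `W`
#'   (unmixing matrix, `S = W Z`) and `converged` flag. Non-convergence is a
#'   warning; the best iterate is returned.
#' @export
fast_ica <- function(Z, max_iter = 500, tol = 1e-7, seed = 1) {
  k <- nrow(Z); n <- ncol(Z)
  W <- with_seed(seed, matrix(rnorm(k * k), k, k))
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WX <- W %*% Z
    G <- tanh(WX)            # g for log-cosh contrast
    gp <- 1 - G^2            # g'
    W1 <- (G %*% t(Z)) / n - diag(rowMeans(gp), k) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("FastICA did not converge within max_iter; returning best iterate")
  }
  S <- W %*% Z
  ## fix signs: maximum-magnitude entry of each source positive
  sgn <- apply(S, 1, function(s) sign(s[which.max(abs(s))]))
  sgn[sgn == 0] <- 1
  S <- S * sgn
  W <- W * sgn
  list(S = S, W = W, converged = converged)
}

sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  vals <- pmax(e$values, .Machine$double.eps)
  K <- e$vectors %*% diag(1 / sqrt(vals), nrow(W)) %*% t(e$vectors)
  K %*% W
}
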