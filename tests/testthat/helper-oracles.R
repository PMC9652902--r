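# Independent oracles and small fixtures shared across tests.

# Dense multivariate-normal log-density with covariance s2 * (I + tau*Kt):
# the brute-force check for the rotated profile likelihood.
denseLoglik <- function(y, X, beta, s2, tau, Kt) {
  n <- length(y)
  V <- s2 * (diag(n) + tau * Kt)
  r <- y - drop(X %*% beta)
  ld <- as.numeric(determinant(V)$modulus)
  drop(-0.5 * (n * log(2 * pi) + ld + t(r) %*% solve(V, r)))
}

# Dense residual covariance Sigma = V - X (X'V^-1 X)^-1 X' and its
# pseudo-inverse GLS estimates, computed without any package internals.
denseScreenGLS <- function(y, X, G, tau, Kt) {
  n <- length(y)
  V <- diag(n) + tau * Kt
  A <- solve(t(X) %*% solve(V, X))
  Sigma <- V - X %*% A %*% t(X)
  Sigma <- (Sigma + t(Sigma)) / 2
  e <- eigen(Sigma, symmetric = TRUE)
  keep <- e$values > 1e-10 * max(e$values)
  Sp <- e$vectors[, keep] %*% (t(e$vectors[, keep]) / e$values[keep])
  rk <- sum(keep)
  yS <- drop(Sp %*% y)
  vapply(seq_len(ncol(G)), function(l) {
    x <- G[, l]
    xSx <- drop(t(x) %*% Sp %*% x)
    b <- sum(x * yS) / xSx
    rss <- sum(y * yS) - b^2 * xSx
    c(beta = b, se = sqrt(rss / (rk - 1) / xSx))
  }, c(beta = 0, se = 0))
}

# random small GWASData with a kinship built from an independent SNP panel
makeToyData <- function(n = 30, L = 8, seed = 1, causal = integer(0),
                        beta = numeric(0), tau = 0.1, sigma2 = 0.2) {
  set.seed(seed)
  G <- matrix(rbinom(n * L, 2, runif(L, 0.15, 0.5)[rep(seq_len(L), each = n)]),
              n, L)
  while (any(apply(G, 2, var) == 0))
    G <- matrix(rbinom(n * L, 2, 0.4), n, L)
  K <- buildKinship(matrix(rbinom(n * 300, 2, 0.3), n, 300))
  mu <- 1 + if (length(causal)) drop(G[, causal, drop = FALSE] %*% beta) else 0
  e <- eigen(K, symmetric = TRUE)
  u <- sqrt(sigma2 * tau) *
    drop(e$vectors %*% (sqrt(pmax(e$values, 0)) * rnorm(n)))
  Y <- mu + u + rnorm(n, 0, sqrt(sigma2))
  GWASData(Y = Y, G = G, K = K)
}

# fast settings for independent-SNP simulation studies
indepSettings <- function(n, L, causal, beta, model = "mixed", seed = 1) {
  SimSettings(n = n, L = L, nBlocks = 10, rho = 0,
              causal = as.integer(causal), beta = beta, model = model,
              seed = seed)
}
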