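test_that("eigenRotate reproduces the covariance factorization", {
  # identity kinship: all eigenvalues 1
  sp <- eigenRotate(diag(5), diag(5))
  expect_equal(sp$values, rep(1, 5))
  expect_equal(crossprod(sp$vectors), diag(5), tolerance = 1e-10)

  # random PSD K: U diag(lambda) U' reconstructs Z K Z'
  set.seed(3)
  A <- matrix(rnorm(100), 10, 10)
  K <- crossprod(A) / 10
  sp <- eigenRotate(diag(10), K)
  rec <- sp$vectors %*% (t(sp$vectors) * sp$values)
  expect_lt(max(abs(rec - K)), 1e-8)

  # zero kinship: i.i.d. errors
  sp0 <- eigenRotate(diag(4), matrix(0, 4, 4))
  expect_equal(sp0$values, rep(0, 4))

  # non-symmetric and NaN inputs refused
  expect_error(eigenRotate(diag(3), matrix(1:9, 3, 3)), "symmetric")
  expect_error(eigenRotate(diag(2), matrix(NaN, 2, 2)), "non-finite")
})

test_that("fitLMM reduces to OLS when tau = 0 and matches the sample mean", {
  set.seed(4)
  n <- 25
  G <- matrix(rbinom(n * 4, 2, 0.4), n, 4)
  d <- GWASData(rnorm(n), G, K = diag(n))
  f <- fitLMM(d, modelSnps = c(1L, 2L), tauFixed = 0)
  ols <- lm(d@Y ~ G[, 1] + G[, 2])
  expect_equal(unname(f@beta), unname(coef(ols)), tolerance = 1e-10)
  expect_equal(f@sigma2, sum(resid(ols)^2) / n, tolerance = 1e-12)

  d2 <- GWASData(c(1, 2, 3, 4), matrix(c(0, 1, 2, 1), 4, 1), K = diag(4))
  f2 <- fitLMM(d2, tauFixed = 0)
  expect_equal(unname(f2@beta), 2.5)
})

test_that("fitLMM log-likelihood matches the dense multivariate-normal oracle", {
  set.seed(5)
  for (i in 1:10) {
    d <- makeToyData(n = 20, L = 5, seed = 100 + i)
    f <- fitLMM(d, modelSnps = 1:2)
    X <- cbind(d@X, d@G[, 1:2])
    o <- denseLoglik(d@Y, X, f@beta, f@sigma2, f@tau, d@Z %*% d@K %*% t(d@Z))
    expect_equal(f@loglik, o, tolerance = 1e-6)
    expect_equal(f@bic, -2 * f@loglik + f@df * log(f@n), tolerance = 1e-10)
  }
})

test_that("profiled tau is a local maximum of the likelihood", {
  # well-identified tau (large n, strong kinship signal) so the optimum is
  # interior to the search space
  for (seed in 21:23) {
    d <- makeToyData(n = 150, L = 5, seed = seed, tau = 1, sigma2 = 0.5)
    f <- fitLMM(d)
    for (mult in c(0.9, 1.1)) {
      fp <- fitLMM(d, tauFixed = f@tau * mult)
      expect_lte(fp@loglik, f@loglik + 1e-6)
    }
  }
})

test_that("rank-deficient designs fail naming the collinear columns", {
  set.seed(6)
  n <- 20
  G <- matrix(rbinom(n * 3, 2, 0.4), n, 3)
  G[, 3] <- G[, 1]  # perfect copy
  d <- suppressWarnings(GWASData(rnorm(n), G, K = diag(n)))
  expect_error(fitLMM(d, modelSnps = c(1L, 3L)), "snp3")
  expect_error(fitLMM(GWASData(c(1, NA, 3), matrix(0:2, 3, 1), K = diag(3),
                               checkPSD = FALSE)),
               "finite")
})

test_that("REML variant runs and differs from ML on small samples", {
  d <- makeToyData(n = 25, L = 4, seed = 31)
  fm <- fitLMM(d)
  fr <- fitLMM(d, reml = TRUE)
  expect_s4_class(fr, "LMMFit")
  expect_identical(fr@method, "REML")
  expect_false(isTRUE(all.equal(fm@tau, fr@tau, tolerance = 1e-12)))
})

test_that("residualize centers under the intercept-only tau = 0 case", {
  set.seed(7)
  n <- 12
  d <- GWASData(rnorm(n), matrix(rbinom(n * 2, 2, 0.4), n, 2), K = diag(n))
  f <- fitLMM(d, tauFixed = 0)
  r <- residualize(d, f)
  expect_equal(r$yhat, d@Y - mean(d@Y), tolerance = 1e-8, ignore_attr = TRUE)
  # Sigma reconstructed from the factorization equals the centering matrix
  S <- r$vectors %*% (t(r$vectors) * r$values)
  expect_equal(S, diag(n) - 1 / n, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(r$rank, n - 1L)
})

test_that("residual covariance annihilates V^-1 X and has rank n - rank(X)", {
  for (seed in c(11, 12)) {
    d <- makeToyData(n = 30, L = 6, seed = seed)
    f <- fitLMM(d, modelSnps = 1:2)
    r <- residualize(d, f)
    X <- cbind(d@X, d@G[, 1:2])
    expect_equal(r$rank, nrow(X) - ncol(X))
    S <- r$vectors %*% (t(r$vectors) * r$values)
    V <- diag(30) + f@tau * d@K
    expect_lt(max(abs(S %*% solve(V, X))), 1e-8)
  }
})
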