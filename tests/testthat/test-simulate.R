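test_that("beta patterns fix seven effects at 0.4 and vary three", {
  for (b1 in c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6)) {
    b <- betaPattern(b1)
    expect_length(b, 10)
    expect_equal(b[c(1, 5, 9)], rep(b1, 3))
    expect_equal(b[-c(1, 5, 9)], rep(0.4, 7))
  }
})

test_that("simulated dosages are valid and reproducible", {
  s <- SimSettings(n = 120, L = 200, nBlocks = 10, seed = 91)
  G1 <- simulateGenotypes(s)
  G2 <- simulateGenotypes(s)
  expect_identical(G1, G2)
  expect_true(all(G1 %in% c(0, 1, 2)))
  expect_true(all(apply(G1, 2, var) > 0))
  maf <- pmin(colMeans(G1) / 2, 1 - colMeans(G1) / 2)
  expect_true(all(maf >= s@mafMin))
  expect_error(simulateGenotypes(SimSettings(n = 10, L = 20, nBlocks = 2,
                                             rho = 1)), "rho")
})

test_that("simulateGWAS is bit-identical under a fixed seed", {
  s <- indepSettings(n = 80, L = 100, causal = 50L, beta = 1, seed = 92)
  a <- simulateGWAS(s)
  b <- simulateGWAS(s)
  expect_identical(phenotypes(a$data), phenotypes(b$data))
  expect_identical(genotypes(a$data), genotypes(b$data))
  expect_identical(a$truth@u, b$truth@u)
})

test_that("LD structure follows the latent AR(1) correlation", {
  sIndep <- SimSettings(n = 1000, L = 60, nBlocks = 3, rho = 0, seed = 93)
  G0 <- simulateGenotypes(sIndep)
  adj0 <- abs(vapply(seq_len(59)[-c(20, 40)], function(j)
    cor(G0[, j], G0[, j + 1]), numeric(1)))
  expect_gte(mean(adj0 <= 0.1), 0.95)

  sLD <- SimSettings(n = 1000, L = 60, nBlocks = 3, rho = 0.9, seed = 94)
  G9 <- simulateGenotypes(sLD)
  adj9 <- vapply(seq_len(59)[-c(20, 40)], function(j)
    cor(G9[, j], G9[, j + 1]), numeric(1))
  expect_gte(median(adj9), 0.5)
})

test_that("VanRaden kinship has unit-scale diagonal and is PSD", {
  set.seed(95)
  G <- matrix(rbinom(300 * 5000, 2, rep(runif(5000, 0.05, 0.5), each = 300)),
              300, 5000)
  K <- buildKinship(G)
  expect_lt(abs(mean(diag(K)) - 1), 0.15)
  expect_true(isSymmetric(K))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8 * max(ev))

  # clones: identical rows give a constant matrix
  Gc <- matrix(rep(rbinom(20, 2, 0.4), each = 6), 6, 20)
  Kc <- suppressWarnings(buildKinship(Gc))  # clones make some SNPs monomorphic
  expect_equal(max(Kc) - min(Kc), 0, tolerance = 1e-12)

  # monomorphic columns are excluded with a warning
  Gm <- cbind(G[1:50, 1:10], 0)
  expect_warning(buildKinship(Gm), "monomorphic")
})

test_that("null-model phenotype variance matches sigma2 (1 + tau) for K = I", {
  set.seed(96)
  s <- SimSettings(n = 100, L = 10, nBlocks = 1, rho = 0, model = "null",
                   causal = integer(0), beta = numeric(0), seed = 96)
  ys <- unlist(lapply(1:200, function(i)
    simulatePhenotype(matrix(0, 100, 1), diag(100), s)$Y))
  expect_equal(var(ys), 0.2 * 1.1, tolerance = 0.1)
})

test_that("null and linear models nest inside the mixed model", {
  s <- indepSettings(n = 150, L = 50, causal = 25L, beta = 0, seed = 97)
  sim <- simulateGWAS(s)
  sNull <- indepSettings(n = 150, L = 50, causal = 25L, beta = 0,
                         model = "null", seed = 97)
  simNull <- simulateGWAS(sNull)
  # beta = 0 mixed draw is distributed as the null draw: identical under
  # the same seed since the RNG consumes the same stream
  expect_identical(phenotypes(sim$data), phenotypes(simNull$data))

  sLin <- indepSettings(n = 200, L = 40, causal = 20L, beta = 0.5,
                        model = "linear", seed = 98)
  simLin <- simulateGWAS(sLin)
  expect_length(simLin$truth@u, 0)
  # linear-model variance around the regression is sigma2 alone
  G <- genotypes(simLin$data)
  res <- resid(lm(phenotypes(simLin$data) ~ G[, 20]))
  expect_equal(var(res), 0.2, tolerance = 0.06)
})

test_that("simulation truth records the causal configuration", {
  s <- indepSettings(n = 60, L = 80, causal = c(10L, 70L), beta = c(0.4, 0.8),
                     seed = 99)
  sim <- simulateGWAS(s)
  expect_identical(sum(sim$truth@causalIndicator), 2L)
  expect_identical(which(sim$truth@causalIndicator == 1L), c(10L, 70L))
  expect_identical(sim$truth@betaTrue[c(10L, 70L)], c(0.4, 0.8))
})
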