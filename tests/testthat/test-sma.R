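test_that("with identity kinship the mixed-model SMA reduces to OLS t-tests", {
  # with K = I the profile likelihood is flat in tau, so the Wald test
  # must coincide with the classic regression t-test
  set.seed(81)
  n <- 60; L <- 15
  G <- matrix(rbinom(n * L, 2, 0.4), n, L)
  d <- GWASData(rnorm(n) + 0.6 * G[, 5], G, K = diag(n))
  ex <- smaExact(d)
  ols <- smaOLS(d)
  pLm <- vapply(seq_len(L), function(l)
    summary(lm(d@Y ~ G[, l]))$coefficients[2, 4], numeric(1))
  expect_equal(ols@pvals, pLm, tolerance = 1e-10)
  expect_equal(ex@pvals, pLm, tolerance = 1e-6)
})

test_that("exact and approx SMA rank SNPs almost identically under kinship", {
  sim <- simulateGWAS(indepSettings(n = 150, L = 300,
                                    causal = c(60L, 180L, 290L),
                                    beta = c(0.8, 0.6, 0.7), seed = 82))
  ex <- smaExact(sim$data)
  ap <- smaApprox(sim$data)
  rc <- cor(-log10(ex@pvals), -log10(ap@pvals), method = "spearman")
  expect_gte(rc, 0.99)
  expect_setequal(ex@significant, ap@significant)
})

test_that("approx SMA is faster than exact SMA", {
  sim <- simulateGWAS(indepSettings(n = 150, L = 2000, causal = 1000L,
                                    beta = 1, seed = 83))
  tEx <- system.time(smaExact(sim$data))[["elapsed"]]
  tAp <- system.time(smaApprox(sim$data))[["elapsed"]]
  expect_lt(tAp, tEx)
})

test_that("mixed-model SMA holds its size under a permuted-phenotype null", {
  set.seed(84)
  rej <- total <- 0
  for (i in 1:3) {
    sim <- simulateGWAS(indepSettings(n = 120, L = 500, causal = 250L,
                                      beta = 1.5, seed = 840 + i))
    d <- GWASData(sample(phenotypes(sim$data)), genotypes(sim$data),
                  K = kinship(sim$data))
    ex <- smaExact(d)
    rej <- rej + sum(ex@pvals < 0.05)
    total <- total + length(ex@pvals)
  }
  expect_gte(rej / total, 0.03)
  expect_lte(rej / total, 0.07)
})

test_that("OLS p-values are uniform under the global null", {
  set.seed(85)
  pool <- unlist(lapply(1:5, function(i) {
    n <- 100
    G <- matrix(rbinom(n * 200, 2, 0.3), n, 200)
    d <- suppressWarnings(GWASData(rnorm(n), G, K = diag(n)))
    smaOLS(d)@pvals
  }))
  expect_gt(ks.test(pool, "punif")$p.value, 0.01)
})

test_that("OLS localizes a single causal SNP", {
  hits <- 0
  for (i in 1:20) {
    set.seed(860 + i)
    n <- 300
    G <- matrix(rbinom(n * 100, 2, 0.3), n, 100)
    Y <- 1 + G[, 37] + rnorm(n, 0, sqrt(0.2))
    d <- GWASData(Y, G, K = diag(n))
    if (which.min(smaOLS(d)@pvals) == 37) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("monomorphic SNPs get p = 1 and Bonferroni is order invariant", {
  set.seed(87)
  n <- 50
  G <- matrix(rbinom(n * 8, 2, 0.4), n, 8)
  G[, 3] <- 2
  d <- suppressWarnings(GWASData(rnorm(n) + G[, 1], G, K = diag(n)))
  r <- smaOLS(d)
  expect_identical(r@pvals[3], 1)
  expect_identical(r@betas[3], 0)

  perm <- sample(8)
  dp <- suppressWarnings(GWASData(d@Y, G[, perm], K = diag(n)))
  rp <- smaOLS(dp)
  expect_setequal(perm[rp@significant], r@significant)
})

test_that("duplicated SNP columns get identical mixed-model p-values", {
  d <- makeToyData(n = 60, L = 8, seed = 88, causal = 2L, beta = 0.9)
  G <- genotypes(d)
  G[, 6] <- G[, 2]
  d2 <- GWASData(phenotypes(d), G, K = kinship(d))
  ex <- smaExact(d2)
  expect_equal(ex@pvals[2], ex@pvals[6], tolerance = 1e-10)
})
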