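test_that("BIC Bayes-factor approximation evaluates exp(-0.5 dBIC)", {
  expect_equal(bayesFactorApprox(100, 100), 1)
  expect_equal(bayesFactorApprox(98, 100), exp(1), tolerance = 1e-12)
  expect_equal(bayesFactorApprox(102, 100), exp(-1), tolerance = 1e-12)
  # overflow clamp keeps the result finite
  expect_equal(bayesFactorApprox(-1e6, 0, log = TRUE), 700)
  expect_error(bayesFactorApprox(NaN, 1), "NaN")
})

test_that("Bernoulli model prior gives the stated log-probabilities", {
  pr <- new("ModelPrior", pi0 = 0.5, s = 1L, source = "estimated")
  expect_equal(priorModelProb(pr, 1), log(0.5))
  pr9 <- new("ModelPrior", pi0 = 0.9, s = 10L, source = "estimated")
  expect_equal(priorModelProb(pr9, 2), log(0.9^8 * 0.1^2), tolerance = 1e-12)
  expect_equal(priorModelProb(pr9, 0), 10 * log(0.9), tolerance = 1e-12)
  expect_error(priorModelProb(pr9, 11), "outside")
})

test_that("model prior normalizes over the full model space", {
  # brute force over all 2^s models
  for (s in c(5L, 12L)) {
    pr <- new("ModelPrior", pi0 = 0.85, s = s, source = "estimated")
    sizes <- vapply(0:(2^s - 1), function(m)
      sum(bitwAnd(m, 2^(0:(s - 1))) > 0), numeric(1))
    expect_equal(sum(exp(priorModelProb(pr, sizes))), 1, tolerance = 1e-10)
  }
})

test_that("pi0 fallback equals 1 - 100/L exactly at genome scale", {
  for (L in c(1e3, 6e4, 8.4e5)) {
    # a hard null: all p-values at 1 forces the conservative branch
    pr <- estimatePi0(rep(1, 1000), L = L)
    expect_identical(pr@source, "fallback")
    expect_identical(pr@pi0, 1 - 100 / L)
  }
})

test_that("uniform p-values usually trigger the conservative fallback", {
  hits <- 0
  set.seed(20)
  for (i in 1:20) {
    pr <- estimatePi0(runif(10000))
    if (pr@source == "fallback") hits <- hits + 1
  }
  expect_gte(hits, 10)
})

test_that("pi0 estimate is calibrated on a null/signal mixture", {
  ok <- 0
  set.seed(21)
  for (i in 1:20) {
    p <- c(runif(5000), rbeta(5000, 0.1, 10))
    pr <- estimatePi0(p)
    if (pr@source == "estimated" && pr@pi0 >= 0.4 && pr@pi0 <= 0.7) ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("single-SNP posterior follows the two-model formula", {
  pr <- new("ModelPrior", pi0 = 0.5, s = 10L, source = "estimated")
  expect_equal(snpPosterior(1, pr), 0.5)
  expect_equal(snpPosterior(9, pr), 0.9, tolerance = 1e-12)
  expect_equal(snpPosterior(0, pr), 0)
  # general pi0
  pr2 <- new("ModelPrior", pi0 = 0.99, s = 10L, source = "estimated")
  bf <- 37
  expect_equal(snpPosterior(bf, pr2),
               (1 - 0.99) * bf / (0.99 + (1 - 0.99) * bf), tolerance = 1e-12)
  # strictly increasing in the Bayes factor
  ps <- snpPosterior(c(0.1, 1, 5, 50, 5000), pr2)
  expect_true(all(diff(ps) > 0))
})

test_that("posteriors over models normalize and are shift invariant", {
  mk <- function(bic, p, prior) new("SNPModel", snps = seq_len(p),
    bic = bic, logBF = -0.5 * bic, logPrior = priorModelProb(prior, p),
    posterior = NA_real_)
  pr <- new("ModelPrior", pi0 = 0.9, s = 6L, source = "estimated")

  two <- posteriorOverModels(list(mk(10, 1, pr), mk(10, 1, pr)))
  expect_equal(vapply(two, function(m) m@posterior, 0), c(0.5, 0.5))

  set.seed(22)
  bics <- rnorm(3, 100, 5)
  ms <- lapply(seq_along(bics), function(i) mk(bics[i], i, pr))
  post <- vapply(posteriorOverModels(ms), function(m) m@posterior, 0)
  w <- exp(vapply(ms, function(m) m@logPrior, 0) - 0.5 * bics + 60)
  expect_equal(post, w / sum(w), tolerance = 1e-10)
  expect_equal(sum(post), 1, tolerance = 1e-8)

  shifted <- lapply(ms, function(m) { m@bic <- m@bic + 123; m@logBF <- m@logBF - 0.5 * 123; m })
  post2 <- vapply(posteriorOverModels(shifted), function(m) m@posterior, 0)
  expect_equal(post, post2, tolerance = 1e-10)
  expect_error(posteriorOverModels(list()), "empty")
})
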