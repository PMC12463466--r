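test_that("plug-in scaling factors follow the stated formulas", {
  Y <- matrix(c(1L, 3L, 2L, 4L), 2, 2,
    dimnames = list(c("a", "b"), c("x", "y"))
  )
  expect_equal(computeSizeFactors(Y), c(x = 0.4, y = 0.6))
  expect_equal(computeGeneFactors(Y), c(a = 3, b = 7))
  # identical spots share s_i = 1/n; a single spot gets s = 1
  Yu <- matrix(2L, 3, 5, dimnames = list(letters[1:3], LETTERS[1:5]))
  expect_equal(unname(computeSizeFactors(Yu)), rep(1 / 5, 5))
  expect_equal(unname(computeSizeFactors(Yu[, 1, drop = FALSE])), 1)
  # zero totals are an error, not a silent drop
  Yz <- Y
  Yz[, 1] <- 0L
  expect_error(computeSizeFactors(Yz), "zero total")
  Yz <- Y
  Yz[1, ] <- 0L
  expect_error(computeGeneFactors(Yz), "zero total")
})

test_that("plug-in gene effects correlate with the generating gene effects", {
  sim <- simulateSRT(
    width = 8, height = 8, p = 150, K = 4, R = 3,
    delta = 1, pi0 = 0.2, seed = 21
  )
  g <- computeGeneFactors(sim$counts)
  expect_gt(cor(g, sim$g_true), 0)
  s <- computeSizeFactors(sim$counts)
  expect_gt(cor(s, sim$s_true), 0)
})

test_that("collapsed block marginal matches closed forms and quadrature", {
  # Poi(2 | mu) with Ga(1,1) prior and unit exposure integrates to 1/8;
  # the function excludes the per-cell constant -log y! = -log 2
  expect_equal(logMarginalBlock(2, 1, 1, 1) - lfactorial(2), log(1 / 8))
  expect_equal(logMarginalBlock(0, 1, 1, 1), log(1 / 2))
  expect_equal(logMarginalBlock(0, 0, 1, 1), 0) # empty block
  expect_error(logMarginalBlock(-1, 1, 1, 1), "negative")
  set.seed(42)
  for (rep in 1:25) {
    N <- rpois(1, 8)
    S <- runif(1, 0.1, 5)
    a <- runif(1, 0.1, 10)
    b <- runif(1, 0.1, 10)
    expect_equal(logMarginalBlock(N, S, a, b), quadLogMarginal(N, S, a, b),
      tolerance = 1e-8
    )
  }
})

test_that("sufficient statistics are internally consistent", {
  Y <- tinyCounts(6, 8, lambda = 6, seed = 3)
  z <- rep(1:2, each = 4)
  rho <- c(0, 1, 2, 1, 0, 2)
  st <- blockSufficientStats(Y, z, rho, K = 2, R = 2)
  # block totals agree with both cross-table margins
  for (r in 1:2) {
    for (k in 1:2) {
      expect_equal(st$N[r, k], sum(st$nspot[r, z == k]))
      expect_equal(st$N[r, k], sum(st$ngene[rho == r, k]))
    }
  }
  expect_equal(sum(st$N) + st$N0, sum(Y))
  expect_equal(sum(st$S), 1)
  expect_equal(st$G0 + sum(st$G), sum(computeGeneFactors(Y)))
})

test_that("collapsed log joint equals a direct quadrature construction", {
  set.seed(3)
  Y <- tinyCounts(2, 3, lambda = 5, seed = 31)
  E <- pathGraph(3)
  z <- c(1, 2, 1)
  rho <- c(1, 0)
  pi0 <- 0.3
  s <- computeSizeFactors(Y)
  g <- computeGeneFactors(Y)
  blockIntegral <- function(js, is, a, b) {
    f <- function(mu) {
      sapply(mu, function(m) {
        cells <- expand.grid(j = js, i = is)
        prod(dpois(
          Y[cbind(cells$j, cells$i)],
          s[cells$i] * g[cells$j] * m
        )) * stats::dgamma(m, a, b)
      })
    }
    stats::integrate(f, 0, 60, rel.tol = 1e-12)$value
  }
  ll <- blockIntegral(1, c(1, 3), 1, 1) * blockIntegral(1, 2, 1, 1) *
    blockIntegral(2, 1:3, 1, 1)
  direct <- log(ll) + polyaUrnLogPrior(rho, 1, 1, pi0) +
    mrfLogJoint(z, E, 2, 1, 1)
  expect_equal(
    logFullMarginal(Y, z, rho, E, K = 2, R = 1, pi0 = pi0), direct,
    tolerance = 1e-9
  )
})

test_that("log joint is invariant to label symmetries", {
  Y <- tinyCounts(5, 6, lambda = 7, seed = 8)
  E <- pathGraph(6)
  z <- c(1, 1, 2, 2, 3, 3)
  rho <- c(1, 2, 0, 1, 2)
  base <- logFullMarginal(Y, z, rho, E, K = 3, R = 2)
  # swapping the two gene-group labels changes nothing
  rhoSwap <- c(2, 1, 0, 2, 1)
  expect_equal(logFullMarginal(Y, z, rhoSwap, E, K = 3, R = 2), base)
  # with h = 0 and equal abundances, spot labels are exchangeable too
  hyp0 <- spotBlockHyperparams(h = 0)
  zSwap <- c(2, 2, 1, 1, 3, 3)
  expect_equal(
    logFullMarginal(Y, z, rho, E, K = 3, R = 2, hyp = hyp0),
    logFullMarginal(Y, zSwap, rho, E, K = 3, R = 2, hyp = hyp0)
  )
})

test_that("merging two spot clusters only changes the affected blocks", {
  Y <- tinyCounts(4, 6, lambda = 6, seed = 13)
  E <- pathGraph(6)
  rho <- c(1, 1, 2, 0)
  hyp <- spotBlockHyperparams(h = 0) # isolate the likelihood terms
  z1 <- c(1, 1, 2, 2, 3, 3)
  z2 <- c(1, 1, 2, 2, 2, 2) # clusters 2 and 3 merged
  term <- function(z, K) {
    st <- blockSufficientStats(Y, z, rho, K, 2)
    logMarginalBlock(st$N, outer(st$G, st$S), 1, 1)
  }
  t1 <- term(z1, 3)
  t2 <- term(z2, 3)
  # cluster 1's block terms are untouched by the merge
  expect_equal(t1[, 1], t2[, 1])
})

test_that("conjugate plug-in means follow the posterior-mean arithmetic", {
  st <- list(
    N = matrix(10, 1, 1), G = 2, S = 2, N0 = 6, G0 = 3, sumS = 1,
    t = c(4, 6), g = c(2, 3), s = 1, rho = c(1, 0)
  )
  mu <- posteriorMeanMu(st, spotBlockHyperparams())
  expect_equal(mu$mu[1, 1], 11 / 5)
  expect_equal(mu$mu0, 7 / 4)
  expect_equal(mu$mu0_gene, (1 + c(4, 6)) / (1 + c(2, 3)))
  # empty block falls back to the prior mean
  stE <- list(N = matrix(0, 1, 1), G = 0, S = 0, N0 = 0, G0 = 0, sumS = 0)
  expect_equal(posteriorMeanMu(stE, spotBlockHyperparams())$mu[1, 1], 1)
})
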