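test_that("initialisation is deterministic and respects label ranges", {
  Y <- tinyCounts(20, 16, lambda = 6, seed = 2)
  s1 <- initializeState(Y, K = 3, R = 2, mode = "random", seed = 5)
  s2 <- initializeState(Y, K = 3, R = 2, mode = "random", seed = 5)
  expect_identical(s1, s2)
  expect_true(all(s1$z %in% 1:3) && all(s1$rho %in% 0:2))
  # degenerate K = R = 1
  s3 <- initializeState(Y, K = 1, R = 1, mode = "random", seed = 1)
  expect_true(all(s3$z == 1L) && all(s3$rho %in% 0:1))
  expect_equal(s3$pi0, 0.5)
  expect_error(initializeState(Y, K = 17, R = 1), "exceeds")
})

test_that("kmeans-pca initialisation beats random on strong-signal data", {
  ariInit <- sapply(1:12, function(sd) {
    sim <- simulateSRT(
      width = 8, height = 8, p = 80, K = 4, R = 3,
      delta = 1.5, pi0 = 0, seed = sd
    )
    km <- initializeState(sim$counts, 4, 3, "kmeans-pca", seed = sd)
    rd <- initializeState(sim$counts, 4, 3, "random", seed = sd)
    c(
      km = adjustedRandIndex(km$z, sim$z_true),
      rd = adjustedRandIndex(rd$z, sim$z_true)
    )
  })
  expect_gt(mean(ariInit["km", ]), mean(ariInit["rd", ]))
})

test_that("spot full conditional equals the normalised joint over completions", {
  Y <- tinyCounts(3, 4, lambda = 7, seed = 10)
  E <- pathGraph(4)
  z <- c(1, 2, 2, 1)
  rho <- c(1, 0, 1)
  for (i in c(1, 3)) {
    pCond <- spotFullConditional(Y, z, rho, i, E, K = 2, R = 1)
    pEnum <- vapply(1:2, function(k) {
      zz <- z
      zz[i] <- k
      exp(logFullMarginal(Y, zz, rho, E, K = 2, R = 1, pi0 = 0.5))
    }, numeric(1))
    expect_equal(pCond, pEnum / sum(pEnum), tolerance = 1e-10)
  }
  # single-spot reduction: prior times that spot's marginal
  Y1 <- tinyCounts(2, 1, lambda = 5, seed = 77)
  E1 <- Matrix::sparseMatrix(
    i = integer(), j = integer(), x = numeric(),
    dims = c(1, 1)
  )
  p1 <- spotFullConditional(Y1, 1L, c(1, 1), 1, E1, K = 2, R = 1)
  pEnum1 <- vapply(1:2, function(k) {
    exp(logFullMarginal(Y1, k, c(1, 1), E1, K = 2, R = 1, pi0 = 0.5))
  }, numeric(1))
  expect_equal(p1, pEnum1 / sum(pEnum1), tolerance = 1e-10)
})

test_that("gene full conditional equals the normalised joint over completions", {
  Y <- tinyCounts(4, 3, lambda = 6, seed = 12)
  E <- pathGraph(3)
  z <- c(1, 1, 1)
  rho <- c(0, 1, 2, 1)
  pi0 <- 0.3
  for (j in 1:4) {
    pCond <- geneFullConditional(Y, z, rho, j, K = 1, R = 2, pi0 = pi0)
    pEnum <- vapply(0:2, function(r) {
      rr <- rho
      rr[j] <- r
      exp(logFullMarginal(Y, z, rr, E, K = 1, R = 2, pi0 = pi0))
    }, numeric(1))
    expect_equal(unname(pCond), pEnum / sum(pEnum), tolerance = 1e-10)
  }
})

test_that("spatial interaction strength pulls a spot towards its neighbours", {
  # flat counts so the likelihood is weak; all neighbours in cluster 1
  Y <- matrix(5L, 3, 5, dimnames = list(paste0("g", 1:3), paste0("s", 1:5)))
  E <- Matrix::sparseMatrix(
    i = rep(5, 4), j = 1:4, x = 1, dims = c(5, 5),
    symmetric = TRUE
  )
  z <- c(1, 1, 1, 1, 2)
  probs <- sapply(c(0, 1, 2, 4, 8), function(h) {
    spotFullConditional(Y, z, c(1, 1, 1), 5, E,
      K = 2, R = 1,
      hyp = spotBlockHyperparams(h = h)
    )[1]
  })
  expect_true(all(diff(probs) > 0))
  expect_gt(probs[5], 0.99)
})

test_that("chains are reproducible and book-keep iterations correctly", {
  Y <- tinyCounts(5, 6, lambda = 6, seed = 4)
  E <- pathGraph(6)
  tr1 <- runChain(Y, E, K = 2, R = 2, iters = 10, burnin = 5, seed = 3)
  tr2 <- runChain(Y, E, K = 2, R = 2, iters = 10, burnin = 5, seed = 3)
  expect_identical(traceDraws(tr1, "z"), traceDraws(tr2, "z"))
  expect_identical(traceDraws(tr1, "rho"), traceDraws(tr2, "rho"))
  expect_identical(tr1@pi0, tr2@pi0)
  expect_identical(logPostTrace(tr1), logPostTrace(tr2))
  expect_equal(nrow(traceDraws(tr1, "z")), 5)
  expect_equal(length(logPostTrace(tr1)), 10)
  # thinning bookkeeping
  tr3 <- runChain(Y, E, K = 2, R = 2, iters = 20, burnin = 6, thin = 3, seed = 1)
  expect_equal(nrow(traceDraws(tr3, "z")), length(seq(7, 20, by = 3)))
  expect_error(runChain(Y, E, K = 2, R = 2, iters = 5, burnin = 9), "burnin")
})

test_that("incremental statistics survive a debug-checked run", {
  sim <- simulateSRT(
    width = 6, height = 6, p = 40, K = 2, R = 2,
    delta = 1, pi0 = 0.3, seed = 6
  )
  E <- buildLatticeAdjacency(sim$coords, "square")
  expect_no_error(
    runChain(sim$counts, E,
      K = 2, R = 2, iters = 120, burnin = 60,
      seed = 2, debug = TRUE
    )
  )
})

test_that("recorded log joint matches the independent R implementation", {
  Y <- tinyCounts(4, 5, lambda = 8, seed = 15)
  E <- pathGraph(5)
  tr <- runChain(Y, E, K = 2, R = 2, iters = 40, burnin = 20, seed = 9)
  for (u in c(1, 10, 20)) {
    expect_equal(
      logPostTrace(tr)[20 + u],
      logFullMarginal(
        Y, traceDraws(tr, "z")[u, ], traceDraws(tr, "rho")[u, ],
        E,
        K = 2, R = 2
      ),
      tolerance = 1e-10
    )
  }
})

test_that("pi0 draws follow the Beta full conditional", {
  # peg the gene labels by making R = 1 irresistible for none of the genes:
  # with a single flat gene pool and strong nulls, p0 stays near p, so the
  # Beta draw is exercised across its support; check moments against the
  # analytic mixture implied by the sampled p0 sequence
  Y <- tinyCounts(6, 5, lambda = 4, seed = 44)
  E <- pathGraph(5)
  tr <- runChain(Y, E, K = 1, R = 1, iters = 4000, burnin = 1000, seed = 2)
  p0 <- rowSums(traceDraws(tr, "rho") == 0L)
  expected <- mean((1 + p0) / (2 + 6))
  expect_equal(mean(tr@pi0), expected, tolerance = 0.05)
})

test_that("independent chains differ only by seed and pool cleanly", {
  Y <- tinyCounts(5, 6, lambda = 6, seed = 18)
  E <- pathGraph(6)
  trs <- runChains(Y, E,
    K = 2, R = 1, iters = 30, burnin = 10, nChains = 3,
    baseSeed = 5
  )
  expect_length(trs, 3)
  expect_equal(
    vapply(trs, function(tr) tr@meta$seed, integer(1)),
    c(5L, 6L, 7L)
  )
  # PPM of pooled chains equals PPM of the concatenated draws
  pooled <- do.call(rbind, lapply(trs, traceDraws, what = "z"))
  fit <- summarizeFit(trs, Y)
  expect_equal(spotPPM(fit), computePPM(pooled))
})
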