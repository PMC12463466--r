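# Shared fixtures and independent oracles for the test suite.

# small count matrix with names
tinyCounts <- function(p = 3, n = 4, lambda = 5, seed = 99) {
  set.seed(seed)
  Y <- matrix(rpois(p * n, lambda), p, n)
  Y[1, 1] <- Y[1, 1] + 1L # guard against all-zero rows at tiny lambda
  dimnames(Y) <- list(paste0("g", seq_len(p)), paste0("s", seq_len(n)))
  Y
}

# path graph on n nodes as a sparse symmetric adjacency
pathGraph <- function(n) {
  E <- Matrix::sparseMatrix(
    i = seq_len(n - 1), j = seq.int(2, n), x = 1,
    dims = c(n, n), symmetric = TRUE
  )
  methods::as(E, "generalMatrix")
}

# numerical quadrature of the Poisson-Gamma block marginal (mu-dependent
# part only): integral of prod_c Poi(y_c | e_c mu) Ga(mu | a, b) dmu with
# the per-cell constant prod e_c^y / y! divided out.
quadLogMarginal <- function(N, S, a, b, upper = Inf) {
  f <- function(mu) mu^(N + a - 1) * exp(-(S + b) * mu) * b^a / gamma(a)
  log(stats::integrate(f, 0, upper, rel.tol = 1e-12)$value)
}

# exhaustive posterior over all K^n * (R+1)^p partitions; returns exact
# co-clustering matrices for spots and genes plus the state grid
enumeratePosterior <- function(Y, E, K, R, hyp = NULL) {
  n <- ncol(Y)
  p <- nrow(Y)
  zs <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  rs <- as.matrix(expand.grid(rep(list(0:R), p)))
  W <- matrix(NA_real_, nrow(zs), nrow(rs))
  for (a in seq_len(nrow(zs))) {
    for (b in seq_len(nrow(rs))) {
      W[a, b] <- logFullMarginal(Y, zs[a, ], rs[b, ], E, K, R, hyp = hyp)
    }
  }
  Wn <- exp(W - max(W))
  Wn <- Wn / sum(Wn)
  pz <- matrix(0, n, n)
  for (a in seq_len(nrow(zs))) {
    pz <- pz + sum(Wn[a, ]) * outer(zs[a, ], zs[a, ], "==")
  }
  pg <- matrix(0, p, p)
  for (b in seq_len(nrow(rs))) {
    pg <- pg + sum(Wn[, b]) * outer(rs[b, ], rs[b, ], "==")
  }
  list(zStates = zs, rhoStates = rs, weights = Wn, ppmSpot = pz, ppmGene = pg)
}

# brute-force PPM by double loop (independent of the C++ path)
bruteForcePPM <- function(draws) {
  U <- nrow(draws)
  m <- ncol(draws)
  P <- matrix(0, m, m)
  for (u in seq_len(U)) {
    for (a in seq_len(m)) {
      for (b in seq_len(m)) {
        if (draws[u, a] == draws[u, b]) P[a, b] <- P[a, b] + 1
      }
    }
  }
  P / U
}

# number of ways to assign R distinct labels to B occupied clusters
labelPerms <- function(R, B) {
  if (B == 0) {
    return(1)
  }
  prod(seq.int(R, R - B + 1))
}
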