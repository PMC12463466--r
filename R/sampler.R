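#' Initialise sampler labels
#'
#' \code{"kmeans-pca"} assigns the spot labels by k-means on the leading
#' principal components of the log1p library-size-normalised counts (a
#' standard quick spatial-domain initialisation) and the gene labels
#' uniformly at random over 0..R; \code{"random"} draws both label vectors
#' uniformly. pi0 starts at its prior mean. Deterministic given
#' \code{seed}.
#'
#' @param Y count matrix.
#' @param K,R numbers of spatial domains and gene groups.
#' @param mode \code{"kmeans-pca"} or \code{"random"}.
#' @param seed integer seed.
#' @param hyp hyperparameters (for the pi0 prior mean).
#' @return list with \code{z}, \code{rho}, \code{pi0}.
#' @export
initializeState <- function(Y, K, R, mode = c("kmeans-pca", "random"),
                            seed = 1L, hyp = NULL) {
  mode <- match.arg(mode)
  Y <- asCountMatrix(Y)
  n <- ncol(Y)
  p <- nrow(Y)
  if (K > n) stop("K exceeds the number of spots")
  if (R > p) stop("R exceeds the number of genes")
  hyp <- .asHyp(hyp, K)
  set.seed(seed)
  if (mode == "kmeans-pca" && K > 1L) {
    tot <- colSums(Y)
    norm <- log1p(sweep(Y, 2L, pmax(tot, 1L), "/") * median(tot))
    npc <- min(10L, n - 1L, p)
    pcs <- prcomp(t(norm), rank. = npc)$x
    z <- kmeans(pcs, centers = K, nstart = 5L)$cluster
  } else {
    z <- sample.int(K, n, replace = TRUE)
  }
  rho <- sample.int(R + 1L, p, replace = TRUE) - 1L
  list(
    z = as.integer(z), rho = as.integer(rho),
    pi0 = hyp$alpha_pi / (hyp$alpha_pi + hyp$beta_pi)
  )
}

#' Reference full conditional of one spot label
#'
#' Normalised probabilities \eqn{P(z_i = k \mid \cdot)} computed directly
#' from the collapsed log joint: the MRF conditional plus, for every gene
#' group, the change in the collapsed block marginals from adding spot
#' \eqn{i}'s group subtotals to domain \eqn{k}. Null genes contribute
#' nothing (their marginal does not depend on z). This is a plain-R
#' reference used to validate the sampler; it recomputes sufficient
#' statistics from scratch.
#'
#' @param Y count matrix.
#' @param z,rho current labels.
#' @param i spot index.
#' @param E adjacency matrix.
#' @param K,R label ranges.
#' @param hyp hyperparameters.
#' @param s,g scaling factors (plug-ins when NULL).
#' @return a length-K probability vector.
#' @export
spotFullConditional <- function(Y, z, rho, i, E, K, R, hyp = NULL,
                                s = NULL, g = NULL) {
  Y <- asCountMatrix(Y)
  hyp <- .asHyp(hyp, K)
  if (is.null(s)) s <- computeSizeFactors(Y)
  if (is.null(g)) g <- computeGeneFactors(Y)
  lw <- vapply(seq_len(K), function(k) {
    zz <- z
    zz[i] <- k
    st <- blockSufficientStats(Y, zz, rho, K, R, s, g)
    sum(logMarginalBlock(st$N, outer(st$G, st$S), hyp$alpha_mu, hyp$beta_mu)) +
      mrfLogConditional(zz, i, E, K, hyp$b, hyp$h)[k]
  }, numeric(1))
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Reference full conditional of one gene label
#'
#' Normalised probabilities \eqn{P(\rho_j = \cdot \mid \cdot)} over
#' \{0, 1..R\}: the Polya urn prior conditional
#' ([geneLabelPriorConditional()]) plus the change in the collapsed null or
#' block marginals from adding gene \eqn{j}'s domain subtotals. Plain-R
#' reference implementation.
#'
#' @inheritParams spotFullConditional
#' @param j gene index.
#' @param pi0 current null probability (explicit mode).
#' @return a length-(R+1) probability vector named "0".."R".
#' @export
geneFullConditional <- function(Y, z, rho, j, K, R, pi0, hyp = NULL,
                                s = NULL, g = NULL) {
  Y <- asCountMatrix(Y)
  hyp <- .asHyp(hyp, K)
  if (is.null(s)) s <- computeSizeFactors(Y)
  if (is.null(g)) g <- computeGeneFactors(Y)
  prior <- geneLabelPriorConditional(rho, j, R,
    gamma = hyp$gamma,
    mode = "explicit", pi0 = pi0
  )
  lw <- vapply(0:R, function(r) {
    rr <- rho
    rr[j] <- r
    st <- blockSufficientStats(Y, z, rr, K, R, s, g)
    sum(logMarginalBlock(st$N, outer(st$G, st$S), hyp$alpha_mu, hyp$beta_mu)) +
      logMarginalBlock(st$N0, st$G0 * st$sumS, hyp$alpha_0, hyp$beta_0)
  }, numeric(1))
  lw <- lw + prior
  w <- exp(lw - max(lw))
  p <- w / sum(w)
  names(p) <- 0:R
  p
}

#' Run one collapsed Gibbs chain
#'
#' One iteration sweeps all spots in a fresh random permutation, then all
#' genes in a fresh random permutation, then draws pi0 from its Beta full
#' conditional \eqn{\mathrm{Be}(\alpha_\pi + p_0, \beta_\pi + p - p_0)}.
#' Block means are never sampled: they are integrated out analytically.
#' The log joint is recorded at every iteration (including burn-in);
#' post-burn-in draws are stored every \code{thin} iterations. Fully
#' reproducible given \code{seed}.
#'
#' @param Y count matrix (genes x spots).
#' @param E spot adjacency matrix (symmetric, zero diagonal).
#' @param K,R numbers of spatial domains and gene groups.
#' @param hyp hyperparameters ([spotBlockHyperparams()]).
#' @param iters,burnin,thin MCMC settings (defaults 10000 / 5000 / 1).
#' @param seed integer seed.
#' @param init \code{"kmeans-pca"} or \code{"random"}, or a list with
#'   elements \code{z}, \code{rho} (and optionally \code{pi0}) to start
#'   from explicitly.
#' @param s,g scaling factors (plug-ins computed from \code{Y} when NULL).
#' @param debug recompute sufficient statistics from scratch every 25
#'   iterations and stop on any discrepancy.
#' @return an [McmcTrace-class] object.
#' @export
runChain <- function(Y, E, K, R, hyp = NULL, iters = 10000L, burnin = 5000L,
                     thin = 1L, seed = 1L, init = "kmeans-pca",
                     s = NULL, g = NULL, debug = FALSE) {
  Y <- asCountMatrix(Y)
  n <- ncol(Y)
  p <- nrow(Y)
  .checkAdjacency(E, n)
  if (burnin >= iters) stop("burnin must be smaller than iters")
  if (thin < 1L) stop("thin must be >= 1")
  hyp <- .asHyp(hyp, K)
  if (is.null(s)) s <- computeSizeFactors(Y)
  if (is.null(g)) g <- computeGeneFactors(Y)
  if (is.list(init)) {
    st0 <- init
    if (is.null(st0$pi0)) st0$pi0 <- hyp$alpha_pi / (hyp$alpha_pi + hyp$beta_pi)
    initName <- "explicit"
    set.seed(seed)
  } else {
    initName <- match.arg(init, c("kmeans-pca", "random"))
    st0 <- initializeState(Y, K, R, initName, seed = seed, hyp = hyp)
    # initializeState seeds the RNG; the sweep RNG continues from it
  }
  stopifnot(
    length(st0$z) == n, all(st0$z >= 1), all(st0$z <= K),
    length(st0$rho) == p, all(st0$rho >= 0), all(st0$rho <= R)
  )
  res <- .lbm_gibbs(
    Y, .adjList(E), as.numeric(s), as.numeric(g), as.integer(K),
    as.integer(R), hyp$alpha_mu, hyp$beta_mu, hyp$alpha_0, hyp$beta_0,
    hyp$alpha_pi, hyp$beta_pi, hyp$gamma, as.numeric(hyp$b), hyp$h,
    as.integer(st0$z) - 1L, as.integer(st0$rho), st0$pi0,
    as.integer(iters), as.integer(burnin), as.integer(thin), debug
  )
  colnames(res$z) <- colnames(Y)
  colnames(res$rho) <- rownames(Y)
  new("McmcTrace",
    z = res$z, rho = res$rho, pi0 = as.numeric(res$pi0),
    logPost = as.numeric(res$log_post),
    meta = list(
      iters = as.integer(iters), burnin = as.integer(burnin),
      thin = as.integer(thin), seed = as.integer(seed), K = as.integer(K),
      R = as.integer(R), init = initName
    )
  )
}

#' Run several independent chains
#'
#' Chains differ only in their seeds (\code{baseSeed + 0:(nChains-1)}),
#' hence in initialisation and sweep randomness; model settings are shared.
#' Traces are returned separately; pooling happens in [summarizeFit()].
#'
#' @inheritParams runChain
#' @param nChains number of chains (default 3).
#' @param baseSeed seed of the first chain.
#' @return a list of [McmcTrace-class] objects.
#' @export
runChains <- function(Y, E, K, R, hyp = NULL, iters = 10000L, burnin = 5000L,
                      thin = 1L, nChains = 3L, baseSeed = 1L,
                      init = "kmeans-pca", s = NULL, g = NULL) {
  stopifnot(nChains >= 1L)
  lapply(seq_len(nChains), function(c) {
    runChain(Y, E, K, R,
      hyp = hyp, iters = iters, burnin = burnin,
      thin = thin, seed = baseSeed + c - 1L, init = init, s = s, g = g
    )
  })
}
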