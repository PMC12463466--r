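#' Pairwise co-clustering probability matrix
#'
#' Entry (a, b) is the fraction of stored draws in which items a and b
#' carry the same label; symmetric with unit diagonal.
#'
#' @param draws U x m integer label matrix (one row per stored draw).
#' @return an m x m matrix of co-clustering probabilities.
#' @export
computePPM <- function(draws) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 1L) stop("no draws")
  storage.mode(draws) <- "integer"
  P <- .ppm_cpp(draws)
  dimnames(P) <- list(colnames(draws), colnames(draws))
  P
}

#' Partition point estimate closest to the PPM
#'
#' Returns the stored draw minimising
#' \eqn{\sum_{a<b} (I(l_a = l_b) - \mathrm{PPM}_{ab})^2}; ties are broken
#' by the earliest draw index. Because the loss depends only on
#' co-clustering indicators, the result is invariant to relabelling within
#' draws.
#'
#' @param draws U x m integer label matrix.
#' @param ppm co-clustering matrix; recomputed from \code{draws} when NULL.
#' @return the selected label vector, with attribute \code{"draw"} (its
#'   row index) and \code{"loss"}.
#' @export
pointEstimateFromPPM <- function(draws, ppm = NULL) {
  draws <- as.matrix(draws)
  if (nrow(draws) < 1L) stop("no draws")
  storage.mode(draws) <- "integer"
  if (is.null(ppm)) ppm <- computePPM(draws)
  loss <- .ppm_losses_cpp(draws, unname(as.matrix(ppm)))
  u <- which.min(loss) # which.min takes the first minimum: earliest draw
  out <- draws[u, ]
  attr(out, "draw") <- u
  attr(out, "loss") <- loss[u]
  out
}

#' Summarise pooled MCMC output into a fit object
#'
#' Pools the post-burn-in draws of one or more chains, computes the spot
#' and gene PPMs, the point partitions closest to each PPM, the posterior
#' mean of pi0, and the conjugate plug-in block means conditioned on the
#' point partition.
#'
#' @param traces an [McmcTrace-class] object or a list of them (chains are
#'   required to share K, R and iteration settings).
#' @param Y the count matrix the chains were run on.
#' @param hyp hyperparameters used for the fit.
#' @param s,g scaling factors (plug-ins when NULL).
#' @return a [SpotBlockFit-class] object.
#' @export
summarizeFit <- function(traces, Y, hyp = NULL, s = NULL, g = NULL) {
  if (is(traces, "McmcTrace")) traces <- list(traces)
  if (!length(traces)) stop("at least one trace is required")
  meta <- traces[[1L]]@meta
  for (tr in traces) {
    if (!identical(tr@meta[c("K", "R", "iters", "burnin", "thin")],
      meta[c("K", "R", "iters", "burnin", "thin")])) {
      stop("traces have mismatched settings and cannot be pooled")
    }
  }
  Y <- asCountMatrix(Y)
  K <- meta$K
  R <- meta$R
  hyp <- .asHyp(hyp, K)
  if (is.null(s)) s <- computeSizeFactors(Y)
  if (is.null(g)) g <- computeGeneFactors(Y)
  zd <- do.call(rbind, lapply(traces, function(tr) tr@z))
  rd <- do.call(rbind, lapply(traces, function(tr) tr@rho))
  pi0d <- unlist(lapply(traces, function(tr) tr@pi0))
  ppmS <- computePPM(zd)
  ppmG <- computePPM(rd)
  zHat <- as.integer(pointEstimateFromPPM(zd, ppmS))
  rhoHat <- as.integer(pointEstimateFromPPM(rd, ppmG))
  names(zHat) <- colnames(Y)
  names(rhoHat) <- rownames(Y)
  st <- blockSufficientStats(Y, zHat, rhoHat, K, R, s, g)
  mu <- posteriorMeanMu(st, hyp)
  mu0g <- mu$mu0_gene[rhoHat == 0L]
  new("SpotBlockFit",
    zHat = zHat, rhoHat = rhoHat, ppmSpot = ppmS, ppmGene = ppmG,
    muHat = mu$mu, mu0Hat = mu$mu0, mu0GeneHat = mu0g,
    pi0Hat = mean(pi0d),
    logPost = lapply(traces, function(tr) tr@logPost),
    traces = traces,
    settings = list(
      K = K, R = R, iters = meta$iters, burnin = meta$burnin,
      thin = meta$thin, hyp = hyp,
      seeds = vapply(traces, function(tr) tr@meta$seed, integer(1))
    )
  )
}

#' Fit the spatial latent block model
#'
#' One-stop fit at fixed (K, R): builds the spot adjacency graph from
#' coordinates if not supplied, runs \code{nChains} independent collapsed
#' Gibbs chains, and pools them into a [SpotBlockFit-class].
#'
#' @param Y genes-by-spots count matrix (or SummarizedExperiment).
#' @param coords n x 2 spot coordinates (used to build the adjacency when
#'   \code{E} is NULL).
#' @param E spot adjacency matrix; overrides \code{coords}.
#' @param K,R numbers of spatial domains and gene groups.
#' @param lattice lattice type passed to [buildLatticeAdjacency()].
#' @param hyp hyperparameters ([spotBlockHyperparams()]).
#' @param iters,burnin,thin,nChains,seed,init MCMC settings; see
#'   [runChain()] and [runChains()].
#' @return a [SpotBlockFit-class] object.
#' @examples
#' sim <- simulateSRT(width = 8, height = 8, p = 60, K = 2, R = 2,
#'                    delta = 1.5, pi0 = 0.2, seed = 1)
#' fit <- spotBlock(sim$counts, coords = sim$coords, K = 2, R = 2,
#'                  iters = 200, burnin = 100, nChains = 1, seed = 1)
#' table(spotDomains(fit), sim$z_true)
#' @export
spotBlock <- function(Y, coords = NULL, E = NULL, K, R,
                      lattice = "square", hyp = NULL, iters = 10000L,
                      burnin = 5000L, thin = 1L, nChains = 3L, seed = 1L,
                      init = "kmeans-pca") {
  Y <- asCountMatrix(Y)
  if (is.null(E)) {
    if (is.null(coords)) stop("provide either coords or an adjacency matrix E")
    E <- buildLatticeAdjacency(coords, lattice = lattice)
  }
  traces <- runChains(Y, E, K, R,
    hyp = hyp, iters = iters, burnin = burnin,
    thin = thin, nChains = nChains, baseSeed = seed, init = init
  )
  summarizeFit(traces, Y, hyp = hyp)
}

#' Write fit artifacts to a directory
#'
#' Writes \code{spot_labels.csv} (spot_id, domain), \code{gene_labels.csv}
#' (gene_id, group; 0 = non-DG), \code{mu_hat.csv} (gene-group rows, domain
#' columns), and \code{summary.json} (pi0 estimate, group sizes, settings,
#' final log joint per chain).
#'
#' @param fit a [SpotBlockFit-class].
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeFit <- function(fit, dir) {
  stopifnot(is(fit, "SpotBlockFit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(
    data.frame(spot_id = names(fit@zHat), domain = fit@zHat),
    file.path(dir, "spot_labels.csv"),
    row.names = FALSE
  )
  write.csv(
    data.frame(gene_id = names(fit@rhoHat), group = fit@rhoHat),
    file.path(dir, "gene_labels.csv"),
    row.names = FALSE
  )
  mu <- fit@muHat
  dimnames(mu) <- list(
    paste0("group", seq_len(nrow(mu))),
    paste0("domain", seq_len(ncol(mu)))
  )
  write.csv(mu, file.path(dir, "mu_hat.csv"))
  s <- fit@settings
  jsonlite::write_json(
    list(
      pi0_hat = fit@pi0Hat, mu0_hat = fit@mu0Hat,
      n_null_genes = sum(fit@rhoHat == 0L),
      domain_sizes = as.list(tabulate(fit@zHat, s$K)),
      group_sizes = as.list(tabulate(fit@rhoHat, s$R)),
      K = s$K, R = s$R, iters = s$iters, burnin = s$burnin, thin = s$thin,
      seeds = as.list(s$seeds),
      final_log_post = lapply(fit@logPost, function(lp) lp[length(lp)])
    ),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
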