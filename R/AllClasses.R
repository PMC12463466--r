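#' McmcTrace: stored draws from one collapsed Gibbs chain
#'
#' Post-burn-in, thinned draws of the spot labels \code{z}, gene labels
#' \code{rho} (0 = non-discriminating), and the null probability \code{pi0},
#' together with the per-iteration log joint (all iterations, including
#' burn-in) and the run metadata.
#'
#' @slot z U x n integer matrix of spot-domain draws (values 1..K).
#' @slot rho U x p integer matrix of gene-group draws (values 0..R).
#' @slot pi0 numeric vector of length U, draws of the null probability.
#' @slot logPost numeric vector of length \code{iters}: the log joint
#'   (block means and pi0 integrated out, MRF term unnormalised) at the end
#'   of every iteration.
#' @slot meta list with elements \code{iters}, \code{burnin}, \code{thin},
#'   \code{seed}, \code{K}, \code{R}, \code{init}.
#'
#' @aliases McmcTrace
#' @exportClass McmcTrace
setClass("McmcTrace",
  representation(
    z = "matrix", rho = "matrix", pi0 = "numeric",
    logPost = "numeric", meta = "list"
  )
)

setValidity("McmcTrace", function(object) {
  U <- nrow(object@z)
  msg <- character()
  if (nrow(object@rho) != U) {
    msg <- c(msg, "z and rho must hold the same number of draws")
  }
  if (length(object@pi0) != U) {
    msg <- c(msg, "pi0 must hold one draw per stored iteration")
  }
  m <- object@meta
  if (!all(c("iters", "burnin", "thin", "seed", "K", "R") %in% names(m))) {
    msg <- c(msg, "meta must contain iters, burnin, thin, seed, K, R")
  } else {
    expU <- length(seq.int(m$burnin + 1L, m$iters, by = m$thin))
    if (U != expU) msg <- c(msg, "number of stored draws inconsistent with meta")
    if (U > 0 && (min(object@z) < 1L || max(object@z) > m$K)) {
      msg <- c(msg, "spot labels out of 1..K")
    }
    if (U > 0 && (min(object@rho) < 0L || max(object@rho) > m$R)) {
      msg <- c(msg, "gene labels out of 0..R")
    }
  }
  if (length(msg)) msg else TRUE
})

#' SpotBlockFit: posterior summary of a latent block model fit
#'
#' Point partitions, pairwise co-clustering probability matrices (PPMs),
#' plug-in block means and the estimated null probability, pooled across
#' one or more MCMC chains.
#'
#' @slot zHat integer vector of length n: spatial-domain point estimate
#'   (the stored draw closest to the spot PPM).
#' @slot rhoHat integer vector of length p: gene-group point estimate
#'   (0 = non-discriminating gene).
#' @slot ppmSpot n x n spot co-clustering probability matrix.
#' @slot ppmGene p x p gene co-clustering probability matrix.
#' @slot muHat R x K matrix of plug-in block means conditioned on the
#'   point partition.
#' @slot mu0Hat numeric: plug-in shared null mean; \code{mu0GeneHat} holds
#'   the per-gene variant for the estimated null genes.
#' @slot mu0GeneHat named numeric vector (per-gene plug-in null means).
#' @slot pi0Hat numeric: posterior mean of the null probability.
#' @slot logPost list of per-chain log-joint traces.
#' @slot traces list of [McmcTrace-class] objects.
#' @slot settings list echoing K, R, hyperparameters and MCMC settings.
#'
#' @aliases SpotBlockFit
#' @exportClass SpotBlockFit
setClass("SpotBlockFit",
  representation(
    zHat = "integer", rhoHat = "integer",
    ppmSpot = "matrix", ppmGene = "matrix",
    muHat = "matrix", mu0Hat = "numeric", mu0GeneHat = "numeric",
    pi0Hat = "numeric", logPost = "list", traces = "list",
    settings = "list"
  )
)

setValidity("SpotBlockFit", function(object) {
  msg <- character()
  n <- length(object@zHat)
  p <- length(object@rhoHat)
  if (!identical(dim(object@ppmSpot), c(n, n))) {
    msg <- c(msg, "ppmSpot dimensions must match the number of spots")
  }
  if (!identical(dim(object@ppmGene), c(p, p))) {
    msg <- c(msg, "ppmGene dimensions must match the number of genes")
  }
  for (nm in c("ppmSpot", "ppmGene")) {
    P <- slot(object, nm)
    if (length(P)) {
      if (min(P) < -1e-12 || max(P) > 1 + 1e-12) {
        msg <- c(msg, paste(nm, "entries must lie in [0, 1]"))
      }
      if (max(abs(P - t(P))) > 1e-12) msg <- c(msg, paste(nm, "must be symmetric"))
      if (max(abs(diag(P) - 1)) > 1e-12) {
        msg <- c(msg, paste(nm, "must have unit diagonal"))
      }
    }
  }
  if (length(object@pi0Hat) != 1 || object@pi0Hat < 0 || object@pi0Hat > 1) {
    msg <- c(msg, "pi0Hat must be a single probability")
  }
  if (length(msg)) msg else TRUE
})

#' SelectionTable: mICL grid-search result
#'
#' One row per (K, R) pair, sorted by ascending mICL; the first row is the
#' selected model.
#'
#' @slot table data.frame with columns \code{K}, \code{R}, \code{mICL},
#'   \code{pi0_hat}, \code{p0_hat}, \code{seconds}, and \code{status}.
#' @slot best named integer vector \code{c(K =, R =)}.
#'
#' @aliases SelectionTable
#' @exportClass SelectionTable
setClass("SelectionTable",
  representation(table = "data.frame", best = "integer")
)

setValidity("SelectionTable", function(object) {
  tb <- object@table
  msg <- character()
  if (!all(c("K", "R", "mICL") %in% names(tb))) {
    msg <- c(msg, "table must contain K, R and mICL columns")
  } else {
    ok <- is.finite(tb$mICL)
    if (any(ok) && is.unsorted(tb$mICL[ok])) {
      msg <- c(msg, "table must be sorted by ascending mICL")
    }
    if (any(ok) &&
      !identical(object@best, c(K = tb$K[ok][1L], R = tb$R[ok][1L]))) {
      msg <- c(msg, "best must be the (K, R) pair attaining the lowest mICL")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "McmcTrace", function(object) {
  m <- object@meta
  cat(
    "McmcTrace:", nrow(object@z), "stored draws (", m$iters, "iterations,",
    m$burnin, "burn-in, thin", m$thin, ")\n"
  )
  cat("  K =", m$K, " R =", m$R, " seed =", m$seed, "\n")
  if (length(object@logPost)) {
    cat("  final log joint:", format(utils::tail(object@logPost, 1)), "\n")
  }
  invisible(NULL)
})

setMethod("show", "SpotBlockFit", function(object) {
  n <- length(object@zHat)
  p <- length(object@rhoHat)
  s <- object@settings
  cat("SpotBlockFit:", n, "spots,", p, "genes; K =", s$K, " R =", s$R, "\n")
  cat(
    "  domains:", paste(tabulate(object@zHat, s$K), collapse = "/"),
    " gene groups (0 = non-DG):",
    paste(tabulate(object@rhoHat + 1L, s$R + 1L), collapse = "/"), "\n"
  )
  cat(
    "  pi0_hat =", round(object@pi0Hat, 3),
    " (", sum(object@rhoHat == 0L), "genes in the null set )\n"
  )
  cat("  chains pooled:", length(object@traces), "\n")
  invisible(NULL)
})

setMethod("show", "SelectionTable", function(object) {
  cat("SelectionTable:", nrow(object@table), "grid cells\n")
  cat("  best: K =", object@best["K"], " R =", object@best["R"], "\n")
  print(head(object@table, 5))
  invisible(NULL)
})
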