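#' Model hyperparameters
#'
#' Container for the fixed hyperparameters of the latent block model:
#' Gamma priors on the block means (\code{alpha_mu}, \code{beta_mu}) and on
#' the null mean (\code{alpha_0}, \code{beta_0}); Beta prior on the null
#' probability pi0 (\code{alpha_pi}, \code{beta_pi}); Polya urn total mass
#' \code{gamma}; MRF abundance offsets \code{b} (scalar, recycled to K) and
#' interaction strength \code{h}. The defaults are the weakly informative
#' choices used throughout: all Gamma/Beta hyperparameters 1, b = 1, h = 1.
#'
#' @param alpha_mu,beta_mu Gamma shape/rate for the block means.
#' @param alpha_0,beta_0 Gamma shape/rate for the null mean.
#' @param alpha_pi,beta_pi Beta parameters for the null probability.
#' @param gamma Polya urn total mass (> 0).
#' @param b MRF abundance offset(s); recycled to length K at fit time.
#' @param h MRF interaction strength (>= 0).
#' @return a validated list of class \code{"SpotBlockHyperparams"}.
#' @export
spotBlockHyperparams <- function(alpha_mu = 1, beta_mu = 1, alpha_0 = 1,
                                 beta_0 = 1, alpha_pi = 1, beta_pi = 1,
                                 gamma = 1, b = 1, h = 1) {
  hyp <- list(
    alpha_mu = alpha_mu, beta_mu = beta_mu, alpha_0 = alpha_0,
    beta_0 = beta_0, alpha_pi = alpha_pi, beta_pi = beta_pi,
    gamma = gamma, b = b, h = h
  )
  pos <- c("alpha_mu", "beta_mu", "alpha_0", "beta_0", "alpha_pi", "beta_pi", "gamma")
  for (nm in pos) {
    if (!is.numeric(hyp[[nm]]) || length(hyp[[nm]]) != 1L || hyp[[nm]] <= 0) {
      stop(nm, " must be a positive scalar")
    }
  }
  if (!is.numeric(b) || !all(is.finite(b))) stop("b must be numeric")
  if (!is.numeric(h) || length(h) != 1L || h < 0) stop("h must be >= 0")
  structure(hyp, class = "SpotBlockHyperparams")
}

.asHyp <- function(hyp, K) {
  if (is.null(hyp)) hyp <- spotBlockHyperparams()
  if (!inherits(hyp, "SpotBlockHyperparams")) {
    hyp <- do.call(spotBlockHyperparams, as.list(hyp))
  }
  hyp$b <- rep_len(hyp$b, K)
  hyp
}

#' Plug-in spot size factors
#'
#' \eqn{s_i} is the spot's total count divided by the grand total, so that
#' \eqn{\sum_i s_i = 1} (identifiability constraint).
#'
#' @param Y count matrix (genes x spots).
#' @return a named numeric vector of length n summing to 1.
#' @export
computeSizeFactors <- function(Y) {
  Y <- asCountMatrix(Y)
  tot <- colSums(Y)
  if (any(tot == 0)) stop("spot with zero total count; see dropEmpty()")
  tot / sum(tot)
}

#' Plug-in gene effects
#'
#' \eqn{g_j} is the gene's total count across spots.
#'
#' @param Y count matrix (genes x spots).
#' @return a named numeric vector of length p.
#' @export
computeGeneFactors <- function(Y) {
  Y <- asCountMatrix(Y)
  tot <- rowSums(Y)
  if (any(tot == 0)) stop("gene with zero total count; see dropEmpty()")
  g <- as.numeric(tot)
  names(g) <- rownames(Y)
  g
}

#' Collapsed log marginal of one block
#'
#' With \eqn{y_{c} \sim \mathrm{Poi}(e_c \mu)} per cell (exposure
#' \eqn{e_c = s_i g_j}) and \eqn{\mu \sim \mathrm{Ga}(\alpha, \beta)},
#' integrating out \eqn{\mu} gives the block marginal up to the
#' partition-invariant per-cell constant \eqn{\sum_c [y_c \log e_c -
#' \log y_c!]}:
#' \deqn{\alpha\log\beta - \log\Gamma(\alpha) + \log\Gamma(\alpha + N) -
#'   (\alpha + N)\log(\beta + S),}
#' where \eqn{N} is the block count total and \eqn{S} the block exposure
#' total. An empty block (\code{N = 0}, \code{S = 0}) contributes 0.
#' Vectorised over \code{N} and \code{S}.
#'
#' @param N block count total(s), non-negative.
#' @param S block exposure total(s), non-negative.
#' @param alpha,beta Gamma prior shape and rate.
#' @return log marginal value(s).
#' @export
logMarginalBlock <- function(N, S, alpha, beta) {
  if (any(N < 0)) stop("negative block count")
  if (any(S < 0)) stop("negative block exposure")
  out <- alpha * log(beta) - lgamma(alpha) + lgamma(alpha + N) -
    (alpha + N) * log(beta + S)
  out[N == 0 & S == 0] <- 0
  out
}

#' Sufficient statistics of a block partition
#'
#' All sums the collapsed sampler needs: \code{N} (R x K block count
#' totals), \code{G} (per-group gene-effect totals), \code{S} (per-domain
#' size-factor totals), the null-set totals \code{N0}, \code{G0}, the cross
#' tables \code{nspot} (R x n) and \code{ngene} (p x K), and the gene totals
#' \code{t}.
#'
#' @param Y count matrix.
#' @param z spot labels in 1..K.
#' @param rho gene labels in 0..R.
#' @param K,R label ranges.
#' @param s,g scaling factors; plug-ins computed from \code{Y} when NULL.
#' @return a list of sufficient statistics.
#' @export
blockSufficientStats <- function(Y, z, rho, K, R, s = NULL, g = NULL) {
  Y <- asCountMatrix(Y)
  p <- nrow(Y)
  n <- ncol(Y)
  stopifnot(length(z) == n, length(rho) == p)
  if (is.null(s)) s <- computeSizeFactors(Y)
  if (is.null(g)) g <- computeGeneFactors(Y)
  zf <- factor(z, levels = seq_len(K))
  rf <- factor(rho, levels = 0:R)
  ngene <- t(apply(Y, 1L, function(row) tapply(row, zf, sum, default = 0)))
  if (K == 1L) ngene <- matrix(ngene, nrow = p, ncol = 1L)
  byGroup <- rowsum(Y, rf)                      # (occupied groups) x n
  nspot <- matrix(0, R + 1L, n, dimnames = list(0:R, colnames(Y)))
  nspot[rownames(byGroup), ] <- byGroup
  N <- matrix(0, R, K)
  for (r in seq_len(R)) {
    N[r, ] <- tapply(nspot[r + 1L, ], zf, sum, default = 0)
  }
  null <- rho == 0
  list(
    N = N,
    G = as.numeric(tapply(g, rf, sum, default = 0))[-1L],
    S = as.numeric(tapply(s, zf, sum, default = 0)),
    N0 = sum(nspot[1L, ]),
    G0 = sum(g[null]),
    nspot = nspot[-1L, , drop = FALSE],
    ngene = ngene,
    t = rowSums(Y),
    sumS = sum(s),
    s = s, g = g, rho = rho
  )
}

#' Collapsed log joint of counts and a partition
#'
#' The log of \eqn{P(Y, z, \rho)} with the block means, the null mean and
#' the null probability all integrated out analytically, and the MRF prior
#' included unnormalised: the sum of the per-block collapsed marginals
#' ([logMarginalBlock()]), the null-set marginal, the zero-inflated Polya
#' urn prior on the gene labels (with pi0 integrated under its Beta prior,
#' or fixed at \code{pi0} when supplied), the MRF log prior on the spot
#' labels, and the partition-invariant per-cell constant
#' \eqn{\sum_{ji} [y_{ji} \log(s_i g_j) - \log y_{ji}!]}. Used for trace
#' diagnostics and as the enumeration oracle in small instances; the MRF
#' normalising constant is common to all partitions and cancels in ratios.
#'
#' @param Y count matrix.
#' @param z spot labels in 1..K.
#' @param rho gene labels in 0..R.
#' @param E spot adjacency matrix.
#' @param K,R label ranges.
#' @param hyp hyperparameters ([spotBlockHyperparams()]).
#' @param s,g scaling factors; plug-ins when NULL.
#' @param pi0 if supplied, the gene-label prior is evaluated at this fixed
#'   null probability instead of integrating it out.
#' @return the log joint (a single number).
#' @export
logFullMarginal <- function(Y, z, rho, E, K, R, hyp = NULL, s = NULL,
                            g = NULL, pi0 = NULL) {
  Y <- asCountMatrix(Y)
  hyp <- .asHyp(hyp, K)
  if (is.null(s)) s <- computeSizeFactors(Y)
  if (is.null(g)) g <- computeGeneFactors(Y)
  st <- blockSufficientStats(Y, z, rho, K, R, s, g)
  lp <- sum(logMarginalBlock(
    st$N, outer(st$G, st$S), hyp$alpha_mu, hyp$beta_mu
  )) +
    logMarginalBlock(st$N0, st$G0 * st$sumS, hyp$alpha_0, hyp$beta_0)
  p <- nrow(Y)
  p0 <- sum(rho == 0)
  if (is.null(pi0)) {
    lp <- lp + lbeta(hyp$alpha_pi + p0, hyp$beta_pi + p - p0) -
      lbeta(hyp$alpha_pi, hyp$beta_pi)
    pr <- tabulate(rho[rho > 0], R)
    occ <- pr > 0
    lp <- lp + sum(occ) * log(hyp$gamma) + sum(lgamma(pr[occ]))
    if (p - p0 > 0) lp <- lp - sum(log(hyp$gamma + seq_len(p - p0) - 1))
  } else {
    lp <- lp + polyaUrnLogPrior(rho, R, gamma = hyp$gamma, pi0 = pi0)
  }
  lp <- lp + mrfLogJoint(z, E, K, b = hyp$b, h = hyp$h)
  # partition-invariant per-cell constant
  lsg <- outer(log(g), log(s), "+")
  lp + sum(Y * lsg) - sum(lgamma(Y + 1))
}

#' Conjugate plug-in block means
#'
#' Posterior means of the block means given a partition:
#' \eqn{\hat\mu_{rk} = (\alpha_\mu + N_{rk}) / (\beta_\mu + G_r S_k)},
#' the shared null mean \eqn{\hat\mu_0 = (\alpha_0 + N_0)/(\beta_0 + G_0)},
#' and the per-gene null variant
#' \eqn{\hat\mu_{0j} = (\alpha_0 + t_j)/(\beta_0 + g_j)}.
#'
#' @param stats sufficient statistics from [blockSufficientStats()].
#' @param hyp hyperparameters.
#' @return list with \code{mu} (R x K), \code{mu0} (scalar), and
#'   \code{mu0_gene} (length-p vector; only entries for null genes are
#'   meaningful).
#' @export
posteriorMeanMu <- function(stats, hyp = NULL) {
  hyp <- .asHyp(hyp, length(stats$S))
  mu <- (hyp$alpha_mu + stats$N) /
    (hyp$beta_mu + outer(stats$G, stats$S))
  mu0 <- (hyp$alpha_0 + stats$N0) /
    (hyp$beta_0 + stats$G0 * stats$sumS)
  out <- list(mu = mu, mu0 = mu0)
  if (!is.null(stats$g)) {
    out$mu0_gene <- (hyp$alpha_0 + stats$t) / (hyp$beta_0 + stats$g * stats$sumS)
  }
  out
}
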