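#' MRF full-conditional log weights for one spot
#'
#' Component \eqn{k} equals \eqn{b_k + h \sum_{i'} e_{ii'} I(z_{i'} = k)};
#' exponentiating and normalising gives the prior full conditional
#' \eqn{P(z_i = k \mid z_{-i})}. With \code{h = 0} or an isolated spot this
#' reduces to a multinomial prior with weights
#' \eqn{\exp(b_k)/\sum_k \exp(b_k)}.
#'
#' @param z spot labels in 1..K.
#' @param i spot index.
#' @param E adjacency matrix.
#' @param K number of domains.
#' @param b abundance offsets (recycled to K).
#' @param h interaction strength.
#' @return a length-K vector of unnormalised log weights.
#' @export
mrfLogConditional <- function(z, i, E, K, b = 1, h = 1) {
  stopifnot(i >= 1, i <= length(z), all(z >= 1), all(z <= K))
  b <- rep_len(b, K)
  nbr <- which(E[i, ] != 0)
  nbr <- nbr[nbr != i]
  cnt <- tabulate(z[nbr], K)
  b + h * cnt
}

#' MRF joint log prior on spot labels (unnormalised)
#'
#' \eqn{\sum_k b_k |C_k| + h \sum_{i < i'} e_{ii'} I(z_i = z_{i'})}. The
#' normalising constant is intractable and never needed: all uses are
#' ratios across label configurations.
#'
#' @inheritParams mrfLogConditional
#' @return the unnormalised log prior.
#' @export
mrfLogJoint <- function(z, E, K, b = 1, h = 1) {
  stopifnot(all(z >= 1), all(z <= K))
  b <- rep_len(b, K)
  idx <- Matrix::which(E != 0, arr.ind = TRUE)
  idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  same <- if (nrow(idx)) sum(z[idx[, 1]] == z[idx[, 2]]) else 0
  sum(b * tabulate(z, K)) + h * same
}

#' Zero-inflated Polya urn log prior on gene labels
#'
#' For labels \eqn{\rho \in \{0, 1..R\}^p} with \eqn{p_0} null genes and
#' occupied group sizes \eqn{p_r}:
#' \deqn{p_0 \log \pi_0 + (p - p_0)\log(1 - \pi_0) +
#'   R_{occ} \log\gamma + \sum_{r\,occ} \log\Gamma(p_r) -
#'   \sum_{j=1}^{p-p_0} \log(\gamma + j - 1).}
#' Empty groups contribute nothing; the prior depends on the group sizes
#' only, so it is invariant to permuting the non-null labels.
#'
#' @param rho gene labels in 0..R.
#' @param R maximum number of gene groups.
#' @param gamma urn total mass.
#' @param pi0 null probability in (0, 1).
#' @return the log prior.
#' @export
polyaUrnLogPrior <- function(rho, R, gamma = 1, pi0) {
  stopifnot(all(rho >= 0), all(rho <= R), pi0 > 0, pi0 < 1)
  p <- length(rho)
  p0 <- sum(rho == 0)
  pr <- tabulate(rho[rho > 0], R)
  occ <- pr > 0
  lp <- p0 * log(pi0) + (p - p0) * log1p(-pi0) +
    sum(occ) * log(gamma) + sum(lgamma(pr[occ]))
  if (p - p0 > 0) lp <- lp - sum(log(gamma + seq_len(p - p0) - 1))
  lp
}

#' Gene-label prior full conditional
#'
#' Log prior weights for \eqn{\rho_j \in \{0, 1..R\}} given the other gene
#' labels. In \code{"explicit"} mode the null weight is \eqn{\log \pi_0}
#' and group \eqn{r} gets
#' \eqn{\log(1-\pi_0) + \log(p_r^{-j} \,\mathrm{or}\, \gamma) -
#' \log(\gamma + p - 1 - p_0^{-j})} (each empty group re-enters with urn
#' weight \eqn{\gamma}). In \code{"collapsed"} mode pi0 is integrated under
#' its Beta prior, so the null weight becomes the Beta-Binomial predictive
#' \eqn{\log(\alpha_\pi + p_0^{-j}) - \log(\alpha_\pi + \beta_\pi + p - 1)}
#' and the non-null mass \eqn{\log(\beta_\pi + p - 1 - p_0^{-j}) -
#' \log(\alpha_\pi + \beta_\pi + p - 1)}. Both modes exponentiate to the
#' normalised ratios of the joint prior over the R + 1 completions of
#' \eqn{\rho_j}.
#'
#' @param rho gene labels in 0..R (entry \code{j} is ignored).
#' @param j gene index.
#' @param R maximum number of gene groups.
#' @param gamma urn total mass.
#' @param mode \code{"explicit"} (pi0 given) or \code{"collapsed"}.
#' @param pi0 null probability, required in explicit mode.
#' @param alpha_pi,beta_pi Beta prior parameters, used in collapsed mode.
#' @return a length-(R+1) vector of log weights, named "0".."R".
#' @export
geneLabelPriorConditional <- function(rho, j, R, gamma = 1,
                                      mode = c("explicit", "collapsed"),
                                      pi0 = NULL, alpha_pi = 1, beta_pi = 1) {
  mode <- match.arg(mode)
  p <- length(rho)
  stopifnot(j >= 1, j <= p)
  rm <- rho[-j]
  p0m <- sum(rm == 0)
  pr <- tabulate(rm[rm > 0], R)
  d <- p - 1 - p0m # number of DGs among the other genes
  urn <- log(ifelse(pr > 0, pr, gamma)) - log(gamma + d)
  if (mode == "explicit") {
    stopifnot(!is.null(pi0), pi0 > 0, pi0 < 1)
    lw <- c(log(pi0), log1p(-pi0) + urn)
  } else {
    den <- log(alpha_pi + beta_pi + p - 1)
    lw <- c(
      log(alpha_pi + p0m) - den,
      log(beta_pi + d) - den + urn
    )
  }
  names(lw) <- 0:R
  lw
}
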