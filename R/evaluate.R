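#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions (Hubert-Arabie
#' permutation-model correction), computed from the contingency table.
#' Equals 1 for identical partitions up to relabelling; has expectation 0
#' under random agreement.
#'
#' @param a,b label vectors of equal length (any label coding).
#' @return the ARI (a single number).
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  n <- length(a)
  if (n == 0L) stop("empty partitions")
  tab <- table(a, b)
  sumIJ <- sum(choose(tab, 2))
  sumI <- sum(choose(rowSums(tab), 2))
  sumJ <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  expected <- sumI * sumJ / tot
  maxIndex <- (sumI + sumJ) / 2
  if (maxIndex == expected) {
    return(1)
  } # both partitions trivial
  (sumIJ - expected) / (maxIndex - expected)
}

#' DG-versus-non-DG confusion summary
#'
#' Binarises both gene-label vectors as discriminating (label != 0) versus
#' non-discriminating (label == 0) and tallies the confusion counts, with
#' DG as the positive class.
#'
#' @param rhoTrue,rhoHat gene labels in 0..R.
#' @return list with counts \code{tp}, \code{fp}, \code{tn}, \code{fn} and
#'   rates \code{sensitivity}, \code{specificity} (NA when undefined).
#' @export
dgConfusion <- function(rhoTrue, rhoHat) {
  if (length(rhoTrue) != length(rhoHat)) {
    stop("label vectors must have equal length")
  }
  if (anyNA(rhoTrue) || anyNA(rhoHat)) stop("missing labels are an error")
  td <- rhoTrue != 0
  hd <- rhoHat != 0
  tp <- sum(td & hd)
  fp <- sum(!td & hd)
  tn <- sum(!td & !hd)
  fn <- sum(td & !hd)
  list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}
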