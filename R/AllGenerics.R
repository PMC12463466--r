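#' Accessors for fitted latent block models
#'
#' @param object a [SpotBlockFit-class] (or, for \code{logPostTrace} and
#'   \code{traceDraws}, an [McmcTrace-class]) object.
#' @param what for \code{traceDraws}, which label draws to return.
#'
#' @return \code{spotDomains} and \code{geneGroups} return the point
#'   partitions (named integer vectors; gene label 0 marks a
#'   non-discriminating gene). \code{spotPPM} / \code{genePPM} return the
#'   co-clustering probability matrices. \code{blockMeans} returns the
#'   R x K plug-in block-mean matrix, \code{nullMean} the plug-in null
#'   mean(s), and \code{nullProportion} the posterior mean of the null
#'   probability. \code{logPostTrace} returns the per-iteration log-joint
#'   trace(s); \code{traceDraws} the stored label draws of one chain.
#'
#' @name accessors
#' @aliases spotDomains geneGroups spotPPM genePPM blockMeans nullMean
#'   nullProportion logPostTrace traceDraws
NULL

#' @rdname accessors
#' @export
setGeneric("spotDomains", function(object) standardGeneric("spotDomains"))

#' @rdname accessors
#' @export
setGeneric("geneGroups", function(object) standardGeneric("geneGroups"))

#' @rdname accessors
#' @export
setGeneric("spotPPM", function(object) standardGeneric("spotPPM"))

#' @rdname accessors
#' @export
setGeneric("genePPM", function(object) standardGeneric("genePPM"))

#' @rdname accessors
#' @export
setGeneric("blockMeans", function(object) standardGeneric("blockMeans"))

#' @rdname accessors
#' @export
setGeneric("nullMean", function(object) standardGeneric("nullMean"))

#' @rdname accessors
#' @export
setGeneric("nullProportion", function(object) standardGeneric("nullProportion"))

#' @rdname accessors
#' @export
setGeneric("logPostTrace", function(object) standardGeneric("logPostTrace"))

#' @rdname accessors
#' @export
setGeneric("traceDraws", function(object, what = c("z", "rho", "pi0")) {
  standardGeneric("traceDraws")
})

#' @rdname accessors
setMethod("spotDomains", "SpotBlockFit", function(object) object@zHat)

#' @rdname accessors
setMethod("geneGroups", "SpotBlockFit", function(object) object@rhoHat)

#' @rdname accessors
setMethod("spotPPM", "SpotBlockFit", function(object) object@ppmSpot)

#' @rdname accessors
setMethod("genePPM", "SpotBlockFit", function(object) object@ppmGene)

#' @rdname accessors
setMethod("blockMeans", "SpotBlockFit", function(object) object@muHat)

#' @rdname accessors
setMethod("nullMean", "SpotBlockFit", function(object) object@mu0Hat)

#' @rdname accessors
setMethod("nullProportion", "SpotBlockFit", function(object) object@pi0Hat)

#' @rdname accessors
setMethod("logPostTrace", "SpotBlockFit", function(object) object@logPost)

#' @rdname accessors
setMethod("logPostTrace", "McmcTrace", function(object) object@logPost)

#' @rdname accessors
setMethod("traceDraws", "McmcTrace", function(object,
                                              what = c("z", "rho", "pi0")) {
  what <- match.arg(what)
  slot(object, what)
})

#' @rdname accessors
#' @export
setGeneric("selectionTable", function(object) standardGeneric("selectionTable"))

#' @rdname accessors
#' @export
setGeneric("bestModel", function(object) standardGeneric("bestModel"))

#' @rdname accessors
setMethod("selectionTable", "SelectionTable", function(object) object@table)

#' @rdname accessors
setMethod("bestModel", "SelectionTable", function(object) object@best)
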