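#' @import methods
#' @importFrom stats pnorm qnorm dnorm quantile median rnorm runif sd var
#'   density predict quantile uniroot setNames
#' @importFrom utils read.table write.table head tail
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the S4 classes in this package. Slot
#' access should always go through these rather than `@`.
#'
#' @param object An object of one of the package's S4 classes.
#' @return The corresponding slot value; see the class documentation.
#' @name dafs-accessors
#' @rdname dafs-accessors
#' @export
setGeneric("exprValues", function(object) standardGeneric("exprValues"))

#' @rdname dafs-accessors
#' @export
setGeneric("exprScale", function(object) standardGeneric("exprScale"))

#' @rdname dafs-accessors
#' @export
setGeneric("sampleName", function(object) standardGeneric("sampleName"))

#' @rdname dafs-accessors
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' @rdname dafs-accessors
#' @export
setGeneric("pGrid", function(object) standardGeneric("pGrid"))

#' @rdname dafs-accessors
#' @export
setGeneric("dValues", function(object) standardGeneric("dValues"))

#' @rdname dafs-accessors
#' @export
setGeneric("p0", function(object) standardGeneric("p0"))

#' @rdname dafs-accessors
#' @export
setGeneric("gridStep", function(object) standardGeneric("gridStep"))

#' @rdname dafs-accessors
#' @export
setGeneric("marsKnots", function(object) standardGeneric("marsKnots"))

#' @rdname dafs-accessors
#' @export
setGeneric("gcv", function(object) standardGeneric("gcv"))

#' Slope-change classification of MARS knots
#'
#' Classifies every knot of a fitted piecewise-linear model by the sign
#' pattern of the fitted slope on its left and right segments.
#'
#' @param model A [MarsModel-class] object.
#' @return A data frame with columns `knot` (numeric) and `change`
#'   (`"min"`, `"max"` or `"bend"`), one row per knot, ordered by knot.
#' @export
setGeneric("slopeChangePoints", function(model) standardGeneric("slopeChangePoints"))

#' Density-intersection cutoff of a two-component Gaussian mixture
#'
#' Returns the point where the two weighted component densities
#' \eqn{\pi_1\phi_1(x)} and \eqn{\pi_2\phi_2(x)} intersect, used as the
#' theoretical LE/HE boundary of the mixture comparator.
#'
#' @param model A [MixtureModel-class] with two components.
#' @param ... Not used.
#' @return A single numeric value lying between the component means
#'   whenever such a crossing exists.
#' @export
setGeneric("intersectionCutoff", function(model, ...) standardGeneric("intersectionCutoff"))

#' @rdname dafs-accessors
#' @export
setGeneric("componentWeights", function(object) standardGeneric("componentWeights"))

#' @rdname dafs-accessors
#' @export
setGeneric("componentMeans", function(object) standardGeneric("componentMeans"))

#' @rdname dafs-accessors
#' @export
setGeneric("componentVariances", function(object) standardGeneric("componentVariances"))

#' @rdname dafs-accessors
#' @export
setGeneric("varianceStructure", function(object) standardGeneric("varianceStructure"))

#' @rdname dafs-accessors
#' @export
setGeneric("bic", function(object) standardGeneric("bic"))

#' @rdname dafs-accessors
#' @export
setGeneric("quantileCutoff", function(object) standardGeneric("quantileCutoff"))

#' @rdname dafs-accessors
#' @export
setGeneric("cutoffLog2", function(object) standardGeneric("cutoffLog2"))

#' @rdname dafs-accessors
#' @export
setGeneric("cutoffRaw", function(object) standardGeneric("cutoffRaw"))

#' @rdname dafs-accessors
#' @export
setGeneric("fallbackUsed", function(object) standardGeneric("fallbackUsed"))

#' @rdname dafs-accessors
#' @export
setGeneric("ksProfile", function(object) standardGeneric("ksProfile"))

#' @rdname dafs-accessors
#' @export
setGeneric("marsModel", function(object) standardGeneric("marsModel"))
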