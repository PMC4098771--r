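## Central S4 classes. Constructors are the exported camelCase functions;
## validity enforces the structural invariants each downstream step relies on.

.SCALES <- c("raw_count", "rpkm", "fpkm", "log2")

#' ExpressionSample: one sample's expression vector
#'
#' Holds a single sample's expression values together with the scale they are
#' measured on. All analysis entry points ([prepareSample()],
#' [computeProfile()], [estimateCutoff()]) take an `ExpressionSample`.
#'
#' On the `raw_count`, `rpkm` and `fpkm` scales a value of 0 means "no
#' signal" and is removed by [prepareSample()] before the log2 transform;
#' on the `log2` scale a 0 is ordinary data.
#'
#' @slot values Numeric vector of expression values (finite; non-negative
#'   unless `scale == "log2"`; integer-valued for `raw_count`).
#' @slot scale One of `"raw_count"`, `"rpkm"`, `"fpkm"`, `"log2"`.
#' @slot name Sample label used in printing and reports.
#' @slot ids Optional gene identifiers (length 0, or one per value).
#'
#' @examples
#' s <- ExpressionSample(c(0, 0, 1, 2, 8), scale = "raw_count")
#' exprValues(prepareSample(s))   # log2 of the nonzero counts: 0 1 3
#' @aliases ExpressionSample
#' @export
setClass("ExpressionSample",
  representation(values = "numeric", scale = "character",
                 name = "character", ids = "character"),
  prototype(values = numeric(), scale = "log2", name = "sample",
            ids = character()))

setValidity("ExpressionSample", function(object) {
  v <- object@values
  if (length(object@scale) != 1L || !object@scale %in% .SCALES)
    return(sprintf("scale must be one of: %s", paste(.SCALES, collapse = ", ")))
  if (anyNA(v) || any(!is.finite(v)))
    return("values must be finite and non-missing")
  if (object@scale != "log2" && any(v < 0))
    return("negative values are not allowed on a non-log2 scale")
  if (object@scale == "raw_count" && any(v != round(v)))
    return("raw_count values must be non-negative integers")
  if (length(object@ids) && length(object@ids) != length(v))
    return("ids must be empty or match length(values)")
  TRUE
})

#' @param values,scale,name,ids See slots.
#' @rdname ExpressionSample-class
#' @export
ExpressionSample <- function(values, scale = c("raw_count", "rpkm", "fpkm", "log2"),
                             name = "sample", ids = character()) {
  scale <- match.arg(scale)
  new("ExpressionSample", values = as.numeric(values), scale = scale,
      name = name, ids = as.character(ids))
}

#' @rdname dafs-accessors
setMethod("exprValues", "ExpressionSample", function(object) object@values)
#' @rdname dafs-accessors
setMethod("exprScale", "ExpressionSample", function(object) object@scale)
#' @rdname dafs-accessors
setMethod("sampleName", "ExpressionSample", function(object) object@name)
#' @rdname dafs-accessors
setMethod("geneIds", "ExpressionSample", function(object) object@ids)

#' @export
setMethod("show", "ExpressionSample", function(object) {
  cat(sprintf("ExpressionSample '%s': %d values on %s scale\n",
              object@name, length(object@values), object@scale))
  if (length(object@values))
    cat(sprintf("  range [%.4g, %.4g], zeros: %d\n",
                min(object@values), max(object@values),
                sum(object@values == 0)))
})

#' ExpressionTable: genes-by-samples expression matrix
#'
#' Light container for a genes-by-samples table read from TSV/CSV, with a
#' single measurement scale shared by all samples. Columns are extracted as
#' [ExpressionSample-class] objects with [getSample()].
#'
#' @slot geneIds Unique gene identifiers (rows).
#' @slot sampleNames Sample names (columns).
#' @slot exprs Numeric matrix, genes x samples.
#' @slot scale Measurement scale, as in [ExpressionSample-class].
#' @aliases ExpressionTable
#' @export
setClass("ExpressionTable",
  representation(geneIds = "character", sampleNames = "character",
                 exprs = "matrix", scale = "character"))

setValidity("ExpressionTable", function(object) {
  m <- object@exprs
  if (!is.numeric(m)) return("exprs must be a numeric matrix")
  if (nrow(m) != length(object@geneIds)) return("nrow(exprs) != length(geneIds)")
  if (ncol(m) != length(object@sampleNames)) return("ncol(exprs) != length(sampleNames)")
  if (anyDuplicated(object@geneIds)) return("duplicate gene IDs")
  if (length(object@scale) != 1L || !object@scale %in% .SCALES)
    return("invalid scale")
  if (anyNA(m)) return("missing values in expression matrix")
  if (object@scale != "log2" && any(m < 0))
    return("negative entries on a non-log2 scale")
  TRUE
})

#' @param geneIds,sampleNames,exprs,scale See slots.
#' @rdname ExpressionTable-class
#' @export
ExpressionTable <- function(exprs, geneIds = rownames(exprs),
                            sampleNames = colnames(exprs),
                            scale = c("raw_count", "rpkm", "fpkm", "log2")) {
  scale <- match.arg(scale)
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  new("ExpressionTable", geneIds = as.character(geneIds),
      sampleNames = as.character(sampleNames), exprs = exprs, scale = scale)
}

#' @rdname dafs-accessors
setMethod("geneIds", "ExpressionTable", function(object) object@geneIds)
#' @rdname dafs-accessors
setMethod("exprScale", "ExpressionTable", function(object) object@scale)
#' @rdname dafs-accessors
setMethod("sampleName", "ExpressionTable", function(object) object@sampleNames)
#' @rdname dafs-accessors
setMethod("exprValues", "ExpressionTable", function(object) object@exprs)

setMethod("show", "ExpressionTable", function(object) {
  cat(sprintf("ExpressionTable: %d genes x %d samples (%s scale)\n",
              nrow(object@exprs), ncol(object@exprs), object@scale))
  cat("  samples:", paste(utils::head(object@sampleNames, 5), collapse = ", "),
      if (ncol(object@exprs) > 5) "..." else "", "\n")
})

#' KSProfile: Kolmogorov-Smirnov distances over trimming percentiles
#'
#' The profile pairs each trimming percentile \eqn{p} on an arithmetic grid
#' from \eqn{p_0} to 0.50 with the scaled Kolmogorov-Smirnov distance
#' \eqn{D_p} between the strict upper tail above the \eqn{p}-th empirical
#' quantile and a normal reference fitted to that tail.
#'
#' @slot pGrid Strictly increasing percentile grid with constant spacing.
#' @slot dValues Non-negative K-S distances, one per grid point.
#' @slot p0 Fraction of (prepared) values tied at the minimum observed
#'   level; the grid start.
#' @slot step Grid spacing (0.01 or 0.005 by convention).
#' @slot nTotal Number of prepared (nonzero) observations profiled.
#' @aliases KSProfile
#' @export
setClass("KSProfile",
  representation(pGrid = "numeric", dValues = "numeric", p0 = "numeric",
                 step = "numeric", nTotal = "integer"))

setValidity("KSProfile", function(object) {
  p <- object@pGrid; d <- object@dValues
  if (length(p) != length(d)) return("pGrid and dValues lengths differ")
  if (length(p) < 2L) return("profile needs at least 2 grid points")
  if (any(!is.finite(d)) || any(d < 0)) return("dValues must be finite and >= 0")
  dp <- diff(p)
  if (any(dp <= 0)) return("pGrid must be strictly increasing")
  if (max(abs(dp - object@step)) > 1e-8) return("pGrid spacing must equal step")
  if (object@p0 < 0 || object@p0 >= 0.5) return("p0 must lie in [0, 0.5)")
  TRUE
})

#' @rdname dafs-accessors
setMethod("pGrid", "KSProfile", function(object) object@pGrid)
#' @rdname dafs-accessors
setMethod("dValues", "KSProfile", function(object) object@dValues)
#' @rdname dafs-accessors
setMethod("p0", "KSProfile", function(object) object@p0)
#' @rdname dafs-accessors
setMethod("gridStep", "KSProfile", function(object) object@step)

setMethod("show", "KSProfile", function(object) {
  cat(sprintf("KSProfile: %d grid points, p in [%.4g, %.4g] (step %.3g), n = %d\n",
              length(object@pGrid), min(object@pGrid), max(object@pGrid),
              object@step, object@nTotal))
  cat(sprintf("  D range [%.4g, %.4g]; grid argmin at p = %.4g\n",
              min(object@dValues), max(object@dValues),
              object@pGrid[which.min(object@dValues)]))
})

#' MarsModel: one-dimensional adaptive regression spline fit
#'
#' A piecewise-linear model built from an intercept, an optional plain
#' linear term, and reflected hinge pairs \eqn{(x-t)_+} and \eqn{(t-x)_+}
#' at knots selected by forward stepwise search and pruned by generalized
#' cross-validation (GCV).
#'
#' @slot basis Data frame describing the retained terms: `type`
#'   (`"intercept"`, `"linear"`, `"hinge+"`, `"hinge-"`), `knot` (NA for
#'   intercept/linear) and `coef`.
#' @slot knots Sorted distinct knots of the retained hinge terms.
#' @slot gcv GCV score of the model on its training data.
#' @slot slopeTol Magnitude below which a fitted segment slope is treated
#'   as zero when classifying knots.
#' @slot xRange,yRange Training data ranges (used for printing/prediction
#'   context only; the model extrapolates linearly).
#' @aliases MarsModel
#' @export
setClass("MarsModel",
  representation(basis = "data.frame", knots = "numeric", gcv = "numeric",
                 slopeTol = "numeric", xRange = "numeric", yRange = "numeric"))

setValidity("MarsModel", function(object) {
  b <- object@basis
  need <- c("type", "knot", "coef")
  if (!all(need %in% names(b))) return("basis must have columns type, knot, coef")
  if (sum(b$type == "intercept") != 1L) return("exactly one intercept term required")
  hk <- b$knot[b$type %in% c("hinge+", "hinge-")]
  if (anyNA(hk)) return("hinge terms must carry a knot")
  if (!setequal(unique(hk), object@knots)) return("knots slot inconsistent with basis")
  if (is.unsorted(object@knots, strictly = TRUE) && length(object@knots) > 1L)
    return("knots must be sorted and distinct")
  TRUE
})

#' @rdname dafs-accessors
setMethod("marsKnots", "MarsModel", function(object) object@knots)
#' @rdname dafs-accessors
setMethod("gcv", "MarsModel", function(object) object@gcv)

#' MixtureModel: univariate Gaussian mixture fit
#'
#' Two-component (in this package) Gaussian mixture fitted by EM, with the
#' variance structure (shared or per-component variances) chosen by BIC.
#' Components are ordered by mean. BIC is reported on the higher-is-better
#' scale \eqn{2\,\log L - k\,\log n}.
#'
#' @slot weights Mixing proportions (sum to 1, all > 0).
#' @slot means Component means, non-decreasing.
#' @slot variances Component variances (> 0; identical when the structure
#'   is `"equal"`).
#' @slot varianceStructure `"equal"` or `"unequal"`.
#' @slot loglik Maximized log-likelihood.
#' @slot bic BIC of this fit.
#' @slot bicAlternative BIC of the rejected variance structure.
#' @slot n Sample size used in fitting.
#' @slot loglikTrace Per-iteration log-likelihoods of the winning EM run.
#' @aliases MixtureModel
#' @export
setClass("MixtureModel",
  representation(weights = "numeric", means = "numeric", variances = "numeric",
                 varianceStructure = "character", loglik = "numeric",
                 bic = "numeric", bicAlternative = "numeric", n = "integer",
                 loglikTrace = "numeric"))

setValidity("MixtureModel", function(object) {
  k <- length(object@means)
  if (length(object@weights) != k || length(object@variances) != k)
    return("weights, means, variances must have equal length")
  if (abs(sum(object@weights) - 1) > 1e-8 || any(object@weights <= 0))
    return("weights must be positive and sum to 1")
  if (any(object@variances <= 0)) return("variances must be positive")
  if (is.unsorted(object@means)) return("components must be ordered by mean")
  if (!object@varianceStructure %in% c("equal", "unequal"))
    return("varianceStructure must be 'equal' or 'unequal'")
  if (object@varianceStructure == "equal" &&
      diff(range(object@variances)) > 1e-8 * max(object@variances))
    return("equal variance structure requires identical variances")
  TRUE
})

#' @rdname dafs-accessors
setMethod("componentWeights", "MixtureModel", function(object) object@weights)
#' @rdname dafs-accessors
setMethod("componentMeans", "MixtureModel", function(object) object@means)
#' @rdname dafs-accessors
setMethod("componentVariances", "MixtureModel", function(object) object@variances)
#' @rdname dafs-accessors
setMethod("varianceStructure", "MixtureModel", function(object) object@varianceStructure)
#' @rdname dafs-accessors
setMethod("bic", "MixtureModel", function(object) object@bic)

setMethod("show", "MixtureModel", function(object) {
  cat(sprintf("MixtureModel: %d components, %s variance (n = %d)\n",
              length(object@means), object@varianceStructure, object@n))
  print(data.frame(weight = round(object@weights, 4),
                   mean = round(object@means, 4),
                   variance = round(object@variances, 4)))
  cat(sprintf("  loglik %.4f, BIC %.4f (alternative structure: %.4f)\n",
              object@loglik, object@bic, object@bicAlternative))
})

#' DafsResult: the estimated LE/HE cutoff for one sample
#'
#' Bundle returned by [estimateCutoff()]: the optimal quantile cutoff
#' \eqn{q_c}, the corresponding expression cutoffs, and the intermediate
#' K-S profile and MARS fit.
#'
#' @slot qc Optimal quantile cutoff in \eqn{[p_0, 0.50]}.
#' @slot cutoffLog2 Empirical \eqn{q_c}-quantile of the prepared (log2)
#'   values; the LE/HE boundary on the log2 scale.
#' @slot cutoffRaw `round(2^cutoffLog2)` for raw-count input, `NA`
#'   otherwise.
#' @slot profile The [KSProfile-class] the cutoff was derived from.
#' @slot model The [MarsModel-class] fitted to the profile.
#' @slot fallbackUsed `TRUE` when the MARS fit exposed no
#'   decreasing-to-increasing knot and the interior grid argmin of the
#'   fitted curve was used instead.
#' @slot sampleName Label of the analyzed sample.
#' @aliases DafsResult
#' @export
setClass("DafsResult",
  representation(qc = "numeric", cutoffLog2 = "numeric", cutoffRaw = "numeric",
                 profile = "KSProfile", model = "MarsModel",
                 fallbackUsed = "logical", sampleName = "character"))

setValidity("DafsResult", function(object) {
  if (object@qc < object@profile@p0 - 1e-12 || object@qc > 0.5 + 1e-12)
    return("qc must lie in [p0, 0.50]")
  if (!object@fallbackUsed && length(object@model@knots) &&
      min(abs(object@model@knots - object@qc)) > 1e-10)
    return("qc must be a model knot unless the fallback was used")
  TRUE
})

#' @rdname dafs-accessors
setMethod("quantileCutoff", "DafsResult", function(object) object@qc)
#' @rdname dafs-accessors
setMethod("cutoffLog2", "DafsResult", function(object) object@cutoffLog2)
#' @rdname dafs-accessors
setMethod("cutoffRaw", "DafsResult", function(object) object@cutoffRaw)
#' @rdname dafs-accessors
setMethod("fallbackUsed", "DafsResult", function(object) object@fallbackUsed)
#' @rdname dafs-accessors
setMethod("ksProfile", "DafsResult", function(object) object@profile)
#' @rdname dafs-accessors
setMethod("marsModel", "DafsResult", function(object) object@model)

setMethod("show", "DafsResult", function(object) {
  cat(sprintf("DafsResult for '%s'\n", object@sampleName))
  cat(sprintf("  q_c = %.4f  (p0 = %.4f%s)\n", object@qc, object@profile@p0,
              if (object@fallbackUsed) ", fallback: fitted-curve argmin" else ""))
  cat(sprintf("  cutoff (log2 scale) = %.4f\n", object@cutoffLog2))
  if (!is.na(object@cutoffRaw))
    cat(sprintf("  cutoff (raw counts) = %d\n", as.integer(object@cutoffRaw)))
})

#' SimulationScenario: a labeled Gaussian-mixture generator
#'
#' Describes a five-component univariate Gaussian mixture whose components
#' are labeled low-expressed (LE) or high-expressed (HE); draws from it
#' emulate one sample's log2-scale expression vector with known truth.
#' The two built-in scenarios are available through [simScenario()].
#'
#' @slot name Scenario label.
#' @slot weights,means,variances Component parameters (weights sum to 1).
#' @slot leComponents Indices of the components labeled LE (non-empty,
#'   proper subset).
#' @slot nGenes Values drawn per replicate (default 5000).
#' @slot nReps Default replicate count for [runStudy()] (default 500).
#' @aliases SimulationScenario
#' @export
setClass("SimulationScenario",
  representation(name = "character", weights = "numeric", means = "numeric",
                 variances = "numeric", leComponents = "integer",
                 nGenes = "integer", nReps = "integer"))

setValidity("SimulationScenario", function(object) {
  k <- length(object@weights)
  if (length(object@means) != k || length(object@variances) != k)
    return("weights, means, variances must have equal length")
  if (abs(sum(object@weights) - 1) > 1e-8) return("weights must sum to 1")
  if (any(object@variances <= 0)) return("variances must be positive")
  le <- object@leComponents
  if (!length(le) || length(le) >= k || any(!le %in% seq_len(k)))
    return("leComponents must be a non-empty proper subset of component indices")
  if (object@nGenes < 1L || object@nReps < 1L) return("nGenes and nReps must be >= 1")
  TRUE
})

setMethod("show", "SimulationScenario", function(object) {
  cat(sprintf("SimulationScenario '%s': %d components, LE = {%s}\n",
              object@name, length(object@weights),
              paste(object@leComponents, collapse = ",")))
  print(data.frame(weight = object@weights, mean = object@means,
                   variance = object@variances))
  cat(sprintf("  %d genes per replicate, %d replicates by default\n",
              object@nGenes, object@nReps))
})
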