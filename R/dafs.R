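#' Prepare an expression sample for profiling
#'
#' On the count/RPKM/FPKM scales, values equal to 0 encode absence of
#' signal: they are removed first, and the remaining values are mapped to
#' the log2 scale. Input already on the log2 scale passes through
#' unchanged -- a 0 there is ordinary data, not absence.
#'
#' @param sample An [ExpressionSample-class] on any scale.
#' @return An [ExpressionSample-class] on the `log2` scale with the
#'   original-scale zeros removed; gene ids (when present) are subset
#'   accordingly.
#' @examples
#' exprValues(prepareSample(ExpressionSample(c(0, 0, 1, 2, 8), "raw_count")))
#' @export
prepareSample <- function(sample) {
  stopifnot(is(sample, "ExpressionSample"))
  if (exprScale(sample) == "log2") return(sample)
  v <- exprValues(sample)
  if (any(v < 0)) stop("negative values on a non-log2 scale")
  keep <- v > 0
  if (!any(keep)) stop("no expressed genes")
  ids <- geneIds(sample)
  new("ExpressionSample", values = log2(v[keep]), scale = "log2",
      name = sampleName(sample),
      ids = if (length(ids)) ids[keep] else character())
}

#' Estimate the LE/HE expression cutoff for one sample
#'
#' Runs the full data-adaptive pipeline on a single sample: prepare
#' (remove original-scale zeros, log2-transform), compute the K-S profile
#' over trimming percentiles ([computeProfile()]), fit a piecewise-linear
#' model to the profile ([fitMars()]), and take as the optimal quantile
#' cutoff \eqn{q_c} the left-most knot at which the fitted slope changes
#' from decreasing to increasing (the left-most local minimum of the
#' fitted profile). When the fit exposes no such knot, the interior grid
#' point minimizing the fitted curve is used and the result is flagged
#' `fallbackUsed`.
#'
#' The expression cutoff is the empirical \eqn{q_c}-quantile of the
#' prepared values; genes at or below it (and genes with zero expression)
#' are considered low-expressed. For raw-count input the cutoff is also
#' reported back on the count scale as `round(2^cutoffLog2)`.
#'
#' @param sample An [ExpressionSample-class]; at least 100 expressed
#'   values are required and fewer than 1,000 triggers a warning (the
#'   method is designed for genome-scale samples).
#' @param step Grid spacing passed to [computeProfile()]; `NULL` selects
#'   0.01 (or 0.005 for samples of 50,000+ values).
#' @param maxTerms,penalty,minSpan Passed to [fitMars()].
#' @return A [DafsResult-class].
#' @examples
#' set.seed(7)
#' v <- c(rnorm(1500, 2, 1), rnorm(3500, 9, 1.2))   # bimodal log2-like data
#' res <- estimateCutoff(ExpressionSample(v, scale = "log2"))
#' quantileCutoff(res); cutoffLog2(res)
#' @export
estimateCutoff <- function(sample, step = NULL, maxTerms = 21L, penalty = 3,
                           minSpan = 2L) {
  stopifnot(is(sample, "ExpressionSample"))
  inputScale <- exprScale(sample)
  prepared <- prepareSample(sample)
  v <- exprValues(prepared)
  if (length(v) < 100L) stop("too few expressed genes (< 100)")
  if (length(v) < 1000L)
    warning("fewer than 1,000 expressed genes; cutoff estimate may be unstable")

  prof <- computeProfile(prepared, step = step)
  fit <- fitMars(pGrid(prof), dValues(prof), maxTerms = maxTerms,
                 penalty = penalty, minSpan = minSpan)
  scp <- slopeChangePoints(fit)
  minKnots <- scp$knot[scp$change == "min"]
  if (length(minKnots)) {
    qc <- min(minKnots)
    fallback <- FALSE
  } else {
    g <- pGrid(prof)
    interior <- g[-c(1L, length(g))]
    qc <- interior[which.min(predict(fit, interior))]
    fallback <- TRUE
  }
  cutLog2 <- stats::quantile(v, qc, names = FALSE, type = 7)
  cutRaw <- if (inputScale == "raw_count") round(2^cutLog2) else NA_real_
  new("DafsResult", qc = qc, cutoffLog2 = cutLog2, cutoffRaw = cutRaw,
      profile = prof, model = fit, fallbackUsed = fallback,
      sampleName = sampleName(sample))
}

#' Flag genes as low- or high-expressed
#'
#' Applies a fitted cutoff to a sample on its original scale. A gene is
#' `HE` when its prepared (log2) value exceeds `cutoffLog2(result)`;
#' zero-expression genes (on the count/RPKM/FPKM scales) are always `LE`.
#'
#' @param sample The [ExpressionSample-class] the cutoff was (or is to be)
#'   estimated from.
#' @param result A [DafsResult-class]; when missing, [estimateCutoff()] is
#'   run on `sample`.
#' @param ... Passed on to [estimateCutoff()] when `result` is missing.
#' @return A data frame with columns `gene_id`, `value` (original scale)
#'   and `flag` (`"LE"`/`"HE"`).
#' @export
flagGenes <- function(sample, result = NULL, ...) {
  stopifnot(is(sample, "ExpressionSample"))
  if (is.null(result)) result <- estimateCutoff(sample, ...)
  stopifnot(is(result, "DafsResult"))
  v <- exprValues(sample)
  if (exprScale(sample) == "log2") {
    lv <- v
    expressed <- rep(TRUE, length(v))
  } else {
    expressed <- v > 0
    lv <- ifelse(expressed, log2(pmax(v, .Machine$double.xmin)), -Inf)
  }
  flag <- ifelse(expressed & lv > cutoffLog2(result), "HE", "LE")
  ids <- geneIds(sample)
  if (!length(ids)) ids <- sprintf("gene_%d", seq_along(v))
  data.frame(gene_id = ids, value = v, flag = flag, stringsAsFactors = FALSE)
}
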