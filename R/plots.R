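#' Plot a K-S profile with its piecewise-linear fit
#'
#' Simple base-graphics view of the profile: K-S distances against the
#' trimming percentile, the MARS fit (when given), and the selected
#' quantile cutoff.
#'
#' @param profile A [KSProfile-class], or a [DafsResult-class] (in which
#'   case the fit and cutoff are taken from it).
#' @param model Optional [MarsModel-class] overlay.
#' @param qc Optional quantile cutoff to mark.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plotProfile <- function(profile, model = NULL, qc = NULL, ...) {
  if (is(profile, "DafsResult")) {
    if (is.null(model)) model <- marsModel(profile)
    if (is.null(qc)) qc <- quantileCutoff(profile)
    profile <- ksProfile(profile)
  }
  stopifnot(is(profile, "KSProfile"))
  p <- pGrid(profile); d <- dValues(profile)
  graphics::plot(p, d, pch = 16, col = "grey40",
                 xlab = "trimming percentile p",
                 ylab = "K-S distance D", ...)
  if (!is.null(model)) {
    px <- seq(min(p), max(p), length.out = 200L)
    graphics::lines(px, predict(model, px), col = "steelblue", lwd = 2)
    if (length(marsKnots(model)))
      graphics::abline(v = marsKnots(model), col = "grey70", lty = 3)
  }
  if (!is.null(qc)) graphics::abline(v = qc, col = "firebrick", lwd = 2, lty = 2)
  invisible(NULL)
}

#' Density plot with cutoff markers
#'
#' Kernel density of the prepared (log2) values with vertical lines at
#' one or more cutoffs -- a quick look at where each method separates the
#' low- and high-expression regions.
#'
#' @param sample An [ExpressionSample-class] (prepared internally if not
#'   yet on the log2 scale).
#' @param cutoffs Named numeric vector of log2-scale cutoffs.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `NULL`.
#' @export
plotDensityCutoff <- function(sample, cutoffs = numeric(), ...) {
  stopifnot(is(sample, "ExpressionSample"))
  v <- exprValues(prepareSample(sample))
  graphics::plot(stats::density(v), main = sampleName(sample),
                 xlab = "log2 expression", ...)
  if (length(cutoffs)) {
    cols <- grDevices::hcl.colors(max(length(cutoffs), 2L), "Dark 3")
    for (i in seq_along(cutoffs))
      graphics::abline(v = cutoffs[i], col = cols[i], lwd = 2, lty = i + 1L)
    if (!is.null(names(cutoffs)))
      graphics::legend("topleft", legend = names(cutoffs), col = cols,
                       lty = seq_along(cutoffs) + 1L, lwd = 2, bty = "n")
  }
  invisible(NULL)
}
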