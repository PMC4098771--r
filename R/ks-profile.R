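#' Scaled Kolmogorov-Smirnov distance to a normal reference
#'
#' Computes \eqn{D = \sqrt{n}\,\sup_y |F_n(y) - F(y)|}, the sup-distance
#' between the empirical CDF of `y` and a reference CDF, scaled by the
#' square root of the subsample size. The sup is taken over both the left
#' and right limits of the empirical step function at every order
#' statistic. The default reference is Normal(`mu`, `sigma^2`); any other
#' continuous reference can be supplied through `cdf`.
#'
#' @param y Non-empty numeric vector (finite values).
#' @param mu,sigma Mean and standard deviation of the normal reference
#'   (`sigma > 0`). Ignored when `cdf` is given.
#' @param cdf Optional vectorized CDF function overriding the normal
#'   reference.
#' @return A single non-negative number.
#' @examples
#' # equally spaced probability points achieve the minimal sup 1/(2n):
#' y <- qnorm((1:100 - 0.5) / 100)
#' ksDistance(y, 0, 1)   # sqrt(100) * 1/200 = 0.05
#' @export
ksDistance <- function(y, mu, sigma, cdf = NULL) {
  n <- length(y)
  if (n == 0L) stop("empty subsample")
  if (anyNA(y) || any(!is.finite(y))) stop("non-finite values in subsample")
  if (is.null(cdf)) {
    if (!is.finite(sigma) || sigma <= 0) stop("degenerate reference")
    cdf <- function(q) stats::pnorm(q, mean = mu, sd = sigma)
  }
  Fy <- cdf(sort(y))
  i <- seq_len(n)
  sup <- max(i / n - Fy, Fy - (i - 1L) / n)
  sqrt(n) * sup
}

#' Trimming-percentile grid
#'
#' Arithmetic grid of trimming percentiles from `p0` up to the stopping
#' value 0.50, built by integer index arithmetic so the spacing is exact.
#' The stopping value 0.50 guarantees that at least half the data always
#' describes the putative normal HE component.
#'
#' @param p0 Grid start in `[0, 0.5)`: the fraction of observations tied
#'   at the minimum expression level.
#' @param step Grid spacing; 0.01 (default) and 0.005 are the conventional
#'   choices, other positive values are accepted with a warning.
#' @return Numeric vector `p0, p0 + step, ...` of length >= 2, whose last
#'   element is the largest grid value `<= 0.50`.
#' @examples
#' length(buildGrid(0.10, 0.01))   # 41
#' @export
buildGrid <- function(p0, step = 0.01) {
  stopifnot(is.numeric(p0), length(p0) == 1L, is.finite(p0),
            is.numeric(step), length(step) == 1L, is.finite(step), step > 0)
  if (p0 < 0) stop("p0 must be non-negative")
  if (p0 >= 0.50)
    stop("minimum-expression mass exceeds stopping value; no HE/LE separation attempted")
  if (abs(step - 0.01) > 1e-12 && abs(step - 0.005) > 1e-12)
    warning(sprintf("non-standard grid step %g (conventional choices: 0.01, 0.005)", step))
  k <- 0L:as.integer(floor((0.50 - p0) / step + 1e-9))
  grid <- p0 + k * step
  if (length(grid) < 2L)
    stop("fewer than 2 grid points between p0 and the 0.50 stopping value")
  grid
}

#' Kolmogorov-Smirnov profile over quantile-trimmed tails
#'
#' For every percentile \eqn{p} on the grid from \eqn{p_0} to 0.50, takes
#' the strict upper tail \eqn{Y_p = \{x_i : x_i > x_{(p)}\}} above the
#' \eqn{p}-th empirical quantile, centers a normal reference at the tail
#' median with the tail standard deviation as scale, and records the
#' scaled K-S distance [ksDistance()] between the tail and that reference.
#' \eqn{p_0} is the fraction of values tied at the minimum observed level,
#' so grid trimming always starts just beyond the minimum-expression mass.
#'
#' The median/SD pairing is deliberate: while low-expressed contamination
#' remains in the lower reaches of the tail, the median stays anchored on
#' the normal high-expression bulk whereas the SD is inflated by the
#' contamination, so the distance keeps falling until the contamination is
#' fully trimmed; the profile minimum then marks the lower boundary of the
#' normal component. A mean-based location drifts with the contamination
#' and places the minimum too early.
#'
#' @param sample An [ExpressionSample-class] already on the log2 scale
#'   (see [prepareSample()]).
#' @param step Grid spacing; when `NULL`, 0.005 is used for samples of
#'   50,000 or more values and 0.01 otherwise.
#' @param minTail Minimum tail size below which the profile aborts.
#' @return A [KSProfile-class].
#' @seealso [estimateCutoff()] for the full pipeline.
#' @export
computeProfile <- function(sample, step = NULL, minTail = 10L) {
  stopifnot(is(sample, "ExpressionSample"))
  if (exprScale(sample) != "log2")
    stop("sample must be on the log2 scale; run prepareSample() first")
  v <- exprValues(sample)
  n <- length(v)
  if (n < 2L) stop("too few observations for a profile")
  sv <- sort(v)
  p0 <- sum(sv == sv[1L]) / n
  if (is.null(step)) step <- if (n >= 50000L) 0.005 else 0.01
  grid <- buildGrid(p0, step)
  d <- numeric(length(grid))
  for (j in seq_along(grid)) {
    xq <- stats::quantile(sv, grid[j], names = FALSE, type = 7)
    yp <- sv[sv > xq]           # strict upper tail; ties with x_(p) excluded
    if (length(yp) < minTail)
      stop(sprintf("insufficient tail data at p=%.4g", grid[j]))
    mu <- stats::median(yp)
    sg <- stats::sd(yp)
    if (sg == 0) stop(sprintf("degenerate subsample at p=%.4g", grid[j]))
    d[j] <- ksDistance(yp, mu, sg)
  }
  new("KSProfile", pGrid = grid, dValues = d, p0 = p0, step = step,
      nTotal = as.integer(n))
}

#' Export a K-S profile as TSV
#'
#' Writes the profile as a two-column table with header `p<TAB>D`.
#'
#' @param profile A [KSProfile-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "KSProfile"))
  df <- data.frame(p = sprintf("%.6g", pGrid(profile)),
                   D = sprintf("%.6g", dValues(profile)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
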