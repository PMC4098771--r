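## One-dimensional MARS: forward selection of reflected hinge pairs
## (x - t)_+ / (t - x)_+ plus an optional plain linear term, backward
## pruning by GCV. Grids are small (<= ~101 points), so plain QR fits are
## used throughout; no downdating tricks.

.marsColumn <- function(x, type, knot) {
  switch(type,
    intercept = rep(1, length(x)),
    linear    = x,
    `hinge+`  = pmax(x - knot, 0),
    `hinge-`  = pmax(knot - x, 0),
    stop("unknown basis type: ", type))
}

.marsDesign <- function(x, types, knots) {
  m <- vapply(seq_along(types),
              function(j) .marsColumn(x, types[j], knots[j]),
              numeric(length(x)))
  if (is.null(dim(m))) m <- matrix(m, nrow = length(x))
  m
}

.rssOf <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

.gcvScore <- function(rss, n, types, knots, penalty) {
  M <- length(types)
  K <- length(unique(knots[types %in% c("hinge+", "hinge-")]))
  C <- M + penalty * K
  if (C >= n) return(Inf)
  (rss / n) / (1 - C / n)^2
}

#' Fit a one-dimensional adaptive regression spline
#'
#' Forward stepwise search greedily adds reflected hinge pairs
#' \eqn{(x-t)_+} and \eqn{(t-x)_+} at observed-`x` knots (and, once, a
#' plain linear term), each step choosing the candidate that most reduces
#' the residual sum of squares. The backward pass deletes terms one at a
#' time and returns the visited sub-model minimizing the GCV score
#' \deqn{GCV(M) = \frac{\sum_i (y_i - \hat f_M(x_i))^2 / N}{(1 - C(M)/N)^2},}
#' with cost-complexity \eqn{C(M) = M + \mathrm{penalty} \times K} for
#' \eqn{M} basis terms (intercept included) and \eqn{K} distinct knots.
#' Hinges are added as pairs but pruned individually.
#'
#' Candidate knots keep at least `minSpan` observations from each data
#' boundary, which protects the pruning from boundary artifacts on short
#' profiles. Interior knots may sit on adjacent observations: the greedy
#' forward search often needs to refine near an earlier placement, and the
#' GCV pruning -- not a spacing rule -- supplies the parsimony. Ties in
#' RSS reduction go to the smaller knot, so the fit is deterministic.
#'
#' @param x Strictly increasing predictor (length >= 5).
#' @param y Response, same length.
#' @param maxTerms Maximum number of basis terms including the intercept
#'   (default 21).
#' @param penalty Per-knot GCV cost (default 3).
#' @param minSpan Minimum observation count between a candidate knot and
#'   each data boundary (default 2).
#' @return A [MarsModel-class].
#' @examples
#' x <- seq(0, 1, by = 0.05)
#' fit <- fitMars(x, abs(x - 0.5))
#' marsKnots(fit)            # 0.5
#' slopeChangePoints(fit)    # a "min" at 0.5
#' @export
fitMars <- function(x, y, maxTerms = 21L, penalty = 3, minSpan = 2L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 5L) stop("need at least 5 observations")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  maxTerms <- as.integer(maxTerms)
  if (maxTerms < 1L) stop("maxTerms must be >= 1")

  tss <- sum((y - mean(y))^2)
  tol <- 1e-10 * max(tss, .Machine$double.xmin)
  tieTol <- 1e-12 * max(tss, 1)

  types <- "intercept"
  knots <- NA_real_
  usedKnotIdx <- integer()
  linUsed <- FALSE
  X <- .marsDesign(x, types, knots)
  rssCur <- tss

  if (minSpan >= 1L && n > 2L * minSpan) {
    candIdx <- seq.int(minSpan + 1L, n - minSpan)
  } else {
    candIdx <- seq_len(n)
  }

  ## ---- forward pass ----
  repeat {
    best <- NULL
    if (!linUsed && length(types) + 1L <= maxTerms) {
      r <- .rssOf(cbind(X, x), y)
      best <- list(rss = r, what = "linear", i = NA_integer_)
    }
    if (length(types) + 2L <= maxTerms) {
      admissible <- setdiff(candIdx, usedKnotIdx)
      for (i in admissible) {       # ascending knot order: ties keep smaller
        t <- x[i]
        r <- .rssOf(cbind(X, pmax(x - t, 0), pmax(t - x, 0)), y)
        if (is.null(best) || r < best$rss - tieTol)
          best <- list(rss = r, what = "hinge", i = i)
      }
    }
    if (is.null(best) || (rssCur - best$rss) < tol) break
    if (best$what == "linear") {
      types <- c(types, "linear"); knots <- c(knots, NA_real_)
      linUsed <- TRUE
    } else {
      t <- x[best$i]
      types <- c(types, "hinge+", "hinge-")
      knots <- c(knots, t, t)
      usedKnotIdx <- c(usedKnotIdx, best$i)
    }
    X <- .marsDesign(x, types, knots)
    rssCur <- best$rss
    if (rssCur < tol) break
  }

  ## ---- backward pass ----
  visited <- list(list(types = types, knots = knots, rss = rssCur,
                       gcv = .gcvScore(rssCur, n, types, knots, penalty)))
  curTypes <- types; curKnots <- knots
  while (sum(curTypes != "intercept") > 0L) {
    removable <- which(curTypes != "intercept")
    bestJ <- NA_integer_; bestRss <- Inf
    for (j in removable) {
      r <- .rssOf(.marsDesign(x, curTypes[-j], curKnots[-j]), y)
      if (r < bestRss - tieTol || is.na(bestJ)) { bestRss <- r; bestJ <- j }
    }
    curTypes <- curTypes[-bestJ]; curKnots <- curKnots[-bestJ]
    visited[[length(visited) + 1L]] <-
      list(types = curTypes, knots = curKnots, rss = bestRss,
           gcv = .gcvScore(bestRss, n, curTypes, curKnots, penalty))
  }
  gcvs <- vapply(visited, `[[`, numeric(1), "gcv")
  pick <- max(which(gcvs <= min(gcvs) + 1e-15))   # prefer the smaller model on ties
  sel <- visited[[pick]]

  ## ---- final refit; drop aliased columns ----
  fTypes <- sel$types; fKnots <- sel$knots
  fit <- stats::lm.fit(.marsDesign(x, fTypes, fKnots), y)
  keep <- !is.na(fit$coefficients)
  if (!all(keep)) {
    fTypes <- fTypes[keep]; fKnots <- fKnots[keep]
    fit <- stats::lm.fit(.marsDesign(x, fTypes, fKnots), y)
  }
  basis <- data.frame(type = fTypes, knot = fKnots,
                      coef = as.numeric(fit$coefficients),
                      stringsAsFactors = FALSE)
  hk <- sort(unique(fKnots[fTypes %in% c("hinge+", "hinge-")]))
  yr <- diff(range(y)); xr <- diff(range(x))
  new("MarsModel", basis = basis, knots = hk, gcv = sel$gcv,
      slopeTol = 1e-8 * (if (yr > 0) yr / xr else 1),
      xRange = range(x), yRange = range(y))
}

#' Predict from a fitted MARS model
#'
#' Evaluates the piecewise-linear fit at new predictor values; segments
#' extrapolate linearly beyond the training range.
#'
#' @param object A [MarsModel-class].
#' @param newdata Numeric vector of predictor values.
#' @param ... Not used.
#' @return Numeric vector of fitted values.
#' @export
setMethod("predict", "MarsModel", function(object, newdata, ...) {
  x <- as.numeric(newdata)
  b <- object@basis
  out <- numeric(length(x))
  for (j in seq_len(nrow(b)))
    out <- out + b$coef[j] * .marsColumn(x, b$type[j], b$knot[j])
  out
})

## analytic derivative of the fit at points strictly between knots
.marsSlopeAt <- function(object, pts) {
  b <- object@basis
  vapply(pts, function(p) {
    s <- 0
    for (j in seq_len(nrow(b))) {
      s <- s + switch(b$type[j],
        intercept = 0,
        linear    = b$coef[j],
        `hinge+`  = if (p > b$knot[j]) b$coef[j] else 0,
        `hinge-`  = if (p < b$knot[j]) -b$coef[j] else 0)
    }
    s
  }, numeric(1))
}

#' @rdname slopeChangePoints
#' @details A segment slope whose magnitude falls below the model's
#'   declared tolerance counts as zero, so a decreasing-to-flat pattern is
#'   a `"bend"`, not a `"min"`. Classification: negative-to-positive =
#'   `"min"`, positive-to-negative = `"max"`, anything else = `"bend"`.
setMethod("slopeChangePoints", "MarsModel", function(model) {
  kn <- model@knots
  if (!length(kn))
    return(data.frame(knot = numeric(), change = character(),
                      stringsAsFactors = FALSE))
  K <- length(kn)
  gap <- if (K > 1L) min(diff(kn)) else 1
  reps <- c(kn[1L] - gap / 2,
            if (K > 1L) (kn[-K] + kn[-1L]) / 2,
            kn[K] + gap / 2)
  slopes <- .marsSlopeAt(model, reps)
  sgn <- ifelse(abs(slopes) <= model@slopeTol, 0L, sign(slopes))
  change <- character(K)
  for (j in seq_len(K)) {
    l <- sgn[j]; r <- sgn[j + 1L]
    change[j] <- if (l < 0 && r > 0) "min" else if (l > 0 && r < 0) "max" else "bend"
  }
  data.frame(knot = kn, change = change, stringsAsFactors = FALSE)
})

setMethod("show", "MarsModel", function(object) {
  b <- object@basis
  cat(sprintf("MarsModel: %d basis terms, %d knots, GCV = %.6g\n",
              nrow(b), length(object@knots), object@gcv))
  if (length(object@knots)) {
    scp <- slopeChangePoints(object)
    for (j in seq_len(nrow(scp)))
      cat(sprintf("  knot %.4g (%s)\n", scp$knot[j], scp$change[j]))
  } else {
    cat("  (no knots: globally linear fit)\n")
  }
})
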