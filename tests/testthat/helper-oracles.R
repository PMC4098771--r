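# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops and stats primitives only.

# brute-force scaled K-S statistic: explicit sup over both empirical-CDF
# corners at every order statistic
bruteKS <- function(y, mu, sigma) {
  n <- length(y)
  ys <- sort(y)
  Fv <- pnorm(ys, mu, sigma)
  sup <- 0
  for (i in seq_len(n)) {
    sup <- max(sup, abs(i / n - Fv[i]), abs((i - 1) / n - Fv[i]))
  }
  sqrt(n) * sup
}

# brute-force K-S profile: independent double loop over grid and tails,
# same median/SD reference convention as the pipeline under test
bruteProfile <- function(v, step) {
  n <- length(v)
  p0 <- sum(v == min(v)) / n
  ks <- seq.int(0L, floor((0.5 - p0) / step + 1e-9))
  grid <- p0 + ks * step
  d <- vapply(grid, function(p) {
    xq <- quantile(v, p, names = FALSE, type = 7)
    yp <- v[v > xq]
    bruteKS(yp, median(yp), sd(yp))
  }, numeric(1))
  list(p = grid, d = d)
}

# exhaustive least-squares search over hinge-knot subsets of size <= 2
# (basis: intercept + linear + full hinge pair per knot), reporting RSS and
# the same GCV formula the MARS engine declares
enumMars <- function(x, y, maxKnots = 2L, penalty = 3) {
  n <- length(x)
  cand <- x[3:(n - 2)]
  design <- function(kn) {
    X <- cbind(1, x)
    for (t in kn) X <- cbind(X, pmax(x - t, 0), pmax(t - x, 0))
    X
  }
  score <- function(kn) {
    X <- design(kn)
    rss <- sum(lm.fit(X, y)$residuals^2)
    M <- ncol(X)
    C <- M + penalty * length(kn)
    gcv <- if (C >= n) Inf else (rss / n) / (1 - C / n)^2
    c(rss = rss, gcv = gcv)
  }
  subsets <- list(numeric(0))
  for (i in seq_along(cand)) subsets[[length(subsets) + 1L]] <- cand[i]
  if (maxKnots >= 2L && length(cand) >= 2L) {
    cmb <- combn(cand, 2L)
    for (j in seq_len(ncol(cmb))) subsets[[length(subsets) + 1L]] <- cmb[, j]
  }
  res <- t(vapply(subsets, score, numeric(2)))
  data.frame(nKnots = lengths(subsets), rss = res[, "rss"], gcv = res[, "gcv"])
}

# analytic quantile of the renormalized HE sub-mixture of a scenario
heMixtureQuantile <- function(scenario, q) {
  he <- setdiff(seq_along(scenario@weights), scenario@leComponents)
  w <- scenario@weights[he] / sum(scenario@weights[he])
  mu <- scenario@means[he]
  s <- sqrt(scenario@variances[he])
  uniroot(function(c) sum(w * pnorm(c, mu, s)) - q,
          c(min(mu) - 10 * max(s), max(mu) + 10 * max(s)),
          tol = 1e-10)$root
}

# bisection root of pi1*phi1(x) - pi2*phi2(x) on (mu1, mu2)
bisectIntersection <- function(w, mu, s2, tol = 1e-12) {
  f <- function(x) w[1] * dnorm(x, mu[1], sqrt(s2[1])) -
    w[2] * dnorm(x, mu[2], sqrt(s2[2]))
  lo <- mu[1]; hi <- mu[2]
  flo <- f(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}
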