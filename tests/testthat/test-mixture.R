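test_that("EM recovers parameters of a well-separated mixture", {
  set.seed(21)
  x <- c(rnorm(1250, -5, 1), rnorm(1250, 5, 1))
  fit <- fitTwoComponent(x)
  expect_lt(abs(componentMeans(fit)[1] + 5), 0.15)
  expect_lt(abs(componentMeans(fit)[2] - 5), 0.15)
  expect_lt(abs(componentWeights(fit)[1] - 0.5), 0.03)
  # log-likelihood is non-decreasing at every EM iteration
  expect_true(all(diff(fit@loglikTrace) > -1e-6))
})

test_that("point masses collapse onto the two locations", {
  x <- c(rep(-5, 100), rep(5, 100))
  fit <- fitTwoComponent(x)
  expect_equal(componentMeans(fit), c(-5, 5), tolerance = 1e-6)
  expect_equal(componentWeights(fit), c(0.5, 0.5), tolerance = 1e-6)
})

test_that("equal-variance data selects the equal structure most of the time", {
  picks <- vapply(1:50, function(s) {
    set.seed(3000 + s)
    x <- c(rnorm(2000, 0, 1), rnorm(3000, 6, 1))
    varianceStructure(fitTwoComponent(x))
  }, character(1))
  expect_gte(mean(picks == "equal"), 0.9)
})

test_that("BIC is consistent with loglik, parameter count and n", {
  set.seed(33)
  x <- c(rnorm(500, 0, 1), rnorm(500, 4, 2))
  fit <- fitTwoComponent(x)
  p <- if (varianceStructure(fit) == "equal") 4 else 5
  expect_equal(bic(fit), 2 * fit@loglik - p * log(1000), tolerance = 1e-8)
  expect_gte(bic(fit), fit@bicAlternative)
})

test_that("degenerate inputs are rejected", {
  expect_error(fitTwoComponent(rnorm(10)), "at least 20")
  expect_error(fitTwoComponent(rep(1, 50)), "constant")
  expect_error(fitTwoComponent(c(1, NA, rep(2, 30))), "non-finite")
})

test_that("intersection cutoff has its closed-form symmetric values", {
  mk <- function(w, mu, s2, vs) new("MixtureModel", weights = w, means = mu,
    variances = s2, varianceStructure = vs, loglik = 0, bic = 0,
    bicAlternative = 0, n = 100L, loglikTrace = 0)
  # equal weights, equal variance: exactly the midpoint, for any variance
  expect_equal(intersectionCutoff(mk(c(.5, .5), c(0, 2), c(1, 1), "equal")), 1)
  expect_equal(intersectionCutoff(mk(c(.5, .5), c(0, 2), c(4, 4), "equal")), 1)
  expect_error(intersectionCutoff(mk(c(.5, .5), c(2, 2), c(1, 2), "unequal")),
               "coincident")
})

test_that("intersection formula agrees with a bisection root-finder", {
  # the documented unequal-variance case
  w <- c(0.36, 0.64); mu <- c(3.5, 9.1); s2 <- c(2.9, 1.9)
  mdl <- new("MixtureModel", weights = w, means = mu, variances = s2,
             varianceStructure = "unequal", loglik = 0, bic = 0,
             bicAlternative = 0, n = 100L, loglikTrace = 0)
  expect_equal(intersectionCutoff(mdl), bisectIntersection(w, mu, s2),
               tolerance = 1e-10)
  # 100 random parameter sets with a crossing between the means
  set.seed(77)
  done <- 0
  while (done < 100) {
    w1 <- runif(1, 0.05, 0.95); w <- c(w1, 1 - w1)
    mu <- sort(runif(2, -10, 10)); if (diff(mu) < 0.5) next
    s2 <- runif(2, 0.2, 6)
    f <- function(x) w[1] * dnorm(x, mu[1], sqrt(s2[1])) -
      w[2] * dnorm(x, mu[2], sqrt(s2[2]))
    if (sign(f(mu[1])) == sign(f(mu[2]))) next   # no crossing between means
    mdl <- new("MixtureModel", weights = w, means = mu, variances = s2,
               varianceStructure = "unequal", loglik = 0, bic = 0,
               bicAlternative = 0, n = 100L, loglikTrace = 0)
    cut <- intersectionCutoff(mdl)
    expect_equal(cut, bisectIntersection(w, mu, s2), tolerance = 1e-8)
    # weighted densities are equal at the crossing
    dens <- c(w[1] * dnorm(cut, mu[1], sqrt(s2[1])),
              w[2] * dnorm(cut, mu[2], sqrt(s2[2])))
    expect_lt(abs(dens[1] - dens[2]), 1e-8 * max(dens))
    done <- done + 1
  }
})

test_that("unequal-variance intersection is continuous at equal variances", {
  w <- c(0.3, 0.7); mu <- c(1, 6)
  evar <- intersectionCutoff(new("MixtureModel", weights = w, means = mu,
    variances = c(2, 2), varianceStructure = "equal", loglik = 0, bic = 0,
    bicAlternative = 0, n = 100L, loglikTrace = 0))
  # exactly equal variances under the unequal branch
  same <- intersectionCutoff(new("MixtureModel", weights = w, means = mu,
    variances = c(2, 2), varianceStructure = "unequal", loglik = 0, bic = 0,
    bicAlternative = 0, n = 100L, loglikTrace = 0))
  expect_equal(same, evar, tolerance = 1e-10)
  # limit from nearby variance ratios
  for (eps in c(1e-4, 1e-6)) {
    near <- intersectionCutoff(new("MixtureModel", weights = w, means = mu,
      variances = c(2, 2 * (1 + eps)), varianceStructure = "unequal",
      loglik = 0, bic = 0, bicAlternative = 0, n = 100L, loglikTrace = 0))
    expect_lt(abs(near - evar), 50 * eps)
  }
})

test_that("fit agrees with the mclust reference on a scenario draw", {
  # Mclust() requires its package attached (it resolves helpers unqualified)
  suppressPackageStartupMessages(library(mclust))
  scen <- simScenario("log2_rpkm")
  d <- sampleScenario(scen, 3)
  ours <- fitTwoComponent(d$values)
  mc <- Mclust(d$values, G = 2, modelNames = c("E", "V"),
               verbose = FALSE)
  mcStruct <- if (mc$modelName == "E") "equal" else "unequal"
  expect_identical(varianceStructure(ours), mcStruct)
  expect_lt(abs(ours@loglik - mc$loglik), 2)
  p <- mc$parameters
  expect_equal(sort(componentMeans(ours)), sort(as.numeric(p$mean)),
               tolerance = 0.2)
})
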