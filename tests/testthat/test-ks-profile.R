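test_that("ksDistance reproduces closed-form cases and rejects bad input", {
  # equally spaced probability points give the minimal sup 1/(2n)
  n <- 100
  y <- qnorm((seq_len(n) - 0.5) / n)
  expect_equal(ksDistance(y, 0, 1), sqrt(n) / (2 * n), tolerance = 1e-12)
  # a single point at the reference median
  expect_equal(ksDistance(0, 0, 1), 0.5)
  expect_error(ksDistance(numeric(0), 0, 1), "empty subsample")
  expect_error(ksDistance(1:5, 0, 0), "degenerate reference")
  expect_error(ksDistance(1:5, 0, -1), "degenerate reference")
  expect_error(ksDistance(c(1, NA), 0, 1), "non-finite")
})

test_that("ksDistance equals the brute-force corner sup on random inputs", {
  set.seed(101)
  for (n in c(1, 2, 17, 200, 2000)) {
    y <- rnorm(n, 3, 2)
    expect_equal(ksDistance(y, 3, 2), bruteKS(y, 3, 2), tolerance = 1e-12)
    # also against stats::ks.test's unscaled statistic
    if (n > 1) {
      dref <- unname(ks.test(y, "pnorm", 3, 2)$statistic)
      expect_equal(ksDistance(y, 3, 2) / sqrt(n), dref, tolerance = 1e-12)
    }
  }
})

test_that("ksDistance is invariant under affine maps of data and reference", {
  set.seed(7)
  y <- rgamma(300, 2, 1)
  base <- ksDistance(y, 1.5, 0.8)
  for (ab in list(c(2, 0), c(0.5, 3), c(10, -4))) {
    a <- ab[1]; b <- ab[2]
    expect_equal(ksDistance(a * y + b, a * 1.5 + b, a * 0.8), base,
                 tolerance = 1e-10)
  }
})

test_that("ksDistance accepts a pluggable reference CDF", {
  set.seed(5)
  y <- rexp(100, 2)
  d1 <- ksDistance(y, NA, NA, cdf = function(q) pexp(q, 2))
  expect_equal(d1 / sqrt(100), unname(ks.test(y, "pexp", 2)$statistic),
               tolerance = 1e-12)
})

test_that("buildGrid arithmetic, warnings and degenerate cases", {
  expect_length(buildGrid(0.10, 0.01), 41L)
  expect_length(buildGrid(0, 0.005), 101L)
  g <- buildGrid(0.10, 0.01)
  expect_equal(g[1], 0.10)
  expect_equal(g[length(g)], 0.50)
  # spacing exact to index arithmetic, not accumulated addition
  expect_true(max(abs(diff(g) - 0.01)) < 1e-15)
  expect_error(buildGrid(0.55, 0.01), "stopping value")
  expect_error(buildGrid(0.497, 0.01), "fewer than 2")
  expect_error(buildGrid(-0.1, 0.01), "non-negative")
  expect_warning(buildGrid(0.1, 0.02), "non-standard")
})

test_that("computeProfile matches an independent brute-force recomputation", {
  set.seed(42)
  v <- c(rnorm(600, 2, 1), rnorm(1400, 8, 1.5))
  prof <- computeProfile(ExpressionSample(v, scale = "log2"), step = 0.01)
  ref <- bruteProfile(v, 0.01)
  expect_equal(pGrid(prof), ref$p, tolerance = 1e-12)
  expect_equal(dValues(prof), ref$d, tolerance = 1e-10)
  # argmin agrees with the independent recomputation
  expect_equal(pGrid(prof)[which.min(dValues(prof))],
               ref$p[which.min(ref$d)])
})

test_that("p0 is the fraction of values tied at the minimum", {
  set.seed(3)
  # 30% of values exactly 0 on the log2 scale (counts of 1)
  v <- c(rep(0, 600), runif(1400, 2, 10))
  prof <- computeProfile(ExpressionSample(v, scale = "log2"))
  expect_equal(p0(prof), 0.30)
  expect_equal(pGrid(prof)[1], 0.30)
  # continuous data: minimum occurs once
  v2 <- rnorm(2000, 8, 1)
  prof2 <- computeProfile(ExpressionSample(v2, scale = "log2"))
  expect_equal(p0(prof2), 1 / 2000)
  # a single normal agrees with its reference before trimming bites
  # (deeply trimmed tails are left-truncated normals, so D necessarily
  # grows toward p = 0.5); crucially there is no interior minimum that
  # would mimic a contamination boundary
  expect_lt(dValues(prof2)[1], 2)
  expect_lte(pGrid(prof2)[which.min(dValues(prof2))], 0.05)
  # beyond the argmin the profile rises essentially monotonically
  tailD <- dValues(prof2)[pGrid(prof2) > 0.1]
  expect_gt(cor(seq_along(tailD), tailD), 0.95)
})

test_that("computeProfile rejects unprepared and degenerate input", {
  expect_error(computeProfile(ExpressionSample(1:100, scale = "raw_count")),
               "log2")
  # more than half the mass at the minimum: no separation attempted
  v <- c(rep(0, 30), rnorm(12, 5, 1))
  expect_error(computeProfile(ExpressionSample(v, scale = "log2")),
               "minimum-expression mass")
  # p0 < 0.5 but the tail thins below the minimum subsample size
  set.seed(8)
  v2 <- c(rep(0, 4), runif(12, 2, 10))
  expect_error(computeProfile(ExpressionSample(v2, scale = "log2")),
               "insufficient tail data")
})

test_that("profile argmin tracks the LE mass for well-separated mixtures", {
  # components 5 SDs apart: the K-S minimum sits at the LE mixing weight
  for (s in 1:20) {
    set.seed(1000 + s)
    piLE <- 0.3
    nLE <- rbinom(1, 4000, piLE)
    v <- c(rnorm(nLE, 0, 1), rnorm(4000 - nLE, 10, 1))
    prof <- computeProfile(ExpressionSample(v, scale = "log2"), step = 0.01)
    argmin <- pGrid(prof)[which.min(dValues(prof))]
    expect_lt(abs(argmin - piLE), 0.05)
  }
})

test_that("writeProfile emits the documented two-column TSV", {
  set.seed(1)
  prof <- computeProfile(ExpressionSample(rnorm(1000, 5, 1), scale = "log2"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeProfile(prof, f)
  lines <- readLines(f)
  expect_equal(lines[1], "p\tD")
  expect_length(lines, length(pGrid(prof)) + 1L)
})
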