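test_that("built-in scenarios carry the published generating parameters", {
  s1 <- simScenario("log2_count")
  expect_equal(sum(s1@weights), 1)
  expect_equal(sum(s1@weights[s1@leComponents]), 0.36)
  s2 <- simScenario("log2_rpkm")
  expect_equal(sum(s2@weights[s2@leComponents]), 0.11)
  expect_true(all(s2@variances == s2@variances[1]))
})

test_that("scenario draws match their analytic moments and labels", {
  s1 <- simScenario("log2_count")
  d <- sampleScenario(s1, 314)
  expect_length(d$values, 5000L)
  # LE fraction is binomial around the LE mass
  expect_lt(abs(mean(d$labels == "LE") - 0.36), 4 * sqrt(0.36 * 0.64 / 5000))
  # sample mean within 3 SE of the mixture mean
  mixMean <- sum(s1@weights * s1@means)
  mixVar <- sum(s1@weights * (s1@variances + s1@means^2)) - mixMean^2
  expect_lt(abs(mean(d$values) - mixMean), 3 * sqrt(mixVar / 5000))
  # labels and components are consistent
  expect_identical(d$labels == "LE", d$components %in% s1@leComponents)
  # same seed, same draw; caller RNG untouched
  set.seed(1); before <- .Random.seed
  d2 <- sampleScenario(s1, 314)
  expect_identical(before, .Random.seed)
  expect_identical(d$values, d2$values)
})

test_that("sensitivity-fixed cutoff is the (1-target) HE quantile", {
  expect_equal(sensitivityFixedCutoff(1:100, rep("HE", 100), 0.95), 5.95)
  v <- c(1:10, 100:109)
  lab <- rep(c("LE", "HE"), each = 10)
  expect_equal(sensitivityFixedCutoff(v, lab, 0.9),
               quantile(100:109, 0.1, names = FALSE))
  expect_error(sensitivityFixedCutoff(1:5, rep("LE", 5), 0.9), "no HE")
})

test_that("evaluateCutoff computes the documented confusion metrics", {
  v <- c(5, 6, 7, 8, 1, 2)
  lab <- c(rep("HE", 4), rep("LE", 2))
  m <- evaluateCutoff(v, lab, 4.5)
  expect_equal(unlist(m[c("sensitivity", "specificity", "ppv", "npv")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1))
  # cutoff below the minimum: everything predicted HE
  m2 <- evaluateCutoff(v, lab, 0)
  expect_equal(m2$sensitivity, 1)
  expect_equal(m2$specificity, 0)
  # counts always sum to n; order permutation leaves metrics unchanged
  set.seed(6)
  idx <- sample(length(v))
  m3 <- evaluateCutoff(v[idx], lab[idx], 4.5)
  expect_equal(m3[c("sensitivity", "specificity", "ppv", "npv")],
               m[c("sensitivity", "specificity", "ppv", "npv")])
  expect_equal(m$tp + m$fp + m$tn + m$fn, length(v))
  expect_error(evaluateCutoff(1:4, rep("HE", 4), 2), "both classes")
})

test_that("mean sensitivity-fixed cutoffs match the analytic mixture quantile", {
  # modest replicate count; the analytic oracle is the renormalized
  # HE-mixture quantile computed from the printed parameters
  for (scenName in c("log2_count", "log2_rpkm")) {
    scen <- simScenario(scenName)
    for (target in c(0.85, 0.95)) {
      cuts <- vapply(1:60, function(r) {
        d <- sampleScenario(scen, 5000 + r)
        sensitivityFixedCutoff(d$values, d$labels, target)
      }, numeric(1))
      oracle <- heMixtureQuantile(scen, 1 - target)
      expect_lt(abs(mean(cuts) - oracle), 3 * sd(cuts) / sqrt(length(cuts)))
    }
  }
})

test_that("specificity drops fast with misclassified LE counts when LE is rare", {
  # scenario 2 has ~550 LE genes in 5000: each misclassified LE gene costs
  # ~1/550 of specificity
  d <- sampleScenario(simScenario("log2_rpkm"), 99)
  nLE <- sum(d$labels == "LE")
  expect_lt(abs(nLE - 550), 4 * sqrt(5000 * 0.11 * 0.89))
  cutLow <- quantile(d$values[d$labels == "LE"], 0.8, names = FALSE)
  m <- evaluateCutoff(d$values, d$labels, cutLow)
  expect_equal(1 - m$specificity, m$fp / nLE, tolerance = 1e-12)
})

test_that("runStudy is deterministic and prefix-stable in the seed", {
  scen <- simScenario("log2_count", nReps = 6L)
  s1 <- runStudy(scen, methods = c("sen90", "sen95"), seed = 5)
  s2 <- runStudy(scen, methods = c("sen90", "sen95"), seed = 5)
  expect_identical(s1$cutoffs, s2$cutoffs)
  expect_identical(s1$table1, s2$table1)
  # a shorter run is a prefix of a longer one
  s3 <- runStudy(scen, methods = "sen95", seed = 5, nReps = 3L)
  expect_identical(s3$cutoffs[, "sen95"], s1$cutoffs[1:3, "sen95"])
  # written tables are byte-identical across repeated runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeStudy(s1, d1); writeStudy(s2, d2)
  expect_identical(readLines(file.path(d1, "table2.tsv")),
                   readLines(file.path(d2, "table2.tsv")))
})

test_that("runStudy evaluates dafs and mixture methods end to end", {
  scen <- simScenario("log2_count", nReps = 3L)
  st <- runStudy(scen, methods = c("dafs", "mclust"), seed = 17)
  expect_identical(colnames(st$cutoffs), c("dafs", "mixture"))
  expect_true(all(is.finite(st$cutoffs)))
  expect_true(all(st$table1$mean >= 0 & st$table1$mean <= 1))
  # cutoffs land between the LE and HE bulk for this well-separated case
  expect_true(all(st$cutoffs > 3 & st$cutoffs < 9))
})
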