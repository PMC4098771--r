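#' Built-in simulation scenarios
#'
#' Two labeled five-component Gaussian mixtures emulating the empirical
#' densities of a log2 raw-count sample and a log2 RPKM sample:
#'
#' * `log2_count`: weights (0.08, 0.28, 0.17, 0.26, 0.21), means
#'   (1.33, 4.68, 7.86, 9.50, 9.32), variances
#'   (0.62, 2.83, 1.17, 0.90, 3.53); the first two components are the
#'   low-expressed (LE) class, so LE mass is 0.36 and the two classes are
#'   well separated (clear bimodality).
#' * `log2_rpkm`: weights (0.11, 0.24, 0.25, 0.31, 0.09), means
#'   (-1.80, 1.30, 3.40, 4.20, 6.60), common variance 1.80; only the
#'   first component is LE (mass 0.11) and the classes overlap heavily
#'   (near-unimodal density).
#'
#' @param name Which scenario to build.
#' @param nGenes Values drawn per replicate (default 5000).
#' @param nReps Default replicate count (default 500).
#' @return A [SimulationScenario-class].
#' @export
simScenario <- function(name = c("log2_count", "log2_rpkm"),
                        nGenes = 5000L, nReps = 500L) {
  name <- match.arg(name)
  par <- switch(name,
    log2_count = list(w = c(0.08, 0.28, 0.17, 0.26, 0.21),
                      mu = c(1.33, 4.68, 7.86, 9.50, 9.32),
                      s2 = c(0.62, 2.83, 1.17, 0.90, 3.53),
                      le = 1:2),
    log2_rpkm  = list(w = c(0.11, 0.24, 0.25, 0.31, 0.09),
                      mu = c(-1.80, 1.30, 3.40, 4.20, 6.60),
                      s2 = rep(1.80, 5),
                      le = 1L))
  new("SimulationScenario", name = name, weights = par$w, means = par$mu,
      variances = par$s2, leComponents = as.integer(par$le),
      nGenes = as.integer(nGenes), nReps = as.integer(nReps))
}

#' Draw one labeled replicate from a scenario
#'
#' Draws `nGenes` values: a component index from the scenario's mixing
#' weights, then a normal deviate from that component. The truth label is
#' `LE` when the component belongs to the scenario's LE set. The caller's
#' RNG state is left untouched.
#'
#' @param scenario A [SimulationScenario-class].
#' @param seed Integer seed for this replicate.
#' @return A list with `values` (numeric), `labels` (factor `LE`/`HE`)
#'   and `components` (integer component indices).
#' @export
sampleScenario <- function(scenario, seed) {
  stopifnot(is(scenario, "SimulationScenario"))
  n <- scenario@nGenes
  .withLocalSeed(seed, {
    comp <- sample.int(length(scenario@weights), n, replace = TRUE,
                       prob = scenario@weights)
    vals <- stats::rnorm(n, scenario@means[comp], sqrt(scenario@variances[comp]))
    list(values = vals,
         labels = factor(ifelse(comp %in% scenario@leComponents, "LE", "HE"),
                         levels = c("LE", "HE")),
         components = comp)
  })
}

#' Cutoff achieving a fixed sensitivity for the HE class
#'
#' The empirical \eqn{(1 - s)}-quantile (linear-interpolation convention)
#' of the HE-labeled values: the expression bound above which a fraction
#' `target` of true HE genes lies.
#'
#' @param values Numeric expression values.
#' @param labels `LE`/`HE` labels, same length.
#' @param target Desired sensitivity in (0, 1).
#' @return The cutoff, a single number.
#' @examples
#' sensitivityFixedCutoff(1:100, rep("HE", 100), 0.95)   # 5.95
#' @export
sensitivityFixedCutoff <- function(values, labels, target) {
  stopifnot(length(values) == length(labels),
            is.numeric(target), length(target) == 1L, target > 0, target < 1)
  he <- values[labels == "HE"]
  if (!length(he)) stop("no HE-labeled values")
  stats::quantile(he, 1 - target, names = FALSE, type = 7)
}

#' Confusion-matrix performance of a cutoff
#'
#' Predicted class is HE when the value exceeds the cutoff (strictly);
#' the positive class is HE. Reports sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), PPV TP/(TP+FP) and NPV TN/(TN+FN) along with the counts.
#'
#' @param values Numeric expression values.
#' @param labels True `LE`/`HE` labels, same length (both classes must be
#'   present).
#' @param cutoff The expression cutoff.
#' @return One-row data frame with columns `cutoff`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `tp`, `fp`, `tn`, `fn`, `n_he`, `n_le`.
#' @export
evaluateCutoff <- function(values, labels, cutoff) {
  stopifnot(length(values) == length(labels))
  isHE <- labels == "HE"
  if (!any(isHE) || all(isHE)) stop("labels must contain both classes")
  predHE <- values > cutoff
  tp <- sum(predHE & isHE); fn <- sum(!predHE & isHE)
  fp <- sum(predHE & !isHE); tn <- sum(!predHE & !isHE)
  data.frame(cutoff = cutoff,
             sensitivity = tp / (tp + fn),
             specificity = tn / (tn + fp),
             ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
             npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
             tp = tp, fp = fp, tn = tn, fn = fn,
             n_he = tp + fn, n_le = tn + fp)
}

.STUDY_METHODS <- c("dafs", "mixture", "sen85", "sen90", "sen95")

.methodCutoff <- function(method, draw, step) {
  switch(method,
    dafs = cutoffLog2(estimateCutoff(
      ExpressionSample(draw$values, scale = "log2"), step = step)),
    mixture = intersectionCutoff(fitTwoComponent(draw$values)),
    sen85 = sensitivityFixedCutoff(draw$values, draw$labels, 0.85),
    sen90 = sensitivityFixedCutoff(draw$values, draw$labels, 0.90),
    sen95 = sensitivityFixedCutoff(draw$values, draw$labels, 0.95),
    stop("unknown method: ", method))
}

#' Run a Monte-Carlo cutoff study
#'
#' For each replicate, draws a labeled sample from the scenario, computes
#' the cutoff of every requested method, and evaluates its confusion-matrix
#' performance against the truth labels. Replicate `r` uses seed
#' `seed + r`, so a shorter run is a prefix of a longer one with the same
#' master seed.
#'
#' Methods: `dafs` (the K-S/MARS pipeline, grid step `step`, values
#' treated as already log2-scale), `mixture` (two-component EM fit and
#' density-intersection cutoff; alias `mclust`), and `sen85`/`sen90`/
#' `sen95` (cutoffs forcing 85/90/95% sensitivity from the truth labels).
#'
#' @param scenario A [SimulationScenario-class].
#' @param methods Subset of `c("dafs", "mixture", "sen85", "sen90",
#'   "sen95")`.
#' @param seed Master seed.
#' @param nReps Number of replicates; defaults to the scenario's.
#' @param step Grid step used by the `dafs` method (default 0.01).
#' @param outDir When given, writes `table1.tsv` (mean +/- SE of the
#'   performance metrics per method) and `table2.tsv` (mean, 2.5%, median
#'   and 97.5% of cutoffs per method) there, 6 significant digits.
#' @param verbose Print per-replicate progress.
#' @return A list of class `dafsStudy`: `table1`, `table2`, `cutoffs`
#'   (replicate x method matrix), `metrics` (long data frame), `failures`
#'   (named count of failed replicates per method), plus the call
#'   parameters.
#' @export
runStudy <- function(scenario, methods = .STUDY_METHODS, seed = 1L,
                     nReps = NULL, step = 0.01, outDir = NULL,
                     verbose = FALSE) {
  stopifnot(is(scenario, "SimulationScenario"))
  methods[methods == "mclust"] <- "mixture"
  methods <- match.arg(methods, .STUDY_METHODS, several.ok = TRUE)
  if (is.null(nReps)) nReps <- scenario@nReps
  nReps <- as.integer(nReps)

  cutoffs <- matrix(NA_real_, nReps, length(methods),
                    dimnames = list(NULL, methods))
  metrics <- vector("list", nReps * length(methods))
  failures <- stats::setNames(integer(length(methods)), methods)
  k <- 0L
  for (r in seq_len(nReps)) {
    draw <- sampleScenario(scenario, seed + r)
    for (m in methods) {
      cut <- tryCatch(.methodCutoff(m, draw, step), error = function(e) {
        warning(sprintf("replicate %d, method %s failed: %s",
                        r, m, conditionMessage(e)), call. = FALSE)
        NA_real_
      })
      if (is.na(cut)) { failures[[m]] <- failures[[m]] + 1L; next }
      cutoffs[r, m] <- cut
      k <- k + 1L
      metrics[[k]] <- cbind(rep = r, method = m,
                            evaluateCutoff(draw$values, draw$labels, cut))
    }
    if (verbose && r %% 25L == 0L)
      message(sprintf("replicate %d/%d", r, nReps))
  }
  metrics <- do.call(rbind, metrics[seq_len(k)])

  meanSE <- function(v) c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)))
  t1 <- do.call(rbind, lapply(methods, function(m) {
    sub <- metrics[metrics$method == m, , drop = FALSE]
    do.call(rbind, lapply(c("sensitivity", "specificity", "ppv", "npv"),
      function(stat) {
        ms <- meanSE(sub[[stat]])
        data.frame(method = m, metric = stat, mean = ms[["mean"]],
                   se = ms[["se"]])
      }))
  }))
  t2 <- do.call(rbind, lapply(methods, function(m) {
    v <- cutoffs[, m]; v <- v[!is.na(v)]
    data.frame(method = m, mean = mean(v),
               p2.5 = stats::quantile(v, 0.025, names = FALSE, type = 7),
               median = stats::median(v),
               p97.5 = stats::quantile(v, 0.975, names = FALSE, type = 7),
               n = length(v))
  }))
  res <- structure(list(table1 = t1, table2 = t2, cutoffs = cutoffs,
                        metrics = metrics, failures = failures,
                        scenario = scenario@name, seed = seed,
                        nReps = nReps, step = step),
                   class = "dafsStudy")
  if (!is.null(outDir)) writeStudy(res, outDir)
  res
}

#' Write study tables as TSV
#'
#' @param study A `dafsStudy` from [runStudy()].
#' @param outDir Output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeStudy <- function(study, outDir) {
  stopifnot(inherits(study, "dafsStudy"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1)) & names(df) != "n"
    df[num] <- lapply(df[num], function(v) sprintf("%.6g", v))
    df
  }
  utils::write.table(fmt(study$table1), file.path(outDir, "table1.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fmt(study$table2), file.path(outDir, "table2.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- c(sprintf("scenario: %s", study$scenario),
           sprintf("seed: %d", study$seed),
           sprintf("replicates: %d", study$nReps),
           sprintf("dafs grid step: %g", study$step),
           sprintf("failed replicates: %s",
                   paste(sprintf("%s=%d", names(study$failures),
                                 study$failures), collapse = " ")))
  writeLines(log, file.path(outDir, "run.log"))
  invisible(outDir)
}

#' @export
print.dafsStudy <- function(x, ...) {
  cat(sprintf("Cutoff study on scenario '%s': %d replicates (seed %d)\n",
              x$scenario, x$nReps, x$seed))
  cat("\nCutoff summaries:\n")
  print(x$table2, row.names = FALSE, digits = 5)
  cat("\nPerformance (mean +/- SE):\n")
  print(x$table1, row.names = FALSE, digits = 5)
  if (any(x$failures > 0)) {
    cat("\nFailed replicates:\n")
    print(x$failures)
  }
  invisible(x)
}
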