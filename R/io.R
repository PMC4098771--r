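#' Read a genes-by-samples expression table
#'
#' Reads a TSV or CSV table whose header row names the samples and whose
#' first column carries gene identifiers. Cells must all be numeric:
#' blank, `NA` or non-numeric cells raise an error naming the offending
#' gene and sample rather than being silently imputed; duplicate gene IDs
#' and ragged rows are errors as well.
#'
#' @param path File path; the delimiter is inferred from the extension
#'   (`.csv` is comma, everything else tab) unless given.
#' @param delimiter Field delimiter, overriding the extension rule.
#' @param scale Measurement scale of the table (see
#'   [ExpressionSample-class]).
#' @return An [ExpressionTable-class].
#' @export
readExpressionTable <- function(path, delimiter = NULL,
                                scale = c("raw_count", "rpkm", "fpkm", "log2")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, colClasses = "character",
                          comment.char = "", quote = "\"",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("table needs a gene-ID column and at least one sample")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate gene IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sampleNames <- colnames(df)[-1L]
  m <- matrix(NA_real_, nrow(df), length(sampleNames),
              dimnames = list(ids, sampleNames))
  for (j in seq_along(sampleNames)) {
    cell <- df[[j + 1L]]
    bad <- which(is.na(cell) | cell == "" | toupper(cell) == "NA")
    if (length(bad))
      stop(sprintf("missing value at gene '%s', sample '%s'",
                   ids[bad[1L]], sampleNames[j]))
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                   cell[bad[1L]], ids[bad[1L]], sampleNames[j]))
    m[, j] <- num
  }
  ExpressionTable(m, geneIds = ids, sampleNames = sampleNames, scale = scale)
}

#' Write an expression table as canonical TSV/CSV
#'
#' Canonical output: header `gene_id` followed by the sample names, one
#' row per gene, values printed with up to 15 significant digits so that
#' reading the file back reproduces the table exactly.
#'
#' @param table An [ExpressionTable-class].
#' @param path Output path; delimiter inferred from the extension unless
#'   given.
#' @param delimiter Field delimiter override.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(table, path, delimiter = NULL) {
  stopifnot(is(table, "ExpressionTable"))
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- exprValues(table)
  lines <- c(paste(c("gene_id", sampleName(table)), collapse = delimiter),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(geneIds(table)[i], sprintf("%.15g", m[i, ])),
                     collapse = delimiter), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a one-value-per-line expression vector
#'
#' @param path File with one numeric value per line (no header).
#' @param scale Measurement scale.
#' @param name Sample label.
#' @return An [ExpressionSample-class].
#' @export
readExpressionVector <- function(path,
                                 scale = c("raw_count", "rpkm", "fpkm", "log2"),
                                 name = basename(path)) {
  scale <- match.arg(scale)
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  v <- suppressWarnings(as.numeric(raw))
  if (anyNA(v))
    stop(sprintf("non-numeric value '%s' at line %d",
                 raw[which(is.na(v))[1L]], which(is.na(v))[1L]))
  ExpressionSample(v, scale = scale, name = name)
}

#' Extract one sample from a table
#'
#' @param table An [ExpressionTable-class].
#' @param sample Sample name or column index.
#' @return An [ExpressionSample-class] carrying the table's gene IDs.
#' @export
getSample <- function(table, sample) {
  stopifnot(is(table, "ExpressionTable"))
  if (is.character(sample)) {
    j <- match(sample, sampleName(table))
    if (is.na(j)) stop("no such sample: ", sample)
  } else {
    j <- as.integer(sample)
    if (j < 1L || j > ncol(exprValues(table))) stop("sample index out of range")
  }
  ExpressionSample(exprValues(table)[, j], scale = exprScale(table),
                   name = sampleName(table)[j], ids = geneIds(table))
}

#' Convert raw counts to RPKM
#'
#' Standard reads-per-kilobase-per-million scaling
#' \eqn{10^9 c / (N L)} with `N` the per-sample total mapped counts and
#' `L` the gene length in base pairs. Zeros map to zero exactly.
#'
#' @param table An [ExpressionTable-class] on the `raw_count` scale.
#' @param geneLengths Named vector of positive gene lengths (bp); every
#'   gene in the table must be present.
#' @return An [ExpressionTable-class] on the `rpkm` scale.
#' @export
toRpkm <- function(table, geneLengths) {
  stopifnot(is(table, "ExpressionTable"))
  if (exprScale(table) != "raw_count") stop("input must be on the raw_count scale")
  missing <- setdiff(geneIds(table), names(geneLengths))
  if (length(missing))
    stop("no length for genes: ", paste(missing, collapse = ", "))
  L <- as.numeric(geneLengths[geneIds(table)])
  if (any(!is.finite(L)) || any(L <= 0)) stop("gene lengths must be positive")
  m <- exprValues(table)
  N <- colSums(m)
  if (any(N <= 0)) stop("per-sample total counts must be positive")
  rpkm <- 1e9 * sweep(sweep(m, 1L, L, `/`), 2L, N, `/`)
  ExpressionTable(rpkm, geneIds = geneIds(table),
                  sampleNames = sampleName(table), scale = "rpkm")
}

#' Median-adjust an FPKM/RPKM table
#'
#' Divides each sample by its median expression over nonzero transcripts,
#' the per-sample normalization used for single-cell FPKM data before
#' log2 transformation. Using the nonzero median keeps the divisor
#' defined when zeros dominate a sample.
#'
#' @param table An [ExpressionTable-class] on the `fpkm` or `rpkm` scale.
#' @return The adjusted [ExpressionTable-class] (same scale).
#' @export
medianAdjust <- function(table) {
  stopifnot(is(table, "ExpressionTable"))
  if (!exprScale(table) %in% c("fpkm", "rpkm"))
    stop("median adjustment expects fpkm or rpkm input")
  m <- exprValues(table)
  for (j in seq_len(ncol(m))) {
    nz <- m[, j][m[, j] > 0]
    if (!length(nz))
      stop("all-zero sample: ", sampleName(table)[j])
    m[, j] <- m[, j] / stats::median(nz)
  }
  ExpressionTable(m, geneIds = geneIds(table), sampleNames = sampleName(table),
                  scale = exprScale(table))
}
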