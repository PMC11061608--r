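## Cross-cohort preprocessing: merge on shared genes, joint quantile
## normalization, gene-wise z-scoring.

#' Merge two cohorts on their shared genes
#'
#' Columns are all samples of `a` followed by all samples of `b`; rows are
#' the shared genes (matched case-insensitively) in `a`'s order and
#' spelling; each sample keeps (or receives) a source-cohort label.
#'
#' @param a,b [CohortExperiment-class] objects.
#' @param sourceA,sourceB source labels applied when the inputs carry none.
#' @return A merged [CohortExperiment-class] with `source_cohort` set for
#'   every sample.
#' @export
mergeCohorts <- function(a, b, sourceA = "cohort_a", sourceB = "cohort_b") {
  va <- exprValues(a); vb <- exprValues(b)
  idx <- .matchGenes(rownames(va), rownames(vb))
  shared <- which(!is.na(idx))
  if (!length(shared)) stop("no shared genes between the two cohorts")
  dup <- intersect(colnames(va), colnames(vb))
  if (length(dup))
    stop("duplicate sample identifier(s) across cohorts: ",
         paste(utils::head(dup, 5), collapse = ", "))
  values <- cbind(va[shared, , drop = FALSE],
                  vb[idx[shared], , drop = FALSE])
  rownames(values) <- rownames(va)[shared]
  fixSource <- function(x, fallback) {
    s <- sampleInfo(x)$source_cohort
    ifelse(is.na(s), fallback, s)
  }
  CohortExperiment(values,
                   source = c(fixSource(a, sourceA), fixSource(b, sourceB)),
                   histology = c(sampleInfo(a)$histology,
                                 sampleInfo(b)$histology),
                   referenceClass = c(sampleInfo(a)$reference_class,
                                      sampleInfo(b)$reference_class))
}

#' Quantile-normalize samples jointly
#'
#' Replaces each sample's values by the mean of the cross-sample order
#' statistics at its rank, so that afterwards every sample's sorted vector
#' is identical; ties within a sample receive the mean of the reference
#' values they span. Applied to the merged matrix across all sources
#' jointly. Idempotent, and rank order within each sample is preserved.
#'
#' @param x a [CohortExperiment-class] (or matrix) with at least 2 samples.
#' @return Object of the same kind with normalized values.
#' @export
quantileNormalize <- function(x) {
  values <- if (is(x, "SummarizedExperiment")) exprValues(x) else
    as.matrix(x)
  if (ncol(values) < 2L) stop("quantile normalization needs >= 2 samples")
  qn <- limma::normalizeQuantiles(values, ties = TRUE)
  dimnames(qn) <- dimnames(values)
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "exprs") <- qn
    x
  } else qn
}

#' Z-score gene rows
#'
#' Centers each gene row and scales it to unit standard deviation using the
#' population (divide-by-n) sd; zero-variance rows are dropped with a
#' warning.
#'
#' @param x a [CohortExperiment-class] (or matrix) with at least 2 samples.
#' @param sd `"population"` (default) or `"sample"` (n - 1 denominator).
#' @return Object of the same kind with scaled values (zero-variance rows
#'   removed).
#' @export
zscoreGenes <- function(x, sd = c("population", "sample")) {
  sd <- match.arg(sd)
  values <- if (is(x, "SummarizedExperiment")) exprValues(x) else
    as.matrix(x)
  if (ncol(values) < 2L) stop("z-scoring needs >= 2 samples")
  mu <- rowMeans(values)
  sdv <- if (sd == "population") sqrt(rowMeans((values - mu)^2)) else
    apply(values, 1L, stats::sd)
  zero <- sdv == 0
  if (any(zero))
    warning(sum(zero), " zero-variance gene row(s) dropped")
  z <- (values[!zero, , drop = FALSE] - mu[!zero]) / sdv[!zero]
  if (is(x, "SummarizedExperiment")) {
    out <- x[!zero, ]
    SummarizedExperiment::assay(out, "exprs") <- z
    out
  } else z
}
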