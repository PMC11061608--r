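#' Correlation-based neuroendocrine score
#'
#' For each sample, the expression vector over the available signature genes
#' is correlated (Pearson, by construction of the published score) with the
#' signature's NE reference mean profile (`r_ne`) and with its non-NE
#' reference mean profile (`r_nonne`); the NE score is
#' `(r_ne - r_nonne) / 2`, bounded in `[-1, 1]`. Samples resembling
#' neuroendocrine tumours score near +1, non-neuroendocrine samples near -1.
#'
#' Signature genes absent from the matrix are dropped symmetrically from
#' both reference vectors (pairwise deletion, no imputation); an error is
#' raised when coverage falls below `minCoverage`. A sample with zero
#' variance over the signature genes has an undefined correlation and is
#' reported as `NA` with a warning.
#'
#' @param expr a [CohortExperiment-class] (or genes x samples matrix) of
#'   log-scale expression; the score itself is scale-free but the unit used
#'   should be reported alongside results.
#' @param signature a [GeneSignature-class] with NE/NON_NE classes and
#'   reference profiles.
#' @param minCoverage minimum fraction of signature genes that must be
#'   present (default 0.8).
#' @param method correlation method, default `"pearson"`.
#' @return data.frame with one row per sample: `sample`, `score`, `r_ne`,
#'   `r_nonne`, `n_genes_used`.
#' @export
computeNEScores <- function(expr, signature, minCoverage = 0.8,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  values <- if (is(expr, "SummarizedExperiment")) exprValues(expr) else
    as.matrix(expr)
  cls <- geneClasses(signature)
  sigGenes <- names(cls)[cls %in% c("NE", "NON_NE")]
  if (!length(sigGenes) || length(unique(cls[sigGenes])) < 2L)
    stop("signature must contain both NE and NON_NE classes")
  idx <- .matchGenes(sigGenes, rownames(values))
  present <- !is.na(idx)
  if (mean(present) < minCoverage)
    stop("signature coverage ", round(100 * mean(present)), "% below the ",
         round(100 * minCoverage), "% floor; missing genes: ",
         paste(sigGenes[!present], collapse = ", "))
  used <- sigGenes[present]
  rp <- referenceProfiles(signature)[used, , drop = FALSE]
  sub <- values[idx[present], , drop = FALSE]
  nUsed <- length(used)

  res <- t(vapply(seq_len(ncol(sub)), function(j) {
    x <- sub[, j]
    if (stats::sd(x) == 0)
      return(c(NA_real_, NA_real_, NA_real_))
    rne <- stats::cor(x, rp[, "mean_NE"], method = method)
    rnn <- stats::cor(x, rp[, "mean_nonNE"], method = method)
    c((rne - rnn) / 2, rne, rnn)
  }, numeric(3)))
  if (anyNA(res))
    warning(sum(is.na(res[, 1])), " sample(s) with zero variance over the ",
            "signature genes; score undefined (NA)")
  data.frame(sample = colnames(sub), score = res[, 1], r_ne = res[, 2],
             r_nonne = res[, 3], n_genes_used = nUsed,
             stringsAsFactors = FALSE, row.names = NULL)
}
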