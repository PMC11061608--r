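#' Assign molecular subtypes by the dominant transcription factor
#'
#' Each sample is labelled by whichever of the four classifier transcription
#' factors (default ASCL1, NEUROD1, POU2F3, YAP1 -> subtypes A, N, P, Y) has
#' the highest expression in that sample, compared on the matrix's given log
#' scale without per-gene standardisation. Exact ties are broken by the
#' declared gene order and flagged.
#'
#' @param expr a [CohortExperiment-class] (or numeric genes x samples
#'   matrix) containing all four classifier genes (matched
#'   case-insensitively).
#' @param tfGenes ordered character vector of the classifier genes.
#' @param labels subtype labels, parallel to `tfGenes`; default the initials
#'   `A`, `N`, `P`, `Y` for the default classifiers, otherwise the gene
#'   names themselves.
#' @return A [SubtypePartition-class].
#' @examples
#' m <- matrix(c(5.1, 1.0, 0.2, 0.9), 4, 1,
#'             dimnames = list(c("ASCL1", "NEUROD1", "POU2F3", "YAP1"), "s1"))
#' subtypeCalls(assignSubtypes(CohortExperiment(m)))  # "A"
#' @export
assignSubtypes <- function(expr,
                           tfGenes = c("ASCL1", "NEUROD1", "POU2F3", "YAP1"),
                           labels = NULL) {
  values <- if (is(expr, "SummarizedExperiment")) exprValues(expr) else
    as.matrix(expr)
  idx <- .matchGenes(tfGenes, rownames(values))
  if (anyNA(idx))
    stop("classifier gene(s) missing from the expression matrix: ",
         paste(tfGenes[is.na(idx)], collapse = ", "))
  if (is.null(labels)) {
    labels <- if (identical(toupper(tfGenes),
                            c("ASCL1", "NEUROD1", "POU2F3", "YAP1")))
      c("A", "N", "P", "Y") else tfGenes
  }
  stopifnot(length(labels) == length(tfGenes))
  tf <- t(values[idx, , drop = FALSE])
  colnames(tf) <- tfGenes
  rownames(tf) <- colnames(values)
  win <- apply(tf, 1L, which.max)          # first maximum = declared order
  tie <- apply(tf, 1L, function(v) sum(v == max(v)) > 1L)
  calls <- factor(labels[win], levels = labels)
  names(calls) <- rownames(tf)
  names(tie) <- rownames(tf)
  new("SubtypePartition", subtype = calls, tfValues = tf, tie = tie,
      tfGenes = tfGenes)
}
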