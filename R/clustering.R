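## Signature-restricted hierarchical clustering, reference-anchored cluster
## labelling, and exclusion of data-source-driven principal components
## before gene selection.

#' Hierarchical clustering on a gene signature
#'
#' Restricts the matrix to the signature genes (case-insensitive match),
#' z-scores the gene rows (population sd) and clusters the samples.
#' Defaults are Euclidean distance with Ward-type linkage (`"ward.D2"`);
#' both are configurable and stamped into the model parameters. Samples are
#' put in lexicographic order before clustering so the output is invariant
#' to input column order (fixed tie-breaking). The flat assignment cuts the
#' tree at `k` clusters.
#'
#' @param m a [CohortExperiment-class] (or genes x samples matrix).
#' @param signature a [GeneSignature-class]; an error is raised when fewer
#'   than 50% of its genes are present, a warning below 80%.
#' @param k number of flat clusters (default 2, for anchor detection).
#' @param distance a [stats::dist] method name.
#' @param linkage a [stats::hclust] method name.
#' @return A [ClusterModel-class].
#' @export
hclusterSignature <- function(m, signature, k = 2L,
                              distance = "euclidean", linkage = "ward.D2") {
  values <- if (is(m, "SummarizedExperiment")) exprValues(m) else
    as.matrix(m)
  if (k < 1L) stop("k must be >= 1")
  if (k > ncol(values)) stop("k exceeds the number of samples")
  sig <- signatureGenes(signature)
  idx <- .matchGenes(sig, rownames(values))
  cov <- mean(!is.na(idx))
  if (cov < 0.5)
    stop("only ", round(100 * cov), "% of signature genes present (< 50%)")
  if (cov < 0.8)
    warning("signature coverage ", round(100 * cov), "% (< 80%)")
  sub <- values[idx[!is.na(idx)], , drop = FALSE]
  sub <- .zscoreRows(sub, warn = FALSE)
  if (nrow(sub) < 2L) stop("fewer than 2 usable signature genes")
  sub <- sub[, order(colnames(sub)), drop = FALSE]   # canonical sample order
  tree <- stats::hclust(stats::dist(t(sub), method = distance),
                        method = linkage)
  assignment <- stats::cutree(tree, k = k)
  new("ClusterModel", tree = tree, assignment = assignment,
      params = list(distance = distance, linkage = linkage, k = as.integer(k),
                    signature = signature@name, n_genes_used = nrow(sub)))
}

#' Label the cluster anchored by reference samples
#'
#' The flat cluster containing the strict majority of the samples annotated
#' with `anchorClass` is labelled as the anchor cluster; when no cluster
#' holds a majority the plurality cluster is used with a warning (ties
#' resolved toward the lowest cluster id). Exactly one cluster ever
#' receives the anchor label.
#'
#' @param model a [ClusterModel-class].
#' @param annotations data.frame with columns `sample` and
#'   `reference_class` (e.g. from [sampleInfo] or the simulator).
#' @param anchorClass reference class to anchor on, e.g. `"SMARCA4-UT"`.
#' @return A list: `anchor_cluster` (id), `members` (samples in it),
#'   `labels` (named `"anchor"`/`"other"` per sample), `anchor_samples`.
#' @export
labelClusters <- function(model, annotations, anchorClass) {
  assignment <- clusterAssignment(model)
  anchors <- annotations$sample[annotations$reference_class %in% anchorClass]
  anchors <- intersect(anchors, names(assignment))
  if (!length(anchors))
    stop("no samples annotated with anchor class '", anchorClass, "'")
  counts <- table(assignment[anchors])
  best <- names(counts)[which.max(counts)]     # ties -> lowest cluster id
  if (max(counts) <= length(anchors) / 2)
    warning("no cluster holds a strict majority of anchor samples; ",
            "plurality cluster ", best, " labelled")
  labels <- ifelse(assignment == as.integer(best), "anchor", "other")
  names(labels) <- names(assignment)
  list(anchor_cluster = as.integer(best),
       members = names(assignment)[assignment == as.integer(best)],
       labels = labels, anchor_samples = anchors)
}

#' Exclude source-driven principal components and pool top-loading genes
#'
#' PCA is run on the gene-wise z-scored matrix with samples as
#' observations. Each of the first `nPCs` components is tested for
#' association with the data source: with two sources a two-sided
#' Wilcoxon rank-sum test on the PC scores with the rank-biserial
#' correlation as effect size, with more sources a Kruskal-Wallis test
#' (p-value criterion only). A PC is excluded when `p < assocAlpha` and
#' (two sources) the rank-biserial effect is at least 0.5 - i.e. the
#' component mostly separates the cohorts, not the biology. The selected
#' gene set is the union, duplicates collapsed, of the `nTop` genes with the
#' largest absolute loading on each retained PC. `excludePCs` overrides the
#' statistical rule with an explicit index list.
#'
#' @param m a [CohortExperiment-class] carrying at least two distinct
#'   `source_cohort` labels (or a matrix plus `source`).
#' @param nPCs how many leading PCs to consider (default 4).
#' @param nTop genes taken per retained PC (default 50).
#' @param assocAlpha significance level for source association (default
#'   0.05).
#' @param excludePCs optional explicit PC indices to exclude instead of the
#'   statistical rule.
#' @param source per-sample source labels when `m` is a plain matrix.
#' @return A [BatchPCReport-class].
#' @export
batchAwareGeneSelection <- function(m, nPCs = 4L, nTop = 50L,
                                    assocAlpha = 0.05, excludePCs = NULL,
                                    source = NULL) {
  if (is(m, "SummarizedExperiment")) {
    values <- exprValues(m)
    if (is.null(source)) source <- sampleInfo(m)$source_cohort
  } else {
    values <- as.matrix(m)
  }
  if (is.null(source) || length(unique(source)) < 2L)
    stop("at least two source cohorts are required")
  if (ncol(values) < nPCs + 1L)
    stop("need at least nPCs + 1 samples")
  z <- .zscoreRows(values, warn = FALSE)
  pca <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  nPCs <- min(nPCs, ncol(pca$x))
  varFrac <- pca$sdev^2 / sum(pca$sdev^2)
  src <- factor(source)

  stat <- pval <- eff <- numeric(nPCs)
  for (i in seq_len(nPCs)) {
    sc <- pca$x[, i]
    if (nlevels(src) == 2L) {
      w <- stats::wilcox.test(sc ~ src, exact = FALSE)
      n1 <- sum(src == levels(src)[1L]); n2 <- sum(src == levels(src)[2L])
      stat[i] <- unname(w$statistic)
      pval[i] <- w$p.value
      eff[i] <- abs(1 - 2 * stat[i] / (n1 * n2))   # rank-biserial |r|
    } else {
      kw <- stats::kruskal.test(sc, src)
      stat[i] <- unname(kw$statistic)
      pval[i] <- kw$p.value
      eff[i] <- NA_real_
    }
  }
  if (is.null(excludePCs)) {
    excluded <- pval < assocAlpha &
      (is.na(eff) | eff >= 0.5)
    ## multi-source: p-value criterion only (eff is NA)
    excluded[is.na(excluded)] <- FALSE
  } else {
    excluded <- seq_len(nPCs) %in% excludePCs
  }
  retained <- which(!excluded)
  if (!length(retained))
    stop("every leading PC is source-associated; pass excludePCs to ",
         "override the exclusion rule explicitly")
  topGenes <- lapply(retained, function(i) {
    ld <- pca$rotation[, i]
    names(sort(abs(ld), decreasing = TRUE))[seq_len(min(nTop, length(ld)))]
  })
  selected <- unique(unlist(topGenes))
  pcTab <- data.frame(pc = seq_len(nPCs), var_frac = varFrac[seq_len(nPCs)],
                      statistic = stat, p_value = pval, effect = eff,
                      excluded = excluded, row.names = NULL)
  new("BatchPCReport", pcStats = pcTab, retained = as.integer(retained),
      selectedGenes = selected,
      params = list(n_pcs = as.integer(nPCs), n_top = as.integer(nTop),
                    assoc_alpha = assocAlpha,
                    manual_exclusion = !is.null(excludePCs)))
}
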