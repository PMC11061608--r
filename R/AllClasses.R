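#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom limma normalizeQuantiles
#' @importFrom fgsea gmtPathways
#' @importFrom stats cor cor.test cutree dist hclust kruskal.test median
#'   p.adjust pnorm prcomp rbinom rnorm sd setNames shapiro.test t.test
#'   wilcox.test
#' @importFrom utils combn head read.delim write.table
NULL

setOldClass("hclust")

## ---------------------------------------------------------------------------
## CohortExperiment: genes x samples log-abundance with per-sample metadata
## ---------------------------------------------------------------------------

#' Cohort of log-scale expression profiles
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' one `exprs` assay of finite log-scale abundances (e.g. log2(TPM + 1) or
#' log RPKM), with gene symbols as rownames, sample identifiers as colnames
#' and three mandatory per-sample annotation columns: `source_cohort`,
#' `histology` and `reference_class`.
#'
#' Gene identifiers are HGNC symbols; duplicates are forbidden even after
#' case-normalisation and whitespace trimming, because downstream gene lookup
#' (`tf` genes, signatures) is case-insensitive.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @export
setClass("CohortExperiment", contains = "SummarizedExperiment")

.validCohortExperiment <- function(object) {
  msg <- character()
  if (!("exprs" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'exprs' is required")
  v <- SummarizedExperiment::assay(object, "exprs")
  if (!is.numeric(v))
    msg <- c(msg, "expression values must be numeric")
  if (is.numeric(v) && any(!is.finite(v)))
    msg <- c(msg, "expression values must all be finite")
  g <- rownames(object)
  s <- colnames(object)
  if (is.null(g) || is.null(s))
    msg <- c(msg, "gene rownames and sample colnames are required")
  if (!is.null(g) && anyDuplicated(toupper(trimws(g))))
    msg <- c(msg, "duplicate gene identifiers (case-insensitive)")
  if (!is.null(s) && anyDuplicated(s))
    msg <- c(msg, "duplicate sample identifiers")
  need <- c("source_cohort", "histology", "reference_class")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("missing colData column(s): ", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
}
setValidity("CohortExperiment", .validCohortExperiment)

#' Construct a CohortExperiment
#'
#' @param values numeric matrix, genes in rows (rownames = HGNC symbols),
#'   samples in columns (colnames = unique identifiers), finite log-scale
#'   abundances.
#' @param source per-sample source-cohort label (recycled if length 1).
#' @param histology per-sample histology label (recycled).
#' @param referenceClass per-sample reference class, e.g. `"SMARCA4-UT"`,
#'   `"SCCOHT"`, `"SCLC"` (recycled; `NA` when unknown).
#' @return A [CohortExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("ASCL1", "NEUROD1", "YAP1"), c("s1", "s2")))
#' CohortExperiment(m)
#' @export
CohortExperiment <- function(values, source = NA_character_,
                             histology = NA_character_,
                             referenceClass = NA_character_) {
  values <- as.matrix(values)
  n <- ncol(values)
  cd <- S4Vectors::DataFrame(
    source_cohort   = as.character(rep_len(source, n)),
    histology       = as.character(rep_len(histology, n)),
    reference_class = as.character(rep_len(referenceClass, n)),
    row.names = colnames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values), colData = cd)
  new("CohortExperiment", se)
}

#' @describeIn CohortExperiment expression matrix accessor.
#' @param x a `CohortExperiment`.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn CohortExperiment per-sample source-cohort labels.
#' @export
sampleSource <- function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$source_cohort, colnames(x))
}

#' @describeIn CohortExperiment per-sample annotation as a data.frame
#'   (columns `sample`, `source_cohort`, `histology`, `reference_class`).
#' @export
sampleInfo <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(sample = colnames(x),
             source_cohort = cd$source_cohort,
             histology = cd$histology,
             reference_class = cd$reference_class,
             stringsAsFactors = FALSE, row.names = NULL)
}

setMethod("show", "CohortExperiment", function(object) {
  cat("CohortExperiment:", nrow(object), "genes x", ncol(object), "samples\n")
  src <- unique(SummarizedExperiment::colData(object)$source_cohort)
  cat("  sources:", paste(utils::head(src, 5), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## MutationTable
## ---------------------------------------------------------------------------

#' Declared MAF variant-classification vocabulary
#'
#' Raw classification terms accepted without remapping. Terms outside this
#' list are retained as `"OTHER"` with a warning.
#' @export
mafVocabulary <- c(
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Frame_Shift_Del", "Frame_Shift_Ins", "Splice_Site",
  "In_Frame_Del", "In_Frame_Ins", "Silent",
  "5'UTR", "3'UTR", "5'Flank", "3'Flank", "Intron", "IGR", "RNA",
  "Start_Codon_SNP", "OTHER")

#' Per-sample somatic mutation records
#'
#' Holds the four MAF columns the screen uses: sample, gene (HGNC symbol),
#' raw variant classification (from [mafVocabulary]) and protein change.
#' `(sample, gene, protein_change)` triples must be unique.
#'
#' @slot records a [S4Vectors::DataFrame] with columns `sample`, `gene`,
#'   `variant_classification`, `protein_change`.
#' @export
setClass("MutationTable", representation(records = "DataFrame"))

.validMutationTable <- function(object) {
  r <- object@records
  need <- c("sample", "gene", "variant_classification", "protein_change")
  if (!all(need %in% colnames(r)))
    return(paste("records must have columns", paste(need, collapse = ", ")))
  if (nrow(r) && !all(r$variant_classification %in% mafVocabulary))
    return("variant_classification outside the declared vocabulary")
  if (anyDuplicated(paste(r$sample, r$gene, r$protein_change, sep = "\r")))
    return("duplicate (sample, gene, protein_change) triples")
  TRUE
}
setValidity("MutationTable", .validMutationTable)

#' Construct a MutationTable
#'
#' Unknown classification terms are mapped to `"OTHER"`, keeping the record,
#' with one warning reporting how many were remapped.
#'
#' @param sample,gene,variant_classification,protein_change parallel
#'   character vectors (one element per variant record). `protein_change`
#'   defaults to `""`.
#' @return A [MutationTable-class].
#' @export
MutationTable <- function(sample = character(), gene = character(),
                          variant_classification = character(),
                          protein_change = "") {
  n <- length(sample)
  vc <- as.character(variant_classification)
  unknown <- !(vc %in% mafVocabulary)
  if (any(unknown)) {
    warning(sum(unknown), " variant classification term(s) outside the ",
            "declared vocabulary mapped to OTHER")
    vc[unknown] <- "OTHER"
  }
  rec <- S4Vectors::DataFrame(
    sample = as.character(sample), gene = as.character(gene),
    variant_classification = vc,
    protein_change = as.character(rep_len(protein_change, n)))
  new("MutationTable", records = rec)
}

#' @describeIn MutationTable variant records as a base data.frame, preserved
#'   in input order.
#' @param x a `MutationTable`.
#' @export
mutationRecords <- function(x) as.data.frame(x@records)

setMethod("show", "MutationTable", function(object) {
  r <- object@records
  cat("MutationTable:", nrow(r), "records,",
      length(unique(r$sample)), "samples,",
      length(unique(r$gene)), "genes\n")
})

setMethod("length", "MutationTable", function(x) nrow(x@records))

## ---------------------------------------------------------------------------
## GeneSignature
## ---------------------------------------------------------------------------

#' Named gene set, optionally split into NE / non-NE classes
#'
#' A plain member set has every gene in class `"MEMBER"`. A two-class
#' neuroendocrine signature labels each gene `"NE"` or `"NON_NE"` and must
#' then carry a reference profile (per-gene mean expression in the NE and
#' non-NE reference groups) for every classed gene; the NE score correlates
#' each sample against those two profiles.
#'
#' @slot name signature name.
#' @slot members named character vector, gene -> class in
#'   `{"NE","NON_NE","MEMBER"}`.
#' @slot referenceProfiles numeric matrix (genes x `c("mean_NE","mean_nonNE")`),
#'   possibly with zero rows when no classed genes exist.
#' @export
setClass("GeneSignature",
         representation(name = "character", members = "character",
                        referenceProfiles = "matrix"))

.validGeneSignature <- function(object) {
  if (!length(object@members)) return("signature has no genes")
  if (is.null(names(object@members)) || any(!nzchar(names(object@members))))
    return("members must be named by gene")
  if (!all(object@members %in% c("NE", "NON_NE", "MEMBER")))
    return("classes must be NE, NON_NE or MEMBER")
  if (anyDuplicated(toupper(trimws(names(object@members)))))
    return("duplicate genes in signature")
  classed <- names(object@members)[object@members %in% c("NE", "NON_NE")]
  if (length(classed)) {
    rp <- object@referenceProfiles
    if (!all(c("mean_NE", "mean_nonNE") %in% colnames(rp)))
      return("NE/NON_NE classes present but reference profiles absent")
    if (!all(classed %in% rownames(rp)))
      return(paste0("reference profile missing for: ",
                    paste(setdiff(classed, rownames(rp)), collapse = ", ")))
    if (any(!is.finite(rp)))
      return("reference profiles must be finite")
  }
  TRUE
}
setValidity("GeneSignature", .validGeneSignature)

#' Construct a GeneSignature
#'
#' @param name signature name.
#' @param genes character vector of gene symbols, or a named character vector
#'   of classes (gene -> class) when `classes` is `NULL`.
#' @param classes per-gene class in `{"NE","NON_NE","MEMBER"}`; default all
#'   `"MEMBER"`.
#' @param referenceProfiles numeric matrix with columns `mean_NE`,
#'   `mean_nonNE` and one row per classed gene. Required whenever any gene
#'   has class `NE`/`NON_NE`.
#' @export
GeneSignature <- function(name, genes, classes = NULL,
                          referenceProfiles = NULL) {
  if (is.null(classes)) {
    if (!is.null(names(genes)) && all(genes %in% c("NE", "NON_NE", "MEMBER"))) {
      members <- genes
    } else {
      members <- stats::setNames(rep("MEMBER", length(genes)), genes)
    }
  } else {
    members <- stats::setNames(as.character(classes), genes)
  }
  if (is.null(referenceProfiles)) {
    referenceProfiles <- matrix(numeric(), nrow = 0, ncol = 2,
                                dimnames = list(NULL, c("mean_NE", "mean_nonNE")))
  }
  new("GeneSignature", name = as.character(name), members = members,
      referenceProfiles = as.matrix(referenceProfiles))
}

#' @describeIn GeneSignature gene symbols in the signature.
#' @param x a `GeneSignature`.
#' @export
signatureGenes <- function(x) names(x@members)

#' @describeIn GeneSignature named vector of gene classes.
#' @export
geneClasses <- function(x) x@members

#' @describeIn GeneSignature reference mean profiles (matrix, possibly 0-row).
#' @export
referenceProfiles <- function(x) x@referenceProfiles

setMethod("show", "GeneSignature", function(object) {
  tab <- table(object@members)
  cat("GeneSignature '", object@name, "': ", length(object@members),
      " genes (", paste(names(tab), tab, sep = "=", collapse = ", "), ")\n",
      sep = "")
})

## ---------------------------------------------------------------------------
## SubtypePartition
## ---------------------------------------------------------------------------

#' Per-sample molecular subtype calls
#'
#' Result of the dominant-transcription-factor rule: each sample is labelled
#' by the transcription factor with the highest expression among the four
#' classifiers, ties broken by declared gene order and flagged.
#'
#' @slot subtype named factor, sample -> subtype label.
#' @slot tfValues samples x 4 matrix of the classifier expression values.
#' @slot tie named logical, `TRUE` where two or more factors tied at the max.
#' @slot tfGenes the (ordered) classifier genes.
#' @export
setClass("SubtypePartition",
         representation(subtype = "factor", tfValues = "matrix",
                        tie = "logical", tfGenes = "character"))

.validSubtypePartition <- function(object) {
  n <- length(object@subtype)
  if (nrow(object@tfValues) != n || length(object@tie) != n)
    return("subtype, tfValues and tie must cover the same samples")
  if (ncol(object@tfValues) != length(object@tfGenes))
    return("tfValues columns must match tfGenes")
  ## the call must be the arg-max of the stored values (first max on ties)
  lab <- levels(object@subtype)[apply(object@tfValues, 1, which.max)]
  if (n && !identical(lab, as.character(object@subtype)))
    return("subtype must equal the arg-max of tfValues")
  TRUE
}
setValidity("SubtypePartition", .validSubtypePartition)

#' @describeIn SubtypePartition named factor of subtype calls.
#' @param x a `SubtypePartition`.
#' @export
subtypeCalls <- function(x) x@subtype

#' @describeIn SubtypePartition calls, classifier values and tie flags as a
#'   data.frame.
#' @export
subtypeTable <- function(x) {
  data.frame(sample = names(x@subtype), subtype = as.character(x@subtype),
             x@tfValues, tie = x@tie, stringsAsFactors = FALSE,
             row.names = NULL, check.names = FALSE)
}

setMethod("show", "SubtypePartition", function(object) {
  cat("SubtypePartition:", length(object@subtype), "samples\n")
  print(table(object@subtype))
  if (any(object@tie)) cat("  ties:", sum(object@tie), "\n")
})

## ---------------------------------------------------------------------------
## ClusterModel & BatchPCReport
## ---------------------------------------------------------------------------

#' Hierarchical clustering of samples on a gene signature
#'
#' @slot tree the `hclust` linkage tree (one merge per internal node).
#' @slot assignment named integer, sample -> flat cluster id at the stored `k`.
#' @slot params list: `distance`, `linkage`, `k`, `signature`, `n_genes_used`.
#' @export
setClass("ClusterModel",
         representation(tree = "hclust", assignment = "integer",
                        params = "list"))

.validClusterModel <- function(object) {
  n <- length(object@assignment)
  if (nrow(object@tree$merge) != n - 1)
    return("tree must have n_samples - 1 merges")
  k <- object@params$k
  if (length(unique(object@assignment)) != min(k, n))
    return("flat assignment must have k clusters")
  TRUE
}
setValidity("ClusterModel", .validClusterModel)

#' @describeIn ClusterModel named cluster assignment at the stored `k`.
#' @param x a `ClusterModel`.
#' @export
clusterAssignment <- function(x) x@assignment

#' @describeIn ClusterModel the `hclust` tree.
#' @export
clusterTree <- function(x) x@tree

setMethod("show", "ClusterModel", function(object) {
  p <- object@params
  cat("ClusterModel:", length(object@assignment), "samples, k =", p$k,
      "|", p$distance, "/", p$linkage, "on", p$n_genes_used, "genes\n")
})

#' Source-associated principal component report
#'
#' Produced by [batchAwareGeneSelection]: each leading PC is tested for
#' association with the data source; associated PCs are excluded and the top
#' loading genes of the retained PCs are pooled.
#'
#' @slot pcStats per-PC data.frame: `pc`, `var_frac`, `statistic`, `p_value`,
#'   `effect` (rank-biserial, two sources), `excluded`.
#' @slot retained indices of retained PCs.
#' @slot selectedGenes union of top-loading genes over the retained PCs.
#' @slot params list of the parameters used.
#' @export
setClass("BatchPCReport",
         representation(pcStats = "data.frame", retained = "integer",
                        selectedGenes = "character", params = "list"))

.validBatchPCReport <- function(object) {
  excl <- object@pcStats$pc[object@pcStats$excluded]
  if (length(intersect(excl, object@retained)))
    return("excluded PCs must not be retained")
  nmax <- object@params$n_top * nrow(object@pcStats)
  if (length(object@selectedGenes) > nmax)
    return("more selected genes than n_top x PCs considered")
  TRUE
}
setValidity("BatchPCReport", .validBatchPCReport)

#' @describeIn BatchPCReport selected (batch-robust) genes.
#' @param x a `BatchPCReport`.
#' @export
selectedGenes <- function(x) x@selectedGenes

#' @describeIn BatchPCReport per-PC association statistics.
#' @export
pcStats <- function(x) x@pcStats

setMethod("show", "BatchPCReport", function(object) {
  cat("BatchPCReport: retained PC", paste(object@retained, collapse = ", "),
      "->", length(object@selectedGenes), "genes\n")
})
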