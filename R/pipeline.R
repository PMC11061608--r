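## End-to-end orchestration: subtype -> mutation screen -> NE score ->
## integration -> clustering -> group statistics, with a per-sample summary
## table and a transparent reclassification heuristic.

#' Pipeline configuration
#'
#' Collects inputs (in-memory objects or file paths) and stage parameters
#' for [runPipeline]. Any input given as a character path is read with the
#' matching reader at run time.
#'
#' @param expression [CohortExperiment-class] or path (TSV/GCT).
#' @param mutations [MutationTable-class] or path, optional.
#' @param annotations data.frame (`sample`, `source_cohort`, `histology`,
#'   `reference_class`) or path, optional (defaults to the expression
#'   object's own sample metadata).
#' @param signature [GeneSignature-class] or path, required for the NE-score
#'   and clustering stages.
#' @param stages character subset of
#'   `c("subtype","mutations","nescore","integrate","cluster","stats")`;
#'   an empty vector yields an empty report.
#' @param genotypeGenes genes reported in the genotype grid.
#' @param threshold,strict prevalence-screen parameters
#'   (see [prevalentGenes]).
#' @param k,distance,linkage clustering parameters.
#' @param anchorClass reference class anchoring the cluster label.
#' @param nPCs,nTop,assocAlpha batch-PC gene-selection parameters; batch-PC
#'   selection runs when the cohort has two or more sources.
#' @param alpha significance level for the statistics stage.
#' @param seed integer seed recorded with the run.
#' @param outdir optional directory; when set, every stage writes its TSV.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(expression, mutations = NULL, annotations = NULL,
                           signature = NULL,
                           stages = c("subtype", "mutations", "nescore",
                                      "integrate", "cluster", "stats"),
                           genotypeGenes = c("TP53", "RB1", "SMARCA4"),
                           threshold = 0.5, strict = FALSE,
                           k = 2L, distance = "euclidean",
                           linkage = "ward.D2",
                           anchorClass = "SMARCA4-UT",
                           nPCs = 4L, nTop = 50L, assocAlpha = 0.05,
                           alpha = 0.05, seed = 1L, outdir = NULL) {
  allStages <- c("subtype", "mutations", "nescore", "integrate", "cluster",
                 "stats")
  stopifnot(all(stages %in% allStages))
  stages <- allStages[allStages %in% stages]
  for (p in list(expression, mutations, annotations, signature)) {
    if (is.character(p) && !file.exists(p))
      stop("input file not found: ", p)
  }
  structure(list(expression = expression, mutations = mutations,
                 annotations = annotations, signature = signature,
                 stages = stages, genotypeGenes = genotypeGenes,
                 threshold = threshold, strict = strict, k = as.integer(k),
                 distance = distance, linkage = linkage,
                 anchorClass = anchorClass, nPCs = as.integer(nPCs),
                 nTop = as.integer(nTop), assocAlpha = assocAlpha,
                 alpha = alpha, seed = as.integer(seed), outdir = outdir),
            class = "PipelineConfig")
}

.loadInput <- function(x, reader) if (is.character(x)) reader(x) else x

#' Run the reclassification pipeline
#'
#' Executes the enabled stages in order, collecting per-stage outputs and a
#' per-sample summary with columns mirroring a revised-classification
#' table: subtype call, genotype (T/M/O/WT per gene), NE score, cluster
#' label, and a transparent heuristic `candidate` flag. A sample is flagged
#' `"SMARCA4-deficient candidate"` when its SMARCA4 genotype is mutant, its
#' NE score falls below the cohort median and (when clustering ran) it sits
#' in the anchor cluster; the flag is a screening heuristic, not a
#' diagnosis, which requires pathology.
#'
#' A stage failure aborts with an error naming the stage; stages completed
#' so far are attached to the condition as `partial`.
#'
#' @param config a [pipelineConfig] object.
#' @return A list of class `PipelineReport`: per-stage results plus
#'   `summary` (data.frame) and `params`.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  report <- list(params = unclass(config)[setdiff(names(config),
                                                  c("expression", "mutations",
                                                    "annotations",
                                                    "signature"))])
  if (!length(config$stages)) {
    return(structure(list(params = report$params, summary = NULL),
                     class = "PipelineReport"))
  }

  runStage <- function(name, fun) {
    tryCatch(fun(), error = function(e) {
      err <- simpleError(paste0("pipeline stage '", name, "' failed: ",
                                conditionMessage(e)))
      err$partial <- report
      stop(err)
    })
  }

  expr <- .loadInput(config$expression, readExpressionMatrix)
  ann <- .loadInput(config$annotations, function(p) .readTSVraw(p))
  if (is.null(ann)) ann <- sampleInfo(expr)
  mut <- .loadInput(config$mutations, readMutationTable)
  sig <- .loadInput(config$signature, readSignature)
  samples <- colnames(expr)
  summary <- data.frame(sample = samples, stringsAsFactors = FALSE)

  if ("subtype" %in% config$stages) {
    part <- runStage("subtype", function() assignSubtypes(expr))
    report$subtype <- part
    summary$subtype <- as.character(subtypeCalls(part)[samples])
    summary$tie <- part@tie[samples]
  }

  if ("mutations" %in% config$stages && !is.null(mut)) {
    screen <- runStage("mutations", function() {
      part <- report$subtype
      prev <- if (!is.null(part))
        prevalentGenes(mut, part, config$threshold, config$strict)
      geno <- genotypeSummary(mut, samples, config$genotypeGenes)
      list(prevalent = prev,
           exclusive = if (!is.null(prev)) exclusiveGenes(prev),
           genotype = geno)
    })
    report$mutations <- screen
    code <- c(TRUNCATING = "T", MISSENSE = "M", OTHER = "O", WT = "WT")
    for (gname in config$genotypeGenes)
      summary[[gname]] <- unname(code[screen$genotype[samples, gname]])
  }

  if ("nescore" %in% config$stages && !is.null(sig)) {
    ne <- runStage("nescore", function() computeNEScores(expr, sig))
    report$nescore <- ne
    summary$ne_score <- ne$score[match(samples, ne$sample)]
  }

  integrated <- expr
  if ("integrate" %in% config$stages) {
    integrated <- runStage("integrate", function() quantileNormalize(expr))
    report$integrated <- integrated
  }

  if ("cluster" %in% config$stages && !is.null(sig)) {
    cl <- runStage("cluster", function() {
      nSources <- length(unique(ann$source_cohort))
      mat <- integrated
      pcReport <- NULL
      if (nSources >= 2L) {
        pcReport <- batchAwareGeneSelection(mat, nPCs = config$nPCs,
                                            nTop = config$nTop,
                                            assocAlpha = config$assocAlpha,
                                            source = ann$source_cohort)
      }
      model <- hclusterSignature(mat, sig, k = config$k,
                                 distance = config$distance,
                                 linkage = config$linkage)
      anchor <- if (config$anchorClass %in% ann$reference_class)
        labelClusters(model, ann, config$anchorClass)
      list(model = model, anchor = anchor, pc_report = pcReport)
    })
    report$cluster <- cl
    summary$cluster <- unname(clusterAssignment(cl$model)[samples])
    if (!is.null(cl$anchor))
      summary$anchor_cluster <- samples %in% cl$anchor$members
  }

  if ("stats" %in% config$stages && !is.null(summary$ne_score) &&
      "SMARCA4" %in% colnames(summary)) {
    report$stats <- runStage("stats", function() {
      grp <- ifelse(summary$SMARCA4 == "WT", "SMARCA4_WT", "SMARCA4_mutant")
      if (length(unique(grp)) == 2L)
        compareTwoGroups(summary$ne_score, grp, alpha = config$alpha)
    })
  }

  ## transparent reclassification heuristic (screening only)
  if (all(c("SMARCA4", "ne_score") %in% colnames(summary))) {
    lowNE <- summary$ne_score < stats::median(summary$ne_score, na.rm = TRUE)
    inAnchor <- if (!is.null(summary$anchor_cluster))
      summary$anchor_cluster else TRUE
    summary$candidate <- ifelse(summary$SMARCA4 != "WT" & lowNE & inAnchor,
                                "SMARCA4-deficient candidate", "")
  }

  report$summary <- summary
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(summary, file.path(config$outdir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(report, class = "PipelineReport")
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat("PipelineReport: stages", paste(x$params$stages, collapse = ", "), "\n")
  if (!is.null(x$summary)) {
    cat("summary (", nrow(x$summary), " samples):\n", sep = "")
    print(utils::head(x$summary))
  } else cat("(empty report)\n")
  invisible(x)
}
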