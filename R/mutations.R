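## The per-subtype mutation screen: variant classification, prevalence
## filtering, subtype-exclusive gene extraction (Venn partition) and the
## per-sample genotype grid.

.truncatingTerms <- c("Nonsense_Mutation", "Frame_Shift_Del",
                      "Frame_Shift_Ins", "Splice_Site", "Nonstop_Mutation")

#' Classify a raw variant term as truncating / missense / other
#'
#' Nonsense, frameshift (insertion or deletion), splice-site and nonstop
#' variants are `TRUNCATING` (expected to abolish protein function);
#' missense variants are `MISSENSE`; every other term, including unknown
#' ones, is `OTHER`. `WT` never arises here - it denotes the absence of any
#' record for a (sample, gene) pair and is produced by [genotypeSummary].
#'
#' @param variant_classification character vector of raw MAF terms.
#' @param protein_change optional parallel protein-change strings (kept in
#'   the interface for dialects that only encode frameshifts there; unused
#'   by the default rule).
#' @return Character vector in `{"TRUNCATING","MISSENSE","OTHER"}`.
#' @examples
#' classifyVariant("Nonsense_Mutation", "p.R1077*")  # TRUNCATING
#' classifyVariant("Missense_Mutation", "p.G1232S")  # MISSENSE
#' @export
classifyVariant <- function(variant_classification, protein_change = NULL) {
  vc <- as.character(variant_classification)
  out <- rep("OTHER", length(vc))
  out[vc %in% .truncatingTerms] <- "TRUNCATING"
  out[vc == "Missense_Mutation"] <- "MISSENSE"
  out
}

#' Per-subtype prevalent mutated genes
#'
#' A gene is prevalent in a subtype when the fraction of that subtype's
#' samples carrying at least one record for the gene reaches the threshold
#' (default 50%). A sample counts once per gene regardless of how many
#' variants it carries.
#'
#' @param mut a [MutationTable-class].
#' @param partition a [SubtypePartition-class] (or named subtype vector).
#' @param threshold prevalence threshold, default `0.5`.
#' @param strict if `FALSE` (default) inclusion requires fraction `>=`
#'   threshold ("at least 50%"); if `TRUE`, strictly `>` ("over 50%").
#' @return Named list, subtype -> character vector of prevalent genes.
#' @export
prevalentGenes <- function(mut, partition, threshold = 0.5, strict = FALSE) {
  calls <- if (is(partition, "SubtypePartition")) subtypeCalls(partition)
           else stats::setNames(factor(partition), names(partition))
  rec <- mutationRecords(mut)
  extraneous <- setdiff(unique(rec$sample), names(calls))
  if (length(extraneous)) {
    warning(length(extraneous), " mutated sample(s) absent from the ",
            "partition dropped: ",
            paste(utils::head(extraneous, 5), collapse = ", "))
    rec <- rec[rec$sample %in% names(calls), , drop = FALSE]
  }
  out <- lapply(levels(calls), function(s) {
    members <- names(calls)[calls == s]
    if (!length(members)) {
      warning("subtype ", s, " has no samples; empty prevalent set")
      return(character())
    }
    sub <- unique(rec[rec$sample %in% members, c("sample", "gene")])
    if (!nrow(sub)) return(character())
    counts <- table(sub$gene)
    frac <- as.numeric(counts) / length(members)
    keep <- if (strict) frac > threshold else frac >= threshold
    sort(names(counts)[keep])
  })
  names(out) <- levels(calls)
  attr(out, "threshold") <- threshold
  attr(out, "strict") <- strict
  out
}

#' Subtype-exclusive and shared prevalent genes (Venn partition)
#'
#' Splits the union of the per-subtype prevalent gene sets by exact
#' membership pattern: `exclusive[s]` holds the genes prevalent in subtype
#' `s` and no other; every multi-subtype pattern goes into `shared`, keyed
#' by the sorted subtype combination (e.g. `"A+N+Y"`). The exclusive and
#' shared cells partition the union.
#'
#' @param prevalent named list, subtype -> gene set (as returned by
#'   [prevalentGenes]).
#' @return A list of class `ExclusiveMutationSets`: `prevalent`,
#'   `exclusive` (per subtype), `shared` (per combination), `threshold`.
#' @export
exclusiveGenes <- function(prevalent) {
  subtypes <- names(prevalent)
  genes <- sort(unique(unlist(prevalent)))
  pattern <- vapply(genes, function(g) {
    hit <- subtypes[vapply(prevalent, function(set) g %in% set, logical(1))]
    paste(sort(hit), collapse = "+")
  }, character(1))
  exclusive <- lapply(subtypes, function(s)
    unname(genes[pattern == s]))
  names(exclusive) <- subtypes
  sharedKeys <- sort(unique(pattern[!(pattern %in% subtypes)]))
  shared <- lapply(sharedKeys, function(k) unname(genes[pattern == k]))
  names(shared) <- sharedKeys
  structure(list(prevalent = prevalent, exclusive = exclusive,
                 shared = shared,
                 threshold = attr(prevalent, "threshold")),
            class = "ExclusiveMutationSets")
}

#' @export
print.ExclusiveMutationSets <- function(x, ...) {
  cat("ExclusiveMutationSets (threshold ",
      if (is.null(x$threshold)) "unknown" else x$threshold, ")\n", sep = "")
  for (s in names(x$exclusive))
    cat("  exclusive[", s, "]: ", length(x$exclusive[[s]]), " gene(s)\n",
        sep = "")
  cat("  shared cells:", length(x$shared), "\n")
  invisible(x)
}

#' Per-sample, per-gene worst-variant genotype grid
#'
#' For each requested (sample, gene) cell, reports the worst variant class
#' present with precedence `TRUNCATING > MISSENSE > OTHER > WT`; `WT` means
#' no record exists for the pair. This is the grid printed as T / M / WT in
#' genotype summary tables.
#'
#' @param mut a [MutationTable-class].
#' @param samples sample identifiers (rows of the grid).
#' @param genes gene symbols (columns).
#' @return Character matrix `samples x genes` of
#'   `{"TRUNCATING","MISSENSE","OTHER","WT"}`.
#' @export
genotypeSummary <- function(mut, samples, genes) {
  rec <- mutationRecords(mut)
  rec$class <- classifyVariant(rec$variant_classification,
                               rec$protein_change)
  rank <- c(TRUNCATING = 3L, MISSENSE = 2L, OTHER = 1L, WT = 0L)
  out <- matrix("WT", length(samples), length(genes),
                dimnames = list(samples, genes))
  rec <- rec[rec$sample %in% samples & rec$gene %in% genes, , drop = FALSE]
  for (i in seq_len(nrow(rec))) {
    cur <- out[rec$sample[i], rec$gene[i]]
    if (rank[[rec$class[i]]] > rank[[cur]])
      out[rec$sample[i], rec$gene[i]] <- rec$class[i]
  }
  out
}

#' Annotate records with pathogenicity flags from a static table
#'
#' Joins variant records against a user-supplied static annotation table
#' (columns `gene`, `protein_change`, `pathogenic`), as an offline stand-in
#' for interactive pathogenicity databases.
#'
#' @param mut a [MutationTable-class].
#' @param pathTable data.frame with columns `gene`, `protein_change`,
#'   `pathogenic` (logical).
#' @return `mutationRecords(mut)` with a logical `pathogenic` column
#'   (`FALSE` where the table has no entry).
#' @export
annotatePathogenic <- function(mut, pathTable) {
  stopifnot(all(c("gene", "protein_change", "pathogenic") %in%
                  colnames(pathTable)))
  rec <- mutationRecords(mut)
  key <- paste(rec$gene, rec$protein_change, sep = "\r")
  tkey <- paste(pathTable$gene, pathTable$protein_change, sep = "\r")
  hit <- match(key, tkey)
  rec$pathogenic <- !is.na(hit) & as.logical(pathTable$pathogenic[hit])
  rec
}
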