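## Readers and writers for the external table formats the pipeline touches:
## expression matrices (TSV, GCT v1.2), MAF-subset mutation tables (TSV) and
## gene signatures (GMT, two-column TSV). All TSV is tab-delimited UTF-8 with
## a header row.

.readTSVraw <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE,
                    quote = "", comment.char = "", na.strings = NULL)
}

## Convert a character matrix of expression values to numeric, failing with
## the (row, column) location of the first offending cell.
.numericCells <- function(chr, genes, samples) {
  num <- suppressWarnings(matrix(as.numeric(chr), nrow = nrow(chr)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric or non-finite value at row ", bad[1, 1],
         " (gene ", genes[bad[1, 1]], "), column ", bad[1, 2],
         " (sample ", samples[bad[1, 2]], ")")
  }
  dimnames(num) <- list(genes, samples)
  num
}

## Collapse duplicate gene rows (case-insensitive) by per-sample max (or
## mean); conservative for "highest expression among the four" subtype calls.
.collapseDuplicateGenes <- function(values, collapse = c("max", "mean")) {
  collapse <- match.arg(collapse)
  key <- toupper(trimws(rownames(values)))
  if (!anyDuplicated(key)) return(values)
  warning(sum(duplicated(key)), " duplicate gene row(s) collapsed by ",
          collapse)
  first <- !duplicated(key)
  fun <- if (collapse == "max") max else mean
  out <- vapply(seq_len(ncol(values)),
                function(j) tapply(values[, j], key, fun),
                numeric(length(unique(key))))
  out <- matrix(out, ncol = ncol(values),
                dimnames = list(sort(unique(key)), colnames(values)))
  ## restore first-occurrence order and original symbol spelling
  out <- out[key[first], , drop = FALSE]
  rownames(out) <- rownames(values)[first]
  out
}

#' Read an expression matrix (TSV or GCT v1.2)
#'
#' TSV layout: header row of sample identifiers, first column gene symbols.
#' GCT v1.2: `#1.2` line, dimension line, then a header with `Name`,
#' `Description` and sample columns. Duplicate gene rows are collapsed
#' (default: per-sample maximum) with a warning; any non-numeric or missing
#' cell is a parse error naming its row and column.
#'
#' @param path file path.
#' @param format `"tsv"` or `"gct"`; default guessed from the extension.
#' @param collapse how duplicate gene rows are merged: `"max"` (default) or
#'   `"mean"`.
#' @param source optional source-cohort label stored for every sample.
#' @return A [CohortExperiment-class].
#' @export
readExpressionMatrix <- function(path, format = c("tsv", "gct"),
                                 collapse = c("max", "mean"),
                                 source = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(format) && grepl("\\.gct$", path, ignore.case = TRUE)) {
    format <- "gct"
  } else {
    format <- match.arg(format)
  }
  collapse <- match.arg(collapse)
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3L || !startsWith(lines[1L], "#1.2"))
      stop("not a GCT v1.2 file (missing #1.2 header): ", path)
    tab <- utils::read.delim(text = lines[-(1:2)], header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character",
                             quote = "", stringsAsFactors = FALSE,
                             na.strings = NULL)
    genes <- tab[[1L]]
    samples <- colnames(tab)[-(1:2)]       # before `[` repairs duplicates
    chr <- as.matrix(tab[, -(1:2), drop = FALSE])
  } else {
    tab <- .readTSVraw(path)
    genes <- tab[[1L]]
    samples <- colnames(tab)[-1L]
    chr <- as.matrix(tab[, -1L, drop = FALSE])
  }
  colnames(chr) <- samples
  if (anyDuplicated(samples))
    stop("duplicate sample identifier(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  values <- .numericCells(chr, genes, samples)
  values <- .collapseDuplicateGenes(values, collapse)
  CohortExperiment(values, source = source)
}

#' Write an expression matrix
#'
#' Inverse of [readExpressionMatrix]; `write -> read` is the identity on the
#' expression values and dimnames.
#'
#' @param x a [CohortExperiment-class] (or plain numeric matrix).
#' @param path output path.
#' @param format `"tsv"` (default) or `"gct"`.
#' @export
writeExpressionMatrix <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  values <- if (is(x, "SummarizedExperiment")) exprValues(x) else as.matrix(x)
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(values), ncol(values), sep = "\t")), con)
    out <- data.frame(Name = rownames(values), Description = "na",
                      values, check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    out <- data.frame(gene = rownames(values), values, check.names = FALSE,
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

## Column-name synonyms accepted for the MAF subset.
.mafColumnMap <- list(
  sample = c("sample", "Tumor_Sample_Barcode", "sample_id", "SampleID"),
  gene = c("gene", "Hugo_Symbol"),
  variant_classification = c("variant_classification",
                             "Variant_Classification"),
  protein_change = c("protein_change", "Protein_Change", "HGVSp_Short"))

#' Read a MAF-subset mutation table
#'
#' Requires columns for sample, gene (Hugo symbol) and variant
#' classification (standard MAF spellings accepted); a protein-change column
#' is used when present. Records keep file order; classification terms
#' outside [mafVocabulary] are retained as `"OTHER"` with a warning.
#'
#' @param path TSV file path.
#' @return A [MutationTable-class].
#' @export
readMutationTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- .readTSVraw(path)
  pick <- function(field, required = TRUE) {
    hit <- intersect(.mafColumnMap[[field]], colnames(tab))
    if (!length(hit)) {
      if (required) stop("missing mandatory column for '", field, "'")
      return(rep("", nrow(tab)))
    }
    tab[[hit[1L]]]
  }
  MutationTable(sample = pick("sample"), gene = pick("gene"),
                variant_classification = pick("variant_classification"),
                protein_change = pick("protein_change", required = FALSE))
}

#' Write a mutation table as TSV
#'
#' Columns, in order: `sample`, `gene`, `variant_classification`,
#' `protein_change`.
#' @param x a [MutationTable-class].
#' @param path output path.
#' @export
writeMutationTable <- function(x, path) {
  utils::write.table(mutationRecords(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene signature (GMT or TSV)
#'
#' GMT: each line is `name<TAB>description<TAB>gene...`; one set is selected
#' (default the first) and all genes get class `"MEMBER"`. TSV: columns
#' `gene`, optional `class` (`NE`/`NON_NE`/`MEMBER`) and, when NE/NON_NE
#' classes appear, mandatory `mean_NE` and `mean_nonNE` reference-profile
#' columns.
#'
#' @param path file path.
#' @param format `"gmt"` or `"tsv"`; default guessed from the extension.
#' @param name for GMT files with several sets, which set to load.
#' @return A [GeneSignature-class].
#' @export
readSignature <- function(path, format = c("tsv", "gmt"), name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(format) && grepl("\\.gmt$", path, ignore.case = TRUE)) {
    format <- "gmt"
  } else {
    format <- match.arg(format)
  }
  if (format == "gmt") {
    sets <- fgsea::gmtPathways(path)
    if (!length(sets)) stop("no gene sets in GMT file: ", path)
    if (is.null(name)) name <- names(sets)[1L]
    if (!name %in% names(sets)) stop("gene set not found in GMT: ", name)
    return(GeneSignature(name, sets[[name]]))
  }
  tab <- .readTSVraw(path)
  if (!"gene" %in% colnames(tab)) stop("signature TSV needs a 'gene' column")
  classes <- if ("class" %in% colnames(tab)) tab$class else
    rep("MEMBER", nrow(tab))
  rp <- NULL
  if (any(classes %in% c("NE", "NON_NE"))) {
    if (!all(c("mean_NE", "mean_nonNE") %in% colnames(tab)))
      stop("NE/NON_NE classes present but reference profile columns ",
           "(mean_NE, mean_nonNE) absent")
    rp <- cbind(mean_NE = as.numeric(tab$mean_NE),
                mean_nonNE = as.numeric(tab$mean_nonNE))
    rownames(rp) <- tab$gene
  }
  GeneSignature(if (is.null(name)) sub("\\.[^.]*$", "", basename(path))
                else name,
                tab$gene, classes, rp)
}

#' Write a gene signature as TSV
#'
#' Columns `gene`, `class` and, when reference profiles exist, `mean_NE`,
#' `mean_nonNE`.
#' @param x a [GeneSignature-class].
#' @param path output path.
#' @export
writeSignature <- function(x, path) {
  out <- data.frame(gene = signatureGenes(x), class = unname(geneClasses(x)),
                    stringsAsFactors = FALSE)
  rp <- referenceProfiles(x)
  if (nrow(rp)) {
    idx <- match(out$gene, rownames(rp))
    out$mean_NE <- rp[idx, "mean_NE"]
    out$mean_nonNE <- rp[idx, "mean_nonNE"]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
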