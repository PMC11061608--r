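## Seeded synthetic-cohort generator. Emulates the statistical structure the
## downstream stages assume: subtype-dominant transcription-factor
## expression, anti-correlated NE / non-NE signature blocks, a
## SMARCA4-deficient subgroup inside subtype Y with reduced SMARCA4
## expression and a non-NE profile, an additive two-source batch shift on a
## fixed gene fraction, and mutation tables with planted subtype-exclusive
## genes at controlled prevalence.

#' Simulation configuration
#'
#' Bundles and validates every generator parameter. Defaults describe a
#' balanced four-subtype cohort of cell lines with a clear dominant-TF
#' signal, a separable NE/non-NE axis, three quarters of subtype-Y samples
#' SMARCA4-deficient, and a moderate two-source batch shift.
#'
#' @param n_per_subtype named integer counts for subtypes `A`, `N`, `P`, `Y`.
#' @param tf_effect log-units added to the dominant transcription factor.
#' @param ne_block_effect log-units: NE-signature genes are shifted `+` and
#'   non-NE genes `-` in the NE-high subtypes (A, N); the shifts reverse in
#'   the non-NE subtypes (P, Y).
#' @param smarca4_fraction_of_Y fraction of subtype-Y samples that are
#'   SMARCA4-deficient (deterministic count, rounded).
#' @param smarca4_expression_drop log-units subtracted from SMARCA4
#'   expression in the deficient subset.
#' @param batch_fraction fraction of genes carrying the batch shift.
#' @param batch_effect log-units added to batch-shifted genes in source 2.
#' @param mutation_prevalence per-subtype named list, gene -> Bernoulli
#'   prevalence in `[0, 1]`. SMARCA4 in subtype Y is governed by
#'   `smarca4_fraction_of_Y` instead (see Details).
#' @param noise_sd Gaussian noise sd on the log scale.
#' @param n_background_genes number of unstructured background genes.
#' @param seed integer seed; identical seeds give byte-identical cohorts.
#'
#' @details In subtype Y the SMARCA4-mutant samples are exactly the
#' expression-deficient subset (truncating mutations abolishing expression),
#' so planted mutation and expression ground truth agree; a `SMARCA4` entry
#' in `mutation_prevalence$Y` is ignored with a warning. All other
#' configured genes are drawn as independent Bernoulli per sample.
#'
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(n_per_subtype = c(A = 20, N = 20, P = 20, Y = 20),
                             tf_effect = 3,
                             ne_block_effect = 2,
                             smarca4_fraction_of_Y = 0.75,
                             smarca4_expression_drop = 3,
                             batch_fraction = 0.3,
                             batch_effect = 2,
                             mutation_prevalence = list(
                               A = c(TP53 = 0.9, RB1 = 0.9),
                               N = c(TP53 = 0.9, RB1 = 0.9),
                               P = c(TP53 = 0.9, RB1 = 0.9),
                               Y = c(TP53 = 0.9, RB1 = 0.05)),
                             noise_sd = 1,
                             n_background_genes = 500,
                             seed = 1L) {
  cfg <- list(n_per_subtype = n_per_subtype, tf_effect = tf_effect,
              ne_block_effect = ne_block_effect,
              smarca4_fraction_of_Y = smarca4_fraction_of_Y,
              smarca4_expression_drop = smarca4_expression_drop,
              batch_fraction = batch_fraction, batch_effect = batch_effect,
              mutation_prevalence = mutation_prevalence,
              noise_sd = noise_sd,
              n_background_genes = as.integer(n_background_genes),
              seed = as.integer(seed))
  stopifnot(all(c("A", "N", "P", "Y") %in% names(cfg$n_per_subtype)),
            all(cfg$n_per_subtype >= 0),
            cfg$smarca4_fraction_of_Y >= 0, cfg$smarca4_fraction_of_Y <= 1,
            cfg$batch_fraction >= 0, cfg$batch_fraction <= 1,
            cfg$noise_sd >= 0, cfg$n_background_genes >= 0,
            all(unlist(cfg$mutation_prevalence) >= 0),
            all(unlist(cfg$mutation_prevalence) <= 1))
  structure(cfg, class = "SimulationConfig")
}

## classifier transcription factors, in declared tie-break order
.simTFGenes <- c("ASCL1", "NEUROD1", "POU2F3", "YAP1")
.neHighSubtypes <- c("A", "N")

## The simulator's NE signature: 25 NE + 25 non-NE synthetic genes,
## reference profiles equal to the configured block means (so the profiles
## of the two classes are exactly anti-correlated).
.simSignature <- function(effect) {
  genes <- c(sprintf("NEG%02d", 1:25), sprintf("NNG%02d", 1:25))
  classes <- rep(c("NE", "NON_NE"), each = 25)
  rp <- cbind(mean_NE = ifelse(classes == "NE", effect, -effect),
              mean_nonNE = ifelse(classes == "NE", -effect, effect))
  rownames(rp) <- genes
  GeneSignature("simulated_NE50", genes, classes, rp)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Expression is baseline Gaussian noise (mean 0, sd `noise_sd`, log scale)
#' plus the dominant-TF effect, the NE/non-NE block effects, the SMARCA4
#' drop for the deficient subset and an additive batch shift on a seeded
#' random gene subset for source-2 samples (samples alternate between the
#' two sources). Mutations are independent per-sample Bernoulli draws at the
#' configured prevalences, except SMARCA4 in subtype Y (see
#' [simulationConfig]). Two deterministic substreams derived from `seed`
#' drive expression and mutations, so changing `n_background_genes` never
#' perturbs the mutation draws.
#'
#' @param config a [simulationConfig] object.
#' @return A list with elements `expression` ([CohortExperiment-class]),
#'   `mutations` ([MutationTable-class]), `annotations` (data.frame:
#'   `sample`, `source_cohort`, `histology`, `reference_class`), and `truth`
#'   (list: `subtype`, `batch`, `planted_exclusive`, `smarca4_deficient`,
#'   `signature`).
#' @examples
#' sim <- simulateCohort(simulationConfig(seed = 1))
#' table(sim$truth$subtype)
#' @export
simulateCohort <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  nsub <- config$n_per_subtype[c("A", "N", "P", "Y")]
  if (sum(nsub) == 0) stop("n_per_subtype must not be all zero")

  subtype <- rep(names(nsub), nsub)
  samples <- paste0(subtype, sprintf("%03d", sequence(nsub)))
  nS <- length(samples)
  names(subtype) <- samples

  sig <- .simSignature(config$ne_block_effect)
  genes <- c(.simTFGenes, "SMARCA4", signatureGenes(sig),
             if (config$n_background_genes > 0)
               sprintf("BG%04d", seq_len(config$n_background_genes)))
  nG <- length(genes)

  ## deficient subset: first round(frac * nY) subtype-Y samples
  ysamples <- samples[subtype == "Y"]
  deficient <- ysamples[seq_len(round(config$smarca4_fraction_of_Y *
                                        length(ysamples)))]

  ## batch: alternate samples between the two sources
  batch <- rep_len(c("source1", "source2"), nS)
  names(batch) <- samples

  ## ---- expression stream -------------------------------------------------
  set.seed(config$seed)
  nShift <- round(config$batch_fraction * nG)
  batchGenes <- if (nShift > 0) sort(sample.int(nG, nShift)) else integer()
  values <- matrix(stats::rnorm(nG * nS, 0, config$noise_sd), nG, nS,
                   dimnames = list(genes, samples))

  tfOf <- c(A = "ASCL1", N = "NEUROD1", P = "POU2F3", Y = "YAP1")
  for (j in seq_len(nS)) {
    values[tfOf[[subtype[j]]], j] <- values[tfOf[[subtype[j]]], j] +
      config$tf_effect
    neSign <- if (subtype[j] %in% .neHighSubtypes) 1 else -1
    cls <- geneClasses(sig)
    values[names(cls)[cls == "NE"], j] <-
      values[names(cls)[cls == "NE"], j] + neSign * config$ne_block_effect
    values[names(cls)[cls == "NON_NE"], j] <-
      values[names(cls)[cls == "NON_NE"], j] - neSign * config$ne_block_effect
    if (batch[j] == "source2" && length(batchGenes))
      values[batchGenes, j] <- values[batchGenes, j] + config$batch_effect
  }
  values["SMARCA4", deficient] <- values["SMARCA4", deficient] -
    config$smarca4_expression_drop

  ## ---- mutation stream ---------------------------------------------------
  set.seed(config$seed + 500009L)
  recS <- recG <- recC <- recP <- character()
  addRecords <- function(who, gene, vc, pc) {
    recS <<- c(recS, who)
    recG <<- c(recG, rep(gene, length(who)))
    recC <<- c(recC, rep(vc, length(who)))
    recP <<- c(recP, rep(pc, length(who)))
  }
  prevMap <- config$mutation_prevalence
  for (s in names(nsub)) {
    prev <- prevMap[[s]]
    if (s == "Y" && "SMARCA4" %in% names(prev)) {
      warning("SMARCA4 prevalence in subtype Y is governed by ",
              "smarca4_fraction_of_Y; configured entry ignored")
      prev <- prev[names(prev) != "SMARCA4"]
    }
    ssamples <- samples[subtype == s]
    if (!length(ssamples)) next
    for (g in names(prev)) {
      hit <- stats::rbinom(length(ssamples), 1L, prev[[g]]) == 1L
      if (any(hit))
        addRecords(ssamples[hit], g, "Missense_Mutation", "p.G12D")
    }
  }
  if (length(deficient))
    addRecords(deficient, "SMARCA4", "Nonsense_Mutation", "p.R1077*")
  mut <- MutationTable(recS, recG, recC, recP)

  ## ---- planted ground truth ----------------------------------------------
  effPrev <- lapply(names(nsub), function(s) {
    prev <- prevMap[[s]]
    prev <- prev[!(s == "Y" & names(prev) == "SMARCA4")]
    if (s == "Y") prev <- c(prev, SMARCA4 = config$smarca4_fraction_of_Y)
    prev
  })
  names(effPrev) <- names(nsub)
  allMutGenes <- unique(unlist(lapply(effPrev, names)))
  planted <- lapply(names(nsub), function(s) {
    keep <- vapply(allMutGenes, function(g) {
      p <- vapply(effPrev, function(pr)
        if (g %in% names(pr)) pr[[g]] else 0, numeric(1))
      p[[s]] > 0.5 && sum(p > 0.5) == 1L
    }, logical(1))
    allMutGenes[keep]
  })
  names(planted) <- names(nsub)

  annotations <- data.frame(
    sample = samples,
    source_cohort = unname(batch),
    histology = "SCLC",
    reference_class = ifelse(samples %in% deficient, "SMARCA4-UT", "SCLC"),
    stringsAsFactors = FALSE)

  expr <- CohortExperiment(values, source = annotations$source_cohort,
                           histology = annotations$histology,
                           referenceClass = annotations$reference_class)

  list(expression = expr, mutations = mut, annotations = annotations,
       truth = list(subtype = subtype, batch = batch,
                    planted_exclusive = planted,
                    smarca4_deficient = deficient,
                    batch_genes = genes[batchGenes],
                    signature = sig))
}
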