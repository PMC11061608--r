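# Shared fixtures, built in code or loaded from the tiny text tables shipped
# under inst/extdata.

table1Samples <- c("H1341", "DMS114", "SBC5", "H841", "H2286", "H157DM",
                   "H196", "SW1271")

table1Mutations <- function() {
  readMutationTable(system.file("extdata", "table1_genotypes_maf.tsv",
                                package = "sclcTyper"))
}

table1Annotations <- function() {
  read.delim(system.file("extdata", "table1_annotations.tsv",
                         package = "sclcTyper"),
             stringsAsFactors = FALSE)
}

# random finite expression cohort
randomCohort <- function(nGenes = 20, nSamples = 6, seed = 1) {
  set.seed(seed)
  m <- matrix(round(rnorm(nGenes * nSamples, 5, 2), 6), nGenes, nSamples,
              dimnames = list(sprintf("G%03d", seq_len(nGenes)),
                              sprintf("S%02d", seq_len(nSamples))))
  CohortExperiment(m)
}

# 6-gene two-class signature with anti-correlated reference profiles
antiCorrelatedSignature <- function() {
  genes <- paste0("g", 1:6)
  rp <- cbind(mean_NE = c(3, 2, 1, 0, -1, -2),
              mean_nonNE = -c(3, 2, 1, 0, -1, -2))
  rownames(rp) <- genes
  GeneSignature("anti", genes, rep(c("NE", "NON_NE"), each = 3), rp)
}

# signature spanning the simulator's structured genes (classifier TFs plus
# the NE / non-NE blocks); used for clustering on planted groups
structuredSignature <- function(sim) {
  GeneSignature("structured",
                c("ASCL1", "NEUROD1", "POU2F3", "YAP1",
                  signatureGenes(sim$truth$signature)))
}

# independent quantile-normalization oracle: rank each column, substitute
# the mean cross-column order statistic at that rank
qnOracle <- function(m) {
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    approx(seq_along(ref), ref, xout = r)$y
  })
  dimnames(out) <- dimnames(m)
  out
}

# exact two-sided Mann-Whitney p by exhaustive enumeration of all group-1
# index subsets (tie-free values)
enumMWp <- function(v1, v2) {
  vals <- c(v1, v2)
  n1 <- length(v1)
  r <- rank(vals)
  uOf <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  obs <- uOf(seq_len(n1))
  splits <- combn(length(vals), n1)
  u <- apply(splits, 2, uOf)
  mid <- n1 * length(v2) / 2
  mean(abs(u - mid) >= abs(obs - mid))
}

ariOf <- function(a, b) mclust::adjustedRandIndex(a, b)
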