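test_that("variant terms classify as truncating, missense or other", {
  expect_equal(classifyVariant("Nonsense_Mutation", "p.R1077*"), "TRUNCATING")
  expect_equal(classifyVariant("Missense_Mutation", "p.G1232S"), "MISSENSE")
  expect_equal(classifyVariant(c("Frame_Shift_Del", "Frame_Shift_Ins",
                                 "Splice_Site", "Nonstop_Mutation")),
               rep("TRUNCATING", 4))
  expect_equal(classifyVariant(c("Silent", "In_Frame_Del", "OTHER")),
               rep("OTHER", 3))
})

test_that("prevalence counts each mutated sample once and respects the threshold mode", {
  # 3 subtypes x 4 samples, hand-enumerable prevalences
  part <- setNames(rep(c("A", "N", "Y"), each = 4),
                   paste0(rep(c("a", "n", "y"), each = 4), 1:4))
  mut <- MutationTable(
    sample = c("a1", "a2", "a1", "n1", "n2", "n3", "y1", "y2", "y3", "y1"),
    gene   = c("TP53", "TP53", "TP53", "RB1", "RB1", "RB1",
               "SMARCA4", "SMARCA4", "SMARCA4", "TP53"),
    variant_classification = rep("Missense_Mutation", 10),
    protein_change = paste0("p.A", 1:10, "V"))
  # a1 has two TP53 records -> still one mutated sample
  prev <- prevalentGenes(mut, part, threshold = 0.5)
  expect_identical(prev[c("A", "N", "Y")],
                   list(A = "TP53", N = "RB1", Y = "SMARCA4"))
  expect_identical(attr(prev, "threshold"), 0.5)
  # strict mode drops exactly-50% genes
  prevStrict <- prevalentGenes(mut, part, threshold = 0.5, strict = TRUE)
  expect_identical(prevStrict$A, character(0))  # TP53 at exactly 2/4
  expect_identical(prevStrict$N, "RB1")         # 3/4 > 0.5

  # brute-force oracle over every (gene, subtype) pair
  rec <- unique(mutationRecords(mut)[, c("sample", "gene")])
  for (s in c("A", "N", "Y")) {
    for (g in c("TP53", "RB1", "SMARCA4")) {
      members <- names(part)[part == s]
      frac <- mean(members %in% rec$sample[rec$gene == g])
      expect_identical(g %in% prev[[s]], frac >= 0.5)
    }
  }
})

test_that("samples missing from the partition are dropped with a warning", {
  part <- setNames(c("A", "Y"), c("s1", "s2"))
  mut <- MutationTable(c("s1", "zz"), c("TP53", "TP53"),
                       rep("Missense_Mutation", 2), c("p.A1V", "p.A2V"))
  expect_warning(prev <- prevalentGenes(mut, part), "absent from the partition")
  expect_identical(prev$A, "TP53")
})

test_that("exclusive sets are the single-subtype Venn cells", {
  prev <- list(Y = c("SMARCA4", "TP53"), A = "TP53", N = "TP53",
               P = character())
  ex <- exclusiveGenes(prev)
  expect_identical(ex$exclusive$Y, "SMARCA4")
  expect_identical(ex$shared[["A+N+Y"]], "TP53")

  # identical prevalent sets everywhere -> all exclusive sets empty
  same <- list(A = c("g1", "g2"), N = c("g1", "g2"), Y = c("g1", "g2"))
  ex2 <- exclusiveGenes(same)
  expect_true(all(lengths(ex2$exclusive) == 0))
  expect_identical(ex2$shared[["A+N+Y"]], c("g1", "g2"))
})

test_that("the Venn partition conserves the union over all membership patterns", {
  subtypes <- c("A", "N", "P", "Y")
  # one gene per nonempty membership pattern: all 2^4 - 1 cells
  patterns <- lapply(1:15, function(i) subtypes[as.logical(bitwAnd(i, c(1, 2, 4, 8)))])
  genes <- sprintf("gene%02d", 1:15)
  prev <- lapply(subtypes, function(s)
    genes[vapply(patterns, function(p) s %in% p, logical(1))])
  names(prev) <- subtypes
  ex <- exclusiveGenes(prev)
  cells <- c(ex$exclusive, ex$shared)
  expect_equal(sum(lengths(cells)), length(genes))      # conservation
  expect_identical(sort(unlist(cells, use.names = FALSE)), genes)
  expect_equal(sum(duplicated(unlist(cells))), 0L)       # pairwise disjoint
  # each single-subtype pattern landed in the right exclusive set
  for (s in subtypes)
    expect_identical(ex$exclusive[[s]],
                     genes[vapply(patterns, identical, logical(1), s)])
})

test_that("enlarging another subtype's prevalent set never grows an exclusive set", {
  prev <- list(A = c("g1", "g2"), Y = c("g2", "g3"))
  before <- exclusiveGenes(prev)$exclusive$Y
  prev$A <- c(prev$A, "g3")
  after <- exclusiveGenes(prev)$exclusive$Y
  expect_true(all(after %in% before))
})

test_that("genotype grid reports the worst class with the declared precedence", {
  mut <- MutationTable(
    sample = c("s1", "s1", "s2"),
    gene = c("SMARCA4", "SMARCA4", "SMARCA4"),
    variant_classification = c("Missense_Mutation", "Nonsense_Mutation",
                               "Silent"),
    protein_change = c("p.G1232S", "p.R1077*", "p.L10L"))
  g <- genotypeSummary(mut, c("s1", "s2", "s3"), c("SMARCA4", "TP53"))
  expect_equal(unname(g[, "SMARCA4"]), c("TRUNCATING", "OTHER", "WT"))
  expect_true(all(g[, "TP53"] == "WT"))
})

test_that("random genotype grids agree with a per-cell brute-force scan", {
  set.seed(42)
  samples <- paste0("s", 1:5)
  genes <- paste0("G", 1:3)
  n <- 12
  mut <- MutationTable(sample(samples, n, TRUE),
                       sample(genes, n, TRUE),
                       sample(c("Missense_Mutation", "Nonsense_Mutation",
                                "Silent", "Frame_Shift_Del"), n, TRUE),
                       protein_change = paste0("p.X", 1:n))
  g <- genotypeSummary(mut, samples, genes)
  rec <- mutationRecords(mut)
  rank <- c(WT = 0, OTHER = 1, MISSENSE = 2, TRUNCATING = 3)
  for (s in samples) for (gn in genes) {
    cls <- classifyVariant(
      rec$variant_classification[rec$sample == s & rec$gene == gn])
    want <- if (length(cls)) names(rank)[max(rank[cls]) + 1] else "WT"
    expect_identical(g[s, gn], want)
  }
})

test_that("the printed genotype grid yields six of eight SMARCA4-mutant lines", {
  g <- genotypeSummary(table1Mutations(), table1Samples,
                       c("TP53", "RB1", "SMARCA4"))
  expect_equal(sum(g[, "SMARCA4"] != "WT"), 6L)
  expect_equal(sum(g[, "RB1"] != "WT"), 1L)
  expect_equal(rownames(g)[g[, "RB1"] != "WT"], "H196")
  # all SMARCA4-mutant lines carry TP53 mutations on an RB1 wild-type background
  mutant <- g[, "SMARCA4"] != "WT"
  expect_true(all(g[mutant, "TP53"] != "WT"))
  expect_true(all(g[mutant, "RB1"] == "WT"))
})

test_that("pathogenicity joins against a static annotation table", {
  mut <- table1Mutations()
  tab <- data.frame(gene = "SMARCA4", protein_change = "p.R1077*",
                    pathogenic = TRUE)
  ann <- annotatePathogenic(mut, tab)
  expect_equal(sum(ann$pathogenic), 1L)
  expect_equal(ann$sample[ann$pathogenic], "H841")
})
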