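## Internal helpers shared across modules.

## Case-insensitive, whitespace-trimmed gene lookup: returns indices of
## `genes` within `universe`, NA where absent.
.matchGenes <- function(genes, universe) {
  match(toupper(trimws(genes)), toupper(trimws(universe)))
}

## Population (divide-by-n) standard deviation.
.popSD <- function(v) sqrt(mean((v - mean(v))^2))

## Significance stars used on group-comparison figures.
.pStars <- function(p) {
  ifelse(p < 1e-4, "****",
         ifelse(p < 1e-3, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

## Z-score matrix rows with the population sd; drops zero-variance rows
## (warning). Returns the scaled matrix.
.zscoreRows <- function(m, warn = TRUE) {
  mu <- rowMeans(m)
  sdv <- sqrt(rowMeans((m - mu)^2))
  zero <- sdv == 0
  if (any(zero) && warn)
    warning(sum(zero), " zero-variance gene row(s) dropped before scaling")
  m <- m[!zero, , drop = FALSE]
  (m - mu[!zero]) / sdv[!zero]
}
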