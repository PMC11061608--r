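test_that("identical groups give an exact two-sided Mann-Whitney p of 1", {
  res <- compareTwoGroups(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$p_value, 1.0)
  expect_false(res$parametric)
})

test_that("fully separated 3 + 3 groups give U = 0 and exact p = 0.1", {
  res <- compareTwoGroups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, enumMWp(c(1, 2, 3), c(4, 5, 6)))
  expect_match(res$test, "exact")
})

test_that("the exact p agrees with exhaustive enumeration for every 3 + 3 split", {
  vals <- c(0.3, 1.1, 2.7, 3.4, 5.9, 8.2)
  for (idx in combn(6, 3, simplify = FALSE)) {
    v1 <- vals[idx]
    v2 <- vals[-idx]
    expect_equal(compareTwoGroups(c(v1, v2),
                                  rep(c("a", "b"), each = 3))$p_value,
                 enumMWp(v1, v2))
  }
})

test_that("the exact Mann-Whitney p is symmetric under group-label swap", {
  set.seed(2)
  v <- sample(seq(0.1, 9.9, 0.7))
  g <- rep(c("x", "y"), c(7, 7))
  a <- compareTwoGroups(v, g)
  b <- compareTwoGroups(v, ifelse(g == "x", "y", "x"))
  expect_equal(a$p_value, b$p_value)
})

test_that("exact and asymptotic branches agree closely for larger tie-free samples", {
  # the normal approximation's *relative* error blows up in the far tail,
  # so the 5% agreement is asserted over the non-extreme range (p >= 0.05)
  checked <- 0
  for (s in 1:20) {
    set.seed(s)
    v1 <- rexp(15)^2              # non-normal, so the gate stays nonparametric
    v2 <- rexp(15)^2 + 0.5
    res <- compareTwoGroups(c(v1, v2), rep(c("a", "b"), each = 15))
    expect_match(res$test, "exact")
    pAsym <- wilcox.test(v1, v2, exact = FALSE, correct = TRUE)$p.value
    if (res$p_value >= 0.05) {
      expect_lt(abs(res$p_value - pAsym) / res$p_value, 0.05)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 10)
})

test_that("normality gating picks the parametric branch only when both groups pass", {
  set.seed(5)
  v1 <- rnorm(20)
  v2 <- rnorm(20, 1)
  res <- compareTwoGroups(c(v1, v2), rep(c("a", "b"), each = 20))
  expect_true(res$parametric)
  expect_true(all(res$normality_p > 0.05))

  skewed <- c(rexp(20)^3, rexp(20)^3 + 4)
  res2 <- compareTwoGroups(skewed, rep(c("a", "b"), each = 20))
  expect_false(res2$parametric)

  expect_warning(res3 <- compareTwoGroups(c(1, 2, 5, 6, 7),
                                          c("a", "a", "b", "b", "b")),
                 "n < 3")
  expect_false(res3$parametric)
})

test_that("three identical groups give a null Kruskal-Wallis result", {
  res <- compareMultiGroups(rep(1:5, 3), rep(c("a", "b", "c"), each = 5))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 1)
})

test_that("Kruskal-Wallis H and Dunn z match a hand rank computation", {
  v <- c(1, 2, 3, 4, 5, 6)
  g <- rep(c("a", "b", "c"), each = 2)
  res <- compareMultiGroups(v, g)
  # ranks are the values themselves (no ties): mean ranks 1.5, 3.5, 5.5
  N <- 6
  H <- 12 / (N * (N + 1)) * 2 * ((1.5 - 3.5)^2 + 0 + (5.5 - 3.5)^2)
  expect_equal(unname(res$statistic), H)
  se <- sqrt((N * (N + 1) / 12) * (1 / 2 + 1 / 2))
  zWant <- c((1.5 - 3.5) / se, (1.5 - 5.5) / se, (3.5 - 5.5) / se)
  expect_equal(res$pairwise$z, zWant)
  expect_equal(res$pairwise$p_value, 2 * pnorm(-abs(zWant)))
  # Bonferroni over all 3 pairs
  expect_equal(res$pairwise$p_adjusted,
               pmin(1, 3 * res$pairwise$p_value))
})

test_that("Dunn adjusted p-values are monotone in the raw p-values", {
  set.seed(12)
  v <- c(rnorm(8), rnorm(8, 1), rnorm(8, 3), rnorm(8, 3.2))
  g <- rep(letters[1:4], each = 8)
  res <- compareMultiGroups(v, g)
  ord <- order(res$pairwise$p_value)
  expect_true(all(diff(res$pairwise$p_adjusted[ord]) >= -1e-15))
  expect_true(all(res$pairwise$p_adjusted >= res$pairwise$p_value))
})

test_that("significance stars follow the conventional tiers", {
  res <- compareMultiGroups(c(rnorm(10), rnorm(10, 10), rnorm(10, 20)),
                            rep(c("a", "b", "c"), each = 10))
  expect_true(all(res$pairwise$stars %in% c("*", "**", "***", "****")))
  null <- compareMultiGroups(rep(1:4, 3), rep(c("a", "b", "c"), each = 4))
  expect_true(all(null$pairwise$stars == "ns"))
})

test_that("Pearson correlation matches the covariance formula and flags degenerate input", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearsonCorrelation(x, x)$r, 1)
  y <- c(2, 1, 4, 3)
  res <- pearsonCorrelation(x, y)
  rOracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, rOracle, tolerance = 1e-12)
  tObs <- rOracle * sqrt((4 - 2) / (1 - rOracle^2))
  expect_equal(res$p_value, 2 * pt(-abs(tObs), df = 2), tolerance = 1e-12)
  expect_error(pearsonCorrelation(x, rep(1, 4)), "zero variance")
  expect_error(pearsonCorrelation(x, y[1:3]), "equal length")
})
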