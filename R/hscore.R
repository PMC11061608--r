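#' Immunohistochemistry H-score
#'
#' The H-score summarises a staining-intensity distribution as
#' `H = 1 * pct_1 + 2 * pct_2 + 3 * pct_3`, where `pct_i` is the percentage
#' of cells staining at intensity `i` in 0-3; the score ranges 0 (all cells
#' negative) to 300 (all cells at maximal intensity). Distributions may be
#' given as percentages (summing to 100) or fractions (summing to 1) via
#' `unit`.
#'
#' @param d numeric vector of length 4 (`pct_0`..`pct_3`), a 4-column
#'   matrix, or a data.frame with columns `pct_0`..`pct_3` (one row per
#'   specimen).
#' @param unit `"percent"` (default) or `"fraction"`.
#' @return Numeric H-score(s) in `[0, 300]`.
#' @examples
#' hScore(c(0, 50, 50, 0))  # 150
#' @export
hScore <- function(d, unit = c("percent", "fraction")) {
  unit <- match.arg(unit)
  if (is.data.frame(d)) {
    need <- paste0("pct_", 0:3)
    if (!all(need %in% colnames(d)))
      stop("data.frame input needs columns pct_0..pct_3")
    d <- as.matrix(d[, need])
  }
  if (is.null(dim(d))) d <- matrix(d, nrow = 1L)
  if (ncol(d) != 4L) stop("four intensity bins (0-3) required")
  if (unit == "fraction") d <- d * 100
  total <- rowSums(d)
  if (any(d < 0) || any(abs(total - 100) > 1e-9))
    stop("intensity percentages must be nonnegative and sum to 100")
  drop(d %*% c(0, 1, 2, 3))
}
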