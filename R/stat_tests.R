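#' One-sample Wilcoxon signed-rank test against a reference median
#'
#' Two-sided signed-rank test of `values - reference`, the annotation used
#' to call a repeat group enriched or depleted relative to the median
#' signal over all repeats.  Values exactly equal to the reference are
#' dropped (Wilcoxon's original treatment); if all values tie the
#' reference the result is `p = 1`, direction `"none"`.  The exact null
#' distribution is used for small samples without ties, the normal
#' approximation with continuity correction otherwise (the `stats`
#' machinery).
#'
#' @param values numeric vector.
#' @param reference reference value (e.g. a global median).
#' @return `list(p, direction)` with direction in
#'   `"enriched"`/`"depleted"`/`"none"` by the sign of the median
#'   difference.
#' @export
wilcoxon_vs_reference <- function(values, reference) {
  d <- values - reference
  d <- d[d != 0]
  if (length(d) == 0) return(list(p = 1, direction = "none"))
  p <- suppressWarnings(wilcox.test(d, mu = 0, alternative = "two.sided"))$p.value
  med <- median(d)
  dir <- if (med > 0) "enriched" else if (med < 0) "depleted" else "none"
  list(p = p, direction = dir)
}

#' Kruskal-Wallis omnibus test across groups
#'
#' @param groups named list of numeric vectors (>= 2 groups).
#' @return The chi-square p-value of the tie-corrected H statistic.
#' @export
kruskal_wallis <- function(groups) {
  stop_if_not(length(groups) >= 2, "need at least 2 groups")
  stop_if_not(all(lengths(groups) >= 1), "empty group")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kruskal.test(x, g)$p.value
}

#' Mann-Whitney U test (two-sided, tie-corrected)
#'
#' @param a,b numeric vectors.
#' @return `list(p, U)` where `U` is the statistic for sample `a`.
#' @export
mann_whitney <- function(a, b) {
  stop_if_not(length(a) >= 1 && length(b) >= 1, "empty sample")
  res <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  list(p = res$p.value, U = unname(res$statistic))
}

#' Pairwise Spearman correlation with significance masking
#'
#' Computes the midrank Spearman correlation for every pair of columns
#' and a logical mask that is `TRUE` where the correlation p-value is
#' below `alpha` (the convention of masked correlation matrices: only
#' significant cells are displayed).  Constant columns have undefined
#' correlations: `rho` is `NA` and the mask `FALSE` there.  The diagonal
#' is `rho = 1`, mask `TRUE`.
#'
#' @param table numeric matrix or data.frame, observations x variables
#'   (>= 3 rows).
#' @param alpha significance threshold (default 0.01).
#' @return `list(rho = matrix, mask = logical matrix)`.
#' @export
spearman_matrix <- function(table, alpha = 0.01) {
  table <- as.matrix(table)
  stop_if_not(nrow(table) >= 3, "need at least 3 rows")
  p <- ncol(table)
  rho <- matrix(NA_real_, p, p, dimnames = list(colnames(table),
                                                colnames(table)))
  mask <- matrix(FALSE, p, p, dimnames = dimnames(rho))
  const <- apply(table, 2, function(x) length(unique(x[!is.na(x)])) <= 1)
  for (i in seq_len(p)) {
    rho[i, i] <- 1
    mask[i, i] <- TRUE
    if (i == p) break
    for (j in (i + 1L):p) {
      if (const[i] || const[j]) next
      ct <- suppressWarnings(cor.test(table[, i], table[, j],
                                      method = "spearman", exact = FALSE))
      rho[i, j] <- rho[j, i] <- unname(ct$estimate)
      mask[i, j] <- mask[j, i] <- ct$p.value < alpha
    }
  }
  list(rho = rho, mask = mask)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement; the output maps
#' back to the input order.
#'
#' @param pvalues numeric vector in `[0, 1]` (`NA` passed through).
#' @return Adjusted p-values in input order.
#' @export
benjamini_hochberg <- function(pvalues) {
  ok <- !is.na(pvalues)
  stop_if_not(all(pvalues[ok] >= 0 & pvalues[ok] <= 1),
              "p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}
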