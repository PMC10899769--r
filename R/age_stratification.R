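#' Per-clade signal summary with rank tests
#'
#' Groups copies by clade rank (oldest = 0) and summarizes one track's
#' abundance per clade: n, median and quartiles, a Kruskal-Wallis
#' omnibus p across clades, and a per-clade one-sample Wilcoxon
#' signed-rank test against a reference median.  The reference is the
#' median over the whole comparison universe — all copies in `table`
#' restricted to `universe` (default: every clade-assigned copy), so the
#' clade boxplot annotations of enrichment/depletion relative to "all
#' repeats" or "all copies of the focal family" are both expressible.
#'
#' @param table an [abundance_table()] matrix.
#' @param catalog the clade-annotated catalog the table rows come from.
#' @param track column name of the track to summarize.
#' @param universe optional copy-id subset defining the reference median.
#' @return `list(summary = data.frame, kruskal_p, reference_median,
#'   n_unassigned)`.
#' @export
clade_summary <- function(table, catalog, track, universe = NULL) {
  idx <- match(catalog$copy_id, rownames(table))
  stop_if_not(!anyNA(idx), "catalog copies missing from abundance table")
  vals <- table[idx, track]
  rank <- catalog$clade_rank
  keep <- !is.na(rank)
  n_unassigned <- sum(!keep)
  if (!is.null(universe)) {
    inu <- catalog$copy_id %in% universe
    ref <- median(vals[inu & keep])
  } else ref <- median(vals[keep])
  vals <- vals[keep]; rank <- rank[keep]
  stop_if_not(length(unique(rank)) >= 2,
              "need >= 2 non-empty clades for the omnibus test")
  groups <- split(vals, rank)
  kw <- kruskal_wallis(groups)
  rows <- lapply(names(groups), function(r) {
    v <- groups[[r]]
    w <- wilcoxon_vs_reference(v, ref)
    data.frame(clade_rank = as.integer(r), n = length(v),
               q1 = unname(quantile(v, 0.25)), median = median(v),
               q3 = unname(quantile(v, 0.75)),
               wilcoxon_p = w$p, direction = w$direction)
  })
  levels <- S4Vectors::metadata(catalog)$clade_levels
  summary <- do.call(rbind, rows)
  if (!is.null(levels))
    summary$clade <- levels[summary$clade_rank + 1L]
  list(summary = summary, kruskal_p = kw, reference_median = ref,
       n_unassigned = n_unassigned)
}

#' Monotone age trend of signal across clades
#'
#' Spearman correlation (midranks) between clade rank and abundance,
#' quantifying the visual old-to-young gradient of clade boxplots as a
#' single statistic.  At `level = "repeat_name"` copies are first
#' aggregated per repeat name (mean of copy values by default).
#'
#' @param table an [abundance_table()] matrix.
#' @param catalog clade-annotated catalog.
#' @param track column name.
#' @param level `"copy"` or `"repeat_name"`.
#' @param aggregator per-name aggregation function (default `mean`).
#' @return `list(rho, p, n)`; `rho` is `NA` with `p = NA` when abundance
#'   is constant (undefined correlation).
#' @export
age_trend <- function(table, catalog, track, level = c("copy", "repeat_name"),
                      aggregator = mean) {
  level <- match.arg(level)
  idx <- match(catalog$copy_id, rownames(table))
  vals <- table[idx, track]
  rank <- catalog$clade_rank
  keep <- !is.na(rank) & !is.na(vals)
  vals <- vals[keep]; rank <- rank[keep]
  if (level == "repeat_name") {
    nm <- catalog$repeat_name[keep]
    vals <- tapply(vals, nm, aggregator)
    rank <- tapply(rank, nm, function(r) r[1])
    vals <- as.numeric(vals); rank <- as.numeric(rank)
  }
  stop_if_not(length(unique(rank)) >= 3,
              "need >= 3 distinct clade ranks")
  if (length(unique(vals)) <= 1)
    return(list(rho = NA_real_, p = NA_real_, n = length(vals)))
  ct <- suppressWarnings(cor.test(rank, vals, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(vals))
}
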