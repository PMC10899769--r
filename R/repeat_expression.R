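#' Per-copy read counting
#'
#' Assigns each alignment to the repeat copy with the largest overlap
#' (>= 1 bp; ties break to the leftmost copy start, then `copy_id`) and
#' accumulates its weight into a copies x samples count matrix.  Under
#' `unique_only` only `n_hits == 1` alignments count with weight 1;
#' under `fractional` every alignment carries weight `1 / n_hits`.
#'
#' @param alignments `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open), `n_hits`, `sample`.
#' @param catalog a repeat catalog.
#' @param policy `"unique_only"` or `"fractional"`.
#' @param samples optional character vector fixing column order.
#' @return Numeric matrix rows = `copy_id`, columns = samples.
#' @export
count_reads <- function(alignments, catalog,
                        policy = c("unique_only", "fractional"),
                        samples = NULL) {
  policy <- match.arg(policy)
  stop_if_not(all(alignments$end > alignments$start),
              "negative- or zero-length alignment span")
  if (is.null(samples)) samples <- unique(as.character(alignments$sample))
  out <- matrix(0, nrow = length(catalog), ncol = length(samples),
                dimnames = list(catalog$copy_id, samples))
  if (policy == "unique_only")
    alignments <- alignments[alignments$n_hits == 1, , drop = FALSE]
  if (nrow(alignments) == 0) return(out)
  w <- if (policy == "fractional") 1 / alignments$n_hits else
    rep(1, nrow(alignments))
  gr <- granges0(alignments$chrom, alignments$start, alignments$end)
  hits <- GenomicRanges::findOverlaps(gr, catalog, ignore.strand = TRUE)
  if (length(hits) == 0) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- interval_overlap_bp(start0(gr)[q], end0(gr)[q],
                            start0(catalog)[s], end0(catalog)[s])
  ord <- order(q, -ov, start0(catalog)[s], catalog$copy_id[s])
  best <- ord[!duplicated(q[ord])]
  qb <- q[best]; sb <- s[best]
  sample_j <- match(as.character(alignments$sample)[qb], samples)
  cell <- (sample_j - 1L) * nrow(out) + sb
  add <- tapply(w[qb], cell, sum)
  at <- as.integer(names(add))
  out[at] <- out[at] + as.numeric(add)
  out
}

#' Sample sheet helper
#'
#' @param sample sample names (count matrix columns).
#' @param condition condition per sample (e.g. `"control"`, `"kd"`).
#' @param replicate replicate id per sample.
#' @return `data.frame` sample sheet.
#' @export
sample_sheet <- function(sample, condition, replicate = NULL) {
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(sample), condition, FUN = seq_along)
  data.frame(sample = as.character(sample),
             condition = as.character(condition),
             replicate = replicate)
}

cond_cols <- function(counts, sheet, condition) {
  stop_if_not(condition %in% sheet$condition,
              "unknown condition '%s'", condition)
  match(sheet$sample[sheet$condition == condition], colnames(counts))
}

#' Expressed / non-expressed split
#'
#' A copy is expressed (`"E"`) in a condition iff its mean count across
#' that condition's replicates is at least `threshold` (the >= 3
#' uniquely-mapped-reads convention), else `"Ne"`.
#'
#' @param counts count matrix from [count_reads()].
#' @param sheet a [sample_sheet()].
#' @param condition condition label to evaluate.
#' @param threshold expressed threshold on the mean count (default 3,
#'   inclusive).
#' @return Named character vector `copy_id` -> `"E"`/`"Ne"`.
#' @export
expressed_split <- function(counts, sheet, condition, threshold = 3) {
  j <- cond_cols(counts, sheet, condition)
  m <- rowMeans(counts[, j, drop = FALSE])
  setNames(ifelse(m >= threshold, "E", "Ne"), rownames(counts))
}

#' Knock-down differential classification of repeat copies
#'
#' A deliberately simple two-group count test (NOT a shrinkage-based
#' negative-binomial GLM; externally produced fold-change/padj tables
#' can be classified with [classify_de()] instead): counts are
#' library-size normalized by total-count scaling, a common NB
#' dispersion is estimated as the genome-wide average of the per-copy
#' within-condition method-of-moments estimates (stable at few
#' replicates, where per-copy estimates are hopelessly noisy), and a
#' two-sided Wald test on the
#' pseudocounted log2 fold change uses the normal approximation with a
#' delta-method standard error.  Copies with total count below
#' `min_total` are excluded before testing (independent filtering);
#' Benjamini-Hochberg correction runs over tested copies only.  Status
#' is `up`/`down` when `|FC| > fc_threshold` (on the linear scale) and
#' `padj < alpha`, else `ns`.
#'
#' @param counts count matrix.
#' @param sheet sample sheet with conditions `reference` and `treatment`
#'   (>= 2 replicates each).
#' @param reference,treatment condition labels (default `"control"`,
#'   `"kd"`); the fold change is treatment over reference.
#' @param fc_threshold linear fold-change threshold (default 1.5).
#' @param alpha adjusted-significance threshold (default 0.05).
#' @param min_total minimum total raw count for testing (default 10).
#' @param pseudocount added to group means for the fold change
#'   (default 0.5).
#' @return `data.frame` per copy: `copy_id`, `base_mean`, `log2fc`, `p`,
#'   `padj`, `status` (`NA` p/padj for untested copies, status `ns`).
#' @export
differential_classification <- function(counts, sheet,
                                        reference = "control",
                                        treatment = "kd",
                                        fc_threshold = 1.5, alpha = 0.05,
                                        min_total = 10,
                                        pseudocount = 0.5) {
  jr <- cond_cols(counts, sheet, reference)
  jt <- cond_cols(counts, sheet, treatment)
  stop_if_not(length(jr) >= 2 && length(jt) >= 2,
              "each condition needs >= 2 replicates")
  lib <- colSums(counts)
  sf <- lib / mean(lib)
  sf[sf == 0] <- 1
  norm <- sweep(counts, 2, sf, "/")
  nr <- length(jr); nt <- length(jt)
  mu_r <- rowMeans(norm[, jr, drop = FALSE])
  mu_t <- rowMeans(norm[, jt, drop = FALSE])
  v_r <- apply(norm[, jr, drop = FALSE], 1, stats::var)
  v_t <- apply(norm[, jt, drop = FALSE], 1, stats::var)
  log2fc <- log2((mu_t + pseudocount) / (mu_r + pseudocount))
  tested <- rowSums(counts) >= min_total
  # common NB dispersion: per-copy within-condition method-of-moments
  # estimates, floored at 0 and averaged over tested copies.  Per-copy
  # MoM at 2-3 replicates is far too noisy to standardize a Wald
  # statistic; the genome-wide average is stable and calibrates the test
  a_r <- ifelse(mu_r > 0, (v_r - mu_r) / mu_r^2, NA_real_)
  a_t <- ifelse(mu_t > 0, (v_t - mu_t) / mu_t^2, NA_real_)
  wsum <- (ifelse(is.na(a_r), 0, nr - 1) + ifelse(is.na(a_t), 0, nt - 1))
  a_pool <- (ifelse(is.na(a_r), 0, (nr - 1) * a_r) +
               ifelse(is.na(a_t), 0, (nt - 1) * a_t)) / pmax(wsum, 1)
  disp <- mean(pmax(a_pool[tested & wsum > 0], 0), na.rm = TRUE)
  if (!is.finite(disp)) disp <- 0
  se2 <- ((mu_r + disp * mu_r^2) / (nr * (mu_r + pseudocount)^2) +
            (mu_t + disp * mu_t^2) / (nt * (mu_t + pseudocount)^2)) /
    log(2)^2
  z <- ifelse(se2 > 0, log2fc / sqrt(se2), 0)
  p <- 2 * pnorm(-abs(z))
  p[!tested] <- NA_real_
  padj <- rep(NA_real_, length(p))
  padj[tested] <- benjamini_hochberg(p[tested])
  res <- data.frame(copy_id = rownames(counts),
                    base_mean = (mu_r + mu_t) / 2,
                    log2fc = log2fc, p = p, padj = padj,
                    tested = tested, row.names = NULL)
  res$status <- classify_de(res$log2fc, res$padj, fc_threshold, alpha)
  res
}

#' @describeIn differential_classification Threshold classification of a
#'   fold-change / adjusted-p table (usable on external DE output).
#' @param log2fc,padj numeric vectors.
#' @export
classify_de <- function(log2fc, padj, fc_threshold = 1.5, alpha = 0.05) {
  lt <- log2(fc_threshold)
  ifelse(!is.na(padj) & padj < alpha & log2fc >= lt, "up",
         ifelse(!is.na(padj) & padj < alpha & log2fc <= -lt, "down", "ns"))
}

#' Group shares of up-regulated copies
#'
#' For each group, the observed share of all up-regulated copies that
#' fall in the group, next to the expected share — the group's fraction
#' of all tested copies (the pie-chart comparison of deregulated
#' elements vs their background availability).
#'
#' @param de a [differential_classification()] result.
#' @param grouping named character vector `copy_id` -> group label,
#'   covering the tested copies.
#' @return `data.frame(group, n_up, observed_pct, n_tested,
#'   expected_pct, enriched)`; zero up-regulated copies yield a
#'   zero-row frame.
#' @export
group_proportions <- function(de, grouping) {
  tested <- de$copy_id[de$tested]
  g_tested <- grouping[tested]
  stop_if_not(!anyNA(g_tested), "grouping does not cover tested copies")
  up <- de$copy_id[de$status == "up"]
  if (length(up) == 0)
    return(data.frame(group = character(), n_up = integer(),
                      observed_pct = numeric(), n_tested = integer(),
                      expected_pct = numeric(), enriched = logical()))
  groups <- sort(unique(g_tested))
  n_up <- table(factor(grouping[up], levels = groups))
  n_te <- table(factor(g_tested, levels = groups))
  obs <- as.numeric(n_up) / length(up) * 100
  exp <- as.numeric(n_te) / length(tested) * 100
  data.frame(group = groups, n_up = as.integer(n_up),
             observed_pct = obs, n_tested = as.integer(n_te),
             expected_pct = exp, enriched = obs > exp, row.names = NULL)
}

#' Read-change categories between two conditions
#'
#' Classifies every copy by how its expression changed from the
#' reference to the treatment condition: `never_expressed` (below the
#' expressed threshold in both), `became_expressed`, `became_silent`,
#' and — among copies expressed in both — `increased` / `decreased`
#' when the pseudocounted ratio of mean counts reaches `change_factor`
#' (resp. its reciprocal), else `unchanged`.
#'
#' @param counts count matrix.
#' @param sheet sample sheet with exactly two conditions.
#' @param reference,treatment condition labels.
#' @param express_threshold expressed cutoff on the mean count
#'   (default 3).
#' @param change_factor fold-change cutoff (default 1.5).
#' @param pseudocount added to both means for the ratio (default 0.5).
#' @return `list(categories = named character vector, fractions =
#'   data.frame(category, n, percent))`; fractions are % of all copies.
#' @export
read_change_categories <- function(counts, sheet, reference = "control",
                                   treatment = "kd",
                                   express_threshold = 3,
                                   change_factor = 1.5,
                                   pseudocount = 0.5) {
  stop_if_not(length(unique(sheet$condition)) == 2,
              "exactly two conditions required")
  jr <- cond_cols(counts, sheet, reference)
  jt <- cond_cols(counts, sheet, treatment)
  mr <- rowMeans(counts[, jr, drop = FALSE])
  mt <- rowMeans(counts[, jt, drop = FALSE])
  er <- mr >= express_threshold
  et <- mt >= express_threshold
  ratio <- (mt + pseudocount) / (mr + pseudocount)
  cat <- ifelse(!er & !et, "never_expressed",
         ifelse(!er & et, "became_expressed",
         ifelse(er & !et, "became_silent",
         ifelse(ratio >= change_factor, "increased",
         ifelse(ratio <= 1 / change_factor, "decreased", "unchanged")))))
  cat <- setNames(cat, rownames(counts))
  lev <- c("never_expressed", "became_expressed", "increased",
           "decreased", "became_silent", "unchanged")
  tab <- table(factor(cat, levels = lev))
  list(categories = cat,
       fractions = data.frame(category = lev, n = as.integer(tab),
                              percent = as.integer(tab) / length(cat) * 100,
                              row.names = NULL))
}

#' Count matrix I/O
#'
#' `write_counts()` writes the counts TSV (first column `copy_id`) and a
#' sample sheet TSV; `read_counts()` reads them back.
#'
#' @param counts count matrix.
#' @param sheet sample sheet.
#' @param counts_path,samples_path file paths.
#' @export
write_counts <- function(counts, sheet, counts_path, samples_path) {
  write.table(data.frame(copy_id = rownames(counts), counts,
                         check.names = FALSE),
              counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sheet, samples_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(counts_path)
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_path, samples_path) {
  tab <- read.table(counts_path, sep = "\t", header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab[[1]]
  sheet <- read.table(samples_path, sep = "\t", header = TRUE,
                      colClasses = "character")
  list(counts = counts, sheet = sheet)
}
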