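#' Assign peaks to repeat copies (>= 50%-of-peak rule)
#'
#' A peak is repeat-assigned iff a single copy overlaps at least half of
#' the peak's length (inclusive at exactly 50%).  Among qualifying
#' copies the largest overlap wins; ties break to the leftmost copy
#' start, then `copy_id`.  Deterministic and invariant to input order.
#'
#' @param peaks `GRanges` of peaks (BED3+/narrowPeak input; see
#'   [read_bed()]).
#' @param catalog a repeat catalog.
#' @return `data.frame` with one row per peak: `peak`, `copy_id` (NA if
#'   unassigned), `class_name`, `family`, `repeat_name`, `overlap_bp`.
#' @export
assign_peaks <- function(peaks, catalog) {
  n <- length(peaks)
  out <- data.frame(peak = seq_len(n), copy_id = NA_character_,
                    class_name = NA_character_, family = NA_character_,
                    repeat_name = NA_character_, overlap_bp = 0L)
  if (n == 0 || length(catalog) == 0) return(out)
  hits <- GenomicRanges::findOverlaps(peaks, catalog, ignore.strand = TRUE)
  if (length(hits) == 0) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- interval_overlap_bp(start0(peaks)[q], end0(peaks)[q],
                            start0(catalog)[s], end0(catalog)[s])
  ord <- order(q, -ov, start0(catalog)[s], catalog$copy_id[s])
  best <- ord[!duplicated(q[ord])]
  qb <- q[best]; sb <- s[best]; ovb <- ov[best]
  qualifies <- 2L * ovb >= GenomicRanges::width(peaks)[qb]
  qb <- qb[qualifies]; sb <- sb[qualifies]; ovb <- ovb[qualifies]
  out$copy_id[qb] <- catalog$copy_id[sb]
  out$class_name[qb] <- catalog$class_name[sb]
  out$family[qb] <- catalog$family[sb]
  out$repeat_name[qb] <- catalog$repeat_name[sb]
  out$overlap_bp[qb] <- ovb
  out
}

#' Fraction of repeats carrying a peak
#'
#' Per group (class, family or repeat name), the percentage of retained
#' copies that contain at least one assigned peak.
#'
#' @param peaks `GRanges` of peaks.
#' @param catalog a repeat catalog.
#' @param level grouping level.
#' @return `data.frame(group, n_copies, n_with_peak, percent)`; groups
#'   with no copies never arise from a catalog, but an all-`NA` percent
#'   marks a 0/0 group if one is requested explicitly.
#' @export
fraction_repeats_with_peak <- function(peaks, catalog,
                                       level = c("class", "family",
                                                 "repeat_name")) {
  level <- match.arg(level)
  asg <- assign_peaks(peaks, catalog)
  grouping <- switch(level, class = catalog$class_name,
                     family = catalog$family,
                     repeat_name = catalog$repeat_name)
  marked <- catalog$copy_id %in% asg$copy_id[!is.na(asg$copy_id)]
  n <- tapply(marked, grouping, length)
  k <- tapply(marked, grouping, sum)
  data.frame(group = names(n), n_copies = as.integer(n),
             n_with_peak = as.integer(k),
             percent = ifelse(n > 0, as.integer(k) / as.integer(n) * 100,
                              NA_real_),
             row.names = NULL)
}

#' Shuffle peaks under blacklist and no-overlap constraints
#'
#' Re-places every peak uniformly at random on its original chromosome,
#' preserving its length, rejecting positions that overlap (>= 1 bp) the
#' blacklist or a previously placed shuffled peak.  Peaks are placed in
#' descending length order for feasibility; given a seed the output is
#' deterministic.
#'
#' @param peaks `GRanges`.
#' @param genome `Seqinfo`.
#' @param blacklist `GRanges` of excluded regions (may be empty).
#' @param seed integer seed.
#' @param max_tries rejection-sampling attempts per peak before erroring.
#' @return `GRanges` of shuffled peaks (input order restored).
#' @export
shuffle_peaks <- function(peaks, genome,
                          blacklist = GenomicRanges::GRanges(),
                          seed = 1L, max_tries = 10000L) {
  n <- length(peaks)
  if (n == 0) return(peaks)
  sl <- GenomeInfoDb::seqlengths(genome)
  chr <- as.character(GenomicRanges::seqnames(peaks))
  len <- GenomicRanges::width(peaks)
  occ <- list()  # per chrom: list(starts=, ends=), sorted, disjoint, 0-based
  if (length(blacklist) > 0) {
    bl <- GenomicRanges::reduce(blacklist, ignore.strand = TRUE)
    for (c1 in unique(as.character(GenomicRanges::seqnames(bl)))) {
      b <- bl[GenomicRanges::seqnames(bl) == c1]
      o <- order(GenomicRanges::start(b))
      occ[[c1]] <- list(starts = start0(b)[o], ends = end0(b)[o])
    }
  }
  overlaps_occ <- function(o, s, e) {
    if (is.null(o) || length(o$starts) == 0) return(FALSE)
    i <- findInterval(e - 1L, o$starts)   # last interval with start < e
    i >= 1 && o$ends[i] > s
  }
  insert_occ <- function(o, s, e) {
    if (is.null(o)) return(list(starts = s, ends = e))
    i <- findInterval(s, o$starts)
    list(starts = append(o$starts, s, after = i),
         ends = append(o$ends, e, after = i))
  }
  new_start <- rep(NA_real_, n)
  ord <- order(-len, chr, start0(peaks))
  with_seed(seed, {
    for (k in ord) {
      L <- sl[[chr[k]]]
      span <- L - len[k]
      stop_if_not(span >= 0, "peak %d longer than its chromosome", k)
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        s <- floor(runif(1, 0, span + 1))
        if (s > span) s <- span  # guard the half-open upper edge
        e <- s + len[k]
        if (!overlaps_occ(occ[[chr[k]]], s, e)) {
          occ[[chr[k]]] <- insert_occ(occ[[chr[k]]], s, e)
          new_start[k] <- s
          placed <- TRUE
          break
        }
      }
      stop_if_not(placed,
                  "no valid placement for peak %d (%s, %d bp) in %d tries",
                  k, chr[k], len[k], max_tries)
    }
  })
  granges0(chr, new_start, new_start + len, genome)
}

#' Peak-repeat enrichment report against the shuffled null
#'
#' Observed per-class percentages among repeat-assigned peaks, compared
#' with the same statistic over `n_shuffles` independent constrained
#' shuffles (per-replicate seeds derived from `seed`).  Also reports the
#' overall percentage of peaks assigned to repeats next to the
#' percentage of the genome that is repetitive, and each class's
#' occupancy share within the repetitive fraction.  The empirical
#' two-sided rank p-value across shuffles is reported as supporting
#' plumbing.
#'
#' @param peaks `GRanges`.
#' @param catalog a repeat catalog.
#' @param genome `Seqinfo`.
#' @param blacklist `GRanges` used by the shuffles.
#' @param n_shuffles number of null replicates (>= 1).
#' @param seed integer seed.
#' @return `list(overall = data.frame, per_class = data.frame,
#'   null_pct_in_repeats = numeric)`.
#' @export
enrichment_report <- function(peaks, catalog, genome,
                              blacklist = GenomicRanges::GRanges(),
                              n_shuffles = 100L, seed = 1L) {
  stop_if_not(n_shuffles >= 1, "n_shuffles must be >= 1")
  classes <- sort(unique(catalog$class_name))
  occ_class <- occupancy(catalog, genome, "class")
  occ_all <- occupancy(catalog, genome, "all")
  pct_genome_rep <- if (nrow(occ_all)) occ_all$percent else 0
  class_pct <- function(asg) {
    assigned <- asg$class_name[!is.na(asg$copy_id)]
    if (length(assigned) == 0)
      return(setNames(rep(NA_real_, length(classes)), classes))
    tab <- table(factor(assigned, levels = classes))
    as.numeric(tab) / length(assigned) * 100
  }
  if (length(peaks) == 0) {
    return(list(overall = data.frame(n_peaks = 0L,
                                     pct_peaks_in_repeats = NA_real_,
                                     pct_genome_repetitive = pct_genome_rep),
                per_class = data.frame(class_name = classes),
                null_pct_in_repeats = numeric(0)))
  }
  obs_asg <- assign_peaks(peaks, catalog)
  obs_pct <- class_pct(obs_asg)
  obs_in_rep <- mean(!is.na(obs_asg$copy_id)) * 100
  null_mat <- matrix(NA_real_, n_shuffles, length(classes),
                     dimnames = list(NULL, classes))
  null_in_rep <- numeric(n_shuffles)
  for (r in seq_len(n_shuffles)) {
    shuf <- shuffle_peaks(peaks, genome, blacklist,
                          seed = derive_seed(seed, r))
    asg <- assign_peaks(shuf, catalog)
    null_mat[r, ] <- class_pct(asg)
    null_in_rep[r] <- mean(!is.na(asg$copy_id)) * 100
  }
  null_mean <- colMeans(null_mat, na.rm = TRUE)
  null_sd <- apply(null_mat, 2, sd, na.rm = TRUE)
  ratio <- ifelse(null_mean > 0, obs_pct / null_mean, Inf)
  p_emp <- vapply(seq_along(classes), function(j) {
    nv <- null_mat[, j][!is.na(null_mat[, j])]
    if (length(nv) == 0 || is.na(obs_pct[j])) return(NA_real_)
    lo <- sum(nv <= obs_pct[j]) + 1L
    hi <- sum(nv >= obs_pct[j]) + 1L
    min(1, 2 * min(lo, hi) / (length(nv) + 1L))
  }, numeric(1))
  occ_in_rep <- occ_class$bp / sum(occ_class$bp) * 100
  per_class <- data.frame(
    class_name = classes,
    observed_pct = as.numeric(obs_pct),
    occupancy_pct_within_repeats =
      occ_in_rep[match(classes, occ_class$group)],
    null_mean_pct = as.numeric(null_mean),
    null_sd_pct = as.numeric(null_sd),
    ratio = as.numeric(ratio),
    ratio_infinite = !is.finite(ratio),
    p_empirical = p_emp,
    row.names = NULL)
  overall <- data.frame(n_peaks = length(peaks),
                        pct_peaks_in_repeats = obs_in_rep,
                        pct_genome_repetitive = pct_genome_rep,
                        null_mean_pct_in_repeats = mean(null_in_rep),
                        null_sd_pct_in_repeats = sd(null_in_rep))
  list(overall = overall, per_class = per_class,
       null_pct_in_repeats = null_in_rep)
}
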