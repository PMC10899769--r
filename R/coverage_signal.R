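#' Coverage tracks
#'
#' A coverage track is a per-chromosome piecewise-constant signal stored
#' as a numeric [S4Vectors::RleList] spanning the whole genome; uncovered
#' positions are value 0 and the run-length encoding is the canonical
#' form (equal-valued adjacent runs merged).  Tracks hold any per-base
#' score: raw coverage, RPM-scaled coverage, or input-subtracted signal
#' (which may be negative).
#'
#' `zero_track()` builds the all-zero track; `track_from_runs()` builds a
#' track from explicit (chrom, start, end, value) runs, 0-based half-open.
#'
#' @param genome `Seqinfo`.
#' @return A numeric `RleList`, one element per chromosome.
#' @export
zero_track <- function(genome) {
  sl <- GenomeInfoDb::seqlengths(genome)
  methods::as(stats::setNames(
    lapply(sl, function(L) S4Vectors::Rle(0, L)), names(sl)), "RleList")
}

#' @describeIn zero_track Track from explicit runs (later runs overwrite
#'   earlier ones where they overlap).
#' @param chrom,start,end,value run coordinates (0-based half-open) and
#'   values.
#' @export
track_from_runs <- function(chrom, start, end, value, genome) {
  tr <- zero_track(genome)
  n <- length(start)
  chrom <- rep(chrom, length.out = n)
  value <- rep(value, length.out = n)
  for (i in seq_len(n)) {
    v <- tr[[chrom[i]]]
    v[(start[i] + 1L):end[i]] <- value[i]
    tr[[chrom[i]]] <- v
  }
  tr
}

#' Coverage from alignment spans
#'
#' Piles up alignment intervals into a coverage track.  Under
#' `unique_only` only alignments with `n_hits == 1` contribute, each with
#' weight 1; under `fractional` every alignment contributes weight
#' `1 / n_hits`, so a read aligned in k places adds total weight 1 when
#' all k alignments are present (equal fractional multi-map weighting).
#'
#' @param alignments `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `n_hits` (>= 1).
#' @param policy `"unique_only"` or `"fractional"`.
#' @param genome `Seqinfo`.
#' @return `list(track = RleList, total_weight = sum of contributed
#'   weights)`.
#' @export
coverage_from_reads <- function(alignments,
                                policy = c("unique_only", "fractional"),
                                genome) {
  policy <- match.arg(policy)
  stop_if_not(all(alignments$end > alignments$start),
              "negative- or zero-length alignment span")
  stop_if_not(all(alignments$n_hits >= 1), "n_hits must be >= 1")
  if (policy == "unique_only") {
    alignments <- alignments[alignments$n_hits == 1, , drop = FALSE]
    w <- rep(1, nrow(alignments))
  } else {
    w <- 1 / alignments$n_hits
  }
  if (nrow(alignments) == 0)
    return(list(track = zero_track(genome), total_weight = 0))
  gr <- granges0(alignments$chrom, alignments$start, alignments$end, genome)
  check_bounds(gr, genome, "alignments")
  cov <- GenomicRanges::coverage(gr, weight = w)
  # coverage() may drop chromosomes with no reads; keep the full genome
  tr <- zero_track(genome)
  for (chr in names(cov)) tr[[chr]] <- cov[[chr]]
  list(track = tr, total_weight = sum(w))
}

#' Reads-per-million scaling
#'
#' Multiplies every value by `1e6 / total_reads`.
#'
#' @param track a coverage track.
#' @param total_reads library size (positive; typically the
#'   `total_weight` from [coverage_from_reads()]).
#' @export
rpm_normalize <- function(track, total_reads) {
  stop_if_not(is.numeric(total_reads) && total_reads > 0,
              "total_reads must be positive")
  track * (1e6 / total_reads)
}

#' Input subtraction
#'
#' Per-base difference `chip - input`.  Negative values are retained:
#' difference tracks are used as-is downstream.
#'
#' @param chip,input_track coverage tracks on the same genome.
#' @export
subtract_input <- function(chip, input_track) {
  stop_if_not(setequal(names(chip), names(input_track)),
              "chromosome sets differ between chip and input")
  chip - input_track[names(chip)]
}

#' Length-weighted mean signal over an interval
#'
#' @param track a coverage track.
#' @param chrom,start,end interval, 0-based half-open, length > 0.
#' @return The mean value over the interval.
#' @export
mean_over <- function(track, chrom, start, end) {
  stop_if_not(end > start, "zero-length interval")
  stop_if_not(chrom %in% names(track), "unknown chromosome '%s'", chrom)
  stop_if_not(start >= 0 && end <= length(track[[chrom]]),
              "interval outside chromosome bounds")
  mean(S4Vectors::window(track[[chrom]], start + 1L, end))
}

#' Per-copy abundance table
#'
#' Summarizes one or more tracks over every catalog copy with the
#' length-weighted mean (the per-repeat "abundance"); alternative
#' aggregators `sum` and `median` are available.
#'
#' @param tracks named list of coverage tracks.
#' @param catalog a repeat catalog.
#' @param stat `"mean"` (default), `"sum"` or `"median"`.
#' @return Numeric matrix, rows = `copy_id`, columns = track names.
#' @export
abundance_table <- function(tracks, catalog,
                            stat = c("mean", "sum", "median")) {
  stat <- match.arg(stat)
  stop_if_not(!is.null(names(tracks)) && all(nzchar(names(tracks))),
              "tracks must be a named list")
  out <- matrix(NA_real_, nrow = length(catalog), ncol = length(tracks),
                dimnames = list(catalog$copy_id, names(tracks)))
  chr <- as.character(GenomicRanges::seqnames(catalog))
  for (tn in names(tracks)) {
    track <- tracks[[tn]]
    for (c1 in unique(chr)) {
      i <- which(chr == c1)
      v <- IRanges::Views(track[[c1]], start = start0(catalog)[i] + 1L,
                          end = end0(catalog)[i])
      out[i, tn] <- switch(stat,
                           mean = IRanges::viewMeans(v),
                           sum = IRanges::viewSums(v),
                           median = vapply(seq_along(v), function(k)
                             median(as.numeric(v[[k]])), numeric(1)))
    }
  }
  out
}

#' Quantile tail of an abundance distribution
#'
#' Returns the copies whose value on one track lies in the top or bottom
#' `fraction` of the given group, e.g. the top 10% of H3K9me3 abundance
#' within a family.  The subset size is `ceiling(fraction * n)`; ties are
#' broken by `copy_id` order (documented, deterministic).
#'
#' @param table an [abundance_table()] matrix.
#' @param track column name.
#' @param group character vector of copy ids defining the comparison
#'   group (default: all rows).
#' @param side `"top"` or `"bottom"`.
#' @param fraction tail fraction in (0, 1).
#' @return Character vector of selected copy ids.
#' @export
filter_by_quantile <- function(table, track, group = rownames(table),
                               side = c("top", "bottom"), fraction = 0.1) {
  side <- match.arg(side)
  stop_if_not(fraction > 0 && fraction < 1, "fraction must be in (0,1)")
  group <- intersect(group, rownames(table))
  stop_if_not(length(group) > 0, "empty group")
  vals <- table[group, track]
  k <- ceiling(fraction * length(group))
  ord <- if (side == "top") order(-vals, group) else order(vals, group)
  group[ord[seq_len(k)]]
}

#' bedGraph input / output
#'
#' Tracks are written as 4-column bedGraph including zero-coverage runs,
#' with full-precision values so that write -> read reproduces the
#' canonical runs exactly.  Reading accepts any bedGraph; positions not
#' covered by a record become 0.
#'
#' @param track a coverage track.
#' @param path bedGraph file.
#' @param genome `Seqinfo` (for reading).
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chr in names(track)) {
    r <- track[[chr]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0L, head(ends, -1L))
    writeLines(sprintf("%s\t%d\t%d\t%.17g", chr, starts, ends,
                       S4Vectors::runValue(r)), con)
  }
  invisible(path)
}

#' @rdname write_bedgraph
#' @export
read_bedgraph <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  tr <- zero_track(genome)
  if (length(gr) == 0) return(tr)
  check_bounds(gr, genome, "bedGraph")
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(genome)
  GenomeInfoDb::seqinfo(gr) <- genome
  # bedGraph records are disjoint, so weighted coverage reconstructs runs
  cov <- GenomicRanges::coverage(gr, weight = gr$score)
  for (chr in names(cov)) tr[[chr]] <- cov[[chr]]
  tr
}
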