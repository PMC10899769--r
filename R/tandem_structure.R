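#' Tandem-position classification of repeat copies
#'
#' Labels each focal copy (e.g. every SVA_F element) by its position
#' relative to neighboring context copies (e.g. all SVA elements) within
#' `window_bp`: no neighbor on either side is `alone`; a neighbor only
#' downstream (3', higher coordinates) is `first`; only upstream (5') is
#' `last`; both sides is `internal`.  The gap is measured end-to-start
#' in genomic coordinates (strand ignored); overlapping or adjacent
#' context copies count as flanking at distance 0 and a gap of exactly
#' `window_bp` qualifies (inclusive).  A context copy is upstream of a
#' focal copy when its start lies left of the focal start, downstream
#' when its end lies right of the focal end; the focal copy itself never
#' counts as its own neighbor.
#'
#' @param focal `GRanges` of focal copies (with `copy_id`).
#' @param context `GRanges` of context copies; may include the focal
#'   copies.
#' @param window_bp maximum qualifying gap (default 500).
#' @return Named character vector: `copy_id` -> label in
#'   `c("alone", "first", "internal", "last")`.
#' @export
classify_tandem <- function(focal, context, window_bp = 500L) {
  stop_if_not(window_bp >= 0, "window_bp must be >= 0")
  ids <- if (!is.null(focal$copy_id)) focal$copy_id else
    as.character(seq_along(focal))
  labels <- setNames(rep("alone", length(focal)), ids)
  fchr <- as.character(GenomicRanges::seqnames(focal))
  cchr <- as.character(GenomicRanges::seqnames(context))
  for (c1 in unique(fchr)) {
    fi <- which(fchr == c1)
    ci <- which(cchr == c1)
    fs <- start0(focal)[fi]; fe <- end0(focal)[fi]
    if (length(ci) == 0) next
    cs <- start0(context)[ci]; ce <- end0(context)[ci]
    # upstream: any context with start < focal start and end >= start - w.
    # Sorted by start, the prefix-max of ends answers the query per focal.
    o <- order(cs)
    cs_s <- cs[o]; ce_s <- ce[o]
    premax_end <- cummax(ce_s)
    n_before <- findInterval(fs - 1L, cs_s)   # contexts with start < fs
    has5 <- n_before >= 1 &
      premax_end[pmax(n_before, 1L)] >= fs - window_bp
    # downstream: any context with end > focal end and start <= end + w.
    o2 <- order(ce)
    cs_e <- cs[o2]; ce_e <- ce[o2]
    sufmin_start <- rev(cummin(rev(cs_e)))
    n_upto <- findInterval(fe, ce_e)          # contexts with end <= fe
    has3 <- n_upto < length(ci) &
      sufmin_start[pmin(n_upto + 1L, length(ci))] <= fe + window_bp
    lab <- ifelse(has5 & has3, "internal",
                  ifelse(has3, "first", ifelse(has5, "last", "alone")))
    labels[fi] <- lab
  }
  labels
}

#' Tandem-position-stratified meta-profiles
#'
#' One scaled meta-repeat profile per tandem label class; empty classes
#' are omitted with a warning.
#'
#' @param track a coverage track.
#' @param focal `GRanges` of the labeled copies.
#' @param labels output of [classify_tandem()] for `focal`.
#' @param ... binning parameters passed to [scaled_profile()].
#' @return Named list of `ProfileMatrix`, one per present label.
#' @export
stratified_profiles <- function(track, focal, labels, ...) {
  ids <- if (!is.null(focal$copy_id)) focal$copy_id else
    as.character(seq_along(focal))
  out <- list()
  for (lab in c("alone", "first", "internal", "last")) {
    sel <- which(ids %in% names(labels)[labels == lab])
    if (length(sel) == 0) {
      warning("no copies with tandem label '", lab, "'")
      next
    }
    out[[lab]] <- scaled_profile(track, focal[sel], ...)
  }
  out
}

#' @describeIn classify_tandem Write tandem labels as BED (name field =
#'   label) and return label counts.
#' @param path output BED path.
#' @export
write_tandem_labels <- function(focal, labels, path) {
  ids <- if (!is.null(focal$copy_id)) focal$copy_id else
    as.character(seq_along(focal))
  write_bed(focal, path, name = unname(labels[ids]))
  table(factor(labels, levels = c("alone", "first", "internal", "last")))
}
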