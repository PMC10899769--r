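# Fractional-apportioned binning: per-base values v are divided into B
# equal-width bins; a base straddling a bin edge contributes to both bins
# in proportion to the overlapped fraction.  Exact via linear
# interpolation of the cumulative sum at fractional positions.
frac_bins <- function(v, B) {
  n <- length(v)
  cum <- c(0, cumsum(v))
  edges <- n * (0:B) / B
  lo <- floor(edges)
  frac <- edges - lo
  at <- cum[pmin(lo, n) + 1L] + frac * c(v, 0)[pmin(lo + 1L, n)]
  diff(at) / (n / B)
}

# Mean signal in fixed-width genomic bins over [start, end); bins not
# fully inside [0, chrlen) are NA (missing, never zero-filled).  Bin
# edges may be fractional; means use the same cumulative interpolation
# as frac_bins.
fixed_bins <- function(rle, start, end, nbins, chrlen) {
  out <- rep(NA_real_, nbins)
  lo <- max(0, floor(start)); hi <- min(chrlen, ceiling(end))
  if (lo >= hi) return(out)
  v <- as.numeric(S4Vectors::window(rle, as.integer(lo) + 1L,
                                    as.integer(hi)))
  cum <- c(0, cumsum(v))
  interp <- function(x) {
    k <- floor(x); f <- x - k
    cum[k + 1L] + f * c(v, 0)[k + 1L]
  }
  width <- (end - start) / nbins
  for (b in seq_len(nbins)) {
    s <- start + width * (b - 1); e <- start + width * b
    if (s < -1e-9 || e > chrlen + 1e-9) next
    out[b] <- (interp(e - lo) - interp(s - lo)) / (e - s)
  }
  out
}

#' Scaled meta-repeat profile
#'
#' Bins the signal over every copy: the copy body is scaled to
#' `body_bins` equal sub-intervals (length-weighted mean per bin, with
#' fractional base apportioning so copies shorter than `body_bins` bases
#' remain valid), plus fixed `flank_bp` flanks on each side split into
#' `flank_bins` bins.  Minus-strand copies are reversed when
#' `orient_by_strand` so that columns always read 5' flank, body, 3'
#' flank.  Flank bins extending past a chromosome end are `NA` and are
#' excluded from averages, never treated as zero.
#'
#' @param track a coverage track.
#' @param copies `GRanges` of repeat copies (a catalog subset).
#' @param body_bins number of body bins (default 100).
#' @param flank_bp flank width in bp (default 3000, the 3-kb convention).
#' @param flank_bins bins per flank (default 60, i.e. 50-bp bins).
#' @param orient_by_strand reverse minus-strand copies (default TRUE).
#' @return A `ProfileMatrix`: numeric matrix rows = `copy_id`, columns =
#'   upstream flank / body / downstream flank bins, with binning metadata
#'   in attributes.
#' @export
scaled_profile <- function(track, copies, body_bins = 100L,
                           flank_bp = 3000L, flank_bins = 60L,
                           orient_by_strand = TRUE) {
  stop_if_not(body_bins >= 1, "body_bins must be >= 1")
  stop_if_not(flank_bp >= 0, "flank_bp must be >= 0")
  stop_if_not(length(copies) > 0, "no copies")
  stop_if_not(all(GenomicRanges::width(copies) > 0), "zero-length copy")
  use_flanks <- flank_bp > 0 && flank_bins > 0
  fb <- if (use_flanks) flank_bins else 0L
  ncol <- 2L * fb + body_bins
  out <- matrix(NA_real_, length(copies), ncol)
  rownames(out) <- if (!is.null(copies$copy_id)) copies$copy_id else
    as.character(seq_along(copies))
  colnames(out) <- c(if (fb) paste0("u", seq_len(fb)),
                     paste0("b", seq_len(body_bins)),
                     if (fb) paste0("d", seq_len(fb)))
  chr <- as.character(GenomicRanges::seqnames(copies))
  str <- as.character(GenomicRanges::strand(copies))
  s0 <- start0(copies); e0 <- end0(copies)
  for (i in seq_along(copies)) {
    rle <- track[[chr[i]]]
    L <- length(rle)
    v <- as.numeric(S4Vectors::window(rle, s0[i] + 1L, e0[i]))
    body <- frac_bins(v, body_bins)
    row <- if (use_flanks)
      c(fixed_bins(rle, s0[i] - flank_bp, s0[i], fb, L), body,
        fixed_bins(rle, e0[i], e0[i] + flank_bp, fb, L))
    else body
    if (orient_by_strand && str[i] == "-") row <- rev(row)
    out[i, ] <- row
  }
  structure(out, body_bins = body_bins, flank_bp = flank_bp,
            flank_bins = fb, oriented = orient_by_strand,
            class = c("ProfileMatrix", "matrix", "array"))
}

#' Reference-point profile
#'
#' Fixed-width bins in a symmetric window around each reference point
#' (e.g. peak midpoints), strand-oriented; bins off the chromosome are
#' `NA`.
#'
#' @param track a coverage track.
#' @param points `data.frame` with columns `chrom`, `pos` (0-based) and
#'   optionally `strand`.
#' @param flank_bp half-window in bp.
#' @param bin_bp bin width; must divide `2 * flank_bp`.
#' @return A `ProfileMatrix` with `2 * flank_bp / bin_bp` columns.
#' @export
reference_point_profile <- function(track, points, flank_bp, bin_bp) {
  stop_if_not((2 * flank_bp) %% bin_bp == 0,
              "bin_bp must divide 2*flank_bp")
  nb <- as.integer(2 * flank_bp / bin_bp)
  if (is.null(points$strand)) points$strand <- "*"
  out <- matrix(NA_real_, nrow(points), nb)
  colnames(out) <- paste0("bin", seq_len(nb))
  for (i in seq_len(nrow(points))) {
    rle <- track[[points$chrom[i]]]
    row <- fixed_bins(rle, points$pos[i] - flank_bp,
                      points$pos[i] + flank_bp, nb, length(rle))
    if (points$strand[i] == "-") row <- rev(row)
    out[i, ] <- row
  }
  structure(out, flank_bp = flank_bp, bin_bp = bin_bp,
            class = c("ProfileMatrix", "matrix", "array"))
}

#' @describeIn scaled_profile Column means of a profile matrix with
#'   missing bins excluded — the average meta-profile.
#' @param profile a `ProfileMatrix`.
#' @export
average_profile <- function(profile) {
  colMeans(profile, na.rm = TRUE)
}

#' Scale and order a summary matrix for heatmap display
#'
#' Row z-scoring (subtract row mean, divide by row SD; constant rows map
#' to all-zero and are flagged) followed by deterministic ordering:
#' `"cluster"` performs agglomerative clustering with euclidean distance
#' and complete linkage on rows and columns of the scaled matrix (rows
#' are canonicalized by label first, so the result is invariant under
#' input row permutation), `"mean_desc"` orders rows by descending mean,
#' `"given"` keeps the input order.
#'
#' @param mat numeric matrix (e.g. family means x tracks).
#' @param scale `"row_z"` or `"none"`.
#' @param order `"cluster"`, `"mean_desc"` or `"given"`.
#' @return `list(matrix, row_order, col_order, constant_rows)`; `matrix`
#'   is scaled but in input order — apply the orders for display.
#' @export
scale_and_order <- function(mat, scale = c("row_z", "none"),
                            order = c("cluster", "mean_desc", "given")) {
  scale <- match.arg(scale)
  order <- match.arg(order)
  mat <- as.matrix(mat)
  constant <- rep(FALSE, nrow(mat))
  sc <- mat
  if (scale == "row_z") {
    mu <- rowMeans(mat)
    sdv <- apply(mat, 1, sd)
    constant <- sdv == 0 | is.na(sdv)
    sdv[constant] <- 1
    sc <- (mat - mu) / sdv
    sc[constant, ] <- 0
  }
  rn <- if (!is.null(rownames(mat))) rownames(mat) else
    as.character(seq_len(nrow(mat)))
  cn <- if (!is.null(colnames(mat))) colnames(mat) else
    as.character(seq_len(ncol(mat)))
  row_order <- seq_len(nrow(mat))
  col_order <- seq_len(ncol(mat))
  if (order == "cluster") {
    stop_if_not(nrow(mat) >= 2, "clustering needs at least 2 rows")
    canon <- base::order(rn)
    hr <- hclust(dist(sc[canon, , drop = FALSE], method = "euclidean"),
                 method = "complete")
    row_order <- canon[hr$order]
    if (ncol(mat) >= 2) {
      ccanon <- base::order(cn)
      hc <- hclust(dist(t(sc)[ccanon, , drop = FALSE],
                        method = "euclidean"), method = "complete")
      col_order <- ccanon[hc$order]
    }
  } else if (order == "mean_desc") {
    row_order <- base::order(-rowMeans(sc, na.rm = TRUE), rn)
  }
  list(matrix = sc, row_order = row_order, col_order = col_order,
       constant_rows = constant)
}

#' Write / plot profile matrices
#'
#' `write_profile()` writes a `ProfileMatrix` as TSV (rows = copies) with
#' a `# key=value` metadata header; `plot_profiles()` draws average
#' meta-profile lines for one or more profiles.
#'
#' @param profile a `ProfileMatrix`.
#' @param path output TSV.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- attributes(profile)[c("body_bins", "flank_bp", "flank_bins",
                                "bin_bp", "oriented")]
  meta <- meta[!vapply(meta, is.null, logical(1))]
  writeLines(sprintf("# %s=%s", names(meta), unlist(meta)), con)
  write.table(data.frame(copy_id = rownames(profile), profile,
                         check.names = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param profiles named list of `ProfileMatrix` objects.
#' @param main plot title.
#' @export
plot_profiles <- function(profiles, main = "meta-repeat profile") {
  avgs <- lapply(profiles, average_profile)
  ylim <- range(unlist(avgs), na.rm = TRUE)
  graphics::plot(NA, xlim = c(1, max(lengths(avgs))), ylim = ylim,
                 xlab = "bin", ylab = "mean signal", main = main)
  for (i in seq_along(avgs))
    graphics::lines(seq_along(avgs[[i]]), avgs[[i]], col = i, lwd = 2)
  graphics::legend("topright", legend = names(profiles),
                   col = seq_along(profiles), lwd = 2, bty = "n")
  invisible(NULL)
}
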