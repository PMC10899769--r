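#' Genome layout constructors and interval file I/O
#'
#' A genome layout is represented as a [GenomeInfoDb::Seqinfo] object:
#' unique chromosome names with positive lengths.  All package coordinates
#' are 0-based half-open internally; `GRanges` objects (1-based closed) are
#' converted at the boundary by the readers/writers below.
#'
#' @param chroms character vector of chromosome names (unique).
#' @param lengths integer vector of chromosome lengths in bp (positive).
#' @return A `Seqinfo` describing the genome.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chroms, lengths) {
  stop_if_not(length(chroms) == length(lengths),
              "chroms and lengths differ in length")
  stop_if_not(!anyDuplicated(chroms), "chromosome names must be unique")
  stop_if_not(all(lengths > 0), "chromosome lengths must be positive")
  GenomeInfoDb::Seqinfo(seqnames = as.character(chroms),
                        seqlengths = as.integer(lengths))
}

#' @describeIn genome_layout Read a two-column `chrom.sizes` TSV.
#' @param path file path.
#' @export
read_chrom_sizes <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "length"),
                    colClasses = c("character", "integer"))
  genome_layout(tab$chrom, tab$length)
}

#' @describeIn genome_layout Write a genome layout as `chrom.sizes`.
#' @param genome a `Seqinfo`.
#' @export
write_chrom_sizes <- function(genome, path) {
  write.table(data.frame(GenomeInfoDb::seqnames(genome),
                         GenomeInfoDb::seqlengths(genome)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

genome_size <- function(genome) {
  sum(as.double(GenomeInfoDb::seqlengths(genome)))
}

# Build a GRanges from 0-based half-open coordinates; bounds are checked
# before seqinfo is attached so violations surface as package errors.
granges0 <- function(chrom, start0, end0, genome = NULL, strand = "*",
                     what = "interval set", ...) {
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start0) + 1L,
                              end = as.integer(end0)),
    strand = strand,
    ...)
  if (!is.null(genome)) {
    check_bounds(gr, genome, what)
    GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(genome)
    GenomeInfoDb::seqinfo(gr) <- genome
  }
  gr
}

start0 <- function(gr) GenomicRanges::start(gr) - 1L
end0 <- function(gr) GenomicRanges::end(gr)

#' Read a BED interval file
#'
#' Reads BED3+ (extra columns beyond the sixth are ignored, as for
#' narrowPeak input).  Coordinates in the file are 0-based half-open and
#' are converted to `GRanges`.
#'
#' @param path BED file path.
#' @param genome optional `Seqinfo`; when given, intervals are checked
#'   against chromosome bounds.
#' @return `GRanges` with optional `name` and `score` metadata columns.
#' @export
read_bed <- function(path, genome = NULL) {
  tab <- tryCatch(
    read.table(path, sep = "\t", header = FALSE, comment.char = "#",
               stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(data.frame())
      stop("malformed BED file '", path, "': ", conditionMessage(e),
           call. = FALSE)
    })
  if (nrow(tab) == 0)
    return(granges0(character(), integer(), integer(), genome))
  stop_if_not(ncol(tab) >= 3, "BED file '%s' has fewer than 3 columns", path)
  gr <- granges0(tab[[1]], tab[[2]], tab[[3]], genome,
                 strand = if (ncol(tab) >= 6)
                   ifelse(tab[[6]] %in% c("+", "-"), tab[[6]], "*") else "*")
  if (ncol(tab) >= 4) gr$name <- as.character(tab[[4]])
  if (ncol(tab) >= 5) gr$score <- suppressWarnings(as.numeric(tab[[5]]))
  if (!is.null(genome)) check_bounds(gr, genome, path)
  gr
}

#' @describeIn read_bed Write a `GRanges` as BED (0-based half-open).
#' @param gr intervals to write.
#' @param name optional character vector for the BED name field.
#' @export
write_bed <- function(gr, path, name = gr$name) {
  score <- if (!is.null(gr$score)) gr$score else 0
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = start0(gr), end = end0(gr))
  if (!is.null(name)) {
    df$name <- name
    df$score <- score
    df$strand <- as.character(GenomicRanges::strand(gr))
    df$strand[df$strand == "*"] <- "."
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

check_bounds <- function(gr, genome, what = "interval set") {
  sl <- GenomeInfoDb::seqlengths(genome)
  chr <- as.character(GenomicRanges::seqnames(gr))
  bad <- !(chr %in% names(sl))
  stop_if_not(!any(bad), "%s: unknown chromosome '%s'", what,
              paste(unique(chr[bad]), collapse = ","))
  over <- end0(gr) > sl[chr] | start0(gr) < 0L
  stop_if_not(!any(over), "%s: %d interval(s) outside chromosome bounds",
              what, sum(over))
  invisible(TRUE)
}
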