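#' Build a repeat catalog
#'
#' A repeat catalog is a `GRanges` carrying the RepeatMasker-style
#' hierarchy as metadata columns: `repeat_name` (e.g. AluYa5), `family`
#' (e.g. Alu), `class_name` (e.g. SINE), a deterministic `copy_id`
#' (`chrom:start-end:repeat_name`, 0-based half-open printed coordinates)
#' and an optional `clade_rank` (see [assign_clades()]).  The constructor
#' enforces the catalog invariants: coordinates within chromosome bounds
#' and a consistent (class, family) pair for every repeat name.
#'
#' @param chrom,start,end copy coordinates, 0-based half-open.
#' @param repeat_name,family,class_name hierarchy labels per copy.
#' @param strand "+", "-" or "*" per copy (recycled).
#' @param genome a `Seqinfo` from [genome_layout()].
#' @return A `GRanges` repeat catalog.
#' @examples
#' g <- genome_layout("chr1", 1e5)
#' repeat_catalog("chr1", c(100, 5000), c(400, 5300),
#'                repeat_name = c("AluY", "AluY"),
#'                family = "Alu", class_name = "SINE", genome = g)
#' @export
repeat_catalog <- function(chrom, start, end, repeat_name, family,
                           class_name, strand = "*", genome = NULL) {
  n <- length(start)
  gr <- granges0(rep(chrom, length.out = n), start, end, genome,
                 strand = rep(strand, length.out = n))
  gr$repeat_name <- as.character(rep(repeat_name, length.out = n))
  gr$family <- as.character(rep(family, length.out = n))
  gr$class_name <- as.character(rep(class_name, length.out = n))
  gr$copy_id <- sprintf("%s:%d-%d:%s",
                        as.character(GenomicRanges::seqnames(gr)),
                        start0(gr), end0(gr), gr$repeat_name)
  gr$clade_rank <- rep(NA_integer_, length(gr))
  if (!is.null(genome)) check_bounds(gr, genome, "repeat catalog")
  validate_catalog(gr)
  gr
}

validate_catalog <- function(gr) {
  if (length(gr) == 0) return(invisible(gr))
  stop_if_not(all(GenomicRanges::width(gr) > 0), "zero-length repeat copy")
  key <- paste(gr$class_name, gr$family, sep = "\r")
  bad <- tapply(key, gr$repeat_name, function(k) length(unique(k)) > 1)
  if (any(bad)) {
    offenders <- names(bad)[bad]
    ids <- gr$copy_id[gr$repeat_name %in% offenders]
    stop("inconsistent class/family labels for repeat name(s) ",
         paste(offenders, collapse = ", "), "; copies: ",
         paste(ids, collapse = ", "), call. = FALSE)
  }
  invisible(gr)
}

#' Read a repeat annotation into a catalog
#'
#' Supported dialects: TEtranscripts-style GTF (1-based closed coordinates;
#' attributes `gene_id` = repeat name, `family_id`, `class_id`) and
#' 6-column BED (0-based half-open; name field encoded as
#' `class/family/name`).  Coordinates are converted to the internal 0-based
#' half-open convention on read.
#'
#' @param path annotation file.
#' @param dialect `"gtf"` or `"bed"`.
#' @param genome `Seqinfo`; copies outside chromosome bounds are an error.
#' @return A repeat catalog `GRanges`.
#' @export
read_repeat_annotation <- function(path, dialect = c("gtf", "bed"), genome) {
  dialect <- match.arg(dialect)
  stop_if_not(file.exists(path), "annotation file '%s' not found", path)
  if (dialect == "bed") {
    gr <- read_bed(path, genome)
    if (length(gr) == 0)
      return(repeat_catalog(character(), integer(), integer(),
                            character(), character(), character(),
                            genome = genome))
    parts <- strsplit(gr$name, "/", fixed = TRUE)
    bad <- which(lengths(parts) != 3)
    stop_if_not(length(bad) == 0,
                "BED name field not class/family/name at record %s",
                paste(head(bad, 5), collapse = ","))
    p <- do.call(rbind, parts)
    return(repeat_catalog(as.character(GenomicRanges::seqnames(gr)),
                          start0(gr), end0(gr),
                          repeat_name = p[, 3], family = p[, 2],
                          class_name = p[, 1],
                          strand = as.character(GenomicRanges::strand(gr)),
                          genome = genome))
  }
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(repeat_catalog(character(), integer(), integer(),
                          character(), character(), character(),
                          genome = genome))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 9)
  stop_if_not(length(bad) == 0, "malformed GTF record at line %d of %s",
              if (length(bad)) bad[1] else 0L, path)
  m <- do.call(rbind, lapply(fields, `[`, 1:9))
  s1 <- suppressWarnings(as.integer(m[, 4]))
  e1 <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(s1) | is.na(e1) | s1 > e1)
  stop_if_not(length(bad) == 0, "malformed GTF coordinates at line %d of %s",
              if (length(bad)) bad[1] else 0L, path)
  attr_get <- function(attrs, key) {
    pat <- paste0(key, "[ =]+\"?([^\";]+)\"?")
    hit <- regmatches(attrs, regexec(pat, attrs))
    val <- vapply(hit, function(h) if (length(h) == 2) h[2] else NA_character_,
                  character(1))
    val
  }
  name <- attr_get(m[, 9], "gene_id")
  fam <- attr_get(m[, 9], "family_id")
  cls <- attr_get(m[, 9], "class_id")
  bad <- which(is.na(name) | is.na(fam) | is.na(cls))
  stop_if_not(length(bad) == 0,
              "GTF record missing gene_id/family_id/class_id at line %d of %s",
              if (length(bad)) bad[1] else 0L, path)
  # GTF is 1-based closed: [s1, e1] -> 0-based half-open [s1-1, e1)
  repeat_catalog(m[, 1], s1 - 1L, e1, repeat_name = name, family = fam,
                 class_name = cls,
                 strand = ifelse(m[, 7] %in% c("+", "-"), m[, 7], "*"),
                 genome = genome)
}

#' @describeIn read_repeat_annotation Write a catalog as 6-column BED
#'   (name = `class/family/name`) or TEtranscripts-style GTF.
#' @param catalog a repeat catalog.
#' @export
write_catalog <- function(catalog, path, dialect = c("bed", "gtf")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    nm <- paste(catalog$class_name, catalog$family, catalog$repeat_name,
                sep = "/")
    return(write_bed(catalog, path, name = nm))
  }
  strand <- as.character(GenomicRanges::strand(catalog))
  strand[strand == "*"] <- "."
  lines <- sprintf(
    paste0("%s\tteprofiler\texon\t%d\t%d\t.\t%s\t.\t",
           "gene_id \"%s\"; transcript_id \"%s\"; family_id \"%s\"; ",
           "class_id \"%s\";"),
    as.character(GenomicRanges::seqnames(catalog)),
    start0(catalog) + 1L, end0(catalog), strand,
    catalog$repeat_name, catalog$copy_id, catalog$family,
    catalog$class_name)
  writeLines(lines, path)
  invisible(path)
}

#' Exclude uncertain and blacklisted repeat copies
#'
#' Removes every copy whose class or family name ends in `'?'` (uncertain
#' RepeatMasker classification) and every copy overlapping a blacklist
#' interval by at least `min_overlap` bp.  Counts removed per reason are
#' stored in `metadata(catalog)$exclusions`.  Idempotent.
#'
#' @param catalog a repeat catalog.
#' @param blacklist `GRanges` of problematic regions (may be empty).
#' @param min_overlap minimum overlap in bp that triggers removal
#'   (default 1).
#' @return The filtered catalog.
#' @export
apply_exclusions <- function(catalog, blacklist = GenomicRanges::GRanges(),
                             min_overlap = 1L) {
  uncertain <- endsWith(catalog$class_name, "?") |
    endsWith(catalog$family, "?")
  kept <- catalog[!uncertain]
  n_black <- 0L
  if (length(blacklist) > 0 && length(kept) > 0) {
    hits <- GenomicRanges::findOverlaps(kept, blacklist,
                                        minoverlap = as.integer(min_overlap),
                                        ignore.strand = TRUE)
    drop <- unique(S4Vectors::queryHits(hits))
    n_black <- length(drop)
    if (n_black > 0) kept <- kept[-drop]
  }
  md <- S4Vectors::metadata(kept)
  md$exclusions <- c(uncertain = sum(uncertain), blacklist = n_black) +
    if (!is.null(md$exclusions)) md$exclusions else c(uncertain = 0L,
                                                      blacklist = 0L)
  S4Vectors::metadata(kept) <- md
  kept
}

#' Genome occupancy of repeat groups
#'
#' Base pairs are the per-group union of copy intervals (overlapping copies
#' are not double-counted); percent is relative to the total genome size.
#'
#' @param catalog a repeat catalog.
#' @param genome `Seqinfo`.
#' @param level `"class"`, `"family"`, `"repeat_name"` or `"all"` (one row
#'   for the whole catalog).
#' @return `data.frame` with columns `group`, `bp`, `percent`.
#' @export
occupancy <- function(catalog, genome,
                      level = c("class", "family", "repeat_name", "all")) {
  level <- match.arg(level)
  gsize <- genome_size(genome)
  stop_if_not(gsize > 0, "zero-length genome")
  grouping <- switch(level,
                     class = catalog$class_name,
                     family = catalog$family,
                     repeat_name = catalog$repeat_name,
                     all = rep("all", length(catalog)))
  if (length(catalog) == 0)
    return(data.frame(group = character(), bp = numeric(),
                      percent = numeric()))
  per <- vapply(split(catalog, grouping), function(g)
    sum(as.double(GenomicRanges::width(GenomicRanges::reduce(
      g, ignore.strand = TRUE)))), numeric(1))
  data.frame(group = names(per), bp = unname(per),
             percent = unname(per) / gsize * 100, row.names = NULL)
}

#' Partition labeled segments into repetitive / non-repetitive pieces
#'
#' Each input segment (e.g. an A/B compartment interval) is split at the
#' boundaries of the repeat union: pieces inside the union are labeled
#' `R`, the remainder `NR`.  The output exactly tiles every input segment.
#'
#' @param segments `GRanges` with a `label` metadata column; segments must
#'   not overlap within a label.
#' @param catalog a repeat catalog.
#' @return `GRanges` with columns `label`, `rclass` (`"R"`/`"NR"`) and
#'   `segment_id` (index into `segments`).
#' @export
partition_repetitive <- function(segments, catalog) {
  if (is.null(segments$label)) segments$label <- "."
  un <- GenomicRanges::reduce(catalog, ignore.strand = TRUE)
  GenomicRanges::strand(segments) <- "*"
  out <- list()
  for (i in seq_along(segments)) {
    seg <- segments[i]
    r <- GenomicRanges::intersect(seg, un, ignore.strand = TRUE)
    nr <- GenomicRanges::setdiff(seg, r, ignore.strand = TRUE)
    piece <- c(r, nr)
    if (length(piece) == 0) next
    piece$label <- seg$label
    piece$rclass <- rep(c("R", "NR"), c(length(r), length(nr)))
    piece$segment_id <- i
    out[[length(out) + 1L]] <- piece
  }
  if (length(out) == 0)
    return(GenomicRanges::GRanges(label = character(), rclass = character(),
                                  segment_id = integer()))
  res <- sort(do.call(c, out), ignore.strand = TRUE)
  res
}

#' Evolutionary clade table
#'
#' Maps repeat names to the oldest taxonomic clade in which orthologous
#' copies occur (Dfam-style classification).  Clade labels are ordered
#' oldest to youngest and carry integer ranks starting at 0.
#'
#' @param repeat_name character vector of repeat names.
#' @param clade character vector of clade labels (same length).
#' @param levels ordered clade labels, oldest first; defaults to the
#'   seven-clade primate lineage scheme.
#' @return `data.frame(repeat_name, clade, clade_rank)` with the ordered
#'   levels in `attr(, "clade_levels")`.
#' @export
clade_table <- function(repeat_name, clade, levels = default_clades()) {
  stop_if_not(length(repeat_name) == length(clade),
              "repeat_name and clade differ in length")
  bad <- setdiff(unique(clade), levels)
  stop_if_not(length(bad) == 0, "clade label(s) not in ordered list: %s",
              paste(bad, collapse = ", "))
  tab <- data.frame(repeat_name = as.character(repeat_name),
                    clade = as.character(clade),
                    clade_rank = match(clade, levels) - 1L)
  attr(tab, "clade_levels") <- levels
  tab
}

#' @describeIn clade_table The default ordered clade labels, oldest first.
#' @export
default_clades <- function() {
  c("Non-Primates", "Primates", "Simiiformes", "Catarrhini",
    "Hominoidea", "Hominidae", "Homo_sapiens")
}

#' @describeIn clade_table Read a two-column TSV (`repeat_name`, `clade`);
#'   an optional header line is detected.  `levels` defaults to the clade
#'   labels in order of first appearance if not supplied.
#' @param path TSV path.
#' @export
read_clade_table <- function(path, levels = NULL) {
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  if (identical(tolower(tab[1, 1]), "repeat_name")) tab <- tab[-1, ]
  if (is.null(levels)) {
    lv <- default_clades()
    levels <- if (all(unique(tab[[2]]) %in% lv)) lv else unique(tab[[2]])
  }
  clade_table(tab[[1]], tab[[2]], levels)
}

#' Attach clade ranks to a catalog
#'
#' Each copy receives the clade rank of its repeat name.  Names absent
#' from the table are handled per `on_missing`: `"label_unknown"` leaves
#' `clade_rank` `NA` and flags the copy (`unknown_clade`); `"error"`
#' stops, naming the repeat.
#'
#' @param catalog a repeat catalog.
#' @param clades a [clade_table()].
#' @param on_missing `"label_unknown"` or `"error"`.
#' @return The catalog with `clade_rank` (and `unknown_clade`) filled in.
#' @export
assign_clades <- function(catalog, clades,
                          on_missing = c("label_unknown", "error")) {
  on_missing <- match.arg(on_missing)
  idx <- match(catalog$repeat_name, clades$repeat_name)
  missing <- is.na(idx)
  if (on_missing == "error" && any(missing))
    stop("no clade for repeat name(s): ",
         paste(unique(catalog$repeat_name[missing]), collapse = ", "),
         call. = FALSE)
  catalog$clade_rank <- clades$clade_rank[idx]
  catalog$unknown_clade <- missing
  md <- S4Vectors::metadata(catalog)
  md$clade_levels <- attr(clades, "clade_levels")
  md$n_unknown_clade <- sum(missing)
  S4Vectors::metadata(catalog) <- md
  catalog
}

#' Restrict a catalog to young clades
#'
#' Keeps repeat names whose clade rank is at least `min_rank` (e.g. the
#' Hominoidea-and-descendants subset).
#'
#' @param catalog a clade-annotated catalog.
#' @param min_rank minimum clade rank retained.
#' @return The catalog subset.
#' @export
select_clade_restricted <- function(catalog, min_rank) {
  catalog[!is.na(catalog$clade_rank) & catalog$clade_rank >= min_rank]
}
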