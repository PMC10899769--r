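#' Fixture specification for the synthetic-data generator
#'
#' Describes a toy genome carrying repeat families of graded
#' evolutionary age, tandem SVA-style clusters, planted per-family
#' signal enrichments with flank spillover, threshold-derived peaks, and
#' negative-binomial count matrices with knock-down effects concentrated
#' in young families.  Every stochastic choice is driven by `seed`.
#'
#' The default family table emulates the statistical structure of a
#' RepeatMasker-style annotation: SINE-Alu, LINE-L1, LTR, DNA and
#' Other-SVA families spanning seven clades from Non-Primates to
#' Homo_sapiens, occupying roughly half of a 2 x 1 Mb genome, with SVA
#' families partly arranged in tandem clusters.  Default planted signal:
#' an `H1X`-like track whose enrichment grows with clade rank (strongest
#' over SVA) and an `H1.2`-like track with the reverse gradient.
#'
#' @param n_chrom,chrom_bp genome shape (default 2 x 1e6).
#' @param families `data.frame` with columns `class_name`, `family`,
#'   `repeat_name`, `clade`, `n_copies`, `mean_len`, `tandem_frac`,
#'   `cluster_size`.
#' @param clade_levels ordered clade labels, oldest first.
#' @param enrichment `data.frame(track, repeat_name, effect,
#'   spillover_bp)`; multiplicative effects > 0.
#' @param baseline,noise_sd,noise_window_bp signal model: baseline track
#'   value, gaussian run-level noise SD, noise run width in bp.
#' @param peak_threshold peaks are contiguous regions of the noise-free
#'   planted signal above this value, trimmed to enriched copy bodies.
#' @param nb_mean,nb_sdlog,nb_dispersion,n_replicates count model:
#'   lognormal per-copy baseline mean around `nb_mean`, NB dispersion,
#'   replicates per condition.
#' @param frac_silent fraction of copies given a near-zero expression
#'   baseline.
#' @param kd_log2fc named numeric: planted knock-down log2 fold change
#'   per repeat name (positive = derepression).
#' @param blacklist_n,blacklist_bp number and width of blacklist
#'   intervals (placed in repeat-free space so exclusion leaves the
#'   planted catalog intact).
#' @param compartment_bp A/B compartment tile width.
#' @param min_gap_bp minimum spacing between placed blocks.
#' @param seed integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_chrom = 2L, chrom_bp = 1e6,
                         families = default_families(),
                         clade_levels = default_clades(),
                         enrichment = NULL,
                         baseline = 1, noise_sd = 0.2,
                         noise_window_bp = 100L,
                         peak_threshold = 1.5,
                         nb_mean = 50, nb_sdlog = 0.5,
                         nb_dispersion = 0.1, n_replicates = 3L,
                         frac_silent = 0.3,
                         kd_log2fc = c(SVA_F = 2, AluYa5 = 2, L1HS = 2),
                         blacklist_n = 5L, blacklist_bp = 2000L,
                         compartment_bp = 1e5, min_gap_bp = 100L,
                         seed = 1L) {
  if (is.null(enrichment))
    enrichment <- default_enrichment(families, clade_levels)
  stop_if_not(all(enrichment$effect > 0), "planted effects must be > 0")
  spec <- list(n_chrom = n_chrom, chrom_bp = chrom_bp,
               families = families, clade_levels = clade_levels,
               enrichment = enrichment, baseline = baseline,
               noise_sd = noise_sd, noise_window_bp = noise_window_bp,
               peak_threshold = peak_threshold, nb_mean = nb_mean,
               nb_sdlog = nb_sdlog, nb_dispersion = nb_dispersion,
               n_replicates = n_replicates, frac_silent = frac_silent,
               kd_log2fc = kd_log2fc, blacklist_n = blacklist_n,
               blacklist_bp = blacklist_bp,
               compartment_bp = compartment_bp, min_gap_bp = min_gap_bp,
               seed = as.integer(seed))
  class(spec) <- "fixture_spec"
  spec
}

#' @describeIn fixture_spec The default family table.
#' @export
default_families <- function() {
  data.frame(
    class_name = c(rep("SINE", 4), rep("LINE", 4), "LTR", "LTR", "DNA",
                   rep("Other", 3)),
    family = c(rep("Alu", 4), rep("L1", 4), "ERVL-MaLR", "ERV1",
               "hAT-Charlie", rep("SVA", 3)),
    repeat_name = c("AluJb", "AluSx", "AluY", "AluYa5",
                    "L1M5", "L1PA7", "L1PA3", "L1HS",
                    "MLT1A", "LTR12C", "MER5A",
                    "SVA_A", "SVA_D", "SVA_F"),
    clade = c("Primates", "Simiiformes", "Hominoidea", "Homo_sapiens",
              "Non-Primates", "Catarrhini", "Hominidae", "Homo_sapiens",
              "Non-Primates", "Hominoidea", "Non-Primates",
              "Hominoidea", "Hominidae", "Homo_sapiens"),
    n_copies = c(250L, 250L, 200L, 100L, 150L, 120L, 100L, 80L,
                 150L, 100L, 150L, 80L, 80L, 80L),
    mean_len = c(300, 300, 300, 300, 800, 800, 800, 800,
                 500, 600, 400, 700, 700, 700),
    tandem_frac = c(rep(0, 11), 0.5, 0.5, 0.6),
    cluster_size = c(rep(1L, 11), 3L, 3L, 3L))
}

#' @describeIn fixture_spec Default planted enrichments: an age-graded
#'   `H1X` track (effect grows with clade rank, boosted over SVA) and an
#'   `H1.2` track with the reverse gradient.
#' @export
default_enrichment <- function(families = default_families(),
                               clade_levels = default_clades()) {
  rk <- match(families$clade, clade_levels) - 1L
  maxrk <- max(rk)
  h1x <- 1 + 0.15 * rk
  h1x[families$family == "SVA"] <- h1x[families$family == "SVA"] * 1.3
  h12 <- 1 + 0.15 * (maxrk - rk)
  rbind(
    data.frame(track = "H1X", repeat_name = families$repeat_name,
               effect = h1x, spillover_bp = 500L),
    data.frame(track = "H1.2", repeat_name = families$repeat_name,
               effect = h12, spillover_bp = 500L))
}

# occupied-interval bookkeeping shared by placement: sorted disjoint
# 0-based half-open intervals per chromosome
occ_overlaps <- function(o, s, e) {
  if (is.null(o) || length(o$starts) == 0) return(FALSE)
  i <- findInterval(e - 1L, o$starts)
  i >= 1 && o$ends[i] > s
}
occ_insert <- function(o, s, e) {
  if (is.null(o)) return(list(starts = s, ends = e))
  i <- findInterval(s, o$starts)
  list(starts = append(o$starts, s, after = i),
       ends = append(o$ends, e, after = i))
}

#' Generate a fixture: genome, catalog, clades, blacklist, compartments
#'
#' Copies are placed uniformly at random with rejection of overlaps
#' (blocks keep at least `min_gap_bp` from each other); tandem clusters
#' are placed as runs of `cluster_size` copies with inter-copy gaps
#' below 500 bp; blacklist intervals land in repeat-free space; A/B
#' compartment segments tile each chromosome alternately.  Deterministic
#' for a seed.
#'
#' @param spec a [fixture_spec()].
#' @return `list(genome, catalog, clades, blacklist, compartments,
#'   spec)`.
#' @export
make_fixture <- function(spec) {
  chroms <- sprintf("chr%d", seq_len(spec$n_chrom))
  genome <- genome_layout(chroms, rep(spec$chrom_bp, spec$n_chrom))
  fam <- spec$families
  req_bp <- sum(fam$n_copies * fam$mean_len) +
    sum(fam$n_copies) * spec$min_gap_bp
  gsize <- genome_size(genome)
  stop_if_not(req_bp <= 0.75 * gsize,
              paste0("infeasible packing: ~%.0f bp of repeats + spacing ",
                     "requested for a %.0f bp genome (%.0f%% occupancy)"),
              req_bp, gsize, req_bp / gsize * 100)
  out <- with_seed(derive_seed(spec$seed, 1L), {
    occ <- list()
    rows <- list()
    place_block <- function(block_len) {
      for (t in seq_len(5000L)) {
        chr <- sample(chroms, 1, prob = rep(spec$chrom_bp, spec$n_chrom))
        span <- spec$chrom_bp - block_len
        if (span < 0) next
        s <- floor(runif(1, 0, span + 1))
        if (s > span) s <- span
        g <- spec$min_gap_bp
        if (!occ_overlaps(occ[[chr]], max(0, s - g), s + block_len + g)) {
          occ[[chr]] <<- occ_insert(occ[[chr]], s, s + block_len)
          return(list(chrom = chr, start = s))
        }
      }
      stop("infeasible packing: no room for a ", block_len,
           " bp block after 5000 tries", call. = FALSE)
    }
    draw_len <- function(mean_len, k)
      pmax(50L, as.integer(round(mean_len * exp(rnorm(k, 0, 0.2)))))
    # blacklist blocks go in first (they are the largest), repeats avoid
    # them, so exclusion leaves the planted catalog intact
    bl <- list()
    for (b in seq_len(spec$blacklist_n)) {
      at <- place_block(spec$blacklist_bp)
      bl[[b]] <- data.frame(chrom = at$chrom, start = at$start,
                            end = at$start + spec$blacklist_bp)
    }
    # larger families first for feasibility
    for (f in order(-fam$mean_len * pmax(fam$cluster_size, 1L))) {
      n <- fam$n_copies[f]
      n_clustered <- 0L
      if (fam$tandem_frac[f] > 0 && fam$cluster_size[f] >= 2) {
        cs <- fam$cluster_size[f]
        n_clusters <- floor(fam$tandem_frac[f] * n / cs)
        n_clustered <- n_clusters * cs
        for (cl in seq_len(n_clusters)) {
          lens <- draw_len(fam$mean_len[f], cs)
          gaps <- floor(runif(cs - 1, 50, 450))
          block <- sum(lens) + sum(gaps)
          at <- place_block(block)
          s <- at$start
          for (j in seq_len(cs)) {
            rows[[length(rows) + 1L]] <- data.frame(
              chrom = at$chrom, start = s, end = s + lens[j],
              strand = sample(c("+", "-"), 1),
              repeat_name = fam$repeat_name[f], family = fam$family[f],
              class_name = fam$class_name[f])
            s <- s + lens[j] + if (j < cs) gaps[j] else 0L
          }
        }
      }
      for (j in seq_len(n - n_clustered)) {
        len <- draw_len(fam$mean_len[f], 1L)
        at <- place_block(len)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = at$chrom, start = at$start, end = at$start + len,
          strand = sample(c("+", "-"), 1),
          repeat_name = fam$repeat_name[f], family = fam$family[f],
          class_name = fam$class_name[f])
      }
    }
    list(rows = do.call(rbind, rows), bl = do.call(rbind, bl))
  })
  tab <- out$rows
  catalog <- repeat_catalog(tab$chrom, tab$start, tab$end,
                            repeat_name = tab$repeat_name,
                            family = tab$family,
                            class_name = tab$class_name,
                            strand = tab$strand, genome = genome)
  catalog <- sort(catalog, ignore.strand = TRUE)
  clades <- clade_table(fam$repeat_name, fam$clade, spec$clade_levels)
  catalog <- assign_clades(catalog, clades)
  blacklist <- if (spec$blacklist_n > 0)
    granges0(out$bl$chrom, out$bl$start, out$bl$end, genome)
  else GenomicRanges::GRanges()
  comp <- local({
    pieces <- list()
    for (chr in chroms) {
      edges <- unique(c(seq(0, spec$chrom_bp, by = spec$compartment_bp),
                        spec$chrom_bp))
      k <- length(edges) - 1L
      pieces[[chr]] <- data.frame(chrom = chr, start = edges[-length(edges)],
                                  end = edges[-1],
                                  label = rep_len(c("A", "B"), k))
    }
    d <- do.call(rbind, pieces)
    granges0(d$chrom, d$start, d$end, genome, label = d$label)
  })
  list(genome = genome, catalog = catalog, clades = clades,
       blacklist = blacklist, compartments = comp, spec = spec)
}

# noise-free planted signal for one track as a per-chromosome function
planted_values <- function(fixture, track) {
  spec <- fixture$spec
  enr <- spec$enrichment[spec$enrichment$track == track, , drop = FALSE]
  cat <- fixture$catalog
  sl <- GenomeInfoDb::seqlengths(fixture$genome)
  vs <- lapply(names(sl), function(chr) rep(spec$baseline, sl[[chr]]))
  names(vs) <- names(sl)
  if (nrow(enr) == 0) return(vs)
  idx <- match(cat$repeat_name, enr$repeat_name)
  sel <- which(!is.na(idx) & enr$effect[idx] != 1)
  chr <- as.character(GenomicRanges::seqnames(cat))
  # chromosome-at-a-time so the working vector is modified in place
  for (c1 in names(vs)) {
    v <- vs[[c1]]
    L <- sl[[c1]]
    for (i in sel[chr[sel] == c1]) {
      eff <- enr$effect[idx[i]]
      spill <- enr$spillover_bp[idx[i]]
      s <- start0(cat)[i]; e <- end0(cat)[i]
      delta <- spec$baseline * (eff - 1)
      v[(s + 1L):e] <- v[(s + 1L):e] + delta
      if (spill > 0) {
        # linear decay from full effect at the copy edge to baseline
        if (s > 0) {
          up <- max(1L, s - spill + 1L):s
          v[up] <- v[up] + delta * (1 - (s - up + 1L) / (spill + 1))
        }
        if (e < L) {
          dn <- (e + 1L):min(L, e + spill)
          v[dn] <- v[dn] + delta * (1 - (dn - e) / (spill + 1))
        }
      }
    }
    vs[[c1]] <- v
  }
  vs
}

#' Simulate signal tracks with planted enrichments
#'
#' Each track is the baseline plus the per-copy multiplicative planted
#' effects (linearly decaying over the spillover width on each side),
#' plus gaussian run-level noise: one draw per `noise_window_bp` window.
#' Seeded per track from the fixture seed.
#'
#' @param fixture a [make_fixture()] result.
#' @return Named list of coverage tracks (one per track in the
#'   enrichment map).
#' @export
simulate_tracks <- function(fixture) {
  spec <- fixture$spec
  tracks <- unique(spec$enrichment$track)
  sl <- GenomeInfoDb::seqlengths(fixture$genome)
  out <- list()
  for (ti in seq_along(tracks)) {
    vs <- planted_values(fixture, tracks[ti])
    with_seed(derive_seed(spec$seed, 100L + ti), {
      for (chr in names(vs)) {
        L <- sl[[chr]]
        if (spec$noise_sd > 0) {
          nwin <- ceiling(L / spec$noise_window_bp)
          noise <- rep(rnorm(nwin, 0, spec$noise_sd),
                       each = spec$noise_window_bp)[seq_len(L)]
          vs[[chr]] <- vs[[chr]] + noise
        }
      }
    })
    out[[tracks[ti]]] <- methods::as(
      stats::setNames(lapply(vs, S4Vectors::Rle), names(vs)),
      "RleList")
  }
  out
}

#' Simulate peaks from the planted signal
#'
#' One peak per contiguous region of the noise-free planted signal above
#' `peak_threshold`, trimmed to the enriched copy bodies; so every peak
#' sits on a planted copy and assigns to it under the >= 50% rule.
#'
#' @param fixture a [make_fixture()] result.
#' @return Named list of `GRanges` peak sets, one per track.
#' @export
simulate_peaks <- function(fixture) {
  spec <- fixture$spec
  tracks <- unique(spec$enrichment$track)
  out <- list()
  for (tk in tracks) {
    vs <- planted_values(fixture, tk)
    pieces <- list()
    for (chr in names(vs)) {
      r <- S4Vectors::Rle(vs[[chr]])
      hot <- IRanges::slice(r, lower = spec$peak_threshold,
                            includeLower = FALSE)
      if (length(hot) == 0) next
      ir <- methods::as(hot, "IRanges")
      pieces[[chr]] <- granges0(chr, GenomicRanges::start(ir) - 1L,
                                GenomicRanges::end(ir), fixture$genome)
    }
    pk <- if (length(pieces)) do.call(c, unname(pieces)) else
      GenomicRanges::GRanges()
    if (length(pk))
      pk <- GenomicRanges::intersect(pk, fixture$catalog,
                                     ignore.strand = TRUE)
    out[[tk]] <- pk
  }
  out
}

#' Simulate a knock-down count matrix
#'
#' Per-copy baseline means are lognormal around `nb_mean` (a
#' `frac_silent` subset gets a near-zero mean); knock-down sample means
#' are scaled by the planted per-name fold change; counts are NB draws
#' with the spec dispersion.  Seeded.
#'
#' @param fixture a [make_fixture()] result.
#' @return `list(counts = matrix, sheet = sample_sheet)`.
#' @export
simulate_counts <- function(fixture) {
  spec <- fixture$spec
  stop_if_not(spec$n_replicates >= 2, "need >= 2 replicates per condition")
  cat <- fixture$catalog
  n <- length(cat)
  nrep <- spec$n_replicates
  sheet <- sample_sheet(c(sprintf("control_%d", seq_len(nrep)),
                          sprintf("kd_%d", seq_len(nrep))),
                        rep(c("control", "kd"), each = nrep))
  with_seed(derive_seed(spec$seed, 500L), {
    mu0 <- rlnorm(n, log(spec$nb_mean), spec$nb_sdlog)
    silent <- runif(n) < spec$frac_silent
    mu0[silent] <- runif(sum(silent), 0, 1)
    fc <- 2^ifelse(cat$repeat_name %in% names(spec$kd_log2fc),
                   spec$kd_log2fc[cat$repeat_name], 0)
    size <- 1 / spec$nb_dispersion
    counts <- matrix(0, n, 2L * nrep,
                     dimnames = list(cat$copy_id, sheet$sample))
    for (j in seq_len(nrep))
      counts[, j] <- rnbinom(n, mu = mu0, size = size)
    for (j in seq_len(nrep))
      counts[, nrep + j] <- rnbinom(n, mu = mu0 * fc, size = size)
    list(counts = counts, sheet = sheet)
  })
}

#' Write a complete fixture directory
#'
#' Writes `genome.chrom.sizes`, `repeats.gtf`, `repeats.bed`,
#' `clades.tsv`, `blacklist.bed`, `compartments.bed`,
#' `<track>.bedgraph`, `<track>.peaks.bed`, `counts.tsv`, `samples.tsv`
#' and `spec.yaml`.
#'
#' @param fixture a [make_fixture()] result.
#' @param dir output directory (created).
#' @param tracks,peaks,counts optional pre-computed simulation outputs;
#'   generated from the fixture when `NULL`.
#' @return The directory path, invisibly.
#' @export
write_fixture <- function(fixture, dir, tracks = NULL, peaks = NULL,
                          counts = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(tracks)) tracks <- simulate_tracks(fixture)
  if (is.null(peaks)) peaks <- simulate_peaks(fixture)
  if (is.null(counts)) counts <- simulate_counts(fixture)
  write_chrom_sizes(fixture$genome, file.path(dir, "genome.chrom.sizes"))
  write_catalog(fixture$catalog, file.path(dir, "repeats.gtf"), "gtf")
  write_catalog(fixture$catalog, file.path(dir, "repeats.bed"), "bed")
  write.table(fixture$clades[, c("repeat_name", "clade")],
              file.path(dir, "clades.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_bed(fixture$blacklist, file.path(dir, "blacklist.bed"),
            name = NULL)
  write_bed(fixture$compartments, file.path(dir, "compartments.bed"),
            name = fixture$compartments$label)
  for (tk in names(tracks)) {
    safe <- gsub("[^A-Za-z0-9._-]", "_", tk)
    write_bedgraph(tracks[[tk]], file.path(dir, paste0(safe, ".bedgraph")))
    write_bed(peaks[[tk]], file.path(dir, paste0(safe, ".peaks.bed")),
              name = NULL)
  }
  write_counts(counts$counts, counts$sheet, file.path(dir, "counts.tsv"),
               file.path(dir, "samples.tsv"))
  sp <- fixture$spec
  sp$families <- as.list(sp$families)
  sp$enrichment <- as.list(sp$enrichment)
  sp$kd_log2fc <- as.list(sp$kd_log2fc)
  yaml::write_yaml(unclass(sp), file.path(dir, "spec.yaml"))
  invisible(dir)
}
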