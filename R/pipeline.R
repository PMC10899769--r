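#' Run one pipeline stage from a config
#'
#' Drives the analysis stages from a YAML configuration (or an
#' equivalent named list): `fixture` writes a synthetic fixture
#' directory; `catalog` reads, filters and annotates a repeat catalog
#' and reports occupancy (and the R/NR partition when compartments are
#' given); `abundance` builds the per-copy abundance table from
#' bedGraph tracks; `profile` writes scaled meta-repeat profiles;
#' `peaks` runs the shuffled-null enrichment report; `tandem` classifies
#' tandem positions; `age` writes clade summaries and the age trend;
#' `expression` runs the expressed split, differential classification
#' and read-change categories.  Every run writes a JSON manifest with
#' input checksums, parameters, the seed and the package version, so
#' deterministic stages are reproducible run-to-run.
#'
#' Config keys: `out_dir` plus per-stage inputs/parameters, e.g.
#' `chrom_sizes`, `annotation` (+`dialect`), `blacklist`, `clades`,
#' `compartments`, `tracks` (named bedGraph paths), `track`, `peaks`,
#' `counts`, `samples`, `seed`, and the stage parameters named after the
#' corresponding function arguments.  Unknown keys are an error.
#'
#' @param stage one of `"fixture"`, `"catalog"`, `"abundance"`,
#'   `"profile"`, `"peaks"`, `"tandem"`, `"age"`, `"expression"`.
#' @param config path to a YAML file, or a named list.
#' @return Invisibly, the list of output paths written.
#' @export
run_stage <- function(stage = c("fixture", "catalog", "abundance",
                                "profile", "peaks", "tandem", "age",
                                "expression"),
                      config) {
  stage <- match.arg(stage)
  if (is.character(config)) {
    stop_if_not(file.exists(config), "config file '%s' not found", config)
    config <- yaml::read_yaml(config)
  }
  allowed <- c("out_dir", "seed", "chrom_sizes", "annotation", "dialect",
               "blacklist", "clades", "compartments", "tracks", "track",
               "peaks", "counts", "samples", "catalog",
               "n_chrom", "chrom_bp", "noise_sd", "nb_mean",
               "nb_dispersion", "n_replicates", "kd_log2fc",
               "body_bins", "flank_bp", "flank_bins", "orient_by_strand",
               "group_level", "group", "n_shuffles", "window_bp",
               "focal", "context_level", "fc_threshold", "alpha",
               "min_total", "express_threshold", "change_factor",
               "reference", "treatment", "level", "min_overlap", "stat")
  bad <- setdiff(names(config), allowed)
  stop_if_not(length(bad) == 0, "invalid config key(s): %s",
              paste(bad, collapse = ", "))
  stop_if_not(!is.null(config$out_dir), "config must set out_dir")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  cfg <- function(key, default) if (!is.null(config[[key]]))
    config[[key]] else default
  need <- function(key) {
    stop_if_not(!is.null(config[[key]]),
                "stage '%s' requires config key '%s'", stage, key)
    if (is.character(config[[key]]) && key != "dialect" &&
        key != "track" && key != "focal" && !all(file.exists(config[[key]])))
      stop("missing input file: ",
           paste(config[[key]][!file.exists(config[[key]])],
                 collapse = ", "), call. = FALSE)
    config[[key]]
  }
  inputs <- character()
  outputs <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <<- c(outputs, p)
    p
  }
  load_catalog <- function() {
    genome <- read_chrom_sizes(need("chrom_sizes"))
    inputs <<- c(inputs, config$chrom_sizes)
    ann <- need("annotation")
    inputs <<- c(inputs, ann)
    cat <- read_repeat_annotation(ann, cfg("dialect", "gtf"), genome)
    if (!is.null(config$blacklist)) {
      inputs <<- c(inputs, need("blacklist"))
      cat <- apply_exclusions(cat, read_bed(config$blacklist, genome),
                              min_overlap = cfg("min_overlap", 1L))
    } else cat <- apply_exclusions(cat)
    if (!is.null(config$clades)) {
      inputs <<- c(inputs, need("clades"))
      cat <- assign_clades(cat, read_clade_table(config$clades))
    }
    list(genome = genome, catalog = cat)
  }
  load_tracks <- function(genome) {
    paths <- need("tracks")
    inputs <<- c(inputs, unlist(paths))
    lapply(paths, read_bedgraph, genome = genome)
  }
  if (stage == "fixture") {
    sp_args <- config[intersect(names(config),
                                names(formals(fixture_spec)))]
    sp_args$seed <- seed
    fx <- make_fixture(do.call(fixture_spec, sp_args))
    write_fixture(fx, out_dir)
    outputs <- list.files(out_dir, full.names = TRUE)
  } else if (stage == "catalog") {
    lc <- load_catalog()
    outputs <- c(outputs, write_catalog(lc$catalog,
                                        file.path(out_dir, "catalog.bed")))
    emit(occupancy(lc$catalog, lc$genome, cfg("level", "class")),
         "occupancy.tsv")
    if (!is.null(config$compartments)) {
      inputs <- c(inputs, need("compartments"))
      segs <- read_bed(config$compartments, lc$genome)
      segs$label <- segs$name
      part <- partition_repetitive(segs, lc$catalog)
      emit(data.frame(chrom = as.character(GenomicRanges::seqnames(part)),
                      start = start0(part), end = end0(part),
                      label = part$label, rclass = part$rclass,
                      segment_id = part$segment_id), "partition.tsv")
    }
  } else if (stage == "abundance") {
    lc <- load_catalog()
    tab <- abundance_table(load_tracks(lc$genome), lc$catalog,
                           stat = cfg("stat", "mean"))
    emit(data.frame(copy_id = rownames(tab), tab, check.names = FALSE),
         "abundance.tsv")
  } else if (stage == "profile") {
    lc <- load_catalog()
    tracks <- load_tracks(lc$genome)
    copies <- lc$catalog
    if (!is.null(config$group)) {
      lev <- cfg("group_level", "family")
      col <- switch(lev, class = copies$class_name,
                    family = copies$family, repeat_name = copies$repeat_name)
      copies <- copies[col %in% config$group]
    }
    for (tn in names(tracks)) {
      pm <- scaled_profile(tracks[[tn]], copies,
                           body_bins = cfg("body_bins", 100L),
                           flank_bp = cfg("flank_bp", 3000L),
                           flank_bins = cfg("flank_bins", 60L),
                           orient_by_strand = cfg("orient_by_strand", TRUE))
      p <- file.path(out_dir, paste0("profile_", tn, ".tsv"))
      write_profile(pm, p)
      outputs <- c(outputs, p)
      emit(data.frame(bin = colnames(pm), mean = average_profile(pm)),
           paste0("avgprofile_", tn, ".tsv"))
    }
  } else if (stage == "peaks") {
    lc <- load_catalog()
    inputs <- c(inputs, need("peaks"))
    pk <- read_bed(config$peaks, lc$genome)
    bl <- if (!is.null(config$blacklist))
      read_bed(config$blacklist, lc$genome) else GenomicRanges::GRanges()
    rep_ <- enrichment_report(pk, lc$catalog, lc$genome, bl,
                              n_shuffles = cfg("n_shuffles", 100L),
                              seed = seed)
    emit(rep_$overall, "enrichment_overall.tsv")
    emit(rep_$per_class, "enrichment_per_class.tsv")
    emit(fraction_repeats_with_peak(pk, lc$catalog,
                                    cfg("level", "class")),
         "repeats_with_peak.tsv")
  } else if (stage == "tandem") {
    lc <- load_catalog()
    focal_names <- need("focal")
    focal <- lc$catalog[lc$catalog$repeat_name %in% focal_names]
    ctx_lev <- cfg("context_level", "class")
    ctx_val <- unique(switch(ctx_lev, class = focal$class_name,
                             family = focal$family))
    context <- lc$catalog[switch(ctx_lev, class = lc$catalog$class_name,
                                 family = lc$catalog$family) %in% ctx_val]
    labels <- classify_tandem(focal, context,
                              window_bp = cfg("window_bp", 500L))
    p <- file.path(out_dir, "tandem_labels.bed")
    counts <- write_tandem_labels(focal, labels, p)
    outputs <- c(outputs, p)
    emit(data.frame(label = names(counts), n = as.integer(counts)),
         "tandem_counts.tsv")
  } else if (stage == "age") {
    lc <- load_catalog()
    stop_if_not(!is.null(config$clades),
                "stage 'age' requires config key 'clades'")
    tab <- abundance_table(load_tracks(lc$genome), lc$catalog)
    tn <- cfg("track", colnames(tab)[1])
    cs <- clade_summary(tab, lc$catalog, tn)
    emit(cs$summary, "clade_summary.tsv")
    tr <- age_trend(tab, lc$catalog, tn, level = cfg("level", "copy"))
    emit(data.frame(track = tn, rho = tr$rho, p = tr$p, n = tr$n,
                    kruskal_p = cs$kruskal_p), "age_trend.tsv")
  } else if (stage == "expression") {
    inputs <- c(inputs, need("counts"), need("samples"))
    cm <- read_counts(config$counts, config$samples)
    de <- differential_classification(
      cm$counts, cm$sheet,
      reference = cfg("reference", "control"),
      treatment = cfg("treatment", "kd"),
      fc_threshold = cfg("fc_threshold", 1.5),
      alpha = cfg("alpha", 0.05), min_total = cfg("min_total", 10))
    emit(de, "de_results.tsv")
    rc <- read_change_categories(
      cm$counts, cm$sheet,
      reference = cfg("reference", "control"),
      treatment = cfg("treatment", "kd"),
      express_threshold = cfg("express_threshold", 3),
      change_factor = cfg("change_factor", 1.5))
    emit(rc$fractions, "read_change_categories.tsv")
  }
  manifest <- list(
    stage = stage, seed = seed,
    package_version = as.character(utils::packageVersion("teprofiler")),
    parameters = config[setdiff(names(config), "out_dir")],
    inputs = as.list(tools::md5sum(unique(inputs))),
    outputs = basename(unlist(outputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(unlist(outputs))
}
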