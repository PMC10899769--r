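# Brute-force oracles and tiny random-instance builders.  Everything here
# works on plain base-R vectors, independent of the package's interval /
# Rle machinery, so agreement is a real two-route check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

# 0-based views of GRanges, and a labeled-segment builder
start0 <- function(gr) GenomicRanges::start(gr) - 1L
end0 <- function(gr) GenomicRanges::end(gr)
granges_segments <- function(chrom, start, end, label, genome) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1, end))
  gr$label <- label
  gr
}

# -- random instances ---------------------------------------------------

rand_intervals <- function(n, L, min_len = 1, max_len = max(2, L %/% 5)) {
  len <- sample(min_len:max_len, n, replace = TRUE)
  len <- pmin(len, L)
  start <- vapply(len, function(l) sample(0:(L - l), 1), integer(1))
  data.frame(start = start, end = start + len)
}

# per-base vector -> single-chromosome track
vec_track <- function(v, chrom = "chrT") {
  methods::as(stats::setNames(list(S4Vectors::Rle(v)), chrom), "RleList")
}

rand_values <- function(L, n_runs = 8) {
  v <- numeric(L)
  for (k in seq_len(n_runs)) {
    iv <- rand_intervals(1, L)
    v[(iv$start + 1):iv$end] <- v[(iv$start + 1):iv$end] +
      round(runif(1, -3, 5), 2)
  }
  v
}

rand_catalog <- function(n, L, genome, families = 3) {
  iv <- rand_intervals(n, L, min_len = 5)
  f <- sample(seq_len(families), n, replace = TRUE)
  repeat_catalog("chrT", iv$start, iv$end,
                 repeat_name = paste0("rep", f), family = paste0("fam", f),
                 class_name = paste0("cls", f),
                 strand = sample(c("+", "-", "*"), n, replace = TRUE),
                 genome = genome)
}

# -- per-base oracles ---------------------------------------------------

oracle_union_bp <- function(start, end, L) {
  v <- logical(L)
  for (i in seq_along(start)) v[(start[i] + 1):end[i]] <- TRUE
  sum(v)
}

oracle_mean_over <- function(v, start, end) mean(v[(start + 1):end])

oracle_coverage <- function(reads, L, policy) {
  v <- numeric(L)
  for (i in seq_len(nrow(reads))) {
    w <- if (policy == "fractional") 1 / reads$n_hits[i] else
      if (reads$n_hits[i] == 1) 1 else 0
    idx <- (reads$start[i] + 1):reads$end[i]
    v[idx] <- v[idx] + w
  }
  v
}

# fractional-apportioned scaled-body bins, naive per-base loop
oracle_body_bins <- function(v, B) {
  n <- length(v)
  bw <- n / B
  out <- numeric(B)
  for (j in seq_len(B)) {
    blo <- (j - 1) * bw; bhi <- j * bw
    acc <- 0
    for (b in seq_len(n)) {       # base b covers [b-1, b)
      ov <- min(bhi, b) - max(blo, b - 1)
      if (ov > 0) acc <- acc + ov * v[b]
    }
    out[j] <- acc / bw
  }
  out
}

# all-pairs >=50% peak assignment
oracle_assign <- function(peaks, cat_df) {
  vapply(seq_len(nrow(peaks)), function(i) {
    ps <- peaks$start[i]; pe <- peaks$end[i]
    ov <- pmax(0, pmin(pe, cat_df$end) - pmax(ps, cat_df$start))
    if (all(ov == 0)) return(NA_character_)
    best <- order(-ov, cat_df$start, cat_df$copy_id)[1]
    if (2 * ov[best] >= (pe - ps)) cat_df$copy_id[best] else NA_character_
  }, character(1))
}

# largest-overlap read-to-copy assignment
oracle_count <- function(reads, cat_df, policy) {
  out <- stats::setNames(numeric(nrow(cat_df)), cat_df$copy_id)
  for (i in seq_len(nrow(reads))) {
    w <- if (policy == "fractional") 1 / reads$n_hits[i] else
      if (reads$n_hits[i] == 1) 1 else 0
    if (w == 0) next
    ov <- pmax(0, pmin(reads$end[i], cat_df$end) -
                 pmax(reads$start[i], cat_df$start))
    if (all(ov == 0)) next
    best <- order(-ov, cat_df$start, cat_df$copy_id)[1]
    out[best] <- out[best] + w
  }
  out
}

# O(n^2) tandem classification by the pairwise predicate
oracle_tandem <- function(focal, context) {
  n <- nrow(focal)
  out <- character(n)
  for (i in seq_len(n)) {
    has5 <- FALSE; has3 <- FALSE
    for (j in seq_len(nrow(context))) {
      if (context$chrom[j] != focal$chrom[i]) next
      if (!is.na(context$copy_id[j]) && !is.na(focal$copy_id[i]) &&
          context$copy_id[j] == focal$copy_id[i]) next
      if (context$start[j] < focal$start[i] &&
          focal$start[i] - context$end[j] <= 500) has5 <- TRUE
      if (context$end[j] > focal$end[i] &&
          context$start[j] - focal$end[i] <= 500) has3 <- TRUE
    }
    out[i] <- if (has5 && has3) "internal" else if (has3) "first" else
      if (has5) "last" else "alone"
  }
  out
}

# exact two-sided signed-rank p by enumerating all sign assignments
oracle_signrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.numeric(signs %*% r)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# exact two-sided Mann-Whitney p by enumerating group assignments
oracle_u_p <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a)
  r <- rank(x)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(x), n1)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# small fixture spec used by several suites: 1 x 120 kb genome, 3 clades
small_spec <- function(seed = 1, chrom_bp = 1.2e5, ...) {
  fams <- data.frame(
    class_name = c("SINE", "LINE", "Other"),
    family = c("Alu", "L1", "SVA"),
    repeat_name = c("AluY", "L1HS", "SVA_F"),
    clade = c("Primates", "Hominidae", "Homo_sapiens"),
    n_copies = c(40L, 25L, 20L),
    mean_len = c(250, 500, 400),
    tandem_frac = c(0, 0, 0.6),
    cluster_size = c(1L, 1L, 3L))
  fixture_spec(n_chrom = 1L, chrom_bp = chrom_bp, families = fams,
               blacklist_n = 2L, blacklist_bp = 1000L,
               compartment_bp = 3e4, seed = seed, ...)
}
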