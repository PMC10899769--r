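test_that("coverage piles up reads per policy with conserved weight", {
  g <- genome_layout("chrT", 100)
  reads <- data.frame(chrom = "chrT", start = c(0, 25), end = c(50, 75),
                      n_hits = 1)
  cov <- coverage_from_reads(reads, "unique_only", g)
  v <- as.numeric(cov$track$chrT)
  expect_equal(v[c(1, 26, 51, 76)], c(1, 2, 1, 0))
  expect_equal(cov$total_weight, 2)
  # one read, 4 hits: 0.25 over each span under fractional, dropped when
  # unique_only
  reads4 <- data.frame(chrom = "chrT", start = c(0, 20, 40, 60),
                       end = c(10, 30, 50, 70), n_hits = 4)
  frac <- coverage_from_reads(reads4, "fractional", g)
  expect_equal(unique(as.numeric(frac$track$chrT))[1:2], c(0.25, 0))
  expect_equal(frac$total_weight, 1)
  expect_equal(coverage_from_reads(reads4, "unique_only", g)$total_weight, 0)
  expect_error(coverage_from_reads(
    data.frame(chrom = "chrT", start = 10, end = 10, n_hits = 1),
    "unique_only", g), "length")
})

test_that("rpm scaling multiplies values and preserves structure", {
  g <- genome_layout("chrT", 200)
  tr <- track_from_runs("chrT", 0, 100, 2, g)
  expect_equal(as.numeric(rpm_normalize(tr, 1e6)$chrT[1]), 2)
  expect_equal(as.numeric(rpm_normalize(tr, 5e5)$chrT[1]), 4)
  expect_error(rpm_normalize(tr, 0), "positive")
  # integral scales by 1e6/N
  set.seed(3)
  v <- rand_values(200)
  tr2 <- vec_track(v)
  expect_equal(sum(as.numeric(rpm_normalize(tr2, 4e5)$chrT)),
               sum(v) * 2.5)
})

test_that("input subtraction is an exact per-base difference", {
  g <- genome_layout("chrT", 150)
  chip <- track_from_runs("chrT", 0, 100, 3, g)
  inp <- track_from_runs("chrT", 50, 150, 1, g)
  d <- subtract_input(chip, inp)
  expect_equal(as.numeric(d$chrT), rep(c(3, 2, -1), each = 50))
  expect_equal(as.numeric(subtract_input(chip, chip)$chrT), rep(0, 150))
  expect_equal(as.numeric(subtract_input(chip, zero_track(g))$chrT),
               as.numeric(chip$chrT))
  g2 <- genome_layout(c("chrT", "chrX"), c(150, 10))
  expect_error(subtract_input(chip, zero_track(g2)), "chromosome sets")
})

test_that("mean_over is the length-weighted mean", {
  g <- genome_layout("chrT", 300)
  tr <- track_from_runs("chrT", c(0, 100), c(100, 200), c(1, 3), g)
  expect_equal(mean_over(tr, "chrT", 50, 150), 2)
  expect_equal(mean_over(tr, "chrT", 200, 300), 0)
  expect_equal(mean_over(track_from_runs("chrT", 0, 300, 7, g),
                         "chrT", 13, 247), 7)
  expect_error(mean_over(tr, "chrT", 50, 50), "zero-length")
})

test_that("abundance table matches per-copy means and group summaries", {
  set.seed(5)
  L <- 5000
  g <- genome_layout("chrT", L)
  v <- rand_values(L)
  cat <- rand_catalog(40, L, g)
  tab <- abundance_table(list(sig = vec_track(v)), cat)
  expect_equal(nrow(tab), 40)
  for (i in c(1, 17, 40))
    expect_equal(tab[i, "sig"],
                 oracle_mean_over(v, start0(cat)[i], end0(cat)[i]))
  # class medians match brute force
  med <- tapply(tab[, "sig"], cat$class_name, median)
  for (cl in names(med)) {
    ids <- which(cat$class_name == cl)
    expect_equal(unname(med[cl]),
                 median(vapply(ids, function(i)
                   oracle_mean_over(v, start0(cat)[i], end0(cat)[i]),
                   numeric(1))))
  }
  # constant track -> all cells equal
  tabc <- abundance_table(list(c5 = track_from_runs("chrT", 0, L, 5, g)),
                          cat)
  expect_true(all(tabc == 5))
})

test_that("quantile tail selection sizes and membership follow the sort", {
  vals <- c(5, 1, 9, 3, 9, 2, 8, 4, 6, 7)
  tab <- matrix(vals, ncol = 1,
                dimnames = list(sprintf("c%02d", 1:10), "x"))
  expect_equal(filter_by_quantile(tab, "x", side = "top", fraction = 0.1),
               "c03")  # first of the tied maxima by id
  expect_equal(filter_by_quantile(tab, "x", side = "bottom",
                                  fraction = 0.25),
               c("c02", "c06", "c04"))
  # ties: all equal -> first ceil(f n) ids
  tabt <- matrix(1, 10, 1, dimnames = list(sprintf("c%02d", 1:10), "x"))
  expect_equal(filter_by_quantile(tabt, "x", side = "top", fraction = 0.3),
               c("c01", "c02", "c03"))
  # n = 137, fraction 0.1 -> 14, matching a sort oracle
  set.seed(9)
  v137 <- rnorm(137)
  tab137 <- matrix(v137, ncol = 1,
                   dimnames = list(sprintf("c%03d", 1:137), "x"))
  top <- filter_by_quantile(tab137, "x", side = "top", fraction = 0.1)
  expect_length(top, 14)
  expect_setequal(top, rownames(tab137)[order(-v137)][1:14])
})

test_that("bedGraph round-trip reproduces canonical runs exactly", {
  set.seed(21)
  g <- genome_layout(c("chrT", "chrU"), c(4000, 2500))
  tr <- zero_track(g)
  tr[["chrT"]] <- S4Vectors::Rle(rand_values(4000))
  tr[["chrU"]] <- S4Vectors::Rle(rand_values(2500))
  f <- tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f, g)
  expect_identical(as.numeric(back$chrT), as.numeric(tr$chrT))
  expect_identical(as.numeric(back$chrU), as.numeric(tr$chrU))
  # zero-coverage runs are written explicitly
  expect_true(any(grepl("\t0$", readLines(f))))
})

test_that("rpm commutes with input subtraction at equal totals", {
  set.seed(8)
  g <- genome_layout("chrT", 1000)
  a <- vec_track(rand_values(1000))
  b <- vec_track(rand_values(1000))
  lhs <- rpm_normalize(subtract_input(a, b), 2e5)
  rhs <- subtract_input(rpm_normalize(a, 2e5), rpm_normalize(b, 2e5))
  expect_equal(as.numeric(lhs$chrT), as.numeric(rhs$chrT))
})
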