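test_that("scaled profiles bin the body with fractional apportioning", {
  g <- genome_layout("chrT", 1000)
  # signal 0 on first half of the copy, 4 on the second
  tr <- track_from_runs("chrT", c(100, 150), c(150, 200), c(0, 4), g)
  copy <- repeat_catalog("chrT", 100, 200, repeat_name = "r",
                         family = "f", class_name = "c", strand = "+",
                         genome = g)
  pm <- scaled_profile(tr, copy, body_bins = 10, flank_bp = 0,
                       flank_bins = 0)
  expect_equal(unname(pm[1, ]), rep(c(0, 4), each = 5))
  # constant track: every bin (incl. flanks) equals the constant
  trc <- track_from_runs("chrT", 0, 1000, 2.5, g)
  pmc <- scaled_profile(trc, copy, body_bins = 7, flank_bp = 70,
                        flank_bins = 7)
  expect_equal(unname(as.vector(pmc)), rep(2.5, 21))
  # copy shorter than body_bins stays valid and conserves the mean
  tiny <- repeat_catalog("chrT", 100, 103, repeat_name = "r",
                         family = "f", class_name = "c", genome = g)
  pmt <- scaled_profile(tr, tiny, body_bins = 10, flank_bp = 0,
                        flank_bins = 0)
  expect_equal(mean(pmt[1, ]), mean_over(tr, "chrT", 100, 103))
})

test_that("flank bins off the chromosome end are missing, not zero", {
  g <- genome_layout("chrT", 500)
  tr <- track_from_runs("chrT", 0, 500, 1, g)
  copy <- repeat_catalog("chrT", 10, 110, repeat_name = "r", family = "f",
                         class_name = "c", strand = "+", genome = g)
  pm <- scaled_profile(tr, copy, body_bins = 5, flank_bp = 100,
                       flank_bins = 10)
  u <- pm[1, 1:10]
  expect_true(all(is.na(u[1:9])))   # bins reaching before position 0
  expect_equal(unname(u[10]), 1)
  expect_true(all(!is.na(pm[1, 11:15])))
  expect_equal(unname(average_profile(pm)[11]), 1)
})

test_that("minus-strand copies are reversed when oriented", {
  g <- genome_layout("chrT", 1000)
  tr <- track_from_runs("chrT", c(100, 150), c(150, 200), c(1, 9), g)
  plus <- repeat_catalog("chrT", 100, 200, repeat_name = "r",
                         family = "f", class_name = "c", strand = "+",
                         genome = g)
  minus <- repeat_catalog("chrT", 100, 200, repeat_name = "r",
                          family = "f", class_name = "c", strand = "-",
                          genome = g)
  pp <- scaled_profile(tr, plus, 10, 50, 5)
  pm <- scaled_profile(tr, minus, 10, 50, 5)
  expect_equal(unname(pm[1, ]), rev(unname(pp[1, ])))
  pm2 <- scaled_profile(tr, minus, 10, 50, 5, orient_by_strand = FALSE)
  expect_equal(unname(pm2[1, ]), unname(pp[1, ]))
})

test_that("body-bin means agree with mean_over and are additive", {
  set.seed(14)
  g <- genome_layout("chrT", 3000)
  v1 <- rand_values(3000); v2 <- rand_values(3000)
  cat <- rand_catalog(15, 3000, g)
  p1 <- scaled_profile(vec_track(v1), cat, 20, 0, 0)
  p2 <- scaled_profile(vec_track(v2), cat, 20, 0, 0)
  p12 <- scaled_profile(vec_track(v1 + v2), cat, 20, 0, 0)
  expect_equal(unclass(p12), unclass(p1) + unclass(p2), tolerance = 1e-9)
  for (i in seq_along(cat)) {
    expect_equal(mean(p1[i, ]),
                 oracle_mean_over(v1, start0(cat)[i], end0(cat)[i]),
                 tolerance = 1e-9)
  }
})

test_that("reference-point profiles are centered and strand-mirrored", {
  g <- genome_layout("chrT", 3000)
  tr <- track_from_runs("chrT", 1000, 1010, 5, g)
  pts <- data.frame(chrom = "chrT", pos = 1005, strand = "+")
  pm <- reference_point_profile(tr, pts, flank_bp = 100, bin_bp = 10)
  expect_equal(ncol(pm), 20)
  expect_equal(unname(pm[1, 10:11]), c(2.5, 2.5))  # spike split at center
  expect_equal(unname(pm[1, c(1, 20)]), c(0, 0))
  ptsm <- data.frame(chrom = "chrT", pos = 1005, strand = "-")
  expect_equal(unname(reference_point_profile(tr, ptsm, 100, 10)[1, ]),
               rev(unname(pm[1, ])))
  expect_error(reference_point_profile(tr, pts, 100, 13), "divide")
  # off-chromosome window bins are missing
  pts0 <- data.frame(chrom = "chrT", pos = 30, strand = "+")
  pm0 <- reference_point_profile(tr, pts0, 100, 10)
  expect_true(all(is.na(pm0[1, 1:7])))
  # constant track -> flat profile
  trc <- track_from_runs("chrT", 0, 3000, 1.5, g)
  expect_true(all(reference_point_profile(trc, pts, 100, 10) == 1.5))
})

test_that("row scaling and clustering are deterministic and canonical", {
  m <- rbind(a = c(0, 1, 2), b = c(0, 1, 2), c = c(2, 1, 0),
             d = c(5, 5, 5))
  out <- scale_and_order(m, "row_z", "cluster")
  expect_equal(unname(out$matrix["d", ]), c(0, 0, 0))
  expect_true(out$constant_rows[4])
  expect_equal(unname(out$matrix["a", ]), unname(out$matrix["b", ]))
  # identical rows are adjacent in the leaf order
  ord <- rownames(m)[out$row_order]
  expect_equal(abs(diff(match(c("a", "b"), ord))), 1)
  # invariance under row permutation (canonical label order)
  perm <- c(3, 1, 4, 2)
  out2 <- scale_and_order(m[perm, ], "row_z", "cluster")
  expect_equal(rownames(m[perm, ])[out2$row_order], ord)
  # given order passes through
  expect_equal(scale_and_order(m, "none", "given")$row_order, 1:4)
  expect_equal(scale_and_order(m, "none", "mean_desc")$row_order,
               c(4, 1, 2, 3))
  expect_error(scale_and_order(m[1, , drop = FALSE], "row_z", "cluster"),
               "2 rows")
})

test_that("profile matrices write with metadata headers", {
  g <- genome_layout("chrT", 1000)
  tr <- track_from_runs("chrT", 0, 1000, 1, g)
  cat <- repeat_catalog("chrT", c(100, 300), c(200, 450),
                        repeat_name = "r", family = "f", class_name = "c",
                        genome = g)
  pm <- scaled_profile(tr, cat, 5, 100, 2)
  f <- tempfile(fileext = ".tsv")
  write_profile(pm, f)
  lines <- readLines(f)
  expect_true(any(grepl("^# body_bins=5", lines)))
  tab <- read.table(f, header = TRUE, comment.char = "#", sep = "\t")
  expect_equal(nrow(tab), 2)
})
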