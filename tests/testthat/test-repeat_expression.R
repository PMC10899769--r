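test_that("reads go to the copy with the largest overlap", {
  g <- genome_layout("chr1", 10000)
  cat <- repeat_catalog("chr1", c(100, 460), c(430, 900),
                        repeat_name = c("A", "B"), family = "f",
                        class_name = "c", genome = g)
  # read [400, 520): 30 bp on A, 60 bp on B
  al <- data.frame(chrom = "chr1", start = c(150, 400), end = c(250, 520),
                   n_hits = 1, sample = "s1")
  cm <- count_reads(al, cat, "unique_only")
  expect_equal(unname(cm[, "s1"]), c(1, 1))
  # fractional: a 2-hit read split across two copies sums to 1
  al2 <- data.frame(chrom = "chr1", start = c(150, 500), end = c(200, 550),
                    n_hits = 2, sample = "s1")
  cm2 <- count_reads(al2, cat, "fractional")
  expect_equal(unname(cm2[, "s1"]), c(0.5, 0.5))
  expect_equal(sum(cm2), 1)
  # unique_only drops multi-mapped alignments entirely
  expect_equal(sum(count_reads(al2, cat, "unique_only")), 0)
})

test_that("count columns conserve assigned read weight (oracle check)", {
  set.seed(17)
  g <- genome_layout("chrT", 20000)
  cat <- rand_catalog(25, 20000, g)
  for (policy in c("unique_only", "fractional")) {
    reads <- rand_intervals(120, 20000, min_len = 30, max_len = 120)
    reads$n_hits <- sample(c(1, 1, 1, 2, 4), 120, replace = TRUE)
    reads$chrom <- "chrT"
    reads$sample <- sample(c("s1", "s2"), 120, replace = TRUE)
    cm <- count_reads(reads, cat, policy, samples = c("s1", "s2"))
    cat_df <- data.frame(chrom = "chrT", start = start0(cat),
                         end = end0(cat), copy_id = cat$copy_id)
    for (s in c("s1", "s2")) {
      want <- oracle_count(reads[reads$sample == s, ], cat_df, policy)
      expect_equal(cm[, s], want[rownames(cm)])
    }
  }
})

test_that("expressed split is inclusive at the mean-count threshold", {
  counts <- rbind(a = c(3, 3, 3, 0, 0, 0), b = c(2, 3, 3.7, 9, 9, 9),
                  c = c(0, 0, 1, 2, 2, 2))
  sheet <- sample_sheet(paste0("s", 1:6), rep(c("control", "kd"), each = 3))
  colnames(counts) <- sheet$sample
  es <- expressed_split(counts, sheet, "control")
  expect_equal(unname(es), c("E", "Ne", "Ne"))  # means 3.0, 2.9, 0.33
  ek <- expressed_split(counts, sheet, "kd")
  expect_equal(unname(ek), c("Ne", "E", "Ne"))
  expect_error(expressed_split(counts, sheet, "mock"), "unknown condition")
})

test_that("status thresholds follow |FC| > 1.5 and padj < 0.05", {
  expect_equal(classify_de(0.70, 0.01), "up")   # 0.70 > log2(1.5)
  expect_equal(classify_de(0.50, 0.01), "ns")   # below log2(1.5) = 0.585
  expect_equal(classify_de(-0.70, 0.01), "down")
  expect_equal(classify_de(3, 0.07), "ns")
  expect_equal(classify_de(3, NA), "ns")
})

test_that("identical conditions give uniform p-values and ns status", {
  set.seed(23)
  n <- 2000
  counts <- matrix(rnbinom(n * 6, mu = 50, size = 10), n, 6,
                   dimnames = list(sprintf("c%04d", 1:n), NULL))
  sheet <- sample_sheet(paste0("s", 1:6), rep(c("control", "kd"), each = 3))
  colnames(counts) <- sheet$sample
  de <- differential_classification(counts, sheet)
  expect_true(all(de$status %in% c("ns", "up", "down")))
  expect_lt(mean(de$status != "ns"), 0.01)
  expect_lt(abs(mean(de$p < 0.5, na.rm = TRUE) - 0.5), 0.05)
  expect_true(all(de$padj >= de$p, na.rm = TRUE))
  expect_error(differential_classification(counts[, c(1, 4)],
                                           sheet[c(1, 4), ]),
               "2 replicates")
})

test_that("planted fold changes on a minority of copies are recovered", {
  set.seed(29)
  n <- 400
  planted <- 1:40
  mu <- rep(50, n)
  counts <- cbind(matrix(rnbinom(n * 3, mu = mu, size = 10), n, 3),
                  matrix(rnbinom(n * 3, mu = mu * ifelse(seq_len(n) %in%
                                                           planted, 4, 1),
                                 size = 10), n, 3))
  rownames(counts) <- sprintf("c%04d", 1:n)
  sheet <- sample_sheet(paste0("s", 1:6), rep(c("control", "kd"), each = 3))
  colnames(counts) <- sheet$sample
  de <- differential_classification(counts, sheet)
  expect_gt(mean(de$status[planted] == "up"), 0.8)
  expect_lt(mean(de$status[-planted] != "ns"), 0.05)
})

test_that("group proportions mirror the observed/expected arithmetic", {
  de <- data.frame(copy_id = sprintf("c%04d", 1:1000),
                   tested = TRUE,
                   status = "ns")
  de$status[1:100] <- "up"
  grouping <- stats::setNames(rep("other", 1000), de$copy_id)
  grouping[c(1:34, 500:662)] <- "G"   # 34 of the up, 197 of all tested
  out <- group_proportions(de, grouping)
  g <- out[out$group == "G", ]
  expect_equal(g$observed_pct, 34)
  expect_equal(g$expected_pct, 19.7)
  expect_true(g$enriched)
  # single group -> 100 vs 100
  out1 <- group_proportions(de, stats::setNames(rep("all", 1000),
                                                de$copy_id))
  expect_equal(out1$observed_pct, 100)
  expect_equal(out1$expected_pct, 100)
  # no up-regulated copies -> empty report
  de$status <- "ns"
  expect_equal(nrow(group_proportions(de, grouping)), 0)
})

test_that("uniformly random up labels track expected proportions", {
  set.seed(35)
  de <- data.frame(copy_id = sprintf("c%04d", 1:2000), tested = TRUE,
                   status = sample(c("up", "ns"), 2000, TRUE,
                                   prob = c(0.1, 0.9)))
  grouping <- stats::setNames(sample(c("A", "B"), 2000, TRUE,
                                     prob = c(0.3, 0.7)), de$copy_id)
  out <- group_proportions(de, grouping)
  n_up <- sum(de$status == "up")
  for (i in seq_len(nrow(out))) {
    p <- out$expected_pct[i] / 100
    se <- sqrt(p * (1 - p) / n_up) * 100
    expect_lt(abs(out$observed_pct[i] - out$expected_pct[i]), 3 * se)
  }
})

test_that("read-change categories cover the two-condition taxonomy", {
  counts <- rbind(a = c(0, 0, 0, 0, 0, 0),
                  b = c(0, 1, 0, 5, 5, 5),
                  c = c(10, 10, 10, 25, 25, 25),
                  d = c(25, 25, 25, 10, 10, 10),
                  e = c(5, 5, 5, 0, 0, 1),
                  f = c(10, 10, 10, 11, 11, 11))
  sheet <- sample_sheet(paste0("s", 1:6), rep(c("control", "kd"), each = 3))
  colnames(counts) <- sheet$sample
  out <- read_change_categories(counts, sheet)
  expect_equal(unname(out$categories),
               c("never_expressed", "became_expressed", "increased",
                 "decreased", "became_silent", "unchanged"))
  # (25 + .5) / (10 + .5) = 2.43 >= 1.5
  expect_equal(sum(out$fractions$percent), 100)
  expect_equal(out$fractions$n, rep(1L, 6))
  sheet3 <- sheet; sheet3$condition[1] <- "x"
  expect_error(read_change_categories(counts, sheet3), "two conditions")
})

test_that("counts round-trip through TSV with the sample sheet", {
  set.seed(41)
  counts <- matrix(round(runif(20, 0, 99), 2), 5, 4,
                   dimnames = list(sprintf("id%d", 1:5),
                                   sprintf("s%d", 1:4)))
  sheet <- sample_sheet(colnames(counts),
                        rep(c("control", "kd"), each = 2))
  fc <- tempfile(); fs <- tempfile()
  write_counts(counts, sheet, fc, fs)
  back <- read_counts(fc, fs)
  expect_equal(back$counts, counts)
  expect_equal(back$sheet$condition, sheet$condition)
})
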