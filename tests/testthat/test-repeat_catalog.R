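test_that("GTF records are converted to 0-based half-open coordinates", {
  g <- genome_layout("chr1", 1000)
  gtf <- tempfile(fileext = ".gtf")
  writeLines(paste0("chr1\trm\texon\t101\t200\t.\t+\t.\t",
                    'gene_id "AluY"; transcript_id "AluY_dup1"; ',
                    'family_id "Alu"; class_id "SINE";'), gtf)
  cat <- read_repeat_annotation(gtf, "gtf", g)
  expect_equal(GenomicRanges::start(cat), 101L)  # 1-based view of [100,200)
  expect_equal(GenomicRanges::end(cat), 200L)
  expect_equal(cat$copy_id, "chr1:100-200:AluY")
  expect_equal(cat$family, "Alu")
  expect_equal(cat$class_name, "SINE")
})

test_that("empty annotation gives an empty catalog", {
  g <- genome_layout("chr1", 1000)
  f <- tempfile(fileext = ".gtf")
  writeLines(character(), f)
  expect_length(read_repeat_annotation(f, "gtf", g), 0)
})

test_that("conflicting family labels for one repeat name are an error", {
  g <- genome_layout("chr1", 10000)
  expect_error(
    repeat_catalog("chr1", c(0, 100, 200), c(50, 150, 250),
                   repeat_name = "AluY", family = c("Alu", "Alu", "L1"),
                   class_name = "SINE", genome = g),
    "inconsistent.*AluY.*chr1:200-250:AluY")
})

test_that("malformed and out-of-bounds records are named errors", {
  g <- genome_layout("chr1", 1000)
  f <- tempfile(fileext = ".gtf")
  writeLines(c(paste0("chr1\trm\texon\t1\t50\t.\t+\t.\t",
                      'gene_id "A"; family_id "F"; class_id "C";'),
               "chr1\tbroken"), f)
  expect_error(read_repeat_annotation(f, "gtf", g), "line 2")
  f2 <- tempfile(fileext = ".gtf")
  writeLines(paste0("chr1\trm\texon\t900\t1200\t.\t+\t.\t",
                    'gene_id "A"; family_id "F"; class_id "C";'), f2)
  expect_error(read_repeat_annotation(f2, "gtf", g), "bounds")
})

test_that("exclusions drop '?' classifications and blacklist overlaps", {
  g <- genome_layout("chr1", 10000)
  cat <- repeat_catalog("chr1", c(0, 100, 300, 500), c(50, 200, 400, 600),
                        repeat_name = c("a", "b", "c", "d"),
                        family = c("Alu", "Alu", "Deu?", "Alu"),
                        class_name = c("SINE?", "SINE", "SINE", "SINE"),
                        genome = g)
  # blacklist [199,300): 1-bp overlap with [100,200), none with [300,400)
  bl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 300))
  out <- apply_exclusions(cat, bl)
  expect_equal(out$repeat_name, "d")
  expect_equal(S4Vectors::metadata(out)$exclusions[["uncertain"]], 2)
  expect_equal(S4Vectors::metadata(out)$exclusions[["blacklist"]], 1)
  # half-open: blacklist starting exactly at copy end does not remove
  bl2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(201, 300))
  out2 <- apply_exclusions(cat, bl2)
  expect_setequal(out2$repeat_name, c("b", "d"))
  # idempotent
  expect_identical(granges(apply_exclusions(out, bl)), granges(out))
})

test_that("occupancy unions overlapping copies and scales to percent", {
  g <- genome_layout("chr1", 1000)
  cat <- repeat_catalog("chr1", c(0, 50), c(100, 150),
                        repeat_name = "r", family = "f", class_name = "c",
                        genome = g)
  occ <- occupancy(cat, g, "class")
  expect_equal(occ$bp, 150)
  expect_equal(occ$percent, 15)
  cat2 <- repeat_catalog("chr1", c(0, 200), c(100, 300),
                         repeat_name = "r", family = "f", class_name = "c",
                         genome = g)
  expect_equal(occupancy(cat2, g, "all")$percent, 20)
  expect_equal(nrow(occupancy(cat2[0], g, "class")), 0)
})

test_that("partition splits segments into R/NR tiles exactly", {
  g <- genome_layout("chr1", 2000)
  cat <- repeat_catalog("chr1", 200, 400, repeat_name = "r", family = "f",
                        class_name = "c", genome = g)
  seg <- granges_segments("chr1", 0, 1000, "A", g)
  out <- partition_repetitive(seg, cat)
  r <- out[out$rclass == "R"]
  nr <- out[out$rclass == "NR"]
  expect_equal(cbind(GenomicRanges::start(r) - 1, GenomicRanges::end(r)),
               cbind(200, 400), ignore_attr = TRUE)
  expect_equal(sum(GenomicRanges::width(out)), 1000)
  expect_equal(sort(GenomicRanges::start(nr) - 1), c(0, 400))
  # no overlap -> single NR identical to input
  seg2 <- granges_segments("chr1", 1200, 1500, "B", g)
  out2 <- partition_repetitive(seg2, cat)
  expect_equal(out2$rclass, "NR")
  expect_equal(GenomicRanges::width(out2), 300)
  # fully covered -> single R
  seg3 <- granges_segments("chr1", 250, 350, "A", g)
  out3 <- partition_repetitive(seg3, cat)
  expect_equal(out3$rclass, "R")
})

test_that("clade assignment is per repeat name with a missing policy", {
  g <- genome_layout("chr1", 10000)
  cat <- repeat_catalog("chr1", c(0, 100, 200), c(50, 150, 250),
                        repeat_name = c("SVA_F", "SVA_A", "NewThing"),
                        family = "SVA", class_name = "Other", genome = g)
  ct <- clade_table(c("SVA_F", "SVA_A"), c("Homo_sapiens", "Hominoidea"))
  out <- assign_clades(cat, ct)
  expect_equal(out$clade_rank, c(6L, 4L, NA))
  expect_equal(out$unknown_clade, c(FALSE, FALSE, TRUE))
  expect_error(assign_clades(cat, ct, on_missing = "error"), "NewThing")
  # same family, different clades: rank differs per name
  expect_false(out$clade_rank[1] == out$clade_rank[2])
  # clade restriction keeps names at or above the threshold
  expect_equal(select_clade_restricted(out, 5)$repeat_name, "SVA_F")
  expect_length(select_clade_restricted(out, 7), 0)
})

test_that("catalog round-trips through BED and GTF", {
  set.seed(11)
  g <- genome_layout("chrT", 50000)
  cat <- rand_catalog(30, 50000, g)
  for (fmt in c("bed", "gtf")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_catalog(cat, f, fmt)
    back <- read_repeat_annotation(f, fmt, g)
    back <- back[match(cat$copy_id, back$copy_id)]
    expect_equal(start0(back), start0(cat))
    expect_equal(end0(back), end0(cat))
    expect_equal(back$family, cat$family)
    expect_equal(as.character(GenomicRanges::strand(back)),
                 as.character(GenomicRanges::strand(cat)))
  }
})
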