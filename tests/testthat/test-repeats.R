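test_that("repeat class filtering drops trf and dust, keeps satellites", {
  ann <- repeat_annotation(data.frame(
    chrom = "chr1", start = c(0, 200, 400, 600),
    end = c(100, 300, 500, 700),
    repeat_id = c("a", "b", "c", "d"),
    class_label = c("trf", "dust", "GSAT_MM", "L1")))
  kept <- filter_repeat_classes(ann)
  expect_equal(kept$repeat_id, c("c", "d"))
  expect_equal(kept$class_label, c("GSAT_MM", "L1"))
  # custom exclusion set
  expect_equal(filter_repeat_classes(ann, "L1")$repeat_id, c("a", "b", "c"))
})

test_that("overlap counting matches the all-pairs brute-force oracle", {
  ann <- repeat_annotation(data.frame(
    chrom = c("chr1", "chr1", "chr2"), start = c(100L, 250L, 100L),
    end = c(200L, 400L, 300L),
    repeat_id = c("rA", "rB", "rC"), class_label = "x"))
  frag <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(90L, 195L, 200L, 10L, 299L),
    end = c(120L, 260L, 250L, 90L, 320L))
  fs <- fragment_set("s", frag)
  counts <- count_fragment_overlaps(fs, ann)
  expect_identical(counts, overlap_oracle(frag, ann))
  # spelled out: rA ([100,200)) overlaps fragments 1 and 2; fragment 2
  # ([195,260)) also reaches rB; fragment 3 ([200,250)) starts exactly at
  # rA's half-open end and stops before rB, touching neither
  expect_equal(unname(counts), c(2L, 1L, 1L))
})

test_that("a fragment spanning two adjacent repeats increments both", {
  ann <- repeat_annotation(data.frame(
    chrom = "chr1", start = c(0L, 100L), end = c(100L, 200L),
    repeat_id = c("left", "right"), class_label = "x"))
  fs <- fragment_set("s", data.frame(chrom = "chr1", start = 80L, end = 120L))
  expect_equal(unname(count_fragment_overlaps(fs, ann)), c(1L, 1L))
  # empty fragment set -> all zeros
  empty <- fragment_set("s", data.frame(chrom = character(),
                                        start = integer(), end = integer()))
  expect_equal(unname(count_fragment_overlaps(empty, ann)), c(0L, 0L))
})

test_that("random interval sets agree with the oracle", {
  withr::with_seed(31L, {
    ann <- repeat_annotation(data.frame(
      chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
      start = st <- sample.int(5000, 40),
      end = st + sample.int(300, 40),
      repeat_id = sprintf("r%02d", 1:40), class_label = "x"))
    frag <- data.frame(chrom = sample(c("chr1", "chr2"), 150, replace = TRUE),
                       start = fst <- sample.int(5200, 150),
                       end = fst + 147L)
  })
  fs <- fragment_set("s", frag)
  expect_identical(count_fragment_overlaps(fs, ann),
                   overlap_oracle(frag, ann))
})

test_that("5-stage normalization equals the frozen spreadsheet oracle", {
  fx <- norm_fixture()
  enr <- normalize_zscore(fx$counts, fx$ann)
  st <- enr$stages
  expect_equal(unname(st$cpm[, "input"]), fx$expected$cpm_input, tolerance = 1e-9)
  expect_equal(unname(st$cpm[, "IP"]), fx$expected$cpm_ip, tolerance = 1e-9)
  expect_equal(unname(st$perbp[, "input"]), fx$expected$perbp_input,
               tolerance = 1e-9)
  expect_equal(unname(st$perbp[, "IP"]), fx$expected$perbp_ip, tolerance = 1e-9)
  expect_equal(unname(st$ratio[, "IP"]), fx$expected$ratio, tolerance = 1e-9)
  expect_equal(unname(st$log2[, "IP"]), fx$expected$log2, tolerance = 1e-9)
  expect_equal(unname(st$zscore[, "IP"]), fx$expected$zscore, tolerance = 1e-9)
})

test_that("z-stage is standardized and pipeline invariants hold", {
  fx <- norm_fixture()
  enr <- normalize_zscore(fx$counts, fx$ann)
  z <- enr$stages$zscore[, "IP"]
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(stats::sd(z), 1, tolerance = 1e-12)
  # depth invariance: doubling all counts of a sample leaves CPM unchanged
  doubled <- repeat_count_matrix(
    list(IP = fx$counts$counts[, "IP"] * 2L,
         input = fx$counts$counts[, "input"]),
    roles = c(IP = "IP", input = "input"), pairing = c(IP = "input"))
  enr2 <- normalize_zscore(doubled, fx$ann)
  expect_equal(enr2$stages$cpm[, "IP"], enr$stages$cpm[, "IP"],
               tolerance = 1e-12)
  expect_equal(enr2$stages$zscore[, "IP"], enr$stages$zscore[, "IP"],
               tolerance = 1e-12)
  # stage idempotence: identical inputs give identical downstream matrices
  enr3 <- normalize_zscore(fx$counts, fx$ann)
  expect_identical(enr3$stages, enr$stages)
})

test_that("degenerate and zero-input cases raise the documented errors", {
  fx <- norm_fixture()
  same <- repeat_count_matrix(
    list(IP = fx$counts$counts[, "input"],
         input = fx$counts$counts[, "input"]),
    roles = c(IP = "IP", input = "input"), pairing = c(IP = "input"))
  expect_error(normalize_zscore(same, fx$ann),
               class = "chromofied_degenerate_error")
  zero <- repeat_count_matrix(
    list(IP = fx$counts$counts[, "IP"],
         input = setNames(c(0L, 0L, 0L), fx$ann$repeat_id)),
    roles = c(IP = "IP", input = "input"), pairing = c(IP = "input"))
  expect_error(normalize_zscore(zero, fx$ann),
               class = "chromofied_data_error")
})

test_that("repeats with zero input are masked, not infinite", {
  ann <- repeat_annotation(data.frame(
    chrom = "chr1", start = c(0L, 200L, 400L, 600L),
    end = c(100L, 300L, 500L, 700L),
    repeat_id = c("a", "b", "c", "d"), class_label = "x"))
  cm <- repeat_count_matrix(
    list(IP = setNames(c(20L, 10L, 30L, 5L), ann$repeat_id),
         input = setNames(c(10L, 0L, 30L, 5L), ann$repeat_id)),
    roles = c(IP = "IP", input = "input"), pairing = c(IP = "input"))
  enr <- normalize_zscore(cm, ann)
  expect_true(is.na(enr$stages$zscore["b", "IP"]))
  zs <- enr$stages$zscore[c("a", "c", "d"), "IP"]
  expect_equal(mean(zs), 0, tolerance = 1e-12)
  # pseudocount path keeps every repeat
  enr_pc <- normalize_zscore(cm, ann, pseudocount = 1)
  expect_true(all(is.finite(enr_pc$stages$zscore[, "IP"])))
})

test_that("class summaries report boxplot statistics per IP sample", {
  fx <- norm_fixture()
  enr <- normalize_zscore(fx$counts, fx$ann)
  # single-repeat class: median equals that repeat's z
  s <- summarize_repeat_class(enr, fx$ann, "GSAT_MM")
  expect_equal(s$n, 1L)
  expect_equal(s$median, unname(enr$stages$zscore["r1", "IP"]))
  expect_true(s$above_zero)
  expect_error(summarize_repeat_class(enr, fx$ann, "SYNT_ABSENT"),
               class = "chromofied_data_error")
  # class filtered away upstream -> error names the class
  ann_f <- filter_repeat_classes(fx$ann, "GSAT_MM")
  expect_error(summarize_repeat_class(enr, ann_f, "GSAT_MM"), "GSAT_MM")
})

test_that("BED I/O round-trips and reports malformed lines", {
  ann <- make_repeat_annotation(n_repeats = 40L, n_gsat = 10L, seed = 2L)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_repeat_bed(ann, bed)
  back <- read_repeat_bed(bed)
  expect_equal(as.data.frame(back), as.data.frame(ann))
  frag <- generate_fragments(ann, 1, 50L, seed = 3L)
  fbed <- withr::local_tempfile(fileext = ".bed")
  write_fragment_bed(frag, fbed)
  fback <- read_fragment_bed(fbed)
  expect_equal(fback$fragments, frag$fragments)
  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t50", "chr1\t60\t40"), bad)
  err <- tryCatch(read_fragment_bed(bad), error = identity)
  expect_s3_class(err, "chromofied_parse_error")
  expect_match(conditionMessage(err), "line 2")
})
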