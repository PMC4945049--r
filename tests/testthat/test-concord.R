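bands <- read_cytoband()

test_that("cytoband fixture loads, tiles, and resolves band prefixes", {
  expect_true(all(c("chrom", "start", "end", "band", "stain") %in% names(bands)))
  # prefix union: 5p14 spans p14.3 through p14.1 (10.5 Mb on hg19)
  iv <- band_interval(bands, "5", "p14")
  expect_equal(iv$start, 18400000)
  expect_equal(iv$end, 28900000)
  # exact band
  iv2 <- band_interval(bands, "chr5", "p15.2")
  expect_equal(c(iv2$start, iv2$end), c(9800000, 15000000))
  # whole arm
  arm <- band_interval(bands, "5", "p")
  expect_equal(c(arm$start, arm$end), c(0, 48400000))
  expect_error(band_interval(bands, "5", "p99"), "not found")
})

test_that("karyotype strings resolve to the sizes the banding implies", {
  # del(5)(p15.33p15.2): 0 - 15.0 Mb
  ev <- parse_truth("46,XX,del(5)(p15.33p15.2)", bands, sample_id = "J01350")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$chrom, "chr5")
  expect_equal(ev$direction, "loss")
  expect_equal(ev$size_mb, 15)
  # del(5)(p14) via prefix union: 10.5 Mb
  ev2 <- parse_truth("46,XY,del(5)(p14)", bands)
  expect_equal(ev2$size_mb, 10.5)
  expect_equal(c(ev2$start_kb, ev2$end_kb), c(18400, 28900))
  # del(5)(p13): 13.6 Mb; del(5)(p15): 18.4 Mb; del(5)(p15p11): 48.4 Mb
  expect_equal(parse_truth("46,XX,del(5)(p13)", bands)$size_mb, 13.6)
  expect_equal(parse_truth("46,XY,del(5)(p15)", bands)$size_mb, 18.4)
  expect_equal(parse_truth("46,XX,del(5)(p15p11)", bands)$size_mb, 48.4)
  # del(5)(p15.32p14.3): 18.8 Mb
  expect_equal(parse_truth("46,XX,del(5)(p15.32p14.3)", bands)$size_mb, 18.8)
  # duplications are gains
  expect_equal(parse_truth("46,XX,dup(1)(p36)", bands)$direction, "gain")
  # uncertain qualifier is tolerated
  expect_equal(parse_truth("46,XX,?del(7)(q32)", bands)$size_mb, 5.5)
})

test_that("array strings take their kb coordinates verbatim", {
  ev <- parse_truth("arr 13q21.2(60,399–61,730)×3", sample_id = "LMQ155")
  expect_equal(ev$chrom, "chr13")
  expect_equal(ev$direction, "gain")
  expect_equal(c(ev$start_kb, ev$end_kb), c(60399, 61730))
  expect_equal(ev$size_mb, 1.331)
  ev2 <- parse_truth("arr 13q31.1(80,281-83,294)x1")
  expect_equal(ev2$direction, "loss")
  expect_equal(ev2$size_mb, 3.013)
})

test_that("normal karyotypes, multi-CNV strings and complex forms behave", {
  expect_equal(nrow(parse_truth("46,XY", bands)), 0)
  expect_equal(nrow(parse_truth("46,XX", bands)), 0)

  multi <- parse_truth("46,XX,del(4)(q34.3q35.2), dup(7)(p22p21.1)", bands)
  expect_equal(nrow(multi), 2)
  expect_setequal(multi$direction, c("loss", "gain"))
  expect_setequal(multi$chrom, c("chr4", "chr7"))
  expect_equal(multi$size_mb[multi$chrom == "chr7"], 20.9)

  expect_error(parse_truth("47,XX,mos +i(18)(p11)[7]/46,xx[23]", bands),
               "manifest")
  expect_error(parse_truth("46,XX,-14,+der(3;14)(q21;p13)", bands), "manifest")
  expect_error(parse_truth("46,XX,Xp-", bands), "manifest")
  expect_error(parse_truth("complete gibberish", bands), "nparseable")
})

test_that("manifest coordinate overrides bypass string parsing", {
  manifest <- tibble::tibble(
    sample_id = c("A", "B"),
    source_string = c("47,XX,mos +i(18)(p11)[7]/46,xx[23]", "46,XY,del(5)(p14)"),
    chrom = c("chr18", NA), start_kb = c(0, NA), end_kb = c(17200, NA),
    direction = c("gain", NA)
  )
  ev <- parse_truth_manifest(manifest, bands)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$direction[ev$sample_id == "A"], "gain")
  expect_equal(ev$size_mb[ev$sample_id == "A"], 17.2)
  expect_equal(ev$size_mb[ev$sample_id == "B"], 10.5)
})

test_that("overlap arithmetic is exact, symmetric, and chromosome-safe", {
  expect_equal(overlap_kb(c(69461, 78014), c(59800, 75091)), 5630)
  expect_equal(overlap_kb(c(25341, 28865), c(23066, 27505)), 2164)
  expect_equal(overlap_kb(c(0, 10), c(20, 30)), 0)
  # symmetry on random intervals
  set.seed(12)
  for (i in 1:25) {
    a <- sort(runif(2, 0, 1e5)); b <- sort(runif(2, 0, 1e5))
    expect_identical(overlap_kb(a, b), overlap_kb(b, a))
  }
  a <- tibble::tibble(chrom = "chr1", start_kb = 0, end_kb = 10)
  b <- tibble::tibble(chrom = "chr2", start_kb = 0, end_kb = 10)
  expect_error(overlap_kb(a, b), "different chromosomes")
})

test_that("classification reproduces the documented worked cases", {
  # covered call inside truth -> consistent
  truths <- tibble::tibble(
    sample_id = "LMQ155", chrom = "chr13", start_kb = 60399, end_kb = 61730,
    direction = "gain"
  )
  calls <- tibble::tibble(
    sample_id = "LMQ155", chrom = "chr13", start_kb = 58259, end_kb = 63190,
    direction = "gain"
  )
  rec <- classify_concordance(calls, truths)
  expect_identical(rec$class, "consistent")
  expect_equal(rec$overlap_kb, 1331)
  expect_equal(rec$frac_truth, 1)

  # small overlap on the right chromosome -> partly consistent
  truths2 <- tibble::tibble(
    sample_id = "mic0012", chrom = "chr5", start_kb = 18400, end_kb = 28900,
    direction = "loss"
  )
  calls2 <- tibble::tibble(
    sample_id = "mic0012", chrom = "chr5", start_kb = 608, end_kb = 20832,
    direction = "loss"
  )
  rec2 <- classify_concordance(calls2, truths2)
  expect_identical(rec2$class, "partly_consistent")
  expect_equal(rec2$overlap_kb, 2432)
  expect_lt(max(rec2$frac_truth, rec2$frac_call), 0.5)

  # zero overlap but same chromosome and direction -> still partly consistent
  truths3 <- tibble::tibble(
    sample_id = "BO00074", chrom = "chr7", start_kb = 127200, end_kb = 132700,
    direction = "loss"
  )
  calls3 <- tibble::tibble(
    sample_id = "BO00074", chrom = "chr7", start_kb = 140295, end_kb = 158820,
    direction = "loss"
  )
  expect_identical(classify_concordance(calls3, truths3)$class,
                   "partly_consistent")

  # no candidate at all -> inconsistent
  truths4 <- tibble::tibble(
    sample_id = "K003762", chrom = "chr9", start_kb = 90000, end_kb = 117300,
    direction = "loss"
  )
  rec4 <- classify_concordance(calls3, truths4)
  expect_identical(rec4$class, "inconsistent")
  expect_true(is.na(rec4$call_start_kb))

  # direction must match: a gain call cannot confirm a loss
  calls5 <- dplyr::mutate(calls2, direction = "gain")
  expect_identical(classify_concordance(calls5, truths2)$class, "inconsistent")
})

test_that("each call confirms at most one truth event (greedy matching)", {
  truths <- tibble::tibble(
    sample_id = "S", chrom = "chr1",
    start_kb = c(0, 30000), end_kb = c(20000, 50000),
    direction = "loss"
  )
  # one call overlapping both events, better with the second
  calls <- tibble::tibble(
    sample_id = "S", chrom = "chr1", start_kb = 15000, end_kb = 45000,
    direction = "loss"
  )
  rec <- classify_concordance(calls, truths)
  expect_equal(sum(rec$class != "inconsistent"), 1)
  expect_identical(rec$class[rec$start_kb == 30000], "consistent")
})

test_that("performance handles perfect and empty strata", {
  records <- tibble::tibble(
    sample_id = c("a", "b"), chrom = "chr1", start_kb = 0,
    end_kb = c(20000, 30000), direction = "loss",
    size_mb = c(20, 30), class = "consistent"
  )
  perf <- performance_summary(records, euploid_calls = tibble::tibble(
    sample_id = character(), size_mb = numeric()
  ), euploid_samples = paste0("E", 1:50))
  total <- perf[perf$stratum == "total", ]
  expect_equal(total$sensitivity, 100)
  expect_equal(total$specificity, 100)
  expect_equal(total$sens_hi, 100)
  expect_equal(total$spec_hi, 100)
  # the small-CNV stratum has no events: NA, not zero
  small <- perf[perf$stratum == "<10Mb", ]
  expect_true(is.na(small$sensitivity))
})

test_that("exact binomial intervals match published screening CIs", {
  # 32/38 events: 68.75%-93.98%
  ci <- plasmacnv:::clopper_pearson(32, 38)
  expect_equal(ci[1], 68.75, tolerance = 0.2 / 68.75)
  expect_equal(ci[2], 93.98, tolerance = 0.2 / 93.98)
  # degenerate edges
  expect_equal(plasmacnv:::clopper_pearson(5, 5)[2], 100)
  expect_equal(plasmacnv:::clopper_pearson(0, 5)[1], 0)
})

test_that("the markdown report renders rates and NA cells", {
  records <- tibble::tibble(
    sample_id = "a", chrom = "chr1", start_kb = 0, end_kb = 20000,
    direction = "loss", size_mb = 20, class = "consistent"
  )
  perf <- performance_summary(records, tibble::tibble(
    sample_id = character(), size_mb = numeric()
  ), euploid_samples = "E1")
  md <- report_performance(perf)
  expect_match(md, "\\| Size of CNV \\|")
  expect_match(md, "100.00%")
  expect_match(md, "\\| NA \\|")  # empty <10Mb stratum
  path <- withr::local_tempfile(fileext = ".md")
  report_performance(perf, path)
  expect_identical(readLines(path), strsplit(md, "\n")[[1]])
})
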