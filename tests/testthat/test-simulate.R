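test_that("bin tiling is contiguous, handles remainder bins and hg19 scale", {
  m <- build_genome_model(tibble::tibble(chrom = "c1", length = 10e6), 1e5,
                          gc_source = 0.4)
  expect_equal(nrow(m$bins), 100)
  expect_true(all(m$bins$end - m$bins$start == 1e5))

  m2 <- build_genome_model(tibble::tibble(chrom = "c1", length = 10.05e6), 1e5,
                           gc_source = 0.4)
  expect_equal(nrow(m2$bins), 101)
  expect_equal(m2$bins$end[101] - m2$bins$start[101], 5e4)

  # tiling invariant on the toy model: contiguous, no overlap, sorted
  bins <- toy_model()$bins
  by_chrom <- split(bins, bins$chrom)
  for (b in by_chrom) {
    expect_equal(b$start[1], 0)
    expect_true(all(b$start[-1] == b$end[-nrow(b)]))
  }

  # full-scale bin count equals sum of ceil(length / bin_size) over the
  # shipped chromosome table
  expected_bins <- sum(ceiling(hg19_chromosomes()$length / 1e5))
  expect_equal(nrow(hg19_model()$bins), expected_bins)
  expect_true(all(hg19_model()$bins$gc >= 0 & hg19_model()$bins$gc <= 1))
})

test_that("genome model rejects bad chromosome tables", {
  expect_error(build_genome_model(
    tibble::tibble(chrom = c("a", "a"), length = c(1e6, 2e6))), "duplicated")
  expect_error(build_genome_model(
    tibble::tibble(chrom = "a", length = -5)), "positive")
})

test_that("expected bin weights implement the maternal/fetal mixture", {
  model <- toy_model()
  weights_ratio <- function(cfg) {
    w <- expected_bin_weights(model, cfg)
    # divide out mappability and GC bias to recover the copy-ratio term
    r <- w / (model$bins$mappability * cfg$gc_bias(model$bins$gc))
    r / r[model$bins$chrom == "chr1"][1]  # normalise to a diploid autosome bin
  }

  # fetal heterozygous loss at f = 0.10: ratio 0.95 inside, 1 outside
  cfg <- simulation_config(fetal_fraction = 0.10, fetus_sex = "male",
                           cnv_specs = cnv_spec("chr2", 10e6, 20e6, "loss"))
  r <- weights_ratio(cfg)
  inside <- model$bins$chrom == "chr2" & model$bins$start >= 10e6 &
    model$bins$end <= 20e6
  expect_equal(unique(round(r[inside], 10)), 0.95)
  expect_equal(unique(round(r[model$bins$chrom == "chr3"], 10)), 1)

  # f = 0: fetal CNV invisible on autosomes
  cfg0 <- simulation_config(fetal_fraction = 0, fetus_sex = "male",
                            cnv_specs = cnv_spec("chr2", 10e6, 20e6, "loss"))
  r0 <- weights_ratio(cfg0)
  expect_true(all(abs(r0[is_auto <- !model$bins$chrom %in% c("chrX", "chrY")] - 1) < 1e-12))

  # maternal+fetal full-dose loss: ratio 0.5 at any f
  cfgb <- simulation_config(fetal_fraction = 0.13, fetus_sex = "female",
                            cnv_specs = cnv_spec("chr2", 10e6, 20e6, "loss",
                                                 origin = "both"))
  rb <- weights_ratio(cfgb)
  expect_equal(unique(round(rb[inside], 10)), 0.5)

  # chrY dosage: beta + f/2 for male fetus, beta for female
  beta <- cfg$chrY_background
  y <- model$bins$chrom == "chrY"
  expect_equal(unique(round(r[y], 10)), round(beta + 0.10 / 2, 10))
  expect_equal(unique(round(rb[y], 10)), beta)

  # weights sum to one
  expect_equal(sum(expected_bin_weights(model, cfg)), 1)
})

test_that("copy-number bounds and bad CNV specs are rejected", {
  model <- toy_model()
  expect_error(expected_bin_weights(model, simulation_config(
    cnv_specs = cnv_spec("chr2", 10e6, 20e6, "loss", copy_delta = -3L,
                         origin = "both"))), "below zero")
  expect_error(expected_bin_weights(model, simulation_config(
    cnv_specs = cnv_spec("chr9", 1e6, 2e6, "loss"))), "unknown chromosome")
  expect_error(cnv_spec("chr1", 5e6, 1e6, "loss"), "start < end")
})

test_that("simulated counts conserve total reads and are seed-deterministic", {
  for (seed in c(1, 99)) {
    sim <- simulate_toy(seed)
    expect_identical(sum(sim$coverage$count), as.integer(toy_reads))
  }
  a <- simulate_toy(5)
  b <- simulate_toy(5)
  expect_identical(a$coverage, b$coverage)
  d <- simulate_toy(6)
  expect_false(identical(a$coverage$count, d$coverage$count))
})

test_that("flat euploid simulation is uniform (chi-square goodness of fit)", {
  model <- build_genome_model(tibble::tibble(chrom = "c1", length = 30e6), 1e5,
                              gc_source = 0.4)
  flat <- function(gc) rep(1, length(gc))
  pvals <- vapply(1:100, function(seed) {
    cfg <- simulation_config(total_reads = 6e4, fetal_fraction = 0,
                             gc_bias = flat)
    s <- simulate_sample(model, cfg, seed = seed)
    suppressWarnings(stats::chisq.test(s$coverage$count)$p.value)
  }, numeric(1))
  # individual draws pass at alpha = 0.01 almost always, and the p-values
  # are not pathologically skewed
  expect_gt(mean(pvals > 0.01), 0.95)
})

test_that("mixture mean inside a CNV converges to the expected copy ratio", {
  # 15 Mb fetal het loss at f = 0.10: corrected ratio inside ~ 0.95
  spec <- cnv_spec("chr2", 20e6, 35e6, "loss")
  means <- vapply(1:20, function(seed) {
    sim <- simulate_toy(seed, cnv_specs = spec)
    norm <- normalize_toy(sim)
    inside <- norm$chrom == "chr2" & norm$start >= 20e6 & norm$end <= 35e6
    mean(norm$ratio[inside])
  }, numeric(1))
  # SE of the replicate average of per-CNV means
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 0.95), 3 * se + 0.005)
})

test_that("mean chrY relative coverage is linear in fetal fraction", {
  model <- toy_model()
  bins <- model$bins
  len_share <- sum(bins$end[bins$chrom == "chrY"] - bins$start[bins$chrom == "chrY"]) /
    sum(bins$end - bins$start)
  # analytic expectation of cr_y under the mixture weights
  expected_cr <- function(f) {
    cfg <- simulation_config(fetal_fraction = f, fetus_sex = "male")
    w <- expected_bin_weights(model, cfg)
    sum(w[bins$chrom == "chrY"]) / len_share
  }
  fs <- c(0.05, 0.10, 0.20)
  d <- dplyr::bind_rows(lapply(fs, function(f) {
    cr <- vapply(1:10, function(seed) {
      sim <- simulate_toy(seed + round(1000 * f), fetal_fraction = f,
                          fetus_sex = "male")
      relative_chrY_coverage(sim$coverage)$cr_y
    }, numeric(1))
    tibble::tibble(f = f, cr_y = mean(cr))
  }))
  slope <- unname(stats::coef(stats::lm(cr_y ~ f, data = d))[2])
  slope_expected <- (expected_cr(0.20) - expected_cr(0.05)) / 0.15
  expect_lt(abs(slope / slope_expected - 1), 0.05)
  # and each mean sits on the analytic line (tolerance: Poisson noise of a
  # few hundred chrY reads per replicate, averaged over 10 replicates)
  for (i in seq_along(fs)) {
    expect_equal(d$cr_y[i], expected_cr(fs[i]), tolerance = 0.06)
  }
})

test_that("cohort simulation keeps books and is byte-identical under a seed", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  # full-scale chromosomes so the default 1-129 Mb size range is placeable
  co1 <- simulate_cohort(hg19_model(), n_euploid = 7, n_cnv = 3,
                         n_male_panel = 2, n_female_panel = 2,
                         total_reads = 1e5, seed = 11, out_dir = dir1)
  co2 <- simulate_cohort(hg19_model(), n_euploid = 7, n_cnv = 3,
                         n_male_panel = 2, n_female_panel = 2,
                         total_reads = 1e5, seed = 11, out_dir = dir2)
  expect_equal(nrow(co1$truth), 3)
  expect_length(co1$samples, 10)
  expect_true(all(co1$truth$direction %in% c("gain", "loss")))
  sizes <- (co1$truth$end_kb - co1$truth$start_kb) / 1000
  expect_true(all(sizes >= 1 & sizes <= 129))

  f1 <- list.files(dir1)
  expect_identical(f1, list.files(dir2))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  }

  # round trip through the TSV reader
  id <- names(co1$samples)[1]
  back <- read_bin_counts(file.path(dir1, paste0(id, ".bins.tsv")), sample_id = id)
  expect_equal(back$count, co1$samples[[id]]$count)
})

test_that("overdispersion inflates count variance beyond multinomial", {
  model <- build_genome_model(tibble::tibble(chrom = "c1", length = 30e6), 1e5,
                              gc_source = 0.4)
  v <- function(disp, seed) {
    cfg <- simulation_config(total_reads = 3e5, fetal_fraction = 0,
                             dispersion = disp)
    var(simulate_sample(model, cfg, seed = seed)$coverage$count)
  }
  plain <- mean(vapply(1:5, function(s) v(0, s), numeric(1)))
  over <- mean(vapply(1:5, function(s) v(0.05, s), numeric(1)))
  expect_gt(over, 2 * plain)
})
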