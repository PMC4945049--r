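#' Specify a copy-number variant for simulation
#'
#' @param chrom Chromosome name (must exist in the genome model).
#' @param start,end Interval in bp, 0-based half-open, within the chromosome.
#' @param direction `"gain"` or `"loss"`; must agree with the sign of
#'   `copy_delta`.
#' @param origin Which genome carries the event: `"fetal"`, `"maternal"` or
#'   `"both"` (a maternal CNV transmitted to the fetus).
#' @param copy_delta Signed integer change in copy number (default +1 for a
#'   gain, -1 for a loss). Resulting copy numbers must stay non-negative.
#'
#' @return One-row tibble describing the event.
#' @export
#' @examples
#' cnv_spec("chr5", 1e6, 16e6, "loss", origin = "fetal")
cnv_spec <- function(chrom, start, end,
                     direction = c("loss", "gain"),
                     origin = c("fetal", "maternal", "both"),
                     copy_delta = NULL) {
  direction <- match.arg(direction)
  origin <- match.arg(origin)
  if (is.null(copy_delta)) copy_delta <- if (direction == "gain") 1L else -1L
  stopifnot(start < end, copy_delta != 0)
  if (sign(copy_delta) != ifelse(direction == "gain", 1, -1)) {
    stop("copy_delta sign must match direction", call. = FALSE)
  }
  tibble::tibble(
    chrom = chrom, start = start, end = end,
    direction = direction, origin = origin, copy_delta = as.integer(copy_delta)
  )
}

#' Configure a single simulated maternal-plasma sample
#'
#' Defines the mixture the simulator draws from: a maternal genome and a
#' fetal (placental) genome mixed at fetal fraction `fetal_fraction`, read
#' depth, fetus sex, CNVs, a smooth GC bias and optional overdispersion.
#' Defaults match the depth reported for 16/24-plex plasma sequencing runs
#' (about 7 million uniquely aligned reads per sample).
#'
#' @param total_reads Total reads drawn per sample (default 7e6).
#' @param fetal_fraction Fetal fraction `f` in \[0, 1\]. Setting `f = 1` with
#'   a male fetus simulates an adult male genome (used for reference panels).
#' @param fetus_sex `"male"` or `"female"`.
#' @param cnv_specs Tibble of events from [cnv_spec()] (zero rows = euploid).
#' @param gc_bias Function `g(gc) > 0` mapping GC fraction to relative bin
#'   efficiency; default a quadratic peaking at GC 0.42 (see
#'   [gc_bias_quadratic()]). Pass `function(gc) rep(1, length(gc))` for no bias.
#' @param dispersion Non-negative overdispersion; when > 0 each bin weight is
#'   multiplied by an independent Gamma(1/d, d) variate before the multinomial
#'   draw. Default 0 (pure multinomial).
#' @param chrY_background Relative chrY coverage in pregnancies with a female
#'   fetus (read mis-mapping proxy), default 0.002.
#'
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(total_reads = 7e6,
                              fetal_fraction = 0.10,
                              fetus_sex = c("female", "male"),
                              cnv_specs = NULL,
                              gc_bias = gc_bias_quadratic(),
                              dispersion = 0,
                              chrY_background = 0.002) {
  fetus_sex <- match.arg(fetus_sex)
  if (is.null(cnv_specs)) {
    cnv_specs <- cnv_spec("chr1", 0, 1, "loss")[0, ]
  }
  stopifnot(
    total_reads > 0,
    fetal_fraction >= 0, fetal_fraction <= 1,
    is.function(gc_bias),
    dispersion >= 0,
    chrY_background >= 0
  )
  if (any(gc_bias(seq(0, 1, by = 0.05)) <= 0)) {
    stop("gc_bias must be strictly positive on [0, 1]", call. = FALSE)
  }
  structure(
    list(
      total_reads = total_reads,
      fetal_fraction = fetal_fraction,
      fetus_sex = fetus_sex,
      cnv_specs = tibble::as_tibble(cnv_specs),
      gc_bias = gc_bias,
      dispersion = dispersion,
      chrY_background = chrY_background
    ),
    class = "simulation_config"
  )
}

#' Quadratic GC bias curve
#'
#' Relative sequencing efficiency as a smooth function of bin GC fraction:
#' `g(gc) = max(height - curvature * (gc - peak)^2, floor)`. The default peaks
#' near GC 0.42 and spans roughly 0.7-1.2 over the GC range of 100 kb bins,
#' the typical shape of Illumina-era library bias.
#'
#' @param peak GC fraction of maximum efficiency.
#' @param height Efficiency at the peak.
#' @param curvature Quadratic fall-off.
#' @param floor Lower clamp keeping the curve positive.
#' @return A vectorised function of GC fraction.
#' @export
gc_bias_quadratic <- function(peak = 0.42, height = 1.2, curvature = 4.6,
                              floor = 0.2) {
  force(peak); force(height); force(curvature); force(floor)
  function(gc) pmax(height - curvature * (gc - peak)^2, floor)
}

# Per-bin maternal/fetal copy numbers implied by the config.
# Autosomes default (2, 2); chrX fetal copy is 1 for a male fetus; chrY is
# handled by expected_bin_weights() directly.
bin_copy_numbers <- function(model, config) {
  bins <- model$bins
  c_m <- rep(2, nrow(bins))
  c_f <- rep(2, nrow(bins))
  c_f[is_chrX(bins$chrom)] <- if (config$fetus_sex == "male") 1 else 2
  specs <- config$cnv_specs
  if (nrow(specs) > 0) {
    known <- stats::setNames(model$chromosomes$length, model$chromosomes$chrom)
    for (i in seq_len(nrow(specs))) {
      s <- specs[i, ]
      if (!s$chrom %in% names(known)) {
        stop("CNV spec on unknown chromosome: ", s$chrom, call. = FALSE)
      }
      if (s$start < 0 || s$end > known[[s$chrom]]) {
        stop("CNV spec outside chromosome bounds: ", s$chrom, call. = FALSE)
      }
      hit <- bins$chrom == s$chrom & bins$start < s$end & bins$end > s$start
      if (s$origin %in% c("maternal", "both")) c_m[hit] <- c_m[hit] + s$copy_delta
      if (s$origin %in% c("fetal", "both")) c_f[hit] <- c_f[hit] + s$copy_delta
    }
  }
  if (any(c_m < 0) || any(c_f < 0)) {
    stop("CNV specs drive a copy number below zero", call. = FALSE)
  }
  list(maternal = c_m, fetal = c_f)
}

#' Expected per-bin read probabilities under the plasma mixture model
#'
#' The sampling weight of bin *i* is `w_i = m_i * g(gc_i) * r_i`, normalised
#' to sum to 1, where `m_i` is mappability, `g` the GC bias and `r_i` the
#' mixture copy ratio. On autosomes and chrX,
#' `r_i = (1 - f) * c_mat / 2 + f * c_fet / 2` with maternal and fetal copy
#' numbers defaulting to 2 (chrX fetal copy is 1 for a male fetus). On chrY,
#' `r_i = beta + f * c_fetY / 2` for a male fetus and `r_i = beta` otherwise,
#' with `beta` the female-background mis-mapping level. A heterozygous fetal
#' deletion therefore shifts `r` by `-f/2`; a full-dose maternal+fetal
#' deletion shifts it to 0.5 regardless of `f`.
#'
#' @param model A [build_genome_model()] object.
#' @param config A [simulation_config()].
#' @return Numeric vector of probabilities aligned to `model$bins`, summing
#'   to 1.
#' @export
expected_bin_weights <- function(model, config) {
  stopifnot(inherits(model, "genome_model"), inherits(config, "simulation_config"))
  bins <- model$bins
  f <- config$fetal_fraction
  cn <- bin_copy_numbers(model, config)
  r <- (1 - f) * cn$maternal / 2 + f * cn$fetal / 2
  y <- is_chrY(bins$chrom)
  if (any(y)) {
    # default fetal chrY copy number is 1 for a male fetus; CNV deltas on chrY
    # shift it via cn$fetal (whose autosomal default of 2 is offset by 1 here)
    r[y] <- config$chrY_background +
      if (config$fetus_sex == "male") f * pmax(cn$fetal[y] - 1, 0) / 2 else 0
  }
  w <- bins$mappability * config$gc_bias(bins$gc) * r
  total <- sum(w)
  if (total <= 0) stop("all bin weights are zero", call. = FALSE)
  w / total
}

#' Simulate one sample of binned plasma read counts
#'
#' Draws all reads in a single multinomial over [expected_bin_weights()], so
#' the per-sample total is exactly `total_reads`. With `dispersion > 0` the
#' weights are first jittered by independent Gamma multipliers
#' (mean 1, variance `dispersion`), giving extra-Poisson noise.
#'
#' @param model A [build_genome_model()] object.
#' @param config A [simulation_config()].
#' @param sample_id Sample identifier stored in the output.
#' @param seed Optional integer; when given the draw is reproducible and the
#'   caller's RNG state is restored afterwards.
#'
#' @return A list with `coverage` (tibble `sample_id`, `chrom`, `start`,
#'   `end`, `gc`, `count` aligned to the model bins), `truth` (the config's
#'   CNV tibble with `sample_id` prepended) and `fetal_fraction` (the true
#'   simulated value).
#' @export
#' @examples
#' m <- build_genome_model(tibble::tibble(chrom = "chr1", length = 5e6))
#' s <- simulate_sample(m, simulation_config(total_reads = 1e4), seed = 1)
#' sum(s$coverage$count)
simulate_sample <- function(model, config, sample_id = "S1", seed = NULL) {
  stopifnot(inherits(model, "genome_model"), inherits(config, "simulation_config"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, globalenv())
      }
    })
    set.seed(seed)
  }
  w <- expected_bin_weights(model, config)
  if (config$dispersion > 0) {
    shape <- 1 / config$dispersion
    w <- w * stats::rgamma(length(w), shape = shape, rate = shape)
    w <- w / sum(w)
  }
  counts <- as.integer(stats::rmultinom(1, size = config$total_reads, prob = w))
  coverage <- dplyr::bind_cols(
    tibble::tibble(sample_id = sample_id),
    model$bins[c("chrom", "start", "end", "gc")],
    tibble::tibble(count = counts)
  )
  truth <- config$cnv_specs
  truth <- if (nrow(truth) > 0) {
    dplyr::bind_cols(tibble::tibble(sample_id = sample_id), truth)
  } else {
    tibble::tibble(
      sample_id = character(), chrom = character(), start = numeric(),
      end = numeric(), direction = character(), origin = character(),
      copy_delta = integer()
    )
  }
  list(coverage = coverage, truth = truth, fetal_fraction = config$fetal_fraction)
}

#' Simulate a cohort of plasma samples plus reference panels
#'
#' Emulates a screening-study design: a set of pregnancies (some carrying a
#' CNV, most euploid) with fetal fractions drawn around a configurable mean,
#' plus dedicated adult-male and female-fetus panels used to train the
#' chromosome-Y fetal-fraction reference regressions. CNV sizes are drawn
#' uniformly over `cnv_size_range_mb` and placed uniformly on a random
#' autosome.
#'
#' @param model A [build_genome_model()] object.
#' @param n_euploid,n_cnv Numbers of euploid and CNV-carrying pregnancies.
#' @param n_male_panel,n_female_panel Reference panel sizes (adult males,
#'   female-fetus pregnancies).
#' @param fetal_fraction_mean,fetal_fraction_sd Normal parameters of the
#'   per-sample fetal fraction, truncated to \[0.03, 0.25\]. Defaults 0.097
#'   and 0.03 match a first-trimester plasma cohort.
#' @param cnv_size_range_mb Uniform range of simulated CNV sizes in Mb
#'   (default 1-129).
#' @param cnv_origin Origin passed to [cnv_spec()] for simulated events.
#' @param total_reads Reads per sample.
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @param out_dir Optional directory: when given, one bin-count TSV per
#'   sample, a truth manifest TSV and a panel TSV are written there.
#' @param ... Further arguments passed to [simulation_config()] (e.g.
#'   `gc_bias`, `dispersion`, `chrY_background`).
#'
#' @return List with `samples` (named list of coverage tibbles), `truth`
#'   (manifest tibble: `sample_id`, `chrom`, `start_kb`, `end_kb`,
#'   `direction`, `origin`, `source_string`), `fetal_fractions` (tibble
#'   `sample_id`, `fetal_fraction`, `fetus_sex`, `class`) and `panels`
#'   (named list of coverage tibbles for `male_adult` and `female_fetus`
#'   panel members).
#' @export
simulate_cohort <- function(model,
                            n_euploid = 7, n_cnv = 3,
                            n_male_panel = 0, n_female_panel = 0,
                            fetal_fraction_mean = 0.097,
                            fetal_fraction_sd = 0.03,
                            cnv_size_range_mb = c(1, 129),
                            cnv_origin = "fetal",
                            total_reads = 7e6,
                            seed = 1L,
                            out_dir = NULL,
                            ...) {
  stopifnot(inherits(model, "genome_model"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(seed)

  autosomes <- dplyr::filter(model$chromosomes, is_autosome(.data$chrom))
  draw_f <- function(n) {
    pmin(0.25, pmax(0.03, stats::rnorm(n, fetal_fraction_mean, fetal_fraction_sd)))
  }
  draw_cnv <- function() {
    size <- stats::runif(1, cnv_size_range_mb[1], cnv_size_range_mb[2]) * 1e6
    ok <- autosomes[autosomes$length > size, ]
    if (nrow(ok) == 0) stop("no autosome long enough for requested CNV size", call. = FALSE)
    row <- ok[sample.int(nrow(ok), 1, prob = ok$length), ]
    start <- floor(stats::runif(1, 0, row$length - size))
    cnv_spec(row$chrom, start, start + size,
             direction = sample(c("loss", "gain"), 1), origin = cnv_origin)
  }

  ids <- c(
    sprintf("CNV%03d", seq_len(n_cnv)),
    sprintf("EUP%03d", seq_len(n_euploid))
  )
  if (anyDuplicated(ids) > 0) stop("duplicate sample IDs", call. = FALSE)
  plan <- tibble::tibble(
    sample_id = ids,
    class = rep(c("cnv", "euploid"), c(n_cnv, n_euploid)),
    fetus_sex = sample(c("male", "female"), n_cnv + n_euploid, replace = TRUE),
    fetal_fraction = draw_f(n_cnv + n_euploid)
  )
  specs <- lapply(seq_len(nrow(plan)), function(i) {
    if (plan$class[i] == "cnv") draw_cnv() else NULL
  })
  sample_seeds <- sample.int(.Machine$integer.max - 1, nrow(plan) + n_male_panel + n_female_panel)

  run_one <- function(i) {
    cfg <- simulation_config(
      total_reads = total_reads,
      fetal_fraction = plan$fetal_fraction[i],
      fetus_sex = plan$fetus_sex[i],
      cnv_specs = specs[[i]],
      ...
    )
    simulate_sample(model, cfg, sample_id = plan$sample_id[i], seed = sample_seeds[i])
  }
  sims <- lapply(seq_len(nrow(plan)), run_one)
  samples <- stats::setNames(lapply(sims, `[[`, "coverage"), plan$sample_id)
  truth <- dplyr::bind_rows(lapply(sims, `[[`, "truth")) |>
    dplyr::mutate(
      start_kb = .data$start / 1000, end_kb = .data$end / 1000,
      source_string = sprintf(
        "%s(%s)(%s-%s)", ifelse(.data$direction == "gain", "dup", "del"),
        sub("^chr", "", .data$chrom),
        format(round(.data$start_kb), big.mark = ",", trim = TRUE),
        format(round(.data$end_kb), big.mark = ",", trim = TRUE)
      )
    ) |>
    dplyr::select("sample_id", "chrom", "start_kb", "end_kb", "direction",
                  "origin", "source_string")

  panel_cfg <- function(kind) {
    if (kind == "male_adult") {
      simulation_config(total_reads = total_reads, fetal_fraction = 1,
                        fetus_sex = "male", ...)
    } else {
      simulation_config(total_reads = total_reads, fetal_fraction = draw_f(1),
                        fetus_sex = "female", ...)
    }
  }
  panel_ids <- c(sprintf("MALE%03d", seq_len(n_male_panel)),
                 sprintf("FEMF%03d", seq_len(n_female_panel)))
  panel_kind <- rep(c("male_adult", "female_fetus"), c(n_male_panel, n_female_panel))
  panels <- lapply(seq_along(panel_ids), function(j) {
    simulate_sample(model, panel_cfg(panel_kind[j]), sample_id = panel_ids[j],
                    seed = sample_seeds[nrow(plan) + j])$coverage
  })
  panels <- list(
    male_adult = stats::setNames(panels[panel_kind == "male_adult"],
                                 panel_ids[panel_kind == "male_adult"]),
    female_fetus = stats::setNames(panels[panel_kind == "female_fetus"],
                                   panel_ids[panel_kind == "female_fetus"])
  )

  out <- list(samples = samples, truth = truth,
              fetal_fractions = plan[c("sample_id", "fetal_fraction", "fetus_sex", "class")],
              panels = panels)
  if (!is.null(out_dir)) write_cohort(out, out_dir)
  out
}

write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$samples)) {
    readr::write_tsv(cohort$samples[[id]][c("chrom", "start", "end", "gc", "count")],
                     file.path(out_dir, paste0(id, ".bins.tsv")))
  }
  readr::write_tsv(cohort$truth, file.path(out_dir, "truth_manifest.tsv"))
  readr::write_tsv(cohort$fetal_fractions, file.path(out_dir, "sample_sheet.tsv"))
  for (kind in names(cohort$panels)) {
    for (id in names(cohort$panels[[kind]])) {
      readr::write_tsv(cohort$panels[[kind]][[id]][c("chrom", "start", "end", "gc", "count")],
                       file.path(out_dir, paste0(id, ".bins.tsv")))
    }
  }
  invisible(out_dir)
}

#' Read a per-sample bin-count TSV
#'
#' @param path TSV with header `chrom`, `start`, `end`, `gc`, `count`
#'   (0-based half-open bp), as written by [simulate_cohort()].
#' @param sample_id Sample identifier to attach (default: file name stem).
#' @return Coverage tibble as produced by [simulate_sample()].
#' @export
read_bin_counts <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- sub("\\.bins\\.tsv$", "", basename(path))
  dat <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), gc = readr::col_double(),
    count = readr::col_integer()
  ))
  dplyr::bind_cols(tibble::tibble(sample_id = sample_id), dat)
}
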