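#' Relative chromosome-Y coverage of a sample
#'
#' The chromosome-Y summary statistic behind the fetal-fraction estimator:
#' the share of reads on chrY divided by chrY's share of the binned genome
#' length, so an adult male (one Y against two copies of each autosome) sits
#' near 0.5 and a pregnancy with a female fetus sits at the mis-mapping
#' background. Also returns the coverage-weighted mean GC of the chrY bins,
#' the covariate of the reference regressions.
#'
#' @param coverage Coverage tibble with `chrom`, `end`, `start`, `gc`,
#'   `count` (raw or normalised; counts are used).
#' @return One-row tibble: `sample_id`, `cr_y`, `gc_y`, `chry_reads`,
#'   `total_reads`.
#' @export
relative_chrY_coverage <- function(coverage) {
  y <- is_chrY(coverage$chrom)
  if (!any(y)) stop("genome model has no chrY bins", call. = FALSE)
  total <- sum(coverage$count)
  len_y <- sum(coverage$end[y] - coverage$start[y])
  len_all <- sum(coverage$end - coverage$start)
  reads_y <- sum(coverage$count[y])
  cr_y <- (reads_y / total) / (len_y / len_all)
  gc_y <- if (reads_y > 0) {
    sum(coverage$gc[y] * coverage$count[y]) / reads_y
  } else {
    mean(coverage$gc[y])
  }
  tibble::tibble(
    sample_id = if ("sample_id" %in% names(coverage)) coverage$sample_id[1] else NA_character_,
    cr_y = cr_y, gc_y = gc_y, chry_reads = reads_y, total_reads = total
  )
}

#' Fit the male and female chromosome-Y reference regressions
#'
#' Ordinary least-squares regressions of relative chrY coverage on chrY GC,
#' one per reference panel: adult males (upper reference, `f_m`) and
#' pregnancies carrying a female fetus (background reference, `f_f`). The
#' fetal-fraction estimate of a sample is its position between the two fitted
#' curves. The male curve must sit strictly above the female curve across
#' the observed GC range; crossing curves are an error.
#'
#' @param male_panel,female_panel Tibbles with columns `cr_y` and `gc_y`
#'   (one row per panel sample), e.g. stacked [relative_chrY_coverage()]
#'   rows. Each needs at least 20 samples.
#' @param degree Polynomial degree of the GC regressions (default 1). When
#'   the panel's GC values are essentially constant the fit drops to an
#'   intercept-only model.
#' @return A `chry_reference` object with `predict_male()` /
#'   `predict_female()` accessors, the female residual SD (used by the sex
#'   call) and panel diagnostics.
#' @export
fit_reference_curves <- function(male_panel, female_panel, degree = 1) {
  male_panel <- tibble::as_tibble(male_panel)
  female_panel <- tibble::as_tibble(female_panel)
  for (p in list(male_panel, female_panel)) {
    stopifnot(all(c("cr_y", "gc_y") %in% names(p)))
  }
  if (nrow(male_panel) < 20 || nrow(female_panel) < 20) {
    stop("each reference panel needs at least 20 samples", call. = FALSE)
  }
  fit_one <- function(panel) {
    if (diff(range(panel$gc_y)) < 1e-4 || degree < 1) {
      stats::lm(cr_y ~ 1, data = panel)
    } else {
      stats::lm(cr_y ~ stats::poly(gc_y, degree, raw = TRUE), data = panel)
    }
  }
  fm <- fit_one(male_panel)
  ff <- fit_one(female_panel)
  pred <- function(fit, panel) {
    lims <- range(panel$gc_y)
    function(gc) {
      gc <- pmin(lims[2], pmax(lims[1], gc))
      as.numeric(stats::predict(fit, newdata = data.frame(gc_y = gc)))
    }
  }
  predict_male <- pred(fm, male_panel)
  predict_female <- pred(ff, female_panel)

  shared <- c(max(min(male_panel$gc_y), min(female_panel$gc_y)),
              min(max(male_panel$gc_y), max(female_panel$gc_y)))
  if (shared[1] > shared[2]) shared <- range(c(male_panel$gc_y, female_panel$gc_y))
  grid <- seq(shared[1], shared[2], length.out = 101)
  gap <- predict_male(grid) - predict_female(grid)
  if (any(gap <= 0)) {
    bad <- range(grid[gap <= 0])
    stop(sprintf(
      "male reference does not exceed female reference over GC [%.4f, %.4f]",
      bad[1], bad[2]), call. = FALSE)
  }

  structure(
    list(
      predict_male = predict_male,
      predict_female = predict_female,
      female_sd = stats::sd(stats::residuals(ff)),
      male_sd = stats::sd(stats::residuals(fm)),
      n_male = nrow(male_panel), n_female = nrow(female_panel),
      gc_range = shared, degree = degree,
      male_fit = fm, female_fit = ff
    ),
    class = "chry_reference"
  )
}

#' @export
print.chry_reference <- function(x, ...) {
  cat(sprintf(
    "<chry_reference> male panel n=%d, female panel n=%d, GC range [%.4f, %.4f]\n",
    x$n_male, x$n_female, x$gc_range[1], x$gc_range[2]
  ))
  invisible(x)
}

#' @rdname tidy.gc_curve
#' @method tidy chry_reference
#' @export
tidy.chry_reference <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(panel = "male", term = names(stats::coef(x$male_fit)),
                   estimate = unname(stats::coef(x$male_fit))),
    tibble::tibble(panel = "female", term = names(stats::coef(x$female_fit)),
                   estimate = unname(stats::coef(x$female_fit)))
  )
}

#' @rdname tidy.gc_curve
#' @method glance chry_reference
#' @export
glance.chry_reference <- function(x, ...) {
  tibble::tibble(
    n_male = x$n_male, n_female = x$n_female, degree = x$degree,
    male_sd = x$male_sd, female_sd = x$female_sd,
    gc_min = x$gc_range[1], gc_max = x$gc_range[2]
  )
}

#' Estimate fetal fraction from chromosome-Y coverage
#'
#' Places the sample's relative chrY coverage between the fitted female and
#' male reference curves:
#' `epsilon = (cr_y - f_f(gc_y)) / (f_m(gc_y) - f_f(gc_y))`,
#' so a sample sitting on the female background gives 0 and an adult male
#' gives 1. For a pregnancy with a male fetus, `epsilon` estimates the fetal
#' fraction. The fetus is called female when `cr_y` is within
#' `k * SD_female` of the female curve (default `k = 3`); female and
#' indeterminate samples get `epsilon = NA` (the raw value is kept in
#' `epsilon_raw`). Estimates slightly outside \[0, 1\] from sampling noise
#' are clamped.
#'
#' @param cr_y,gc_y Sample statistics from [relative_chrY_coverage()] (a
#'   one-row tibble may be passed as `cr_y` with `gc_y` missing).
#' @param ref A [fit_reference_curves()] object.
#' @param k Sex-call threshold in female-reference residual SDs.
#' @param sample_id Optional identifier for the output.
#' @return One-row tibble: `sample_id`, `cr_y`, `gc_y`, `epsilon`,
#'   `epsilon_raw`, `sex_call` (`"male"`, `"female"` or `"indeterminate"`),
#'   `qc` flag string.
#' @export
estimate_fetal_fraction <- function(cr_y, gc_y = NULL, ref, k = 3,
                                    sample_id = NA_character_) {
  if (is.data.frame(cr_y)) {
    df <- cr_y
    if ("sample_id" %in% names(df) && is.na(sample_id)) sample_id <- df$sample_id[1]
    gc_y <- df$gc_y[1]
    cr_y <- df$cr_y[1]
  }
  stopifnot(inherits(ref, "chry_reference"), is.numeric(cr_y), is.numeric(gc_y))
  lo <- ref$predict_female(gc_y)
  hi <- ref$predict_male(gc_y)
  denom <- hi - lo
  if (denom <= 0) {
    stop("reference curves cross at this GC value; reference invariant broken",
         call. = FALSE)
  }
  eps_raw <- (cr_y - lo) / denom
  bound <- lo + k * ref$female_sd
  sex_call <- if (cr_y > bound) "male" else if (cr_y < bound) "female" else "indeterminate"
  eps <- if (sex_call == "male") min(1, max(0, eps_raw)) else NA_real_
  qc <- if (sex_call == "male" && (eps_raw < -0.02 || eps_raw > 1.02)) {
    "epsilon_outside_unit_interval"
  } else {
    "ok"
  }
  tibble::tibble(
    sample_id = sample_id, cr_y = cr_y, gc_y = gc_y,
    epsilon = eps, epsilon_raw = eps_raw, sex_call = sex_call, qc = qc
  )
}

#' Build a chrY reference panel table from coverage tibbles
#'
#' Convenience wrapper: applies [relative_chrY_coverage()] to each coverage
#' tibble in a list (e.g. `simulate_cohort()$panels$male_adult`) and stacks
#' the rows.
#'
#' @param coverages Named list of coverage tibbles.
#' @param class Optional panel label stored in a `class` column.
#' @return Tibble with one row per sample.
#' @export
chry_panel <- function(coverages, class = NA_character_) {
  dplyr::bind_rows(lapply(coverages, relative_chrY_coverage)) |>
    dplyr::mutate(class = class)
}
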