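#' Assign read start positions to genome-model bins
#'
#' Real-data entry point: turns BED-like read start records into the binned
#' count table the rest of the pipeline consumes. Each read start is assigned
#' to exactly one bin under the 0-based half-open convention (a read exactly
#' at a bin end belongs to the next bin). Reads on chromosomes absent from
#' the model are dropped with a message; more than 10% unresolvable reads is
#' an error.
#'
#' @param reads Tibble/data frame with columns `chrom` and `pos` (0-based bp
#'   read start). A BED-style `start` column is accepted as an alias.
#' @param model A [build_genome_model()] object.
#' @param sample_id Sample identifier for the output.
#' @return Coverage tibble (`sample_id`, `chrom`, `start`, `end`, `gc`,
#'   `count`) aligned to the model bins.
#' @export
count_reads <- function(reads, model, sample_id = "S1") {
  stopifnot(inherits(model, "genome_model"))
  reads <- tibble::as_tibble(reads)
  if (!"pos" %in% names(reads) && "start" %in% names(reads)) {
    reads$pos <- reads$start
  }
  stopifnot(all(c("chrom", "pos") %in% names(reads)))
  if (nrow(reads) == 0) stop("no reads supplied", call. = FALSE)

  known <- reads$chrom %in% model$chromosomes$chrom
  n_dropped <- sum(!known)
  if (n_dropped / nrow(reads) > 0.10) {
    stop(sprintf("%d of %d reads (%.1f%%) on chromosomes absent from the model",
                 n_dropped, nrow(reads), 100 * n_dropped / nrow(reads)),
         call. = FALSE)
  }
  if (n_dropped > 0) {
    message(n_dropped, " reads on unknown chromosomes dropped")
  }
  reads <- reads[known, ]

  bins <- model$bins
  bins$.bin <- seq_len(nrow(bins))
  counts <- integer(nrow(bins))
  for (chrom in unique(reads$chrom)) {
    b <- bins[bins$chrom == chrom, ]
    pos <- reads$pos[reads$chrom == chrom]
    chrom_len <- model$chromosomes$length[model$chromosomes$chrom == chrom]
    if (any(pos < 0 | pos >= chrom_len)) {
      stop("read positions outside chromosome ", chrom, call. = FALSE)
    }
    idx <- findInterval(pos, b$start)  # half-open: pos == end goes right
    tab <- tabulate(idx, nbins = nrow(b))
    counts[b$.bin] <- counts[b$.bin] + tab
  }
  dplyr::bind_cols(
    tibble::tibble(sample_id = sample_id),
    model$bins[c("chrom", "start", "end", "gc")],
    tibble::tibble(count = counts)
  )
}

#' Fit the GC-bias curve of one sample
#'
#' Local linear (tricube-weighted) regression of per-bin read count on bin GC
#' fraction over autosomal bins presumed diploid, the regression-based GC
#' correction step of the caller. Sex chromosomes, bins with GC outside
#' `gc_range`, zero-mappability bins and masked-out bins are excluded from
#' fitting (but are still corrected by [gc_correct()] using the fitted
#' curve). Evaluation outside the fitted GC range is clamped to its edge.
#'
#' @param coverage Coverage tibble from [simulate_sample()], [count_reads()]
#'   or [read_bin_counts()].
#' @param model The matching [build_genome_model()] object.
#' @param mask Optional logical vector aligned to the bins: `TRUE` for bins
#'   presumed diploid and usable for fitting. Default: all bins.
#' @param span Loess span (fraction of points in each local fit), default 0.3.
#' @param gc_range GC interval of bins used for fitting, default
#'   \[0.25, 0.75\]; extreme-GC bins are noise-dominated.
#' @param max_fit_bins Upper bound on bins entering the loess fit; larger
#'   masks are thinned to an evenly spaced subset of this size (deterministic).
#'
#' @return A `gc_curve` object: `predict(curve, gc)` evaluates the expected
#'   count; fields record the fit diagnostics.
#' @details Degenerate GC variation (range of usable GC < 0.02) falls back to
#'   a constant global-median curve with a warning; fewer than 200 usable
#'   bins or a usable GC span < 0.10 is an error.
#' @export
fit_gc_curve <- function(coverage, model, mask = NULL, span = 0.3,
                         gc_range = c(0.25, 0.75), max_fit_bins = 5000) {
  stopifnot(inherits(model, "genome_model"))
  bins <- model$bins
  stopifnot(nrow(coverage) == nrow(bins))
  if (is.null(mask)) mask <- rep(TRUE, nrow(bins))
  stopifnot(length(mask) == nrow(bins))

  use <- mask &
    is_autosome(bins$chrom) &
    bins$mappability > 0 &
    bins$gc >= gc_range[1] & bins$gc <= gc_range[2]
  gc <- coverage$gc[use]
  count <- coverage$count[use]

  if (diff(range(gc)) < 0.02) {
    warning("degenerate GC variation; falling back to a constant median curve",
            call. = FALSE)
    med <- stats::median(count)
    return(new_gc_curve(
      fun = function(g) rep(med, length(g)),
      gc_limits = range(gc), n_bins = length(count),
      residual_sd = stats::mad(count - med), span = NA_real_, constant = TRUE
    ))
  }
  if (sum(use) < 200) {
    stop("fewer than 200 usable diploid autosomal bins for GC fitting", call. = FALSE)
  }
  if (diff(range(gc)) < 0.10) {
    stop("usable bins span less than 0.10 of GC range", call. = FALSE)
  }

  if (length(gc) > max_fit_bins) {
    keep <- unique(round(seq(1, length(gc), length.out = max_fit_bins)))
    gc <- gc[keep]; count <- count[keep]
  }
  fit <- stats::loess(count ~ gc, degree = 1, span = span,
                      family = "gaussian",
                      control = stats::loess.control(surface = "interpolate"))
  lims <- range(gc)
  fun <- function(g) {
    g <- pmin(lims[2], pmax(lims[1], g))
    as.numeric(stats::predict(fit, newdata = data.frame(gc = g)))
  }
  new_gc_curve(
    fun = fun, gc_limits = lims, n_bins = length(count),
    residual_sd = stats::sd(stats::residuals(fit)), span = span, constant = FALSE
  )
}

new_gc_curve <- function(fun, gc_limits, n_bins, residual_sd, span, constant) {
  structure(
    list(fun = fun, gc_limits = gc_limits, n_bins = n_bins,
         residual_sd = residual_sd, span = span, constant = constant),
    class = "gc_curve"
  )
}

#' @export
predict.gc_curve <- function(object, gc, ...) object$fun(gc)

#' @export
print.gc_curve <- function(x, ...) {
  cat(sprintf(
    "<gc_curve> %s fit on %d bins, GC range [%.3f, %.3f], residual SD %.1f\n",
    if (x$constant) "constant (fallback)" else sprintf("loess span %.2f", x$span),
    x$n_bins, x$gc_limits[1], x$gc_limits[2], x$residual_sd
  ))
  invisible(x)
}

#' Tidy and summarise fitted objects
#'
#' Broom-style accessors: `tidy()` returns the per-unit table of a fitted or
#' constructed object (curve evaluations on a GC grid, per-bin table of a
#' genome model, per-panel coefficients of a chromosome-Y reference model);
#' `glance()` returns a one-row summary.
#'
#' @param x A `gc_curve`, `genome_model` or `chry_reference` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy.gc_curve
#' @method tidy gc_curve
#' @export
tidy.gc_curve <- function(x, ...) {
  gc <- seq(x$gc_limits[1], x$gc_limits[2], length.out = 50)
  tibble::tibble(gc = gc, expected_count = x$fun(gc))
}

#' @rdname tidy.gc_curve
#' @method glance gc_curve
#' @export
glance.gc_curve <- function(x, ...) {
  tibble::tibble(
    n_bins = x$n_bins, span = x$span, constant = x$constant,
    residual_sd = x$residual_sd,
    gc_min = x$gc_limits[1], gc_max = x$gc_limits[2]
  )
}

#' GC-correct and normalise binned coverage to copy ratios
#'
#' Divides each bin count by the expected count at its GC fraction and
#' rescales so that the autosomal median copy ratio is exactly 1. Sex
#' chromosomes are corrected with the autosomal curve but excluded from the
#' scaling median, so their ratios reflect dosage (chrX near 1, chrY near the
#' fetal-fraction signal). The per-bin standard error uses a Poisson
#' approximation, `sigma_i = sqrt(max(count, 1)) / chat(gc_i) / scale`, and
#' feeds the caller's dynamic threshold.
#'
#' @param coverage Coverage tibble aligned to `model`.
#' @param curve A [fit_gc_curve()] object fitted on the same genome model.
#' @param model The [build_genome_model()] object.
#' @return Normalised-coverage tibble: the input columns plus `ratio` and
#'   `sigma`, with attribute `scale_factor` (the autosomal median divisor).
#' @export
gc_correct <- function(coverage, curve, model) {
  stopifnot(inherits(curve, "gc_curve"), inherits(model, "genome_model"))
  stopifnot(nrow(coverage) == nrow(model$bins))
  expected <- predict(curve, coverage$gc)
  if (any(!is.finite(expected)) || any(expected <= 0)) {
    stop("fitted GC curve is non-positive over the data's GC range", call. = FALSE)
  }
  rho <- coverage$count / expected
  auto <- is_autosome(coverage$chrom) & model$bins$mappability > 0
  scale <- stats::median(rho[auto])
  if (!is.finite(scale) || scale <= 0) {
    stop("autosomal median ratio is not positive; cannot normalise", call. = FALSE)
  }
  out <- coverage
  out$ratio <- rho / scale
  out$sigma <- sqrt(pmax(coverage$count, 1)) / expected / scale
  attr(out, "scale_factor") <- scale
  class(out) <- c("plasma_coverage", class(tibble::as_tibble(out)))
  out
}

#' Write / read normalised coverage TSV
#'
#' @param normalized Output of [gc_correct()].
#' @param path File path.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_normalized_coverage <- function(normalized, path) {
  readr::write_tsv(
    normalized[c("chrom", "start", "end", "gc", "count", "ratio", "sigma")],
    path
  )
  invisible(path)
}

#' @rdname write_normalized_coverage
#' @param sample_id Sample identifier to attach on read.
#' @export
read_normalized_coverage <- function(path, sample_id = NULL) {
  if (is.null(sample_id)) sample_id <- sub("\\..*$", "", basename(path))
  dat <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(), start = readr::col_double(),
    end = readr::col_double(), gc = readr::col_double(),
    count = readr::col_integer(), ratio = readr::col_double(),
    sigma = readr::col_double()
  ))
  dplyr::bind_cols(tibble::tibble(sample_id = sample_id), dat)
}
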