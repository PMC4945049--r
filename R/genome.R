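#' Chromosome lengths of the hg19 reference assembly
#'
#' Returns the 24 canonical hg19 chromosome lengths (chr1-chr22, chrX, chrY)
#' as a two-column tibble. These are the coordinates all shipped fixtures and
#' worked examples use; [build_genome_model()] accepts any table of the same
#' shape for other assemblies or toy genomes.
#'
#' @return A tibble with columns `chrom` (character) and `length` (bp).
#' @export
#' @examples
#' hg19_chromosomes()
hg19_chromosomes <- function() {
  path <- system.file("extdata", "hg19_chromosomes.tsv", package = "plasmacnv")
  readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    length = readr::col_double()
  ))
}

#' Build a binned genome model
#'
#' Tiles each chromosome with fixed-size bins (the last bin of a chromosome
#' may be short) and attaches a GC fraction and a mappability weight to every
#' bin. The model is the coordinate frame for simulation, coverage
#' normalisation and CNV calling: all per-bin tables downstream are aligned
#' to its `bins` tibble.
#'
#' @param chromosome_table Tibble/data frame with columns `chrom` and
#'   `length` (bp). Names must be unique, lengths positive.
#' @param bin_size Bin width in bp (default 100 kb).
#' @param gc_source Either a data frame with columns `chrom`, `start`, `gc`
#'   aligned to the tiling, a single numeric in (0, 1) used as a constant GC
#'   fraction, or `NULL` (default) to draw a smooth seeded random GC field
#'   typical of a mammalian genome.
#' @param gc_seed Seed for the random GC field (ignored when `gc_source`
#'   is supplied). The field is deterministic given the seed.
#' @param mappability Per-bin mappability weight; a single number (default 1)
#'   or a vector aligned to the tiling. Bins with weight 0 receive no reads
#'   and are excluded from GC-curve fitting.
#'
#' @return An object of class `genome_model`: a list with elements
#'   `chromosomes` (tibble `chrom`, `length`), `bins` (tibble `chrom`,
#'   `start`, `end`, `gc`, `mappability`; 0-based half-open bp, sorted by
#'   chromosome order then start) and `bin_size`.
#' @export
#' @examples
#' toy <- tibble::tibble(chrom = c("chr1", "chrX"), length = c(1e7, 5e6))
#' model <- build_genome_model(toy, bin_size = 1e5, gc_seed = 1)
#' model
build_genome_model <- function(chromosome_table, bin_size = 1e5,
                               gc_source = NULL, gc_seed = 1L,
                               mappability = 1) {
  chromosome_table <- tibble::as_tibble(chromosome_table)
  stopifnot(all(c("chrom", "length") %in% names(chromosome_table)))
  if (anyDuplicated(chromosome_table$chrom) > 0) {
    stop("chromosome table has duplicated names", call. = FALSE)
  }
  if (any(chromosome_table$length <= 0)) {
    stop("chromosome lengths must be positive", call. = FALSE)
  }
  if (bin_size <= 0) stop("bin_size must be positive", call. = FALSE)

  bins <- chromosome_table |>
    dplyr::mutate(chrom = factor(.data$chrom, levels = .data$chrom)) |>
    dplyr::rowwise() |>
    dplyr::reframe(
      chrom = .data$chrom,
      start = seq(0, .data$length - 1, by = bin_size),
      end = pmin(.data$start + bin_size, .data$length)
    ) |>
    dplyr::mutate(chrom = as.character(.data$chrom))

  n <- nrow(bins)
  bins$gc <- resolve_gc(gc_source, bins, gc_seed)
  if (any(bins$gc < 0 | bins$gc > 1)) {
    stop("GC fractions must lie in [0, 1]", call. = FALSE)
  }
  if (length(mappability) == 1) mappability <- rep(mappability, n)
  if (length(mappability) != n || any(mappability < 0)) {
    stop("mappability must be a non-negative scalar or per-bin vector", call. = FALSE)
  }
  bins$mappability <- as.numeric(mappability)

  structure(
    list(
      chromosomes = tibble::as_tibble(chromosome_table[c("chrom", "length")]),
      bins = tibble::as_tibble(bins),
      bin_size = bin_size
    ),
    class = "genome_model"
  )
}

resolve_gc <- function(gc_source, bins, gc_seed) {
  if (is.null(gc_source)) {
    return(smooth_gc_field(bins, gc_seed))
  }
  if (is.numeric(gc_source) && length(gc_source) == 1) {
    return(rep(gc_source, nrow(bins)))
  }
  gc_source <- tibble::as_tibble(gc_source)
  stopifnot(all(c("chrom", "start", "gc") %in% names(gc_source)))
  key <- paste(bins$chrom, bins$start)
  src <- stats::setNames(gc_source$gc, paste(gc_source$chrom, gc_source$start))
  gc <- unname(src[key])
  if (anyNA(gc)) stop("gc_source does not cover every bin of the tiling", call. = FALSE)
  gc
}

# Smooth per-bin GC fraction: low-frequency anchors every ~50 bins,
# spline-interpolated, plus mild bin-level jitter. Range ~[0.30, 0.62],
# centred near 0.42 as in mammalian 100 kb bins.
smooth_gc_field <- function(bins, gc_seed) {
  rng <- local_rng(gc_seed)
  unlist(lapply(split(seq_len(nrow(bins)), bins$chrom), function(idx) {
    n <- length(idx)
    k <- max(4L, ceiling(n / 50))
    anchors <- rng$rnorm(k, mean = 0.42, sd = 0.05)
    xout <- seq(1, k, length.out = n)
    base <- stats::spline(seq_len(k), anchors, xout = xout)$y
    pmin(0.62, pmax(0.30, base + rng$rnorm(n, sd = 0.01)))
  })[unique(bins$chrom)], use.names = FALSE)
}

# Seed-local RNG wrapper so model construction never disturbs the caller's
# random stream.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  })
  draw <- function(fn) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      out <- fn(...)
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
      out
    }
  }
  list(rnorm = draw(stats::rnorm), runif = draw(stats::runif))
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(
    "<genome_model> %d chromosomes, %d bins of %s bp (last bin per chromosome may be short)\n",
    nrow(x$chromosomes), nrow(x$bins), format(x$bin_size, big.mark = ",")
  ))
  print(x$chromosomes, n = 5)
  invisible(x)
}

#' @rdname tidy.gc_curve
#' @method tidy genome_model
#' @export
tidy.genome_model <- function(x, ...) x$bins

#' @rdname tidy.gc_curve
#' @method glance genome_model
#' @export
glance.genome_model <- function(x, ...) {
  tibble::tibble(
    n_chromosomes = nrow(x$chromosomes),
    n_bins = nrow(x$bins),
    bin_size = x$bin_size,
    genome_bp = sum(x$chromosomes$length)
  )
}

is_autosome <- function(chrom) !chrom %in% c("chrX", "chrY", "X", "Y")
is_chrY <- function(chrom) chrom %in% c("chrY", "Y")
is_chrX <- function(chrom) chrom %in% c("chrX", "X")
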