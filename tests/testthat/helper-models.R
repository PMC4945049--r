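# Shared fixtures: a small five-chromosome genome for fast unit tests and a
# cached full-scale model for the tests that need realistic bin counts.

toy_chromosomes <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr2", "chr3", "chrX", "chrY"),
    length = c(60e6, 50e6, 40e6, 30e6, 10e6)
  )
}

toy_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_genome_model(toy_chromosomes(), 1e5, gc_seed = 42)
    cache
  }
})

hg19_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_genome_model(hg19_chromosomes(), 1e5, gc_seed = 7)
    cache
  }
})

toy_reads <- 5e5  # ~263 reads per 100 kb bin, matching full-scale depth

simulate_toy <- function(seed, fetal_fraction = 0.10, fetus_sex = "male",
                         cnv_specs = NULL, total_reads = toy_reads, ...) {
  cfg <- simulation_config(total_reads = total_reads,
                           fetal_fraction = fetal_fraction,
                           fetus_sex = fetus_sex, cnv_specs = cnv_specs, ...)
  simulate_sample(toy_model(), cfg, seed = seed)
}

normalize_toy <- function(sim) {
  gc_correct(sim$coverage, fit_gc_curve(sim$coverage, toy_model()), toy_model())
}

is_autosome_chrom <- function(chrom) !chrom %in% c("chrX", "chrY")
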