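#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end synthetic experiment: genome,
#' cohort composition, simulation parameters, caller configuration and
#' output location. The one seed drives every stochastic stage.
#'
#' @param out_dir Output directory (created if missing).
#' @param chromosome_table Chromosome table for [build_genome_model()]
#'   (default [hg19_chromosomes()]).
#' @param bin_size Bin size in bp.
#' @param n_euploid,n_cnv Cohort composition.
#' @param n_male_panel,n_female_panel chrY reference panel sizes.
#' @param total_reads Reads per sample.
#' @param cnv_size_range_mb CNV size range (Mb) for simulated events.
#' @param cnv_origin Origin of simulated CNVs.
#' @param caller A [caller_config()].
#' @param size_cut_mb Performance stratification cut.
#' @param seed Integer master seed.
#' @param ... Extra arguments forwarded to [simulate_cohort()] /
#'   [simulation_config()].
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            chromosome_table = hg19_chromosomes(),
                            bin_size = 1e5,
                            n_euploid = 7, n_cnv = 3,
                            n_male_panel = 20, n_female_panel = 20,
                            total_reads = 7e6,
                            cnv_size_range_mb = c(1, 129),
                            cnv_origin = "fetal",
                            caller = caller_config(),
                            size_cut_mb = 10,
                            seed = 1L,
                            ...) {
  structure(
    list(out_dir = out_dir, chromosome_table = chromosome_table,
         bin_size = bin_size, n_euploid = n_euploid, n_cnv = n_cnv,
         n_male_panel = n_male_panel, n_female_panel = n_female_panel,
         total_reads = total_reads, cnv_size_range_mb = cnv_size_range_mb,
         cnv_origin = cnv_origin, caller = caller, size_cut_mb = size_cut_mb,
         seed = as.integer(seed), extra = list(...)),
    class = "pipeline_config"
  )
}

#' Run the end-to-end synthetic screening experiment
#'
#' Simulates a cohort, then processes every sample blind to its truth
#' status: GC-corrects the binned counts, estimates fetal fraction from
#' chromosome-Y coverage against simulated reference panels, calls CNVs with
#' the dynamic-threshold caller, and only then evaluates the calls against
#' the simulation's truth manifest. Writes per-sample normalised coverage,
#' a calls table, a fetal-fraction table, the performance summary (JSON and
#' markdown) and a manifest of every artefact with its MD5 hash.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-sample progress messages.
#' @return List: `calls`, `fetal_fractions`, `records` (concordance),
#'   `performance`, `manifest` (tibble `file`, `md5`), `truth`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)

  say("building genome model (bin size ", config$bin_size, " bp)")
  model <- build_genome_model(config$chromosome_table, config$bin_size,
                              gc_seed = config$seed)

  say("simulating cohort: ", config$n_cnv, " CNV + ", config$n_euploid,
      " euploid samples, panels ", config$n_male_panel, "M/",
      config$n_female_panel, "F")
  cohort <- do.call(simulate_cohort, c(
    list(model = model, n_euploid = config$n_euploid, n_cnv = config$n_cnv,
         n_male_panel = config$n_male_panel,
         n_female_panel = config$n_female_panel,
         cnv_size_range_mb = config$cnv_size_range_mb,
         cnv_origin = config$cnv_origin,
         total_reads = config$total_reads, seed = config$seed),
    config$extra
  ))

  ref <- fit_reference_curves(
    chry_panel(cohort$panels$male_adult, class = "male_adult"),
    chry_panel(cohort$panels$female_fetus, class = "female_fetus")
  )

  results <- lapply(names(cohort$samples), function(id) {
    say("  sample ", id)
    cov <- cohort$samples[[id]]
    curve <- fit_gc_curve(cov, model)
    norm <- gc_correct(cov, curve, model)
    ff <- estimate_fetal_fraction(relative_chrY_coverage(cov), ref = ref)
    calls <- call_cnvs(norm, f = ff$epsilon, config = config$caller,
                       sex = if (ff$sex_call == "male") "male" else "female")
    write_normalized_coverage(norm, file.path(config$out_dir, paste0(id, ".norm.tsv")))
    list(ff = ff, calls = calls)
  })

  fetal_fractions <- dplyr::bind_rows(lapply(results, `[[`, "ff"))
  calls <- dplyr::bind_rows(lapply(results, `[[`, "calls"))
  write_calls(calls, file.path(config$out_dir, "calls.tsv"))
  readr::write_tsv(fetal_fractions, file.path(config$out_dir, "fetal_fractions.tsv"))
  readr::write_tsv(cohort$truth, file.path(config$out_dir, "truth_manifest.tsv"))

  say("evaluating against truth manifest")
  truth_events <- parse_truth_manifest(cohort$truth)
  records <- classify_concordance(calls, truth_events)
  euploid_ids <- cohort$fetal_fractions$sample_id[cohort$fetal_fractions$class == "euploid"]
  euploid_calls <- calls[calls$sample_id %in% euploid_ids, ]
  perf <- performance_summary(records, euploid_calls, euploid_ids,
                              size_cut_mb = config$size_cut_mb)
  jsonlite::write_json(perf, file.path(config$out_dir, "performance.json"),
                       dataframe = "rows", na = "null", digits = NA)
  report_performance(perf, file.path(config$out_dir, "performance.md"))

  files <- sort(list.files(config$out_dir, full.names = TRUE))
  manifest <- tibble::tibble(
    file = basename(files),
    md5 = unname(tools::md5sum(files))
  )
  readr::write_tsv(manifest, file.path(config$out_dir, "MANIFEST.tsv"))

  list(calls = calls, fetal_fractions = fetal_fractions, records = records,
       performance = perf, manifest = manifest, truth = cohort$truth)
}
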