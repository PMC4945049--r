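#' Read a UCSC-format cytoband table
#'
#' Reads the five-column UCSC `cytoBand` format (chrom, start, end, band,
#' stain; tab-separated, no header, 0-based half-open bp) used to translate
#' karyotype band names into genomic coordinates. The package ships a
#' synthetic hg19-like banding table
#' (`system.file("extdata", "cytoband_hg19_synthetic.tsv", package = "plasmacnv")`):
#' the chr5 short-arm boundaries follow the standard hg19 ideogram, other
#' chromosomes are plausible tilings for demonstration; supply a real
#' assembly file for clinical strings.
#'
#' @param path Cytoband file path; default the shipped synthetic table.
#' @return Tibble: `chrom`, `start`, `end`, `band`, `stain`, ordered and
#'   validated to tile each chromosome without overlap.
#' @export
read_cytoband <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cytoband_hg19_synthetic.tsv",
                        package = "plasmacnv")
  }
  bands <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "band", "stain"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), band = readr::col_character(),
      stain = readr::col_character()
    ),
    comment = "#"
  )
  bands <- dplyr::arrange(bands, .data$chrom, .data$start)
  bad <- bands |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(gap = any(.data$start[-1] != .data$end[-dplyr::n()]) ||
                       .data$start[1] != 0) |>
    dplyr::filter(.data$gap)
  if (nrow(bad) > 0) {
    stop("cytoband table does not tile chromosome(s): ",
         paste(bad$chrom, collapse = ", "), call. = FALSE)
  }
  bands
}

#' Resolve a band name or prefix to genomic coordinates
#'
#' An exact band name (`"p15.33"`) resolves to that band's interval; a
#' prefix (`"p14"`, `"q21"`, or a whole arm `"p"`) resolves to the union of
#' all sub-bands sharing the prefix (`p14.1`-`p14.3` etc.), following the
#' hierarchical band nomenclature.
#'
#' @param bands Cytoband tibble from [read_cytoband()].
#' @param chrom Chromosome (with or without the `"chr"` prefix).
#' @param band Band name or prefix, e.g. `"p15.2"` or `"q21"`.
#' @return One-row tibble `chrom`, `start`, `end` (bp, half-open).
#' @export
band_interval <- function(bands, chrom, band) {
  chrom <- norm_chrom(chrom)
  cb <- bands[bands$chrom == chrom, ]
  if (nrow(cb) == 0) stop("no bands for chromosome ", chrom, call. = FALSE)
  # hierarchical prefix match: "p14" covers p14.1-p14.3, "p11.2" covers
  # p11.21-p11.23, "p" covers the whole arm
  rest <- ifelse(startsWith(cb$band, band),
                 substring(cb$band, nchar(band) + 1), NA_character_)
  hit <- !is.na(rest) & (rest == "" | grepl("^[.0-9]", rest))
  if (!any(hit)) {
    stop(sprintf("band '%s' not found on %s", band, chrom), call. = FALSE)
  }
  tibble::tibble(chrom = chrom, start = min(cb$start[hit]), end = max(cb$end[hit]))
}

norm_chrom <- function(chrom) {
  ifelse(startsWith(chrom, "chr"), chrom, paste0("chr", chrom))
}
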