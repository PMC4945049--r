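#' Parse a karyotype / microarray result string into truth events
#'
#' Translates the reporting dialects of clinical confirmation results into
#' coordinate intervals:
#'
#' * karyotype CNVs: `"46,XX,del(5)(p15.33p15.2)"`, `"dup(1)(p36)"`,
#'   `"46,XX,?del(7)(q32)"` — a band pair resolves to the outer boundaries
#'   of the first and last named bands, a single band (or band prefix like
#'   `p14`) to that band's (union) interval, via the cytoband table;
#' * microarray: `"arr 13q21.2(60,399-61,730)x3"` — coordinates taken
#'   verbatim as kb; copy number 1 is a loss, 3 a gain;
#' * a plain normal karyotype (`"46,XX"`, `"46,XY"`) yields no events.
#'
#' Derivative/mosaic/otherwise complex forms (`der`, `mos`, arm shorthand
#' like `"Xp-"`) are not guessed at: they raise an error directing the user
#' to explicit coordinate columns in the truth manifest
#' (see [parse_truth_manifest()]).
#'
#' @param raw Result string.
#' @param bands Cytoband tibble from [read_cytoband()] (needed for karyotype
#'   dialects).
#' @param sample_id Optional identifier attached to the events.
#' @return Tibble of truth events: `sample_id`, `chrom`, `start_kb`,
#'   `end_kb`, `direction`, `size_mb`, `source` (`"karyotype"` or
#'   `"array"`), `raw`. Zero rows for a normal karyotype.
#' @export
parse_truth <- function(raw, bands = NULL, sample_id = NA_character_) {
  stopifnot(is.character(raw), length(raw) == 1)
  txt <- trimws(raw)

  empty <- tibble::tibble(
    sample_id = character(), chrom = character(), start_kb = numeric(),
    end_kb = numeric(), direction = character(), size_mb = numeric(),
    source = character(), raw = character()
  )

  if (grepl("\\b(der|mos|\\+i)\\b|[XY]p-|[XY]q-|\\+\\s*i\\(", txt)) {
    stop("complex karyotype form not parseable: '", raw,
         "'; supply explicit coordinates in the truth manifest", call. = FALSE)
  }

  # microarray dialect: arr <band>(<start>-<end>)x<n>, coordinates in kb
  if (grepl("^arr\\b", txt)) {
    m <- regmatches(txt, regexec(
      "^arr\\s+([0-9XY]+)[pq][0-9.q]*\\(([0-9,]+)\\s*[-–]\\s*([0-9,]+)\\)\\s*[x×](\\d+)",
      txt))[[1]]
    if (length(m) == 0) {
      stop("unparseable array result: '", raw, "'", call. = FALSE)
    }
    cn <- as.integer(m[5])
    if (cn == 2) return(empty)
    start_kb <- as.numeric(gsub(",", "", m[3]))
    end_kb <- as.numeric(gsub(",", "", m[4]))
    return(tibble::tibble(
      sample_id = sample_id, chrom = norm_chrom(m[2]),
      start_kb = start_kb, end_kb = end_kb,
      direction = if (cn > 2) "gain" else "loss",
      size_mb = (end_kb - start_kb) / 1000,
      source = "array", raw = raw
    ))
  }

  # karyotype dialect: optional "4x,X?," prefix, then del/dup terms
  body <- sub("^4[5-7]\\s*,\\s*[Xx]\\s*[XxYy?]?\\s*,?\\s*", "", txt)
  if (body == "" || grepl("^4[5-7]\\s*,\\s*[Xx][XxYy?]?$", txt)) return(empty)

  terms <- regmatches(body, gregexpr(
    "\\??(del|dup)\\s*\\(\\s*([0-9XY]+)\\s*\\)\\s*\\(([^)]*)\\)", body))[[1]]
  if (length(terms) == 0) {
    stop("unparseable karyotype result: '", raw,
         "'; supply explicit coordinates in the truth manifest", call. = FALSE)
  }
  leftover <- gsub("\\??(del|dup)\\s*\\(\\s*[0-9XY]+\\s*\\)\\s*\\([^)]*\\)", "", body)
  if (grepl("[A-Za-z(]", gsub("[,;\\s]", "", leftover))) {
    stop("unparseable karyotype component in '", raw,
         "'; supply explicit coordinates in the truth manifest", call. = FALSE)
  }
  if (is.null(bands)) {
    stop("a cytoband table is required to resolve karyotype band names",
         call. = FALSE)
  }

  events <- lapply(terms, function(term) {
    m <- regmatches(term, regexec(
      "(del|dup)\\s*\\(\\s*([0-9XY]+)\\s*\\)\\s*\\(([^)]*)\\)", term))[[1]]
    op <- m[2]; chrom <- m[3]; spec <- gsub("\\s", "", m[4])
    band_names <- regmatches(spec, gregexpr("[pq][0-9]+(\\.[0-9]+)?", spec))[[1]]
    if (length(band_names) == 0 && spec %in% c("p", "q")) band_names <- spec
    if (length(band_names) < 1 || length(band_names) > 2) {
      stop("cannot resolve band specification '", spec, "' in '", raw, "'",
           call. = FALSE)
    }
    first <- band_interval(bands, chrom, band_names[1])
    last <- band_interval(bands, chrom, band_names[length(band_names)])
    start <- min(first$start, last$start)
    end <- max(first$end, last$end)
    tibble::tibble(
      sample_id = sample_id, chrom = norm_chrom(chrom),
      start_kb = start / 1000, end_kb = end / 1000,
      direction = if (op == "dup") "gain" else "loss",
      size_mb = (end - start) / 1e6,
      source = "karyotype", raw = raw
    )
  })
  dplyr::bind_rows(events)
}

#' Parse a truth manifest table
#'
#' Applies [parse_truth()] to each row of a manifest of clinical findings.
#' Rows carrying explicit coordinates (`chrom`, `start_kb`, `end_kb`,
#' `direction` all non-missing) bypass string parsing — the escape hatch for
#' derivative chromosomes, mosaics and arm-level shorthand.
#'
#' @param manifest Tibble with `sample_id` and either `source_string` or the
#'   explicit coordinate columns.
#' @param bands Cytoband tibble from [read_cytoband()].
#' @return Truth-event tibble (one row per event) as from [parse_truth()].
#' @export
parse_truth_manifest <- function(manifest, bands = NULL) {
  manifest <- tibble::as_tibble(manifest)
  stopifnot("sample_id" %in% names(manifest))
  has_coords <- all(c("chrom", "start_kb", "end_kb", "direction") %in% names(manifest))
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    if (has_coords && !is.na(row$chrom) && !is.na(row$start_kb) &&
        !is.na(row$end_kb) && !is.na(row$direction)) {
      return(tibble::tibble(
        sample_id = row$sample_id, chrom = norm_chrom(row$chrom),
        start_kb = row$start_kb, end_kb = row$end_kb,
        direction = row$direction,
        size_mb = (row$end_kb - row$start_kb) / 1000,
        source = "manifest",
        raw = if ("source_string" %in% names(row)) row$source_string else NA_character_
      ))
    }
    parse_truth(row$source_string, bands = bands, sample_id = row$sample_id)
  })
  dplyr::bind_rows(rows)
}
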