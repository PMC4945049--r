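#' Caller configuration
#'
#' Tuning parameters of the CNV caller. Defaults target 7M reads in 100 kb
#' bins (about 226 reads per bin): `z_split = 5.4` is the ~99th percentile
#' of the genome-wide null maximum of the split statistic over an hg19-sized
#' genome at this resolution (about 31k bins in 24 chromosomes), holding the
#' per-sample false-split rate near 1-2%; the dynamic threshold combines a
#' depth/length-scaled statistical term (`z_call` standard errors of the
#' segment mean) with a biological floor of `kappa * f / 2`, half the
#' expected copy-ratio shift of a heterozygous fetal CNV at fetal fraction
#' `f`. When no fetal-fraction estimate is available (female fetus), the
#' fallback `f0` is used.
#'
#' @param min_seg_bins Minimum child-segment length in bins (default 10 =
#'   1 Mb at 100 kb bins).
#' @param z_split Split-statistic magnitude required to accept a breakpoint.
#' @param z_call Multiplier of the segment-mean standard error in the
#'   statistical term of the dynamic threshold.
#' @param kappa Multiplier of `f/2` in the biological floor.
#' @param f0 Fallback fetal fraction when none is supplied (default 0.07,
#'   near the low end of observed male-pregnancy fractions).
#' @param min_report_mb Minimum reported call size in Mb (default 1).
#' @param chrY_background Expected female-background chrY ratio used as the
#'   chrY baseline.
#' @return A `caller_config` list.
#' @export
caller_config <- function(min_seg_bins = 10L, z_split = 5.4, z_call = 3.5,
                          kappa = 0.5, f0 = 0.07, min_report_mb = 1,
                          chrY_background = 0.002) {
  stopifnot(min_seg_bins >= 2, z_split > 0, z_call > 0, kappa > 0,
            f0 > 0, min_report_mb > 0)
  structure(
    list(min_seg_bins = as.integer(min_seg_bins), z_split = z_split,
         z_call = z_call, kappa = kappa, f0 = f0,
         min_report_mb = min_report_mb, chrY_background = chrY_background),
    class = "caller_config"
  )
}

# Interval-vs-complement t scan over x[lo:hi] with pooled segment SD:
# t(a, b) = (mean(x[a:b]) - mean(rest)) / (sd_seg * sqrt(1/n_in + 1/n_out)).
# Pooling the whole segment's SD (rather than per-window variances) keeps
# the null tails Gaussian for short windows. Candidate intervals [a, b]
# must have at least min_bins bins, leave a complement of at least min_bins,
# and leave no stub flank shorter than min_bins (a flank of length 0 is a
# plain prefix/suffix split). Returns the maximising interval,
# leftmost-first on ties (smallest a, then smallest b). O(n^2) candidates
# via prefix sums.
interval_scan <- function(x, lo, hi, min_bins) {
  n <- hi - lo + 1
  if (n < 2 * min_bins) return(NULL)
  xs <- x[lo:hi]
  sd_seg <- stats::sd(xs)
  if (!is.finite(sd_seg) || sd_seg == 0) return(NULL)
  cs <- c(0, cumsum(xs))
  tot <- cs[n + 1]
  best <- list(t = 0, a = NA_integer_, b = NA_integer_)
  for (len in min_bins:(n - min_bins)) {
    a <- seq_len(n - len + 1)                     # window [a, a+len-1]
    left <- a - 1
    right <- n - (a + len - 1)
    # a suffix window (right == 0, left > 0) describes the same partition as
    # the prefix window [1, a-1]; keep only the prefix representative
    ok <- (left == 0 | left >= min_bins) & right >= min_bins
    if (!any(ok)) next
    a <- a[ok]
    s_in <- cs[a + len] - cs[a]
    n_out <- n - len
    t <- (s_in / len - (tot - s_in) / n_out) / (sd_seg * sqrt(1 / len + 1 / n_out))
    i <- which.max(abs(t))                        # first (leftmost) maximum
    cand <- list(t = t[i], a = a[i], b = a[i] + len - 1)
    if (abs(cand$t) > abs(best$t) ||
        (abs(cand$t) == abs(best$t) && !is.na(best$a) &&
         (cand$a < best$a || (cand$a == best$a && cand$b < best$b)))) {
      best <- cand
    }
  }
  if (is.na(best$a)) return(NULL)
  list(t = best$t, a = lo + best$a - 1, b = lo + best$b - 1)
}

#' Binary segmentation of one chromosome's copy-ratio profile
#'
#' Recursive change-point detection with an interval-vs-complement test: at
#' each segment, the candidate sub-interval maximising the two-sample t
#' statistic between its mean and the mean of the rest of the segment —
#' standardised by the pooled standard deviation of the whole segment — is
#' located (an exhaustive scan; a prefix or suffix interval is the ordinary
#' single-breakpoint split). When `|t| >= z_split`, the segment is split at
#' the interval's boundaries — into two or three children, each at least
#' `min_seg_bins` long — and each child is segmented in turn. This is the
#' segmentation scheme of circular binary segmentation, with a fixed
#' analytic threshold in place of permutation p-values, so the procedure is
#' exact and fully deterministic; ties are broken toward the leftmost
#' maximising interval. The interval form is essential for fetal CNVs: a
#' shift of `f/2` in the middle of a long chromosome is nearly invisible to
#' a plain prefix/suffix mean comparison but stands out against its
#' complement. A profile shorter than `2 * min_seg_bins` is returned as a
#' single segment.
#'
#' @param ratios Numeric vector of per-bin copy ratios (one chromosome).
#' @param sigmas Per-bin standard errors (same length); used for the pooled
#'   segment error, not for the split statistic.
#' @param config A [caller_config()].
#' @return Tibble of segments partitioning the profile: `start_bin`,
#'   `end_bin` (1-based, inclusive), `n_bins`, `mean_ratio`, `se` (pooled
#'   sigma / sqrt(n)), `t_split` (the statistic that created the segment's
#'   founding split; `NA` for a never-split root).
#' @export
binary_segment <- function(ratios, sigmas = NULL, config = caller_config()) {
  stopifnot(is.numeric(ratios), length(ratios) >= 1)
  if (is.null(sigmas)) sigmas <- rep(stats::sd(ratios), length(ratios))
  stopifnot(length(sigmas) == length(ratios))
  min_bins <- config$min_seg_bins

  boundaries <- list()
  recurse <- function(lo, hi, founding_t) {
    scan <- interval_scan(ratios, lo, hi, min_bins)
    if (!is.null(scan) && abs(scan$t) >= config$z_split) {
      if (scan$a > lo) recurse(lo, scan$a - 1, scan$t)
      recurse(scan$a, scan$b, scan$t)
      if (scan$b < hi) recurse(scan$b + 1, hi, scan$t)
      return(invisible(NULL))
    }
    boundaries[[length(boundaries) + 1]] <<- c(lo, hi, founding_t)
    invisible(NULL)
  }
  recurse(1, length(ratios), NA_real_)

  segs <- do.call(rbind, boundaries)
  tibble::tibble(
    start_bin = as.integer(segs[, 1]),
    end_bin = as.integer(segs[, 2]),
    n_bins = as.integer(segs[, 2] - segs[, 1] + 1),
    mean_ratio = vapply(seq_len(nrow(segs)), function(i) {
      mean(ratios[segs[i, 1]:segs[i, 2]])
    }, numeric(1)),
    se = vapply(seq_len(nrow(segs)), function(i) {
      n <- segs[i, 2] - segs[i, 1] + 1
      sqrt(mean(sigmas[segs[i, 1]:segs[i, 2]]^2) / n)
    }, numeric(1)),
    t_split = segs[, 3]
  )
}

#' Dynamic calling threshold for a segment
#'
#' The minimum copy-ratio deviation `|mean - baseline|` a segment must show
#' to become a call:
#' `theta = max(z_call * se_segment, kappa * f_eff / 2)`.
#' The first term scales with sequencing depth and segment length (long
#' segments at high depth are held to a tight statistical standard); the
#' second enforces a biologically meaningful minimum shift — half the
#' expected single-copy signal of a fetal CNV at fetal fraction `f_eff`
#' (`f` when supplied, otherwise the fallback `f0`). As segment length grows
#' the threshold converges to the biological floor.
#'
#' @param f Fetal fraction, or `NA` when unknown.
#' @param segment One-row segment (needs `se`), e.g. a [binary_segment()]
#'   row; alternatively pass `se` directly.
#' @param config A [caller_config()].
#' @param se Segment-mean standard error, overriding `segment$se`.
#' @return Threshold on `|mean ratio - baseline|`.
#' @export
dynamic_threshold <- function(f, segment = NULL, config = caller_config(),
                              se = NULL) {
  if (is.null(se)) se <- segment$se
  f_eff <- if (length(f) == 1 && is.finite(f)) f else config$f0
  max(config$z_call * se, config$kappa * f_eff / 2)
}

#' Call CNVs from normalised coverage
#'
#' The caller core: segments every chromosome's copy-ratio profile with
#' [binary_segment()], then reports each segment whose mean deviates from
#' its dosage baseline by at least the [dynamic_threshold()] and whose size
#' reaches `min_report_mb`. Adjacent same-direction calls separated by fewer
#' than `min_seg_bins` bins are merged. Autosomes are tested against a
#' baseline of 1; sex chromosomes against the expected dosage of the called
#' fetal sex (chrX `1 - f/2` for a male fetus; chrY `beta + f/2` male,
#' `beta` female). Truth data never enters this function.
#'
#' @param normalized Normalised coverage from [gc_correct()].
#' @param f Fetal-fraction estimate or `NA` (the fallback `f0` is then used
#'   in the threshold).
#' @param config A [caller_config()].
#' @param sex Fetal sex for sex-chromosome baselines: `"male"`, `"female"`
#'   or `"auto"` (male when `f` is available).
#' @return Calls tibble: `sample_id`, `chrom`, `start`, `end` (bp),
#'   `start_kb`, `end_kb`, `direction`, `size_mb`, `mean_ratio`, `z`,
#'   `n_bins`. Zero rows for a negative sample.
#' @export
call_cnvs <- function(normalized, f = NA_real_, config = caller_config(),
                      sex = c("auto", "male", "female")) {
  sex <- match.arg(sex)
  if (sex == "auto") sex <- if (is.finite(f)) "male" else "female"
  f_eff <- if (length(f) == 1 && is.finite(f)) f else config$f0
  stopifnot(all(c("chrom", "start", "end", "ratio", "sigma") %in% names(normalized)))
  sample_id <- if ("sample_id" %in% names(normalized)) normalized$sample_id[1] else NA_character_

  baseline_for <- function(chrom) {
    if (is_chrX(chrom)) {
      if (sex == "male") 1 - f_eff / 2 else 1
    } else if (is_chrY(chrom)) {
      config$chrY_background + if (sex == "male") f_eff / 2 else 0
    } else {
      1
    }
  }

  per_chrom <- lapply(unique(normalized$chrom), function(chrom) {
    dat <- normalized[normalized$chrom == chrom, ]
    segs <- binary_segment(dat$ratio, dat$sigma, config)
    base <- baseline_for(chrom)
    segs$dev <- segs$mean_ratio - base
    segs$theta <- vapply(seq_len(nrow(segs)), function(i) {
      dynamic_threshold(f, config = config, se = segs$se[i])
    }, numeric(1))
    hits <- segs[abs(segs$dev) >= segs$theta, ]
    if (nrow(hits) == 0) return(NULL)
    hits$direction <- ifelse(hits$dev > 0, "gain", "loss")
    hits <- merge_adjacent_calls(hits, config$min_seg_bins)
    tibble::tibble(
      sample_id = sample_id,
      chrom = chrom,
      start = dat$start[hits$start_bin],
      end = dat$end[hits$end_bin],
      direction = hits$direction,
      mean_ratio = hits$mean_ratio,
      z = (hits$mean_ratio - base) / hits$se,
      n_bins = hits$n_bins
    )
  })
  calls <- dplyr::bind_rows(per_chrom)
  if (nrow(calls) == 0) {
    return(tibble::tibble(
      sample_id = character(), chrom = character(), start = numeric(),
      end = numeric(), start_kb = numeric(), end_kb = numeric(),
      direction = character(), size_mb = numeric(), mean_ratio = numeric(),
      z = numeric(), n_bins = integer()
    ))
  }
  calls |>
    dplyr::mutate(
      start_kb = .data$start / 1000,
      end_kb = .data$end / 1000,
      size_mb = (.data$end - .data$start) / 1e6
    ) |>
    dplyr::filter(.data$size_mb >= config$min_report_mb) |>
    dplyr::select("sample_id", "chrom", "start", "end", "start_kb", "end_kb",
                  "direction", "size_mb", "mean_ratio", "z", "n_bins")
}

# Merge same-direction candidate calls separated by fewer than min_seg_bins
# bins; the merged mean/se pool the members (gap bins are not included).
merge_adjacent_calls <- function(hits, min_seg_bins) {
  hits <- hits[order(hits$start_bin), ]
  out <- hits[0, ]
  cur <- hits[1, ]
  flush <- function(out, cur) dplyr::bind_rows(out, cur)
  for (i in seq_len(nrow(hits))[-1]) {
    nxt <- hits[i, ]
    if (nxt$direction == cur$direction &&
        (nxt$start_bin - cur$end_bin - 1) < min_seg_bins) {
      w <- c(cur$n_bins, nxt$n_bins)
      cur$mean_ratio <- sum(w * c(cur$mean_ratio, nxt$mean_ratio)) / sum(w)
      cur$se <- sqrt((cur$n_bins^2 * cur$se^2 + nxt$n_bins^2 * nxt$se^2)) / sum(w)
      cur$end_bin <- nxt$end_bin
      cur$n_bins <- cur$n_bins + nxt$n_bins
    } else {
      out <- flush(out, cur)
      cur <- nxt
    }
  }
  flush(out, cur)
}

#' Write calls in the kb-interval reporting convention
#'
#' @param calls Calls tibble from [call_cnvs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  readr::write_tsv(
    calls[c("sample_id", "chrom", "start_kb", "end_kb", "direction",
            "size_mb", "mean_ratio", "z")],
    path
  )
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), chrom = readr::col_character(),
    start_kb = readr::col_double(), end_kb = readr::col_double(),
    direction = readr::col_character(), size_mb = readr::col_double(),
    mean_ratio = readr::col_double(), z = readr::col_double()
  ))
}
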