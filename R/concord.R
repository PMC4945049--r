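#' Overlap length of two intervals in kb
#'
#' Closed-interval kb arithmetic used throughout the concordance evaluation:
#' `max(0, min(ends) - max(starts))`. Both intervals must lie on the same
#' chromosome.
#'
#' @param a,b Length-2 numeric vectors `c(start_kb, end_kb)` or one-row data
#'   frames with `start_kb`/`end_kb` (and optionally `chrom`).
#' @return Overlap length in kb (0 for disjoint intervals).
#' @export
#' @examples
#' overlap_kb(c(69461, 78014), c(59800, 75091))  # 5630 kb
overlap_kb <- function(a, b) {
  as_int <- function(x) {
    if (is.data.frame(x)) {
      list(start = x$start_kb[1], end = x$end_kb[1],
           chrom = if ("chrom" %in% names(x)) x$chrom[1] else NA_character_)
    } else {
      list(start = x[1], end = x[2], chrom = NA_character_)
    }
  }
  ia <- as_int(a); ib <- as_int(b)
  if (!is.na(ia$chrom) && !is.na(ib$chrom) && ia$chrom != ib$chrom) {
    stop("intervals are on different chromosomes", call. = FALSE)
  }
  max(0, min(ia$end, ib$end) - max(ia$start, ib$start))
}

#' Classify truth events against CNV calls
#'
#' For each confirmed (truth) event, candidate calls are those in the same
#' sample on the same chromosome with the same direction; the best candidate
#' maximises the kb overlap. The event is classified
#'
#' * `consistent` — the call is fully contained in the truth interval, or
#'   the overlap reaches 50% of either interval's length;
#' * `partly_consistent` — a candidate exists but overlaps less than 50% of
#'   both intervals (including zero overlap on the right chromosome);
#' * `inconsistent` — no candidate call exists (a missed event).
#'
#' Each call is matched to at most one truth event, assigned greedily by
#' decreasing overlap with ties going to the larger truth interval.
#'
#' @param calls Calls tibble (needs `sample_id`, `chrom`, `start_kb`,
#'   `end_kb`, `direction`).
#' @param truths Truth-event tibble (same columns; e.g. from
#'   [parse_truth_manifest()]).
#' @return Concordance tibble, one row per truth event: the truth columns
#'   plus `call_start_kb`, `call_end_kb`, `call_size_mb`, `overlap_kb`,
#'   `frac_truth`, `frac_call`, `class`.
#' @export
classify_concordance <- function(calls, truths) {
  calls <- tibble::as_tibble(calls)
  truths <- tibble::as_tibble(truths)
  need <- c("sample_id", "chrom", "start_kb", "end_kb", "direction")
  stopifnot(all(need %in% names(calls)), all(need %in% names(truths)))
  if (nrow(truths) == 0) {
    return(tibble::tibble(
      sample_id = character(), chrom = character(), start_kb = numeric(),
      end_kb = numeric(), direction = character(), size_mb = numeric(),
      call_start_kb = numeric(), call_end_kb = numeric(),
      call_size_mb = numeric(), overlap_kb = numeric(),
      frac_truth = numeric(), frac_call = numeric(), class = character()
    ))
  }
  truths$.truth_id <- seq_len(nrow(truths))
  if (!"size_mb" %in% names(truths)) {
    truths$size_mb <- (truths$end_kb - truths$start_kb) / 1000
  }
  calls$.call_id <- seq_len(max(nrow(calls), 1))[seq_len(nrow(calls))]

  pairs <- dplyr::inner_join(
    truths, calls,
    by = c("sample_id", "chrom", "direction"),
    suffix = c("", ".call"), relationship = "many-to-many"
  )
  if (nrow(pairs) > 0) {
    pairs$overlap <- pmax(0, pmin(pairs$end_kb, pairs$end_kb.call) -
                            pmax(pairs$start_kb, pairs$start_kb.call))
    pairs$truth_len <- pairs$end_kb - pairs$start_kb
    pairs$call_len <- pairs$end_kb.call - pairs$start_kb.call
    # greedy one-to-one matching: best overlap first, ties to larger truth
    pairs <- pairs[order(-pairs$overlap, -pairs$truth_len), ]
    used_call <- logical(nrow(calls))
    used_truth <- logical(nrow(truths))
    keep <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      ti <- pairs$.truth_id[i]; ci <- pairs$.call_id[i]
      if (!used_call[ci] && !used_truth[ti]) {
        keep[i] <- TRUE
        used_call[ci] <- TRUE
        used_truth[ti] <- TRUE
      }
    }
    matched <- pairs[keep, ]
  } else {
    matched <- pairs
  }

  rows <- lapply(seq_len(nrow(truths)), function(i) {
    tr <- truths[i, ]
    m <- matched[matched$.truth_id == tr$.truth_id, ]
    if (nrow(m) == 0) {
      return(dplyr::mutate(
        tr[setdiff(names(tr), ".truth_id")],
        call_start_kb = NA_real_, call_end_kb = NA_real_,
        call_size_mb = NA_real_, overlap_kb = NA_real_,
        frac_truth = NA_real_, frac_call = NA_real_,
        class = "inconsistent"
      ))
    }
    covered <- m$start_kb.call >= m$start_kb & m$end_kb.call <= m$end_kb
    frac_truth <- m$overlap / m$truth_len
    frac_call <- m$overlap / m$call_len
    cls <- if (covered || max(frac_truth, frac_call) >= 0.5) {
      "consistent"
    } else {
      "partly_consistent"
    }
    dplyr::mutate(
      tr[setdiff(names(tr), ".truth_id")],
      call_start_kb = m$start_kb.call, call_end_kb = m$end_kb.call,
      call_size_mb = m$call_len / 1000, overlap_kb = m$overlap,
      frac_truth = frac_truth, frac_call = frac_call, class = cls
    )
  })
  dplyr::bind_rows(rows)
}

# Clopper-Pearson exact binomial interval, as percentages.
clopper_pearson <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  alpha <- 1 - conf
  lo <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  100 * c(lo, hi)
}

#' Stratified screening performance
#'
#' Computes the screening operating characteristics of the caller against
#' confirmed results, stratified by event size. True positives are truth
#' events classified `consistent` or `partly_consistent`; false negatives
#' are `inconsistent` events. Sensitivity is per event,
#' `TP / (TP + FN)`. False positives are calls in confirmed-euploid samples,
#' stratified by call size; specificity is `TN / (TN + FP)` where `TN` is
#' the number of euploid samples with no call at all (a sample-level
#' negative) — the hybrid event/sample accounting used in screening
#' evaluations of this design. PPV is `TP / (TP + FP)`. Confidence
#' intervals are Clopper-Pearson exact binomial. Empty strata yield `NA`
#' rates rather than 0.
#'
#' @param records Concordance tibble from [classify_concordance()].
#' @param euploid_calls Calls tibble restricted to confirmed-euploid samples
#'   (zero rows if none); needs `sample_id` and `size_mb`.
#' @param euploid_samples Character vector of all confirmed-euploid sample
#'   IDs (including those with no calls).
#' @param size_cut_mb Stratification cut on event/call size (default 10).
#' @param conf Confidence level of the intervals.
#' @return Tibble with one row per stratum (`>cut`, `<=cut`, `total`):
#'   counts (`consistent`, `partly_consistent`, `inconsistent`, `tp`, `fn`,
#'   `fp_calls`, `tn_samples`), `sensitivity`, `sens_lo`, `sens_hi`,
#'   `specificity`, `spec_lo`, `spec_hi`, `ppv` (all in percent).
#' @export
performance_summary <- function(records, euploid_calls, euploid_samples,
                                size_cut_mb = 10, conf = 0.95) {
  records <- tibble::as_tibble(records)
  euploid_calls <- tibble::as_tibble(euploid_calls)
  if (nrow(euploid_calls) > 0) {
    if (!all(euploid_calls$sample_id %in% euploid_samples)) {
      stop("euploid_calls contains samples not listed in euploid_samples",
           call. = FALSE)
    }
  }
  n_euploid <- length(unique(euploid_samples))
  fp_ids <- unique(euploid_calls$sample_id)
  tn <- n_euploid - length(fp_ids)

  strata <- list(
    list(name = sprintf(">%gMb", size_cut_mb),
         ev = function(s) s > size_cut_mb, cl = function(s) s > size_cut_mb),
    list(name = sprintf("<%gMb", size_cut_mb),
         ev = function(s) s <= size_cut_mb, cl = function(s) s <= size_cut_mb),
    list(name = "total",
         ev = function(s) rep(TRUE, length(s)), cl = function(s) rep(TRUE, length(s)))
  )

  rows <- lapply(strata, function(st) {
    ev <- records[st$ev(records$size_mb), ]
    n_cons <- sum(ev$class == "consistent")
    n_part <- sum(ev$class == "partly_consistent")
    n_inc <- sum(ev$class == "inconsistent")
    tp <- n_cons + n_part
    fn <- n_inc
    fp <- if (nrow(euploid_calls) > 0) sum(st$cl(euploid_calls$size_mb)) else 0L

    sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    sens_ci <- clopper_pearson(tp, tp + fn, conf)
    spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
    spec_ci <- clopper_pearson(tn, tn + fp, conf)
    ppv <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_

    tibble::tibble(
      stratum = st$name,
      consistent = n_cons, partly_consistent = n_part, inconsistent = n_inc,
      tp = tp, fn = fn, fp_calls = fp, tn_samples = tn,
      sensitivity = sens, sens_lo = sens_ci[1], sens_hi = sens_ci[2],
      specificity = spec, spec_lo = spec_ci[1], spec_hi = spec_ci[2],
      ppv = ppv
    )
  })
  dplyr::bind_rows(rows)
}

#' Render a performance summary as a markdown table
#'
#' @param perf Tibble from [performance_summary()].
#' @param path Optional file to write the report to.
#' @return The markdown string, invisibly when written to file.
#' @export
report_performance <- function(perf, path = NULL) {
  fmt_rate <- function(r, lo, hi) {
    ifelse(is.na(r), "NA",
           sprintf("%.2f%% (%.2f%%-%.2f%%)", r, lo, hi))
  }
  lines <- c(
    "| Size of CNV | Consistent | Partly consistent | Inconsistent | FP calls | Sensitivity (95% CI) | Specificity (95% CI) | PPV |",
    "|---|---|---|---|---|---|---|---|",
    vapply(seq_len(nrow(perf)), function(i) {
      p <- perf[i, ]
      sprintf("| %s | %d | %d | %d | %d | %s | %s | %s |",
              p$stratum, p$consistent, p$partly_consistent, p$inconsistent,
              p$fp_calls,
              fmt_rate(p$sensitivity, p$sens_lo, p$sens_hi),
              fmt_rate(p$specificity, p$spec_lo, p$spec_hi),
              ifelse(is.na(p$ppv), "NA", sprintf("%.2f%%", p$ppv)))
    }, character(1))
  )
  out <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
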