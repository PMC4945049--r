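# Independent brute-force oracle for the segmentation split statistic:
# enumerates every admissible interval and computes the pooled-SD t from its
# definition, with no prefix-sum shortcuts.
brute_force_first_split <- function(x, min_bins) {
  n <- length(x)
  if (n < 2 * min_bins) return(NULL)
  sd_seg <- sd(x)
  best <- NULL
  for (a in 1:n) {
    for (b in a:n) {
      len <- b - a + 1
      left <- a - 1
      right <- n - b
      if (len < min_bins || (n - len) < min_bins) next
      if (left != 0 && left < min_bins) next
      if (right < min_bins) next  # suffix windows: use the prefix complement
      inside <- x[a:b]
      outside <- x[-(a:b)]
      t <- (mean(inside) - mean(outside)) /
        (sd_seg * sqrt(1 / len + 1 / (n - len)))
      if (is.null(best) || abs(t) > abs(best$t)) {
        best <- list(t = t, a = a, b = b)
      }
    }
  }
  best
}
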