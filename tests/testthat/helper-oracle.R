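# Deliberately naive reference implementations, kept independent of the
# package internals so they can serve as oracles.

# Exhaustive candidate scan: walks the series run by run, emits every strict
# local extremum (plateau midpoint), drops candidates whose symmetry window
# would truncate, and checks +/-`vw`-sample dominance by direct window scan.
oracle_candidates <- function(x, vw = 150L, sw = 240L) {
  n <- length(x)
  idx <- integer(0); kind <- character(0); verified <- logical(0)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    if (i > 1L && j < n) {
      k <- if (x[i - 1L] < x[i] && x[j + 1L] < x[i]) "peak"
           else if (x[i - 1L] > x[i] && x[j + 1L] > x[i]) "trough"
           else NA_character_
      if (!is.na(k)) {
        m <- (i + j) %/% 2L
        if (m > sw && m <= n - sw) {
          w <- x[max(1L, m - vw):min(n, m + vw)]
          v <- if (k == "peak") !any(w > x[m]) else !any(w < x[m])
          idx <- c(idx, m); kind <- c(kind, k); verified <- c(verified, v)
        }
      }
    }
    i <- j + 1L
  }
  data.frame(index = idx, kind = kind, verified = verified)
}

# Realized inverted-beat fraction of one channel of a recording.
truth_fraction <- function(rec, channel = "ir") {
  gt <- rec$ground_truth[rec$ground_truth$channel == channel, ]
  mean(gt$inverted)
}

# Fraction of symmetry-passing candidates whose +1/-1 label matches the
# ground-truth polarity of the beat they fall in.
pulse_label_accuracy <- function(rec, fit, channel = "ir") {
  gt <- rec$ground_truth[rec$ground_truth$channel == channel, ]
  cand <- fit$candidates[fit$candidates$symmetry_pass, ]
  if (nrow(cand) == 0L) return(NA_real_)
  beat <- findInterval(cand$index, gt$onset_sample)
  ok <- beat >= 1L & beat <= nrow(gt)
  mean((cand$label[ok] == -1) == gt$inverted[beat[ok]])
}
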