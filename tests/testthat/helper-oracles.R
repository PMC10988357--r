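# Independent brute-force oracles used across the test files.

# auROC by exhaustive pair enumeration.
auroc_oracle <- function(x, y) {
  s <- 0
  for (xi in x) for (yi in y) {
    s <- s + (xi > yi) + 0.5 * (xi == yi)
  }
  s / (length(x) * length(y))
}

# Two-sided Fisher exact p by hypergeometric enumeration with fixed margins.
fisher_oracle <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(a_range, r1, n - r1, c1)
  p_obs <- stats::dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Jensen-Shannon distance by direct summation.
jsd_oracle <- function(p, q) {
  m <- (p + q) / 2
  term <- function(a) {
    i <- a > 0
    sum(a[i] * log(a[i] / m[i]))
  }
  sqrt(0.5 * term(p) + 0.5 * term(q))
}

# Mean silhouette score of a labeled 2-D point set.
silhouette_oracle <- function(coords, labels) {
  d <- as.matrix(stats::dist(coords))
  sil <- vapply(seq_len(nrow(coords)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(coords)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

# Small USV table helper for audio fixtures.
usv_row <- function(onset, offset, fmin, fmax, bout = 1L, first = TRUE) {
  data.frame(onset_s = onset, offset_s = offset, fmin_khz = fmin,
             fmax_khz = fmax, bout_id = bout, is_first = first,
             call_class = ifelse(fmax - fmin < 15, "flat", "FM"))
}
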