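#' Two-sided Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Computes the Mann-Whitney statistic U = #\{x > y\} + 0.5 #\{x = y\}. When
#' both samples have at most 8 observations the two-sided p-value is obtained
#' by exhaustive enumeration of all rank splits of the pooled sample (so ties
#' are handled exactly); otherwise a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param x,y Numeric samples (each length >= 1).
#' @return List with `statistic` (U), `p.value`, and `method`
#'   (`"exact"` or `"normal"`).
#' @examples
#' rank_sum_test(c(0, 0, 0, 0, 0), c(8, 10, 12, 9, 11))$p.value  # 2/252
#' @export
rank_sum_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1 || n2 < 1) stop("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= 8 && n2 <= 8) {
    splits <- utils::combn(n1 + n2, n1)
    u_all <- colSums(matrix(r[splits], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
    return(list(statistic = u_obs, p.value = p, method = "exact"))
  }
  n <- n1 + n2
  ties <- table(pooled)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(statistic = u_obs, p.value = 1,
                               method = "normal"))
  z <- (abs(u_obs - mu) - 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-max(z, 0)))
  list(statistic = u_obs, p.value = p, method = "normal")
}

# Spike count of a sorted spike train in (onset + a, onset + b], vectorized
# over onsets.
window_counts <- function(spikes, onsets, a, b) {
  findInterval(onsets + b, spikes) - findInterval(onsets + a, spikes)
}

#' Per-trial baseline firing rates
#'
#' The baseline sample of a unit: firing rate in the window 1.0 to 0.5 s
#' before each first-call onset.
#'
#' @param spikes Sorted spike times (s).
#' @param first_onsets First-call onset times (s).
#' @return Numeric vector of rates (spikes/s), one per first call.
#' @export
baseline_rates <- function(spikes, first_onsets) {
  if (length(first_onsets) < 1) stop("need at least one first call")
  window_counts(spikes, first_onsets, -1.0, -0.5) / 0.5
}

#' Peri-event spike-count matrix
#'
#' Bins spikes around each event onset into 50 ms bins spanning -1 to +1 s
#' (40 bins), and smooths the per-trial rate rows with a centered 5-bin
#' moving average (window truncated and renormalized at the edges).
#'
#' @param spikes Sorted spike times (s).
#' @param onsets Event onset times (s).
#' @param window Peri-event window (s), default `c(-1, 1)`.
#' @param bin_width Bin width (s), default 0.05.
#' @param smooth_bins Moving-average window in bins (odd), default 5.
#' @return List of class `peri_event_matrix`: `counts`, `rates`, `smoothed`
#'   (trials x bins matrices), `bin_left`/`bin_right` (bin edges relative to
#'   onset), `bin_width`.
#' @export
peri_event_matrix <- function(spikes, onsets, window = c(-1, 1),
                              bin_width = 0.05, smooth_bins = 5) {
  breaks <- seq(window[1], window[2], by = bin_width)
  n_bins <- length(breaks) - 1L
  n_trials <- length(onsets)
  counts <- matrix(0L, n_trials, n_bins)
  if (n_trials > 0) {
    edges <- outer(onsets, breaks, `+`)
    idx <- matrix(findInterval(edges, spikes), n_trials)
    counts <- idx[, -1, drop = FALSE] - idx[, -ncol(idx), drop = FALSE]
  }
  rates <- counts / bin_width
  structure(list(counts = counts, rates = rates,
                 smoothed = moving_average_rows(rates, smooth_bins),
                 bin_left = breaks[-length(breaks)], bin_right = breaks[-1],
                 bin_width = bin_width),
            class = "peri_event_matrix")
}

# Centered moving average along rows with a shrinking window at the edges.
moving_average_rows <- function(m, w = 5) {
  if (ncol(m) == 0 || nrow(m) == 0) return(m)
  half <- (w - 1) %/% 2
  out <- m
  for (j in seq_len(ncol(m))) {
    cols <- max(1, j - half):min(ncol(m), j + half)
    out[, j] <- rowMeans(m[, cols, drop = FALSE])
  }
  out
}

#' Peri-call responsiveness test
#'
#' Compares baseline firing rates against per-trial rates in four peri-call
#' windows — 0.5 s before and 0.25 s after first-call onsets, and 0.25 s
#' before and after subsequent-call onsets — using two-sided rank-sum tests
#' with Bonferroni correction (p-values multiplied by 4, capped at 1). A unit
#' is responsive when any adjusted p-value is below `alpha`.
#'
#' For each comparison the baseline sample is built from the baseline period
#' (1.0 to 0.5 s before each first call) tiled into sub-windows of the same
#' duration as the comparison window (one 0.5 s window, or two 0.25 s
#' windows, per trial). Matching the window duration keeps the discrete
#' count-to-rate support of the two samples identical, so the rank-sum test
#' holds its nominal level at low firing rates; comparing a 0.5 s baseline
#' rate directly against 0.25 s window rates is markedly anticonservative.
#'
#' @param spikes Sorted spike times (s).
#' @param first_onsets,subsequent_onsets Onset times (s) of first and
#'   subsequent calls (each needs >= 2 trials; otherwise the unit is
#'   untestable and `responsive` is `NA`).
#' @param alpha Family-wise significance level (default 0.05).
#' @return List with `responsive`, `p_raw` and `p_adj` (length-4, windows in
#'   the order first-pre, first-post, subsequent-pre, subsequent-post), and
#'   `baseline` (the baseline rate sample).
#' @export
responsiveness_test <- function(spikes, first_onsets, subsequent_onsets,
                                alpha = 0.05) {
  wins <- list(first_pre = c(-0.5, 0), first_post = c(0, 0.25),
               subsequent_pre = c(-0.25, 0), subsequent_post = c(0, 0.25))
  ons <- list(first_onsets, first_onsets,
              subsequent_onsets, subsequent_onsets)
  if (length(first_onsets) < 2 || length(subsequent_onsets) < 2)
    return(list(responsive = NA, p_raw = rep(NA_real_, 4),
                p_adj = rep(NA_real_, 4), baseline = NULL))
  base <- baseline_rates(spikes, first_onsets)
  # baseline sample at the duration of the comparison window: one 0.5 s or
  # two 0.25 s sub-windows per trial tiling (-1.0, -0.5]
  base_sample <- function(len) {
    starts <- seq(-1, -0.5 - len, by = len)
    unlist(lapply(starts, function(a)
      window_counts(spikes, first_onsets, a, a + len) / len))
  }
  p_raw <- vapply(seq_along(wins), function(i) {
    w <- wins[[i]]
    rates <- window_counts(spikes, ons[[i]], w[1], w[2]) / (w[2] - w[1])
    rank_sum_test(base_sample(w[2] - w[1]), rates)$p.value
  }, numeric(1))
  names(p_raw) <- names(wins)
  p_adj <- pmin(p_raw * 4, 1)
  list(responsive = any(p_adj < alpha), p_raw = p_raw, p_adj = p_adj,
       baseline = base)
}

#' Area under the ROC curve of two rate samples
#'
#' auROC between a bin's across-trial rate distribution and the baseline
#' distribution, via the Mann-Whitney identity
#' auROC = P(bin > baseline) + 0.5 P(bin = baseline) over all pairs.
#' 0.5 means no modulation, values above 0.5 excitation, below inhibition.
#'
#' @param x Bin rates across trials.
#' @param baseline Baseline rates across trials (non-empty).
#' @return auROC in \[0, 1\].
#' @export
auroc <- function(x, baseline) {
  if (length(baseline) == 0) stop("empty baseline sample")
  if (length(x) == 0) stop("empty bin sample")
  n1 <- length(x); n2 <- length(baseline)
  r <- rank(c(x, baseline))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' auROC time course of a peri-event matrix
#'
#' Applies [auroc()] per 50 ms bin, comparing the smoothed per-trial rates in
#' that bin with the baseline rate sample.
#'
#' @param peri A [peri_event_matrix()].
#' @param baseline Baseline rate sample from [baseline_rates()].
#' @return Numeric vector of auROC values, one per bin.
#' @export
auroc_timecourse <- function(peri, baseline) {
  stopifnot(inherits(peri, "peri_event_matrix"))
  if (length(baseline) == 0) stop("empty baseline sample")
  apply(peri$smoothed, 2, auroc, baseline = baseline)
}

#' 25-dimensional response-pattern vector
#'
#' Concatenates the auROC values of the 15 bins covering -0.5 to +0.25 s
#' around first-call onsets with the 10 bins covering -0.25 to +0.25 s around
#' subsequent-call onsets, both on the standard 50 ms grid over -1 to +1 s.
#'
#' @param auroc_first,auroc_subsequent Length-40 auROC time courses.
#' @return Named numeric vector of length 25.
#' @export
response_vector <- function(auroc_first, auroc_subsequent) {
  if (length(auroc_first) != 40 || length(auroc_subsequent) != 40)
    stop("auROC time courses must be on the 40-bin grid over -1 to +1 s")
  v <- c(auroc_first[11:25], auroc_subsequent[16:25])
  names(v) <- c(sprintf("first_%+.2f", seq(-0.5, 0.2, by = 0.05)),
                sprintf("subs_%+.2f", seq(-0.25, 0.2, by = 0.05)))
  v
}

#' Call-type discrimination test
#'
#' Two-sided rank-sum test comparing per-trial firing rates in the window
#' -0.25 to +0.25 s around flat versus FM first-call onsets; a unit
#' discriminates call types when p < `alpha`.
#'
#' @param spikes Sorted spike times (s).
#' @param flat_first_onsets,fm_first_onsets First-call onsets (s) by call
#'   class (>= 2 trials each; otherwise untestable, `discriminating = NA`).
#' @param alpha Significance level (default 0.05).
#' @return List with `p.value` and `discriminating`.
#' @export
call_discrimination_test <- function(spikes, flat_first_onsets,
                                     fm_first_onsets, alpha = 0.05) {
  if (length(flat_first_onsets) < 2 || length(fm_first_onsets) < 2)
    return(list(p.value = NA_real_, discriminating = NA))
  r_flat <- window_counts(spikes, flat_first_onsets, -0.25, 0.25) / 0.5
  r_fm <- window_counts(spikes, fm_first_onsets, -0.25, 0.25) / 0.5
  p <- rank_sum_test(r_flat, r_fm)$p.value
  list(p.value = p, discriminating = p < alpha)
}

#' Full peri-call response profile of one unit
#'
#' Runs the responsiveness test, builds smoothed peri-event matrices for
#' first and subsequent calls, computes both auROC time courses and the
#' 25-dimensional response vector, and records the mean baseline rate.
#'
#' @param spikes Sorted spike times (s).
#' @param usv Syllable table with `onset_s` and `is_first` (e.g. from
#'   [gen_usv_stream()] or [segment_audio()]).
#' @param alpha Significance level for the responsiveness test.
#' @return List of class `response_profile`: `responsive`, `p_adj`,
#'   `auroc_first`, `auroc_subsequent`, `vector25`, `baseline_rate`,
#'   `n_first`, `n_subsequent`.
#' @export
unit_response_profile <- function(spikes, usv, alpha = 0.05) {
  first_onsets <- usv$onset_s[usv$is_first]
  subsequent_onsets <- usv$onset_s[!usv$is_first]
  rt <- responsiveness_test(spikes, first_onsets, subsequent_onsets,
                            alpha = alpha)
  if (is.na(rt$responsive))
    return(structure(list(responsive = NA, p_adj = rt$p_adj,
                          auroc_first = NULL, auroc_subsequent = NULL,
                          vector25 = NULL, baseline_rate = NA_real_,
                          n_first = length(first_onsets),
                          n_subsequent = length(subsequent_onsets)),
                     class = "response_profile"))
  base <- rt$baseline
  af <- auroc_timecourse(peri_event_matrix(spikes, first_onsets), base)
  as <- auroc_timecourse(peri_event_matrix(spikes, subsequent_onsets), base)
  structure(list(responsive = rt$responsive, p_adj = rt$p_adj,
                 auroc_first = af, auroc_subsequent = as,
                 vector25 = response_vector(af, as),
                 baseline_rate = mean(base),
                 n_first = length(first_onsets),
                 n_subsequent = length(subsequent_onsets)),
            class = "response_profile")
}
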