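#' First-spike latency histograms for the SALT test
#'
#' For every light pulse, the baseline period (-150 to 0 ms before pulse
#' onset by default) is tiled into 10 ms epochs; a 16th epoch covers the
#' 10 ms test window after the pulse. In each epoch the latency of the first
#' spike (in 1 ms bins), or the absence of any spike, is recorded and
#' accumulated over pulses.
#'
#' @param spikes Sorted spike times (s).
#' @param pulse_onsets Light-pulse onset times (s); consecutive pulses must
#'   be at least `baseline_span_ms + epoch_ms` apart.
#' @param epoch_ms Epoch (and test-window) length in ms.
#' @param baseline_span_ms Length of the tiled baseline period in ms.
#' @param bin_ms Latency bin width in ms.
#' @return List of class `latency_histograms`: `baseline` (epochs x bins+1
#'   count matrix, last column = no-spike), `test` (1 x bins+1), `n_pulses`,
#'   `bin_ms`, `epoch_ms`.
#' @export
latency_histograms <- function(spikes, pulse_onsets, epoch_ms = 10,
                               baseline_span_ms = 150, bin_ms = 1) {
  if (length(pulse_onsets) < 10) stop("need at least 10 pulses")
  min_sep <- (baseline_span_ms + epoch_ms) / 1000
  if (any(diff(sort(pulse_onsets)) < min_sep - 1e-9))
    stop("pulses closer than the baseline span + test window overlap")
  n_epochs <- baseline_span_ms / epoch_ms
  n_bins <- epoch_ms / bin_ms
  epoch_starts_ms <- c(seq(-baseline_span_ms, -epoch_ms, by = epoch_ms), 0)
  counts <- matrix(0L, length(epoch_starts_ms), n_bins + 1)
  for (e in seq_along(epoch_starts_ms)) {
    a <- pulse_onsets + epoch_starts_ms[e] / 1000
    idx <- findInterval(a, spikes) + 1L
    lat_ms <- ifelse(idx <= length(spikes), (spikes[idx] - a) * 1000, Inf)
    hit <- lat_ms < epoch_ms
    bins <- floor(lat_ms[hit] / bin_ms + 1e-9) + 1L
    tb <- tabulate(bins, nbins = n_bins)
    counts[e, seq_len(n_bins)] <- tb
    counts[e, n_bins + 1] <- sum(!hit)
  }
  structure(list(baseline = counts[seq_len(n_epochs), , drop = FALSE],
                 test = counts[n_epochs + 1, , drop = TRUE],
                 n_pulses = length(pulse_onsets),
                 bin_ms = bin_ms, epoch_ms = epoch_ms),
            class = "latency_histograms")
}

#' Jensen-Shannon distance between two probability vectors
#'
#' The square root of the Jensen-Shannon divergence
#' JSD(p, q) = KL(p || m)/2 + KL(q || m)/2 with m = (p + q)/2, in nats.
#' Zero-probability bins follow the convention 0 log(0/x) = 0, so the
#' distance is always finite and bounded by sqrt(log 2).
#'
#' @param p,q Probability vectors of equal length summing to 1.
#' @return Non-negative distance (a metric on probability vectors).
#' @export
js_distance <- function(p, q) {
  if (length(p) != length(q)) stop("p and q must have equal length")
  if (any(p < 0) || any(q < 0) ||
      abs(sum(p) - 1) > 1e-8 || abs(sum(q) - 1) > 1e-8)
    stop("p and q must be normalized probability vectors")
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  sqrt(0.5 * kl(p, m) + 0.5 * kl(q, m))
}

#' Stimulus-associated spike latency test (SALT)
#'
#' Tests whether light pulses change the first-spike latency distribution.
#' All pairwise Jensen-Shannon distances among the baseline-epoch histograms
#' form the null distance set; the test statistic is the median distance
#' from the test-window histogram to the baseline histograms. The p-value is
#' the null-rank of the statistic with a +1/(n+1) correction, and the
#' associated information difference is the excess of the statistic over the
#' median null distance.
#'
#' @param hists A [latency_histograms()] object.
#' @return List with `salt_p` and `salt_info`.
#' @export
salt <- function(hists) {
  stopifnot(inherits(hists, "latency_histograms"))
  B <- hists$baseline
  tot <- rowSums(B)
  if (sum(tot > 0) < 2) stop("need at least 2 baseline epochs with events")
  P <- B / rowSums(B)
  nb <- nrow(P)
  null_d <- numeric(0)
  for (i in seq_len(nb - 1)) {
    for (j in (i + 1):nb) null_d <- c(null_d, js_distance(P[i, ], P[j, ]))
  }
  q <- hists$test / sum(hists$test)
  test_d <- vapply(seq_len(nb), function(i) js_distance(q, P[i, ]),
                   numeric(1))
  m_star <- stats::median(test_d)
  p <- (sum(null_d >= m_star - 1e-12) + 1) / (length(null_d) + 1)
  list(salt_p = p, salt_info = m_star - stats::median(null_d))
}

#' Waveform similarity between light-evoked and spontaneous spikes
#'
#' Pearson correlation between the mean evoked and mean spontaneous
#' waveforms, computed over the samples of all four tetrode channels
#' concatenated.
#'
#' @param evoked,spontaneous Channels x samples waveform matrices of equal
#'   shape.
#' @return Pearson r.
#' @export
waveform_similarity <- function(evoked, spontaneous) {
  if (!all(dim(evoked) == dim(spontaneous)))
    stop("waveforms must have identical shape")
  ev <- as.vector(evoked); sp <- as.vector(spontaneous)
  if (stats::sd(ev) == 0 || stats::sd(sp) == 0)
    stop("zero-variance waveform")
  stats::cor(ev, sp)
}

#' Classify a unit as light-responsive
#'
#' A unit is light-responsive when all three criteria hold: the firing rate
#' in the 10 ms test window exceeds the pre-pulse baseline rate
#' (`rate_ratio > 1`), the SALT p-value is below `alpha`, and the Pearson
#' correlation between evoked and spontaneous waveforms exceeds `r_min`.
#'
#' @param session List with `spikes`, `pulse_times`, `wf_evoked`,
#'   `wf_spontaneous` (e.g. from [gen_tagging_session()]).
#' @param alpha SALT significance threshold (default 0.01).
#' @param r_min Waveform-correlation threshold (default 0.9).
#' @param epoch_ms,baseline_span_ms,bin_ms Passed to [latency_histograms()].
#' @return List of class `tag_result`: `salt_p`, `salt_info`, `waveform_r`,
#'   `rate_ratio`, `light_responsive`.
#' @export
classify_tag <- function(session, alpha = 0.01, r_min = 0.9, epoch_ms = 10,
                         baseline_span_ms = 150, bin_ms = 1) {
  if (is.null(session$wf_evoked) || is.null(session$wf_spontaneous))
    return(structure(list(salt_p = NA_real_, salt_info = NA_real_,
                          waveform_r = NA_real_, rate_ratio = NA_real_,
                          light_responsive = NA),
                     class = "tag_result"))
  spikes <- session$spikes
  pulses <- session$pulse_times
  hists <- latency_histograms(spikes, pulses, epoch_ms = epoch_ms,
                              baseline_span_ms = baseline_span_ms,
                              bin_ms = bin_ms)
  s <- salt(hists)
  r <- waveform_similarity(session$wf_evoked, session$wf_spontaneous)
  n_test <- sum(window_counts(spikes, pulses, 0, epoch_ms / 1000))
  n_base <- sum(window_counts(spikes, pulses, -baseline_span_ms / 1000, 0))
  rate_test <- n_test / (length(pulses) * epoch_ms / 1000)
  rate_base <- n_base / (length(pulses) * baseline_span_ms / 1000)
  ratio <- if (rate_base == 0) {
    if (rate_test > 0) Inf else NA_real_
  } else rate_test / rate_base
  structure(list(salt_p = s$salt_p, salt_info = s$salt_info,
                 waveform_r = r, rate_ratio = ratio,
                 light_responsive = isTRUE(ratio > 1 & s$salt_p < alpha &
                                             r > r_min)),
            class = "tag_result")
}
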