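#' Unit inclusion criteria
#'
#' A sorted unit is kept when it has at least `min_spikes` recorded spikes
#' and its inter-spike-interval distribution respects an absolute refractory
#' period: the fraction of intervals shorter than `refractory` must not
#' exceed `max_violation_fraction`.
#'
#' @param spike_times Sorted spike times (s).
#' @param min_spikes Minimum spike count (default 100).
#' @param refractory Refractory period in seconds (default 1 ms).
#' @param max_violation_fraction Tolerated fraction of refractory violations
#'   (default 0.5%; a criterion this strict excludes contaminated multi-unit
#'   clusters while tolerating rare coincidences).
#' @return List with `pass` (logical), `reasons` (character), `n_spikes`,
#'   and `violation_fraction`.
#' @export
qc_unit <- function(spike_times, min_spikes = 100, refractory = 0.001,
                    max_violation_fraction = 0.005) {
  if (is.unsorted(spike_times)) stop("`spike_times` must be sorted")
  n <- length(spike_times)
  viol <- if (n > 1) mean(diff(spike_times) < refractory) else 0
  reasons <- character(0)
  if (n < min_spikes) reasons <- c(reasons, "too_few_spikes")
  if (viol > max_violation_fraction)
    reasons <- c(reasons, "refractory_violations")
  list(pass = length(reasons) == 0, reasons = reasons,
       n_spikes = n, violation_fraction = viol)
}

#' Trough-to-peak spike width
#'
#' Measures the duration from the global trough to the subsequent peak of the
#' mean waveform, on the channel with the largest peak-to-trough amplitude.
#' Expects the standard negative-going extracellular spike; a waveform whose
#' dominant deflection is positive, or with no peak after the trough, is an
#' error.
#'
#' @param waveform Numeric matrix, channels x samples (µV), or a vector for a
#'   single channel.
#' @param sample_rate Waveform sampling rate in Hz.
#' @return Spike width in milliseconds.
#' @examples
#' wf <- spike_waveform_template()
#' spike_width(wf, 30e3)
#' @export
spike_width <- function(waveform, sample_rate) {
  if (is.vector(waveform)) waveform <- matrix(waveform, nrow = 1)
  amp <- apply(waveform, 1, function(v) max(v) - min(v))
  v <- waveform[which.max(amp), ]
  if (abs(max(v)) >= abs(min(v)))
    stop("dominant deflection is positive; expected a negative-going spike")
  trough <- which.min(v)
  if (trough == length(v)) stop("no peak after the trough (monotone tail)")
  tail_v <- v[(trough + 1):length(v)]
  peak <- trough + which.max(tail_v)
  if (all(diff(tail_v) <= 0)) stop("waveform is monotone after the trough")
  (peak - trough) / sample_rate * 1000
}

#' Classify units into narrow- and wide-spiking types
#'
#' k-means (k = 2, 10 restarts, fixed seed) on the 1-D spike widths; the
#' cluster with the smaller mean width is labeled `"narrow"` (putative
#' interneuron) and the other `"wide"` (putative pyramidal neuron).
#'
#' @param widths Spike widths in ms (length >= 2, not all identical).
#' @param seed Integer seed for the k-means restarts.
#' @return Character vector (`"narrow"`/`"wide"`), one entry per unit, with
#'   attribute `centers` (sorted cluster mean widths).
#' @export
classify_cell_type <- function(widths, seed = 0) {
  if (length(widths) < 2) stop("need at least 2 units")
  if (length(unique(widths)) < 2)
    stop("all widths identical; clustering is degenerate")
  set.seed(seed)
  km <- stats::kmeans(widths, centers = 2, nstart = 10)
  narrow_cluster <- which.min(km$centers)
  out <- ifelse(km$cluster == narrow_cluster, "narrow", "wide")
  attr(out, "centers") <- sort(as.numeric(km$centers))
  out
}
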