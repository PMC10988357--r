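#' Optogenetic tagging protocol parameters
#'
#' Describes one light-stimulation session: trains of brief light pulses with
#' long intertrain intervals, and the evoked-spike statistics of a tagged
#' unit. Defaults mirror the standard tagging protocol of 10 trains of 10
#' pulses (10 ms pulses at 5 Hz) with 10 s between trains.
#'
#' @param latency_mean Mean first-spike latency of evoked spikes (ms).
#' @param latency_jitter_sd SD of the evoked latency (ms).
#' @param reliability Probability that a pulse evokes a spike, in \[0, 1\].
#' @param n_trains,pulses_per_train Number of trains and pulses per train.
#' @param pulse_duration_ms Light-pulse duration (ms).
#' @param pulse_rate_hz Within-train pulse rate (Hz).
#' @param intertrain_interval_s Silent gap between trains (s).
#' @return An object of class `tagging_spec`.
#' @export
tagging_spec <- function(latency_mean = 3, latency_jitter_sd = 1,
                         reliability = 0.8, n_trains = 10,
                         pulses_per_train = 10, pulse_duration_ms = 10,
                         pulse_rate_hz = 5, intertrain_interval_s = 10) {
  if (reliability < 0 || reliability > 1)
    stop("`reliability` must be in [0, 1]")
  if (n_trains < 1 || pulses_per_train < 1 || pulse_rate_hz <= 0)
    stop("invalid train structure")
  structure(list(latency_mean = latency_mean,
                 latency_jitter_sd = latency_jitter_sd,
                 reliability = reliability, n_trains = n_trains,
                 pulses_per_train = pulses_per_train,
                 pulse_duration_ms = pulse_duration_ms,
                 pulse_rate_hz = pulse_rate_hz,
                 intertrain_interval_s = intertrain_interval_s),
            class = "tagging_spec")
}

#' Simulate a light-tagging session
#'
#' Background activity is homogeneous Poisson. For a tagged unit, each pulse
#' additionally evokes one spike with probability `reliability` at a latency
#' drawn from Normal(`latency_mean`, `latency_jitter_sd`) ms. Mean spike
#' waveforms (4 tetrode channels) are returned for the light-evoked and
#' spontaneous spikes; for a tagged unit they share the same underlying
#' template up to averaging noise, and the evoked waveform of an untagged
#' unit is the same template averaged over the few background spikes that
#' fall in the light windows (hence noisier).
#'
#' @param spec A [tagging_spec()].
#' @param background_rate Background firing rate (spikes/s).
#' @param tagged Logical: does the unit express the opsin?
#' @param seed Optional integer seed.
#' @param wf_sample_rate Waveform sampling rate (Hz).
#' @return List with `pulse_times` (s), `spikes` (s, sorted), `wf_spontaneous`
#'   and `wf_evoked` (4 x 32 matrices, µV), `wf_sample_rate`, `tagged`, and
#'   the generating `spec`.
#' @examples
#' s <- gen_tagging_session(tagging_spec(), background_rate = 5,
#'                          tagged = TRUE, seed = 1)
#' length(s$pulse_times)
#' @export
gen_tagging_session <- function(spec = tagging_spec(), background_rate = 5,
                                tagged = TRUE, seed = NULL,
                                wf_sample_rate = 30e3) {
  stopifnot(inherits(spec, "tagging_spec"))
  if (background_rate < 0) stop("`background_rate` must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  ipi <- 1 / spec$pulse_rate_hz
  train_len <- (spec$pulses_per_train - 1) * ipi
  starts <- 1 + (seq_len(spec$n_trains) - 1) *
    (train_len + spec$intertrain_interval_s)
  pulse_times <- as.vector(vapply(
    starts, function(s) s + (seq_len(spec$pulses_per_train) - 1) * ipi,
    numeric(spec$pulses_per_train)))
  duration <- max(pulse_times) + 1

  n_bg <- stats::rpois(1, background_rate * duration)
  spikes <- stats::runif(n_bg, 0, duration)
  n_evoked <- 0L
  if (tagged) {
    evoke <- stats::runif(length(pulse_times)) < spec$reliability
    lat <- stats::rnorm(sum(evoke), spec$latency_mean,
                        spec$latency_jitter_sd) / 1000
    lat <- pmax(lat, 1e-4)
    spikes <- c(spikes, pulse_times[evoke] + lat)
    n_evoked <- sum(evoke)
  }
  spikes <- sort(spikes)

  template <- spike_waveform_template()
  n_spont <- max(1L, n_bg)
  # averaging noise shrinks with the number of spikes contributing
  n_in_light <- if (tagged) max(1L, n_evoked) else
    max(1L, stats::rpois(1, background_rate * length(pulse_times) *
                            spec$pulse_duration_ms / 1000))
  noise_sd <- 8  # per-spike waveform noise, µV
  wf_spont <- template + matrix(stats::rnorm(length(template),
                                             sd = noise_sd / sqrt(n_spont)),
                                nrow(template))
  wf_evoked <- template + matrix(stats::rnorm(length(template),
                                              sd = noise_sd / sqrt(n_in_light)),
                                 nrow(template))
  list(pulse_times = pulse_times, spikes = spikes,
       wf_spontaneous = wf_spont, wf_evoked = wf_evoked,
       wf_sample_rate = wf_sample_rate, tagged = tagged, spec = spec)
}

#' Biphasic extracellular spike-waveform template
#'
#' A canonical negative-going spike on 4 tetrode channels with a decaying
#' amplitude profile, used as the shared template for evoked and spontaneous
#' mean waveforms in simulated sessions.
#'
#' @param n_samples Samples per channel.
#' @param trough_amp Trough amplitude on the largest channel (µV).
#' @return 4 x `n_samples` numeric matrix.
#' @export
spike_waveform_template <- function(n_samples = 32, trough_amp = 120) {
  t <- seq_len(n_samples)
  shape <- -exp(-((t - 10)^2) / 8) + 0.45 * exp(-((t - 18)^2) / 30)
  amps <- c(1, 0.7, 0.45, 0.25) * trough_amp
  outer(amps, shape)
}
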