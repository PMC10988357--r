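#' Simulate a stream of ultrasonic-vocalization syllables
#'
#' Generates a session of 50-kHz USV bouts with known ground truth. Syllables
#' are organized into bouts: within-bout inter-onset intervals are
#' Gamma-distributed with the given mean and SD (Gamma rather than Normal so
#' intervals are guaranteed positive), and consecutive bouts are separated by
#' silent gaps strictly longer than `bout_gap` seconds. Each syllable is
#' either flat (frequency extent < 15 kHz) or frequency-modulated
#' (extent > 15 kHz).
#'
#' @param duration Session length in seconds.
#' @param bout_rate Target bout rate in bouts per minute. The realized rate is
#'   approximate because bout lengths are random; `bout_rate = 0` returns an
#'   empty table.
#' @param syllables_per_bout Function of `n` returning `n` integer bout sizes
#'   (>= 1). Default: geometric with mean 4, truncated at 1.
#' @param isi_mean,isi_sd Mean and SD (s) of within-bout inter-onset
#'   intervals. Must satisfy `isi_mean > isi_sd >= 0`.
#' @param flat_fraction Probability that a syllable is a flat call.
#' @param bout_gap Minimum silent gap (s) between the offset of one bout and
#'   the onset of the next; gaps are `bout_gap` plus an exponential excess.
#' @param dur_mean,dur_sd Mean and SD (s) of syllable durations
#'   (Gamma-distributed, clipped below at 6 ms).
#' @param seed Optional integer seed; fixed seed gives an identical table.
#'
#' @return A data.frame with one row per syllable and columns `onset_s`,
#'   `offset_s`, `fmin_khz`, `fmax_khz`, `bout_id`, `is_first` (first syllable
#'   of its bout), and `call_class` (`"flat"` or `"FM"`). Attributes `isi_mean`,
#'   `isi_sd` and `bout_gap` record the generating parameters.
#' @examples
#' usv <- gen_usv_stream(duration = 60, seed = 1)
#' head(usv)
#' @export
gen_usv_stream <- function(duration, bout_rate = 12,
                           syllables_per_bout = NULL,
                           isi_mean = 0.366, isi_sd = 0.064,
                           flat_fraction = 0.5, bout_gap = 1.0,
                           dur_mean = 0.05, dur_sd = 0.02,
                           seed = NULL) {
  if (!is.numeric(duration) || duration <= 0)
    stop("`duration` must be a positive number of seconds")
  if (bout_rate < 0) stop("`bout_rate` must be non-negative")
  if (!(isi_mean > isi_sd && isi_sd >= 0))
    stop("need isi_mean > isi_sd >= 0")
  if (flat_fraction < 0 || flat_fraction > 1)
    stop("`flat_fraction` must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(syllables_per_bout))
    syllables_per_bout <- function(n) 1L + stats::rgeom(n, prob = 1 / 4)

  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      fmin_khz = numeric(0), fmax_khz = numeric(0),
                      bout_id = integer(0), is_first = logical(0),
                      call_class = character(0))
  attr(empty, "isi_mean") <- isi_mean
  attr(empty, "isi_sd") <- isi_sd
  attr(empty, "bout_gap") <- bout_gap
  if (bout_rate == 0) return(empty)

  # exponential excess on top of the hard bout gap, sized so that the mean
  # bout cycle roughly matches the requested bout rate
  mean_bout_len <- (mean(syllables_per_bout(1000L)) - 1) * isi_mean + dur_mean
  gap_excess <- max(0.25, 60 / bout_rate - mean_bout_len - bout_gap)

  rows <- list()
  bout_id <- 0L
  t <- bout_gap + stats::rexp(1, rate = 1 / gap_excess)
  while (t < duration) {
    bout_id <- bout_id + 1L
    n_syl <- max(1L, syllables_per_bout(1L))
    isis <- rgamma_mean_sd(n_syl - 1L, isi_mean, isi_sd)
    # keep within-bout intervals strictly shorter than the bout gap
    isis <- pmin(isis, bout_gap - 1e-3)
    onsets <- t + cumsum(c(0, isis))
    durs <- pmax(0.006, rgamma_mean_sd(n_syl, dur_mean, dur_sd))
    if (n_syl > 1L) durs[-n_syl] <- pmin(durs[-n_syl], isis - 0.005)
    offsets <- onsets + durs
    flat <- stats::runif(n_syl) < flat_fraction
    fr <- syllable_freqs(flat)
    rows[[bout_id]] <- data.frame(
      onset_s = onsets, offset_s = offsets,
      fmin_khz = fr$fmin, fmax_khz = fr$fmax,
      bout_id = bout_id,
      is_first = c(TRUE, rep(FALSE, n_syl - 1L)),
      call_class = ifelse(flat, "flat", "FM"))
    t <- offsets[n_syl] + bout_gap +
      stats::rexp(1, rate = 1 / gap_excess)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[out$offset_s <= duration, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "isi_mean") <- isi_mean
  attr(out, "isi_sd") <- isi_sd
  attr(out, "bout_gap") <- bout_gap
  out
}

# Gamma draws parameterized by mean and sd (sd = 0 collapses to the mean).
rgamma_mean_sd <- function(n, mean, sd) {
  if (n <= 0) return(numeric(0))
  if (sd <= 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

# Frequency extents: flat calls span < 15 kHz, FM calls > 15 kHz, all within
# the 20-120 kHz USV band (50-kHz call family).
syllable_freqs <- function(flat) {
  n <- length(flat)
  fmin <- fmax <- numeric(n)
  nf <- sum(flat)
  if (nf > 0) {
    ctr <- stats::runif(nf, 50, 70)
    half <- stats::runif(nf, 1, 6.5)
    fmin[flat] <- ctr - half
    fmax[flat] <- ctr + half
  }
  if (n - nf > 0) {
    lo <- stats::runif(n - nf, 35, 60)
    ext <- stats::runif(n - nf, 18, 45)
    fmin[!flat] <- lo
    fmax[!flat] <- pmin(lo + ext, 119)
  }
  list(fmin = fmin, fmax = fmax)
}

#' Synthesize ultrasonic audio for a syllable table
#'
#' Renders each syllable as a linear chirp from `fmin_khz` to `fmax_khz`
#' (a flat call is a chirp with a small extent, an FM call a wide one) with
#' 2 ms Hann on/off ramps, added to white Gaussian background noise. This is
#' a fixture generator for the segmenter, not a model of rat vocal acoustics.
#'
#' @param usv Syllable table as returned by [gen_usv_stream()].
#' @param sample_rate Sampling rate in Hz; must be at least twice the highest
#'   syllable frequency.
#' @param duration Length of the waveform in seconds (default: last offset
#'   plus 50 ms).
#' @param noise_sd Standard deviation of the background noise.
#' @param amplitude Peak amplitude of each syllable tone. The default
#'   (`amplitude = 1`, `noise_sd = 0.05`) gives a tone-to-noise power ratio of
#'   about 23 dB.
#' @param seed Optional integer seed for the noise.
#' @return Numeric waveform vector with attribute `sample_rate`.
#' @examples
#' usv <- gen_usv_stream(duration = 2, seed = 1)
#' wav <- gen_audio(usv, sample_rate = 250e3, seed = 1)
#' @export
gen_audio <- function(usv, sample_rate = 250e3, duration = NULL,
                      noise_sd = 0.05, amplitude = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (nrow(usv) > 0 && sample_rate < 2 * max(usv$fmax_khz) * 1000)
    stop("sample_rate violates the Nyquist limit for the highest syllable")
  if (is.null(duration))
    duration <- if (nrow(usv) == 0) 1 else max(usv$offset_s) + 0.05
  n <- round(duration * sample_rate)
  x <- stats::rnorm(n, sd = noise_sd)
  for (i in seq_len(nrow(usv))) {
    i0 <- floor(usv$onset_s[i] * sample_rate) + 1L
    i1 <- min(n, ceiling(usv$offset_s[i] * sample_rate))
    if (i1 <= i0) next
    tau <- (seq.int(i0, i1) - i0) / sample_rate
    dur <- tau[length(tau)]
    f0 <- usv$fmin_khz[i] * 1000
    f1 <- usv$fmax_khz[i] * 1000
    phase <- 2 * pi * (f0 * tau + (f1 - f0) / (2 * dur) * tau^2)
    env <- hann_ramp(length(tau), ramp = round(0.002 * sample_rate))
    x[i0:i1] <- x[i0:i1] + amplitude * env * sin(phase)
  }
  attr(x, "sample_rate") <- sample_rate
  x
}

hann_ramp <- function(n, ramp) {
  env <- rep(1, n)
  r <- min(ramp, floor(n / 2))
  if (r > 0) {
    w <- 0.5 * (1 - cos(pi * seq_len(r) / r))
    env[seq_len(r)] <- w
    env[n + 1 - seq_len(r)] <- w
  }
  env
}
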