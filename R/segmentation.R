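#' Short-time spectrogram of an ultrasonic recording
#'
#' Thin wrapper around [signal::specgram()] returning magnitudes with axes in
#' seconds and kHz. Defaults (512-sample Hann window, 75% overlap) give
#' ~2 ms windows and ~0.5 ms steps at a 250 kHz sampling rate.
#'
#' @param wave Numeric waveform (attribute `sample_rate` used when
#'   `sample_rate` is missing).
#' @param sample_rate Sampling rate in Hz.
#' @param window_s,step_s Analysis window and hop sizes in seconds
#'   (`window_s >= step_s > 0`).
#' @return Object of class `usv_spectrogram`: list with `mag`
#'   (frequency x time magnitude matrix), `t_s` (frame center times, s),
#'   `f_khz` (bin frequencies, kHz), `step_s` and `window_s`.
#' @export
usv_spectrogram <- function(wave, sample_rate = attr(wave, "sample_rate"),
                            window_s = 512 / 250e3, step_s = 128 / 250e3) {
  if (is.null(sample_rate)) stop("`sample_rate` is required")
  if (!(window_s >= step_s && step_s > 0))
    stop("need window_s >= step_s > 0")
  n <- round(window_s * sample_rate)
  step <- max(1L, round(step_s * sample_rate))
  if (n > length(wave)) stop("analysis window longer than the signal")
  sp <- signal::specgram(as.numeric(wave), n = n, Fs = sample_rate,
                         overlap = n - step)
  structure(list(mag = abs(sp$S),
                 t_s = as.numeric(sp$t) + window_s / 2,
                 f_khz = as.numeric(sp$f) / 1000,
                 step_s = step / sample_rate,
                 window_s = n / sample_rate),
            class = "usv_spectrogram")
}

#' Detect USV syllables in a spectrogram
#'
#' A threshold segmenter: within the analysis band, a frame is marked active
#' when its peak magnitude exceeds that frequency bin's noise floor (median
#' plus `threshold_sd` robust SDs, MAD-based, across time). Active runs
#' separated by less than `min_gap` are merged, runs shorter than `min_dur`
#' are discarded, and each syllable's frequency extent is taken from its
#' per-frame peak-frequency track.
#'
#' @param spec A `usv_spectrogram`.
#' @param band Analysis band in kHz (default 20-120).
#' @param threshold_sd Detection threshold in robust (MAD-based) SDs above
#'   the per-bin median. The default of 10 keeps the chance of marking a
#'   pure-noise frame negligible even with ~200 frequency bins per frame,
#'   while tonal syllables down to a 10 dB broadband SNR exceed it by nearly
#'   an order of magnitude.
#' @param min_dur Minimum syllable duration (s), default 5 ms.
#' @param min_gap Minimum silent gap between syllables (s), default 20 ms;
#'   shorter gaps are merged.
#' @return data.frame with columns `onset_s`, `offset_s`, `fmin_khz`,
#'   `fmax_khz`, `duration_s` and a list column `peak_track` of per-frame
#'   (time, peak frequency) data.frames.
#' @export
detect_syllables <- function(spec, band = c(20, 120), threshold_sd = 10,
                             min_dur = 0.005, min_gap = 0.020) {
  stopifnot(inherits(spec, "usv_spectrogram"))
  empty <- data.frame(onset_s = numeric(0), offset_s = numeric(0),
                      fmin_khz = numeric(0), fmax_khz = numeric(0),
                      duration_s = numeric(0))
  empty$peak_track <- list()
  if (length(spec$t_s) == 0) return(empty)
  if (band[1] < min(spec$f_khz) - 1e-9 || band[2] > max(spec$f_khz) + 1e-9)
    stop("`band` outside the spectrogram frequency range")
  in_band <- spec$f_khz >= band[1] & spec$f_khz <= band[2]
  m <- spec$mag[in_band, , drop = FALSE]
  f <- spec$f_khz[in_band]
  med <- apply(m, 1, stats::median)
  rsd <- apply(m, 1, stats::mad)
  thr <- med + threshold_sd * rsd
  above <- m > thr
  active <- colSums(above) > 0
  if (!any(active)) return(empty)
  peak_bin <- max.col(t(m), ties.method = "first")

  # A frame's window smears energy by +/- window/2 around its center, so the
  # first/last marked frame centers over-reach the true onset/offset by about
  # (window - step)/2; shrink run boundaries accordingly (clamped so a
  # single-frame run keeps a step-wide extent).
  shrink <- (spec$window_s - spec$step_s) / 2
  runs <- active_runs(active)
  on_raw <- spec$t_s[runs$start]
  off_raw <- spec$t_s[runs$end]
  mid <- (on_raw + off_raw) / 2
  iv <- merge_segments(
    data.frame(onset_s = pmin(on_raw + shrink, mid - spec$step_s / 2),
               offset_s = pmax(off_raw - shrink, mid + spec$step_s / 2)),
    min_gap = min_gap, min_dur = 0)
  half_w <- spec$window_s / 2
  tracks <- lapply(seq_len(nrow(iv)), function(i) {
    fr <- which(spec$t_s >= iv$onset_s[i] - half_w &
                  spec$t_s <= iv$offset_s[i] + half_w & active)
    data.frame(t_s = spec$t_s[fr], f_khz = f[peak_bin[fr]])
  })
  out_df <- data.frame(
    onset_s = iv$onset_s, offset_s = iv$offset_s,
    fmin_khz = vapply(tracks, function(tr) min(tr$f_khz), numeric(1)),
    fmax_khz = vapply(tracks, function(tr) max(tr$f_khz), numeric(1)),
    duration_s = iv$offset_s - iv$onset_s)
  out_df$peak_track <- tracks
  out_df <- out_df[out_df$duration_s >= min_dur, , drop = FALSE]
  rownames(out_df) <- NULL
  out_df
}

active_runs <- function(active) {
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

#' Merge and duration-filter detection intervals
#'
#' Intervals separated by a gap shorter than `min_gap` are merged, then
#' intervals shorter than `min_dur` are dropped. The operation is idempotent:
#' applying it to its own output changes nothing.
#'
#' @param intervals data.frame with `onset_s`, `offset_s` (sorted by onset).
#' @param min_gap Gaps < `min_gap` seconds are merged.
#' @param min_dur Intervals shorter than `min_dur` seconds are dropped.
#' @return data.frame with `onset_s`, `offset_s`.
#' @export
merge_segments <- function(intervals, min_gap = 0.020, min_dur = 0.005) {
  n <- nrow(intervals)
  if (n == 0) return(intervals[, c("onset_s", "offset_s")])
  o <- order(intervals$onset_s)
  on <- intervals$onset_s[o]
  off <- intervals$offset_s[o]
  m_on <- on[1]; m_off <- off[1]
  res_on <- numeric(0); res_off <- numeric(0)
  for (i in seq_len(n - 1) + 1) {
    if (on[i] - m_off < min_gap) {
      m_off <- max(m_off, off[i])
    } else {
      res_on <- c(res_on, m_on); res_off <- c(res_off, m_off)
      m_on <- on[i]; m_off <- off[i]
    }
  }
  res_on <- c(res_on, m_on); res_off <- c(res_off, m_off)
  keep <- (res_off - res_on) >= min_dur
  data.frame(onset_s = res_on[keep], offset_s = res_off[keep])
}

#' Split syllables into first and subsequent calls
#'
#' The first syllable of a record, and every syllable whose onset follows the
#' previous onset by strictly more than `gap` seconds, is a "first" call;
#' all others are "subsequent" calls within a bout.
#'
#' @param onsets Sorted syllable onset times (s).
#' @param gap Bout-defining silent interval (s), default 1.
#' @return Logical vector: `TRUE` for first calls.
#' @examples
#' split_calls(c(0, 0.3, 0.6, 2.0, 2.2))
#' @export
split_calls <- function(onsets, gap = 1.0) {
  if (length(onsets) == 0) return(logical(0))
  if (is.unsorted(onsets)) stop("`onsets` must be sorted ascending")
  c(TRUE, diff(onsets) > gap)
}

#' Classify syllables as flat or frequency-modulated
#'
#' A call is flat when its frequency extent (`fmax - fmin`) is below 15 kHz
#' and frequency-modulated (FM) otherwise; an extent of exactly 15 kHz is
#' assigned to FM.
#'
#' @param fmin,fmax Frequency extent of each syllable in kHz.
#' @return Character vector: `"flat"` or `"FM"`.
#' @export
classify_call <- function(fmin, fmax) {
  if (any(fmax < fmin)) stop("need fmax >= fmin")
  ifelse(fmax - fmin < 15, "flat", "FM")
}

#' Segment a waveform into an annotated syllable table
#'
#' Convenience wrapper: spectrogram, syllable detection, first/subsequent
#' splitting and flat/FM call typing in one call.
#'
#' @inheritParams usv_spectrogram
#' @inheritParams detect_syllables
#' @param bout_gap Bout-defining gap (s) passed to [split_calls()].
#' @return Syllable data.frame with `onset_s`, `offset_s`, `fmin_khz`,
#'   `fmax_khz`, `is_first`, `call_class`.
#' @export
segment_audio <- function(wave, sample_rate = attr(wave, "sample_rate"),
                          band = c(20, 120), threshold_sd = 10,
                          min_dur = 0.005, min_gap = 0.020, bout_gap = 1.0) {
  sp <- usv_spectrogram(wave, sample_rate)
  syl <- detect_syllables(sp, band = band, threshold_sd = threshold_sd,
                          min_dur = min_dur, min_gap = min_gap)
  syl$peak_track <- NULL
  syl$is_first <- split_calls(syl$onset_s, gap = bout_gap)
  syl$call_class <- if (nrow(syl)) classify_call(syl$fmin_khz, syl$fmax_khz)
                    else character(0)
  syl
}
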