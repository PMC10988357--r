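#' Planted peri-call response profiles
#'
#' Builds the specification of one unit's response to USVs: a baseline firing
#' rate plus multiplicative, piecewise-constant gain kernels applied around
#' first-call and subsequent-call onsets. Eight canonical profiles are
#' provided: two excitatory (`E1` sustained, `E2` transient), four inhibitory
#' (`I1` sustained, `I2` transient, `I3` anticipatory, `I4` delayed), a weak
#' "other" responder (`O`) and a nonresponder (`NR`, gain identically 1).
#' Where kernels from several calls overlap their gains multiply; the rate
#' never goes negative because gains are non-negative.
#'
#' @param type One of `"E1"`, `"E2"`, `"I1"`, `"I2"`, `"I3"`, `"I4"`, `"O"`,
#'   `"NR"`.
#' @param baseline_rate Baseline firing rate in spikes/s (> 0).
#' @param kernel_first,kernel_subsequent Optional data.frames with columns
#'   `t0`, `t1`, `gain` (peri-onset interval `(t0, t1]` in seconds, gain >= 0)
#'   overriding the canonical kernel for the given type.
#' @return An object of class `response_profile_spec`.
#' @examples
#' response_profile_spec("E1", baseline_rate = 5)
#' @export
response_profile_spec <- function(type = c("E1", "E2", "I1", "I2", "I3", "I4",
                                           "O", "NR"),
                                  baseline_rate = 5,
                                  kernel_first = NULL,
                                  kernel_subsequent = NULL) {
  type <- match.arg(type)
  if (!is.numeric(baseline_rate) || baseline_rate <= 0)
    stop("`baseline_rate` must be > 0")
  defaults <- default_kernels(type)
  kf <- if (is.null(kernel_first)) defaults$first else kernel_first
  ks <- if (is.null(kernel_subsequent)) defaults$subsequent else kernel_subsequent
  for (k in list(kf, ks)) {
    if (nrow(k) > 0 && (any(k$gain < 0) || any(k$t1 <= k$t0)))
      stop("kernel pieces need gain >= 0 and t1 > t0")
  }
  structure(list(type = type, baseline_rate = baseline_rate,
                 kernel_first = kf, kernel_subsequent = ks),
            class = "response_profile_spec")
}

kernel_piece <- function(t0, t1, gain) data.frame(t0 = t0, t1 = t1, gain = gain)
no_kernel <- function() data.frame(t0 = numeric(0), t1 = numeric(0),
                                   gain = numeric(0))

# Canonical kernels. The empirical types are defined by their data, not a
# formula; these rectangular kernels are the package's modeling choice and
# are deliberately distinct in onset, duration and sign.
default_kernels <- function(type) {
  switch(type,
    E1 = list(first = kernel_piece(0, 0.5, 3.0),
              subsequent = kernel_piece(0, 0.25, 2.0)),
    E2 = list(first = kernel_piece(0, 0.1, 3.5),
              subsequent = no_kernel()),
    I1 = list(first = kernel_piece(0, 0.5, 0.15),
              subsequent = kernel_piece(0, 0.25, 0.4)),
    I2 = list(first = kernel_piece(0, 0.1, 0.05),
              subsequent = no_kernel()),
    I3 = list(first = kernel_piece(-0.5, 0.25, 0.3),
              subsequent = kernel_piece(-0.25, 0.25, 0.5)),
    I4 = list(first = kernel_piece(0.1, 0.6, 0.15),
              subsequent = no_kernel()),
    O  = list(first = kernel_piece(0, 0.25, 1.4),
              subsequent = kernel_piece(0, 0.25, 1.4)),
    NR = list(first = no_kernel(), subsequent = no_kernel()))
}

#' Evaluate the multiplicative rate gain of a response profile
#'
#' @param spec A [response_profile_spec()].
#' @param t Times (s) at which to evaluate the gain.
#' @param first_onsets,subsequent_onsets Sorted onset times (s) of first and
#'   subsequent calls.
#' @return Numeric vector of gains (>= 0); 1 where no kernel is active.
#' @export
profile_gain <- function(spec, t, first_onsets, subsequent_onsets) {
  log_g <- numeric(length(t))
  add_pieces <- function(log_g, kernel, onsets) {
    if (length(onsets) == 0 || nrow(kernel) == 0) return(log_g)
    onsets <- sort(onsets)
    for (i in seq_len(nrow(kernel))) {
      if (kernel$gain[i] == 1) next
      # number of onsets with t - onset in (t0, t1]
      n_active <- findInterval(t - kernel$t0[i], onsets) -
        findInterval(t - kernel$t1[i], onsets)
      log_g <- log_g + n_active * log(max(kernel$gain[i], 1e-12))
    }
    log_g
  }
  log_g <- add_pieces(log_g, spec$kernel_first, first_onsets)
  log_g <- add_pieces(log_g, spec$kernel_subsequent, subsequent_onsets)
  exp(log_g)
}

# Upper bound on the gain: for each excitatory piece, the largest number of
# onsets that can be simultaneously active, found by sliding a window of the
# piece length over the onsets. Exact for piecewise-constant kernels.
max_profile_gain <- function(spec, first_onsets, subsequent_onsets) {
  bound_for <- function(kernel, onsets) {
    if (length(onsets) == 0 || nrow(kernel) == 0) return(1)
    onsets <- sort(onsets)
    b <- 1
    for (i in seq_len(nrow(kernel))) {
      g <- kernel$gain[i]
      if (g <= 1) next
      len <- kernel$t1[i] - kernel$t0[i]
      k <- max(findInterval(onsets + len, onsets) - seq_along(onsets) + 1L)
      b <- b * g^k
    }
    b
  }
  bound_for(spec$kernel_first, first_onsets) *
    bound_for(spec$kernel_subsequent, subsequent_onsets)
}

#' Simulate a spike train with a planted peri-call response
#'
#' Draws an inhomogeneous Poisson spike train whose rate is
#' `baseline_rate * gain(t)`, where the gain is the product of all kernels
#' active at `t` (see [response_profile_spec()]). Sampling uses thinning
#' against an exact upper bound on the gain, so the peri-event rate profile
#' converges to the planted kernel as the number of calls grows.
#'
#' @param spec A [response_profile_spec()].
#' @param usv Syllable table from [gen_usv_stream()] (uses `onset_s` and
#'   `is_first`), or a list with elements `first_onsets` and
#'   `subsequent_onsets`.
#' @param duration Session length in seconds.
#' @param seed Optional integer seed.
#' @return Sorted numeric vector of spike times in seconds.
#' @examples
#' usv <- gen_usv_stream(duration = 120, seed = 1)
#' spk <- gen_spike_train(response_profile_spec("E1"), usv, 120, seed = 2)
#' @export
gen_spike_train <- function(spec, usv, duration, seed = NULL) {
  stopifnot(inherits(spec, "response_profile_spec"))
  if (duration <= 0) stop("`duration` must be positive")
  if (!is.null(seed)) set.seed(seed)
  if (is.data.frame(usv)) {
    first_onsets <- usv$onset_s[usv$is_first]
    subsequent_onsets <- usv$onset_s[!usv$is_first]
  } else {
    first_onsets <- usv$first_onsets
    subsequent_onsets <- usv$subsequent_onsets
  }
  rate_max <- spec$baseline_rate *
    max_profile_gain(spec, first_onsets, subsequent_onsets)
  n_cand <- stats::rpois(1, rate_max * duration)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(stats::runif(n_cand, 0, duration))
  rate <- spec$baseline_rate *
    profile_gain(spec, cand, first_onsets, subsequent_onsets)
  keep <- stats::runif(n_cand) < rate / rate_max
  cand[keep]
}

#' Simulate a recorded population with planted response types
#'
#' Generates one spike train per unit over a shared USV stream, together with
#' unit metadata (anterior-posterior and medio-lateral coordinates, region)
#' drawn uniformly over the recorded span. The planted type of every unit is
#' returned as ground truth.
#'
#' @param types Character vector of planted types, one entry per unit
#'   (recycled from `n_per_type` if given as a named count vector).
#' @param usv Syllable table from [gen_usv_stream()].
#' @param duration Session length (s).
#' @param baseline_rate Baseline rate (spikes/s) given to every unit.
#' @param seed Integer seed (also seeds the per-unit spike trains).
#' @return List with `units` (data.frame: `unit_id`, `planted_type`, `ap_mm`,
#'   `ml_mm`, `region`, `baseline_rate`) and `spikes` (list of spike-time
#'   vectors, one per unit).
#' @export
gen_population <- function(types, usv, duration, baseline_rate = 5,
                           seed = 0) {
  set.seed(seed)
  n <- length(types)
  units <- data.frame(
    unit_id = seq_len(n),
    planted_type = types,
    ap_mm = stats::runif(n, -2.0, 4.5),
    ml_mm = stats::runif(n, 0.5, 4.5),
    region = sample(c("M1", "M2"), n, replace = TRUE),
    baseline_rate = baseline_rate)
  spikes <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- response_profile_spec(types[i], baseline_rate = baseline_rate)
    spikes[[i]] <- gen_spike_train(spec, usv, duration)
  }
  list(units = units, spikes = spikes)
}
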