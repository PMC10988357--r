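test_that("USV stream matches the targeted bout statistics", {
  usv <- gen_usv_stream(1200, bout_rate = 12, isi_mean = 0.366,
                        isi_sd = 0.064, seed = 42)
  expect_true(all(diff(usv$onset_s) > 0))
  expect_true(all(usv$offset_s > usv$onset_s))

  isis <- unlist(tapply(usv$onset_s, usv$bout_id, diff), use.names = FALSE)
  expect_gt(length(isis), 500)
  expect_lt(abs(mean(isis) - 0.366), 0.02)
  # within-bout inter-onset intervals stay below the bout gap
  expect_true(all(isis < attr(usv, "bout_gap")))
  # silent gap between consecutive bouts exceeds the bout gap
  by_bout <- split(usv, usv$bout_id)
  offs <- vapply(by_bout, function(b) max(b$offset_s), numeric(1))
  ons <- vapply(by_bout, function(b) min(b$onset_s), numeric(1))
  gaps <- ons[-1] - offs[-length(offs)]
  expect_true(all(gaps >= attr(usv, "bout_gap")))
  # the first/subsequent splitter recovers exactly the planted bout starts
  expect_identical(split_calls(usv$onset_s), usv$is_first)
})

test_that("USV stream handles edge parameters and is deterministic", {
  expect_identical(nrow(gen_usv_stream(100, bout_rate = 0, seed = 1)), 0L)
  expect_error(gen_usv_stream(-5), "duration")
  expect_error(gen_usv_stream(10, isi_mean = 0.05, isi_sd = 0.1), "isi")
  a <- gen_usv_stream(300, seed = 7)
  b <- gen_usv_stream(300, seed = 7)
  expect_identical(a, b)
  # flat calls span < 15 kHz, FM calls more
  expect_true(all((a$fmax_khz - a$fmin_khz < 15) == (a$call_class == "flat")))
  expect_true(all(a$fmin_khz >= 20 & a$fmax_khz <= 120))
})

test_that("nonresponder spike counts follow homogeneous Poisson", {
  usv <- gen_usv_stream(100, seed = 3)
  spk <- gen_spike_train(response_profile_spec("NR", baseline_rate = 5),
                         usv, 100, seed = 4)
  expect_true(length(spk) >= 390 && length(spk) <= 610)  # 500 +/- 4 SD
  expect_false(is.unsorted(spk))
  expect_identical(
    spk, gen_spike_train(response_profile_spec("NR", 5), usv, 100, seed = 4))
})

test_that("planted excitatory gain is recovered by the PSTH", {
  # isolated single-syllable bouts so kernels never overlap
  onsets <- seq(2, by = 3, length.out = 200)
  usv <- usv_row(onsets, onsets + 0.05, 60, 62, bout = seq_along(onsets))
  spec <- response_profile_spec(
    "E1", baseline_rate = 8,
    kernel_first = data.frame(t0 = 0, t1 = 0.25, gain = 3),
    kernel_subsequent = data.frame(t0 = numeric(0), t1 = numeric(0),
                                   gain = numeric(0)))
  spk <- gen_spike_train(spec, usv, max(onsets) + 2, seed = 11)
  resp <- mean(vocalmod:::window_counts(spk, onsets, 0, 0.25)) / 0.25
  base <- mean(baseline_rates(spk, onsets))
  expect_lt(abs(resp / base - 3), 0.3)
})

test_that("planted inhibition drives auROC below chance", {
  usv <- gen_usv_stream(400, seed = 5)
  spk <- gen_spike_train(response_profile_spec("I1", baseline_rate = 8),
                         usv, 400, seed = 6)
  prof <- unit_response_profile(spk, usv)
  post_first <- prof$vector25[11:15]
  expect_true(all(post_first < 0.5))
})

test_that("gain kernels multiply where calls overlap and never go negative", {
  spec <- response_profile_spec("E1", baseline_rate = 5)
  first <- c(10, 10.3)  # second kernel overlaps the first
  g <- profile_gain(spec, c(10.4, 9.0, 10.9), first, numeric(0))
  expect_equal(g, c(9, 1, 1))  # 3 * 3 inside both kernels
  expect_true(all(profile_gain(response_profile_spec("I1", 5),
                               seq(9, 12, 0.01), first, numeric(0)) >= 0))
})

test_that("synthesized audio places energy at the planted frequency", {
  usv <- usv_row(0.1, 0.15, 59.5, 60.5)
  wav <- gen_audio(usv, sample_rate = 250e3, duration = 0.4,
                   noise_sd = 0.05, seed = 2)
  sp <- usv_spectrogram(wav)
  inside <- sp$t_s > 0.105 & sp$t_s < 0.145
  peaks <- sp$f_khz[apply(sp$mag[, inside], 2, which.max)]
  expect_true(all(abs(peaks - 60) < 2))
  # empty ground truth: pure noise of the stated length
  quiet <- gen_audio(usv[0, ], sample_rate = 250e3, duration = 0.5, seed = 3)
  expect_length(quiet, 125000)
  expect_lt(max(abs(quiet)), 0.05 * 6)
  expect_error(gen_audio(usv_row(0, 0.1, 100, 119), sample_rate = 150e3),
               "Nyquist")
})

test_that("tagging sessions follow the pulse protocol and reliability", {
  s <- gen_tagging_session(tagging_spec(), background_rate = 5,
                           tagged = TRUE, seed = 9)
  expect_length(s$pulse_times, 100)
  # 10 trains: large gaps between trains, 5 Hz within
  gaps <- diff(s$pulse_times)
  expect_identical(sum(gaps > 5), 9L)
  expect_true(all(abs(gaps[gaps < 5] - 0.2) < 1e-9))

  # ~80 evoked spikes in the 10 ms test window (binomial 100 x 0.8 + bg)
  n_test <- sum(vocalmod:::window_counts(s$spikes, s$pulse_times, 0, 0.01))
  expect_true(n_test > 60 && n_test < 100)

  u <- gen_tagging_session(tagging_spec(), background_rate = 20,
                           tagged = FALSE, seed = 10)
  r_test <- sum(vocalmod:::window_counts(u$spikes, u$pulse_times, 0, 0.01)) /
    (100 * 0.01)
  r_base <- sum(vocalmod:::window_counts(u$spikes, u$pulse_times, -0.15, 0)) /
    (100 * 0.15)
  expect_lt(abs(r_test / r_base - 1), 0.5)
})
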