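test_that("latency histograms partition epochs and conserve pulse counts", {
  pulses <- seq(1, by = 0.2, length.out = 20)
  h0 <- latency_histograms(numeric(0), pulses)
  expect_true(all(h0$baseline[, 11] == 20))
  expect_true(all(h0$baseline[, 1:10] == 0))
  expect_identical(h0$test[11], 20L)

  # one spike exactly 3 ms after every pulse
  h3 <- latency_histograms(pulses + 0.003, pulses)
  expect_identical(unname(h3$test[4]), 20L)  # bin [3, 4) ms is index 4
  expect_identical(sum(h3$test[-4]), 0L)
  expect_true(all(h3$baseline[, 11] == 20))

  # totals conserved: counts + no-spike = pulses, per epoch
  set.seed(51)
  spk <- sort(runif(2000, 0, 100))
  h <- latency_histograms(spk, seq(2, 98, by = 0.5))
  expect_true(all(rowSums(h$baseline) == h$n_pulses))
  expect_identical(sum(h$test), h$n_pulses)

  # homogeneous Poisson 20 Hz: no-spike probability per epoch ~ exp(-0.2)
  p_empty <- mean(h$baseline[, 11] / h$n_pulses)
  spk20 <- sort(runif(20 * 100, 0, 100))
  h20 <- latency_histograms(spk20, seq(2, 98, by = 0.5))
  p20 <- mean(h20$baseline[, 11] / h20$n_pulses)
  expect_lt(abs(p20 - exp(-0.2)), 0.03)

  expect_error(latency_histograms(spk, c(1, 1.1)), "overlap|at least")
  expect_error(latency_histograms(spk, seq(1, 2, by = 0.1)), "overlap")
})

test_that("Jensen-Shannon distance matches direct summation and is a metric", {
  expect_equal(js_distance(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(js_distance(c(1, 0), c(0, 1)), sqrt(log(2)))
  p <- c(0.5, 0.5); q <- c(0.9, 0.1)
  expect_equal(js_distance(p, q), jsd_oracle(p, q))
  expect_error(js_distance(c(0.5, 0.6), c(0.5, 0.5)), "normalized")
  expect_error(js_distance(c(1, 0), c(0.5, 0.5, 0)), "length")

  set.seed(52)
  for (i in 1:25) {
    tri <- lapply(1:3, function(j) {
      v <- rgamma(6, 1); v / sum(v)
    })
    d12 <- js_distance(tri[[1]], tri[[2]])
    d13 <- js_distance(tri[[1]], tri[[3]])
    d23 <- js_distance(tri[[2]], tri[[3]])
    expect_equal(d12, js_distance(tri[[2]], tri[[1]]))
    expect_lte(d12, d13 + d23 + 1e-12)
  }
})

test_that("SALT ranks a locked response at the extreme of the null", {
  pulses <- seq(1, by = 0.2, length.out = 100)
  set.seed(53)
  bg <- sort(runif(5 * 21, 0, 21))
  locked <- sort(c(bg, pulses + 0.003))
  s <- salt(latency_histograms(locked, pulses))
  expect_equal(s$salt_p, 1 / 106)  # minimum attainable with 105 null pairs
  expect_gt(s$salt_info, 0)

  # identical histograms: p = 1
  h3 <- latency_histograms(pulses + 0.0035, pulses)
  h3$baseline <- matrix(rep(h3$test, 15), 15, byrow = TRUE)
  expect_equal(salt(h3)$salt_p, 1)
})

test_that("SALT p-values are conservative on untagged units", {
  ps <- vapply(1:120, function(i) {
    s <- gen_tagging_session(tagging_spec(), background_rate = 8,
                             tagged = FALSE, seed = 5200 + i)
    salt(latency_histograms(s$spikes, s$pulse_times))$salt_p
  }, numeric(1))
  expect_true(all(abs(ps * 106 - round(ps * 106)) < 1e-9))  # support k/106
  for (t in c(0.05, 0.1, 0.25)) expect_lte(mean(ps <= t), t + 0.05)
})

test_that("waveform similarity behaves like a Pearson correlation", {
  wf <- spike_waveform_template()
  expect_equal(waveform_similarity(wf, wf), 1)
  expect_equal(waveform_similarity(-wf, wf), -1)
  set.seed(54)
  noisy <- wf + matrix(rnorm(length(wf), sd = 0.1 * sd(wf)), nrow(wf))
  expect_gt(waveform_similarity(noisy, wf), 0.95)
  expect_error(waveform_similarity(wf * 0, wf), "variance")
  expect_error(waveform_similarity(wf[, 1:10], wf), "shape")
})

test_that("light-responsive classification is a three-way conjunction", {
  s <- gen_tagging_session(tagging_spec(), 5, tagged = TRUE, seed = 55)
  r <- classify_tag(s)
  expect_true(r$light_responsive)
  expect_lt(r$salt_p, 0.01)
  expect_gt(r$waveform_r, 0.9)
  expect_gt(r$rate_ratio, 1)

  # same spikes but mismatched waveform: rejected by the r > 0.9 criterion
  s_bad <- s
  s_bad$wf_evoked <- -s$wf_evoked
  r_bad <- classify_tag(s_bad)
  expect_lt(r_bad$salt_p, 0.01)
  expect_false(r_bad$light_responsive)

  # missing waveforms: indeterminate
  s_na <- s
  s_na$wf_evoked <- NULL
  expect_true(is.na(classify_tag(s_na)$light_responsive))

  u <- gen_tagging_session(tagging_spec(), 5, tagged = FALSE, seed = 56)
  expect_false(classify_tag(u)$light_responsive)
})
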