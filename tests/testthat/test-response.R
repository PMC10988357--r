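test_that("rank-sum test enumerates exactly under ties", {
  r <- rank_sum_test(c(0, 0, 0, 0, 0), c(8, 10, 12, 9, 11))
  expect_identical(r$method, "exact")
  expect_equal(r$p.value, 2 / 252)                 # 0.0079
  expect_equal(min(r$p.value * 4, 1), 0.031746, tolerance = 1e-4)
})

test_that("rank-sum test agrees with wilcox.test", {
  set.seed(31)
  for (i in 1:20) {
    x <- round(rnorm(sample(3:8, 1)), 6)  # continuous: no ties
    y <- round(rnorm(sample(3:8, 1), mean = runif(1, -1, 1)), 6)
    mine <- rank_sum_test(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_identical(mine$method, "exact")
    expect_equal(mine$p.value, ref$p.value, tolerance = 1e-10)
  }
  # normal-approximation branch tracks the exact p for moderate n
  for (i in 1:10) {
    x <- rnorm(25)
    y <- rnorm(30, mean = runif(1, -0.8, 0.8))
    mine <- rank_sum_test(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_identical(mine$method, "normal")
    expect_lt(abs(mine$p.value - ref$p.value), 0.01)
  }
})

test_that("baseline rates count the -1.0 to -0.5 s window", {
  onsets <- c(10, 20, 30)
  expect_equal(baseline_rates(numeric(0), onsets), c(0, 0, 0))
  expect_equal(baseline_rates(c(9.25), onsets), c(2, 0, 0))  # 1 / 0.5 s
  # spikes at the window edges: (-1.0, -0.5] convention
  expect_equal(baseline_rates(c(9.0, 9.5), onsets)[1], 2)

  set.seed(32)
  spk <- sort(runif(10 * 200, 0, 200))
  ons <- seq(2, 199, length.out = 100)
  expect_lt(abs(mean(baseline_rates(spk, ons)) - 10), 1)
})

test_that("peri-event matrices have the stated geometry and smoothing", {
  set.seed(33)
  spk <- sort(runif(500, 0, 100))
  pem <- peri_event_matrix(spk, c(20, 40, 60))
  expect_identical(dim(pem$counts), c(3L, 40L))
  expect_equal(pem$rates, pem$counts / 0.05)
  # interior smoothed bin equals the 5-bin mean of the raw rates
  expect_equal(pem$smoothed[, 10], rowMeans(pem$rates[, 8:12]))
  # edge bins use a truncated, renormalized window
  expect_equal(pem$smoothed[, 1], rowMeans(pem$rates[, 1:3]))
  # every spike near an event lands in exactly one bin
  expect_equal(rowSums(pem$counts),
               vocalmod:::window_counts(spk, c(20, 40, 60), -1, 1))
})

test_that("responsiveness testing is Bonferroni-guarded and detects gain", {
  usv <- gen_usv_stream(300, seed = 34)
  f <- usv$onset_s[usv$is_first]
  s <- usv$onset_s[!usv$is_first]
  # unmodulated Poisson unit: not responsive
  spk <- gen_spike_train(response_profile_spec("NR", 5), usv, 300, seed = 1)
  r <- responsiveness_test(spk, f, s)
  expect_false(r$responsive)
  expect_true(all(r$p_adj > 0.05))

  # too few trials: untestable
  expect_true(is.na(responsiveness_test(spk, f[1], s)$responsive))

  # planted strong excitation is flagged
  e1 <- gen_spike_train(response_profile_spec("E1", 5), usv, 300, seed = 35)
  expect_true(responsiveness_test(e1, f, s)$responsive)
})

test_that("auROC equals the exhaustive pairwise oracle", {
  expect_equal(auroc(c(2, 4), c(1, 3)), 0.75)
  expect_equal(auroc(c(5, 5), c(5, 5)), 0.5)
  expect_equal(auroc(10:12, 1:3), 1)
  set.seed(36)
  for (i in 1:30) {
    x <- sample(0:5, sample(2:10, 1), replace = TRUE)
    y <- sample(0:5, sample(2:10, 1), replace = TRUE)
    expect_equal(auroc(x, y), auroc_oracle(x, y))
    # antisymmetry under sample swap
    expect_equal(auroc(y, x), 1 - auroc(x, y))
    # invariance under a strictly monotone transform
    expect_equal(auroc(exp(x), exp(y)), auroc(x, y))
  }
  # baseline against itself is exactly chance
  b <- c(0, 2, 2, 4, 8)
  expect_identical(auroc(b, b), 0.5)
  expect_error(auroc(c(1, 2), numeric(0)), "baseline")
})

test_that("the response vector concatenates the stated windows", {
  flat40 <- rep(0.5, 40)
  v <- response_vector(flat40, flat40)
  expect_length(v, 25)
  expect_true(all(v == 0.5))
  expect_error(response_vector(rep(0.5, 39), flat40), "grid")
  # windows map to the right bins: first segment = (-0.5, 0.25], bins 11-25
  marked <- replace(flat40, 11:25, 1)
  v2 <- response_vector(marked, flat40)
  expect_equal(unname(v2), c(rep(1, 15), rep(0.5, 10)))
})

test_that("call discrimination flags rate differences between call types", {
  flat_on <- seq(5, 300, by = 6)
  fm_on <- seq(8, 300, by = 6)
  set.seed(37)
  spk <- sort(c(
    unlist(lapply(flat_on, function(o) o + runif(1, -0.2, 0.2))),
    unlist(lapply(fm_on, function(o) o + runif(10, -0.25, 0.25)))))
  r <- call_discrimination_test(spk, flat_on, fm_on)
  expect_lt(r$p.value, 0.001)
  expect_true(r$discriminating)
  same <- call_discrimination_test(spk, flat_on, flat_on)
  expect_false(same$discriminating)
  expect_true(is.na(call_discrimination_test(spk, flat_on, 8)$discriminating))
})

test_that("unit profiles expose planted response structure", {
  usv <- gen_usv_stream(300, seed = 38)
  spk <- gen_spike_train(response_profile_spec("E1", 5), usv, 300, seed = 39)
  p <- unit_response_profile(spk, usv)
  expect_true(p$responsive)
  expect_length(p$vector25, 25)
  expect_gt(mean(p$vector25[11:15]), 0.5)       # post-onset excitation
  expect_gt(mean_auroc_response(p$auroc_first), 0.5)
  expect_lt(abs(p$baseline_rate - 5), 1.5)
})
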