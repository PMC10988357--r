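test_that("anterior/posterior assignment divides at AP = 1.5 mm", {
  expect_identical(assign_part(3.0), "anterior")
  expect_identical(assign_part(0.0), "posterior")
  expect_identical(assign_part(1.5), "posterior")  # boundary -> posterior
  expect_identical(assign_part(c(2, 1, 1.5)),
                   c("anterior", "posterior", "posterior"))
})

test_that("Fisher p-values equal hypergeometric enumeration", {
  expect_equal(fisher_exact_p(matrix(c(3, 1, 1, 3), 2)), 0.4857,
               tolerance = 1e-4)
  expect_equal(fisher_exact_p(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-9)
  set.seed(61)
  for (i in 1:40) {
    m <- matrix(rmultinom(1, sample(8:30, 1), rep(0.25, 4)), 2)
    expect_equal(fisher_exact_p(m), fisher_oracle(m), tolerance = 1e-9)
  }
  # zero margin is degenerate
  expect_equal(fisher_exact_p(matrix(c(0, 0, 3, 5), 2, byrow = TRUE)), 1)
})

test_that("odds-ratio CIs reproduce the published region contrasts", {
  tabs <- region_contrast_tables(usv_response_counts())
  printed <- list(
    m2_responsive = c(1.28, 2.84),
    m1_excitatory = c(0.29, 0.88),
    m1_inhibitory = c(1.02, 2.91),
    m1_e1 = c(0.25, 0.89),
    m2_e1 = c(0.19, 0.84))
  for (nm in names(printed)) {
    ci <- odds_ratio_ci(tabs[[nm]])
    expect_equal(round(c(ci$lower, ci$upper), 2), printed[[nm]])
  }
  # balanced table: OR 1, CI symmetric on the log scale
  ci1 <- odds_ratio_ci(matrix(1, 2, 2))
  expect_equal(ci1$or, 1)
  expect_equal(log(ci1$upper), -log(ci1$lower))
  # zero cell triggers the continuity correction
  ci0 <- odds_ratio_ci(matrix(c(5, 0, 3, 4), 2))
  expect_true(ci0$continuity_corrected)
  expect_true(is.finite(ci0$upper))
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(0.02, 2), 0.04)
  expect_equal(bonferroni_adjust(0.7, 4), 1)
  # boundary semantics: 0.0125 * 4 = 0.05 is NOT < 0.05
  expect_false(bonferroni_adjust(0.0125, 4) < 0.05)
  expect_error(bonferroni_adjust(0.5, 0), "repetitions")
})

test_that("mean auROC responses average the aligned window", {
  flat <- rep(0.5, 40)
  expect_equal(mean_auroc_response(flat), 0.5)
  stepped <- replace(flat, 16:25, 0.8)
  expect_equal(mean_auroc_response(stepped), 0.8)
  expect_equal(mean_auroc_response(stepped, window = c(-0.5, -0.25)), 0.5)
  expect_error(mean_auroc_response(stepped, window = c(-0.26, 0.25)),
               "align")
  expect_error(mean_auroc_response(rep(0.5, 30)), "grid")
})

test_that("permutation median test matches full enumeration", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  # independent oracle: enumerate all C(6, 3) = 20 label splits
  pooled <- c(a, b)
  splits <- combn(6, 3)
  perm_stats <- apply(splits, 2, function(ix)
    median(pooled[ix]) - median(pooled[-ix]))
  p_oracle <- mean(abs(perm_stats) >= abs(median(a) - median(b)))
  r <- permutation_median_test(a, b, seed = 1)
  expect_identical(r$method, "exact")
  expect_equal(r$p.value, p_oracle)
  expect_equal(p_oracle, 4 / 20)  # the two extreme splits and one tied pair
  expect_equal(r$statistic, -10)
  expect_true(r$ci[1] <= r$statistic && r$statistic <= r$ci[2])

  same <- permutation_median_test(c(1, 5, 9, 2), c(1, 5, 9, 2), seed = 1)
  expect_equal(same$statistic, 0)
  expect_gt(same$p.value, 0.9)

  expect_error(permutation_median_test(1, c(1, 2)), ">= 2")
  expect_identical(
    permutation_median_test(rnorm(30), rnorm(30), n_perm = 50,
                            seed = 2)$warning,
    "n_perm < 100: p-value resolution is coarse")
})

test_that("permutation test has power for a 1 SD median shift", {
  set.seed(62)
  hits <- vapply(1:20, function(i) {
    a <- rnorm(30)
    b <- rnorm(30, mean = 1)
    permutation_median_test(a, b, n_perm = 1000, n_boot = 200,
                            seed = i)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("count tables cross-tabulate with derived margins", {
  counts <- usv_response_counts()
  expect_identical(as.integer(rowSums(counts)), c(855L, 266L, 737L, 168L))
  expect_identical(sum(counts), 2026L)

  type <- rep(colnames(counts), counts["M1-A", ])
  built <- build_count_table(type, rep("M1-A", length(type)))
  expect_identical(unname(built["M1-A", colnames(counts)]),
                   unname(counts["M1-A", ]))
  expect_identical(unname(attr(built, "responsive")), 271L)
  expect_identical(unname(attr(built, "total")), 855L)

  empty <- build_count_table(character(0), character(0))
  expect_identical(sum(empty), 0L)
  expect_error(build_count_table(c("E1", NA), c("M1-A", "M1-A")), "labeled")
})
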