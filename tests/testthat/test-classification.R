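test_that("feature construction follows the PCA + log-rate recipe", {
  set.seed(41)
  V <- matrix(runif(100 * 25, 0.2, 0.8), 100)
  rates <- runif(100, 0.5, 20)
  bf <- build_features(V, rates)
  expect_identical(dim(bf$features), c(100L, 4L))
  expect_equal(unname(colMeans(bf$features)), rep(0, 4), tolerance = 1e-10)
  expect_equal(unname(apply(bf$features, 2, sd)), rep(1, 4),
               tolerance = 1e-10)
  # reconstruction from all PCs is exact; 3-PC share equals eigenvalue share
  rec <- bf$pca$x %*% t(bf$pca$rotation) +
    matrix(bf$pca$center, 100, 25, byrow = TRUE)
  expect_equal(rec, V, ignore_attr = TRUE)
  evar <- bf$pca$sdev^2
  expect_equal(sum(evar[1:3]) / sum(evar),
               sum(apply(bf$pca$x[, 1:3], 2, var)) / sum(apply(V, 2, var)))

  # degenerate inputs are rejected
  expect_error(build_features(V[1:3, ], rates[1:3]), "at least 4")
  expect_error(build_features(matrix(0.5, 10, 25), rates[1:10]),
               "zero-variance")

  # variance along one axis only: PC1 captures ~100%
  V1 <- matrix(0.5, 50, 25)
  V1[, 3] <- seq(0, 1, length.out = 50)
  V1 <- V1 + matrix(rnorm(50 * 25, sd = 1e-6), 50)
  p1 <- prcomp(V1)
  expect_gt(p1$sdev[1]^2 / sum(p1$sdev^2), 0.999)
})

test_that("the 2-D embedding is deterministic and preserves planted clusters", {
  set.seed(42)
  centers <- rbind(c(5, 0, 0, 0), c(0, 5, 0, 0), c(0, 0, 5, 0))
  X <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(40 * 4, sd = 0.3), 40), 2, centers[k, ], `+`)))
  labels <- rep(1:3, each = 40)
  y1 <- embed_2d(X, perplexity = 15, seed = 0)
  y2 <- embed_2d(X, perplexity = 15, seed = 0)
  expect_identical(y1, y2)
  expect_gt(silhouette_oracle(y1, labels), 0.5)
  expect_error(embed_2d(X, perplexity = 100), "perplexity")

  # duplicated rows embed to nearly coincident points
  Xd <- rbind(X, X[1, , drop = FALSE])
  yd <- embed_2d(Xd, perplexity = 15, seed = 0)
  d_dup <- sqrt(sum((yd[121, ] - yd[1, ])^2))
  spread <- mean(sqrt(rowSums(sweep(yd, 2, colMeans(yd))^2)))
  expect_lt(d_dup, spread * 0.05)
})

test_that("watershed separates distant blobs and keeps one blob whole", {
  set.seed(43)
  blob <- function(cx, cy, n = 200) cbind(rnorm(n, cx), rnorm(n, cy))
  two <- rbind(blob(-6, 0), blob(6, 0))
  lab <- density_watershed(two)
  expect_identical(length(unique(lab)), 2L)
  planted <- rep(1:2, each = 200)
  # ≤ 2% mixing up to label permutation
  tab <- table(planted, lab)
  expect_gte(sum(apply(tab, 1, max)) / 400, 0.98)

  one <- blob(0, 0, 300)
  expect_identical(length(unique(density_watershed(one, sigma_bins = 4))), 1L)

  # labels invariant to point-order permutation
  perm <- sample(400)
  lab_p <- density_watershed(two[perm, ])
  expect_true(all(table(lab[perm], lab_p)[table(lab[perm], lab_p) > 0] ==
                    apply(table(lab[perm], lab_p), 1, max)))

  expect_identical(density_watershed(matrix(1, 5, 2))[1:5], rep(1L, 5))
})

test_that("cluster naming reflects sign and duration of the mean response", {
  post <- c(11:15, 21:25)
  mk <- function(dev, cols = post) {
    v <- rep(0.5, 25); v[cols] <- 0.5 + dev; v
  }
  V <- rbind(
    matrix(mk(0.3), 10, 25, byrow = TRUE),          # sustained excitation
    matrix(mk(0.3, 11:12), 10, 25, byrow = TRUE),   # transient excitation
    matrix(mk(-0.3), 10, 25, byrow = TRUE),         # inhibition
    matrix(mk(0.0), 10, 25, byrow = TRUE))          # flat -> O
  labels <- rep(1:4, each = 10)
  ty <- name_types(labels, V)
  nm <- attr(ty, "cluster_names")
  expect_identical(unname(nm[c("1", "2")]), c("E1", "E2"))  # sustained first
  expect_identical(unname(nm[["3"]]), "I1")
  expect_identical(unname(nm[["4"]]), "O")
})
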