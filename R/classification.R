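#' Build the feature matrix for response-type discovery
#'
#' PCA (centered, unscaled) is fitted on the 25-dimensional response vectors
#' of all responsive units; the first three principal-component scores plus
#' the common logarithm of the baseline firing rate form the feature matrix,
#' and each column is z-scored. Baseline rates are floored at 0.01 spikes/s
#' before taking log10.
#'
#' @param vectors25 Numeric matrix, units x 25 response-vector entries.
#' @param baseline_rates Baseline firing rates (spikes/s), one per unit.
#' @return List with `features` (units x 4 z-scored matrix, columns PC1-PC3
#'   and `log10_rate`) and `pca` (the `prcomp` fit).
#' @export
build_features <- function(vectors25, baseline_rates) {
  vectors25 <- as.matrix(vectors25)
  if (nrow(vectors25) < 4) stop("need at least 4 responsive units")
  if (ncol(vectors25) != 25) stop("response vectors must have 25 columns")
  if (length(baseline_rates) != nrow(vectors25))
    stop("one baseline rate per unit is required")
  pca <- stats::prcomp(vectors25, center = TRUE, scale. = FALSE)
  feats <- cbind(pca$x[, 1:3, drop = FALSE],
                 log10_rate = log10(pmax(baseline_rates, 0.01)))
  colnames(feats) <- c("PC1", "PC2", "PC3", "log10_rate")
  sds <- apply(feats, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance feature column (degenerate input): ",
         paste(colnames(feats)[sds == 0], collapse = ", "))
  feats <- scale(feats)
  attr(feats, "scaled:center") <- NULL
  attr(feats, "scaled:scale") <- NULL
  list(features = feats, pca = pca)
}

#' Embed the feature matrix in two dimensions with t-SNE
#'
#' Exact t-SNE (theta = 0) with PCA initialization, so a fixed seed gives
#' identical coordinates across runs.
#'
#' @param features Units x d feature matrix (z-scored).
#' @param perplexity t-SNE perplexity (requires `nrow >= 3 * perplexity + 1`).
#' @param seed Integer seed.
#' @param max_iter Number of gradient iterations.
#' @return Units x 2 matrix of embedding coordinates.
#' @export
embed_2d <- function(features, perplexity = 30, seed = 0, max_iter = 1000) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n < 3 * perplexity + 1)
    stop("perplexity too large for ", n, " rows")
  set.seed(seed)
  p <- stats::prcomp(features, center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(p$x))
  init <- p$x[, seq_len(k), drop = FALSE]
  if (k < 2) init <- cbind(init, 0)
  init <- init / stats::sd(init[, 1]) * 1e-4
  fit <- Rtsne::Rtsne(features, dims = 2, perplexity = perplexity,
                      theta = 0, max_iter = max_iter, Y_init = init,
                      pca = FALSE, check_duplicates = FALSE, verbose = FALSE)
  fit$Y
}

#' Watershed segmentation of the embedded density
#'
#' Builds a 2-D histogram of the embedding on a square grid (square bounding
#' box over the larger axis span, padded by 5%, so grid cells are square in
#' data units), smooths it with a Gaussian filter, and applies a watershed
#' transform to the smoothed density. Each unit is labeled by the basin
#' containing its grid cell; units falling on ridge lines or in basins that
#' contain no other unit's peak are assigned to the nearest unit-occupied
#' basin centroid. Labels are relabeled to contiguous integers, largest
#' basin first.
#'
#' @param coords Units x 2 embedding coordinates.
#' @param grid_size Histogram grid resolution per axis (default 100).
#' @param sigma_bins Gaussian smoothing SD in grid bins (default 2).
#' @param tolerance_frac Watershed merge tolerance as a fraction of the peak
#'   smoothed density (default 0.2); basins whose peak rises less than this
#'   above a contact point are merged.
#' @return Integer vector of basin labels (1..K), one per unit, with
#'   attribute `density` (the smoothed grid).
#' @export
density_watershed <- function(coords, grid_size = 100, sigma_bins = 2,
                              tolerance_frac = 0.2) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 units")
  rng_x <- range(coords[, 1]); rng_y <- range(coords[, 2])
  if (diff(rng_x) == 0 && diff(rng_y) == 0)
    return(structure(rep(1L, n), density = NULL))
  # square cells: both axes use the larger span, so the smoothing sigma has
  # the same extent in data units in x and y
  span <- max(diff(rng_x), diff(rng_y), .Machine$double.eps)
  expand <- function(r) mean(r) + c(-0.5, 0.5) * span * 1.05
  rng_x <- expand(rng_x); rng_y <- expand(rng_y)
  gx <- seq(rng_x[1], rng_x[2], length.out = grid_size + 1)
  gy <- seq(rng_y[1], rng_y[2], length.out = grid_size + 1)
  ix <- pmin(pmax(findInterval(coords[, 1], gx, all.inside = TRUE), 1),
             grid_size)
  iy <- pmin(pmax(findInterval(coords[, 2], gy, all.inside = TRUE), 1),
             grid_size)
  h <- matrix(0, grid_size, grid_size)
  for (k in seq_len(n)) h[ix[k], iy[k]] <- h[ix[k], iy[k]] + 1
  sm <- as.matrix(EBImage::gblur(EBImage::as.Image(h), sigma = sigma_bins))
  ws <- EBImage::watershed(EBImage::as.Image(sm),
                           tolerance = tolerance_frac * max(sm), ext = 1)
  lab_grid <- as.matrix(ws)
  labs <- lab_grid[cbind(ix, iy)]

  # basins actually carrying units, ordered by unit count
  tab <- sort(table(labs[labs > 0]), decreasing = TRUE)
  keep <- as.integer(names(tab))
  if (length(keep) == 0) return(structure(rep(1L, n), density = sm))
  # centroid (in grid coordinates, density-weighted) of each kept basin
  cent <- t(vapply(keep, function(l) {
    cells <- which(lab_grid == l, arr.ind = TRUE)
    w <- sm[cells]
    c(sum(cells[, 1] * w), sum(cells[, 2] * w)) / sum(w)
  }, numeric(2)))
  out <- match(labs, keep)
  orphan <- which(is.na(out))
  for (k in orphan) {
    d2 <- (cent[, 1] - ix[k])^2 + (cent[, 2] - iy[k])^2
    out[k] <- which.min(d2)
  }
  structure(as.integer(out), density = sm)
}

#' Name discovered response-type clusters
#'
#' Each cluster is named from its mean response vector: excitatory (`E`) when
#' the mean post-onset auROC exceeds 0.5 by more than `delta`, inhibitory
#' (`I`) when it falls below 0.5 by more than `delta`, and `O` otherwise.
#' Within the E and I families, clusters are numbered by descending response
#' duration (number of vector entries deviating from 0.5 in the family's
#' direction), so sustained types come before transient ones.
#'
#' @param labels Integer cluster labels (1..K), one per unit.
#' @param vectors25 Units x 25 response-vector matrix.
#' @param delta auROC deviation defining an excitatory/inhibitory cluster
#'   (default 0.05).
#' @return Character vector of type names per unit, with attribute
#'   `cluster_names` (named character vector, one entry per cluster label).
#' @export
name_types <- function(labels, vectors25, delta = 0.05) {
  vectors25 <- as.matrix(vectors25)
  stopifnot(length(labels) == nrow(vectors25))
  post_cols <- c(11:15, 21:25)  # post-onset bins of both vector segments
  ks <- sort(unique(labels))
  mean_dev <- vapply(ks, function(k) {
    mean(colMeans(vectors25[labels == k, , drop = FALSE])[post_cols]) - 0.5
  }, numeric(1))
  duration <- vapply(seq_along(ks), function(i) {
    m <- colMeans(vectors25[labels == ks[i], , drop = FALSE]) - 0.5
    sum(sign(m) == sign(mean_dev[i]) & abs(m) > delta)
  }, numeric(1))
  family <- ifelse(mean_dev > delta, "E", ifelse(mean_dev < -delta, "I", "O"))
  cluster_names <- character(length(ks))
  for (fam in c("E", "I")) {
    idx <- which(family == fam)
    if (length(idx) == 0) next
    ord <- idx[order(-duration[idx], -abs(mean_dev[idx]))]
    cluster_names[ord] <- paste0(fam, seq_along(ord))
  }
  o_idx <- which(family == "O")
  cluster_names[o_idx] <- if (length(o_idx) == 1) "O" else
    paste0("O", seq_along(o_idx))
  names(cluster_names) <- ks
  structure(cluster_names[match(labels, ks)], cluster_names = cluster_names)
}

#' Discover response types from response vectors
#'
#' End-to-end unsupervised typing of responsive units: feature construction
#' ([build_features()]), 2-D embedding ([embed_2d()]), watershed segmentation
#' of the embedded density ([density_watershed()]) and cluster naming
#' ([name_types()]).
#'
#' @inheritParams build_features
#' @inheritParams embed_2d
#' @inheritParams density_watershed
#' @inheritParams name_types
#' @return List with `features`, `coords`, `labels`, `type` (per-unit type
#'   name) and `cluster_names`.
#' @export
classify_response_types <- function(vectors25, baseline_rates,
                                    perplexity = 30, seed = 0,
                                    grid_size = 100, sigma_bins = 2,
                                    tolerance_frac = 0.2, delta = 0.05) {
  bf <- build_features(vectors25, baseline_rates)
  coords <- embed_2d(bf$features, perplexity = perplexity, seed = seed)
  labels <- density_watershed(coords, grid_size = grid_size,
                              sigma_bins = sigma_bins,
                              tolerance_frac = tolerance_frac)
  types <- name_types(labels, vectors25, delta = delta)
  list(features = bf$features, coords = coords, labels = labels,
       type = as.character(types),
       cluster_names = attr(types, "cluster_names"))
}
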