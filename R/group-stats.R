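#' Reference counts of USV response types by motor-cortex subregion
#'
#' Published survey counts of rat motor-cortex neurons by response type
#' (E1, E2, I1-I4, O, NR) in the anterior and posterior parts of M1 and M2,
#' used by the worked examples and the group-statistics demonstrations.
#' Rows: M1-A, M1-P, M2-A, M2-P.
#'
#' @return Integer matrix 4 x 8 with region-part rownames and type colnames.
#' @examples
#' counts <- usv_response_counts()
#' rowSums(counts)   # neurons recorded per area
#' @export
usv_response_counts <- function() {
  m <- rbind(
    `M1-A` = c(36, 29, 54, 35, 33, 22, 62, 584),
    `M1-P` = c(18, 10, 14,  8,  4,  3, 16, 193),
    `M2-A` = c(46, 45, 51, 22, 29, 11, 48, 485),
    `M2-P` = c(13,  3, 11,  2,  0,  1,  6, 132))
  colnames(m) <- c("E1", "E2", "I1", "I2", "I3", "I4", "O", "NR")
  storage.mode(m) <- "integer"
  m
}

#' Assign a recording site to the anterior or posterior part
#'
#' The motor cortex is divided at AP = +1.5 mm from bregma: sites anterior
#' to the boundary (`ap > 1.5`) are `"anterior"`, the boundary itself and
#' everything behind it `"posterior"`.
#'
#' @param ap Anterior-posterior coordinate(s) in mm.
#' @param boundary Division boundary in mm (default 1.5).
#' @return Character vector `"anterior"`/`"posterior"`.
#' @export
assign_part <- function(ap, boundary = 1.5) {
  ifelse(ap > boundary, "anterior", "posterior")
}

#' Two-sided Fisher's exact test p-value for a 2 x 2 table
#'
#' The two-sided p-value sums the hypergeometric probabilities of all tables
#' (with margins fixed) that are no more probable than the observed one.
#' A table with a zero margin is degenerate and returns p = 1.
#'
#' @param x 2 x 2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact_p(matrix(c(252, 36, 485, 132), 2))
#' @export
fisher_exact_p <- function(x) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2, 2)) || any(x < 0))
    stop("`x` must be a 2 x 2 matrix of non-negative counts")
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) return(1)
  stats::fisher.test(x)$p.value
}

#' Sample odds ratio with Woolf log-normal confidence interval
#'
#' OR = ad/bc with the CI `exp(log OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#' If any cell is zero, a 0.5 continuity correction is added to every cell
#' before computing both the estimate and the interval.
#'
#' @param x 2 x 2 matrix: rows are groups, columns outcome/complement.
#' @param level Confidence level (default 0.95).
#' @return List with `or`, `lower`, `upper`, `level`, and
#'   `continuity_corrected`.
#' @examples
#' odds_ratio_ci(matrix(c(252, 36, 485, 132), 2))
#' @export
odds_ratio_ci <- function(x, level = 0.95) {
  x <- as.matrix(x)
  if (!all(dim(x) == c(2, 2)) || any(x < 0))
    stop("`x` must be a 2 x 2 matrix of non-negative counts")
  corrected <- any(x == 0)
  if (corrected) x <- x + 0.5
  a <- x[1, 1]; b <- x[1, 2]; c <- x[2, 1]; d <- x[2, 2]
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = or, lower = exp(log(or) - z * se), upper = exp(log(or) + z * se),
       level = level, continuity_corrected = corrected)
}

#' Bonferroni adjustment
#'
#' Multiplies p-values by the number of repetitions, capping at 1.
#'
#' @param p Numeric vector of p-values.
#' @param repetitions Number of comparisons in the family (>= 1).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, repetitions) {
  if (repetitions < 1) stop("`repetitions` must be >= 1")
  pmin(p * repetitions, 1)
}

#' Mean auROC response in a peri-onset window
#'
#' Averages the auROC time course over the bins covering the given window
#' (default -0.25 to +0.25 s) on the standard 50 ms grid over -1 to +1 s.
#' The window must align with the bin grid.
#'
#' @param auroc_course Length-40 auROC time course.
#' @param window Window in seconds relative to onset.
#' @return Scalar mean auROC.
#' @export
mean_auroc_response <- function(auroc_course, window = c(-0.25, 0.25)) {
  if (length(auroc_course) != 40)
    stop("auROC time course must be on the 40-bin grid")
  edges <- seq(-1, 1, by = 0.05)
  i0 <- match(TRUE, abs(edges - window[1]) < 1e-9)
  i1 <- match(TRUE, abs(edges - window[2]) < 1e-9)
  if (is.na(i0) || is.na(i1) || i1 <= i0)
    stop("`window` does not align with the 50 ms bin grid")
  mean(auroc_course[i0:(i1 - 1)])
}

#' Permutation test for a difference of medians with bootstrap CI
#'
#' The statistic is `median(a) - median(b)`. The two-sided p-value permutes
#' group labels (full enumeration when the number of distinct splits does
#' not exceed `n_perm`, Monte-Carlo with the +1/(n+1) correction otherwise)
#' and the confidence interval is the bootstrap percentile interval of the
#' median difference under independent resampling of both groups.
#'
#' @param a,b Numeric samples (each length >= 2).
#' @param n_perm Number of label permutations (default 5000).
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return List of class `estimation_result`: `statistic`, `p.value`, `ci`,
#'   `method`, `n_perm`, `n_boot`, `seed`, and `warning` (set when
#'   `n_perm < 100`).
#' @export
permutation_median_test <- function(a, b, n_perm = 5000, n_boot = 5000,
                                    level = 0.95, seed = 0) {
  if (length(a) < 2 || length(b) < 2) stop("both groups need >= 2 values")
  set.seed(seed)
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  obs <- stats::median(a) - stats::median(b)
  n_splits <- choose(na + nb, na)
  if (n_splits <= n_perm) {
    splits <- utils::combn(na + nb, na)
    perm <- apply(splits, 2, function(ix)
      stats::median(pooled[ix]) - stats::median(pooled[-ix]))
    p <- mean(abs(perm) >= abs(obs) - 1e-12)
    method <- "exact"
  } else {
    perm <- replicate(n_perm, {
      ix <- sample.int(na + nb, na)
      stats::median(pooled[ix]) - stats::median(pooled[-ix])
    })
    p <- (sum(abs(perm) >= abs(obs) - 1e-12) + 1) / (n_perm + 1)
    method <- "sampled"
  }
  boot <- replicate(n_boot, {
    stats::median(sample(a, na, replace = TRUE)) -
      stats::median(sample(b, nb, replace = TRUE))
  })
  alpha <- 1 - level
  ci <- unname(stats::quantile(boot, c(alpha / 2, 1 - alpha / 2)))
  structure(list(statistic = obs, p.value = p, ci = ci, method = method,
                 n_perm = n_perm, n_boot = n_boot, seed = seed,
                 warning = if (n_perm < 100)
                   "n_perm < 100: p-value resolution is coarse" else NULL),
            class = "estimation_result")
}

#' Cross-tabulate units by region-part and response type
#'
#' Builds the counts-by-area table feeding the contingency statistics.
#' Every unit must carry a type label and a region-part assignment.
#'
#' @param type Character vector of type labels (E1, E2, I1-I4, O, NR, or any
#'   subset; unseen canonical types get zero columns).
#' @param region_part Character vector like `"M1-A"`, `"M2-P"` (any set of
#'   row labels is accepted).
#' @param type_levels Column order (default the canonical eight types).
#' @return Integer matrix rows = region-parts, columns = types, with
#'   attributes `responsive` and `total` (per-row derived counts).
#' @export
build_count_table <- function(type, region_part,
                              type_levels = c("E1", "E2", "I1", "I2", "I3",
                                              "I4", "O", "NR")) {
  if (length(type) != length(region_part))
    stop("`type` and `region_part` must have equal length")
  if (any(is.na(type)) || any(is.na(region_part)))
    stop("every unit must be labeled")
  extra <- setdiff(unique(type), type_levels)
  lv <- c(type_levels, sort(extra))
  tb <- table(factor(region_part), factor(type, levels = lv))
  m <- matrix(as.integer(tb), nrow(tb), ncol(tb),
              dimnames = dimnames(tb))
  total <- as.integer(rowSums(m))
  names(total) <- rownames(m)
  responsive <- total - (if ("NR" %in% colnames(m)) m[, "NR"] else 0L)
  attr(m, "total") <- total
  attr(m, "responsive") <- structure(as.integer(responsive),
                                     names = rownames(m))
  m
}

#' The five region-contrast 2 x 2 tables derived from a count table
#'
#' From a counts-by-area matrix (rows `M1-A`, `M1-P`, `M2-A`, `M2-P`;
#' columns the eight types) builds the standard anterior-vs-posterior
#' contrasts: responsive vs nonresponsive neurons per region, excitatory
#' (E1+E2) and inhibitory (I1-I4) neurons among responsive ones in M1, and
#' type-E1 neurons among responsive ones in M1 and M2. Rows of each 2 x 2
#' table are anterior/posterior, columns are the focal category and its
#' complement.
#'
#' @param counts Count matrix as from [usv_response_counts()] or
#'   [build_count_table()].
#' @return Named list of 2 x 2 matrices: `m1_responsive`, `m2_responsive`,
#'   `m1_excitatory`, `m1_inhibitory`, `m1_e1`, `m2_e1`.
#' @export
region_contrast_tables <- function(counts) {
  need <- c("M1-A", "M1-P", "M2-A", "M2-P")
  if (!all(need %in% rownames(counts)))
    stop("`counts` must have rows ", paste(need, collapse = ", "))
  resp_cols <- setdiff(colnames(counts), "NR")
  resp <- rowSums(counts[, resp_cols, drop = FALSE])
  two_by_two <- function(a_focal, a_other, p_focal, p_other) {
    matrix(c(a_focal, p_focal, a_other, p_other), 2, 2,
           dimnames = list(c("anterior", "posterior"),
                           c("focal", "other")))
  }
  out <- list()
  for (reg in c("M1", "M2")) {
    a <- paste0(reg, "-A"); p <- paste0(reg, "-P")
    out[[paste0(tolower(reg), "_responsive")]] <-
      two_by_two(resp[a], counts[a, "NR"], resp[p], counts[p, "NR"])
  }
  e_cols <- intersect(c("E1", "E2"), colnames(counts))
  i_cols <- intersect(c("I1", "I2", "I3", "I4"), colnames(counts))
  a <- "M1-A"; p <- "M1-P"
  eA <- sum(counts[a, e_cols]); eP <- sum(counts[p, e_cols])
  iA <- sum(counts[a, i_cols]); iP <- sum(counts[p, i_cols])
  out$m1_excitatory <- two_by_two(eA, resp[a] - eA, eP, resp[p] - eP)
  out$m1_inhibitory <- two_by_two(iA, resp[a] - iA, iP, resp[p] - iP)
  for (reg in c("M1", "M2")) {
    a <- paste0(reg, "-A"); p <- paste0(reg, "-P")
    out[[paste0(tolower(reg), "_e1")]] <-
      two_by_two(counts[a, "E1"], resp[a] - counts[a, "E1"],
                 counts[p, "E1"], resp[p] - counts[p, "E1"])
  }
  out
}
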