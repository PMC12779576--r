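#' Half-swap permutation test for comparing brain measures
#'
#' Tests whether an effect estimated on measure X differs from the effect
#' estimated on measure Y when both are observed on the same individuals.
#' X and Y are first standardized to a common scale (z-scores for
#' parametric statistics, ranks for non-parametric ones), pooling X and Y
#' per column so both live on one scale. Each permutation then replaces a
#' random half (floor(n/2)) of X's observations with the corresponding
#' observations of Y — independently per column when X and Y are matrices —
#' and re-evaluates the statistic, building a null that embodies "it does
#' not matter whether an observation belongs to X or Y". The p-value is the
#' proportion of permuted statistics at or above the empirical one.
#'
#' @param X,Y Numeric vectors or matrices of identical shape.
#' @param statistic Function mapping a standardized X-shaped input to a
#'   scalar. Wrap in `abs()` if the sign is not of interest.
#' @param n_perm Number of permutations (default 10000).
#' @param standardization `"zscore"` or `"rank"`.
#' @param seed RNG seed.
#' @return A `half_swap_result`: `statistic` (empirical), `null`
#'   (permuted statistics), `p`, `n_perm`, `standardization`.
#' @export
half_swap_perm_test <- function(X, Y, statistic, n_perm = 10000,
                                standardization = c("zscore", "rank"),
                                seed = 1L) {
  standardization <- match.arg(standardization)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (!identical(dim(X), dim(Y))) abort("X and Y must have the same shape.")
  n <- nrow(X)
  if (n < 2L) abort("need n >= 2 observations.")
  vector_input <- ncol(X) == 1L
  # pool X and Y per column onto one scale
  for (j in seq_len(ncol(X))) {
    pooled <- c(X[, j], Y[, j])
    std <- if (standardization == "zscore") {
      (pooled - mean(pooled)) / sd(pooled)
    } else {
      rank(pooled)
    }
    X[, j] <- std[seq_len(n)]
    Y[, j] <- std[n + seq_len(n)]
  }
  eval_stat <- function(m) statistic(if (vector_input) m[, 1] else m)
  emp <- eval_stat(X)
  set.seed(seed)
  k <- floor(n / 2)
  null <- vapply(seq_len(n_perm), function(i) {
    Xb <- X
    for (j in seq_len(ncol(X))) {
      rows <- sample.int(n, k)
      Xb[rows, j] <- Y[rows, j]
    }
    eval_stat(Xb)
  }, numeric(1))
  structure(list(statistic = emp, null = null,
                 p = mean(null >= emp), n_perm = n_perm,
                 standardization = standardization),
            class = "half_swap_result")
}

#' @export
print.half_swap_result <- function(x, ...) {
  cat(sprintf("<half_swap_result> statistic = %.4f, p = %.4g (%d perms)\n",
              x$statistic, x$p, x$n_perm))
  invisible(x)
}

#' @export
glance.half_swap_result <- function(x, ...) {
  tibble(statistic = x$statistic, p = x$p, n_perm = x$n_perm,
         null_mean = mean(x$null), null_sd = sd(x$null))
}

#' Williams' test for two dependent correlations sharing a variable
#'
#' Tests whether two variables (e.g. two brain measures) are equally
#' correlated with a third (e.g. age) when all three are observed on the
#' same n individuals: H0 rho13 = rho23, using the Steiger-modified
#' Williams t with n - 3 degrees of freedom. With `absolute = TRUE` the
#' comparison is between absolute effect sizes: both correlations are
#' reflected to be positive and the sign flips are propagated into r12.
#'
#' @param r12 Correlation between the two compared variables.
#' @param r13,r23 Correlations of each compared variable with the third.
#' @param n Sample size (>= 4).
#' @param absolute Compare absolute effect sizes (default `FALSE`).
#' @return A one-row tibble: `t`, `df`, `p`, plus the (possibly
#'   reflected) correlations used.
#' @export
williams_test <- function(r12, r13, r23, n, absolute = FALSE) {
  for (r in c(r12, r13, r23)) {
    if (!is.finite(r) || abs(r) > 1) abort("correlations must be in [-1, 1].")
  }
  if (n < 4L) abort("need n >= 4.")
  if (absolute) {
    r12 <- r12 * sign(r13) * sign(r23)
    r13 <- abs(r13)
    r23 <- abs(r23)
  }
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (detR < -1e-12) abort("degenerate correlation matrix (non-PSD).")
  detR <- max(detR, 0)
  rbar <- (r13 + r23) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r12)^3
  t_stat <- if (denom <= 0) {
    if (r13 == r23) 0 else sign(r13 - r23) * Inf
  } else {
    (r13 - r23) * sqrt(((n - 1) * (1 + r12)) / denom)
  }
  df <- n - 3
  tibble(t = t_stat, df = df, p = 2 * pt(-abs(t_stat), df),
         r12 = r12, r13 = r13, r23 = r23, n = as.integer(n))
}

#' Partial correlation of x and y given z
#'
#' Correlation of x and y after linear removal of z:
#' \eqn{(r_{xy} - r_{xz} r_{yz}) / \sqrt{(1 - r_{xz}^2)(1 - r_{yz}^2)}},
#' identical to correlating the residuals of the two regressions on z.
#'
#' @param x,y,z Numeric vectors of equal length >= 4.
#' @return The partial correlation coefficient.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) abort("equal lengths required.")
  if (n < 4L) abort("need n >= 4.")
  rxy <- cor(x, y)
  rxz <- cor(x, z)
  ryz <- cor(y, z)
  if (abs(rxz) >= 1 || abs(ryz) >= 1) {
    abort("z is collinear with x or y: partial correlation undefined.")
  }
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Fisher r-to-z transform
#'
#' @param r Correlation coefficient(s) in (-1, 1).
#' @return `atanh(r)`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) abort("`r` must lie strictly within (-1, 1).")
  atanh(r)
}

#' Thresholded region-by-region covariance network
#'
#' Pairwise Pearson correlation of regional features over subjects,
#' thresholded to the strongest positive and inverse covariance: only
#' off-diagonal entries at or beyond the upper and lower `percentile` of
#' the off-diagonal distribution are retained; all others become `NA`.
#'
#' @param features A [feature_table()] with >= 3 subjects.
#' @param percentile Tail percentile retained on each side (default 1).
#' @return A region-by-region matrix with suppressed entries `NA` and
#'   attributes `lower_cut` / `upper_cut`.
#' @export
covariance_network <- function(features, percentile = 1) {
  stopifnot(inherits(features, "feature_table"))
  m <- feature_matrix(features)
  if (nrow(m) < 3L) abort("need >= 3 subjects.")
  if (any(apply(m, 2, sd) == 0)) abort("constant region column.")
  cc <- cor(m)
  off <- cc[upper.tri(cc)]
  lo <- quantile(off, percentile / 100)
  hi <- quantile(off, 1 - percentile / 100)
  keep <- (cc <= lo | cc >= hi)
  diag(keep) <- FALSE
  out <- ifelse(keep, cc, NA_real_)
  diag(out) <- NA_real_
  attr(out, "lower_cut") <- unname(lo)
  attr(out, "upper_cut") <- unname(hi)
  out
}
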