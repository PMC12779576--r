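#' Pairwise brain-to-brain dissimilarity
#'
#' The overall shape (or size) difference between two scans is the L1 norm
#' (Manhattan distance) between their regional feature vectors: all regions
#' weigh equally and single-region deviations are not amplified by
#' squaring. The result is a symmetric, zero-diagonal matrix satisfying the
#' triangle inequality.
#'
#' @param features A [feature_table()] without missing values.
#' @return A `dissimilarity_matrix`: symmetric numeric matrix with scan ids
#'   as dimnames and attribute `measure`.
#' @examples
#' ft <- feature_table(tibble::tibble(scan_id = c("a", "b"),
#'                                    r1 = c(1, 2), r2 = c(2, 4)))
#' dissimilarity_matrix(ft)["a", "b"] # |1-2| + |2-4| = 3
#' @export
dissimilarity_matrix <- function(features) {
  stopifnot(inherits(features, "feature_table"))
  m <- feature_matrix(features)
  if (anyNA(m)) abort("feature table contains missing values.")
  d <- as.matrix(dist(m, method = "manhattan"))
  attr(d, "measure") <- attr(features, "measure")
  class(d) <- c("dissimilarity_matrix", class(d))
  d
}

#' Age-matched comparison pairs
#'
#' Unordered pairs of scans whose post-menstrual ages at scan differ by at
#' most `threshold_days` (default 1 day), the matching criterion for all
#' twin analyses. Twin pairs whose own two members were scanned further
#' apart than the threshold are flagged ineligible and excluded from twin
#' analyses.
#'
#' @param metadata A [cohort_metadata()] (one row per scan used).
#' @param threshold_days Maximum scan-age difference in days (default 1).
#' @return A list: `pairs` (tibble of matched scan pairs with an
#'   `is_twin_pair` flag) and `eligible_twin_pairs` /
#'   `excluded_twin_pairs` (pair ids).
#' @export
age_matched_comparisons <- function(metadata, threshold_days = 1) {
  meta <- as_tibble(metadata)
  if (anyNA(meta$scan_age_days)) abort("scan ages must be present.")
  n <- nrow(meta)
  idx <- which(abs(outer(meta$scan_age_days, meta$scan_age_days, "-")) <=
                 threshold_days & upper.tri(matrix(0, n, n)),
               arr.ind = TRUE)
  pairs <- tibble(
    id_a = meta$subject_id[idx[, 1]], id_b = meta$subject_id[idx[, 2]],
    pair_a = meta$twin_pair[idx[, 1]], pair_b = meta$twin_pair[idx[, 2]]) |>
    dplyr::mutate(is_twin_pair = !is.na(.data$pair_a) &
                    !is.na(.data$pair_b) & .data$pair_a == .data$pair_b)
  all_pairs <- unique(stats::na.omit(meta$twin_pair))
  eligible <- pairs$pair_a[pairs$is_twin_pair]
  list(pairs = pairs[, c("id_a", "id_b", "is_twin_pair")],
       eligible_twin_pairs = intersect(all_pairs, eligible),
       excluded_twin_pairs = setdiff(all_pairs, eligible))
}

#' Twin z-score against age-matched unrelated comparisons
#'
#' Standardizes the twin dissimilarity against the distribution of the
#' target's dissimilarities to all age-matched unrelated infants, using
#' the sample (n-1) standard deviation: strongly negative values mean the
#' twin is much more similar to the target than unrelated infants of the
#' same age.
#'
#' @param d_twin Dissimilarity between the target and its twin.
#' @param d_unrelated Dissimilarities between the target and its
#'   age-matched unrelated comparisons (length >= 2).
#' @return The z-score.
#' @examples
#' twin_zscore(1, c(3, 5)) # (1 - 4) / sqrt(2)
#' @export
twin_zscore <- function(d_twin, d_unrelated) {
  if (length(d_unrelated) < 2L) abort("need >= 2 unrelated comparisons.")
  s <- sd(d_unrelated)
  if (s == 0) abort("zero s.d. among unrelated comparisons.")
  (d_twin - mean(d_unrelated)) / s
}

#' Identify twins from brain-shape dissimilarity
#'
#' For every eligible twin pair and both directions (A identifying B, B
#' identifying A), the candidate set is the target's twin plus all
#' age-matched unrelated infants; the candidate with the lowest
#' dissimilarity to the target is predicted to be the twin. A prediction is
#' correct only when the twin is the strict unique minimum. The rank loss
#' is the proportion of unrelated candidates at least as similar to the
#' target as the twin (ties count against identification); per-prediction
#' chance is one over the number of candidates.
#'
#' @param dissim A [dissimilarity_matrix()] over one scan per subject.
#' @param metadata Matching [cohort_metadata()].
#' @param threshold_days Age-matching threshold in days (default 1).
#' @return A `twin_prediction` object: per-prediction tibble
#'   (`target`, `twin`, `pair`, `zygosity`, `n_candidates`, `d_twin`,
#'   `rank_loss`, `correct`, `chance`, `z`), overall `accuracy`, and the
#'   number of predictions.
#' @export
identify_twins <- function(dissim, metadata, threshold_days = 1) {
  stopifnot(inherits(dissim, "dissimilarity_matrix"))
  meta <- as_tibble(metadata)
  ids <- rownames(dissim)
  key <- if (all(ids %in% meta$subject_id)) meta$subject_id else
    paste(meta$subject_id, meta$session_id, sep = "_")
  if (!all(ids %in% key)) {
    abort("dissimilarity ids not found in metadata.")
  }
  meta <- meta[match(ids, key), ]
  preds <- list()
  pair_ids <- unique(stats::na.omit(meta$twin_pair))
  for (pid in pair_ids) {
    members <- which(meta$twin_pair == pid)
    if (length(members) != 2L) next
    if (abs(diff(meta$scan_age_days[members])) > threshold_days) next
    for (ord in list(members, rev(members))) {
      target <- ord[1]
      twin <- ord[2]
      unrel <- which(
        abs(meta$scan_age_days - meta$scan_age_days[target]) <=
          threshold_days &
          (is.na(meta$twin_pair) | meta$twin_pair != pid))
      if (length(unrel) < 1L) next
      d_t <- dissim[target, twin]
      d_u <- dissim[target, unrel]
      zyg <- meta$zygosity[target]
      target_id <- ids[target]
      twin_id <- ids[twin]
      preds[[length(preds) + 1L]] <- tibble(
        target = target_id, twin = twin_id, pair = pid,
        zygosity = zyg,
        n_candidates = length(unrel) + 1L,
        d_twin = d_t,
        rank_loss = sum(d_u <= d_t) / length(unrel),
        correct = all(d_u > d_t),
        chance = 1 / (length(unrel) + 1L),
        z = if (length(unrel) >= 2L) twin_zscore(d_t, d_u) else NA_real_)
    }
  }
  if (length(preds) == 0L) abort("no eligible twin pairs.")
  predictions <- dplyr::bind_rows(preds)
  structure(list(predictions = predictions,
                 accuracy = mean(predictions$correct),
                 n_predictions = nrow(predictions)),
            class = "twin_prediction")
}

#' @export
print.twin_prediction <- function(x, ...) {
  cat(sprintf("<twin_prediction> %d predictions, accuracy %.1f%%\n",
              x$n_predictions, 100 * x$accuracy))
  invisible(x)
}

#' @export
tidy.twin_prediction <- function(x, ...) x$predictions

#' @export
glance.twin_prediction <- function(x, ...) {
  tibble(accuracy = x$accuracy, n_predictions = x$n_predictions,
         mean_chance = mean(x$predictions$chance),
         null_mean = if (!is.null(x$null)) mean(x$null) else NA_real_,
         p_perm = if (!is.null(x$p_perm)) x$p_perm else NA_real_)
}

#' Permutation null for twin identification
#'
#' Candidate counts differ across predictions, so overall chance is not a
#' single number: under the null each prediction's twin receives a uniform
#' random rank among its candidates, and the proportion of rank-one
#' (correct) identifications over all predictions is recorded per shuffle.
#' The p-value is the proportion of null accuracies at or above the
#' empirical accuracy.
#'
#' @param result A `twin_prediction` from [identify_twins()].
#' @param n_perm Number of shuffles (default 5000).
#' @param seed RNG seed.
#' @return `result` with `null` (null accuracies), `null_mean`, `null_sd`
#'   and `p_perm` added.
#' @export
permutation_null <- function(result, n_perm = 5000, seed = 1L) {
  stopifnot(inherits(result, "twin_prediction"))
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  set.seed(seed)
  nc <- result$predictions$n_candidates
  null_acc <- vapply(seq_len(n_perm), function(i) {
    mean(floor(runif(length(nc)) * nc) == 0)
  }, numeric(1))
  result$null <- null_acc
  result$null_mean <- mean(null_acc)
  result$null_sd <- sd(null_acc)
  result$p_perm <- mean(null_acc >= result$accuracy)
  result
}

#' @export
autoplot.twin_prediction <- function(object, ...) {
  df <- object$predictions |>
    dplyr::arrange(.data$rank_loss) |>
    dplyr::mutate(prop = seq_len(dplyr::n()) / dplyr::n())
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank_loss, y = .data$prop)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "rank loss", y = "proportion of predictions") +
    ggplot2::theme_minimal()
}
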