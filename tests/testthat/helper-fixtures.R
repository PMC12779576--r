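# Random solid blob: union of axis-aligned balls on a small lattice.
random_blob <- function(extent = 20L, n_balls = 4L, r_range = c(3, 6)) {
  d <- rep(extent, 3L)
  grid <- array(FALSE, d)
  idx <- arrayInd(seq_len(prod(d)), d)
  for (b in seq_len(n_balls)) {
    centre <- runif(3, 1 + r_range[1], extent - r_range[1])
    r <- runif(1, r_range[1], r_range[2])
    grid[rowSums(sweep(idx, 2, centre)^2) <= r^2] <- TRUE
  }
  if (!any(grid)) grid[extent %/% 2, extent %/% 2, extent %/% 2] <- TRUE
  voxel_mask(grid)
}

# Random sparse mask (possibly disconnected).
random_mask <- function(extent = 12L, density = 0.3) {
  voxel_mask(array(runif(extent^3) < density, rep(extent, 3L)))
}

# Small metadata table with controllable twin structure.
toy_metadata <- function(scan_age_days, twin_pair = NULL,
                         zygosity = NULL, birth_age_weeks = 40) {
  n <- length(scan_age_days)
  cohort_metadata(tibble::tibble(
    subject_id = sprintf("s%02d", seq_len(n)),
    session_id = "ses_1",
    sex = rep(c("female", "male"), length.out = n),
    birth_age_weeks = rep(birth_age_weeks, length.out = n),
    scan_age_days = scan_age_days,
    pregnancy = if (is.null(twin_pair)) "singleton" else
      ifelse(is.na(twin_pair), "singleton", "multifetal"),
    twin_pair = twin_pair %||% rep(NA_character_, n),
    zygosity = zygosity %||% rep("unknown", n)))
}

# One-region feature table: L1 dissimilarity equals |x_i - x_j|.
toy_features <- function(values, ids = sprintf("s%02d", seq_along(values))) {
  feature_table(tibble::tibble(scan_id = ids, region_a = values))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
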