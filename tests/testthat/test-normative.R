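ref_fixture <- function() {
  # four term-term scans with fixed values, one preterm scan
  md <- toy_metadata(c(280, 281, 282, 283, 250),
                     birth_age_weeks = c(39.5, 39.6, 39.8, 40, 32))
  ft <- feature_table(tibble::tibble(
    scan_id = sprintf("s%02d", 1:5),
    r1 = c(1, 2, 3, 4, 9), r2 = c(2, 2, 2, 2, 5), r3 = c(5, 6, 7, 8, 1)))
  list(md = md, ft = ft)
}

test_that("reference profiles are means and s.d. over the term-term group", {
  fx <- ref_fixture()
  ref <- build_reference(fx$ft, fx$md)
  expect_equal(ref$n_reference, 4L)
  expect_equal(ref$profile$mu, c(2.5, 2, 6.5))
  expect_equal(ref$profile$sigma, c(sd(1:4), 0, sd(5:8)))

  # identical reference subjects give zero s.d.
  md2 <- toy_metadata(c(280, 281), birth_age_weeks = c(39.5, 39.8))
  ft2 <- feature_table(tibble::tibble(scan_id = c("s01", "s02"),
                                      r1 = c(1, 1), r2 = c(3, 3)))
  expect_equal(build_reference(ft2, md2)$profile$sigma, c(0, 0))

  # a window excluding everyone is an error
  expect_error(build_reference(fx$ft, fx$md,
                               term_window_days = c(100, 101)),
               "fewer than 2")
})

test_that("departure index hits 0 and 2 at rank identity and reversal", {
  fx <- ref_fixture()
  ref <- build_reference(fx$ft, fx$md)
  mu <- setNames(ref$profile$mu, ref$profile$region)

  expect_equal(departure_index(ref, mu)$d, 0)
  expect_equal(departure_index(ref, -mu)$d, 2)

  # invariant under strictly monotone transforms
  v <- setNames(c(1.1, 0.4, 2.2), ref$profile$region)
  d0 <- departure_index(ref, v)$d
  expect_equal(departure_index(ref, exp(v))$d, d0)
  expect_equal(departure_index(ref, v^3 + 5)$d, d0)
  expect_true(d0 >= 0 && d0 <= 2)

  expect_error(departure_index(ref, setNames(rep(1, 3),
                                             ref$profile$region)),
               "constant")
})

test_that("independent random profiles depart by about 1 on average", {
  set.seed(55)
  p <- 40
  md <- toy_metadata(rep(280, 4), birth_age_weeks = rep(39.6, 4))
  vals <- matrix(rnorm(4 * p), 4, p)
  colnames(vals) <- sprintf("r%02d", 1:p)
  ft <- feature_table(dplyr::bind_cols(
    tibble::tibble(scan_id = sprintf("s%02d", 1:4)),
    tibble::as_tibble(vals)))
  ref <- build_reference(ft, md)
  d <- replicate(400, departure_index(
    ref, setNames(rnorm(p), ref$profile$region))$d)
  expect_lt(abs(mean(d) - 1), 3 * sd(d) / sqrt(400))
})

test_that("norm z-scores standardize against the reference exactly", {
  fx <- ref_fixture()
  ref <- build_reference(fx$ft, fx$md)
  mu <- setNames(ref$profile$mu, ref$profile$region)
  sigma <- setNames(ref$profile$sigma, ref$profile$region)

  z0 <- suppressWarnings(norm_z(ref, mu))
  expect_equal(z0$z[c(1, 3)], c(0, 0))
  expect_true(is.na(z0$z[2])) # zero-sigma region is unscorable
  z1 <- suppressWarnings(norm_z(ref, mu + sigma))
  expect_equal(z1$z[c(1, 3)], c(1, 1))
})

test_that("injected preterm offsets are recovered as mean z-scores", {
  delta <- 1.5
  cfg <- cohort_config(n_subjects = 600, n_regions = 10,
                       preterm_fraction = 0.3,
                       scan_delay_weeks_range = c(0.2, 8),
                       beta_pos_range = c(0, 0), beta_neg_range = c(0, 0),
                       sex_effect_sd = 0, genetic_sd = 0,
                       twin_fraction = 0, longitudinal_fraction = 0,
                       preterm_fd_offset_sd = delta, seed = 21)
  coh <- generate_feature_cohort(cfg)
  ref <- build_reference(coh$fd, coh$metadata)
  meta <- coh$metadata
  target <- which(meta$birth_age_weeks < 37 & meta$scan_age_days >= 37 * 7)
  m <- neoshape:::feature_matrix(coh$fd)
  sgn <- coh$params$offset_sign
  zs <- vapply(target, function(i) {
    mean(norm_z(ref, setNames(m[i, ], colnames(m)))$z * sgn)
  }, numeric(1))
  expect_lt(abs(mean(zs) - delta), 0.25)
  # unaffected term-term subjects sit at zero on the same scale
  term <- which(coh$metadata$birth_age_weeks * 7 >= 273 &
                  coh$metadata$birth_age_weeks * 7 <= 286 &
                  coh$metadata$scan_age_days >= 273 &
                  coh$metadata$scan_age_days <= 286)
  z0 <- vapply(term, function(i) {
    mean(norm_z(ref, setNames(m[i, ], colnames(m)))$z * sgn)
  }, numeric(1))
  expect_lt(abs(mean(z0)), 0.25)
})

test_that("departure flags the offset channel and spares the clean one", {
  # age, sex and genetic effects off: any group difference in the clean
  # (volume) channel would be spurious, while the offset drives the FD one
  cfg <- cohort_config(n_subjects = 300, n_regions = 20,
                       preterm_fraction = 0.3,
                       scan_delay_weeks_range = c(0.2, 8),
                       beta_pos_range = c(0, 0), beta_neg_range = c(0, 0),
                       sex_effect_sd = 0, genetic_sd = 0,
                       twin_fraction = 0, longitudinal_fraction = 0,
                       preterm_fd_offset_sd = 2, seed = 22)
  coh <- generate_feature_cohort(cfg)
  meta <- coh$metadata
  target <- which(meta$birth_age_weeks < 37 & meta$scan_age_days >= 37 * 7)
  term <- which(meta$birth_age_weeks * 7 >= 273 &
                  meta$birth_age_weeks * 7 <= 286 &
                  meta$scan_age_days >= 273 & meta$scan_age_days <= 286)
  dep <- function(features) {
    ref <- build_reference(features, meta)
    m <- neoshape:::feature_matrix(features)
    list(target = vapply(target, function(i) departure_index(
           ref, setNames(m[i, ], colnames(m)))$d, numeric(1)),
         term = vapply(term, function(i) departure_index(
           ref, setNames(m[i, ], colnames(m)))$d, numeric(1)))
  }
  fd_dep <- dep(coh$fd)
  vol_dep <- dep(coh$volume)
  p_fd <- wilcox.test(fd_dep$target, fd_dep$term)$p.value
  p_vol <- wilcox.test(vol_dep$target, vol_dep$term)$p.value
  expect_lt(p_fd, 0.01)
  expect_gt(p_vol, 0.05)
})

test_that("weekly change rates match hand arithmetic and age ordering", {
  wc <- weekly_change(c(r1 = 2), c(r1 = 2.2), dt_weeks = 2)
  expect_equal(wc$rates$rate, 0.05)
  expect_equal(wc$total, 0.05)

  none <- weekly_change(c(1, 2, 3), c(1, 2, 3), dt_weeks = 4)
  expect_true(all(none$rates$rate == 0) && none$total == 0)

  # opposite-signed changes do not cancel in the default aggregate
  mixed <- weekly_change(c(2, 2), c(2.2, 1.8), dt_weeks = 1)
  expect_equal(mixed$total, 0.1)
  expect_equal(weekly_change(c(2, 2), c(2.2, 1.8), 1,
                             aggregate = "mean")$total, 0, tolerance = 1e-12)

  expect_error(weekly_change(1, 2, 0), "positive")
  expect_error(weekly_change(0, 2, 1), "zero baseline")

  # cohorts with steeper early trajectories: total rate falls with birth age
  sat <- function(w) 8 * (1 - exp(-(w - 28) / 5))
  cfg <- cohort_config(n_subjects = 150, n_regions = 10,
                       preterm_fraction = 0.5, residual_sd = 0,
                       sex_effect_sd = 0, genetic_sd = 0, twin_fraction = 0,
                       longitudinal_fraction = 1, followup_weeks = 4,
                       age_profile = sat, seed = 23)
  coh <- generate_feature_cohort(cfg)
  meta <- coh$metadata
  m <- neoshape:::feature_matrix(coh$fd)
  base <- which(meta$session_id == "ses_1")
  totals <- vapply(base, function(i) {
    j <- which(meta$subject_id == meta$subject_id[i] &
                 meta$session_id == "ses_2")
    weekly_change(m[i, ], m[j, ], dt_weeks = 4)$total
  }, numeric(1))
  ct <- suppressWarnings(cor.test(totals, meta$birth_age_weeks[base],
                                  method = "spearman"))
  expect_lt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})
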