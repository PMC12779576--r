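linear_fixture <- function(n = 120, p = 5, noise = 0, seed = 9) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("r", seq_len(p))
  ages <- 280 + 3 * X[, 1] - 2 * X[, 2] + rnorm(n, 0, noise)
  list(features = feature_table(dplyr::bind_cols(
    tibble::tibble(scan_id = sprintf("s%03d", seq_len(n))),
    tibble::as_tibble(X))), ages = ages)
}

test_that("controls recover a noiseless linear age signal exactly", {
  fx <- linear_fixture()
  cfg <- prediction_config(regressor = "mlr", spline_df = 0,
                           variance_retained = 1, seed = 2)
  m <- fit_age_model(fx$features, fx$ages, cfg)
  expect_lt(mean(abs(predict(m, fx$features) - fx$ages)), 1e-8)

  # RVR gives equivalent predictions on the same noiseless linear data
  cfg_rvr <- prediction_config(regressor = "rvr", spline_df = 0,
                               variance_retained = 1, seed = 2)
  m_rvr <- fit_age_model(fx$features, fx$ages, cfg_rvr)
  expect_lt(max(abs(predict(m_rvr, fx$features) -
                      predict(m, fx$features))), 1e-4)

  # too few rows and degenerate inputs are rejected
  expect_error(fit_age_model(fx$features[1:5, ], fx$ages[1:5], cfg),
               "at least 10")
  bad <- fx$features
  bad$r1 <- 1
  expect_error(fit_age_model(bad, fx$ages, cfg), "constant predictor")
})

test_that("RVR concentrates weight mass on informative features", {
  set.seed(10)
  n <- 300
  X <- matrix(rnorm(n * 55), n, 55)
  colnames(X) <- paste0("f", 1:55)
  y <- as.numeric(X[, 1:5] %*% rep(2, 5) + rnorm(n, 0, 0.5))
  ft <- feature_table(dplyr::bind_cols(
    tibble::tibble(scan_id = sprintf("s%03d", 1:n)), tibble::as_tibble(X)))
  m <- fit_age_model(ft, y, prediction_config(regressor = "rvr",
                                              spline_df = 0,
                                              variance_retained = 1,
                                              seed = 5))
  w <- abs(m$fit$weights)
  expect_gte(sum(w[1:5]) / sum(w), 0.9)
})

test_that("cross-validation metrics match their definitions", {
  fx <- linear_fixture(n = 60)
  cfg <- prediction_config(regressor = "mlr", spline_df = 0,
                           variance_retained = 1, folds = 5, seed = 3)
  cv <- cross_validate(fx$features, fx$ages, cfg)
  # perfect predictor: MAE 0 and R^2 1 on every fold
  expect_true(all(cv$folds$mae < 1e-8))
  expect_true(all(cv$folds$r2 > 1 - 1e-10))

  # MAE / R^2 definitions recomputed by hand from the predictions
  fx2 <- linear_fixture(n = 60, noise = 5, seed = 12)
  cv2 <- cross_validate(fx2$features, fx2$ages, cfg)
  pred <- cv2$predictions
  pooled_mae <- mean(abs(pred$predicted - pred$true))
  expect_equal(weighted.mean(cv2$folds$mae, cv2$folds$n_test), pooled_mae,
               tolerance = 1e-12)
  # reconstruct one fold and check both metrics exactly
  set.seed(cfg$seed)
  assign <- sample(rep(seq_len(cfg$folds), length.out = 60))
  ids1 <- fx2$features$scan_id[assign == 1]
  p1 <- pred[match(ids1, pred$scan_id), ]
  expect_equal(cv2$folds$mae[1], mean(abs(p1$predicted - p1$true)),
               tolerance = 1e-12)
  expect_equal(cv2$folds$r2[1],
               1 - sum((p1$true - p1$predicted)^2) /
                 sum((p1$true - mean(p1$true))^2),
               tolerance = 1e-12)

  # same seed reproduces identical folds and metrics
  cv3 <- cross_validate(fx2$features, fx2$ages, cfg)
  expect_identical(as.data.frame(cv2$folds), as.data.frame(cv3$folds))

  expect_error(cross_validate(fx$features, fx$ages[-1], cfg), "one age")
  expect_error(cross_validate(fx$features[1:4, ], fx$ages[1:4],
                              prediction_config(folds = 10)), "folds")
})

test_that("held-out fold labels never influence that fold's predictions", {
  fx <- linear_fixture(n = 80, noise = 4, seed = 14)
  cfg <- prediction_config(regressor = "mlr", spline_df = 0,
                           variance_retained = 1, folds = 5, seed = 6)
  # reproduce the seeded fold assignment used by cross_validate
  set.seed(cfg$seed)
  assign <- sample(rep(seq_len(cfg$folds), length.out = 80))
  fold1 <- which(assign == 1)

  cv_a <- cross_validate(fx$features, fx$ages, cfg)
  ages_b <- fx$ages
  ages_b[fold1] <- ages_b[fold1] + 1000 # corrupt held-out labels
  cv_b <- cross_validate(fx$features, ages_b, cfg)

  ids1 <- fx$features$scan_id[fold1]
  pa <- cv_a$predictions[match(ids1, cv_a$predictions$scan_id), "predicted"]
  pb <- cv_b$predictions[match(ids1, cv_b$predictions$scan_id), "predicted"]
  expect_equal(pa, pb, tolerance = 1e-10)
})

test_that("CV error sits at the Gaussian noise floor of the target", {
  tau <- 5
  fx <- linear_fixture(n = 400, noise = tau, seed = 15)
  cfg <- prediction_config(regressor = "rvr", seed = 7)
  cv <- cross_validate(fx$features, fx$ages, cfg)
  mae <- glance(cv)$mae
  floor <- tau * sqrt(2 / pi)
  expect_gt(mae, 0.8 * floor)
  expect_lt(mae, 1.2 * floor)
})

test_that("model comparison ranks channels by their signal content", {
  set.seed(16)
  n <- 150
  age <- runif(n, 260, 300)
  strong <- sapply(1:6, function(j) 0.02 * age + rnorm(n, 0, 0.3))
  weak <- sapply(1:6, function(j) 0.02 * age + rnorm(n, 0, 3))
  mk <- function(m) {
    colnames(m) <- paste0("r", 1:6)
    feature_table(dplyr::bind_cols(
      tibble::tibble(scan_id = sprintf("s%03d", 1:n)), tibble::as_tibble(m)))
  }
  cfg <- prediction_config(regressor = "mlr", spline_df = 0,
                           variance_retained = 1, seed = 8)
  cv_strong <- cross_validate(mk(strong), age, cfg)
  cv_weak <- cross_validate(mk(weak), age, cfg)
  wins <- sum(cv_strong$folds$mae < cv_weak$folds$mae)
  expect_gt(wins, 8)

  rep_cmp <- compare_models(cv_strong, cv_weak)
  expect_equal(rep_cmp$metric, c("mae", "r2", "mae_variance"))
  expect_lt(rep_cmp$p[rep_cmp$metric == "mae"], 0.05)
  expect_lt(rep_cmp$mean_a[1], rep_cmp$mean_b[1])

  # identical inputs: no difference, p = 1
  same <- compare_models(cv_strong, cv_strong)
  expect_equal(same$p[same$metric == "mae"], 1)

  cfg2 <- prediction_config(regressor = "mlr", spline_df = 0,
                            variance_retained = 1, folds = 5, seed = 8)
  expect_error(compare_models(cv_strong,
                              cross_validate(mk(weak), age, cfg2)),
               "mismatched")
})
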