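#' Age-prediction pipeline configuration
#'
#' The pipeline standardizes the regional predictors, expands each through
#' a natural cubic spline basis (smoothing 0, i.e. near least squares;
#' knots at training quantiles), reduces the concatenated basis by
#' principal components retaining a fixed share of variance, and regresses
#' age on the scores with relevance vector regression (RVR; sparse
#' Bayesian linear regression with per-weight precision hyperpriors).
#' Multiple linear regression and linear-kernel support vector regression
#' are available as control regressors, and both the spline and reduction
#' stages can be switched off, so the insensitivity of performance to the
#' pipeline internals is itself testable.
#'
#' @param spline_df Degrees of freedom per feature for the natural cubic
#'   spline basis; `0` disables the expansion (default 4).
#' @param variance_retained Share of variance kept by the principal
#'   component reduction, in (0, 1]; `1` keeps all components (default
#'   0.95).
#' @param regressor `"rvr"`, `"mlr"` or `"svr_linear"`.
#' @param folds Number of cross-validation folds (default 10).
#' @param n_repeats Repeated random fold splits (default 1; the repeated
#'   analysis uses 500).
#' @param rvr_tol,rvr_max_iter RVR convergence tolerance and iteration cap.
#' @param seed RNG seed governing fold assignment.
#' @return A list of class `prediction_config`.
#' @export
prediction_config <- function(spline_df = 4L, variance_retained = 0.95,
                              regressor = c("rvr", "mlr", "svr_linear"),
                              folds = 10L, n_repeats = 1L,
                              rvr_tol = 1e-6, rvr_max_iter = 1000L,
                              seed = 1L) {
  regressor <- match.arg(regressor)
  if (folds < 2L) abort("`folds` must be >= 2.")
  if (variance_retained <= 0 || variance_retained > 1) {
    abort("`variance_retained` must lie in (0, 1].")
  }
  if (spline_df != 0L && spline_df < 2L) {
    abort("`spline_df` must be 0 (off) or >= 2.")
  }
  structure(list(spline_df = as.integer(spline_df),
                 variance_retained = variance_retained,
                 regressor = regressor, folds = as.integer(folds),
                 n_repeats = as.integer(n_repeats), rvr_tol = rvr_tol,
                 rvr_max_iter = as.integer(rvr_max_iter),
                 seed = as.integer(seed)),
            class = "prediction_config")
}

# Evidence-maximization sparse Bayesian linear regression (the RVR core):
# fixed-point updates of per-weight precisions alpha and noise precision
# beta; weights whose precision diverges past `prune_at` leave the active
# set (their weights are exactly zero), which is what makes the regressor
# sparse and the iteration stable.
rvr_fit <- function(Phi, t, tol = 1e-6, max_iter = 1000L) {
  n <- nrow(Phi)
  m <- ncol(Phi)
  active <- seq_len(m)
  alpha <- rep(1, m)
  beta <- 1 / max(var(t) * 0.1, 1e-12)
  prune_at <- 1e8
  weights <- rep(0, m)
  converged <- FALSE
  iter <- 0L
  delta <- Inf
  for (iter in seq_len(max_iter)) {
    Pa <- Phi[, active, drop = FALSE]
    Sigma <- solve(beta * crossprod(Pa) +
                     diag(alpha[active], length(active)))
    mu <- as.numeric(beta * Sigma %*% crossprod(Pa, t))
    gam <- 1 - alpha[active] * diag(Sigma)
    alpha_new <- as.numeric(gam / pmax(mu^2, 1e-300))
    resid <- t - Pa %*% mu
    beta <- max(n - sum(gam), 1e-6) / max(sum(resid^2), 1e-12)
    delta <- max(abs(log(pmin(alpha_new, prune_at)) -
                       log(pmin(alpha[active], prune_at))))
    alpha[active] <- alpha_new
    weights[] <- 0
    weights[active] <- mu
    keep <- alpha[active] < prune_at
    if (!any(keep)) {
      weights[] <- 0
      converged <- TRUE
      break
    }
    if (!all(keep)) {
      active <- active[keep]
      weights[setdiff(seq_len(m), active)] <- 0
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warn(sprintf("RVR did not converge in %d iterations (delta %.2g).",
                 max_iter, delta))
  }
  list(weights = weights, alpha = alpha, beta = beta,
       n_active = length(active), iterations = iter,
       converged = converged)
}

#' Fit the shape-based age-prediction model
#'
#' All pipeline statistics — predictor standardization, spline knots, the
#' principal-component basis and the regressor weights — are derived from
#' the training data only, so the fitted object can score held-out scans
#' without leakage.
#'
#' @param features A [feature_table()] (training rows).
#' @param ages Numeric target, one value per training row (e.g. age at
#'   scan in days).
#' @param config A [prediction_config()].
#' @return An `age_model` object with a [predict()] method.
#' @export
fit_age_model <- function(features, ages, config = prediction_config()) {
  stopifnot(inherits(features, "feature_table"))
  X <- feature_matrix(features)
  if (length(ages) != nrow(X)) abort("one age per training row required.")
  if (anyNA(X) || anyNA(ages)) abort("missing values in training data.")
  if (nrow(X) < 10L) abort("need at least 10 training rows.")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(scl == 0)) abort("degenerate input: constant predictor column.")
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  bases <- NULL
  if (config$spline_df > 0L) {
    bases <- lapply(seq_len(ncol(Xs)), function(j) {
      splines::ns(Xs[, j], df = config$spline_df)
    })
    B <- do.call(cbind, lapply(seq_along(bases), function(j) {
      unclass(bases[[j]])
    }))
  } else {
    B <- Xs
  }

  pca <- NULL
  if (config$variance_retained < 1) {
    pca <- prcomp(B, center = TRUE, scale. = FALSE)
    cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
    ncomp <- max(which(cum >= config$variance_retained)[1], 1L)
    S <- pca$x[, seq_len(ncomp), drop = FALSE]
  } else {
    S <- B
    ncomp <- ncol(B)
  }

  y_mean <- mean(ages)
  yc <- ages - y_mean
  fit <- switch(config$regressor,
    rvr = rvr_fit(S, yc, tol = config$rvr_tol,
                  max_iter = config$rvr_max_iter),
    mlr = {
      df <- data.frame(y = yc, S)
      lm(y ~ ., data = df)
    },
    svr_linear = e1071::svm(x = S, y = yc, kernel = "linear"))
  structure(list(config = config, regions = colnames(X), center = ctr,
                 scale = scl, bases = bases, pca = pca, ncomp = ncomp,
                 y_mean = y_mean, fit = fit),
            class = "age_model")
}

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("<age_model> %s on %d components (%d regions)\n",
              x$config$regressor, x$ncomp, length(x$regions)))
  invisible(x)
}

#' Predict ages for new scans
#'
#' @param object An `age_model`.
#' @param newdata A [feature_table()] with the training regions.
#' @param ... Unused.
#' @return Numeric predictions, one per row of `newdata`.
#' @export
predict.age_model <- function(object, newdata, ...) {
  X <- feature_matrix(newdata)[, object$regions, drop = FALSE]
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  B <- if (!is.null(object$bases)) {
    do.call(cbind, lapply(seq_along(object$bases), function(j) {
      predict(object$bases[[j]], Xs[, j])
    }))
  } else {
    Xs
  }
  S <- if (!is.null(object$pca)) {
    sweep(B, 2, object$pca$center) %*%
      object$pca$rotation[, seq_len(object$ncomp), drop = FALSE]
  } else {
    B
  }
  pred <- switch(object$config$regressor,
    rvr = as.numeric(S %*% object$fit$weights),
    mlr = {
      df <- as.data.frame(S)
      colnames(df) <- names(coef(object$fit))[-1]
      as.numeric(predict(object$fit, newdata = df))
    },
    svr_linear = as.numeric(predict(object$fit, S)))
  pred + object$y_mean
}

#' Cross-validated age prediction
#'
#' Seeded k-fold cross-validation (optionally repeated with re-drawn fold
#' assignments): in each iteration the pipeline is fitted on the training
#' folds only and predicts the held-out fold; performance is summarized
#' per fold as MAE (mean |predicted - true|) and R-squared
#' (1 - residual sum of squares / total sum of squares on the test fold).
#' Rows must be one scan per subject; duplicated keys are rejected.
#'
#' @inheritParams fit_age_model
#' @return A `cv_result`: `folds` tibble (`repeat_id`, `fold`, `n_test`,
#'   `mae`, `r2`) and `predictions` tibble (`repeat_id`, `scan_id`,
#'   `true`, `predicted`).
#' @export
cross_validate <- function(features, ages, config = prediction_config()) {
  stopifnot(inherits(features, "feature_table"))
  n <- nrow(features)
  if (anyDuplicated(features$scan_id)) abort("duplicate scan keys.")
  if (length(ages) != n) abort("one age per row required.")
  if (config$folds > n) abort("more folds than rows.")
  set.seed(config$seed)
  res <- purrr::map(seq_len(config$n_repeats), function(rep_i) {
    assign <- sample(rep(seq_len(config$folds), length.out = n))
    per_fold <- purrr::map(seq_len(config$folds), function(f) {
      test <- which(assign == f)
      model <- fit_age_model(features[-test, ], ages[-test], config)
      pred <- predict(model, features[test, ])
      truth <- ages[test]
      list(folds = tibble(repeat_id = rep_i, fold = f,
                          n_test = length(test),
                          mae = mean(abs(pred - truth)),
                          r2 = 1 - sum((truth - pred)^2) /
                            sum((truth - mean(truth))^2)),
           predictions = tibble(repeat_id = rep_i,
                                scan_id = features$scan_id[test],
                                true = truth, predicted = pred))
    })
    list(folds = dplyr::bind_rows(purrr::map(per_fold, "folds")),
         predictions = dplyr::bind_rows(purrr::map(per_fold,
                                                   "predictions")))
  })
  structure(list(folds = dplyr::bind_rows(purrr::map(res, "folds")),
                 predictions = dplyr::bind_rows(purrr::map(res,
                                                           "predictions")),
                 config = config),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<cv_result> %d folds x %d repeats: MAE %.3f, R2 %.3f\n",
              x$config$folds, x$config$n_repeats, g$mae, g$r2))
  invisible(x)
}

#' @export
tidy.cv_result <- function(x, ...) x$folds

#' @export
glance.cv_result <- function(x, ...) {
  tibble(mae = mean(x$folds$mae), r2 = mean(x$folds$r2),
         mae_sd = sd(x$folds$mae), r2_sd = sd(x$folds$r2),
         n_folds = nrow(x$folds))
}

#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$true, y = .data$predicted)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "true age", y = "predicted age") +
    ggplot2::theme_minimal()
}

#' Compare two cross-validated models
#'
#' Paired two-sided signed-rank tests on fold-wise MAE and R-squared, plus
#' a comparison of performance variability across the repeated-split
#' distributions (Levene's test on fold MAE). Requires identical fold
#' structure (same seed, folds and repeats), so fold pairs are matched.
#'
#' @param cv_a,cv_b `cv_result` objects from [cross_validate()].
#' @return A tibble with one row per comparison: `metric`, `mean_a`,
#'   `mean_b`, `statistic`, `p`.
#' @export
compare_models <- function(cv_a, cv_b) {
  stopifnot(inherits(cv_a, "cv_result"), inherits(cv_b, "cv_result"))
  fa <- cv_a$folds
  fb <- cv_b$folds
  if (!identical(fa[, c("repeat_id", "fold", "n_test")],
                 fb[, c("repeat_id", "fold", "n_test")])) {
    abort("mismatched fold structures.")
  }
  sr <- function(a, b) {
    if (all(a == b)) return(list(statistic = NA_real_, p.value = 1))
    wilcox.test(a, b, paired = TRUE, exact = FALSE)
  }
  w_mae <- sr(fa$mae, fb$mae)
  w_r2 <- sr(fa$r2, fb$r2)
  lev_df <- data.frame(mae = c(fa$mae, fb$mae),
                       model = factor(rep(c("a", "b"),
                                          times = c(nrow(fa), nrow(fb)))))
  lev <- car::leveneTest(mae ~ model, data = lev_df)
  tibble(metric = c("mae", "r2", "mae_variance"),
         mean_a = c(mean(fa$mae), mean(fa$r2), var(fa$mae)),
         mean_b = c(mean(fb$mae), mean(fb$r2), var(fb$mae)),
         statistic = c(unname(w_mae$statistic %||% NA_real_),
                       unname(w_r2$statistic %||% NA_real_),
                       lev[1, "F value"]),
         p = c(w_mae$p.value, w_r2$p.value, lev[1, "Pr(>F)"]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
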