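#' Full-term reference profile
#'
#' Per-region mean and sample s.d. of a feature over the reference group of
#' infants both born and scanned within the full-term window (default
#' 39+0 to 40+6 post-menstrual weeks, i.e. 273-286 days).
#'
#' @param features A [feature_table()].
#' @param metadata Matching [cohort_metadata()]; rows are matched to the
#'   feature table by `subject_id` or `subject_id_session_id` keys.
#' @param term_window_days Two-element window in days (default
#'   `c(273, 286)`) applied to both birth age (converted from weeks) and
#'   scan age.
#' @return A `reference_profile`: tibble (`region`, `mu`, `sigma`),
#'   `n_reference`, and the window.
#' @export
build_reference <- function(features, metadata,
                            term_window_days = c(273, 286)) {
  stopifnot(inherits(features, "feature_table"))
  meta <- as_tibble(metadata)
  key <- if (all(features$scan_id %in% meta$subject_id)) meta$subject_id else
    paste(meta$subject_id, meta$session_id, sep = "_")
  meta <- meta[match(features$scan_id, key), ]
  in_win <- meta$birth_age_weeks * 7 >= term_window_days[1] &
    meta$birth_age_weeks * 7 <= term_window_days[2] &
    meta$scan_age_days >= term_window_days[1] &
    meta$scan_age_days <= term_window_days[2]
  if (sum(in_win, na.rm = TRUE) < 2L) {
    abort("fewer than 2 subjects born and scanned within the term window.")
  }
  m <- feature_matrix(features)[which(in_win), , drop = FALSE]
  structure(list(profile = tibble(region = colnames(m),
                                  mu = unname(colMeans(m)),
                                  sigma = unname(apply(m, 2, sd))),
                 n_reference = nrow(m),
                 term_window_days = term_window_days,
                 measure = attr(features, "measure")),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf(
    "<reference_profile> %s over %d term-term infants, %d regions\n",
    x$measure, x$n_reference, nrow(x$profile)))
  invisible(x)
}

#' Departure from the normative reference
#'
#' The departure index is \eqn{d = 1 - \varrho}, with \eqn{\varrho} the
#' Spearman rank correlation (average ranks for ties) between a subject's
#' regional profile and the reference means: 0 when the subject preserves
#' the reference's regional rank ordering exactly, 2 when it reverses it,
#' and about 1 for unrelated profiles. Being rank-based, it is invariant to
#' strictly monotone transforms of the subject vector.
#'
#' @param profile A `reference_profile` from [build_reference()].
#' @param subject_vector Named numeric vector over the same regions (any
#'   order; matched by name when named).
#' @return A one-row tibble: `rho`, `d`.
#' @export
departure_index <- function(profile, subject_vector) {
  stopifnot(inherits(profile, "reference_profile"))
  x <- align_regions(profile, subject_vector)
  if (length(x) < 3L) abort("need >= 3 regions.")
  if (sd(x) == 0) abort("constant subject vector: ranks undefined.")
  rho <- cor(x, profile$profile$mu, method = "spearman")
  tibble(rho = rho, d = 1 - rho)
}

align_regions <- function(profile, subject_vector) {
  regions <- profile$profile$region
  if (!is.null(names(subject_vector))) {
    if (!all(regions %in% names(subject_vector))) {
      abort("subject vector is missing regions of the reference profile.")
    }
    subject_vector <- subject_vector[regions]
  } else if (length(subject_vector) != length(regions)) {
    abort("subject vector length does not match the reference profile.")
  }
  as.numeric(subject_vector)
}

#' Norm-referenced z-scores
#'
#' Standardizes each regional value against the full-term reference:
#' \eqn{z_{ij} = (x_{ij} - \mu_j) / \sigma_j}. Regions with zero reference
#' s.d. are unscorable and returned as `NA` with a warning.
#'
#' @inheritParams departure_index
#' @return A tibble: `region`, `x`, `z`.
#' @export
norm_z <- function(profile, subject_vector) {
  stopifnot(inherits(profile, "reference_profile"))
  x <- align_regions(profile, subject_vector)
  sigma <- profile$profile$sigma
  scorable <- sigma > 0
  if (!any(scorable)) abort("all regions unscorable (zero reference s.d.).")
  if (any(!scorable)) {
    warn(sprintf("%d regions unscorable (zero reference s.d.).",
                 sum(!scorable)))
  }
  z <- ifelse(scorable, (x - profile$profile$mu) / sigma, NA_real_)
  tibble(region = profile$profile$region, x = x, z = z)
}

#' Weekly relative change between two sessions
#'
#' Per-region rate: \eqn{((v_{follow} - v_{base}) / v_{base}) / \Delta t}
#' per week. The total is aggregated as the mean of absolute per-region
#' rates by default, so that simultaneous increases (sheet-like regions)
#' and decreases (block-like regions) do not cancel; signed alternatives
#' are available.
#'
#' @param baseline_vector,followup_vector Regional values at the two
#'   sessions (same order; names taken from the baseline when present).
#' @param dt_weeks Inter-session interval in weeks, positive.
#' @param aggregate `"mean_abs"` (default), `"mean"` or `"sum"`.
#' @return A list: `rates` (tibble `region`, `rate`), `total`.
#' @examples
#' weekly_change(c(r1 = 2), c(r1 = 2.2), dt_weeks = 2)$total # 0.05
#' @export
weekly_change <- function(baseline_vector, followup_vector, dt_weeks,
                          aggregate = c("mean_abs", "mean", "sum")) {
  aggregate <- match.arg(aggregate)
  if (dt_weeks <= 0) abort("`dt_weeks` must be positive.")
  if (length(baseline_vector) != length(followup_vector)) {
    abort("vectors differ in length.")
  }
  if (any(baseline_vector == 0)) abort("zero baseline value.")
  rate <- ((followup_vector - baseline_vector) / baseline_vector) / dt_weeks
  total <- switch(aggregate,
                  mean_abs = mean(abs(rate)),
                  mean = mean(rate),
                  sum = sum(rate))
  nm <- names(baseline_vector)
  if (is.null(nm)) nm <- sprintf("region_%02d", seq_along(rate))
  list(rates = tibble(region = nm, rate = unname(rate)), total = total)
}
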