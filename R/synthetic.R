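#' Synthetic voxel phenotypes
#'
#' Deterministic geometric phenotypes whose complexity varies monotonically
#' with a latent age parameter `a`, emulating the two tissue trends seen in
#' the developing brain: a "sheet-like" compartment (grey-matter-like) that
#' folds increasingly with age, raising its fractal dimensionality, and a
#' "block-like" compartment (white-matter-like) that loses space-fillingness
#' as indentations are carved into it, lowering FD.
#'
#' The sheet is a constant-thickness surface
#' \eqn{z = z_0 + A(a)\sin(\omega x)\sin(\omega y)} rasterized with local
#' slope-corrected thickness (so voxel count tracks surface area); the
#' block is a solid slab with pyramidal indentations of depth `D(a)` carved
#' from one face on a regular grid.
#'
#' @param kind `"sheet"` or `"block"`.
#' @param lattice Lattice extents (default `c(48, 48, 24)`).
#' @param age_param Latent age `a` in `[0, 1]`.
#' @param folding_freq Cycles of folding across the lattice (default 8 for
#'   sheets — fold wavelengths inside the counting scales, so folding
#'   raises measured FD from the first increment — and 3 for blocks).
#' @param folding_amp_max Maximum fold amplitude / indentation depth in
#'   voxels, reached at `a = 1` (default 6 for sheets, 12 for blocks).
#' @param thickness Sheet thickness / slab depth in voxels (default 2 for
#'   sheets, 16 for blocks).
#' @param seed RNG seed (reserved for stochastic variants; the default
#'   phenotypes are deterministic).
#' @return A list of class `phenotype_params`.
#' @export
phenotype_params <- function(kind = c("sheet", "block"),
                             lattice = c(48L, 48L, 24L), age_param = 0.5,
                             folding_freq = NULL, folding_amp_max = NULL,
                             thickness = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (age_param < 0 || age_param > 1) abort("`age_param` must be in [0, 1].")
  if (is.null(folding_freq)) folding_freq <- if (kind == "sheet") 8 else 3
  if (is.null(folding_amp_max)) {
    folding_amp_max <- if (kind == "sheet") 6 else 12
  }
  if (is.null(thickness)) thickness <- if (kind == "sheet") 2 else 16
  structure(list(kind = kind, lattice = as.integer(lattice),
                 age_param = age_param, folding_freq = folding_freq,
                 folding_amp_max = folding_amp_max, thickness = thickness,
                 seed = as.integer(seed)),
            class = "phenotype_params")
}

#' @rdname phenotype_params
#' @param params A `phenotype_params` object.
#' @return `make_phenotype_mask()` returns a [voxel_mask()].
#' @export
make_phenotype_mask <- function(params) {
  stopifnot(inherits(params, "phenotype_params"))
  d <- params$lattice
  a <- params$age_param
  grid <- if (params$kind == "sheet") {
    amp <- params$folding_amp_max * a
    om <- 2 * pi * params$folding_freq / d[1]
    x <- seq_len(d[1])
    y <- seq_len(d[2])
    h <- (d[3] + 1) / 2 + amp * outer(sin(om * x), sin(om * y))
    gx <- amp * om * outer(cos(om * x), sin(om * y))
    gy <- amp * om * outer(sin(om * x), cos(om * y))
    half <- params$thickness / 2 * sqrt(1 + gx^2 + gy^2)
    z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
    abs(z - c(h)) <= c(half)
  } else {
    depth <- params$folding_amp_max * a
    slab_top <- params$thickness
    spacing <- max(4L, round(d[1] / (2 * params$folding_freq)))
    x <- seq_len(d[1])
    y <- seq_len(d[2])
    cx <- ((x - 1) %% spacing) - (spacing - 1) / 2
    cy <- ((y - 1) %% spacing) - (spacing - 1) / 2
    # inverted pyramids: local cut depth peaks at each notch centre
    cut <- depth * pmax(0, 1 - 2 * outer(abs(cx), abs(cy), pmax) / spacing)
    top <- slab_top - cut
    z <- array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
    z <= c(top)
  }
  grid <- array(grid, d)
  if (!any(grid)) abort("phenotype parameters produced an empty mask.")
  voxel_mask(grid, origin_note = sprintf("synthetic %s phenotype, a = %g",
                                         params$kind, a))
}

#' Synthetic cohort configuration
#'
#' Defaults emulate a neonatal imaging cohort: 780 subjects with regional
#' profiles over 70 regions, additive age, sex and shared-genetic (twin)
#' structure plus residual noise; around 11% of subjects are twins (pairs
#' share birth and scan age), with a fraction of monozygotic pairs sharing
#' their latent genetic vector exactly while dizygotic pairs correlate 0.5;
#' a longitudinal fraction receives a follow-up session. A companion
#' "volume-like" channel carries the same age structure with weaker genetic
#' loading, emulating the greater individual specificity of shape over
#' size.
#'
#' @param n_subjects Number of subjects (default 780).
#' @param n_regions Number of regions (default 70).
#' @param birth_age_range_weeks Term birth-age range; preterm births are
#'   drawn below its lower end (defaults 37-42 and 28-36.9 weeks).
#' @param preterm_fraction Fraction born preterm (default 0.17).
#' @param scan_delay_weeks_range Scan delay after birth (default 0-4 weeks).
#' @param beta_pos_range,beta_neg_range Per-region age slopes (units per
#'   week) for the increasing and decreasing halves of the regions.
#' @param mu_range Per-region intercept range at 40 weeks.
#' @param sex_effect_sd S.d. of per-region sex contrasts (sex coded
#'   \eqn{\pm 1/2}).
#' @param genetic_sd Scale of the shared-genetic regional effects in the
#'   shape channel; the volume-like channel uses
#'   `genetic_sd * volume_genetic_factor`.
#' @param volume_genetic_factor Relative genetic loading of the volume-like
#'   channel (default 0.3).
#' @param latent_dim Dimension of the latent genetic vector (default 5).
#' @param residual_sd Residual noise s.d. (default 0.02).
#' @param twin_fraction Fraction of subjects who are twins (default 0.11).
#' @param mz_ratio Fraction of twin pairs that are monozygotic
#'   (default 0.4).
#' @param twin_age_jitter_days Within-pair scan-age jitter (default 0).
#' @param longitudinal_fraction Fraction with a follow-up scan
#'   (default 0.13).
#' @param followup_weeks Follow-up interval (default 6 weeks).
#' @param preterm_fd_offset_sd Offset magnitude, in units of the
#'   term-born-and-scanned group's regional s.d., applied to the shape
#'   channel of preterm-born subjects scanned at term-equivalent age
#'   (default 0). The offset is signed by compartment — positive on the
#'   sheet-like (first) half of the regions and negative on the block-like
#'   half — so it genuinely reorders regional profiles; a uniform shift
#'   would leave the rank-based departure index untouched. The sign
#'   pattern is returned in `params$offset_sign`.
#' @param age_profile Optional function mapping post-menstrual age at scan
#'   (weeks) to the age covariate; `NULL` (default) uses the linear
#'   `age - 40`. A concave profile encodes steeper change at younger ages.
#' @param seed RNG seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 780L, n_regions = 70L,
                          birth_age_range_weeks = c(37, 42),
                          preterm_fraction = 0.17,
                          scan_delay_weeks_range = c(0, 4),
                          beta_pos_range = c(0.01, 0.03),
                          beta_neg_range = c(-0.02, -0.005),
                          mu_range = c(2.0, 2.6),
                          sex_effect_sd = 0.005,
                          genetic_sd = 0.05,
                          volume_genetic_factor = 0.3,
                          latent_dim = 5L,
                          residual_sd = 0.02,
                          twin_fraction = 0.11,
                          mz_ratio = 0.4,
                          twin_age_jitter_days = 0,
                          longitudinal_fraction = 0.13,
                          followup_weeks = 6,
                          preterm_fd_offset_sd = 0,
                          age_profile = NULL,
                          seed = 1L) {
  if (n_subjects < 4L) abort("need at least 4 subjects.")
  if (twin_fraction * n_subjects / 2 > n_subjects / 2) {
    abort("more twins than subjects.")
  }
  if (residual_sd < 0 || genetic_sd < 0 || sex_effect_sd < 0) {
    abort("variances must be non-negative.")
  }
  cfg <- as.list(environment())
  cfg$n_subjects <- as.integer(n_subjects)
  cfg$n_regions <- as.integer(n_regions)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic feature-level cohort
#'
#' Draws metadata and two regional feature tables (shape-like and
#' volume-like) under the generative model
#' \deqn{x_{ij} = \mu_j + \beta_j \cdot age_i + s_j \cdot sex_i +
#'       g_j (L_j^\top \gamma_i) + \epsilon_{ij}}
#' where \eqn{\gamma_i} is a latent genetic vector shared exactly within
#' monozygotic pairs and correlated 0.5 within dizygotic pairs, sex is
#' coded \eqn{\pm 1/2}, and age enters as post-menstrual age at scan
#' centred at 40 weeks. Longitudinal subjects contribute a second session
#' under the same subject id and latent vector.
#'
#' @param config A [cohort_config()].
#' @return A list: `fd` ([feature_table()]), `volume` ([feature_table()]),
#'   `metadata` ([cohort_metadata()]).
#' @export
generate_feature_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  p <- config$n_regions
  regions <- sprintf("region_%02d", seq_len(p))

  # region-level parameters
  half <- p %/% 2
  beta <- c(runif(half, config$beta_pos_range[1], config$beta_pos_range[2]),
            runif(p - half, config$beta_neg_range[1],
                  config$beta_neg_range[2]))
  mu <- runif(p, config$mu_range[1], config$mu_range[2])
  sex_eff <- rnorm(p, 0, config$sex_effect_sd)
  g <- config$genetic_sd * runif(p, 0.5, 1.5)
  L <- matrix(rnorm(config$latent_dim * p), config$latent_dim, p)
  L <- sweep(L, 2, sqrt(colSums(L^2)), "/")

  # subjects: twin pairing, sex, ages
  n_pairs <- floor(config$twin_fraction * n / 2)
  twin_pair <- rep(NA_character_, n)
  zygosity <- rep("unknown", n)
  if (n_pairs > 0) {
    pair_ids <- sprintf("pair_%03d", seq_len(n_pairs))
    idx <- seq_len(2 * n_pairs)
    twin_pair[idx] <- rep(pair_ids, each = 2)
    n_mz <- round(config$mz_ratio * n_pairs)
    zyg_pair <- c(rep("MZ", n_mz), rep("DZ", n_pairs - n_mz))
    zygosity[idx] <- rep(zyg_pair, each = 2)
  }
  sex <- sample(c("female", "male"), n, replace = TRUE)
  preterm <- runif(n) < config$preterm_fraction
  birth <- ifelse(preterm,
                  runif(n, 28, config$birth_age_range_weeks[1] - 0.1),
                  runif(n, config$birth_age_range_weeks[1],
                        config$birth_age_range_weeks[2]))
  delay <- runif(n, config$scan_delay_weeks_range[1],
                 config$scan_delay_weeks_range[2])
  scan <- birth + delay
  # twins share sex (always for MZ), birth age and scan age
  for (pid in unique(stats::na.omit(twin_pair))) {
    m <- which(twin_pair == pid)
    birth[m[2]] <- birth[m[1]]
    scan[m[2]] <- scan[m[1]] +
      config$twin_age_jitter_days / 7 * stats::rnorm(1)
    if (zygosity[m[1]] == "MZ") sex[m[2]] <- sex[m[1]]
  }

  # latent genetic vectors
  gamma <- matrix(rnorm(n * config$latent_dim), n, config$latent_dim)
  for (pid in unique(stats::na.omit(twin_pair))) {
    m <- which(twin_pair == pid)
    if (zygosity[m[1]] == "MZ") {
      gamma[m[2], ] <- gamma[m[1], ]
    } else {
      gamma[m[2], ] <- 0.5 * gamma[m[1], ] +
        sqrt(0.75) * rnorm(config$latent_dim)
    }
  }

  n_long <- floor(config$longitudinal_fraction * n)
  long_idx <- if (n_long > 0) sample.int(n, n_long) else integer(0)

  subj <- sprintf("sub_%04d", seq_len(n))
  meta <- tibble(
    subject_id = subj, session_id = "ses_1", sex = sex,
    birth_age_weeks = birth, scan_age_days = scan * 7,
    pregnancy = ifelse(is.na(twin_pair), "singleton", "multifetal"),
    twin_pair = twin_pair, zygosity = zygosity)
  if (n_long > 0) {
    meta <- dplyr::bind_rows(meta, meta[long_idx, ] |>
      dplyr::mutate(session_id = "ses_2",
                    scan_age_days = .data$scan_age_days +
                      config$followup_weeks * 7))
  }
  row_subject <- match(meta$subject_id, subj)

  profile <- config$age_profile
  if (is.null(profile)) profile <- function(w) w - 40
  # offsets are expressed in units of the term-born-and-scanned group's s.d.
  term_rows <- which(meta$birth_age_weeks * 7 >= 273 &
                       meta$birth_age_weeks * 7 <= 286 &
                       meta$scan_age_days >= 273 & meta$scan_age_days <= 286)
  draw_channel <- function(mu_c, beta_c, sex_c, g_c, resid_sd, offset_rows) {
    age_c <- profile(meta$scan_age_days / 7)
    sex_n <- ifelse(meta$sex == "female", -0.5, 0.5)
    genet <- (gamma[row_subject, , drop = FALSE] %*% L) *
      rep(g_c, each = nrow(meta))
    vals <- matrix(mu_c, nrow(meta), p, byrow = TRUE) +
      outer(age_c, beta_c) + outer(sex_n, sex_c) + genet +
      matrix(rnorm(nrow(meta) * p, 0, resid_sd), nrow(meta), p)
    if (config$preterm_fd_offset_sd != 0 && length(offset_rows) > 0) {
      sd_rows <- if (length(term_rows) >= 2L) term_rows else
        seq_len(nrow(vals))
      ref_sd <- apply(vals[sd_rows, , drop = FALSE], 2, sd)
      vals[offset_rows, ] <- vals[offset_rows, ] +
        rep(config$preterm_fd_offset_sd * ref_sd * offset_sign,
            each = length(offset_rows))
    }
    vals
  }
  # preterm-born, scanned at term-equivalent age (>= 37 weeks)
  offset_rows <- which(meta$birth_age_weeks < 37 &
                         meta$scan_age_days >= 37 * 7)
  offset_sign <- rep(c(1, -1), times = c(half, p - half))
  scan_id <- paste(meta$subject_id, meta$session_id, sep = "_")
  fd_vals <- draw_channel(mu, beta, sex_eff, g, config$residual_sd,
                          offset_rows)
  # volume-like channel: same age structure on a 20x scale, weaker genetics
  vol_mu <- runif(p, 1, 10)
  vol_vals <- draw_channel(vol_mu, beta * 20, sex_eff * 20,
                           g * config$volume_genetic_factor * 20,
                           config$residual_sd * 20, integer(0))
  to_table <- function(v, measure) {
    colnames(v) <- regions
    feature_table(dplyr::bind_cols(tibble(scan_id = scan_id),
                                   as_tibble(v)), measure = measure)
  }
  list(fd = to_table(fd_vals, "fd"),
       volume = to_table(vol_vals, "volume"),
       metadata = cohort_metadata(meta),
       params = list(mu = mu, beta = beta, sex_eff = sex_eff, g = g,
                     offset_sign = offset_sign))
}
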