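#' Theoretical dimension from the self-similarity scaling law
#'
#' For an object recoverable from `N` copies of itself scaled by a factor
#' `x`, the scaling law \eqn{N(x) = x^{-D}} gives the dimension
#' \eqn{D = -\log N / \log x}. A line halved (`x = 1/2`, `N = 2`) has
#' `D = 1`; a square gives 2, a cube 3; the Koch curve (`x = 1/3`,
#' `N = 4`) gives the non-integer ~1.2619.
#'
#' @param x Scaling factor, positive and different from 1.
#' @param N Number of scaled measurement units, positive.
#' @return The dimension `D` as a single number.
#' @examples
#' theoretical_dimension(1 / 2, 8) # cube: 3
#' theoretical_dimension(1 / 3, 4) # Koch curve: ~1.26
#' @export
theoretical_dimension <- function(x, N) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0 ||
      x == 1) {
    abort("`x` must be a positive number different from 1.")
  }
  if (!is.numeric(N) || length(N) != 1L || !is.finite(N) || N <= 0) {
    abort("`N` must be a positive number.")
  }
  -log(N) / log(x)
}

#' Dyadic scale set for box counting
#'
#' Kernel widths \eqn{\varepsilon = 2^k} voxels for the exponents `k`;
#' the default `k = 0:4` gives widths 1, 2, 4, 8, 16.
#'
#' @param k Non-negative integer exponents, strictly increasing.
#' @return Integer vector of kernel widths with class `scale_set`.
#' @export
scale_set <- function(k = 0:4) {
  k <- as.integer(k)
  if (length(k) < 2L) abort("at least 2 scales are required.")
  if (any(k < 0L) || any(diff(k) <= 0L)) {
    abort("`k` must be non-negative and strictly increasing.")
  }
  structure(2L^k, k = k, class = "scale_set")
}

#' Estimate fractal dimensionality of a voxel mask
#'
#' Box counting with a sliding grid, realized as a dilation: for each kernel
#' width \eqn{\varepsilon} the mask is padded by \eqn{\varepsilon - 1}
#' background voxels on every side and convolved with an all-ones
#' \eqn{\varepsilon^3} kernel; the number of strictly positive output
#' voxels, divided by \eqn{\varepsilon^3}, is the box count
#' \eqn{N(\varepsilon)} — exactly the mean over all \eqn{\varepsilon^3}
#' grid offsets of the classical box count (see [box_count_oracle()]).
#' The FD estimate is the ordinary-least-squares slope of
#' \eqn{\log N(\varepsilon)} against \eqn{\log(1/\varepsilon)} over all
#' provided scales.
#'
#' @param mask A [voxel_mask()] with at least one foreground voxel.
#' @param scales A [scale_set()]; default widths 1, 2, 4, 8, 16.
#' @return An object of class `fd_estimate`: per-scale counts, the fitted
#'   slope (`fd`), intercept, and fit \eqn{R^2}.
#' @examples
#' plane <- voxel_mask(array(TRUE, c(20, 20, 1)))
#' estimate_fd(plane)$fd # close to 2
#' @export
estimate_fd <- function(mask, scales = scale_set()) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!inherits(scales, "scale_set")) scales <- scale_set(scales)
  if (!any(mask$grid)) abort("cannot estimate FD of an empty mask.")
  widths <- as.integer(scales)
  if (max(widths) > max(dim(mask$grid))) {
    warn(sprintf(
      "mask extents (%s) are smaller than the largest kernel (%d); counts saturate at 1.",
      paste(dim(mask$grid), collapse = "x"), max(widths)))
  }
  card <- cpp_dilation_counts(mask$grid, dim(mask$grid), widths)
  counts <- card / widths^3
  fit <- fd_loglog_fit(widths, counts)
  structure(
    list(scales = tibble(k = attr(scales, "k"), epsilon = widths,
                         count = counts),
         fd = fit$slope, intercept = fit$intercept, fit_r2 = fit$r2,
         n_foreground = sum(mask$grid)),
    class = "fd_estimate"
  )
}

fd_loglog_fit <- function(widths, counts) {
  x <- log(1 / widths)
  y <- log(counts)
  xc <- x - mean(x)
  slope <- sum(xc * y) / sum(xc^2)
  intercept <- mean(y) - slope * mean(x)
  ss_res <- sum((y - intercept - slope * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(slope = slope, intercept = intercept, r2 = r2)
}

#' @export
print.fd_estimate <- function(x, ...) {
  cat(sprintf("<fd_estimate> fd = %.4f (fit R2 = %.4f over %d scales)\n",
              x$fd, x$fit_r2, nrow(x$scales)))
  invisible(x)
}

#' @export
tidy.fd_estimate <- function(x, ...) x$scales

#' @export
glance.fd_estimate <- function(x, ...) {
  tibble(fd = x$fd, intercept = x$intercept, fit_r2 = x$fit_r2,
         n_scales = nrow(x$scales), n_foreground = x$n_foreground)
}

#' @export
autoplot.fd_estimate <- function(object, ...) {
  ggplot2::ggplot(object$scales,
                  ggplot2::aes(x = log(1 / .data$epsilon),
                               y = log(.data$count))) +
    ggplot2::geom_abline(slope = object$fd, intercept = object$intercept,
                         linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = expression(log(1 / epsilon)),
                  y = expression(log(N(epsilon))),
                  title = sprintf("FD = %.3f", object$fd)) +
    ggplot2::theme_minimal()
}

#' Brute-force sliding-grid box count (test oracle)
#'
#' Counts the boxes of width `epsilon`, on the grid shifted by `offset`,
#' that intersect the mask — by direct enumeration. Averaging this count
#' over all `epsilon^3` offsets equals the dilation-based
#' \eqn{N(\varepsilon)} of [estimate_fd()] exactly; the function exists to
#' pin that equivalence in tests and is far too slow for real use.
#'
#' @param mask A [voxel_mask()].
#' @param epsilon Box width (positive integer).
#' @param offset Integer grid shift, each component in `[0, epsilon)`.
#' @return Number of occupied boxes.
#' @export
box_count_oracle <- function(mask, epsilon, offset = c(0L, 0L, 0L)) {
  stopifnot(inherits(mask, "voxel_mask"))
  epsilon <- as.integer(epsilon)
  offset <- as.integer(offset)
  if (length(offset) != 3L || any(offset < 0L) || any(offset >= epsilon)) {
    abort("`offset` components must lie in [0, epsilon).")
  }
  fg <- which(mask$grid)
  if (length(fg) == 0L) return(0L)
  coords <- arrayInd(fg, dim(mask$grid))
  box <- sweep(coords - 1L, 2L, offset, "+") %/% epsilon
  nrow(unique(box))
}

#' Surface voxels, volume and surface-to-volume ratio
#'
#' A surface voxel is a foreground voxel with at least one of its six
#' face-neighbours background (voxels outside the lattice count as
#' background). SVR is the number of surface voxels over the number of all
#' foreground voxels: 1 for a one-voxel-thick plane, and
#' \eqn{(100^3 - 98^3)/100^3 \approx 0.0588} for a full 100-voxel cube.
#'
#' @param mask A non-empty [voxel_mask()].
#' @return A one-row tibble: `volume_voxels`, `volume_ml`,
#'   `surface_voxels`, `svr`.
#' @export
morph_metrics <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  vol <- sum(mask$grid)
  if (vol == 0L) abort("empty mask.")
  surf <- sum(cpp_surface(mask$grid, dim(mask$grid)))
  tibble(volume_voxels = vol,
         volume_ml = vol * prod(mask$voxel_size_mm) / 1000,
         surface_voxels = surf,
         svr = surf / vol)
}

#' Hollow a mask to its surface shell
#'
#' Reduces a solid segmentation to its 6-connectivity surface voxels and
#' reports \eqn{\Delta FD = FD(original) - FD(shell)}. Shells of solids are
#' geometrically simpler than the solids themselves, so `delta_fd` is
#' non-negative for solid objects; an already one-voxel-thick object is its
#' own shell and has `delta_fd = 0`.
#'
#' @param mask A non-empty [voxel_mask()].
#' @param scales A [scale_set()] used for both FD estimates.
#' @return A list: `shell` ([voxel_mask()]), `delta_fd`, and the two
#'   `fd_estimate` objects (`fd_original`, `fd_shell`).
#' @export
hollow <- function(mask, scales = scale_set()) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!any(mask$grid)) abort("empty mask.")
  surf <- array(cpp_surface(mask$grid, dim(mask$grid)), dim(mask$grid))
  shell <- voxel_mask(surf, voxel_size_mm = mask$voxel_size_mm,
                      origin_note = paste("shell of", mask$origin_note))
  fd_orig <- estimate_fd(mask, scales)
  fd_shell <- estimate_fd(shell, scales)
  list(shell = shell, delta_fd = fd_orig$fd - fd_shell$fd,
       fd_original = fd_orig, fd_shell = fd_shell)
}

#' Regional feature extraction
#'
#' Computes one morphological measure (FD or volume in ml) for every region
#' mask of every scan, yielding the scans-by-regions [feature_table()] that
#' downstream similarity, normative and prediction stages consume. All
#' scans must share the same region set; regions with empty masks are
#' recorded as `NA` and reported with a warning, never silently zeroed.
#'
#' @param masks_by_scan Named list (scan id) of named lists
#'   (region -> [voxel_mask()]), e.g. from [parcellate()] per scan.
#' @param measure `"fd"` or `"volume"`.
#' @param scales A [scale_set()] (used for `measure = "fd"`).
#' @return A [feature_table()].
#' @export
extract_features <- function(masks_by_scan, measure = c("fd", "volume"),
                             scales = scale_set()) {
  measure <- match.arg(measure)
  if (length(masks_by_scan) == 0L) abort("no scans supplied.")
  regions <- names(masks_by_scan[[1]])
  if (is.null(regions)) abort("region masks must be named.")
  vals <- purrr::map(masks_by_scan, function(rl) {
    if (!identical(names(rl), regions)) {
      abort("inconsistent region sets across scans.")
    }
    purrr::map_dbl(rl, function(m) {
      if (!any(m$grid)) return(NA_real_)
      if (measure == "fd") estimate_fd(m, scales)$fd
      else morph_metrics(m)$volume_ml
    })
  })
  tab <- dplyr::bind_rows(vals)
  tab <- dplyr::bind_cols(tibble(scan_id = names(masks_by_scan)), tab)
  n_na <- sum(is.na(tab[, -1L]))
  if (n_na > 0) {
    warn(sprintf("%d empty region masks recorded as missing.", n_na))
  }
  feature_table(tab, measure = measure)
}

#' Median T1w/T2w ratio in the white-matter border band
#'
#' Samples voxels of the mask whose face-distance to background is at most
#' `band_depth_mm` (converted to voxels with the first voxel-size
#' component, rounded up) and summarizes the T1w/T2w intensity ratio over
#' that band by its median — a microstructural proxy for the tissue
#' boundary. Voxels with zero T2w intensity are excluded and counted.
#'
#' @param t1w,t2w Numeric 3-D arrays on the mask's lattice.
#' @param wm A [voxel_mask()] (e.g. the white-matter segmentation).
#' @param band_depth_mm Band depth in millimetres (default 1).
#' @return A list: `median_ratio`, `n_band`, `n_excluded_zero_t2w`,
#'   `band` ([voxel_mask()]).
#' @export
t1t2_border_median <- function(t1w, t2w, wm, band_depth_mm = 1) {
  stopifnot(inherits(wm, "voxel_mask"))
  if (!identical(dim(t1w), dim(wm$grid)) ||
      !identical(dim(t2w), dim(wm$grid))) {
    abort("intensity volumes and mask must share one lattice.")
  }
  if (band_depth_mm <= 0) abort("`band_depth_mm` must be positive.")
  k <- ceiling(band_depth_mm / wm$voxel_size_mm[1])
  remaining <- wm$grid
  band <- array(FALSE, dim(wm$grid))
  for (i in seq_len(k)) {
    if (!any(remaining)) break
    peel <- array(cpp_surface(remaining, dim(remaining)), dim(remaining))
    band <- band | peel
    remaining <- remaining & !peel
  }
  if (!any(band)) abort("band is empty.")
  t1 <- t1w[band]
  t2 <- t2w[band]
  keep <- t2 != 0
  if (!any(keep)) abort("band is empty after excluding zero-T2w voxels.")
  list(median_ratio = median(t1[keep] / t2[keep]),
       n_band = sum(band),
       n_excluded_zero_t2w = sum(!keep),
       band = voxel_mask(band, voxel_size_mm = wm$voxel_size_mm,
                         origin_note = "T1w/T2w border band"))
}
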