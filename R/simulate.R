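#' Configuration for the plane-to-cube morphological simulation
#'
#' The simulation transforms a one-voxel-thick plane (theoretical FD 2,
#' SVR 1) into a filled cube (theoretical FD 3, SVR
#' \eqn{(100^3-98^3)/100^3 \approx 0.0588}) — or the reverse — through
#' random additions (removals) of `block`-width cubes centred at uniformly
#' drawn surface voxels. FD and SVR are evaluated at the start, at every
#' `eval_stride`-th iteration, and at the final state.
#'
#' @param lattice Lattice extents (default `c(100, 100, 100)`).
#' @param block Block width, odd (default 5). Blocks are clipped at
#'   lattice bounds.
#' @param iterations Maximum iterations per run (default 30000); a run ends
#'   early once the lattice is full (grow) or only the seed plane remains
#'   (shrink, where the seed plane is protected from removal).
#' @param runs Number of repeated runs (default 100).
#' @param eval_stride Evaluate FD/SVR every this many iterations
#'   (default 1; the per-iteration evaluation).
#' @param direction `"grow"` (plane to cube) or `"shrink"` (cube to plane).
#' @param scales [scale_set()] for the FD evaluations.
#' @param seed RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(lattice = c(100L, 100L, 100L), block = 5L,
                       iterations = 30000L, runs = 100L, eval_stride = 1L,
                       direction = c("grow", "shrink"),
                       scales = scale_set(), seed = 1L) {
  direction <- match.arg(direction)
  lattice <- as.integer(lattice)
  if (length(lattice) != 3L || any(lattice < 2L)) {
    abort("`lattice` must be 3 extents >= 2.")
  }
  block <- as.integer(block)
  if (block < 1L || block %% 2L == 0L) abort("`block` must be odd.")
  if (iterations < 1L) abort("`iterations` must be >= 1.")
  if (eval_stride < 1L) abort("`eval_stride` must be >= 1.")
  if (runs < 1L) abort("`runs` must be >= 1.")
  structure(list(lattice = lattice, block = block,
                 iterations = as.integer(iterations),
                 runs = as.integer(runs),
                 eval_stride = as.integer(eval_stride),
                 direction = direction, scales = scales,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Run the morphological simulation
#'
#' @param config A [sim_config()].
#' @return A tibble of class `sim_trajectory` with one row per evaluation
#'   point: `run`, `iteration`, `foreground`, `surface_voxels`, `svr`,
#'   `fd`, `terminal` (whether that run reached its theoretical endpoint
#'   within the iteration budget).
#' @examples
#' cfg <- sim_config(lattice = c(20, 20, 20), iterations = 500, runs = 1,
#'                   eval_stride = 50, seed = 7)
#' traj <- run_simulation(cfg)
#' trajectory_correlation(traj)
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  widths <- as.integer(config$scales)
  plane_z <- config$lattice[3] %/% 2L
  set.seed(config$seed)
  out <- purrr::map(seq_len(config$runs), function(r) {
    res <- cpp_run_sim(config$lattice, plane_z, config$block,
                       config$iterations, config$eval_stride,
                       config$direction == "grow", widths)
    traj <- res$trajectory
    counts <- traj[, -(1:3), drop = FALSE]
    fd <- vapply(seq_len(nrow(traj)), function(i) {
      fd_loglog_fit(widths, counts[i, ] / widths^3)$slope
    }, numeric(1))
    tibble(run = r, iteration = as.integer(traj[, 1]),
           foreground = traj[, 2], surface_voxels = traj[, 3],
           svr = traj[, 3] / traj[, 2], fd = fd,
           terminal = res$terminal)
  })
  traj <- dplyr::bind_rows(out)
  class(traj) <- c("sim_trajectory", class(traj))
  attr(traj, "config") <- config
  traj
}

#' FD-SVR coupling along a trajectory
#'
#' Pearson product-moment correlation of FD against SVR across the
#' evaluation points of a simulation trajectory. Along the plane-to-cube
#' transformation the coupling is strongly negative: the object fills space
#' (FD rises towards 3) exactly as its surface-to-volume ratio collapses.
#'
#' @param traj A `sim_trajectory` (or any data frame with `fd` and `svr`).
#' @return The correlation coefficient.
#' @export
trajectory_correlation <- function(traj) {
  if (!all(c("fd", "svr") %in% names(traj))) {
    abort("`traj` needs columns `fd` and `svr`.")
  }
  if (nrow(traj) < 3L) abort("need >= 3 evaluation points.")
  if (sd(traj$fd) == 0 || sd(traj$svr) == 0) {
    abort("constant series: correlation undefined.")
  }
  cor(traj$fd, traj$svr)
}

#' @export
autoplot.sim_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("run", "iteration", "fd", "svr")],
    cols = c("fd", "svr"), names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value,
                                     group = .data$run)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}
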