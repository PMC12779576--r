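test_that("scaling-law dimension matches the Euclidean and Koch cases", {
  expect_equal(theoretical_dimension(1 / 2, 2), 1, tolerance = 1e-12)
  expect_equal(theoretical_dimension(1 / 2, 4), 2, tolerance = 1e-12)
  expect_equal(theoretical_dimension(1 / 2, 8), 3, tolerance = 1e-12)
  expect_equal(theoretical_dimension(1 / 3, 4), log(4) / log(3),
               tolerance = 1e-12)
  expect_error(theoretical_dimension(1, 4), "different from 1")
  expect_error(theoretical_dimension(1 / 2, 0), "positive")
})

test_that("dilation counts equal sliding-grid box-count means over offsets", {
  set.seed(101)
  for (i in 1:6) {
    m <- random_mask(extent = sample(6:12, 1), density = runif(1, 0.1, 0.6))
    if (!any(m$grid)) next
    fe <- suppressWarnings(estimate_fd(m, scale_set(0:2)))
    for (eps in c(2L, 4L)) {
      offs <- as.matrix(expand.grid(0:(eps - 1), 0:(eps - 1), 0:(eps - 1)))
      oracle <- mean(apply(offs, 1, function(o) box_count_oracle(m, eps, o)))
      n_eps <- fe$scales$count[fe$scales$epsilon == eps]
      expect_equal(n_eps, oracle, tolerance = 1e-9)
    }
  }
  # eps = 1 count equals the foreground voxel count
  m <- random_mask(8)
  expect_equal(box_count_oracle(m, 1L), sum(m$grid))
  # 4x4x1 square at eps = 2 covers 4 boxes
  sq <- voxel_mask(array(TRUE, c(4, 4, 1)))
  expect_equal(box_count_oracle(sq, 2L), 4L)
})

test_that("FD behaves like a dimension on canonical objects", {
  single <- suppressWarnings(estimate_fd(voxel_mask(array(TRUE, c(1, 1, 1)))))
  expect_true(all(single$scales$count == 1))
  expect_equal(single$fd, 0)

  line <- suppressWarnings(estimate_fd(voxel_mask(array(TRUE, c(100, 1, 1)))))
  plane <- estimate_fd(voxel_mask(array(TRUE, c(100, 100, 1))))
  cube <- estimate_fd(voxel_mask(array(TRUE, c(100, 100, 100))))
  expect_lt(abs(line$fd - 1), 0.15)
  expect_lt(abs(plane$fd - 2), 0.15)
  expect_lt(abs(cube$fd - 3), 0.15)
  expect_true(line$fd < plane$fd && plane$fd < cube$fd)

  expect_error(estimate_fd(voxel_mask(array(FALSE, c(3, 3, 3)))), "empty")
  expect_error(scale_set(2), "at least 2")
})

test_that("FD is invariant to translation, axis permutation and flips", {
  set.seed(11)
  blob <- random_blob(18)
  fd0 <- estimate_fd(blob, scale_set(0:3))$fd

  # zero-padding on any side
  padded <- array(FALSE, dim(blob$grid) + c(4L, 2L, 6L))
  padded[3:20, 1:18, 5:22] <- blob$grid
  expect_lt(abs(estimate_fd(voxel_mask(padded), scale_set(0:3))$fd - fd0),
            1e-12)

  # axis permutation and flips
  expect_lt(abs(estimate_fd(voxel_mask(aperm(blob$grid, c(3, 1, 2))),
                            scale_set(0:3))$fd - fd0), 1e-12)
  expect_lt(abs(estimate_fd(voxel_mask(blob$grid[dim(blob$grid)[1]:1, , ]),
                            scale_set(0:3))$fd - fd0), 1e-12)
})

test_that("box counts are non-increasing in box width", {
  set.seed(5)
  for (i in 1:5) {
    m <- random_blob(16, n_balls = sample(1:5, 1))
    fe <- suppressWarnings(estimate_fd(m, scale_set(0:4)))
    expect_true(all(diff(fe$scales$count) <= 1e-9))
  }
})

test_that("surface metrics match enumeration on simple solids", {
  plane <- morph_metrics(voxel_mask(array(TRUE, c(100, 100, 1))))
  expect_equal(plane$svr, 1)

  cube3 <- morph_metrics(voxel_mask(array(TRUE, c(3, 3, 3))))
  expect_equal(cube3$surface_voxels, 26L)
  expect_equal(cube3$volume_voxels, 27L)
  expect_equal(cube3$svr, 26 / 27)

  cube100 <- morph_metrics(voxel_mask(array(TRUE, c(100, 100, 100)),
                                      voxel_size_mm = 0.5))
  expect_equal(cube100$surface_voxels, 100L^3 - 98L^3)
  expect_equal(cube100$volume_ml, 100^3 * 0.5^3 / 1000)
  expect_error(morph_metrics(voxel_mask(array(FALSE, c(2, 2, 2)))), "empty")
})

test_that("hollowing produces the surface shell and never raises FD", {
  # a 1-thick plane is its own shell
  plane <- voxel_mask(array(TRUE, c(30, 30, 1)))
  h <- hollow(plane, scale_set(0:3))
  expect_identical(h$shell$grid, plane$grid)
  expect_equal(h$delta_fd, 0)

  # 20^3 solid cube: shell has 20^3 - 18^3 voxels
  cube <- voxel_mask(array(TRUE, c(20, 20, 20)))
  h2 <- hollow(cube, scale_set(0:3))
  expect_equal(sum(h2$shell$grid), 20L^3 - 18L^3)
  expect_true(all(h2$shell$grid[!cube$grid] == FALSE))

  set.seed(33)
  for (i in 1:5) {
    hb <- hollow(random_blob(20), scale_set(0:3))
    expect_gte(hb$delta_fd, -1e-12)
  }
})

test_that("regional extraction assembles scans-by-regions tables", {
  mk <- function(n) voxel_mask(array(TRUE, c(n, n, n)))
  scans <- list(
    scan1 = list(a = mk(6), b = mk(8), c = mk(10)),
    scan2 = list(a = mk(6), b = mk(12), c = mk(10)))
  ft <- extract_features(scans, measure = "volume")
  expect_equal(dim(ft), c(2L, 4L))
  # identical region masks give identical columns
  expect_equal(ft$a[1], ft$a[2])
  expect_equal(ft$b[2], 12^3 / 1000)

  # empty region -> missing value with a warning, never zero
  scans$scan2$c <- voxel_mask(array(FALSE, c(2, 2, 2)))
  expect_warning(ft2 <- extract_features(scans, measure = "volume"),
                 "missing")
  expect_true(is.na(ft2$c[2]))
  expect_false(isTRUE(ft2$c[2] == 0))

  scans$scan2 <- scans$scan2[c("b", "a", "c")]
  expect_error(extract_features(scans, "volume"), "inconsistent")
})

test_that("sheet FD increases and block FD decreases with the age parameter", {
  ages <- seq(0, 1, by = 0.25)
  fd_sheet <- vapply(ages, function(a) {
    estimate_fd(make_phenotype_mask(phenotype_params("sheet", age_param = a)),
                scale_set(0:3))$fd
  }, numeric(1))
  expect_true(all(diff(fd_sheet) > 0))
  # flat thickened plane sits near dimension 2
  expect_lt(abs(fd_sheet[1] - 2), 0.25)

  fd_block <- vapply(c(0, 1), function(a) {
    estimate_fd(make_phenotype_mask(phenotype_params("block", age_param = a)),
                scale_set(0:3))$fd
  }, numeric(1))
  expect_lt(fd_block[2], fd_block[1])
})

test_that("the T1w/T2w border band selects the outer rind and its median", {
  cube <- voxel_mask(array(TRUE, c(10, 10, 10)), voxel_size_mm = 0.5)
  t1 <- array(3, c(10, 10, 10))
  t2 <- array(2, c(10, 10, 10))
  res <- t1t2_border_median(t1, t2, cube, band_depth_mm = 1)
  expect_equal(res$median_ratio, 1.5)
  # 1 mm at 0.5 mm voxels: outer 2-voxel rind
  expect_equal(res$n_band, 10L^3 - 6L^3)

  t2[2, 2, 1] <- 0
  res2 <- t1t2_border_median(t1, t2, cube, band_depth_mm = 1)
  expect_equal(res2$n_excluded_zero_t2w, 1L)

  expect_error(t1t2_border_median(t1, array(0, c(10, 10, 10)), cube),
               "empty")
  expect_error(t1t2_border_median(array(1, c(2, 2, 2)), t2, cube),
               "lattice")
})
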