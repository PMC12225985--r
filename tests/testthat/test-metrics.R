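# Lesion metrics: maximum absorption, 50%-contour diameter, R^2 and the
# group contrast summary.

gaussian_blob <- function(grid, sigma, center = c(0, 0, 1.5), amp = 0.2) {
  co <- grid_coords(grid)
  d2 <- (co[, 1] - center[1])^2 + (co[, 2] - center[2])^2
  zslice <- abs(co[, 3] - center[3]) < grid$dz / 2
  vals <- amp * exp(-d2 / (2 * sigma^2)) * zslice
  absorption_volume(vals, grid)
}

test_that("max_mua is the global maximum and permutation invariant", {
  grid <- tiny_grid()
  expect_equal(max_mua(absorption_volume(numeric(n_voxels(grid)), grid)), 0)
  sp <- rasterize_sphere(sphere_spec(c(0, 0, 1), 0.8, 0.2), grid, 0.05)
  expect_equal(max_mua(sp), 0.15, tolerance = 1e-12)
  set.seed(2)
  v <- abs(rnorm(n_voxels(grid)))
  p <- sample(v)
  expect_equal(max_mua(absorption_volume(v, grid)),
               max_mua(absorption_volume(p, grid)))
})

test_that("Gaussian blob diameter matches the FWHM closed form", {
  grid <- recon_grid()
  for (sigma in c(0.4, 0.6, 0.9)) {
    res <- contour_diameter(gaussian_blob(grid, sigma))
    expect_equal(res$level, 0.5 * 0.2, tolerance = 1e-12)
    expect_equal(res$diameter, 2 * sigma * sqrt(2 * log(2)),
                 tolerance = grid$dx / 2)
  }
  # diameter scales linearly with sigma
  d1 <- contour_diameter(gaussian_blob(grid, 0.4))$diameter
  d2 <- contour_diameter(gaussian_blob(grid, 0.8))$diameter
  expect_equal(d2 / d1, 2, tolerance = 0.05)
})

test_that("a uniform disk's 50% contour hugs the disk edge", {
  grid <- recon_grid()
  co <- grid_coords(grid)
  r <- 1.1
  vals <- 0.3 * ((co[, 1]^2 + co[, 2]^2 <= r^2) &
                   abs(co[, 3] - 1.5) < grid$dz / 2)
  res <- contour_diameter(absorption_volume(vals, grid))
  expect_equal(res$diameter, 2 * r, tolerance = 2 * grid$dx)
})

test_that("degenerate cases: single voxel gives zero diameter, flat errors", {
  grid <- recon_grid()
  v <- numeric(n_voxels(grid)); v[5000] <- 0.2
  res <- contour_diameter(absorption_volume(v, grid))
  expect_equal(res$diameter, 0)
  expect_error(contour_diameter(absorption_volume(numeric(n_voxels(grid)),
                                                  grid)),
               "positive maximum")
})

test_that("contour diameter agrees with a brute-force supra-threshold scan", {
  grid <- recon_grid()
  set.seed(31)
  for (i in 1:5) {
    sigma <- runif(1, 0.35, 0.9)
    ctr <- c(runif(2, -0.8, 0.8), 1.5)
    vol <- gaussian_blob(grid, sigma, center = ctr)
    res <- contour_diameter(vol)
    # brute force: max pairwise distance among voxel centers >= level on
    # the max slice (inside the contour), which can differ from the
    # interpolated contour by at most ~one voxel diagonal
    iz <- res$slice_index
    sl <- vol$values[, , iz]
    ax <- grid_axes(grid)
    supra <- which(sl >= res$level, arr.ind = TRUE)
    pts <- cbind(ax$x[supra[, 1]], ax$y[supra[, 2]])
    bf <- max(dist(pts))
    expect_lt(abs(res$diameter - bf), sqrt(grid$dx^2 + grid$dy^2) * 1.5)
  }
})

test_that("the contour enclosing the peak is chosen among several blobs", {
  grid <- recon_grid()
  co <- grid_coords(grid)
  zslice <- abs(co[, 3] - 1.5) < grid$dz / 2
  # main blob (amp 0.2, sd 0.5) + side blob above half-max (amp 0.15, sd 1.0)
  main <- 0.2 * exp(-((co[, 1] - 1.5)^2 + co[, 2]^2) / (2 * 0.5^2))
  side <- 0.15 * exp(-((co[, 1] + 2)^2 + co[, 2]^2) / (2 * 1.0^2))
  vol <- absorption_volume((main + side) * zslice, grid)
  res <- contour_diameter(vol)
  # the chosen contour surrounds the global peak near x = 1.5, so all its
  # points sit on the right half of the slice
  expect_true(all(res$points[, 1] > 0))
  expect_lt(res$diameter, 2.5)
})

test_that("r_squared matches its definition and brute-force value", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  truth <- c(1, 2, 4)
  expect_equal(r_squared(rep(mean(truth), 3), truth), 0)
  # brute-force frozen value for ([1,2,3] vs [1,2,4])
  pred <- c(1, 2, 3)
  ss_res <- sum((pred - truth)^2)           # 1
  ss_tot <- sum((truth - mean(truth))^2)    # 4.666...
  expect_equal(r_squared(pred, truth), 1 - ss_res / ss_tot)
  expect_equal(r_squared(pred, truth), 1 - 1 / (14 / 3), tolerance = 1e-12)
  expect_error(r_squared(c(1, 2), c(3, 3)), "constant")
})

test_that("group_contrast summarizes groups and separates contrasts", {
  grid <- tiny_grid()
  mk <- function(amp) {
    v <- numeric(n_voxels(grid)); v[100] <- amp
    absorption_volume(v, grid)
  }
  # identical volumes -> zero SD and zero CI width
  same <- group_contrast(list(a = list(mk(0.11), mk(0.11), mk(0.11))))
  expect_equal(same$sd, 0)
  expect_equal(same$ci_hi - same$ci_lo, 0)
  # low/high contrast groups mirroring benign vs malignant-like lesions
  set.seed(41)
  low <- lapply(rnorm(12, 0.11, 0.01), mk)
  high <- lapply(rnorm(12, 0.23, 0.02), mk)
  gc <- group_contrast(list(low = low, high = high))
  expect_s3_class(gc, "tbl_df")
  expect_lt(gc$ci_hi[gc$group == "low"], gc$ci_lo[gc$group == "high"])
  # order invariance of group means
  gc2 <- group_contrast(list(low = rev(low), high = rev(high)))
  expect_equal(gc$mean, gc2$mean)
})
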