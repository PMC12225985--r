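# Frequency-domain diffusion physics: wavenumber closed form, semi-infinite
# Green's function boundary behavior, and the Born sensitivity system.

test_that("wavenumber follows the closed form and round-trips", {
  bg <- default_bg()
  k <- wavenumber(bg)
  # direct evaluation of sqrt((-mua + i w/v)/D), decaying branch
  v <- 2.99792458e10 / 1.33
  D <- 1 / (3 * 7)
  k_ref <- sqrt(complex(real = -0.05, imaginary = 2 * pi * 1.4e8 / v) / D)
  if (Im(k_ref) < 0) k_ref <- -k_ref
  expect_equal(k, k_ref, tolerance = 1e-12)
  # frozen regression value for the default background
  expect_equal(Re(k), 0.3754708, tolerance = 1e-6)
  expect_equal(Im(k), 1.0913196, tolerance = 1e-6)
  # round trip through the closed-form inversion
  iv <- invert_wavenumber(Re(k), Im(k))
  expect_equal(iv$mua0, 0.05, tolerance = 1e-10)
  expect_equal(iv$musp0, 7, tolerance = 1e-10)
})

test_that("DC limit gives a purely decaying wave with sqrt(3 mua musp) rate", {
  bg <- default_bg(0.04, 6)
  k0 <- wavenumber(bg, list(light_speed_vacuum = 2.99792458e10,
                            angular_frequency = 0))
  expect_equal(Re(k0), 0, tolerance = 1e-12)
  expect_equal(Im(k0), sqrt(3 * 0.04 * 6), tolerance = 1e-12)
  # doubling musp scales the DC decay constant by sqrt(2)
  k2 <- wavenumber(default_bg(0.04, 12),
                   list(light_speed_vacuum = 2.99792458e10,
                        angular_frequency = 0))
  expect_equal(Im(k2) / Im(k0), sqrt(2), tolerance = 1e-12)
})

test_that("fluence vanishes on the extrapolated boundary for any source", {
  bg <- default_bg()
  k <- wavenumber(bg)
  D <- 1 / (3 * bg$musp0)
  A <- (1 + (-1.440 / 1.33^2 + 0.710 / 1.33 + 0.668 + 0.0636 * 1.33)) /
    (1 - (-1.440 / 1.33^2 + 0.710 / 1.33 + 0.668 + 0.0636 * 1.33))
  zb <- 2 * D * A
  for (src in list(c(0, 0, 0), c(-2, 1, 0), c(3, -3, 0))) {
    pts <- cbind(runif(20, -4, 4), runif(20, -4, 4), -zb)
    g <- greens_semi_infinite(matrix(rep(src, each = 20), ncol = 3), pts,
                              k, bg)
    expect_lt(max(Mod(g)), 1e-14)
  }
})

test_that("Green's function is mirror-symmetric and reciprocal", {
  bg <- default_bg()
  k <- wavenumber(bg)
  g1 <- greens_semi_infinite(c(1, 0, 0), c(2.5, 1.3, 1.2), k, bg)
  g2 <- greens_semi_infinite(c(1, 0, 0), c(2.5, -1.3, 1.2), k, bg)
  expect_equal(g1, g2, tolerance = 1e-14)
  # endpoint exchange (reciprocity of the image construction)
  ga <- greens_semi_infinite(c(-1, 2, 0), c(2, -1, 1.7), k, bg)
  gb <- greens_semi_infinite(c(2, -1, 1.7), c(-1, 2, 0), k, bg)
  expect_equal(ga, gb, tolerance = 1e-14)
})

test_that("surface fluence decays faster than the 1/r^2 envelope", {
  bg <- default_bg()
  k <- wavenumber(bg)
  g1 <- Mod(greens_semi_infinite(c(0, 0, 0), c(2, 0, 0), k, bg))
  g2 <- Mod(greens_semi_infinite(c(0, 0, 0), c(4, 0, 0), k, bg))
  expect_lt(g2 / g1, 1 / 4)
})

test_that("Born system rows reproduce a dense brute-force product", {
  geom <- default_probe_geometry()
  grid <- tiny_grid()
  bg <- default_bg(0.03, 5)
  sys <- build_born_system(geom, grid, bg)
  expect_equal(dim(sys$W), c(126L, n_voxels(grid)))
  # brute-force W from first principles for a handful of channels/voxels
  k <- wavenumber(bg)
  D <- 1 / (3 * bg$musp0)
  co <- grid_coords(grid)
  vv <- grid$dx * grid$dy * grid$dz
  r_floor <- 0.5 * sqrt(grid$dx^2 + grid$dy^2 + grid$dz^2)
  set.seed(11)
  for (i in 1:20) {
    s <- sample(9, 1); d <- sample(14, 1); v <- sample(nrow(co), 1)
    gs <- greens_semi_infinite(geom$source_positions[s, ], co[v, ], k, bg,
                               r_floor = r_floor)
    gd <- greens_semi_infinite(co[v, ], geom$detector_positions[d, ], k, bg,
                               r_floor = r_floor)
    w_ref <- -gs * gd * vv / (D * sys$U0[s, d])
    expect_equal(sys$W[(s - 1) * 14 + d, v], w_ref, tolerance = 1e-12)
  }
})

test_that("simulate_perturbation equals the dense matrix product", {
  geom <- default_probe_geometry()
  grid <- tiny_grid()
  bg <- default_bg()
  sys <- build_born_system(geom, grid, bg)
  set.seed(3)
  delta <- numeric(n_voxels(grid))
  delta[sample(length(delta), 25)] <- runif(25, 0.01, 0.25)
  vol <- absorption_volume(delta, grid)
  p <- simulate_perturbation(sys, vol)
  # independent brute-force accumulation over voxels
  acc <- rep(0 + 0i, 126)
  for (v in which(delta != 0)) acc <- acc + sys$W[, v] * delta[v]
  expect_equal(as.vector(t(p$values)), acc, tolerance = 1e-12)
})

test_that("Born model is linear: superposition and zero map to zero", {
  geom <- default_probe_geometry()
  grid <- tiny_grid()
  sys <- build_born_system(geom, grid, default_bg())
  nv <- n_voxels(grid)
  expect_equal(max(Mod(simulate_perturbation(
    sys, absorption_volume(numeric(nv), grid))$values)), 0)
  set.seed(4)
  d1 <- numeric(nv); d1[sample(nv, 10)] <- 0.1
  d2 <- numeric(nv); d2[sample(nv, 10)] <- 0.2
  p1 <- simulate_perturbation(sys, absorption_volume(d1, grid))$values
  p2 <- simulate_perturbation(sys, absorption_volume(d2, grid))$values
  p12 <- simulate_perturbation(sys, absorption_volume(d1 + d2, grid))$values
  expect_equal(p12, p1 + p2, tolerance = 1e-12)
  expect_equal(simulate_perturbation(
    sys, absorption_volume(2 * d1, grid))$values, 2 * p1, tolerance = 1e-12)
})

test_that("sensitivity decays with voxel depth under a channel midpoint", {
  geom <- default_probe_geometry()
  grid <- recon_grid()
  sys <- build_born_system(geom, grid, default_bg())
  # column of voxels under the midpoint of source 5 / detector 7
  mid <- (geom$source_positions[5, 1:2] + geom$detector_positions[7, 1:2]) / 2
  co <- grid_coords(grid)
  col <- which(abs(co[, 1] - mid[1]) < grid$dx / 2 &
                 abs(co[, 2] - mid[2]) < grid$dy / 2)
  col <- col[order(co[col, 3])]
  w <- Mod(sys$W[(5 - 1) * 14 + 7, col])
  # the semi-infinite sensitivity is banana-shaped: it peaks at a shallow
  # depth (the boundary suppresses near-surface fluence) and then decays
  # strictly with depth
  pk <- which.max(w)
  expect_lte(pk, 2L)
  expect_true(all(diff(w[pk:length(w)]) < 0))
  expect_lt(w[length(w)], 0.05 * w[pk])
})

test_that("noise is seeded and reproducible", {
  geom <- default_probe_geometry()
  grid <- tiny_grid()
  sys <- build_born_system(geom, grid, default_bg())
  vol <- absorption_volume(numeric(n_voxels(grid)), grid)
  p1 <- simulate_perturbation(sys, vol, noise_frac = 0.01, seed = 9)
  p2 <- simulate_perturbation(sys, vol, noise_frac = 0.01, seed = 9)
  p3 <- simulate_perturbation(sys, vol, noise_frac = 0.01, seed = 10)
  expect_identical(p1$values, p2$values)
  expect_false(identical(p1$values, p3$values))
  expect_equal(sd(Re(p1$values)), 0.01, tolerance = 0.5)
})
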