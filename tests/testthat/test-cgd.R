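# Regularized conjugate-gradient baseline: closed-form identity systems,
# dense-solve equivalence, objective behavior.

# toy Born system with an arbitrary W for closed-form checks
toy_system <- function(W, grid) {
  structure(list(W = W, U0 = matrix(1 + 0i, 9, 14), grid = grid,
                 voxel_idx = seq_len(ncol(W)), background = default_bg(),
                 tikhonov_lambda = 0, diffusion_D = 1 / 21),
            class = "dot_born")
}

full_mask <- function(grid) {
  lesion_mask(array(TRUE, c(grid$nx, grid$ny, grid$nz)), grid,
              center = c(0, 0, 1), semi_axes = c(9, 9, 9))
}

test_that("identity system returns the data (lambda = 0) and shrinks it", {
  grid <- recon_grid(nx = 6, ny = 7, nz = 3)  # 126 voxels
  W <- diag(126) + 0i
  sys <- toy_system(W, grid)
  set.seed(5)
  usc <- matrix(complex(real = rnorm(126), imaginary = rnorm(126)), 9, 14,
                byrow = TRUE)
  p <- perturbation(usc)
  rec0 <- reconstruct_cgd(p, sys, full_mask(grid),
                          cgd_settings(tikhonov_lambda = 0))
  # complex rows are stacked, so the real solution is Re(usc) per voxel
  expect_equal(as.vector(rec0$values), as.vector(t(Re(usc))),
               tolerance = 1e-8)
  lam <- 0.7
  rec1 <- reconstruct_cgd(p, sys, full_mask(grid),
                          cgd_settings(tikhonov_lambda = lam))
  expect_equal(as.vector(rec1$values),
               as.vector(t(Re(usc))) / (1 + lam^2), tolerance = 1e-8)
})

test_that("CGD matches a dense direct solve on small systems", {
  grid <- recon_grid(nx = 6, ny = 5, nz = 3)  # 90 voxels
  set.seed(8)
  W <- matrix(complex(real = rnorm(126 * 90), imaginary = rnorm(126 * 90)),
              126, 90) * 0.1
  sys <- toy_system(W, grid)
  usc <- matrix(complex(real = rnorm(126), imaginary = rnorm(126)), 9, 14,
                byrow = TRUE)
  p <- perturbation(usc)
  lam <- 0.3
  rec <- reconstruct_cgd(p, sys, full_mask(grid),
                         cgd_settings(tikhonov_lambda = lam,
                                      residual_tolerance = 1e-12))
  A <- rbind(Re(W), Im(W))
  b <- c(Re(as.vector(t(usc))), Im(as.vector(t(usc))))
  x_ref <- solve(crossprod(A) + lam^2 * diag(90), crossprod(A, b))
  expect_lt(sqrt(sum((as.vector(rec$values) - x_ref)^2)) /
              sqrt(sum(x_ref^2)), 1e-8)
})

test_that("noiseless single-voxel Born data is recovered exactly", {
  geom <- default_probe_geometry()
  grid <- tiny_grid()
  bg <- default_bg()
  sys <- build_born_system(geom, grid, bg)
  co <- grid_coords(grid)
  v <- which.min((co[, 1] - 0.4)^2 + (co[, 2] + 0.4)^2 + (co[, 3] - 1)^2)
  delta <- numeric(n_voxels(grid)); delta[v] <- 0.12
  p <- simulate_perturbation(sys, absorption_volume(delta, grid))
  # restrict to a small ROI containing the voxel -> full-rank subproblem
  roi <- array(FALSE, c(grid$nx, grid$ny, grid$nz))
  ai <- arrayInd(v, dim(roi))
  roi[ai[1] + (-1:1), ai[2] + (-1:1), ai[3]] <- TRUE
  mask <- lesion_mask(roi, grid, center = co[v, ], semi_axes = c(1, 1, 1))
  rec <- reconstruct_cgd(p, sys, mask,
                         cgd_settings(tikhonov_lambda = 0,
                                      residual_tolerance = 1e-12))
  expect_lt(abs(rec$values[v] - 0.12) / 0.12, 1e-6)
})

test_that("objective is the Tikhonov functional and decreases monotonically", {
  grid <- recon_grid(nx = 6, ny = 5, nz = 3)
  set.seed(13)
  W <- matrix(complex(real = rnorm(126 * 90), imaginary = rnorm(126 * 90)),
              126, 90) * 0.1
  sys <- toy_system(W, grid)
  usc <- matrix(complex(real = rnorm(126), imaginary = rnorm(126)), 9, 14,
                byrow = TRUE)
  p <- perturbation(usc)
  # delta = 0 -> ||USC||^2
  expect_equal(cgd_objective(p, sys, numeric(90), tikhonov_lambda = 0.5),
               sum(Mod(usc)^2), tolerance = 1e-12)
  rec <- reconstruct_cgd(p, sys, full_mask(grid),
                         cgd_settings(tikhonov_lambda = 0.5))
  tr <- attr(rec, "objective_trace")
  expect_true(all(diff(tr) <= 1e-10))
  # local optimality: perturbing the minimizer increases the objective
  x <- as.vector(rec$values)
  o0 <- cgd_objective(p, sys, x, tikhonov_lambda = 0.5)
  set.seed(14)
  for (i in 1:5) {
    eps <- rnorm(90, 0, 1e-3)
    expect_gt(cgd_objective(p, sys, x + eps, tikhonov_lambda = 0.5), o0)
  }
})

test_that("exact noiseless solve has objective ~ 0 at lambda = 0", {
  grid <- recon_grid(nx = 5, ny = 5, nz = 2)  # 50 voxels, overdetermined
  set.seed(17)
  W <- matrix(complex(real = rnorm(126 * 50), imaginary = rnorm(126 * 50)),
              126, 50)
  x_true <- runif(50)
  sys <- toy_system(W, grid)
  usc <- matrix(as.vector(W %*% x_true), 9, 14, byrow = TRUE)
  p <- perturbation(usc)
  rec <- reconstruct_cgd(p, sys, full_mask(grid),
                         cgd_settings(tikhonov_lambda = 0,
                                      residual_tolerance = 1e-12))
  expect_lt(cgd_objective(p, sys, as.vector(rec$values),
                          tikhonov_lambda = 0), 1e-12)
})

test_that("large lambda drives the solution norm toward zero monotonically", {
  grid <- recon_grid(nx = 5, ny = 5, nz = 2)
  set.seed(19)
  W <- matrix(complex(real = rnorm(126 * 50), imaginary = rnorm(126 * 50)),
              126, 50)
  sys <- toy_system(W, grid)
  usc <- matrix(as.vector(W %*% runif(50)), 9, 14, byrow = TRUE)
  p <- perturbation(usc)
  norms <- sapply(c(0.1, 1, 10, 300), function(lam) {
    rec <- reconstruct_cgd(p, sys, full_mask(grid),
                           cgd_settings(tikhonov_lambda = lam))
    sqrt(sum(rec$values^2))
  })
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[4], 0.05 * norms[1])
})

test_that("voxels outside the mask stay exactly zero", {
  geom <- default_probe_geometry()
  grid <- tiny_grid()
  sys <- build_born_system(geom, grid, default_bg())
  ci <- one_case()
  p <- simulate_perturbation(sys, absorption_volume(
    rep(0.05, n_voxels(grid)), grid))
  mask <- make_mask(c(0, 0, 1), 0.6, 2.5, grid)
  rec <- suppressWarnings(reconstruct_cgd(p, sys, mask, cgd_settings()))
  expect_true(all(rec$values[!mask$values] == 0))
  expect_true(any(rec$values[mask$values] != 0))
})
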