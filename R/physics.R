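#' Physical constants for frequency-domain photon diffusion
#'
#' @param modulation_frequency source modulation frequency in Hz.
#' @return list with `light_speed_vacuum` (cm/s) and `angular_frequency`
#'   (rad/s).
#' @export
physics_constants <- function(modulation_frequency = 1.4e8) {
  list(light_speed_vacuum = 2.99792458e10,
       angular_frequency = 2 * pi * modulation_frequency)
}

diffusion_coefficient <- function(musp0) {
  if (musp0 <= 0) stop("musp0 must be positive")
  1 / (3 * musp0)
}

# Groenhuis polynomial for the internal-reflection parameter A of the
# extrapolated-boundary condition.
boundary_A <- function(n) {
  rd <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  (1 + rd) / (1 - rd)
}

#' Complex wavenumber of the diffuse photon-density wave
#'
#' `k = sqrt((-mua0 + i w / v) / D)` with `v = c / n` the light speed in
#' tissue and `D = 1/(3 musp0)`; the branch with positive imaginary part is
#' taken so that the fluence `exp(i k r) / r` decays with distance. `Re(k)`
#' sets the phase slope versus distance and `Im(k)` the log-amplitude decay.
#'
#' @param background a `dot_background`.
#' @param constants output of [physics_constants()].
#' @return complex scalar `k` in cm^-1.
#' @export
wavenumber <- function(background, constants = physics_constants()) {
  if (background$musp0 <= 0) stop("musp0 must be positive")
  v <- constants$light_speed_vacuum / background$refractive_index
  D <- diffusion_coefficient(background$musp0)
  k <- sqrt(complex(real = -background$mua0,
                    imaginary = constants$angular_frequency / v) / D)
  if (Im(k) < 0) k <- -k
  k
}

#' Recover optical properties from wavenumber components
#'
#' Inverts the closed form of [wavenumber()]: with `k = kr + i ki`,
#' `musp0 = 2 kr ki v / (3 w)` and `mua0 = (ki^2 - kr^2) / (3 musp0)`.
#'
#' @param kr,ki real and imaginary wavenumber parts in cm^-1.
#' @param refractive_index tissue refractive index.
#' @param constants output of [physics_constants()].
#' @return list with `mua0` and `musp0` in cm^-1.
#' @export
invert_wavenumber <- function(kr, ki, refractive_index = 1.33,
                              constants = physics_constants()) {
  w <- constants$angular_frequency
  if (w <= 0) stop("modulated data required: angular frequency must be > 0")
  v <- constants$light_speed_vacuum / refractive_index
  musp0 <- 2 * kr * ki * v / (3 * w)
  if (!is.finite(musp0) || musp0 <= 0)
    stop("non-physical slopes: inferred musp0 <= 0 (check sign conventions)")
  mua0 <- (ki^2 - kr^2) / (3 * musp0)
  if (!is.finite(mua0) || mua0 <= 0)
    stop("non-physical slopes: inferred mua0 <= 0 (check sign conventions)")
  list(mua0 = mua0, musp0 = musp0)
}

#' Semi-infinite medium Green's function
#'
#' Image-source construction for the extrapolated boundary condition: a point
#' with z = 0 is an optode and is embedded at depth `z0 = 1/musp0`; the
#' negative image sits mirrored about the extrapolated boundary plane at
#' `z = -zb`, `zb = 2 D A`. The construction is symmetric in its two
#' endpoints, so source-detector reciprocity holds exactly.
#'
#' @param p_source source position(s), length-3 vector or n x 3 matrix (cm).
#' @param p_field field position(s), length-3 vector or n x 3 matrix (cm).
#' @param k complex wavenumber from [wavenumber()].
#' @param background a `dot_background`.
#' @param constants output of [physics_constants()].
#' @param r_floor minimum source-field distance in cm (0 = error on
#'   coincidence); used to stabilize shallow voxels next to optodes.
#' @return complex fluence value(s).
#' @export
greens_semi_infinite <- function(p_source, p_field, k = NULL,
                                 background, constants = physics_constants(),
                                 r_floor = 0) {
  if (is.null(k)) k <- wavenumber(background, constants)
  D <- diffusion_coefficient(background$musp0)
  z0 <- 1 / background$musp0
  zb <- 2 * D * boundary_A(background$refractive_index)
  ps <- if (is.null(dim(p_source))) matrix(p_source, ncol = 3) else p_source
  pf <- if (is.null(dim(p_field))) matrix(p_field, ncol = 3) else p_field
  # optode embedding: probe-face points move to depth z0
  zs <- ifelse(ps[, 3] == 0, z0, ps[, 3])
  zf <- ifelse(pf[, 3] == 0, z0, pf[, 3])
  dx <- ps[, 1] - pf[, 1]; dy <- ps[, 2] - pf[, 2]
  r1 <- sqrt(dx^2 + dy^2 + (zs - zf)^2)
  if (r_floor > 0) r1 <- pmax(r1, r_floor)
  if (any(r1 == 0)) stop("coincident source and field point")
  r2 <- sqrt(dx^2 + dy^2 + (zs + zf + 2 * zb)^2)
  (exp(1i * k * r1) / r1 - exp(1i * k * r2) / r2) / (4 * pi * D)
}

#' Homogeneous-medium channel predictions
#'
#' Predicted complex field U0 for every source-detector pair of the probe in
#' a lesion-free homogeneous background: the denominator of the relative
#' perturbation and the reference-side measurement model.
#'
#' @param geometry a `dot_probe`.
#' @param background a `dot_background`.
#' @param constants output of [physics_constants()].
#' @return 9 x 14 complex matrix.
#' @export
homogeneous_field <- function(geometry, background,
                              constants = physics_constants(
                                geometry$modulation_frequency)) {
  k <- wavenumber(background, constants)
  s <- geometry$source_positions
  d <- geometry$detector_positions
  U0 <- matrix(0i, 9, 14)
  for (i in 1:9) {
    U0[i, ] <- greens_semi_infinite(s[i, ], d, k, background, constants)
  }
  U0
}

#' Synthesize a reference-side measurement set
#'
#' Amplitude and phase of the homogeneous-medium prediction, optionally with
#' multiplicative per-channel noise, as the contralateral reference the
#' calibration module fits.
#'
#' @param geometry a `dot_probe`.
#' @param background a `dot_background`.
#' @param noise_frac relative Gaussian noise on the complex field (0 = none).
#' @param seed optional integer seed.
#' @return a `dot_measurement` with `side = "reference"`.
#' @export
simulate_reference <- function(geometry, background, noise_frac = 0,
                               seed = NULL) {
  U0 <- homogeneous_field(geometry, background)
  if (noise_frac > 0) {
    U0 <- with_seed(seed, {
      n <- length(U0)
      U0 * (1 + complex(real = stats::rnorm(n, 0, noise_frac),
                        imaginary = stats::rnorm(n, 0, noise_frac)))
    })
  }
  measurement_set(Mod(U0), Arg(U0), side = "reference")
}

#' Build the Born sensitivity system
#'
#' Linearizes the forward problem: each entry maps a unit absorption contrast
#' in one voxel to the relative perturbation on one channel,
#' `W[c, v] = -G(s -> v) G(v -> d) Vvox / (D U0[s, d])`, so that
#' `USC ~ W delta_mua`. Rows are source-major (s1d1, s1d2, ...); columns
#' follow the grid's linear voxel order (or `voxel_idx` when given).
#'
#' @param geometry a `dot_probe`.
#' @param grid a `dot_grid`.
#' @param background a `dot_background`.
#' @param tikhonov_lambda Tikhonov regularization weight carried by the
#'   system for downstream reconstruction.
#' @param voxel_idx optional integer vector restricting columns to a voxel
#'   subset (used for sparse lesions and masked reconstruction).
#' @param constants output of [physics_constants()].
#' @return an object of class `dot_born` with fields `W`, `U0`, `grid`,
#'   `voxel_idx`, `background`, `tikhonov_lambda`.
#' @export
build_born_system <- function(geometry, grid, background,
                              tikhonov_lambda = 0, voxel_idx = NULL,
                              constants = physics_constants(
                                geometry$modulation_frequency)) {
  k <- wavenumber(background, constants)
  D <- diffusion_coefficient(background$musp0)
  coords <- grid_coords(grid)
  if (!is.null(voxel_idx)) coords <- coords[voxel_idx, , drop = FALSE]
  nv <- nrow(coords)
  r_floor <- 0.5 * sqrt(grid$dx^2 + grid$dy^2 + grid$dz^2)
  Gs <- matrix(0i, 9, nv)
  for (i in 1:9) {
    Gs[i, ] <- greens_semi_infinite(geometry$source_positions[i, ], coords, k,
                                    background, constants, r_floor = r_floor)
  }
  Gd <- matrix(0i, 14, nv)
  for (j in 1:14) {
    Gd[j, ] <- greens_semi_infinite(coords, geometry$detector_positions[j, ],
                                    k, background, constants,
                                    r_floor = r_floor)
  }
  U0 <- homogeneous_field(geometry, background, constants)
  vv <- voxel_volume(grid)
  W <- matrix(0i, 126, nv)
  for (s in 1:9) {
    rows <- (s - 1) * 14 + (1:14)
    W[rows, ] <- -(Gd * rep(Gs[s, ], each = 14)) * (vv / D) / U0[s, ]
  }
  if (!all(is.finite(Re(W)) & is.finite(Im(W))))
    stop("non-finite Born weight encountered")
  structure(list(W = W, U0 = U0, grid = grid, voxel_idx = voxel_idx,
                 background = background, geometry = geometry,
                 tikhonov_lambda = tikhonov_lambda, diffusion_D = D),
            class = "dot_born")
}

#' Simulate a relative perturbation from an absorption contrast
#'
#' Applies the Born system to a contrast volume and reshapes to the 9 x 14
#' channel layout, optionally adding seeded complex Gaussian noise expressed
#' as a fraction of the per-channel reference amplitude (the perturbation is
#' already normalized by the reference field, so the noise standard deviation
#' is `noise_frac` per real/imaginary component).
#'
#' @param system a `dot_born`.
#' @param delta_mua a `dot_volume` of contrast (delta mu_a), or a numeric
#'   vector matching the system's columns.
#' @param noise_frac relative noise amplitude (default 0).
#' @param seed optional integer seed for the noise.
#' @return a `dot_perturbation`.
#' @export
simulate_perturbation <- function(system, delta_mua, noise_frac = 0,
                                  seed = NULL) {
  if (inherits(delta_mua, "dot_volume")) {
    if (!grids_equal(delta_mua$grid, system$grid))
      stop("delta_mua grid does not match the Born system grid")
    v <- as.vector(delta_mua$values)
    if (!is.null(system$voxel_idx)) v <- v[system$voxel_idx]
  } else {
    v <- as.numeric(delta_mua)
    if (length(v) != ncol(system$W))
      stop("delta_mua length does not match the Born system")
  }
  vals <- as.vector(system$W %*% v)
  if (noise_frac > 0) {
    vals <- with_seed(seed, vals + complex(
      real = stats::rnorm(126, 0, noise_frac),
      imaginary = stats::rnorm(126, 0, noise_frac)))
  }
  perturbation(matrix(vals, nrow = 9, ncol = 14, byrow = TRUE))
}
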