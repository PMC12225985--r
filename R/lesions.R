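#' Spherical lesion specification
#'
#' @param center lesion center (x, y, z) in cm; z is depth below the probe.
#' @param radius lesion radius in cm.
#' @param mua_lesion lesion absorption coefficient in cm^-1.
#' @return an object of class `sphere_spec`.
#' @export
sphere_spec <- function(center, radius, mua_lesion) {
  stopifnot(length(center) == 3, radius > 0, mua_lesion > 0)
  structure(list(center = as.numeric(center), radius = radius,
                 mua_lesion = mua_lesion), class = "sphere_spec")
}

#' Irregular (island-blur) lesion specification
#'
#' Parameters of the four-step irregular-target generator: place one to
#' three random islands inside the bounding box, Gaussian-blur, normalize
#' to \[0, 1\], and scale by the maximum absorption level.
#'
#' @param center lateral/depth center (x, y, z) of the bounding box in cm.
#' @param bounding_dims full extents (lx, ly, lz) of the bounding box in cm.
#' @param n_islands number of islands, 1 to 3.
#' @param blur_sigma Gaussian blur width in cm (default 0.3).
#' @param mua_max maximum absorption level in cm^-1 (0.10 to 0.30 by
#'   default sampling).
#' @param seed integer seed making the target fully regenerable.
#' @return an object of class `irregular_spec`.
#' @export
irregular_spec <- function(center, bounding_dims, n_islands, blur_sigma = 0.3,
                           mua_max, seed) {
  if (n_islands < 1 || n_islands > 3) stop("n_islands must be in 1..3")
  if (blur_sigma <= 0) stop("blur_sigma must be positive")
  stopifnot(mua_max > 0)
  structure(list(center = as.numeric(center),
                 bounding_dims = as.numeric(bounding_dims),
                 n_islands = as.integer(n_islands), blur_sigma = blur_sigma,
                 mua_max = mua_max, seed = as.integer(seed)),
            class = "irregular_spec")
}

#' Rasterize a spherical lesion as a contrast volume
#'
#' Voxels whose centers fall inside the sphere receive
#' `delta = mua_lesion - mua0`; all others are zero.
#'
#' @param spec a [sphere_spec()].
#' @param grid a `dot_grid`.
#' @param mua0 background absorption in cm^-1.
#' @return a `dot_volume` of kind `"delta"`.
#' @export
rasterize_sphere <- function(spec, grid, mua0) {
  co <- grid_coords(grid)
  inside <- (co[, 1] - spec$center[1])^2 + (co[, 2] - spec$center[2])^2 +
    (co[, 3] - spec$center[3])^2 <= spec$radius^2
  if (!any(inside)) stop("sphere lies fully outside the reconstruction grid")
  vals <- numeric(nrow(co))
  vals[inside] <- spec$mua_lesion - mua0
  absorption_volume(vals, grid, kind = "delta")
}

# separable Gaussian blur of an nx x ny x nz array; sigma in cm per axis
gaussian_blur3 <- function(arr, sigma_vox) {
  blur_axis <- function(a, n, sigma) {
    if (sigma <= 0) return(a)
    half <- max(1L, ceiling(3 * sigma))
    kern <- stats::dnorm(seq(-half, half), sd = sigma)
    kern <- kern / sum(kern)
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- pmin(pmax(i + seq(-half, half), 1L), n)  # replicate edges
      for (t in seq_along(j)) K[i, j[t]] <- K[i, j[t]] + kern[t]
    }
    K %*% a
  }
  d <- dim(arr)
  m <- matrix(arr, d[1], d[2] * d[3])
  m <- blur_axis(m, d[1], sigma_vox[1])
  arr <- array(m, d)
  arr <- aperm(arr, c(2, 1, 3))
  m <- blur_axis(matrix(arr, d[2], d[1] * d[3]), d[2], sigma_vox[2])
  arr <- aperm(array(m, c(d[2], d[1], d[3])), c(2, 1, 3))
  arr <- aperm(arr, c(3, 1, 2))
  m <- blur_axis(matrix(arr, d[3], d[1] * d[2]), d[3], sigma_vox[3])
  aperm(array(m, c(d[3], d[1], d[2])), c(2, 3, 1))
}

#' Generate an irregular island-blur lesion target
#'
#' Implements the four-step generator: (1) drop `n_islands` random
#' super-ellipsoid islands inside the bounding box, (2) smooth with a
#' Gaussian blur, (3) normalize the result to \[0, 1\], (4) multiply by
#' `mua_max`. Deterministic given the spec's seed. If an extreme blur
#' flattens the volume to (numerically) nothing, the draw is retried with a
#' fresh sub-seed and a message is emitted.
#'
#' @param spec an [irregular_spec()].
#' @param grid a `dot_grid`.
#' @return a `dot_volume` of kind `"absolute"` whose global maximum equals
#'   `mua_max` exactly.
#' @export
generate_irregular <- function(spec, grid) {
  co <- grid_coords(grid)
  seed <- spec$seed
  for (attempt in 1:10) {
    vals <- with_seed(seed, {
      half <- spec$bounding_dims / 2
      acc <- numeric(nrow(co))
      for (i in seq_len(spec$n_islands)) {
        ctr <- spec$center + stats::runif(3, -0.5, 0.5) * half
        radii <- pmax(stats::runif(3, 0.25, 0.9) * half, 1e-6)
        p <- stats::runif(1, 1.5, 4)  # super-ellipsoid exponent jitter
        u <- (abs(co[, 1] - ctr[1]) / radii[1])^p +
          (abs(co[, 2] - ctr[2]) / radii[2])^p +
          (abs(co[, 3] - ctr[3]) / radii[3])^p
        acc <- acc + as.numeric(u <= 1)
      }
      acc
    })
    arr <- gaussian_blur3(array(vals, c(grid$nx, grid$ny, grid$nz)),
                          spec$blur_sigma / c(grid$dx, grid$dy, grid$dz))
    mx <- max(arr)
    if (mx > 1e-8) {
      return(absorption_volume(arr / mx * spec$mua_max, grid,
                               kind = "absolute"))
    }
    seed <- derive_seed(seed, attempt, salt = 7001)
    message("island draw vanished under blur; retrying with sub-seed ", seed)
  }
  stop("failed to generate a nonempty irregular target")
}

#' Build an inflated ellipsoidal ultrasound mask
#'
#' Ellipsoid at the lesion center with semi-axes `inflation` times the
#' lesion radii (2-3x, mirroring the deliberate over-sizing of masks drawn
#' from ultrasound), rasterized on the grid and clipped to it.
#'
#' @param center lesion center (x, y, z) in cm.
#' @param radii lesion semi-axes (rx, ry, rz) in cm (scalar recycled).
#' @param inflation factor in \[2, 3\].
#' @param grid a `dot_grid`.
#' @return a `dot_mask`.
#' @export
make_mask <- function(center, radii, inflation, grid) {
  if (inflation < 2 || inflation > 3)
    stop("mask inflation must lie in [2, 3]")
  radii <- rep(as.numeric(radii), length.out = 3)
  semi <- inflation * radii
  co <- grid_coords(grid)
  inside <- ((co[, 1] - center[1]) / semi[1])^2 +
    ((co[, 2] - center[2]) / semi[2])^2 +
    ((co[, 3] - center[3]) / semi[3])^2 <= 1
  if (!any(inside)) {
    # fully clipped: keep the voxel nearest the center so the mask is usable
    inside[which.min((co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 +
                       (co[, 3] - center[3])^2)] <- TRUE
  }
  lesion_mask(inside, grid, center = center, semi_axes = semi)
}

#' Default sampling ranges for the synthetic study
#'
#' Lesion radius 0.45-1.2 cm, lesion mu_a 0.10-0.30 cm^-1, lesion center
#' depth 0.5-3.0 cm, background mu_a 0.02-0.09 cm^-1, background mu_s'
#' 4-9 cm^-1, mask inflation 2-3x; lateral lesion centers within +/- 1 cm
#' of the probe axis (the region jointly covered by sources and detectors).
#'
#' @return named list of length-2 numeric ranges.
#' @export
default_ranges <- function() {
  list(radius = c(0.45, 1.2), mua_lesion = c(0.10, 0.30),
       depth = c(0.5, 3.0), lateral = c(-1, 1),
       mua0 = c(0.02, 0.09), musp0 = c(4, 9), inflation = c(2, 3),
       n_islands = c(1, 3), blur_sigma = c(0.3, 0.3))
}

#' Sample a synthetic training/evaluation dataset
#'
#' Labeled cases: a random background and spherical lesion are drawn, the
#' Born system is built for that background, and the noisy relative
#' perturbation, ground-truth contrast volume and inflated ultrasound mask
#' are attached. Unlabeled cases: irregular island-blur targets with masks
#' and backgrounds but no perturbation and no ground truth (regenerable from
#' their stored seed). All draws derive from `master_seed`.
#'
#' @param n_labeled,n_unlabeled case counts.
#' @param ranges sampling ranges, see [default_ranges()].
#' @param geometry a `dot_probe`.
#' @param grid a `dot_grid`.
#' @param master_seed integer master seed.
#' @param noise_frac relative measurement noise on labeled perturbations
#'   (default 0.01).
#' @return list of `dot_case` with attribute `manifest` (counts per
#'   provenance).
#' @export
sample_dataset <- function(n_labeled, n_unlabeled, ranges = default_ranges(),
                           geometry = default_probe_geometry(),
                           grid = recon_grid(), master_seed = 1L,
                           noise_frac = 0.01) {
  co <- grid_coords(grid)
  cases <- vector("list", n_labeled + n_unlabeled)
  runif_r <- function(r) stats::runif(1, r[1], r[2])
  for (i in seq_len(n_labeled)) {
    seed <- derive_seed(master_seed, i, salt = 1)
    cases[[i]] <- with_seed(seed, {
      bg <- optical_background(runif_r(ranges$mua0), runif_r(ranges$musp0),
                               modulation_frequency =
                                 geometry$modulation_frequency)
      sp <- sphere_spec(c(runif_r(ranges$lateral), runif_r(ranges$lateral),
                          runif_r(ranges$depth)),
                        runif_r(ranges$radius), runif_r(ranges$mua_lesion))
      vox <- which((co[, 1] - sp$center[1])^2 + (co[, 2] - sp$center[2])^2 +
                     (co[, 3] - sp$center[3])^2 <= sp$radius^2)
      if (length(vox) == 0)
        vox <- which.min((co[, 1] - sp$center[1])^2 +
                           (co[, 2] - sp$center[2])^2 +
                           (co[, 3] - sp$center[3])^2)
      sys <- build_born_system(geometry, grid, bg, voxel_idx = vox)
      delta <- rep(sp$mua_lesion - bg$mua0, length(vox))
      pert <- simulate_perturbation(sys, delta, noise_frac = noise_frac,
                                    seed = derive_seed(seed, 1, salt = 2))
      truth <- numeric(nrow(co)); truth[vox] <- delta
      mask <- make_mask(sp$center, sp$radius, runif_r(ranges$inflation), grid)
      case_record(perturbation = pert, background = bg, mask = mask,
                  truth = absorption_volume(truth, grid, kind = "delta"),
                  provenance = "born_spherical", seed = seed,
                  lesion_spec = sp, id = sprintf("L%06d", i))
    })
  }
  for (i in seq_len(n_unlabeled)) {
    seed <- derive_seed(master_seed, i, salt = 3)
    cases[[n_labeled + i]] <- with_seed(seed, {
      bg <- optical_background(runif_r(ranges$mua0), runif_r(ranges$musp0),
                               modulation_frequency =
                                 geometry$modulation_frequency)
      dims <- stats::runif(3, 2 * ranges$radius[1], 2 * ranges$radius[2])
      ctr <- c(runif_r(ranges$lateral), runif_r(ranges$lateral),
               runif_r(ranges$depth))
      spec <- irregular_spec(ctr, dims,
                             sample(ranges$n_islands[1]:ranges$n_islands[2], 1),
                             blur_sigma = runif_r(ranges$blur_sigma),
                             mua_max = runif_r(ranges$mua_lesion),
                             seed = derive_seed(seed, 2, salt = 4))
      mask <- make_mask(ctr, dims / 2, runif_r(ranges$inflation), grid)
      case_record(perturbation = NULL, background = bg, mask = mask,
                  truth = NULL, provenance = "irregular_unlabeled",
                  seed = seed, lesion_spec = spec,
                  id = sprintf("U%06d", i))
    })
  }
  attr(cases, "manifest") <- dataset_manifest(cases)
  attr(cases, "geometry") <- geometry
  attr(cases, "grid") <- grid
  cases
}

#' Counts per provenance for a case list
#' @param cases list of `dot_case`.
#' @return named integer vector.
#' @export
dataset_manifest <- function(cases) {
  prov <- vapply(cases, function(c) c$provenance, character(1))
  c(born_spherical = sum(prov == "born_spherical"),
    irregular_unlabeled = sum(prov == "irregular_unlabeled"))
}

#' Materialize the target volume of a case
#'
#' For labeled cases this is the stored ground-truth contrast; for irregular
#' cases the island-blur shape is regenerated deterministically from its
#' spec and seed.
#'
#' @param case a `dot_case`.
#' @param grid a `dot_grid`.
#' @return a `dot_volume`.
#' @export
case_target_volume <- function(case, grid = NULL) {
  if (!is.null(case$truth)) return(case$truth)
  if (inherits(case$lesion_spec, "irregular_spec")) {
    if (is.null(grid)) stop("grid required to regenerate an irregular target")
    return(generate_irregular(case$lesion_spec, grid))
  }
  stop("case has neither stored truth nor a regenerable spec")
}
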