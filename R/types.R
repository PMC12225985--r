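#' Amplitude/phase measurement set for one breast side
#'
#' A full acquisition is 9 x 14 x 2 numbers: amplitude and phase for every
#' source-detector pair. The lesion side carries the target; the contralateral
#' side serves as the homogeneous reference.
#'
#' @param amplitude 9 x 14 non-negative amplitudes.
#' @param phase 9 x 14 phases in radians.
#' @param side `"lesion"` or `"reference"`.
#' @param valid optional 9 x 14 logical matrix of valid channels.
#' @return an object of class `dot_measurement`.
#' @export
measurement_set <- function(amplitude, phase, side = c("lesion", "reference"),
                            valid = NULL) {
  side <- match.arg(side)
  amplitude <- as.matrix(amplitude); phase <- as.matrix(phase)
  if (!all(dim(amplitude) == c(9L, 14L)) || !all(dim(phase) == c(9L, 14L)))
    stop("amplitude and phase must both be 9 x 14 matrices")
  if (is.null(valid)) valid <- matrix(TRUE, 9, 14)
  if (any(amplitude[valid] <= 0))
    stop("amplitude must be strictly positive on valid channels")
  structure(list(amplitude = amplitude, phase = phase, side = side,
                 valid = valid),
            class = "dot_measurement")
}

#' Complex perturbation matrix
#'
#' The relative scattered field `(Ul - Ur) / Ur` per source-detector channel:
#' the datum consumed by every reconstruction route in the package.
#'
#' @param values 9 x 14 complex matrix.
#' @param channel_mask 9 x 14 logical matrix of valid channels.
#' @return an object of class `dot_perturbation`.
#' @export
perturbation <- function(values, channel_mask = NULL) {
  values <- as.matrix(values)
  if (!all(dim(values) == c(9L, 14L))) stop("perturbation must be 9 x 14")
  if (is.null(channel_mask)) channel_mask <- matrix(TRUE, 9, 14)
  if (!all(is.finite(Re(values)[channel_mask])) ||
      !all(is.finite(Im(values)[channel_mask])))
    stop("perturbation must be finite on all unmasked channels")
  structure(list(values = values, channel_mask = channel_mask),
            class = "dot_perturbation")
}

#' Homogeneous background optical properties
#'
#' Background absorption and reduced scattering of the tissue surrounding the
#' lesion, assumed homogeneous under the Born approximation. On construction
#' the complex diffuse-wave wavenumber is derived and its real/imaginary parts
#' (`kr`, `ki`) stored: `kr` sets the phase-vs-distance slope and `ki` the
#' log-amplitude decay of the photon-density wave.
#'
#' @param mua0 background absorption coefficient, cm^-1.
#' @param musp0 background reduced scattering coefficient, cm^-1.
#' @param refractive_index tissue refractive index (default 1.33).
#' @param modulation_frequency Hz, used to derive the wavenumber.
#' @return an object of class `dot_background` with fields `mua0`, `musp0`,
#'   `refractive_index`, `kr`, `ki`.
#' @export
optical_background <- function(mua0, musp0, refractive_index = 1.33,
                               modulation_frequency = 1.4e8) {
  if (!is.finite(mua0) || !is.finite(musp0) || mua0 <= 0 || musp0 <= 0)
    stop("mua0 and musp0 must be positive finite")
  if (mua0 >= musp0)
    stop("diffusion regime requires mua0 < musp0")
  bg <- structure(list(mua0 = mua0, musp0 = musp0,
                       refractive_index = refractive_index,
                       modulation_frequency = modulation_frequency),
                  class = "dot_background")
  k <- wavenumber(bg, physics_constants(modulation_frequency))
  bg$kr <- Re(k); bg$ki <- Im(k)
  bg
}

#' Absorption-coefficient volume
#'
#' A 3-D map of mu_a (or delta mu_a over background) on a reconstruction
#' grid. The default grid covers 9 x 9 cm laterally in 7 depth slices.
#'
#' @param values numeric array `nx x ny x nz` (cm^-1), or a vector of length
#'   `n_voxels(grid)` in grid ordering.
#' @param grid a `dot_grid`.
#' @param kind `"delta"` for contrast over background (may be any sign under
#'   noise) or `"absolute"` (must be non-negative).
#' @return an object of class `dot_volume`.
#' @export
absorption_volume <- function(values, grid, kind = c("delta", "absolute")) {
  kind <- match.arg(kind)
  dims <- c(grid$nx, grid$ny, grid$nz)
  if (is.null(dim(values))) {
    if (length(values) != prod(dims)) stop("values length does not match grid")
    values <- array(values, dims)
  }
  if (!all(dim(values) == dims)) stop("values dims do not match grid")
  if (!all(is.finite(values))) stop("absorption volume must be finite")
  if (kind == "absolute" && any(values < 0))
    stop("absolute mu_a volume must be non-negative")
  structure(list(values = values, grid = grid, kind = kind),
            class = "dot_volume")
}

#' Ellipsoidal lesion mask
#'
#' Region-of-interest mask derived from co-registered ultrasound: an ellipsoid
#' at the sonographically measured lesion center whose semi-axes are inflated
#' to 2-3x the measured lesion radii, so that the true lesion is certain to be
#' contained.
#'
#' @param values logical/0-1 array congruent with `grid`.
#' @param grid a `dot_grid`.
#' @param center lesion center (x, y, z) in cm.
#' @param semi_axes inflated ellipsoid semi-axes (rx, ry, rz) in cm.
#' @return an object of class `dot_mask`.
#' @export
lesion_mask <- function(values, grid, center, semi_axes) {
  dims <- c(grid$nx, grid$ny, grid$nz)
  if (is.null(dim(values))) values <- array(values, dims)
  if (!all(dim(values) == dims)) stop("mask dims do not match grid")
  values <- array(as.logical(values), dims)
  if (!any(values)) stop("lesion mask must be nonempty")
  structure(list(values = values, grid = grid, center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes)),
            class = "dot_mask")
}

#' One reconstruction case
#'
#' Bundles everything one reconstruction needs. Cases from the Born simulator
#' (`provenance = "born_spherical"`) carry the ground-truth contrast volume;
#' irregular island-blur cases (`provenance = "irregular_unlabeled"`) have no
#' ground-truth perturbation, so `truth` is absent and the target shape is
#' regenerable from the stored spec and seed.
#'
#' @param perturbation a `dot_perturbation`, or NULL for irregular cases.
#' @param background a `dot_background`.
#' @param mask a `dot_mask`.
#' @param truth a `dot_volume` (delta mu_a) or NULL.
#' @param provenance `"born_spherical"` or `"irregular_unlabeled"`.
#' @param seed integer seed the case was generated from.
#' @param lesion_spec the generating `sphere_spec()` or `irregular_spec()`.
#' @param id optional case identifier.
#' @return an object of class `dot_case`.
#' @export
case_record <- function(perturbation = NULL, background, mask, truth = NULL,
                        provenance = c("born_spherical", "irregular_unlabeled"),
                        seed = NA_integer_, lesion_spec = NULL, id = NULL) {
  provenance <- match.arg(provenance)
  if (provenance == "born_spherical" && is.null(truth))
    stop("born_spherical cases must carry a ground-truth volume")
  if (provenance == "irregular_unlabeled" && !is.null(truth))
    stop("irregular_unlabeled cases have unknown ground truth; truth must be absent")
  structure(list(perturbation = perturbation, background = background,
                 mask = mask, truth = truth, provenance = provenance,
                 seed = as.integer(seed), lesion_spec = lesion_spec, id = id),
            class = "dot_case")
}

#' @export
print.dot_volume <- function(x, ...) {
  cat(sprintf("<dot_volume %s> %d x %d x %d, max %.4g cm^-1\n", x$kind,
              x$grid$nx, x$grid$ny, x$grid$nz, max(x$values)))
  invisible(x)
}

#' @export
print.dot_case <- function(x, ...) {
  cat(sprintf("<dot_case %s> seed %d%s\n", x$provenance, x$seed,
              if (is.null(x$truth)) "" else sprintf(
                ", truth max %.3f cm^-1", max(x$truth$values))))
  invisible(x)
}

# complex 9x14 <-> length-252 real vector (re then im, channel source-major)
usc_to_vec <- function(values) {
  v <- as.vector(t(values))  # source-major channel order s0d0, s0d1, ...
  c(Re(v), Im(v))
}

vec_to_usc <- function(vec) {
  n <- length(vec) / 2
  v <- vec[seq_len(n)] + 1i * vec[n + seq_len(n)]
  matrix(v, nrow = 9, ncol = 14, byrow = TRUE)
}
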