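#' Probe geometry for a handheld US-guided DOT probe
#'
#' Positions of the optical sources and detectors on the probe face, plus the
#' modulation frequency of the frequency-domain system. The probe face lies in
#' the plane z = 0; z increases with depth into the tissue. All positions are
#' in cm.
#'
#' @param source_positions numeric matrix, 9 x 3, source (x, y, z) in cm with
#'   z = 0.
#' @param detector_positions numeric matrix, 14 x 3, detector (x, y, z) in cm
#'   with z = 0.
#' @param modulation_frequency modulation frequency in Hz (default 140 MHz).
#' @return an object of class `dot_probe`.
#' @export
probe_geometry <- function(source_positions, detector_positions,
                           modulation_frequency = 1.4e8) {
  source_positions <- as.matrix(source_positions)
  detector_positions <- as.matrix(detector_positions)
  if (nrow(source_positions) != 9L || ncol(source_positions) != 3L)
    stop("source_positions must be a 9 x 3 matrix (9 sources)")
  if (nrow(detector_positions) != 14L || ncol(detector_positions) != 3L)
    stop("detector_positions must be a 14 x 3 matrix (14 detectors)")
  if (any(source_positions[, 3] != 0) || any(detector_positions[, 3] != 0))
    stop("all probe-face positions must have z = 0")
  if (!is.numeric(modulation_frequency) || modulation_frequency <= 0)
    stop("modulation_frequency must be positive")
  geom <- structure(
    list(source_positions = source_positions,
         detector_positions = detector_positions,
         modulation_frequency = modulation_frequency),
    class = "dot_probe")
  rho <- source_detector_distances(geom)
  if (any(rho <= 0)) stop("all source-detector distances must be positive")
  geom
}

#' Default probe layout
#'
#' A 9 x 9 cm probe face with the ultrasound transducer slot in the center:
#' nine sources in a 3 x 3 grid on one side and fourteen detectors in a 2 x 7
#' grid on the other. Source-detector separations span roughly 3.2 to 8 cm,
#' which keeps the reference-side measurements in the regime where the
#' semi-infinite slope fits of the calibration module are accurate.
#'
#' @param modulation_frequency modulation frequency in Hz.
#' @return a `dot_probe`.
#' @export
default_probe_geometry <- function(modulation_frequency = 1.4e8) {
  src <- as.matrix(expand.grid(x = c(-3.5, -2.5, -1.5), y = c(-2, 0, 2)))
  det <- as.matrix(expand.grid(x = c(1.5, 3.0), y = seq(-3, 3, by = 1)))
  probe_geometry(cbind(src, z = 0), cbind(det, z = 0), modulation_frequency)
}

#' Source-detector distances on the probe face
#'
#' @param geometry a `dot_probe`.
#' @return 9 x 14 matrix of Euclidean distances rho in cm (z = 0 for both
#'   optodes).
#' @export
source_detector_distances <- function(geometry) {
  s <- geometry$source_positions
  d <- geometry$detector_positions
  outer(seq_len(nrow(s)), seq_len(nrow(d)), function(i, j) {
    sqrt((s[i, 1] - d[j, 1])^2 + (s[i, 2] - d[j, 2])^2)
  })
}

#' Reconstruction grid
#'
#' Regular voxel grid covering the 9 x 9 cm lateral field of view in `nz`
#' depth slices. Voxel centers sit at `origin + (i + 0.5) * d` along each
#' axis (0-based i), so the default grid spans x, y in (-4.5, 4.5) cm and
#' depth slices centered at 0.5, 1.0, ..., 3.5 cm.
#'
#' @param nx,ny,nz voxel counts (default 33 x 33 x 7).
#' @param dx,dy,dz voxel pitch in cm.
#' @param origin numeric length-3, corner of the grid in cm.
#' @return an object of class `dot_grid`.
#' @export
recon_grid <- function(nx = 33L, ny = 33L, nz = 7L,
                       dx = 9 / nx, dy = 9 / ny, dz = 0.5,
                       origin = c(-4.5, -4.5, 0.25)) {
  stopifnot(nx >= 1, ny >= 1, nz >= 1, dx > 0, dy > 0, dz > 0)
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
         dx = dx, dy = dy, dz = dz, origin = as.numeric(origin)),
    class = "dot_grid")
}

#' Number of voxels in a grid
#' @param grid a `dot_grid`.
#' @return integer voxel count.
#' @export
n_voxels <- function(grid) grid$nx * grid$ny * grid$nz

#' Voxel center coordinates
#'
#' Linear voxel ordering is column-major over (x, y, z): index
#' `v = ix + nx * (iy - 1) + nx * ny * (iz - 1)`, matching `as.vector()` on an
#' `nx x ny x nz` array.
#'
#' @param grid a `dot_grid`.
#' @return matrix `n_voxels x 3` of (x, y, z) voxel centers in cm.
#' @export
grid_coords <- function(grid) {
  xs <- grid$origin[1] + (seq_len(grid$nx) - 0.5) * grid$dx
  ys <- grid$origin[2] + (seq_len(grid$ny) - 0.5) * grid$dy
  zs <- grid$origin[3] + (seq_len(grid$nz) - 0.5) * grid$dz
  cbind(x = rep(xs, times = grid$ny * grid$nz),
        y = rep(rep(ys, each = grid$nx), times = grid$nz),
        z = rep(zs, each = grid$nx * grid$ny))
}

#' Grid axis coordinates
#' @param grid a `dot_grid`.
#' @return list with numeric vectors `x`, `y`, `z` of voxel-center coordinates.
#' @export
grid_axes <- function(grid) {
  list(x = grid$origin[1] + (seq_len(grid$nx) - 0.5) * grid$dx,
       y = grid$origin[2] + (seq_len(grid$ny) - 0.5) * grid$dy,
       z = grid$origin[3] + (seq_len(grid$nz) - 0.5) * grid$dz)
}

voxel_volume <- function(grid) grid$dx * grid$dy * grid$dz

grids_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a), unclass(b), tolerance = 1e-12))
}

#' @export
print.dot_probe <- function(x, ...) {
  cat("<dot_probe> 9 sources, 14 detectors,",
      sprintf("%.0f MHz modulation\n", x$modulation_frequency / 1e6))
  invisible(x)
}

#' @export
print.dot_grid <- function(x, ...) {
  cat(sprintf("<dot_grid> %d x %d x %d voxels, pitch (%.3f, %.3f, %.3f) cm\n",
              x$nx, x$ny, x$nz, x$dx, x$dy, x$dz))
  invisible(x)
}
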