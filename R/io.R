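#' Write a case archive
#'
#' HDF5 layout: `/geometry` (source/detector positions, modulation
#' frequency) and `/grid` stored once; one `/cases/<id>` group per case with
#' the complex perturbation split into real and imaginary planes, the
#' background coefficients, the mask parameters (masks are rasterized on
#' load), the lesion spec, provenance and seed. Ground-truth volumes of
#' labeled cases are stored dense; irregular targets are regenerated from
#' their seed on demand rather than stored.
#'
#' @param cases list of `dot_case` sharing one geometry and grid.
#' @param path output `.h5` file path (overwritten).
#' @param geometry a `dot_probe` (defaults to the attribute stored by
#'   [sample_dataset()]).
#' @param grid a `dot_grid` (same default).
#' @return invisibly, the manifest (named counts per provenance).
#' @export
write_dataset <- function(cases, path, geometry = attr(cases, "geometry"),
                          grid = attr(cases, "grid")) {
  geometry <- geometry %||% default_probe_geometry()
  grid <- grid %||% recon_grid()
  for (i in seq_along(cases)) {
    ci <- cases[[i]]
    if (!inherits(ci, "dot_case"))
      stop("element ", i, " is not a dot_case")
    if (!is.null(ci$truth) && !grids_equal(ci$truth$grid, grid))
      stop("case ", ci$id %||% i, " has a mismatched grid shape")
    if (!grids_equal(ci$mask$grid, grid))
      stop("case ", ci$id %||% i, " has a mismatched mask grid shape")
  }
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "geometry")
  rhdf5::h5write(geometry$source_positions, path, "geometry/source_positions")
  rhdf5::h5write(geometry$detector_positions, path,
                 "geometry/detector_positions")
  rhdf5::h5write(geometry$modulation_frequency, path,
                 "geometry/modulation_frequency")
  rhdf5::h5createGroup(path, "grid")
  rhdf5::h5write(c(grid$nx, grid$ny, grid$nz), path, "grid/shape")
  rhdf5::h5write(c(grid$dx, grid$dy, grid$dz), path, "grid/pitch")
  rhdf5::h5write(grid$origin, path, "grid/origin")
  rhdf5::h5createGroup(path, "cases")
  for (i in seq_along(cases)) {
    ci <- cases[[i]]
    g <- sprintf("cases/%s", ci$id %||% sprintf("case%06d", i))
    rhdf5::h5createGroup(path, g)
    rhdf5::h5write(ci$provenance, path, file.path(g, "provenance"))
    rhdf5::h5write(ci$seed, path, file.path(g, "seed"))
    rhdf5::h5write(c(ci$background$mua0, ci$background$musp0,
                     ci$background$refractive_index), path,
                   file.path(g, "background"))
    rhdf5::h5write(ci$mask$center, path, file.path(g, "mask_center"))
    rhdf5::h5write(ci$mask$semi_axes, path, file.path(g, "mask_semi_axes"))
    if (!is.null(ci$perturbation)) {
      rhdf5::h5write(Re(ci$perturbation$values), path,
                     file.path(g, "perturbation_real"))
      rhdf5::h5write(Im(ci$perturbation$values), path,
                     file.path(g, "perturbation_imag"))
      rhdf5::h5write(ci$perturbation$channel_mask + 0L, path,
                     file.path(g, "channel_mask"))
    }
    if (!is.null(ci$truth))
      rhdf5::h5write(ci$truth$values, path, file.path(g, "truth"))
    sp <- ci$lesion_spec
    if (inherits(sp, "sphere_spec")) {
      rhdf5::h5write(c(sp$center, sp$radius, sp$mua_lesion), path,
                     file.path(g, "sphere_spec"))
    } else if (inherits(sp, "irregular_spec")) {
      rhdf5::h5write(c(sp$center, sp$bounding_dims, sp$n_islands,
                       sp$blur_sigma, sp$mua_max, sp$seed), path,
                     file.path(g, "irregular_spec"))
    }
  }
  manifest <- dataset_manifest(cases)
  rhdf5::h5write(as.integer(manifest), path, "manifest")
  invisible(manifest)
}

#' Read a case archive written by [write_dataset()]
#'
#' Validates every record against the type invariants (shapes, finiteness,
#' truth present iff the provenance is `born_spherical`) and fails naming
#' the offending case.
#'
#' @param path `.h5` file path.
#' @return list of `dot_case` with `manifest`, `geometry` and `grid`
#'   attributes.
#' @export
read_dataset <- function(path) {
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  top <- rhdf5::h5ls(path, recursive = FALSE)$name
  if (!"geometry" %in% top) stop("format error: missing geometry group")
  if (!"grid" %in% top) stop("format error: missing grid group")
  geometry <- probe_geometry(
    rhdf5::h5read(path, "geometry/source_positions"),
    rhdf5::h5read(path, "geometry/detector_positions"),
    as.numeric(rhdf5::h5read(path, "geometry/modulation_frequency")))
  shp <- as.integer(rhdf5::h5read(path, "grid/shape"))
  pitch <- as.numeric(rhdf5::h5read(path, "grid/pitch"))
  origin <- as.numeric(rhdf5::h5read(path, "grid/origin"))
  grid <- recon_grid(shp[1], shp[2], shp[3], pitch[1], pitch[2], pitch[3],
                     origin)
  ids <- rhdf5::h5ls(path)
  ids <- ids$name[ids$group == "/cases" & ids$otype == "H5I_GROUP"]
  cases <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    g <- sprintf("cases/%s", ids[i])
    rec <- rhdf5::h5read(path, g)
    prov <- as.character(rec$provenance)
    pert <- NULL
    if (!is.null(rec$perturbation_real)) {
      re <- as.matrix(rec$perturbation_real)
      im <- as.matrix(rec$perturbation_imag)
      if (!all(dim(re) == c(9L, 14L)) || !all(dim(im) == c(9L, 14L)))
        stop("case ", ids[i], ": perturbation is not 9 x 14")
      if (!all(is.finite(re)) || !all(is.finite(im)))
        stop("case ", ids[i], ": non-finite perturbation values")
      pert <- perturbation(matrix(complex(real = re, imaginary = im), 9, 14),
                           channel_mask = matrix(
                             as.logical(rec$channel_mask), 9, 14))
    }
    bgv <- as.numeric(rec$background)
    bg <- optical_background(bgv[1], bgv[2], bgv[3],
                             geometry$modulation_frequency)
    ctr <- as.numeric(rec$mask_center)
    semi <- as.numeric(rec$mask_semi_axes)
    co <- grid_coords(grid)
    inside <- ((co[, 1] - ctr[1]) / semi[1])^2 +
      ((co[, 2] - ctr[2]) / semi[2])^2 +
      ((co[, 3] - ctr[3]) / semi[3])^2 <= 1
    if (!any(inside))
      inside[which.min((co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 +
                         (co[, 3] - ctr[3])^2)] <- TRUE
    mask <- lesion_mask(inside, grid, center = ctr, semi_axes = semi)
    truth <- NULL
    if (!is.null(rec$truth)) {
      tv <- rec$truth
      if (!all(dim(tv) == shp))
        stop("case ", ids[i], ": truth volume shape mismatch")
      truth <- absorption_volume(tv, grid, kind = "delta")
    }
    spec <- NULL
    if (!is.null(rec$sphere_spec)) {
      sv <- as.numeric(rec$sphere_spec)
      spec <- sphere_spec(sv[1:3], sv[4], sv[5])
    } else if (!is.null(rec$irregular_spec)) {
      sv <- as.numeric(rec$irregular_spec)
      spec <- irregular_spec(sv[1:3], sv[4:6], sv[7], sv[8], sv[9],
                             as.integer(sv[10]))
    }
    cases[[i]] <- case_record(perturbation = pert, background = bg,
                              mask = mask, truth = truth,
                              provenance = prov,
                              seed = as.integer(rec$seed),
                              lesion_spec = spec, id = ids[i])
  }
  attr(cases, "manifest") <- dataset_manifest(cases)
  attr(cases, "geometry") <- geometry
  attr(cases, "grid") <- grid
  cases
}
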