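#' Maximum absorption coefficient of a volume
#'
#' @param volume a `dot_volume` (or numeric array).
#' @return global maximum in cm^-1.
#' @export
max_mua <- function(volume) {
  v <- if (inherits(volume, "dot_volume")) volume$values else volume
  if (!all(is.finite(v))) stop("volume must be finite")
  max(v)
}

#' 50 percent-contour diameter of an absorption map
#'
#' Takes the depth slice containing the volume's global maximum, draws the
#' iso-contour at `C = 0.5 * max` by marching squares with linear sub-voxel
#' interpolation, keeps the contour enclosing the maximum (lesion-centric
#' choice when several exist), and returns the largest pairwise Euclidean
#' distance between contour points:
#' `D = max_ij sqrt((xi - xj)^2 + (yi - yj)^2)`.
#'
#' @param volume a `dot_volume` with a positive maximum.
#' @param level_frac contour level as a fraction of the maximum (0.5).
#' @return an object of class `dot_contour` with `level` (cm^-1),
#'   `diameter` (cm), `slice_index`, and the contour `points` matrix.
#' @export
contour_diameter <- function(volume, level_frac = 0.5) {
  grid <- volume$grid
  v <- volume$values
  mx <- max(v)
  if (mx <= 0) stop("undefined contour: the volume has no positive maximum")
  C <- level_frac * mx
  # the slice containing the global maximum; plateau maxima can span
  # several slices, in which case the widest supra-level cross-section
  # (the lesion's equator) breaks the tie
  peak_slices <- unique(which(v == mx, arr.ind = TRUE)[, 3])
  iz <- peak_slices[which.max(vapply(peak_slices, function(z)
    sum(v[, , z] >= C), numeric(1)))]
  slice <- v[, , iz]
  idx <- which(slice == mx, arr.ind = TRUE)[1, ]
  idx <- c(idx, iz)
  ax <- grid_axes(grid)
  supra <- slice >= C
  if (sum(supra) <= 1) {
    return(structure(list(level = C, diameter = 0, slice_index = iz,
                          points = NULL), class = "dot_contour"))
  }
  cl <- grDevices::contourLines(ax$x, ax$y, slice, levels = C)
  if (length(cl) == 0) {
    return(structure(list(level = C, diameter = 0, slice_index = iz,
                          points = NULL), class = "dot_contour"))
  }
  peak <- c(ax$x[idx[1]], ax$y[idx[2]])
  pick <- NULL
  for (cc in cl) {
    if (point_in_polygon(peak, cc$x, cc$y)) { pick <- cc; break }
  }
  if (is.null(pick)) {
    # open contour at the grid edge, or the peak on the contour itself:
    # fall back to the contour nearest the peak
    d2 <- vapply(cl, function(cc)
      min((cc$x - peak[1])^2 + (cc$y - peak[2])^2), numeric(1))
    pick <- cl[[which.min(d2)]]
  }
  pts <- cbind(pick$x, pick$y)
  structure(list(level = C, diameter = max_pairwise_distance(pts),
                 slice_index = unname(iz), points = pts),
            class = "dot_contour")
}

# ray-casting point-in-polygon test
point_in_polygon <- function(p, px, py) {
  n <- length(px)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    if ((py[i] > p[2]) != (py[j] > p[2]) &&
        p[1] < (px[j] - px[i]) * (p[2] - py[i]) / (py[j] - py[i]) + px[i])
      inside <- !inside
    j <- i
  }
  inside
}

max_pairwise_distance <- function(pts) {
  if (nrow(pts) < 2) return(0)
  hull <- grDevices::chull(pts)
  h <- pts[hull, , drop = FALSE]
  d2 <- outer(seq_len(nrow(h)), seq_len(nrow(h)), function(i, j) {
    (h[i, 1] - h[j, 1])^2 + (h[i, 2] - h[j, 2])^2
  })
  sqrt(max(d2))
}

#' Coefficient of determination of predictions against truth
#'
#' `R^2 = 1 - SS_res / SS_tot` of `pred` against `truth` (no refitting:
#' predictions are compared to the identity line).
#'
#' @param pred,truth equal-length numeric vectors (length >= 2, truth not
#'   constant).
#' @return dimensionless scalar (1 = perfect agreement).
#' @export
r_squared <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(truth) >= 2)
  sst <- sum((truth - mean(truth))^2)
  if (sst == 0) stop("truth is constant; R^2 undefined")
  1 - sum((pred - truth)^2) / sst
}

#' Group contrast of maximum absorption
#'
#' Per-group mean, SD and normal-approximation 95% confidence interval of
#' the maximum absorption coefficient: the synthetic analog of contrasting
#' low-absorption (benign-like) and high-absorption (malignant-like)
#' lesion groups.
#'
#' @param volumes_by_group named list of lists of `dot_volume` (>= 2
#'   volumes per group).
#' @return a tibble with columns `group`, `n`, `mean`, `sd`, `ci_lo`,
#'   `ci_hi`.
#' @export
group_contrast <- function(volumes_by_group) {
  rows <- lapply(names(volumes_by_group), function(g) {
    vols <- volumes_by_group[[g]]
    if (length(vols) < 2) stop("group '", g, "' needs >= 2 cases")
    x <- vapply(vols, max_mua, numeric(1))
    m <- mean(x); s <- stats::sd(x)
    half <- 1.96 * s / sqrt(length(x))
    tibble::tibble(group = g, n = length(x), mean = m, sd = s,
                   ci_lo = m - half, ci_hi = m + half)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.dot_contour <- function(x, ...) {
  cat(sprintf("<dot_contour> level %.4g cm^-1, diameter %.3f cm (slice %d)\n",
              x$level, x$diameter, x$slice_index))
  invisible(x)
}
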