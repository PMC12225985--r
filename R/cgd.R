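#' Settings for the regularized conjugate-gradient baseline
#'
#' @param tikhonov_lambda Tikhonov weight; `NULL` selects it by the
#'   discrepancy principle against `noise_floor`.
#' @param max_iterations iteration cap (default 500).
#' @param residual_tolerance relative residual stopping threshold.
#' @param roi_policy `"mask_only"` restricts unknowns to the ultrasound mask.
#' @param noise_floor relative data-noise level used by the discrepancy rule.
#' @return an object of class `cgd_settings`.
#' @export
cgd_settings <- function(tikhonov_lambda = NULL, max_iterations = 500L,
                         residual_tolerance = 1e-6,
                         roi_policy = c("mask_only", "full"),
                         noise_floor = 0.01) {
  roi_policy <- match.arg(roi_policy)
  if (!is.null(tikhonov_lambda) && tikhonov_lambda < 0)
    stop("tikhonov_lambda must be >= 0")
  if (max_iterations < 1) stop("max_iterations must be >= 1")
  if (residual_tolerance <= 0 || residual_tolerance >= 1)
    stop("residual_tolerance must be in (0, 1)")
  structure(list(tikhonov_lambda = tikhonov_lambda,
                 max_iterations = as.integer(max_iterations),
                 residual_tolerance = residual_tolerance,
                 roi_policy = roi_policy, noise_floor = noise_floor),
            class = "cgd_settings")
}

#' Tikhonov objective of a candidate reconstruction
#'
#' `||USC - W delta_mua||^2 + lambda^2 ||delta_mua||^2` over the unmasked
#' channels, with the complex residual counted as stacked real and imaginary
#' parts.
#'
#' @param perturbation a `dot_perturbation`.
#' @param system a `dot_born`.
#' @param delta_mua numeric vector over the system's columns, or a
#'   `dot_volume`.
#' @param tikhonov_lambda overrides the system's lambda when given.
#' @return non-negative scalar.
#' @export
cgd_objective <- function(perturbation, system, delta_mua,
                          tikhonov_lambda = NULL) {
  lam <- tikhonov_lambda %||% system$tikhonov_lambda
  x <- if (inherits(delta_mua, "dot_volume")) {
    v <- as.vector(delta_mua$values)
    if (!is.null(system$voxel_idx)) v[system$voxel_idx] else v
  } else as.numeric(delta_mua)
  ch <- as.vector(t(perturbation$channel_mask))
  b <- as.vector(t(perturbation$values))[ch]
  r <- b - as.vector(system$W[ch, , drop = FALSE] %*% x)
  sum(Re(r)^2 + Im(r)^2) + lam^2 * sum(x^2)
}

#' Baseline reconstruction by Tikhonov-regularized conjugate gradients
#'
#' Minimizes `||USC - W delta_mua||^2 + lambda^2 ||delta_mua||^2` over the
#' voxels selected by the ultrasound-derived mask (under the default
#' `mask_only` policy), by conjugate gradients on the regularized normal
#' equations with real and imaginary channel rows stacked (252 rows for the
#' full probe). Voxels outside the region of interest are returned as zero.
#'
#' @param perturbation a `dot_perturbation`.
#' @param system a `dot_born` built on the full grid (no `voxel_idx`), or on
#'   exactly the mask voxels.
#' @param mask a `dot_mask`; ignored under `roi_policy = "full"`.
#' @param settings a [cgd_settings()].
#' @return a `dot_volume` (delta mu_a) with attributes `objective_trace`,
#'   `iterations`, `converged`, `tikhonov_lambda`.
#' @export
reconstruct_cgd <- function(perturbation, system, mask = NULL,
                            settings = cgd_settings()) {
  grid <- system$grid
  if (settings$roi_policy == "mask_only") {
    if (is.null(mask)) stop("mask_only policy requires a lesion mask")
    roi <- which(as.vector(mask$values))
    if (length(roi) == 0) stop("empty region of interest")
  } else {
    roi <- seq_len(if (is.null(system$voxel_idx)) n_voxels(grid)
                   else ncol(system$W))
  }
  cols <- if (is.null(system$voxel_idx)) roi else {
    m <- match(roi, system$voxel_idx)
    if (anyNA(m)) stop("system columns do not cover the mask voxels")
    m
  }
  ch <- as.vector(t(perturbation$channel_mask))
  Wc <- system$W[ch, cols, drop = FALSE]
  A <- rbind(Re(Wc), Im(Wc))
  bvec <- as.vector(t(perturbation$values))[ch]
  b <- c(Re(bvec), Im(bvec))
  lam <- settings$tikhonov_lambda %||%
    discrepancy_lambda(A, b, settings$noise_floor)
  # CG on (A'A + lam^2 I) x = A'b
  x <- numeric(ncol(A))
  Atb <- crossprod(A, b)
  r <- Atb  # residual of the normal equations at x = 0
  p <- r
  rs <- sum(r^2)
  obj <- function(x) {
    res <- b - A %*% x
    sum(res^2) + lam^2 * sum(x^2)
  }
  trace <- obj(x)
  nrm_atb <- sqrt(rs)
  it <- 0L
  while (it < settings$max_iterations) {
    it <- it + 1L
    Ap <- crossprod(A, A %*% p) + lam^2 * p
    alpha <- rs / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    rs_new <- sum(r^2)
    trace <- c(trace, obj(x))
    if (sqrt(rs_new) < settings$residual_tolerance * nrm_atb) break
    p <- r + (rs_new / rs) * p
    rs <- rs_new
  }
  converged <- sqrt(sum(r^2)) < settings$residual_tolerance * nrm_atb
  if (!converged)
    warning(sprintf("CGD stopped at %d iterations with relative residual %.2e",
                    it, sqrt(sum(r^2)) / nrm_atb))
  full <- numeric(n_voxels(grid))
  idx <- if (is.null(system$voxel_idx)) roi else system$voxel_idx[cols]
  full[idx] <- x
  out <- absorption_volume(full, grid, kind = "delta")
  attr(out, "objective_trace") <- trace
  attr(out, "iterations") <- it
  attr(out, "converged") <- converged
  attr(out, "tikhonov_lambda") <- lam
  out
}

# Discrepancy principle: smallest lambda on a geometric grid whose Tikhonov
# solution leaves a data residual at or above the noise floor. Uses the dual
# (channel-space) form, so the cost is one m x m eigendecomposition with
# m = 2 x channels regardless of voxel count.
discrepancy_lambda <- function(A, b, noise_floor) {
  target <- noise_floor * sqrt(length(b))
  e <- eigen(tcrossprod(A), symmetric = TRUE)
  ev <- pmax(e$values, 0)
  bt <- as.vector(crossprod(e$vectors, b))
  lams <- sqrt(max(ev)) * 10^seq(-6, 0, by = 0.25)
  for (lam in lams) {
    res <- sqrt(sum((lam^2 / (ev + lam^2) * bt)^2))
    if (res >= target) return(lam)
  }
  lams[length(lams)]
}
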