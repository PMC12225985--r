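#' Compute the relative perturbation from paired measurements
#'
#' Per channel, with amplitude ratio `a = Al/Ar` and phase difference
#' `dphi = phi_l - phi_r`:
#' `USC = (a cos(dphi) - 1) + j a sin(dphi)`,
#' i.e. the complex ratio `(Ul - Ur)/Ur`. Channels whose reference amplitude
#' falls below `floor_frac` of the per-source maximum are masked out.
#'
#' @param lesion a `dot_measurement` from the lesion side.
#' @param reference a `dot_measurement` from the contralateral side.
#' @param floor_frac amplitude validity floor relative to each source's
#'   strongest channel (default 1e-6).
#' @return a `dot_perturbation`.
#' @export
compute_usc <- function(lesion, reference, floor_frac = 1e-6) {
  if (!inherits(lesion, "dot_measurement") ||
      !inherits(reference, "dot_measurement"))
    stop("inputs must be dot_measurement objects")
  Ar <- reference$amplitude
  floor_amp <- apply(Ar, 1, max) * floor_frac
  mask <- (Ar >= floor_amp) & lesion$valid & reference$valid
  if (any(Ar[mask] == 0)) {
    ch <- which(Ar == 0 & mask, arr.ind = TRUE)[1, ]
    stop(sprintf("zero reference amplitude on unmasked channel (s%d, d%d)",
                 ch[1], ch[2]))
  }
  a <- lesion$amplitude / Ar
  dphi <- lesion$phase - reference$phase
  vals <- complex(real = a * cos(dphi) - 1, imaginary = a * sin(dphi))
  vals[!mask] <- 0
  perturbation(matrix(vals, 9, 14), channel_mask = mask)
}

#' Unwrap phases along increasing source-detector distance
#'
#' 1-D unwrapping per source: channels are visited in order of increasing
#' rho and multiples of 2 pi are added/removed so that successive phase
#' differences stay within (-pi, pi].
#'
#' @param phase 9 x 14 phase matrix in radians.
#' @param rho 9 x 14 matrix of source-detector distances (cm); defaults to
#'   the standard probe layout.
#' @return unwrapped 9 x 14 phase matrix.
#' @export
phase_unwrap <- function(phase, rho = source_detector_distances(
                           default_probe_geometry())) {
  out <- phase
  for (s in 1:9) {
    ord <- order(rho[s, ])
    p <- phase[s, ord]
    for (i in seq_along(p)[-1]) {
      jump <- round((p[i] - p[i - 1]) / (2 * pi))
      p[i] <- p[i] - 2 * pi * jump
    }
    out[s, ord] <- p
  }
  out
}

#' Fit background optical properties from a reference measurement
#'
#' Semi-infinite slope calibration: regress `log(Ar rho^2)` and the unwrapped
#' phase against the source-detector distance rho (one pooled slope per
#' regressand, per-source intercepts absorbing source-strength differences).
#' The two slopes estimate `-Im(k)` and `Re(k)`; inverting the wavenumber
#' closed form yields `(mua0, musp0)`. Because the straight-line model is
#' only the asymptotic far-field form of the image-source Green's function,
#' a Gauss-Newton refinement against the full semi-infinite model (with
#' per-source complex gains profiled out) polishes the slope estimate;
#' set `refine = FALSE` for the raw slope inversion.
#'
#' @param reference a `dot_measurement` (reference side).
#' @param geometry a `dot_probe`.
#' @param constants output of [physics_constants()].
#' @param refractive_index assumed tissue refractive index.
#' @param refine logical; run the model-based refinement (default TRUE).
#' @return a `dot_background` with a `fit` attribute carrying slopes,
#'   intercepts, residual RMS and channel count.
#' @export
fit_background <- function(reference, geometry,
                           constants = physics_constants(
                             geometry$modulation_frequency),
                           refractive_index = 1.33, refine = TRUE) {
  rho <- source_detector_distances(geometry)
  ok <- reference$valid & (reference$amplitude > 0)
  if (sum(ok) < 3) stop("need at least 3 valid channels for the slope fit")
  if (diff(range(rho[ok])) < 1) stop("degenerate rho spread (< 1 cm)")
  src <- factor(row(rho)[ok])
  x <- rho[ok]
  y_amp <- log(reference$amplitude[ok] * x^2)
  ph <- phase_unwrap(reference$phase, rho)
  # anchor each source's phase so the pooled fit sees one smooth curve
  y_ph <- ph[ok]
  fit_amp <- stats::lm(y_amp ~ x + src)
  fit_ph <- stats::lm(y_ph ~ x + src)
  slope_amp <- unname(stats::coef(fit_amp)["x"])
  slope_ph <- unname(stats::coef(fit_ph)["x"])
  ki <- -slope_amp
  kr <- slope_ph
  if (kr <= 0 || ki <= 0)
    stop(paste0("non-physical fitted slopes (kr = ", signif(kr, 4),
                ", ki = ", signif(ki, 4),
                "): check the phase sign convention"))
  est <- invert_wavenumber(kr, ki, refractive_index, constants)
  if (refine) {
    U <- complex(modulus = reference$amplitude[ok], argument = ph[ok])
    obj <- function(p) {
      bg_try <- try(optical_background(exp(p[1]), exp(p[2]), refractive_index,
                                       constants$angular_frequency / (2 * pi)),
                    silent = TRUE)
      if (inherits(bg_try, "try-error")) return(1e6)
      U0 <- homogeneous_field(geometry, bg_try, constants)[ok]
      resid <- 0
      for (s in levels(src)) {
        i <- src == s
        g <- sum(Conj(U0[i]) * U[i]) / sum(Mod(U0[i])^2)  # per-source gain
        resid <- resid + sum(Mod(U[i] - g * U0[i])^2 / Mod(U[i])^2)
      }
      resid
    }
    opt <- stats::optim(log(c(est$mua0, est$musp0)), obj,
                        method = "Nelder-Mead",
                        control = list(reltol = 1e-12, maxit = 400))
    est <- list(mua0 = exp(opt$par[1]), musp0 = exp(opt$par[2]))
  }
  bg <- optical_background(est$mua0, est$musp0, refractive_index,
                           constants$angular_frequency / (2 * pi))
  attr(bg, "fit") <- list(
    slope_log_amp = slope_amp, slope_phase = slope_ph,
    ki = ki, kr = kr,
    residual_rms_amp = sqrt(mean(stats::resid(fit_amp)^2)),
    residual_rms_phase = sqrt(mean(stats::resid(fit_ph)^2)),
    channels_used = sum(ok), refined = refine)
  bg
}
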