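#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-case metric rows of an evaluation
#' @param x an `aegan_eval`.
#' @param ... unused.
#' @return the per-case tibble.
#' @method tidy aegan_eval
#' @export
tidy.aegan_eval <- function(x, ...) x$per_case

#' One-row summary of an evaluation
#' @param x an `aegan_eval`.
#' @param ... unused.
#' @return tibble with `n`, `r2_max_mua`, `r2_diameter` (plus baseline
#'   columns when present).
#' @method glance aegan_eval
#' @export
glance.aegan_eval <- function(x, ...) {
  out <- tibble::tibble(n = x$n, r2_max_mua = x$r2_max_mua,
                        r2_diameter = x$r2_diameter)
  if (!is.null(x$r2_cgd_max_mua)) {
    out$r2_cgd_max_mua <- x$r2_cgd_max_mua
    out$r2_cgd_diameter <- x$r2_cgd_diameter
  }
  out
}

#' Loss history of a training run
#' @param x an `aegan_fit`.
#' @param ... unused.
#' @return tibble of per-step losses.
#' @method tidy aegan_fit
#' @export
tidy.aegan_fit <- function(x, ...) x$history

#' One-row summary of a training run
#' @param x an `aegan_fit`.
#' @param ... unused.
#' @return tibble with epochs, steps and final-epoch mean losses.
#' @method glance aegan_fit
#' @export
glance.aegan_fit <- function(x, ...) {
  h <- x$history
  if (is.null(h) || nrow(h) == 0)
    return(tibble::tibble(epochs = 0L, steps = 0L))
  last <- h[h$epoch == max(h$epoch), ]
  tibble::tibble(epochs = max(h$epoch), steps = nrow(h),
                 l_p2p = mean(last$l_p2p), l_r = mean(last$l_r),
                 l_gan = mean(last$l_gan))
}

#' Slope-fit diagnostics of a calibrated background
#' @param x a `dot_background` returned by [fit_background()].
#' @param ... unused.
#' @return one-row tibble of coefficients and fit diagnostics.
#' @method glance dot_background
#' @export
glance.dot_background <- function(x, ...) {
  f <- attr(x, "fit")
  out <- tibble::tibble(mua0 = x$mua0, musp0 = x$musp0, kr = x$kr,
                        ki = x$ki)
  if (!is.null(f)) {
    out$slope_log_amp <- f$slope_log_amp
    out$slope_phase <- f$slope_phase
    out$residual_rms_amp <- f$residual_rms_amp
    out$residual_rms_phase <- f$residual_rms_phase
    out$channels_used <- f$channels_used
  }
  out
}
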