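#' Evaluate a trained model on labeled test cases
#'
#' Reconstructs every test case with the inverse operator, measures the
#' maximum absorption contrast and the 50 percent-contour diameter, and
#' summarizes agreement with the ground truth by the two headline
#' coefficients of determination. Optionally runs the conjugate-gradient
#' baseline on the same cases for side-by-side columns.
#'
#' @param bundle a trained `aegan_bundle`.
#' @param cases list of labeled `dot_case` (each with a truth volume).
#' @param include_cgd also reconstruct each case with [reconstruct_cgd()]
#'   (slower: builds a Born system per case).
#' @param geometry probe geometry used when `include_cgd = TRUE`.
#' @return an object of class `aegan_eval`: list with `per_case` (tibble:
#'   truth/predicted max contrast and diameter per case), `r2_max_mua`,
#'   `r2_diameter`, and `n`.
#' @export
evaluate <- function(bundle, cases, include_cgd = FALSE,
                     geometry = default_probe_geometry()) {
  stopifnot(length(cases) >= 1)
  grid <- bundle$config$grid
  prov <- vapply(cases, function(c) c$provenance, character(1))
  if (any(prov != "born_spherical"))
    stop("evaluation requires labeled cases with ground truth")
  la <- collate_labeled(cases, grid)
  R_hat <- inv_forward(bundle, la$M, la$U, la$Bg,
                       basis = radial_basis(la$centers, grid, bundle$config))
  n <- length(cases)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- cases[[i]]
    vol_hat <- absorption_volume(R_hat[i, ], grid, kind = "delta")
    true_d <- if (inherits(ci$lesion_spec, "sphere_spec"))
      2 * ci$lesion_spec$radius else
        contour_diameter(ci$truth)$diameter
    d_hat <- if (max(vol_hat$values) > 0)
      contour_diameter(vol_hat)$diameter else 0
    rows[[i]] <- tibble::tibble(
      id = ci$id %||% sprintf("case%04d", i),
      true_max_mua = max_mua(ci$truth),
      pred_max_mua = max_mua(vol_hat),
      true_diameter = true_d,
      pred_diameter = d_hat)
    if (include_cgd) {
      sys <- build_born_system(geometry, grid, ci$background)
      rec <- suppressWarnings(
        reconstruct_cgd(ci$perturbation, sys, ci$mask, cgd_settings()))
      rows[[i]]$cgd_max_mua <- max_mua(rec)
      rows[[i]]$cgd_diameter <- if (max(rec$values) > 0)
        contour_diameter(rec)$diameter else 0
    }
  }
  per_case <- dplyr::bind_rows(rows)
  out <- list(per_case = per_case,
              r2_max_mua = r_squared(per_case$pred_max_mua,
                                     per_case$true_max_mua),
              r2_diameter = r_squared(per_case$pred_diameter,
                                      per_case$true_diameter),
              n = n)
  if (include_cgd) {
    out$r2_cgd_max_mua <- r_squared(per_case$cgd_max_mua,
                                    per_case$true_max_mua)
    out$r2_cgd_diameter <- r_squared(per_case$cgd_diameter,
                                     per_case$true_diameter)
  }
  structure(out, class = "aegan_eval")
}

#' @export
print.aegan_eval <- function(x, ...) {
  cat(sprintf("<aegan_eval> %d cases: R^2(max mua) = %.3f, R^2(diameter) = %.3f\n",
              x$n, x$r2_max_mua, x$r2_diameter))
  invisible(x)
}

#' Input-ablation experiment
#'
#' Trains one model per input combination - the perturbation always on,
#' the mask and background optionally zero-filled at the network boundary
#' (architecture unchanged) - and reports mean absolute and mean squared
#' error of the reconstructed maximum absorption coefficient on held-out
#' labeled cases.
#'
#' @param train_cases labeled + irregular `dot_case` list for training.
#' @param test_cases labeled `dot_case` list for evaluation.
#' @param config a [training_config()] reused across every run (same seed,
#'   same schedule).
#' @param specs list of logical vectors over
#'   `c(perturbation, mask, background)`; defaults to the four standard
#'   rows.
#' @return a tibble with columns `ablation`, `mae`, `mse`, ordered as
#'   given.
#' @export
run_ablation <- function(train_cases, test_cases,
                         config = training_config(epochs = 6L),
                         specs = NULL) {
  if (is.null(specs)) {
    specs <- list(
      "perturbation only" = c(perturbation = TRUE, mask = FALSE,
                              background = FALSE),
      "perturbation + mask" = c(perturbation = TRUE, mask = TRUE,
                                background = FALSE),
      "perturbation + background" = c(perturbation = TRUE, mask = FALSE,
                                      background = TRUE),
      "perturbation + mask + background" = c(perturbation = TRUE,
                                             mask = TRUE, background = TRUE))
  }
  grid <- attr(train_cases, "grid") %||% recon_grid()
  rows <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    bundle <- init_aegan(aegan_config(grid = grid,
                                      inputs_enabled = specs[[i]]),
                         seed = derive_seed(config$master_seed, 1, 11))
    fit <- train(train_cases, config, bundle)
    ev <- evaluate(fit$bundle, test_cases)
    err <- ev$per_case$pred_max_mua - ev$per_case$true_max_mua
    rows[[i]] <- tibble::tibble(ablation = names(specs)[i],
                                mae = mean(abs(err)), mse = mean(err^2))
  }
  dplyr::bind_rows(rows)
}

#' End-to-end simulation study
#'
#' The package's headline experiment: sample a labeled + irregular training
#' set and a held-out labeled test set, train the hybrid model, and
#' evaluate maximum-absorption and contour-diameter agreement. Everything
#' derives from one seed.
#'
#' @param n_labeled,n_unlabeled,n_test dataset sizes.
#' @param config a [training_config()].
#' @param geometry a `dot_probe`.
#' @param grid a `dot_grid`.
#' @param seed master seed for data and initialization.
#' @param include_cgd include conjugate-gradient baseline columns in the
#'   evaluation.
#' @return list with `fit` (from [train()]), `eval` (an `aegan_eval`),
#'   `train_cases`, `test_cases`.
#' @export
run_study <- function(n_labeled = 5000L, n_unlabeled = 20000L,
                      n_test = 500L, config = training_config(),
                      geometry = default_probe_geometry(),
                      grid = recon_grid(), seed = 1L,
                      include_cgd = FALSE) {
  config$master_seed <- as.integer(seed)
  train_cases <- sample_dataset(n_labeled, n_unlabeled,
                                geometry = geometry, grid = grid,
                                master_seed = derive_seed(seed, 1, 101))
  test_cases <- sample_dataset(n_test, 0, geometry = geometry, grid = grid,
                               master_seed = derive_seed(seed, 2, 102))
  fit <- train(train_cases, config)
  ev <- evaluate(fit$bundle, test_cases, include_cgd = include_cgd,
                 geometry = geometry)
  list(fit = fit, eval = ev, train_cases = train_cases,
       test_cases = test_cases)
}
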