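#' Training configuration
#'
#' @param gan_weight weight of the adversarial term in the
#'   reconstruction-to-reconstruction objective (default 0.001).
#' @param batch_size cases per batch (default 32).
#' @param epochs passes over the labeled set.
#' @param lr_generator Adam learning rate of the single optimizer shared by
#'   the inverse and forward operators across both sequences.
#' @param lr_discriminator Adam learning rate of the discriminator's own
#'   optimizer.
#' @param master_seed seed fanning out to data order and initialization.
#' @param rmax_floor floor applied to the per-case maximum in the normalized
#'   loss terms.
#' @param usc_term_weight weight of the perturbation reconstruction term in
#'   the supervised loss; `NULL` (default) balances the per-element
#'   gradient scales of the volume and channel blocks by weighting the
#'   channel term `252 / n_voxels`.
#' @param fine_tune_fraction fraction of a transfer dataset used for
#'   fine-tuning (the rest evaluates), see [fine_tune()].
#' @param fine_tune_lr_factor learning-rate reduction during fine-tuning.
#' @param verbose print per-epoch loss summaries.
#' @return an object of class `training_config`.
#' @export
training_config <- function(gan_weight = 0.001, batch_size = 32L,
                            epochs = 10L, lr_generator = 1e-3,
                            lr_discriminator = 1e-3, master_seed = 1L,
                            rmax_floor = 1e-6, usc_term_weight = NULL,
                            fine_tune_fraction = 0.5,
                            fine_tune_lr_factor = 0.1, verbose = FALSE) {
  if (gan_weight <= 0) stop("gan_weight must be positive")
  structure(list(gan_weight = gan_weight,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr_generator = lr_generator,
                 lr_discriminator = lr_discriminator,
                 master_seed = as.integer(master_seed),
                 rmax_floor = rmax_floor,
                 usc_term_weight = usc_term_weight,
                 fine_tune_fraction = fine_tune_fraction,
                 fine_tune_lr_factor = fine_tune_lr_factor,
                 verbose = verbose),
            class = "training_config")
}

#' Supervised perturbation-to-perturbation loss
#'
#' Mean over the batch of three absolute-error terms: the volume error
#' `|R - Rhat|`, the same error normalized by each case's maximum
#' `|R - Rhat| / Rmax`, and the perturbation error `|USC - USChat|`
#' (volume terms averaged over voxels, the perturbation term over its 252
#' real components). Degenerate cases with `Rmax <= 0` have their
#' normalized term skipped with a warning.
#'
#' @param R,R_hat `B x n_voxels` truth and predicted volume matrices.
#' @param usc,usc_hat `B x 252` true and predicted perturbation values.
#' @param rmax optional per-case maxima (defaults to row maxima of `R`).
#' @param rmax_floor floor for the normalization.
#' @return non-negative scalar.
#' @export
p2p_loss <- function(R, R_hat, usc, usc_hat, rmax = NULL,
                     rmax_floor = 1e-6) {
  if (is.null(rmax)) rmax <- apply(R, 1, max)
  w <- rmax_weights(rmax, rmax_floor)
  mean(abs(R - R_hat)) + mean(w * abs(R - R_hat)) +
    mean(abs(usc - usc_hat))
}

rmax_weights <- function(rmax, rmax_floor) {
  bad <- rmax <= 0
  if (any(bad))
    warning(sum(bad), " case(s) with Rmax <= 0: normalized term skipped")
  w <- ifelse(bad, 0, 1 / pmax(rmax, rmax_floor))
  # one weight per row, broadcast over columns
  w
}

#' Reconstruction and adversarial losses of the R2R sequence
#'
#' Evaluates, without updating anything, the reconstruction loss
#' `L_R = mean(|R - Rhat| + |R - Rhat|/Rmax)` on irregular targets passed
#' through forward-then-inverse, the adversarial value
#' `L_GAN = E[log D(real)] + E[log(1 - D(fake))]` with real tuples drawn
#' from the labeled pool and fake tuples from the forward operator's
#' outputs, and the combined `L_R + gan_weight * L_GAN`.
#'
#' @param bundle an `aegan_bundle`.
#' @param irregular list of irregular `dot_case` (the fake/reconstruction
#'   batch).
#' @param labeled list of labeled `dot_case` (the real-sample pool).
#' @param gan_weight adversarial weight (default 0.001).
#' @param rmax_floor normalization floor.
#' @return list with `l_r`, `l_gan`, `l_total`.
#' @export
r2r_losses <- function(bundle, irregular, labeled, gan_weight = 0.001,
                       rmax_floor = 1e-6) {
  if (length(labeled) == 0)
    stop("the R2R sequence requires a concurrent labeled (real-sample) pool")
  grid <- bundle$config$grid
  un <- collate_unlabeled(irregular, grid)
  la <- collate_labeled(labeled, grid)
  usc_f <- fwd_forward(bundle, un$R, un$Bg)
  R_hat <- inv_forward(bundle, un$M, usc_f, un$Bg,
                       basis = radial_basis(un$centers, grid, bundle$config))
  w <- rmax_weights(un$rmax, rmax_floor)
  l_r <- mean(abs(un$R - R_hat)) + mean(w * abs(un$R - R_hat))
  p_real <- disc_forward(bundle, la$msum, la$Bg, la$U, la$rmax)
  p_fake <- disc_forward(bundle, un$msum, un$Bg, usc_f, un$rmax)
  eps <- .Machine$double.eps
  l_gan <- mean(log(pmax(p_real, eps))) + mean(log(pmax(1 - p_fake, eps)))
  list(l_r = l_r, l_gan = l_gan, l_total = l_r + gan_weight * l_gan)
}

# ---- batch collation ------------------------------------------------------

collate_labeled <- function(cases, grid) {
  nv <- n_voxels(grid)
  B <- length(cases)
  U <- matrix(0, B, 252L); Bg <- matrix(0, B, 2L)
  M <- matrix(0, B, nv); R <- matrix(0, B, nv)
  for (i in seq_len(B)) {
    ci <- cases[[i]]
    U[i, ] <- usc_to_vec(ci$perturbation$values)
    Bg[i, ] <- c(ci$background$mua0, ci$background$musp0)
    M[i, as.vector(ci$mask$values)] <- 1
    R[i, ] <- as.vector(ci$truth$values)
  }
  list(U = U, Bg = Bg, M = M, R = R, rmax = apply(R, 1, max),
       msum = mask_summary(lapply(cases, `[[`, "mask")),
       centers = t(vapply(cases, function(c) c$mask$center, numeric(3))))
}

collate_unlabeled <- function(cases, grid, volume_cache = NULL) {
  nv <- n_voxels(grid)
  B <- length(cases)
  Bg <- matrix(0, B, 2L); M <- matrix(0, B, nv); R <- matrix(0, B, nv)
  for (i in seq_len(B)) {
    ci <- cases[[i]]
    Bg[i, ] <- c(ci$background$mua0, ci$background$musp0)
    M[i, as.vector(ci$mask$values)] <- 1
    vol <- if (!is.null(volume_cache)) volume_cache(ci)
    else case_target_volume(ci, grid)
    R[i, ] <- as.vector(vol$values)
  }
  list(Bg = Bg, M = M, R = R, rmax = apply(R, 1, max),
       msum = mask_summary(lapply(cases, `[[`, "mask")),
       centers = t(vapply(cases, function(c) c$mask$center, numeric(3))))
}

# ---- training -------------------------------------------------------------

#' Train the hybrid model by alternating P2P and R2R sequences
#'
#' Every training step runs one supervised perturbation-to-perturbation
#' update of the shared inverse+forward operators on a labeled batch (the
#' discriminator untouched), followed by one reconstruction-to-
#' reconstruction step that updates the same operators on the combined
#' reconstruction + adversarial objective and then the discriminator on its
#' own adversarial objective. A single Adam optimizer serves the shared
#' operators across both sequences; the discriminator has its own.
#'
#' @param cases list of `dot_case` containing both provenances.
#' @param config a [training_config()].
#' @param bundle optional pre-initialized `aegan_bundle`; by default a
#'   small-preset bundle seeded from the config.
#' @return list with `bundle` (trained) and `history` (a tibble of per-step
#'   losses: `l_p2p`, `l_r`, `l_gan`, `l_total_r2r`).
#' @export
train <- function(cases, config = training_config(), bundle = NULL) {
  prov <- vapply(cases, function(c) c$provenance, character(1))
  labeled <- cases[prov == "born_spherical"]
  unlabeled <- cases[prov == "irregular_unlabeled"]
  if (length(labeled) == 0) stop("training requires labeled cases")
  if (length(unlabeled) == 0)
    stop("training requires irregular (unlabeled) cases for the R2R sequence")
  grid <- attr(cases, "grid") %||% labeled[[1]]$truth$grid
  if (is.null(bundle))
    bundle <- init_aegan(aegan_config(grid = grid),
                         seed = derive_seed(config$master_seed, 1, 11))
  params <- deep_copy_params(bundle$params)
  cfg <- bundle$config
  gen_names <- grep("^(inv|fwd)\\.", names(params), value = TRUE)
  disc_names <- grep("^disc\\.", names(params), value = TRUE)
  st_gen <- adam_state(); st_disc <- adam_state()
  la <- collate_labeled(labeled, grid)
  # compact cache of irregular volumes, filled on first use
  vol_cache <- new.env(parent = emptyenv())
  get_unlab <- function(idx) {
    B <- length(idx); nv <- n_voxels(grid)
    R <- matrix(0, B, nv); M <- matrix(0, B, nv); Bg <- matrix(0, B, 2)
    for (t in seq_len(B)) {
      ci <- unlabeled[[idx[t]]]
      key <- as.character(idx[t])
      if (is.null(vol_cache[[key]])) {
        v <- case_target_volume(ci, grid)
        nzi <- which(v$values != 0)
        vol_cache[[key]] <- list(i = nzi, x = v$values[nzi])
      }
      cv <- vol_cache[[key]]
      R[t, cv$i] <- cv$x
      M[t, as.vector(ci$mask$values)] <- 1
      Bg[t, ] <- c(ci$background$mua0, ci$background$musp0)
    }
    list(R = R, M = M, Bg = Bg, rmax = apply(R, 1, max),
         msum = un_msum[idx, , drop = FALSE],
         centers = un_centers[idx, , drop = FALSE])
  }
  un_msum <- mask_summary(lapply(unlabeled, `[[`, "mask"))
  un_centers <- t(vapply(unlabeled, function(c) c$mask$center, numeric(3)))
  n_lab <- length(labeled)
  w_usc <- config$usc_term_weight %||% (252 / n_voxels(grid))
  steps_per_epoch <- max(1L, n_lab %/% config$batch_size)
  hist <- vector("list", config$epochs * steps_per_epoch)
  step <- 0L
  lam <- config$gan_weight
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$master_seed, epoch, 21),
                     sample.int(n_lab))
    r2r_idx <- with_seed(derive_seed(config$master_seed, epoch, 22),
                         matrix(sample.int(length(unlabeled),
                                           steps_per_epoch *
                                             config$batch_size,
                                           replace = TRUE),
                                nrow = steps_per_epoch))
    real_idx <- with_seed(derive_seed(config$master_seed, epoch, 23),
                          matrix(sample.int(n_lab,
                                            steps_per_epoch *
                                              config$batch_size,
                                            replace = TRUE),
                                 nrow = steps_per_epoch))
    for (s in seq_len(steps_per_epoch)) {
      step <- step + 1L
      bi <- ord[((s - 1) * config$batch_size + 1):(s * config$batch_size)]
      # ---- P2P: supervised update of INV + FWD, D frozen ----
      tape <- ag_tape()
      Rb <- la$R[bi, , drop = FALSE]
      rmaxb <- la$rmax[bi]
      basis_b <- radial_basis(la$centers[bi, , drop = FALSE], grid, cfg)
      R_hat <- inv_forward(bundle, la$M[bi, , drop = FALSE],
                           la$U[bi, , drop = FALSE],
                           la$Bg[bi, , drop = FALSE], tape, params,
                           basis = basis_b)
      usc_hat <- fwd_forward(bundle, R_hat, la$Bg[bi, , drop = FALSE],
                             tape, params)
      w <- rmax_weights(rmaxb, config$rmax_floor)
      l1 <- ag_wmae(R_hat, Rb, NULL, tape)
      l2 <- ag_wmae(R_hat, Rb, matrix(w, nrow(Rb), ncol(Rb)), tape)
      l3 <- ag_wmae(usc_hat, la$U[bi, , drop = FALSE], NULL, tape)
      l_p2p <- ag_axpby(ag_axpby(l1, l2, tape = tape), l3, 1, w_usc,
                        tape = tape)
      if (!is.finite(ag_val(l_p2p)))
        stop("non-finite P2P loss at step ", step, " (labeled batch ",
             paste(bi[1:3], collapse = ","), "...)")
      grads <- ag_backward(l_p2p, tape)
      adam_step(params, grads[intersect(names(grads), gen_names)],
                st_gen, lr = config$lr_generator)
      # ---- R2R: generator objective on irregular targets ----
      un <- get_unlab(r2r_idx[s, ])
      tape <- ag_tape()
      usc_f <- fwd_forward(bundle, un$R, un$Bg, tape, params)
      R_hat2 <- inv_forward(bundle, un$M, usc_f, un$Bg, tape, params,
                            basis = radial_basis(un$centers, grid, cfg))
      wu <- rmax_weights(un$rmax, config$rmax_floor)
      lr1 <- ag_wmae(R_hat2, un$R, NULL, tape)
      lr2 <- ag_wmae(R_hat2, un$R, matrix(wu, nrow(un$R), ncol(un$R)), tape)
      l_r <- ag_axpby(lr1, lr2, tape = tape)
      fake_logits <- disc_forward(bundle, un$msum, un$Bg, usc_f, un$rmax,
                                  tape, params, logits = TRUE)
      # non-saturating generator loss -log D(fake)
      l_gen_adv <- ag_bce_logits(fake_logits, 1, tape)
      l_gen <- ag_axpby(l_r, l_gen_adv, 1, lam, tape)
      if (!is.finite(ag_val(l_gen)))
        stop("non-finite R2R generator loss at step ", step)
      grads <- ag_backward(l_gen, tape)
      adam_step(params, grads[intersect(names(grads), gen_names)],
                st_gen, lr = config$lr_generator)
      # ---- R2R: discriminator update (fake detached) ----
      ri <- real_idx[s, ]
      tape <- ag_tape()
      real_logits <- disc_forward(bundle, la$msum[ri, , drop = FALSE],
                                  la$Bg[ri, , drop = FALSE],
                                  la$U[ri, , drop = FALSE], la$rmax[ri],
                                  tape, params, logits = TRUE)
      fake_const <- ag_val(usc_f)
      fake_logits_d <- disc_forward(bundle, un$msum, un$Bg, fake_const,
                                    un$rmax, tape, params, logits = TRUE)
      bce_r <- ag_bce_logits(real_logits, 1, tape)
      bce_f <- ag_bce_logits(fake_logits_d, 0, tape)
      l_d <- ag_axpby(bce_r, bce_f, tape = tape)
      grads <- ag_backward(l_d, tape)
      adam_step(params, grads[intersect(names(grads), disc_names)],
                st_disc, lr = config$lr_discriminator)
      # classic minimax value of the adversarial term, for reporting
      l_gan_val <- -ag_val(l_d)
      hist[[step]] <- c(epoch = epoch, step = step,
                        l_p2p = ag_val(l_p2p), l_r = ag_val(l_r),
                        l_gan = l_gan_val,
                        l_total_r2r = ag_val(l_r) + lam * l_gan_val)
    }
    if (config$verbose) {
      ep <- do.call(rbind, hist[(step - steps_per_epoch + 1):step])
      message(sprintf(
        "epoch %d/%d  l_p2p %.4f  l_r %.4f  l_gan %.3f", epoch,
        config$epochs, mean(ep[, "l_p2p"]), mean(ep[, "l_r"]),
        mean(ep[, "l_gan"])))
    }
  }
  bundle$params <- params
  history <- tibble::as_tibble(do.call(rbind, hist))
  structure(list(bundle = bundle, history = history,
                 config = config), class = "aegan_fit")
}

#' Fine-tune a trained bundle on a new domain
#'
#' Continues training at a reduced learning rate on a (typically small)
#' labeled dataset from a shifted domain, mirroring the protocol of
#' adapting a simulation-trained model with phantom measurements. With
#' `epochs = 0` the bundle is returned unchanged.
#'
#' @param bundle a trained `aegan_bundle`.
#' @param cases labeled + irregular `dot_case` list of the new domain. If
#'   no irregular cases are present, only P2P updates run.
#' @param config a [training_config()]; its `epochs` and learning rates
#'   (times `fine_tune_lr_factor`) govern the fine-tuning run.
#' @return list with `bundle` and `history` (NULL when `epochs = 0`).
#' @export
fine_tune <- function(bundle, cases, config = training_config(epochs = 2L)) {
  if (config$epochs == 0L) {
    return(structure(list(bundle = bundle, history = NULL, config = config),
                     class = "aegan_fit"))
  }
  cfg <- config
  cfg$lr_generator <- config$lr_generator * config$fine_tune_lr_factor
  cfg$lr_discriminator <- config$lr_discriminator * config$fine_tune_lr_factor
  prov <- vapply(cases, function(c) c$provenance, character(1))
  if (!any(prov == "irregular_unlabeled")) {
    # P2P-only fine-tuning when the transfer set has no irregular targets
    fit <- train_p2p_only(cases[prov == "born_spherical"], cfg, bundle)
    return(fit)
  }
  train(cases, cfg, bundle)
}

# Supervised-only loop used for P2P-only fine-tuning and ablation presets.
train_p2p_only <- function(labeled, config, bundle) {
  grid <- bundle$config$grid
  w_usc <- config$usc_term_weight %||% (252 / n_voxels(grid))
  params <- deep_copy_params(bundle$params)
  gen_names <- grep("^(inv|fwd)\\.", names(params), value = TRUE)
  st_gen <- adam_state()
  la <- collate_labeled(labeled, grid)
  n_lab <- length(labeled)
  steps_per_epoch <- max(1L, n_lab %/% config$batch_size)
  hist <- list(); step <- 0L
  for (epoch in seq_len(config$epochs)) {
    ord <- with_seed(derive_seed(config$master_seed, epoch, 31),
                     sample.int(n_lab))
    for (s in seq_len(steps_per_epoch)) {
      step <- step + 1L
      bi <- ord[((s - 1) * config$batch_size + 1):
                  min(s * config$batch_size, n_lab)]
      tape <- ag_tape()
      Rb <- la$R[bi, , drop = FALSE]
      R_hat <- inv_forward(bundle, la$M[bi, , drop = FALSE],
                           la$U[bi, , drop = FALSE],
                           la$Bg[bi, , drop = FALSE], tape, params,
                           basis = radial_basis(la$centers[bi, , drop = FALSE],
                                                grid, bundle$config))
      usc_hat <- fwd_forward(bundle, R_hat, la$Bg[bi, , drop = FALSE],
                             tape, params)
      w <- rmax_weights(la$rmax[bi], config$rmax_floor)
      l1 <- ag_wmae(R_hat, Rb, NULL, tape)
      l2 <- ag_wmae(R_hat, Rb, matrix(w, nrow(Rb), ncol(Rb)), tape)
      l3 <- ag_wmae(usc_hat, la$U[bi, , drop = FALSE], NULL, tape)
      l_p2p <- ag_axpby(ag_axpby(l1, l2, tape = tape), l3, 1, w_usc,
                        tape = tape)
      grads <- ag_backward(l_p2p, tape)
      adam_step(params, grads[intersect(names(grads), gen_names)],
                st_gen, lr = config$lr_generator)
      hist[[step]] <- c(epoch = epoch, step = step, l_p2p = ag_val(l_p2p),
                        l_r = NA_real_, l_gan = NA_real_,
                        l_total_r2r = NA_real_)
    }
  }
  bundle$params <- params
  structure(list(bundle = bundle,
                 history = tibble::as_tibble(do.call(rbind, hist)),
                 config = config), class = "aegan_fit")
}

#' Hash of a parameter group (freeze-contract checks)
#' @param bundle an `aegan_bundle`.
#' @param prefix parameter-name prefix, e.g. `"disc"`.
#' @return character digest.
#' @export
param_hash <- function(bundle, prefix = "disc") {
  nms <- grep(paste0("^", prefix, "\\."), names(bundle$params), value = TRUE)
  v <- unlist(lapply(bundle$params[sort(nms)], as.vector), use.names = FALSE)
  paste(format(sum(v * seq_along(v)), digits = 17),
        format(sum(abs(v)), digits = 17))
}
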