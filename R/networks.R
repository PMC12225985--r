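#' Network configuration for the hybrid reconstruction model
#'
#' Presets size the inverse operator (attention/residual encoder-decoder
#' over the volume grid with a weight-shared lesion-centric radial head),
#' the forward operator (feed-forward residual network mapping volume to
#' 252 perturbation values) and the multilayer perceptron discriminator.
#' `"small"` is the desk-scale preset used by the bundled simulation study;
#' `"large"` approaches the 12.5M-parameter budget of the full-scale model.
#'
#' The perturbation enters the networks in a per-case normalized form: the
#' 252 real values divided by their root-mean-square (the channel pattern)
#' plus the log of that scale as one extra feature. This decouples lesion
#' geometry (pattern) from contrast (scale) across the large dynamic range
#' of the Born-linearized perturbation.
#'
#' @param preset `"small"` or `"large"`.
#' @param grid a `dot_grid`.
#' @param n_heads attention heads (embedding width must divide by it).
#' @param inputs_enabled named logical vector over
#'   `c("perturbation", "mask", "background")`; disabled inputs are
#'   zero-filled at the network boundary so the architecture is unchanged
#'   (the ablation mechanism). The perturbation is the primary signal and
#'   must stay enabled.
#' @param gate_floor additive floor of the multiplicative mask gate.
#' @return an object of class `aegan_config`.
#' @export
aegan_config <- function(preset = c("small", "large"), grid = recon_grid(),
                         n_heads = 4L,
                         inputs_enabled = c(perturbation = TRUE, mask = TRUE,
                                            background = TRUE),
                         gate_floor = 0.1) {
  preset <- match.arg(preset)
  if (!isTRUE(inputs_enabled[["perturbation"]]))
    stop("the perturbation input is the primary signal and cannot be disabled")
  w <- switch(preset,
              small = list(feat = 192L, token_dim = 32L, dec = 128L,
                           fwd = 128L, disc = c(128L, 64L),
                           n_blocks = 2L),
              large = list(feat = 384L, token_dim = 48L, dec = 768L,
                           fwd = 384L, disc = c(256L, 128L),
                           n_blocks = 2L))
  if (w$token_dim %% n_heads != 0)
    stop("token embedding width must be divisible by n_heads")
  structure(c(w, list(preset = preset, grid = grid,
                      n_heads = as.integer(n_heads),
                      n_tokens = w$feat %/% w$token_dim,
                      inputs_enabled = inputs_enabled,
                      gate_floor = gate_floor,
                      # fixed scalings (methods vignette): standardized
                      # background coefficients and output scale factors
                      bg_center = c(0.055, 6.5), bg_scale = c(0.0202, 1.44),
                      r_scale = 5, fwd_out_scale = 5, rmax_scale = 5,
                      # fixed Gaussian smoothing of the decoder output in
                      # voxel units (x, y, z): the smoothed-map prior
                      output_blur = c(0.8, 0.8, 0.5),
                      blur_kernels = list(
                        blur_matrix(grid$nx, 0.8),
                        blur_matrix(grid$ny, 0.8),
                        blur_matrix(grid$nz, 0.5)),
                      # radii (cm) and edge width of the lesion-centric
                      # radial-basis decoder head; the edge width equals
                      # the radius spacing so the half-maximum crossing
                      # interpolates continuously between radii
                      radial_radii = seq(0.3, 3.3, by = 0.3),
                      radial_tau = 0.3)),
            class = "aegan_config")
}

glorot <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / (n_in + n_out))), n_in, n_out)
}

#' Initialize the network bundle
#'
#' Creates the inverse operator, forward operator and discriminator
#' parameters with seeded Glorot-style initialization.
#'
#' @param config an [aegan_config()].
#' @param seed integer initialization seed.
#' @return an object of class `aegan_bundle` with elements `params`
#'   (named matrices, prefixed `inv.`, `fwd.`, `disc.`), `config`, `seed`.
#' @export
init_aegan <- function(config = aegan_config(), seed = 1L) {
  V <- n_voxels(config$grid)
  Ft <- config$feat; d <- config$token_dim
  p <- with_seed(seed, {
    p <- list()
    p[["inv.Wm"]] <- glorot(V, Ft)
    p[["inv.Wu"]] <- glorot(252L, Ft)
    p[["inv.wl"]] <- glorot(1L, Ft)   # log-scale feature
    p[["inv.b0"]] <- matrix(0, 1, Ft)
    p[["inv.We"]] <- glorot(2L, d)    # perturbation token embedding
    p[["inv.be"]] <- matrix(0, 1, d)
    for (i in seq_len(config$n_blocks)) {
      for (nm in c("Wqs", "Wks", "Wvs", "Wos",   # self-attention
                   "Wqc", "Wkc", "Wvc", "Woc"))  # cross-attention
        p[[sprintf("inv.%s%d", nm, i)]] <- glorot(d, d)
      p[[sprintf("inv.Wr1%d", i)]] <- glorot(Ft, Ft)
      p[[sprintf("inv.br1%d", i)]] <- matrix(0, 1, Ft)
      p[[sprintf("inv.Ws%d", i)]] <- glorot(2L, Ft)
      p[[sprintf("inv.bs%d", i)]] <- matrix(0, 1, Ft)
      p[[sprintf("inv.Wt%d", i)]] <- glorot(2L, Ft)
      p[[sprintf("inv.bt%d", i)]] <- matrix(0, 1, Ft)
      p[[sprintf("inv.Wr2%d", i)]] <- glorot(Ft, Ft) * 0.1
    }
    p[["inv.Wd1"]] <- glorot(Ft, config$dec)
    p[["inv.bd1"]] <- matrix(0, 1, config$dec)
    # dense output head: small weights so the early reconstruction is
    # dominated by the radial head
    p[["inv.Wd2"]] <- glorot(config$dec, V) * 0.3
    p[["inv.bd2"]] <- matrix(0, 1, V)
    K <- length(config$radial_radii)
    # dedicated radial branch: its own parameters keep the lesion-profile
    # learning signal out of the dense decoder's noisy Adam moments
    p[["inv.Wg1"]] <- glorot(262L, 128L)
    p[["inv.bg1"]] <- matrix(0, 1, 128L)
    p[["inv.Wg2"]] <- glorot(128L, 64L)
    p[["inv.bg2"]] <- matrix(0, 1, 64L)
    # profile = amplitude x softmax shape: the reconstruction maximum is
    # the single amplitude scalar, so its gradient aggregates the whole
    # in-profile voxel mass
    p[["inv.Wamp"]] <- glorot(64L, 1L) * 0.3
    p[["inv.bamp"]] <- matrix(0.5, 1, 1)
    p[["inv.Wsh"]] <- glorot(64L, K) * 0.3
    p[["inv.bsh"]] <- matrix(0, 1, K)
    Ff <- config$fwd
    p[["fwd.W1"]] <- glorot(V, Ff)
    p[["fwd.b1"]] <- matrix(0, 1, Ff)
    p[["fwd.Wr1"]] <- glorot(Ff, Ff)
    p[["fwd.br1"]] <- matrix(0, 1, Ff)
    p[["fwd.Ws"]] <- glorot(2L, Ff)
    p[["fwd.bs"]] <- matrix(0, 1, Ff)
    p[["fwd.Wt"]] <- glorot(2L, Ff)
    p[["fwd.bt"]] <- matrix(0, 1, Ff)
    p[["fwd.Wr2"]] <- glorot(Ff, Ff) * 0.1
    p[["fwd.W2"]] <- glorot(Ff, 252L)
    p[["fwd.b2"]] <- matrix(0, 1, 252L)
    dd <- config$disc
    # half-scale first layer keeps untrained scores near 0.5 despite the
    # wide dynamic range of the log-scale input
    p[["disc.W1"]] <- glorot(263L, dd[1]) * 0.5
    p[["disc.b1"]] <- matrix(0, 1, dd[1])
    p[["disc.W2"]] <- glorot(dd[1], dd[2])
    p[["disc.b2"]] <- matrix(0, 1, dd[2])
    p[["disc.W3"]] <- glorot(dd[2], 1L)
    p[["disc.b3"]] <- matrix(0, 1, 1L)
    p
  })
  structure(list(params = p, config = config, seed = as.integer(seed)),
            class = "aegan_bundle")
}

#' Parameter counts per sub-network
#' @param bundle an `aegan_bundle`.
#' @return named numeric vector with `inv`, `fwd`, `disc`, `total` and
#'   `generator` (inv + fwd, the budget the parameter comparisons use).
#' @export
count_params <- function(bundle) {
  n <- vapply(bundle$params, length, numeric(1))
  grp <- sub("\\..*$", "", names(n))
  out <- tapply(n, grp, sum)
  c(inv = unname(out["inv"]), fwd = unname(out["fwd"]),
    disc = unname(out["disc"]),
    generator = unname(out["inv"] + out["fwd"]), total = sum(n))
}

# wrap a parameter as a leaf node when recording, else pass the raw matrix
prm <- function(params, name, tape) {
  if (is.null(tape)) params[[name]] else ag_param(params[[name]], name, tape)
}

# fixed input preprocessing ------------------------------------------------

normalize_bg <- function(Bg, config) {
  sweep(sweep(Bg, 2, config$bg_center, "-"), 2, config$bg_scale, "/")
}

apply_ablation <- function(config, M, Bg) {
  en <- config$inputs_enabled
  if (!isTRUE(en[["mask"]])) M <- M * 0
  if (!isTRUE(en[["background"]])) Bg <- Bg * 0
  list(M = M, Bg = Bg)
}

# one attention block: self-attention then cross-attention from the
# normalized perturbation tokens, each with a residual connection
attention_block <- function(h, usc_tok, params, config, i, tape) {
  nt <- config$n_tokens
  nb <- nrow(ag_val(h))
  t <- ag_to_tokens(h, nt, tape)
  a_self <- ag_attention(
    ag_mm(t, prm(params, sprintf("inv.Wqs%d", i), tape), tape),
    ag_mm(t, prm(params, sprintf("inv.Wks%d", i), tape), tape),
    ag_mm(t, prm(params, sprintf("inv.Wvs%d", i), tape), tape),
    nb, config$n_heads, tape)
  h <- ag_add(h, ag_from_tokens(
    ag_mm(a_self, prm(params, sprintf("inv.Wos%d", i), tape), tape),
    nb, tape), tape)
  t <- ag_to_tokens(h, nt, tape)
  a_cross <- ag_attention(
    ag_mm(t, prm(params, sprintf("inv.Wqc%d", i), tape), tape),
    ag_mm(usc_tok, prm(params, sprintf("inv.Wkc%d", i), tape), tape),
    ag_mm(usc_tok, prm(params, sprintf("inv.Wvc%d", i), tape), tape),
    nb, config$n_heads, tape)
  ag_add(h, ag_from_tokens(
    ag_mm(a_cross, prm(params, sprintf("inv.Woc%d", i), tape), tape),
    nb, tape), tape)
}

# residual block conditioned on the background optical coefficients:
# u = relu(h W1 + b1) modulated by a learned affine embedding of
# (mua0, musp0) broadcast over features, then projected and added back
residual_block <- function(h, Bgn, params, prefix, i, tape) {
  nm <- function(s) if (is.null(i)) sprintf("%s.%s", prefix, s)
    else sprintf("%s.%s%d", prefix, s, i)
  u <- ag_relu(ag_addrow(ag_mm(h, prm(params, nm("Wr1"), tape), tape),
                         prm(params, nm("br1"), tape), tape), tape)
  s <- ag_addrow(ag_mm(Bgn, prm(params, nm("Ws"), tape), tape),
                 prm(params, nm("bs"), tape), tape)
  t <- ag_addrow(ag_mm(Bgn, prm(params, nm("Wt"), tape), tape),
                 prm(params, nm("bt"), tape), tape)
  # u * (1 + s) + t, written as u + u*s + t
  mod <- ag_add(ag_add(u, ag_mul(u, s, tape), tape), t, tape)
  ag_add(h, ag_mm(mod, prm(params, nm("Wr2"), tape), tape), tape)
}

#' Inverse operator: perturbation + mask + background to reconstruction
#'
#' Encoder-decoder over the flattened volume grid with alternating
#' attention blocks (self-attention plus cross-attention whose keys and
#' values come from the normalized perturbation tokens) and residual
#' blocks conditioned on the background optical coefficients. The decoder
#' sums a dense per-voxel path with a weight-shared radial-basis head
#' around the mask center, rectifies to non-negative values, applies the
#' fixed Gaussian smoothing, and gates multiplicatively by the ultrasound
#' mask plus a small floor so energy concentrates in the region of
#' interest.
#'
#' @param bundle an `aegan_bundle`.
#' @param M batch mask matrix, `B x n_voxels` (0/1).
#' @param U batch perturbation matrix, `B x 252` (re, im stacked in channel
#'   order), or an autograd node.
#' @param Bg batch background matrix, `B x 2` of (mua0, musp0).
#' @param tape optional autograd tape (NULL = fast inference).
#' @param params optional parameter list override.
#' @param basis radial basis array from [radial_basis()] for the batch.
#' @return `B x n_voxels` matrix (or node) of non-negative contrast values.
#' @export
inv_forward <- function(bundle, M, U, Bg, tape = NULL, params = NULL,
                        basis = NULL) {
  config <- bundle$config
  params <- params %||% bundle$params
  if (is.null(M) || is.null(U) || is.null(Bg))
    stop("inverse operator requires mask, perturbation and background ",
         "inputs; disable inputs explicitly via the config's inputs_enabled")
  if (is.null(basis))
    stop("inv_forward needs the lesion-centric radial basis; ",
         "build it with radial_basis()")
  if (!isTRUE(config$inputs_enabled[["mask"]]))
    basis <- lapply(basis, function(m) m * 0)
  inp <- apply_ablation(config, M, Bg)
  M <- inp$M; Bg <- inp$Bg
  Bgn <- if (isTRUE(config$inputs_enabled[["background"]]))
    normalize_bg(Bg, config) else Bg  # zero-filled when disabled
  # per-case scale normalization of the perturbation
  s <- ag_row_rms(U, tape)
  Un <- ag_rowdiv(U, s, tape)
  ls <- ag_log(s, tape)
  nb <- nrow(M)
  usc_tok <- ag_relu(ag_addrow(
    ag_mm(ag_usc_tokens(Un, tape), prm(params, "inv.We", tape), tape),
    prm(params, "inv.be", tape), tape), tape)
  h <- ag_relu(ag_addrow(ag_add(
    ag_add(ag_mm(M, prm(params, "inv.Wm", tape), tape),
           ag_mm(Un, prm(params, "inv.Wu", tape), tape), tape),
    ag_mm(ls, prm(params, "inv.wl", tape), tape), tape),
    prm(params, "inv.b0", tape), tape), tape)
  for (i in seq_len(config$n_blocks)) {
    h <- attention_block(h, usc_tok, params, config, i, tape)
    h <- residual_block(h, Bgn, params, "inv", i, tape)
  }
  d1 <- ag_relu(ag_addrow(ag_mm(h, prm(params, "inv.Wd1", tape), tape),
                          prm(params, "inv.bd1", tape), tape), tape)
  z <- ag_addrow(ag_mm(d1, prm(params, "inv.Wd2", tape), tape),
                 prm(params, "inv.bd2", tape), tape)
  # weight-shared radial head: non-negative coefficients over nested
  # smooth balls around the mask center, predicted by a dedicated branch
  # over the normalized perturbation, its log scale, the background and
  # pooled mask moments (absolute-value rectification: no saturating tail
  # for optimizer momentum to die in)
  mfeat <- mask_moments(M, config$grid)
  xr <- ag_cbind(list(Un, ls, Bgn, mfeat), tape)
  g1 <- ag_relu(ag_addrow(ag_mm(xr, prm(params, "inv.Wg1", tape), tape),
                          prm(params, "inv.bg1", tape), tape), tape)
  g2 <- ag_relu(ag_addrow(ag_mm(g1, prm(params, "inv.Wg2", tape), tape),
                          prm(params, "inv.bg2", tape), tape), tape)
  A <- ag_abs(ag_addrow(ag_mm(g2, prm(params, "inv.Wamp", tape), tape),
                        prm(params, "inv.bamp", tape), tape), tape)
  sh <- ag_rowsoftmax(ag_addrow(ag_mm(g2, prm(params, "inv.Wsh", tape), tape),
                                prm(params, "inv.bsh", tape), tape), tape)
  a_r <- ag_rowmul(sh, A, tape)
  rad <- ag_radial(a_r, basis, tape)
  # the dense path is rectified and smoothed (it mops up non-radial
  # structure); the radial profile is already smooth and stays sharp so
  # the peak and half-maximum contour calibrate against the truth
  dense <- ag_blur_rows(ag_abs(z, tape),
                        c(config$grid$nx, config$grid$ny, config$grid$nz),
                        config$blur_kernels, tape)
  out <- ag_add(dense, rad, tape)
  gate <- (M + config$gate_floor) / config$r_scale
  ag_mul(out, gate, tape)
}

#' Forward operator: reconstruction + background to perturbation
#'
#' Feed-forward residual network standing in for photon transport: maps a
#' contrast volume (plus the background coefficients it propagates in) to
#' the 252 real perturbation values.
#'
#' @inheritParams inv_forward
#' @param R batch volume matrix, `B x n_voxels`.
#' @return `B x 252` matrix (or node).
#' @export
fwd_forward <- function(bundle, R, Bg, tape = NULL, params = NULL) {
  config <- bundle$config
  params <- params %||% bundle$params
  if (is.null(R) || is.null(Bg))
    stop("forward operator requires reconstruction and background inputs")
  Bgn <- if (isTRUE(config$inputs_enabled[["background"]]))
    normalize_bg(ag_val(Bg), config) else ag_val(Bg) * 0
  Rin <- ag_scale(R, config$r_scale, tape)
  g <- ag_relu(ag_addrow(ag_mm(Rin, prm(params, "fwd.W1", tape), tape),
                         prm(params, "fwd.b1", tape), tape), tape)
  g <- residual_block(g, Bgn, params, "fwd", NULL, tape)
  ag_scale(ag_addrow(ag_mm(g, prm(params, "fwd.W2", tape), tape),
                     prm(params, "fwd.b2", tape), tape),
           config$fwd_out_scale, tape)
}

# pooled moment features of a batch mask matrix (B x V): volume fraction,
# center of mass and axis spreads, normalized to probe-scale units; zero
# rows (ablated masks) yield all-zero features
mask_moments <- function(M, grid) {
  co <- grid_coords(grid)
  n <- rowSums(M)
  safe <- pmax(n, 1)
  cx <- (M %*% co[, 1]) / safe
  cy <- (M %*% co[, 2]) / safe
  cz <- (M %*% co[, 3]) / safe
  sx <- sqrt(pmax((M %*% co[, 1]^2) / safe - cx^2, 0))
  sy <- sqrt(pmax((M %*% co[, 2]^2) / safe - cy^2, 0))
  sz <- sqrt(pmax((M %*% co[, 3]^2) / safe - cz^2, 0))
  out <- cbind(n / ncol(M), cx / 4.5, cy / 4.5, cz / 3.5,
               sx / 2, sy / 2, sz / 2)
  out[n == 0, ] <- 0
  out
}

# pooled 7-number mask summary for the discriminator: normalized center,
# semi-axes and in-mask volume fraction
mask_summary <- function(masks) {
  t(vapply(masks, function(m) {
    c(m$center / c(4.5, 4.5, 3.5), m$semi_axes / 3.5, mean(m$values))
  }, numeric(7)))
}

#' Discriminator: scores a (mask, background, perturbation, max R) tuple
#'
#' Multilayer perceptron over the concatenated pooled mask summary,
#' background coefficients, normalized perturbation (pattern + log scale)
#' and reconstruction maximum, ending in a sigmoid.
#'
#' @inheritParams inv_forward
#' @param Ms `B x 7` pooled mask summary.
#' @param rmax length-B vector of per-case reconstruction maxima (cm^-1).
#' @param logits return pre-sigmoid scores (training).
#' @return `B x 1` matrix (or node) of scores; probabilities in (0, 1)
#'   unless `logits = TRUE`.
#' @export
disc_forward <- function(bundle, Ms, Bg, U, rmax, tape = NULL, params = NULL,
                         logits = FALSE) {
  config <- bundle$config
  params <- params %||% bundle$params
  Bgn <- normalize_bg(ag_val(Bg), config)
  s <- ag_row_rms(U, tape)
  Un <- ag_rowdiv(U, s, tape)
  ls <- ag_log(s, tape)
  x <- ag_cbind(list(Ms, Bgn, Un, ls,
                     matrix(rmax * config$rmax_scale, ncol = 1)), tape)
  z <- ag_relu(ag_addrow(ag_mm(x, prm(params, "disc.W1", tape), tape),
                         prm(params, "disc.b1", tape), tape), tape)
  z <- ag_relu(ag_addrow(ag_mm(z, prm(params, "disc.W2", tape), tape),
                         prm(params, "disc.b2", tape), tape), tape)
  z <- ag_addrow(ag_mm(z, prm(params, "disc.W3", tape), tape),
                 prm(params, "disc.b3", tape), tape)
  if (logits) return(z)
  if (is_node(z)) stop("probability output is an inference-mode operation")
  stats::plogis(z)
}

#' Lesion-centric radial basis for the inverse operator's shared head
#'
#' For each case, nested smooth-step balls of the configured radii around
#' the ultrasound mask center, evaluated at every voxel: the fixed spatial
#' basis whose non-negative coefficients the inverse operator predicts.
#' Weight sharing across voxels enters through this basis, mirroring the
#' spatial inductive bias a convolutional decoder would provide.
#'
#' @param centers `B x 3` matrix of mask centers in cm.
#' @param grid a `dot_grid`.
#' @param config an `aegan_config`.
#' @return list of K matrices, each `B x n_voxels`, one per radius.
#' @export
radial_basis <- function(centers, grid, config) {
  radial_basis_cpp(as.matrix(centers), grid_coords(grid),
                   config$radial_radii, config$radial_tau)
}

#' Reconstruct one case with the trained inverse operator
#'
#' @param bundle a trained `aegan_bundle`.
#' @param case a `dot_case` with a perturbation.
#' @return a `dot_volume` (delta mu_a contrast).
#' @export
reconstruct_aegan <- function(bundle, case) {
  grid <- bundle$config$grid
  M <- matrix(as.numeric(case$mask$values), 1)
  U <- matrix(usc_to_vec(case$perturbation$values), 1)
  Bg <- matrix(c(case$background$mua0, case$background$musp0), 1)
  basis <- radial_basis(matrix(case$mask$center, 1), grid, bundle$config)
  vals <- inv_forward(bundle, M, U, Bg, basis = basis)
  absorption_volume(as.vector(vals), grid, kind = "delta")
}

#' @export
print.aegan_bundle <- function(x, ...) {
  n <- count_params(x)
  cat(sprintf("<aegan_bundle %s> inv %s + fwd %s + disc %s params\n",
              x$config$preset, format(n["inv"], big.mark = ","),
              format(n["fwd"], big.mark = ","),
              format(n["disc"], big.mark = ",")))
  invisible(x)
}
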