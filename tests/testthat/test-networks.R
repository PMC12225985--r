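# Network building blocks: attention oracle equivalence, residual block
# contracts, shape contracts, gradient connectivity of all three inputs,
# and the forward operators' determinism.

test_that("attention equals a brute-force softmax(QK'/sqrt(dk))V loop", {
  set.seed(51)
  B <- 3; nq <- 5; nk <- 7; d <- 8; heads <- 2
  q <- matrix(rnorm(B * nq * d), B * nq, d)
  k <- matrix(rnorm(B * nk * d), B * nk, d)
  v <- matrix(rnorm(B * nk * d), B * nk, d)
  out <- dotae:::ag_attention(q, k, v, B, heads)
  dk <- d / heads
  for (b in seq_len(B)) {
    qi <- (b - 1) * nq + seq_len(nq)
    ki <- (b - 1) * nk + seq_len(nk)
    for (h in seq_len(heads)) {
      hc <- (h - 1) * dk + seq_len(dk)
      S <- q[qi, hc] %*% t(k[ki, hc]) / sqrt(dk)
      A <- exp(S) / rowSums(exp(S))
      expect_equal(out[qi, hc], A %*% v[ki, hc], tolerance = 1e-12)
    }
  }
})

test_that("attention edge cases: uniform logits and permutation symmetry", {
  set.seed(52)
  B <- 1; nq <- 4; nk <- 6; d <- 4
  q <- matrix(rnorm(nq * d), nq, d)
  k0 <- matrix(0, nk, d)                  # all-equal keys -> uniform weights
  v <- matrix(rnorm(nk * d), nk, d)
  out <- dotae:::ag_attention(q, k0, v, B, 1)
  expect_equal(out, matrix(rep(colMeans(v), each = nq), nq, d),
               tolerance = 1e-12)
  # jointly permuting K and V rows leaves the output unchanged
  k <- matrix(rnorm(nk * d), nk, d)
  pi <- sample(nk)
  o1 <- dotae:::ag_attention(q, k, v, B, 1)
  o2 <- dotae:::ag_attention(q, k[pi, ], v[pi, ], B, 1)
  expect_equal(o1, o2, tolerance = 1e-12)
  # a dominating key's value row wins under softmax saturation
  k_sat <- k * 0; k_sat[3, ] <- 50 * q[2, ] / sqrt(sum(q[2, ]^2))
  o3 <- dotae:::ag_attention(q * 50, k_sat, v, B, 1)
  expect_equal(o3[2, ], v[3, ], tolerance = 1e-6)
})

test_that("residual block is the identity under a zeroed projection", {
  grid <- tiny_grid()
  cfg <- aegan_config(grid = grid)
  bundle <- init_aegan(cfg, seed = 7)
  params <- bundle$params
  params[["inv.Wr21"]] <- params[["inv.Wr21"]] * 0
  h <- matrix(rnorm(4 * cfg$feat), 4)
  bgn <- matrix(rnorm(8), 4)
  out <- dotae:::residual_block(h, bgn, params, "inv", 1L, NULL)
  expect_equal(out, h, tolerance = 1e-12)
  # live background conditioning: different B gives different outputs
  out1 <- dotae:::residual_block(h, bgn, bundle$params, "inv", 1L, NULL)
  out2 <- dotae:::residual_block(h, bgn + 1, bundle$params, "inv", 1L, NULL)
  expect_false(isTRUE(all.equal(out1, out2)))
  expect_equal(dim(out1), dim(h))
})

test_that("inverse operator honors shape contracts and is deterministic", {
  grid <- recon_grid()
  bundle <- init_aegan(aegan_config(grid = grid), seed = 5)
  cases <- small_dataset()[1:3]
  la <- dotae:::collate_labeled(cases, grid)
  basis <- radial_basis(la$centers, grid, bundle$config)
  r1 <- inv_forward(bundle, la$M, la$U, la$Bg, basis = basis)
  r2 <- inv_forward(bundle, la$M, la$U, la$Bg, basis = basis)
  expect_identical(r1, r2)
  expect_equal(dim(r1), c(3L, 33L * 33L * 7L))
  expect_true(all(r1 >= 0))
  expect_error(inv_forward(bundle, NULL, la$U, la$Bg, basis = basis),
               "requires")
  u1 <- fwd_forward(bundle, r1, la$Bg)
  expect_equal(dim(u1), c(3L, 252L))
  expect_identical(u1, fwd_forward(bundle, r1, la$Bg))
  expect_true(all(is.finite(fwd_forward(bundle, r1 * 0, la$Bg))))
})

test_that("discriminator scores are probabilities and init is centered", {
  grid <- recon_grid()
  bundle <- init_aegan(aegan_config(grid = grid), seed = 6)
  cases <- small_dataset()[1:32]
  la <- dotae:::collate_labeled(cases, grid)
  p <- disc_forward(bundle, la$msum, la$Bg, la$U, la$rmax)
  expect_true(all(p > 0 & p < 1))
  expect_lt(abs(mean(p) - 0.5), 0.2)
})

test_that("every declared input influences the respective outputs", {
  grid <- recon_grid()
  bundle <- init_aegan(aegan_config(grid = grid), seed = 8)
  cases <- small_dataset()[1:2]
  la <- dotae:::collate_labeled(cases, grid)
  basis <- radial_basis(la$centers, grid, bundle$config)
  base <- inv_forward(bundle, la$M, la$U, la$Bg, basis = basis)
  # perturbation input is live
  U2 <- la$U; U2[1, ] <- U2[1, ] * 1.5
  expect_false(isTRUE(all.equal(
    base, inv_forward(bundle, la$M, U2, la$Bg, basis = basis))))
  # mask input is live
  M2 <- la$M; M2[1, ] <- 0
  expect_false(isTRUE(all.equal(
    base, inv_forward(bundle, M2, la$U, la$Bg, basis = basis))))
  # background input is live
  B2 <- la$Bg; B2[1, ] <- B2[1, ] * 1.3
  expect_false(isTRUE(all.equal(
    base, inv_forward(bundle, la$M, la$U, B2, basis = basis))))
  # and for the forward operator
  fb <- fwd_forward(bundle, base, la$Bg)
  expect_false(isTRUE(all.equal(fb, fwd_forward(bundle, base, B2))))
})

test_that("ablation zero-fills inputs without changing architecture", {
  grid <- recon_grid()
  cases <- small_dataset()[1:2]
  la <- dotae:::collate_labeled(cases, grid)
  cfg_full <- aegan_config(grid = grid)
  cfg_nomask <- aegan_config(grid = grid,
                             inputs_enabled = c(perturbation = TRUE,
                                                mask = FALSE,
                                                background = TRUE))
  b1 <- init_aegan(cfg_full, seed = 9)
  b2 <- init_aegan(cfg_nomask, seed = 9)
  expect_identical(count_params(b1), count_params(b2))
  basis <- radial_basis(la$centers, grid, cfg_nomask)
  r_nomask <- inv_forward(b2, la$M, la$U, la$Bg, basis = basis)
  r_zeroed <- inv_forward(b2, la$M * 0, la$U, la$Bg,
                          basis = lapply(basis, function(m) m * 0))
  expect_identical(r_nomask, r_zeroed)
  expect_error(aegan_config(grid = grid,
                            inputs_enabled = c(perturbation = FALSE,
                                               mask = TRUE,
                                               background = TRUE)),
               "primary signal")
})

test_that("parameter counts are reported per network and configurable", {
  grid <- recon_grid()
  n_small <- count_params(init_aegan(aegan_config("small", grid), seed = 1))
  n_large <- count_params(init_aegan(aegan_config("large", grid), seed = 1))
  expect_true(all(c("inv", "fwd", "disc", "generator", "total") %in%
                    names(n_small)))
  expect_equal(n_small[["generator"]], n_small[["inv"]] + n_small[["fwd"]])
  expect_gt(n_large[["generator"]], 2 * n_small[["generator"]])
  expect_gt(n_large[["generator"]], 9e6)
})

test_that("checkpoints round-trip parameters exactly", {
  grid <- tiny_grid()
  bundle <- init_aegan(aegan_config(grid = grid), seed = 12)
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  save_bundle(bundle, path)
  back <- load_bundle(path)
  expect_identical(names(back$params), names(bundle$params))
  for (nm in names(bundle$params))
    expect_identical(back$params[[nm]], bundle$params[[nm]])
  expect_equal(back$config$feat, bundle$config$feat)
  # loaded bundle reproduces inference exactly
  cases <- small_dataset()[1]
  ci <- cases[[1]]
  ci$mask <- make_mask(ci$mask$center, 0.4, 2.5, grid)
  ci$truth <- NULL; ci$provenance <- "irregular_unlabeled"
  U <- matrix(rnorm(252), 1)
  M <- matrix(as.numeric(ci$mask$values), 1)
  Bg <- matrix(c(0.05, 7), 1)
  basis <- radial_basis(matrix(ci$mask$center, 1), grid, bundle$config)
  expect_identical(inv_forward(bundle, M, U, Bg, basis = basis),
                   inv_forward(back, M, U, Bg, basis = basis))
})
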