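# Training contracts: loss definitions, alternation and freeze contracts,
# shared-optimizer behavior, determinism, and a scaled-down convergence
# probe.

test_that("P2P loss is zero at perfect prediction and increases with error", {
  set.seed(61)
  B <- 4; V <- 50
  R <- matrix(pmax(0, rnorm(B * V, 0.05, 0.05)), B)
  U <- matrix(rnorm(B * 252), B)
  expect_equal(p2p_loss(R, R, U, U), 0)
  R_hat <- R + 0.01
  l1 <- p2p_loss(R, R_hat, U, U)
  l2 <- p2p_loss(R, R + 0.02, U, U)
  expect_gt(l1, 0)
  expect_gt(l2, l1)
})

test_that("P2P loss matches its hand-computed single-element value", {
  # one case, one voxel, one channel-pair value:
  # R = 0.2, Rhat = 0.1, Rmax = 0.2, USC = (1, 0), UhatSC = (0, 0)
  R <- matrix(0.2, 1, 1); R_hat <- matrix(0.1, 1, 1)
  U <- matrix(c(1, 0), 1, 2); U_hat <- matrix(0, 1, 2)
  # |R-Rhat| + |R-Rhat|/Rmax + mean(|USC-Uhat|) = 0.1 + 0.5 + 0.5
  expect_equal(p2p_loss(R, R_hat, U, U_hat), 1.1, tolerance = 1e-12)
})

test_that("degenerate Rmax cases skip the normalized term with a warning", {
  R <- matrix(0, 2, 5); R[2, 3] <- 0.2
  R_hat <- R + 0.01
  U <- matrix(0, 2, 4)
  expect_warning(l <- p2p_loss(R, R_hat, U, U), "Rmax")
  expect_true(is.finite(l))
})

test_that("r2r_losses accounting: l_total = l_r + gan_weight * l_gan", {
  cases <- small_dataset()
  prov <- vapply(cases, function(c) c$provenance, character(1))
  bundle <- init_aegan(aegan_config(grid = attr(cases, "grid")), seed = 3)
  out <- r2r_losses(bundle, cases[prov == "irregular_unlabeled"][1:8],
                    cases[prov == "born_spherical"][1:8])
  expect_equal(out$l_total, out$l_r + 0.001 * out$l_gan, tolerance = 1e-15)
  expect_gte(out$l_r, 0)
  expect_true(is.finite(out$l_gan))
  expect_error(r2r_losses(bundle, cases[prov == "irregular_unlabeled"][1:4],
                          list()),
               "labeled|real")
})

test_that("a perfect discriminator saturates the adversarial terms", {
  cases <- small_dataset()
  grid <- attr(cases, "grid")
  bundle <- init_aegan(aegan_config(grid = grid), seed = 3)
  # rig the discriminator head to output huge logits from the bias alone
  bundle$params[["disc.W3"]] <- bundle$params[["disc.W3"]] * 0
  bundle$params[["disc.b3"]][] <- 50   # D ~ 1 on everything
  prov <- vapply(cases, function(c) c$provenance, character(1))
  out <- r2r_losses(bundle, cases[prov == "irregular_unlabeled"][1:4],
                    cases[prov == "born_spherical"][1:4])
  # log D(real) ~ 0, log(1 - D(fake)) at the clamped floor
  expect_lt(out$l_gan, -30)
  expect_true(is.finite(out$l_gan))
})

test_that("training alternates P2P and R2R, freezes D during P2P, and is seeded", {
  cases <- small_dataset()
  cfg <- training_config(epochs = 1L, batch_size = 32L, master_seed = 7)
  bundle0 <- init_aegan(aegan_config(grid = attr(cases, "grid")), seed = 99)
  d_before <- bundle0$params[grep("^disc", names(bundle0$params))]
  fit1 <- suppressMessages(train(cases, cfg, bundle0))
  # D trained only in the R2R phase, so it moved across the run
  d_after <- fit1$bundle$params[grep("^disc", names(fit1$bundle$params))]
  expect_false(identical(d_before, d_after))
  # history carries both sequences for every step (strict alternation)
  h <- fit1$history
  expect_true(all(c("l_p2p", "l_r", "l_gan", "l_total_r2r") %in% names(h)))
  expect_true(all(is.finite(h$l_p2p)))
  expect_true(all(is.finite(h$l_r)))
  expect_equal(h$l_total_r2r, h$l_r + 0.001 * h$l_gan, tolerance = 1e-12)
  # same master seed -> identical loss traces and final parameters
  fit2 <- suppressMessages(train(cases, cfg,
                                 init_aegan(aegan_config(
                                   grid = attr(cases, "grid")), seed = 99)))
  expect_equal(fit1$history$l_p2p, fit2$history$l_p2p, tolerance = 1e-12)
  expect_identical(param_hash(fit1$bundle), param_hash(fit2$bundle))
  # the input bundle is not mutated in place
  expect_identical(bundle0$params[["disc.W1"]], d_before[["disc.W1"]])
})

test_that("a P2P-only update leaves the discriminator bit-identical", {
  cases <- small_dataset()
  prov <- vapply(cases, function(c) c$provenance, character(1))
  labeled <- cases[prov == "born_spherical"]
  bundle <- init_aegan(aegan_config(grid = attr(cases, "grid")), seed = 21)
  h0 <- param_hash(bundle, "disc")
  fit <- dotae:::train_p2p_only(labeled[1:64],
                                training_config(epochs = 1L,
                                                batch_size = 32L,
                                                master_seed = 3),
                                bundle)
  expect_identical(param_hash(fit$bundle, "disc"), h0)
  for (nm in grep("^disc", names(bundle$params), value = TRUE))
    expect_identical(fit$bundle$params[[nm]], bundle$params[[nm]])
  # while the generator parameters moved
  expect_false(identical(fit$bundle$params[["inv.Wamp"]],
                         bundle$params[["inv.Wamp"]]))
})

test_that("supervised loss halves over twenty epochs on a 200-case toy set", {
  cases <- suppressMessages(sample_dataset(200, 200, master_seed = 11))
  cfg <- training_config(epochs = 20L, batch_size = 32L, master_seed = 11)
  fit <- suppressMessages(train(cases, cfg))
  h <- fit$history
  first <- mean(h$l_p2p[h$epoch == 1])
  last <- mean(h$l_p2p[h$epoch == max(h$epoch)])
  expect_lt(last, 0.5 * first)
})

test_that("fine_tune respects the zero-epoch identity and adapts otherwise", {
  cases <- small_dataset()
  cfg <- training_config(epochs = 1L, batch_size = 32L, master_seed = 5)
  fit <- suppressMessages(train(cases, cfg))
  # zero epochs: bit-identical bundle
  ft0 <- fine_tune(fit$bundle, cases, training_config(epochs = 0L))
  expect_identical(param_hash(ft0$bundle, "inv"), param_hash(fit$bundle, "inv"))
  # a shifted-noise domain: labeled cases with 5x the measurement noise
  shifted <- suppressMessages(sample_dataset(64, 0, master_seed = 777,
                                             noise_frac = 0.05))
  before <- eval_p2p_loss(fit$bundle, shifted[1:32])
  ft <- fine_tune(fit$bundle, shifted[33:64],
                  training_config(epochs = 8L, batch_size = 32L,
                                  master_seed = 6))
  after <- eval_p2p_loss(ft$bundle, shifted[1:32])
  expect_lt(after, before)
  # parameter shapes preserved
  expect_identical(lapply(ft$bundle$params, dim),
                   lapply(fit$bundle$params, dim))
})
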