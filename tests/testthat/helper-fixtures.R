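# Shared fixtures. Small deterministic objects are built fresh per file;
# anything expensive is memoised in this environment so the suite builds it
# once per session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

default_bg <- function(mua0 = 0.05, musp0 = 7) optical_background(mua0, musp0)

tiny_grid <- function() recon_grid(nx = 11L, ny = 11L, nz = 3L,
                                   dx = 9 / 11, dy = 9 / 11, dz = 0.5)

# a modest labeled/unlabeled dataset reused across training-related tests
small_dataset <- function() {
  fixture("small_dataset", function() {
    suppressMessages(sample_dataset(96, 160, master_seed = 401))
  })
}

# one labeled case on the default grid
one_case <- function() small_dataset()[[1]]

# supervised loss of a bundle on labeled cases (inference mode)
eval_p2p_loss <- function(bundle, cases) {
  grid <- bundle$config$grid
  la <- dotae:::collate_labeled(cases, grid)
  basis <- radial_basis(la$centers, grid, bundle$config)
  R_hat <- inv_forward(bundle, la$M, la$U, la$Bg, basis = basis)
  U_hat <- fwd_forward(bundle, R_hat, la$Bg)
  p2p_loss(la$R, R_hat, la$U, U_hat, rmax = la$rmax)
}
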