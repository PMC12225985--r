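# The scaled-down simulation study shared by the acceptance tests: one
# training run reused by the end-to-end recovery and baseline-contrast
# checks. Sizes follow the bundled study defaults (5,000 labeled + 20,000
# irregular training cases, 500 held-out spheres); the epoch count is the
# desk-scale training schedule.

study_seed <- 1L
study_epochs <- 9L

get_study <- function() {
  fixture("acceptance_study", function() {
    suppressMessages(run_study(
      n_labeled = 5000L, n_unlabeled = 20000L, n_test = 500L,
      config = training_config(epochs = study_epochs, batch_size = 64L),
      seed = study_seed))
  })
}

# fixed sphere set for the baseline-contrast experiment: radii and depths
# on a grid, all other parameters held at mid-range
baseline_sphere_cases <- function(geometry = default_probe_geometry(),
                                  grid = recon_grid()) {
  fixture("baseline_spheres", function() {
    specs <- expand.grid(radius = c(0.5, 0.8, 1.1),
                         depth = c(1, 1.5, 2, 2.5))
    cases <- vector("list", nrow(specs))
    for (i in seq_len(nrow(specs))) {
      bg <- optical_background(0.05, 7)
      sp <- sphere_spec(c(0, 0, specs$depth[i]), specs$radius[i], 0.2)
      truth <- rasterize_sphere(sp, grid, bg$mua0)
      vox <- which(as.vector(truth$values) != 0)
      sys <- build_born_system(geometry, grid, bg, voxel_idx = vox)
      pert <- simulate_perturbation(sys, truth$values[vox],
                                    noise_frac = 0.01, seed = 9000 + i)
      mask <- make_mask(sp$center, sp$radius, 2.5, grid)
      cases[[i]] <- case_record(perturbation = pert, background = bg,
                                mask = mask, truth = truth,
                                provenance = "born_spherical",
                                seed = 9000 + i, lesion_spec = sp,
                                id = sprintf("B%02d", i))
    }
    attr(cases, "geometry") <- geometry
    attr(cases, "grid") <- grid
    cases
  })
}
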