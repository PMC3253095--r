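# Shared fixtures, built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- make()
  .fixtures[[name]]
}

# a small phantom used across registration/extraction tests
test_phantom <- function() fixture("phantom", function()
  make_phantom(c(32, 32, 9), c(1.5, 1.5, 2), seed = 7))

config_with <- function(base, ...) {
  do.call(sim_config, utils::modifyList(base, list(...)))
}

# reduced session config: 2 runs x 100 volumes, 4 trials of 12 volumes
small_config <- function(...) {
  config_with(list(grid = c(40, 40, 9), voxel_size = c(1.5, 1.5, 2),
                   n_runs = 2, volumes_per_run = 100, n_trials_per_run = 4,
                   trial_length_vols = 12, gap_length_vols = 8, seed = 5),
              ...)
}

# same conditions with every corruption switched off
degenerate_config <- function(...) {
  config_with(list(grid = c(40, 40, 9), voxel_size = c(1.5, 1.5, 2),
                   n_runs = 2, volumes_per_run = 100, n_trials_per_run = 4,
                   trial_length_vols = 12, gap_length_vols = 8, seed = 5,
                   shift_amplitude_mm = 0, affine_translation_mm = 0,
                   affine_rotation_rad = 0, affine_scale = 0,
                   affine_shear = 0, ghost_fraction = 0, drift_linear = 0,
                   drift_cosine_amplitude = 0, run_step_offset = 0),
              ...)
}

# ghost-only corruption: the artefact-detection study conditions
ghost_only_config <- function(...) {
  config_with(list(grid = c(40, 40, 9), voxel_size = c(1.5, 1.5, 2),
                   n_runs = 2, volumes_per_run = 100, n_trials_per_run = 4,
                   trial_length_vols = 12, gap_length_vols = 8, seed = 5,
                   shift_amplitude_mm = 0, affine_translation_mm = 0,
                   affine_rotation_rad = 0, affine_scale = 0,
                   affine_shear = 0),
              ...)
}

small_sim <- function() fixture("small_sim", function()
  simulate_session(small_config(bad_trial_ids = 2)))

# a tiny single-run series for I/O and filter unit tests
tiny_series <- function(nt = 12, nruns = 1) {
  set.seed(3)
  dat <- array(rnorm(6 * 6 * 4 * nt, mean = 50, sd = 5), c(6, 6, 4, nt))
  volume_series(dat, c(2, 2, 2.5), 1.5, "y",
                run_lengths = rep(nt / nruns, nruns))
}

# a compact fully interior blob image for centroid tests
interior_blob <- function(shape = c(32, 32, 9), vox = c(1.5, 1.5, 2)) {
  co <- arrayInd(seq_len(prod(shape)), shape)
  ctr <- (shape + 1) / 2
  r2 <- ((co[, 1] - ctr[1]) / 6)^2 + ((co[, 2] - ctr[2]) / 6)^2 +
    ((co[, 3] - ctr[3]) / 2.5)^2
  array(100 * exp(-r2), shape)
}
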