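vox <- c(1.5, 1.5, 2)

test_that("single-axis shift estimation recovers known translations", {
  # fully interior object: estimation must not be confounded by content
  # leaving the field of view
  vol <- interior_blob()
  expect_lt(abs(estimate_shift_1d(vol, vol, "y", vox)), 0.02 * 1.5)
  for (sh in c(0.75 * 1.5, 3 * 1.5)) {
    mov <- resample_affine(vol, diag(3), c(0, -sh, 0), vox)
    est <- estimate_shift_1d(mov, vol, "y", vox)
    tol <- if (sh == 3 * 1.5) 0.05 else 0.1
    expect_lt(abs(est - sh) / 1.5, tol)
  }
  expect_error(estimate_shift_1d(array(1, dim(vol)), vol, "y", vox),
               "degenerate")
})

test_that("within-trial realignment is null on static data", {
  sim <- simulate_session(degenerate_config(
    volumes_per_run = 24, n_trials_per_run = 2, trial_length_vols = 8,
    gap_length_vols = 4, noise_sd = 0.005, seed = 41))
  cc <- concatenate(sim$series, sim$trials)
  shifts <- within_trial_realign(cc$series, cc$index$kept$trial_id)
  expect_lt(max(abs(shifts)) / 1.5, 0.05)
  # single-volume trial yields a single zero shift
  one <- volume_series(array(test_phantom()$baseline,
                             c(32, 32, 9, 1)), vox, 2, "y", run_lengths = 1)
  expect_identical(within_trial_realign(one, 0L), 0)
})

test_that("within-trial realignment tracks the injected sinusoid", {
  cfg <- small_config(volumes_per_run = 50, n_trials_per_run = 2,
                      shift_amplitude_mm = 0.5, affine_translation_mm = 0,
                      affine_rotation_rad = 0, affine_scale = 0,
                      affine_shear = 0, ghost_fraction = 0, seed = 42)
  sim <- simulate_session(cfg)
  cc <- concatenate(sim$series, sim$trials)
  shifts <- within_trial_realign(cc$series, cc$index$kept$trial_id)
  truth <- sim$truth$injected_shift1d[
    cc$index$kept$run_id * 50 + cc$index$kept$orig_vol + 1]
  expect_gt(cor(shifts, truth), 0.95)
  # first volume of every trial is exactly zero
  firsts <- !duplicated(cc$index$kept$trial_id)
  expect_identical(unique(shifts[firsts]), 0)
})

test_that("trial means undo known offsets", {
  ph <- test_phantom()
  vol <- ph$baseline
  e <- c(0, 1, 0)
  plus <- resample_affine(vol, diag(3), -1.5 * e, vox)
  minus <- resample_affine(vol, diag(3), 1.5 * e, vox)
  dat <- array(c(plus, minus), c(dim(vol), 2))
  ser <- volume_series(dat, vox, 2, "y", run_lengths = 2)
  m <- trial_mean(ser, 1:2, c(1.5, -1.5))
  interior <- trialfmri:::erode6(trialfmri:::erode6(ph$brain_mask))
  expect_lt(max(abs((m - vol)[interior])) / mean(vol[ph$brain_mask]), 0.02)
  # identical volumes, zero shifts -> the volume itself; order-invariant
  dat2 <- array(rep(vol, 2), c(dim(vol), 2))
  ser2 <- volume_series(dat2, vox, 2, "y", run_lengths = 2)
  expect_equal(trial_mean(ser2, 1:2, c(0, 0)), vol)
  expect_equal(trial_mean(ser, 2:1, c(1.5, -1.5)), m)
  expect_error(trial_mean(ser, integer(0), c(0, 0)), "empty")
})

test_that("affine estimation recovers jitter-scale transforms", {
  ph <- test_phantom()
  vol <- ph$baseline
  # identity case
  p_id <- estimate_affine(vol, vol, vox)
  expect_lt(max(abs(p_id[1:3])) / 1.5, 0.05)
  expect_lt(max(abs(p_id[7:9] - 1)), 0.005)
  # batch of random small affines: median errors within tolerance
  set.seed(99)
  errs <- NULL
  for (i in 1:4) {
    p0 <- identity_affine()
    p0[1:3] <- runif(3, -1, 1) * 1.5
    p0[4:6] <- runif(3, -1, 1) * 0.02
    p0[7:9] <- 1 + runif(3, -1, 1) * 0.01
    p0[10:12] <- runif(3, -1, 1) * 0.01
    M <- affine_matrix(p0)
    mov <- resample_affine(vol, M[1:3, 1:3], M[1:3, 4], vox)
    est <- estimate_affine(mov, vol, vox)
    errs <- rbind(errs, abs(as.numeric(est) - p0))
  }
  expect_lt(median(errs[, 1:3]) / 1.5, 0.1)
  expect_lt(median(errs[, 4:6]), 0.01)
  expect_lt(median(errs[, 7:12]), 0.01)
})

test_that("pure translations agree between the affine and 1-DOF estimators", {
  ph <- test_phantom()
  vol <- ph$baseline
  mov <- resample_affine(vol, diag(3), c(0, -1.2, 0), vox)
  s1 <- estimate_shift_1d(mov, vol, "y", vox)
  pa <- estimate_affine(mov, vol, vox, dof = "rigid6")
  # the scalar shift reports object displacement; the affine maps moving to
  # reference coordinates, so its translation is the negative of the shift
  expect_lt(abs(pa["ty"] + s1) / 1.5, 0.1)
})

test_that("composed single reslice undoes the injected corruption", {
  cfg <- small_config(volumes_per_run = 50, n_trials_per_run = 2,
                      affine_translation_mm = 1.5,
                      affine_rotation_rad = 0.02, affine_scale = 0.01,
                      affine_shear = 0.01, shift_amplitude_mm = 0.5,
                      noise_sd = 0, seed = 43)
  sim <- simulate_session(cfg)
  clean <- simulate_session(trialfmri:::clean_config(cfg))
  cc <- concatenate(sim$series, sim$trials)
  ccc <- concatenate(clean$series, clean$trials)
  truth_shift <- sim$truth$injected_shift1d[
    cc$index$kept$run_id * 50 + cc$index$kept$orig_vol + 1]
  inv <- compose_and_reslice(cc$series, truth_shift,
                             sim$truth$injected_affine,
                             cc$index$kept$trial_id)
  # interior = away from the tissue boundary, where a double resample of
  # the steep edge gradient dominates the residual
  interior <- trialfmri:::erode6(trialfmri:::erode6(sim$truth$brain_mask))
  base <- mean(sim$truth$clean_baseline[sim$truth$brain_mask])
  worst <- max(vapply(seq_len(n_volumes(inv)), function(v)
    max(abs((inv$data[, , , v] - ccc$series$data[, , , v])[interior])),
    numeric(1)))
  expect_lt(worst / base, 0.02)
  # identity transforms reproduce the input to interpolation round-off
  idmap <- lapply(sim$truth$injected_affine, function(x) identity_affine())
  same <- compose_and_reslice(cc$series, rep(0, n_volumes(cc$series)),
                              idmap, cc$index$kept$trial_id)
  expect_lt(max(abs(same$data - cc$series$data)) / max(cc$series$data),
            1e-6)
  expect_error(compose_and_reslice(cc$series, truth_shift, list(),
                                   cc$index$kept$trial_id), "missing affine")
})

test_that("2-step realignment reduces the cost of every trial mean", {
  sim <- small_sim()
  cc <- concatenate(sim$series, sim$trials)
  shifts <- within_trial_realign(cc$series, cc$index$kept$trial_id)
  bt <- between_trial_realign(cc$series, cc$index$kept$trial_id, shifts)
  sm <- function(v) smooth3d(v, fwhm_to_sigma(2))
  ref_s <- sm(bt$reference)
  for (id in names(bt$means)[-1]) {
    before <- trialfmri:::msd_cost(sm(bt$means[[id]]), ref_s, diag(3),
                                   c(0, 0, 0), sim$series$voxel_size)
    expect_lte(attr(bt$affines[[id]], "cost"), before + 1e-9)
  }
  # the first trial's affine is the identity
  first <- bt$affines[[1]]
  expect_equal(as.numeric(first), as.numeric(identity_affine()))
})

test_that("one composed reslice beats two sequential reslices", {
  cfg <- small_config(volumes_per_run = 50, n_trials_per_run = 2,
                      affine_translation_mm = 1.5, affine_rotation_rad = 0.02,
                      affine_scale = 0.01, shift_amplitude_mm = 0.5,
                      noise_sd = 0, seed = 44)
  sim <- simulate_session(cfg)
  clean <- simulate_session(trialfmri:::clean_config(cfg))
  cc <- concatenate(sim$series, sim$trials)
  ccc <- concatenate(clean$series, clean$trials)
  shift <- sim$truth$injected_shift1d[
    cc$index$kept$run_id * 50 + cc$index$kept$orig_vol + 1]
  affs <- sim$truth$injected_affine
  trial_of <- cc$index$kept$trial_id
  one_pass <- compose_and_reslice(cc$series, shift, affs, trial_of)
  # two passes: shift-reslice, then affine-reslice
  idmap <- lapply(affs, function(x) identity_affine())
  pass1 <- compose_and_reslice(cc$series, shift, idmap, trial_of)
  two_pass <- compose_and_reslice(pass1, rep(0, length(shift)), affs,
                                  trial_of)
  interior <- trialfmri:::erode6(sim$truth$brain_mask)
  err <- function(s) mean(vapply(seq_len(n_volumes(s)), function(v)
    mean(abs((s$data[, , , v] - ccc$series$data[, , , v])[interior])),
    numeric(1)))
  e1 <- err(one_pass)
  e2 <- err(two_pass)
  expect_lt(e1, e2)          # strictly lower residual vs the clean truth
  expect_lt(e2, 2 * e1 + 1e-9)  # and the two agree within 2x interp error
})
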