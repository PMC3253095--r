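test_that("canonical HRF has the double-gamma shape", {
  h <- canonical_hrf(0.1)
  expect_equal(h[1], 0)                       # zero at onset
  expect_equal((which.max(h) - 1) * 0.1, 5, tolerance = 0.1 + 1e-9)
  expect_equal(max(h), 1)                     # peak-normalised
  expect_gt(sum(h) * 0.1, 0)                  # positive integral
  expect_lt(min(h), 0)                        # undershoot
  expect_error(canonical_hrf(0), "dt > 0")
})

test_that("regressors peak ~6 s after onset and add linearly", {
  tt <- trial_table(0, 0, 0, 39, events = list(
    data.frame(condition = "stimulation", onset = 10, duration = 2)))
  r <- build_regressors(tt, 40, 1, "stimulation")
  expect_equal(which.max(r[, 1]) - 1, 16, tolerance = 1)
  # two non-overlapping events sum to their single-event regressors
  t2 <- trial_table(0, 0, 0, 59, events = list(
    data.frame(condition = "stimulation", onset = c(5, 40),
               duration = c(2, 2))))
  ta <- trial_table(0, 0, 0, 59, events = list(
    data.frame(condition = "stimulation", onset = 5, duration = 2)))
  tb <- trial_table(0, 0, 0, 59, events = list(
    data.frame(condition = "stimulation", onset = 40, duration = 2)))
  expect_equal(build_regressors(t2, 60, 1, "stimulation"),
               build_regressors(ta, 60, 1, "stimulation") +
                 build_regressors(tb, 60, 1, "stimulation"),
               tolerance = 1e-10)
  # empty trial table -> all-zero; unknown condition -> error
  empty <- trial_table(integer(0), integer(0), integer(0), integer(0))
  expect_true(all(build_regressors(empty, 20, 1, "stimulation") == 0))
  expect_error(build_regressors(tt, 40, 1, "saccade"), "unknown condition")
})

test_that("regressor row selection mirrors the concatenation", {
  sim <- small_sim()
  reg <- build_regressors(sim$trials, unname(run_lengths(sim$series)),
                          sim$series$intervolume_time,
                          c("stimulation", "fixation"))
  cc <- concatenate(sim$series, sim$trials)
  sel <- select_regressor_rows(reg, cc$index)
  expect_identical(nrow(sel), n_volumes(cc$series))
  # selection commutes with summing regressors
  expect_equal(select_regressor_rows(reg[, 1, drop = FALSE], cc$index) +
                 select_regressor_rows(reg[, 2, drop = FALSE], cc$index),
               select_regressor_rows(reg[, 1, drop = FALSE] +
                                       reg[, 2, drop = FALSE], cc$index))
  expect_error(select_regressor_rows(reg[-1, , drop = FALSE], cc$index),
               "length")
})

test_that("spatial smoothing conserves intensity and respects fwhm 0", {
  ser <- tiny_series(nt = 3)
  expect_identical(smooth_spatial(ser, c(0, 0, 0))$data, ser$data)
  ph <- test_phantom()
  dat <- array(ph$baseline, c(dim(ph$baseline), 1))
  one <- volume_series(dat, c(1.5, 1.5, 2), 2, "y", run_lengths = 1)
  sm <- smooth_spatial(one, c(2, 2, 2))
  expect_equal(sum(sm$data), sum(one$data), tolerance = 1e-3)
})

test_that("noise-free OLS recovers beta exactly with orthogonal residuals", {
  set.seed(8)
  n <- 40
  X <- cbind(stim = rnorm(n), fix = rnorm(n), run_0 = 1)
  b0 <- c(2, -1, 50)
  y <- as.numeric(X %*% b0)
  dat <- array(rep(y, each = 27), c(3, 3, 3, n))
  ser <- volume_series(dat, c(1, 1, 1), 1, "y", run_lengths = n)
  fit <- fit_glm(ser, X, c(1, -1, 0), grand_mean_scale = FALSE)
  expect_equal(max(abs(fit$beta - b0)), 0, tolerance = 1e-10)
  expect_true(all(fit$degenerate))           # zero residual variance
  expect_true(all(fit$t == 0))               # degenerate voxels report t = 0
  res <- y - X %*% fit$beta[, 1]
  expect_lt(max(abs(crossprod(X, res))), 1e-9)
})

test_that("t-maps are invariant to joint row permutation and to scaling", {
  set.seed(9)
  n <- 30
  X <- cbind(stim = rnorm(n), run_0 = 1)
  dat <- array(rnorm(8 * n, 100, 5), c(2, 2, 2, n))
  ser <- volume_series(dat, c(1, 1, 1), 1, "y", run_lengths = n)
  fit <- fit_glm(ser, X, c(1, 0))
  perm <- sample(n)
  ser_p <- ser
  ser_p$data <- ser$data[, , , perm, drop = FALSE]
  fit_p <- fit_glm(ser_p, X[perm, ], c(1, 0))
  expect_equal(fit_p$t, fit$t, tolerance = 1e-9)
  # grand-mean scaling rescales beta/sigma but leaves t untouched
  fit_raw <- fit_glm(ser, X, c(1, 0), grand_mean_scale = FALSE)
  expect_equal(fit$t, fit_raw$t, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(fit$beta, fit_raw$beta)))
})

test_that("one-hot artefact columns zero their volume's residual", {
  set.seed(10)
  n <- 24
  reg <- matrix(rnorm(n), n, 1, dimnames = list(NULL, "stim"))
  des <- design_matrix(reg, run_id = rep(0L, n), artefact_vols = c(5L, 11L))
  expect_identical(ncol(des$X), 4L)   # stim + 2 one-hots + intercept
  y <- rnorm(n, 100)
  y[5] <- 500                          # a wild artefact volume
  dat <- array(rep(y, each = 8), c(2, 2, 2, n))
  ser <- volume_series(dat, c(1, 1, 1), 1, "y", run_lengths = n)
  fit <- fit_glm(ser, des, c(1, 0, 0, 0), grand_mean_scale = FALSE)
  res <- y - des$X %*% fit$beta[, 1]
  expect_lt(abs(res[5]), 1e-9)
  expect_lt(abs(res[11]), 1e-9)
})

test_that("suprathreshold counting is exact and monotone in the threshold", {
  tmap <- array(0, c(5, 5, 4))
  mask <- array(TRUE, c(5, 5, 4))
  expect_identical(count_suprathreshold(tmap, mask, 3.11)$count, 0L)
  tmap[] <- 5
  out <- count_suprathreshold(tmap, mask, 3.11)
  expect_identical(out$count, 100L)
  expect_identical(out$proportion, 1)
  set.seed(11)
  tmap[] <- rnorm(100, 3, 1)
  c3 <- count_suprathreshold(tmap, mask, 3)$count
  c4 <- count_suprathreshold(tmap, mask, 4)$count
  expect_lte(c4, c3)
  expect_error(count_suprathreshold(tmap, array(FALSE, c(5, 5, 4)), 3),
               "empty mask")
})

test_that("simulated activation yields power inside and control outside", {
  cfg <- degenerate_config(n_runs = 1, volumes_per_run = 150,
                           n_trials_per_run = 5, seed = 71)
  sim <- simulate_session(cfg)
  mc <- method_config(brain_roi = sim$truth$brain_mask)
  reg <- build_regressors(sim$trials, unname(run_lengths(sim$series)),
                          sim$series$intervolume_time, mc$conditions)
  res <- trialfmri:::glm_stage(sim$series, reg, mc)
  act <- sim$truth$activation_map
  # exclude the smoothing halo around the blobs: spill there is real signal
  halo <- trialfmri:::dilate6(trialfmri:::dilate6(act))
  outside <- sim$truth$brain_mask & !halo
  expect_gt(mean(res$fit$t[act]), 3.11)
  expect_lt(mean(res$fit$t[outside] > 3.11), 0.01)
})

test_that("method 2 adds exactly one column per artefact volume", {
  sim <- small_sim()
  mc <- method_config(brain_roi = sim$truth$brain_mask)
  flags <- trialfmri:::method_flags(sim$series, mc)
  rows <- trialfmri:::artefact_rows(sim$series, sim$trials, flags)
  m1 <- run_method(sim$series, sim$trials, 1, mc)
  m2 <- run_method(sim$series, sim$trials, 2, mc)
  expect_identical(m2$n_columns, m1$n_columns + length(rows))
})
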