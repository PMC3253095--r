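test_that("CoM shift is zero for identical volumes and tracks translations", {
  blob <- interior_blob()
  vox <- c(1.5, 1.5, 2)
  dat <- array(rep(blob, 3), c(dim(blob), 3))
  ser <- volume_series(dat, vox, 1, "y", run_lengths = 3)
  cs <- com_shift(ser, 0)
  expect_equal(max(abs(cs)), 0)
  # +2 voxels along y (fully interior object) -> +3 mm
  shifted <- trialfmri:::shift_pad(blob, 2, 2L, 0)
  dat[, , , 2] <- shifted
  ser <- volume_series(dat, vox, 1, "y", run_lengths = 3)
  cs <- com_shift(ser, 0)
  # brute-force centroid oracle
  co <- arrayInd(seq_len(prod(dim(shifted))), dim(shifted))
  cen <- function(v) colSums(co * as.numeric(v)) / sum(v) * vox
  expect_equal(cs[2, ], cen(shifted) - cen(blob),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(unname(cs[2, "y"]), 3, tolerance = 0.05)
  # a ghost displaces the centroid along the phase axis (the object must be
  # off-centre, else the wrapped ghost lands symmetrically)
  off <- trialfmri:::shift_pad(blob, 2, -6L, 0)
  dat[, , , 1] <- off
  dat[, , , 2] <- off
  dat[, , , 3] <- inject_ghost(off, "y", 0.3)
  ser <- volume_series(dat, vox, 1, "y", run_lengths = 3)
  cs <- com_shift(ser, 0)
  expect_gt(abs(cs[3, "y"]), 1)
  # all-zero volume has no centroid
  dat[, , , 3] <- 0
  ser <- volume_series(dat, vox, 1, "y", run_lengths = 3)
  expect_error(com_shift(ser, 0), "centroid")
})

test_that("ghost ratio behaves as mean(brain)/mean(ghost region)", {
  ph <- test_phantom()
  d <- dim(ph$baseline)
  uniform <- array(5, d)
  roi_a <- array(FALSE, d); roi_a[1:5, 1:5, 1:2] <- TRUE
  roi_b <- array(FALSE, d); roi_b[20:25, 20:25, 3:4] <- TRUE
  expect_equal(ghost_ratio(uniform, roi_a, roi_b), 1, tolerance = 1e-9)
  expect_error(ghost_ratio(uniform, roi_a, roi_a), "disjoint")
  expect_error(ghost_ratio(uniform, array(FALSE, d), roi_b), "non-empty")
  # ghost strictly lowers the ratio; verify against direct ROI means
  groi <- default_ghost_roi(ph$brain_mask, "y")
  clean_r <- ghost_ratio(ph$baseline, ph$brain_mask, groi)
  gvol <- inject_ghost(ph$baseline, "y", 0.25)
  ghost_r <- ghost_ratio(gvol, ph$brain_mask, groi)
  eps <- 1e-12 * max(gvol)
  expect_equal(ghost_r,
               mean(gvol[ph$brain_mask]) / (mean(gvol[groi]) + eps))
  expect_lt(ghost_r, clean_r)
})

test_that("default ghost ROI is the out-of-brain N/2 footprint", {
  ph <- test_phantom()
  roi <- default_ghost_roi(ph$brain_mask, "y")
  expect_gt(sum(roi), 0)
  expect_false(any(roi & ph$brain_mask))
  expect_error(default_ghost_roi(array(TRUE, c(8, 8, 4)), "y"), "empty")
  expect_error(default_ghost_roi(array(FALSE, c(8, 8, 4)), "y"), "empty")
})

test_that("auto_flag is quiet on clean runs and monotone in its thresholds", {
  sim <- simulate_session(ghost_only_config(ghost_fraction = 0, seed = 31))
  st <- qc_stats(sim$series, sim$truth$brain_mask)
  expect_identical(sum(auto_flag(st)), 0L)
  # identical volumes -> 0 flags whatever the thresholds
  dat <- array(rep(test_phantom()$baseline, 4), c(32, 32, 9, 4))
  ser <- volume_series(dat, c(1.5, 1.5, 2), 1, "y", run_lengths = 4)
  st0 <- qc_stats(ser, test_phantom()$brain_mask)
  expect_identical(sum(auto_flag(st0, 1, 0.01)), 0L)
  # monotonicity on a corrupted session
  sim2 <- simulate_session(ghost_only_config(seed = 32))
  st2 <- qc_stats(sim2$series, sim2$truth$brain_mask)
  n_strict <- sum(auto_flag(st2, ratio_threshold = 3, com_threshold_mm = 0.5))
  n_loose <- sum(auto_flag(st2, ratio_threshold = 2, com_threshold_mm = 1.5))
  expect_gte(n_strict, n_loose)
})

test_that("flagged ghosts match the injected truth", {
  sim <- simulate_session(ghost_only_config(seed = 33))
  st <- qc_stats(sim$series, sim$truth$brain_mask)
  flags <- auto_flag(st)
  expect_setequal(which(flags) - 1L, sim$truth$artefact_volumes)
})

test_that("whole-trial rejection and overrides follow precedence rules", {
  tt <- trial_table(0:3, c(0, 0, 1, 1), c(2, 10, 2, 10), c(5, 13, 5, 13))
  rl <- c(20, 20)
  flags <- rep(FALSE, 40)
  expect_identical(reject_trials(tt, flags, rl)$status, rep("accepted", 4))
  flags[4] <- TRUE            # volume 3 of run 0: inside trial 0
  flags[33] <- TRUE           # volume 12 of run 1: inside trial 3
  out <- reject_trials(tt, flags, rl)
  expect_identical(out$status, c("auto_flagged", "accepted", "accepted",
                                 "auto_flagged"))
  # overrides win, both directions
  ov <- data.frame(trial_id = c(0, 1), status = c("accepted",
                                                  "manually_rejected"))
  out2 <- reject_trials(tt, flags, rl, ov)
  expect_identical(out2$status, c("accepted", "manually_rejected",
                                  "accepted", "auto_flagged"))
  expect_error(reject_trials(tt, flags, rl,
                             data.frame(trial_id = 99, status = "accepted")),
               "unknown trial_id")
})

test_that("concatenation keeps exactly the accepted volumes and all gaps", {
  sim <- small_sim()
  cc <- concatenate(sim$series, sim$trials)
  n_trials <- nrow(sim$trials)
  expect_identical(n_volumes(cc$series), n_trials * 12L)
  # kept + gaps partition the original index set
  tot <- nrow(cc$index$kept) + nrow(cc$index$gaps)
  expect_identical(tot, n_volumes(sim$series))
  key <- function(df) paste(df$run_id, df$orig_vol)
  expect_length(intersect(key(cc$index$kept), key(cc$index$gaps)), 0)
  # sum of accepted trial lengths equals concatenated length (exact)
  expect_identical(sum(sim$trials$end_vol - sim$trials$start_vol + 1L),
                   n_volumes(cc$series))
  # volumes appear in original order with run_id preserved
  expect_true(all(diff(order(cc$index$kept$run_id,
                             cc$index$kept$orig_vol)) == 1))
  expect_identical(cc$series$run_id, cc$index$kept$run_id)
  # concatenation of an already-pruned all-accepted series is the identity
  tt2 <- trial_table(sim$trials$trial_id, sim$trials$run_id,
                     start_vol = (seq_len(n_trials) - 1) %% 4 * 12,
                     end_vol = (seq_len(n_trials) - 1) %% 4 * 12 + 11)
  cc2 <- concatenate(cc$series, tt2)
  expect_identical(cc2$series$data, cc$series$data)
  expect_identical(nrow(cc2$index$gaps), 0L)
  # rejecting everything errors
  all_rej <- sim$trials
  all_rej$status <- "manually_rejected"
  expect_error(concatenate(sim$series, all_rej), "no accepted trials")
})

test_that("concat index round trips through JSON", {
  sim <- small_sim()
  cc <- concatenate(sim$series, sim$trials)
  path <- file.path(withr::local_tempdir(), "idx.json")
  write_concat_index(cc$index, path)
  back <- read_concat_index(path)
  expect_equal(back$kept, cc$index$kept)
  expect_equal(back$gaps, cc$index$gaps)
  expect_identical(back$run_lengths, cc$index$run_lengths)
})
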