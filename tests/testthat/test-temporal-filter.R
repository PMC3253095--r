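one_voxel_series <- function(values, tr = 1, runs = 1) {
  volume_series(array(values, c(1, 1, 1, length(values))), c(1, 1, 1), tr,
                "y", run_lengths = rep(length(values) / runs, runs))
}

test_that("gap interpolation reproduces the worked two-anchor example", {
  ser <- one_voxel_series(c(1, 1, 0, 0, 5, 5))
  tt <- trial_table(c(0, 1), c(0, 0), c(0, 4), c(1, 5))
  cc <- concatenate(ser, tt)
  cont <- interpolate_gaps(cc$series, cc$index)
  # anchors (0.5 s, 1) and (4.5 s, 5); line evaluated at t = 2, 3
  expect_equal(as.numeric(cont$data[1, 1, 1, ]), c(1, 1, 2.5, 3.5, 5, 5))
})

test_that("leading and trailing gaps extend the nearest anchor", {
  ser <- one_voxel_series(c(0, 7, 7, 3, 3, 0))
  tt <- trial_table(c(0, 1), c(0, 0), c(1, 3), c(2, 4))
  cc <- concatenate(ser, tt)
  cont <- interpolate_gaps(cc$series, cc$index)
  v <- as.numeric(cont$data[1, 1, 1, ])
  expect_equal(v[1], 7)   # leading gap <- first trial's first anchor
  expect_equal(v[6], 3)   # trailing gap <- last trial's last anchor
})

test_that("single-volume trials anchor with that volume", {
  ser <- one_voxel_series(c(2, 0, 6))
  tt <- trial_table(c(0, 1), c(0, 0), c(0, 2), c(0, 2))
  cc <- concatenate(ser, tt)
  cont <- interpolate_gaps(cc$series, cc$index)
  expect_equal(as.numeric(cont$data[1, 1, 1, ]), c(2, 4, 6))
})

test_that("gap-free input passes through interpolation untouched", {
  ser <- tiny_series(nt = 8)
  tt <- trial_table(0, 0, 0, 7)
  cc <- concatenate(ser, tt)
  cont <- interpolate_gaps(cc$series, cc$index)
  expect_identical(cont$data, cc$series$data)
  # and drop o interpolate is the identity
  expect_identical(drop_interpolated(cont, cc$index)$data, cc$series$data)
})

test_that("high-pass projection has the specified frequency response", {
  n <- 150; tr <- 2
  t <- (0:(n - 1)) * tr
  slow <- one_voxel_series(cos(2 * pi * t / 200), tr = tr)
  fast <- one_voxel_series(sin(2 * pi * t / 10), tr = tr)
  flat <- one_voxel_series(rep(4, n), tr = tr)
  fs <- filter_settings(cutoff = 96)
  expect_lt(max(abs(highpass(slow, fs)$data)), 0.05)
  expect_gt(max(abs(highpass(fast, fs)$data)), 0.95)
  expect_equal(highpass(flat, fs)$data, flat$data)  # DC retained
  expect_warning(highpass(flat, filter_settings(cutoff = 3)), "cutoff")
})

test_that("high-pass is idempotent and linear to float precision", {
  ser <- tiny_series(nt = 40)
  fs <- filter_settings(cutoff = 20)
  once <- highpass(ser, fs)
  twice <- highpass(once, fs)
  expect_lt(max(abs(twice$data - once$data)), 1e-10)
  # linearity of the full gap-filter pipeline for a fixed index
  tt <- trial_table(c(0, 1), c(0, 0), c(0, 20), c(9, 29))
  base <- tiny_series(nt = 40)
  other <- tiny_series(nt = 40)
  other$data <- other$data[, , , c(2:40, 1)]
  ccx <- concatenate(base, tt)
  ccy <- concatenate(other, tt)
  mix <- base
  mix$data <- 2 * base$data - 0.5 * other$data
  ccm <- concatenate(mix, tt)
  f <- function(cc) gap_filtered_highpass(cc$series, ccx$index, fs)$data
  expect_equal(f(ccm), 2 * f(ccx) - 0.5 * f(ccy), tolerance = 1e-10)
})

test_that("gap-filtered output equals plain high-pass on gap-free data", {
  ser <- tiny_series(nt = 30)
  tt <- trial_table(0, 0, 0, 29)
  cc <- concatenate(ser, tt)
  fs <- filter_settings(cutoff = 15)
  a <- gap_filtered_highpass(cc$series, cc$index, fs)
  b <- highpass(cc$series, fs)
  expect_identical(a$data, b$data)
})

test_that("runs are filtered independently and their steps remain", {
  n <- 30; tr <- 1
  y <- c(rnorm(n, 10, 0.1), rnorm(n, 20, 0.1))
  ser <- one_voxel_series(y, tr = tr, runs = 2)
  fs <- filter_settings(cutoff = 10)
  out <- highpass(ser, fs)
  m1 <- mean(out$data[1, 1, 1, 1:n])
  m2 <- mean(out$data[1, 1, 1, (n + 1):(2 * n)])
  expect_gt(abs(m2 - m1), 5)   # the between-run step is retained
  # modifying run 2 leaves run 1's output bit-identical
  ser2 <- ser
  ser2$data[, , , (n + 1):(2 * n)] <- ser2$data[, , , (n + 1):(2 * n)] + 7
  out2 <- highpass(ser2, fs)
  expect_identical(out2$data[, , , 1:n], out$data[, , , 1:n])
})

test_that("gap filtering reduces kept-sample variance on drifting data", {
  cfg <- degenerate_config(drift_linear = 0.04, drift_cosine_amplitude = 0.02,
                           noise_sd = 0.005, activation_amplitude = 0,
                           seed = 51)
  sim <- simulate_session(cfg)
  cc <- concatenate(sim$series, sim$trials)
  filt <- gap_filtered_highpass(cc$series, cc$index, filter_settings(96))
  mask <- sim$truth$brain_mask
  vox_ids <- which(mask)[seq(1, sum(mask), by = 37)]
  d_in <- matrix(cc$series$data, ncol = n_volumes(cc$series))[vox_ids, ]
  d_out <- matrix(filt$data, ncol = n_volumes(filt))[vox_ids, ]
  v_in <- apply(d_in, 1, stats::var)
  v_out <- apply(d_out, 1, stats::var)
  expect_true(all(v_out < v_in))
})

test_that("interpolation requires every run to keep at least one trial", {
  ser <- one_voxel_series(rep(1, 12), runs = 2)
  tt <- trial_table(0, 1, 0, 3)       # only run 1 has a trial
  cc <- concatenate(ser, tt)
  expect_error(interpolate_gaps(cc$series, cc$index), "no accepted trials")
})
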