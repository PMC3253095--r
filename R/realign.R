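# 2-step realignment: within-trial single-axis registration along the
# phase-encode direction, between-trial 12-parameter affine registration of
# trial mean images to the first trial's mean, composition of the two, and a
# single reslice per volume. Cost is mean squared intensity difference after
# Gaussian pre-smoothing; optimisation is bounded golden-section (1 DOF) and
# staged Nelder-Mead simplex (affine).

#' Registration settings
#'
#' @param smooth_fwhm_vox pre-smoothing FWHM in voxels applied to both images
#'   before cost evaluation
#' @param bracket_vox half-width of the 1-DOF search bracket, voxels
#' @param tol_vox termination tolerance of the 1-DOF search, voxels
#' @param maxit_stage simplex iteration budget per affine stage
#'   (translations; + rotations; full 12)
#' @param reslice_order interpolation order for the final reslice (3 = cubic)
#' @param cost_order interpolation order during cost evaluation (1 = trilinear)
#' @return a list of class `reg_settings`
#' @export
reg_settings <- function(smooth_fwhm_vox = 2, bracket_vox = 5,
                         tol_vox = 0.01, maxit_stage = c(150, 200, 400),
                         reslice_order = 3L, cost_order = 1L) {
  stopifnot(tol_vox > 0, bracket_vox > 0)
  structure(list(smooth_fwhm_vox = smooth_fwhm_vox,
                 bracket_vox = bracket_vox, tol_vox = tol_vox,
                 maxit_stage = maxit_stage,
                 reslice_order = as.integer(reslice_order),
                 cost_order = as.integer(cost_order)),
            class = "reg_settings")
}

pre_smooth <- function(vol, settings) {
  if (settings$smooth_fwhm_vox <= 0) return(vol)
  smooth3d(vol, fwhm_to_sigma(settings$smooth_fwhm_vox))
}

#' Estimate the single-axis shift between two volumes
#'
#' Finds the continuous translation along the phase axis that minimises the
#' smoothed mean squared difference to the reference, by golden-section
#' search over a bracket of +/- `bracket_vox` voxels. Positive shifts mean
#' the object moved toward increasing voxel index.
#'
#' @param moving,reference 3D arrays on the same grid
#' @param phase_axis shift axis (label or number)
#' @param voxel_size mm voxel size
#' @param settings a [reg_settings]
#' @return shift in mm
#' @export
estimate_shift_1d <- function(moving, reference, phase_axis, voxel_size,
                              settings = reg_settings()) {
  if (stats::sd(moving) == 0 || stats::sd(reference) == 0)
    stop("degenerate input: flat image has no registration signal")
  a <- axis_num(phase_axis)
  vm <- pre_smooth(moving, settings)
  vr <- pre_smooth(reference, settings)
  e <- c(0, 0, 0); e[a] <- 1
  vx <- voxel_size[a]
  f <- function(s) msd_cost(vm, vr, diag(3), s * e, voxel_size,
                            settings$cost_order)
  search_shift(f, settings$bracket_vox * vx, settings$tol_vox * vx, vx)
}

# coarse half-voxel scan followed by golden-section refinement: the MSD
# profile need not be unimodal over the full bracket
search_shift <- function(f, bracket, tol, vx) {
  grid <- seq(-bracket, bracket, by = vx / 2)
  coarse <- vapply(grid, f, numeric(1))
  s0 <- grid[which.min(coarse)]
  optimize(f, interval = c(max(-bracket, s0 - vx), min(bracket, s0 + vx)),
           tol = tol)$minimum
}

#' Within-trial realignment: per-volume shifts to each trial's first volume
#'
#' Estimates, for every volume of every accepted trial, the phase-axis shift
#' to that trial's first volume. Only the transformation parameters are
#' kept; no voxel data are modified (reslicing happens once, later, in
#' [compose_and_reslice()]).
#'
#' @param series a [volume_series] (typically the concatenated series)
#' @param trial_of per-volume trial id (e.g. `index$kept$trial_id`); volumes
#'   with `NA` get shift 0
#' @param settings a [reg_settings]
#' @return numeric vector of per-volume shifts in mm; exactly 0 at each
#'   trial's first volume
#' @export
within_trial_realign <- function(series, trial_of,
                                 settings = reg_settings()) {
  nt <- n_volumes(series)
  stopifnot(length(trial_of) == nt)
  shifts <- rep(0, nt)
  for (id in unique(trial_of[!is.na(trial_of)])) {
    rows <- which(trial_of == id)
    if (length(rows) < 2) next
    ref <- series$data[, , , rows[1]]
    refs <- pre_smooth(ref, settings)
    a <- axis_num(series$phase_axis)
    e <- c(0, 0, 0); e[a] <- 1
    vx <- series$voxel_size[a]
    for (v in rows[-1]) {
      vm <- pre_smooth(series$data[, , , v], settings)
      f <- function(s) msd_cost(vm, refs, diag(3), s * e,
                                series$voxel_size, settings$cost_order)
      shifts[v] <- search_shift(f, settings$bracket_vox * vx,
                                settings$tol_vox * vx, vx)
    }
  }
  log_step("within_trial_realign", list(n_volumes = nt,
                                        phase_axis = series$phase_axis))
  shifts
}

#' Mean image of one trial after applying its within-trial shifts
#'
#' The shifts are applied transiently (the stored volumes are untouched) and
#' the voxelwise mean is taken.
#'
#' @param series a [volume_series]
#' @param rows 1-based volume indices of the trial
#' @param shift1d per-volume shifts (mm) for the whole series
#' @param settings a [reg_settings]
#' @return 3D mean image
#' @export
trial_mean <- function(series, rows, shift1d, settings = reg_settings()) {
  if (length(rows) == 0) stop("empty trial")
  a <- axis_num(series$phase_axis)
  e <- c(0, 0, 0); e[a] <- 1
  acc <- array(0, dim(series$data)[1:3])
  for (v in rows) {
    vol <- series$data[, , , v]
    if (abs(shift1d[v]) > 0)
      vol <- translate_volume(vol, shift1d[v] * e, series$voxel_size,
                              order = settings$reslice_order)
    acc <- acc + vol
  }
  acc / length(rows)
}

#' Estimate a 12-parameter affine between two mean images
#'
#' Staged derivative-free minimisation of the smoothed mean squared
#' difference: translations first, then translations + rotations, then the
#' full 12 parameters, each stage warm-started from the previous. The
#' returned transform maps moving coordinates to reference coordinates about
#' the grid centre.
#'
#' @param moving_mean,reference_mean 3D arrays on the same grid
#' @param voxel_size mm voxel size
#' @param settings a [reg_settings]
#' @param dof one of `"affine12"` (default) or `"rigid6"` (translations and
#'   rotations only, the standard whole-series realignment baseline)
#' @param init optional starting parameter vector
#' @return named length-12 parameter vector with attributes `cost` (final
#'   MSD) and `converged` (logical)
#' @export
estimate_affine <- function(moving_mean, reference_mean, voxel_size,
                            settings = reg_settings(), dof = "affine12",
                            init = NULL) {
  dof <- match.arg(dof, c("affine12", "rigid6"))
  vm <- pre_smooth(moving_mean, settings)
  vr <- pre_smooth(reference_mean, settings)
  p <- init %||% identity_affine()
  stages <- list(1:3, 1:6)
  if (dof == "affine12") stages <- c(stages, list(1:12))
  scale <- c(rep(mean(voxel_size), 3), rep(0.02, 3), rep(0.02, 3),
             rep(0.02, 3))
  cost <- function(pfull) {
    m <- inv_map(affine_matrix(pfull))
    msd_cost(vm, vr, m$A, m$b, voxel_size, settings$cost_order)
  }
  converged <- TRUE
  for (si in seq_along(stages)) {
    idx <- stages[[si]]
    fn <- function(px) {
      pf <- p
      pf[idx] <- px
      cost(pf)
    }
    o <- optim(p[idx], fn, method = "Nelder-Mead",
               control = list(maxit = settings$maxit_stage[
                 min(si, length(settings$maxit_stage))],
                 parscale = scale[idx], reltol = 1e-9))
    p[idx] <- o$par
    if (o$convergence != 0) converged <- FALSE
  }
  structure(stats::setNames(p, AFFINE_NAMES), cost = cost(p),
            converged = converged)
}

#' Between-trial registration of trial means to the first trial's mean
#'
#' @param series a [volume_series]
#' @param trial_of per-volume trial id (NA outside trials)
#' @param shift1d per-volume within-trial shifts (mm)
#' @param settings a [reg_settings]
#' @param dof `"affine12"` or `"rigid6"`
#' @return list: `affines` (named list of parameter vectors by trial id, the
#'   first trial's being identity), `reference` (the first trial's mean
#'   image), `means` (list of trial means)
#' @export
between_trial_realign <- function(series, trial_of, shift1d,
                                  settings = reg_settings(),
                                  dof = "affine12") {
  ids <- unique(trial_of[!is.na(trial_of)])
  means <- lapply(ids, function(id)
    trial_mean(series, which(trial_of == id), shift1d, settings))
  names(means) <- as.character(ids)
  reference <- means[[1]]
  affines <- list()
  affines[[as.character(ids[1])]] <- identity_affine()
  for (id in ids[-1]) {
    affines[[as.character(id)]] <-
      estimate_affine(means[[as.character(id)]], reference,
                      series$voxel_size, settings, dof = dof)
  }
  log_step("between_trial_realign", list(n_trials = length(ids), dof = dof))
  list(affines = affines, reference = reference, means = means)
}

#' Compose within- and between-trial transforms and reslice once
#'
#' Every volume is resampled exactly once through the composed map: the
#' within-trial shift first, then its trial's affine, onto the grid of the
#' first trial's mean. Out-of-field voxels are set to 0.
#'
#' @param series a [volume_series]
#' @param shift1d per-volume shifts (mm)
#' @param affines named list of per-trial affine parameter vectors
#' @param trial_of per-volume trial id; volumes with `NA` use the identity
#'   affine
#' @param settings a [reg_settings]
#' @return the realigned [volume_series]
#' @export
compose_and_reslice <- function(series, shift1d, affines, trial_of,
                                settings = reg_settings()) {
  nt <- n_volumes(series)
  stopifnot(length(shift1d) == nt, length(trial_of) == nt)
  a <- axis_num(series$phase_axis)
  e <- c(0, 0, 0); e[a] <- 1
  out <- array(0, dim(series$data))
  for (v in seq_len(nt)) {
    id <- trial_of[v]
    p <- if (is.na(id)) identity_affine() else {
      pv <- affines[[as.character(id)]]
      if (is.null(pv)) stop("missing affine for trial ", id)
      pv
    }
    m <- inv_map(affine_matrix(p))
    # sampling point: M^-1 x + s e  (undo the affine, then the shift)
    out[, , , v] <- resample_affine(series$data[, , , v], m$A,
                                    m$b + shift1d[v] * e,
                                    series$voxel_size,
                                    order = settings$reslice_order)
  }
  log_step("compose_and_reslice", list(n_volumes = nt,
                                       order = settings$reslice_order))
  replace_data(series, out)
}

#' 2-step realignment of a concatenated series
#'
#' Convenience wrapper: within-trial shifts, between-trial affines of trial
#' means, composition, single reslice.
#'
#' @param series a concatenated [volume_series]
#' @param trial_of per-volume trial id (e.g. `index$kept$trial_id`)
#' @param settings a [reg_settings]
#' @return list: `series` (realigned), `transforms` (a [transform_set])
#' @export
realign_2step <- function(series, trial_of, settings = reg_settings()) {
  shifts <- within_trial_realign(series, trial_of, settings)
  bt <- between_trial_realign(series, trial_of, shifts, settings)
  out <- compose_and_reslice(series, shifts, bt$affines, trial_of, settings)
  list(series = out,
       transforms = transform_set(shifts, bt$affines, trial_of,
                                  series$phase_axis))
}

#' Whole-series rigid-body realignment (standard baseline)
#'
#' Registers every volume to the first volume with 6 degrees of freedom
#' (translations + rotations), warm-starting each volume from its
#' predecessor, and reslices. This is the conventional whole-session
#' approach that ignores the trial structure.
#'
#' @param series a [volume_series]
#' @param settings a [reg_settings]
#' @return list: `series` (realigned), `params` (matrix of per-volume
#'   6-DOF estimates embedded in 12-parameter rows)
#' @export
realign_rigid6 <- function(series, settings = reg_settings()) {
  nt <- n_volumes(series)
  ref <- series$data[, , , 1]
  out <- array(0, dim(series$data))
  out[, , , 1] <- ref
  params <- matrix(rep(identity_affine(), nt), nrow = nt, byrow = TRUE,
                   dimnames = list(NULL, AFFINE_NAMES))
  prev <- identity_affine()
  for (v in seq_len(nt)[-1]) {
    p <- estimate_affine(series$data[, , , v], ref, series$voxel_size,
                         settings, dof = "rigid6", init = prev)
    params[v, ] <- p
    prev <- stats::setNames(as.numeric(p), AFFINE_NAMES)
    m <- inv_map(affine_matrix(p))
    out[, , , v] <- resample_affine(series$data[, , , v], m$A, m$b,
                                    series$voxel_size,
                                    order = settings$reslice_order)
  }
  log_step("realign_rigid6", list(n_volumes = nt))
  list(series = replace_data(series, out), params = params)
}
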