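# Seeded simulator of an awake-NHP-like fMRI session with full ground truth.
# The generated session has trial-locked activation, slow drifts, a stepwise
# intensity offset between runs, within-trial respiratory shifts along the
# phase axis, between-trial affine distortion, and N/2 ghosts concentrated in
# the inter-trial reward periods.

#' Simulation configuration
#'
#' Defaults emulate a 2-segment EPI awake-macaque session at desk scale:
#' a 64x64x11 grid at 1.5x1.5x2 mm, 2 runs of 150 volumes at an intervolume
#' time of 2 s, 5 trials per run of 15 volumes separated by 10-volume reward
#' gaps. Artefact amplitudes are chosen for test discriminability: 30% N/2
#' ghosts in 10% of inter-trial volumes, 0.3 mm respiratory shifts within
#' trials, and sub-voxel affine jitter (with percent-level scale/shear
#' distortion) between trials.
#'
#' @param grid spatial grid (3 integers)
#' @param voxel_size voxel size in mm (length 3)
#' @param n_runs number of runs (5-minute acquisitions)
#' @param volumes_per_run volumes per run
#' @param intervolume_time seconds between volumes
#' @param phase_axis phase-encode axis label
#' @param n_trials_per_run,trial_length_vols,gap_length_vols trial layout;
#'   trials start after a leading gap and are separated by gaps
#' @param fixation_duration,stim_onset,stim_duration event scheme per trial,
#'   seconds from trial start
#' @param activation_centers list of voxel-coordinate blob centres (defaults
#'   to two blobs inside the brain)
#' @param activation_radius_mm blob radius in mm
#' @param activation_amplitude activation peak as a fraction of baseline
#' @param drift_linear linear drift over one run, fraction of baseline
#' @param drift_cosine_period,drift_cosine_amplitude slow cosine drift
#'   (seconds, fraction of baseline)
#' @param noise_sd white-noise sd as a fraction of mean brain baseline
#' @param shift_amplitude_mm,shift_period_s within-trial sinusoidal shift
#'   along the phase axis (zero at each trial's first volume)
#' @param affine_translation_mm,affine_rotation_rad,affine_scale,affine_shear
#'   maximal between-trial jitter per affine parameter class
#' @param ghost_fraction fraction of inter-trial volumes receiving a ghost
#' @param ghost_amplitude ghost amplitude g (fraction of the source image)
#' @param bad_trial_ids trials whose every volume is ghosted (slight
#'   undetected in-trial movement)
#' @param run_step_offset per-run stepwise intensity offset, fraction of
#'   baseline per run index
#' @param bias_center,bias_strength receive-coil bias field (voxel coords and
#'   unitless strength; centre defaults to the brain centre)
#' @param seed integer seed fixing all randomness
#' @return an object of class `sim_config`
#' @export
sim_config <- function(grid = c(64, 64, 11), voxel_size = c(1.5, 1.5, 2),
                       n_runs = 2, volumes_per_run = 150,
                       intervolume_time = 2, phase_axis = "y",
                       n_trials_per_run = 5, trial_length_vols = 15,
                       gap_length_vols = 10,
                       fixation_duration = 6, stim_onset = 6,
                       stim_duration = 2,
                       activation_centers = NULL,
                       activation_radius_mm = 4.5,
                       activation_amplitude = 0.02,
                       drift_linear = 0.02,
                       drift_cosine_period = 120,
                       drift_cosine_amplitude = 0.01,
                       noise_sd = 0.01,
                       shift_amplitude_mm = 0.3, shift_period_s = 7,
                       affine_translation_mm = 0.15,
                       affine_rotation_rad = 0.01,
                       affine_scale = 0.01, affine_shear = 0.005,
                       ghost_fraction = 0.1, ghost_amplitude = 0.3,
                       bad_trial_ids = integer(0),
                       run_step_offset = 0.03,
                       bias_center = NULL, bias_strength = 1,
                       seed = 1) {
  cfg <- as.list(environment())
  span <- gap_length_vols +
    n_trials_per_run * (trial_length_vols + gap_length_vols) -
    gap_length_vols
  if (span > volumes_per_run)
    stop("trial layout does not fit in volumes_per_run (needs ", span, ")")
  trial_span_s <- trial_length_vols * intervolume_time
  if (stim_onset + stim_duration > trial_span_s ||
      fixation_duration > trial_span_s)
    stop("event scheme does not fit within one trial")
  amps <- c(activation_amplitude, drift_linear, drift_cosine_amplitude,
            noise_sd, shift_amplitude_mm, ghost_fraction, ghost_amplitude,
            run_step_offset, bias_strength)
  if (any(amps < 0)) stop("all amplitudes must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

#' Build a head phantom with brain and brain-adjacent muscle tissue
#'
#' An ellipsoidal brain with smooth internal texture, a partial muscle shell
#' of similar mean intensity on the jaw side, and dark background. The
#' similar-intensity shell is what makes purely intensity-based extraction
#' fail and the radial weighting necessary.
#'
#' @param shape grid (3 integers, each >= 16)
#' @param voxel_size mm voxel size (length 3)
#' @param seed integer seed for the intensity texture
#' @return list with `baseline` (3D image), `brain_mask`, `muscle_mask`
#'   (disjoint logical arrays)
#' @export
make_phantom <- function(shape, voxel_size, seed = 1) {
  if (any(shape[1:2] < 16) || shape[3] < 4)
    stop("phantom grid must be at least 16x16 in plane and 4 slices")
  set.seed(seed)
  ctr <- (shape + 1) / 2
  fov <- shape * voxel_size
  ax <- c(0.28 * fov[1], 0.28 * fov[2], 0.30 * fov[3])   # semi-axes, mm
  co <- arrayInd(seq_len(prod(shape)), shape)
  dx <- (co[, 1] - ctr[1]) * voxel_size[1] / ax[1]
  dy <- (co[, 2] - ctr[2]) * voxel_size[2] / ax[2]
  dz <- (co[, 3] - ctr[3]) * voxel_size[3] / ax[3]
  r2 <- dx^2 + dy^2 + dz^2
  brain <- array(r2 <= 1, shape)
  # partial lateral shell on the jaw side, similar intensity to brain;
  # confined in-plane (jaw musculature is lateral, not a polar cap)
  shell <- array(r2 > 1.2^2 & r2 <= 2^2, shape)
  side <- array(co[, 2] > ctr[2] + 0.08 * shape[2], shape)
  inplane <- array(abs(dz) < 0.85, shape)
  muscle <- shell & side & inplane
  tex <- smooth3d(array(rnorm(prod(shape)), shape), 3 / voxel_size)
  tex <- tex / stats::sd(tex)
  img <- array(0, shape)
  img[brain] <- 100 * (1 + 0.08 * tex[brain])
  img[muscle] <- 96 * (1 + 0.08 * tex[muscle])
  # partial-volume rolloff at tissue boundaries, as in real EPI
  img <- smooth3d(img, 1.1)
  img[img < 0] <- 0
  list(baseline = img, brain_mask = brain, muscle_mask = muscle)
}

#' Apply a multiplicative receive-coil bias field
#'
#' The field is `b(x) = 1 + strength * (1 - d(x, center)/d_max)`, decreasing
#' monotonically with mm distance from the coil centre; `strength = 0` is the
#' identity.
#'
#' @param image 3D array
#' @param center voxel coordinates of the field centre (inside the grid)
#' @param strength unitless field strength, >= 0
#' @param voxel_size mm voxel size (length 3)
#' @return biased image
#' @export
apply_bias_field <- function(image, center, strength, voxel_size) {
  if (strength < 0) stop("strength must be >= 0")
  d <- dim(image)
  if (any(center < 1) || any(center > d))
    stop("bias centre must lie inside the grid")
  if (strength == 0) return(image)
  image * bias_field(d, center, strength, voxel_size)
}

bias_field <- function(shape, center, strength, voxel_size) {
  co <- arrayInd(seq_len(prod(shape)), shape)
  dmm <- sqrt(((co[, 1] - center[1]) * voxel_size[1])^2 +
                ((co[, 2] - center[2]) * voxel_size[2])^2 +
                ((co[, 3] - center[3]) * voxel_size[3])^2)
  corners <- as.matrix(expand.grid(c(1, shape[1]), c(1, shape[2]),
                                   c(1, shape[3])))
  dmax <- max(sqrt(colSums(((t(corners) - center) * voxel_size)^2)))
  array(1 + strength * (1 - dmm / dmax), shape)
}

#' Inject an N/2 ghost into a volume
#'
#' The dominant segmented-EPI movement artefact: a half-field-of-view
#' circularly shifted copy of the object appears along the phase-encode
#' direction. `output = volume + g * circshift(volume, FOV/2, phase_axis)`.
#'
#' @param volume 3D array
#' @param phase_axis phase-encode axis (label or number)
#' @param amplitude ghost amplitude g >= 0
#' @return ghosted volume
#' @export
inject_ghost <- function(volume, phase_axis, amplitude) {
  if (amplitude < 0) stop("ghost amplitude must be >= 0")
  if (amplitude == 0) return(volume)
  a <- axis_num(phase_axis)
  volume + amplitude * circshift3d(volume, a, dim(volume)[a] %/% 2L)
}

# trial layout for one run: 0-based start volumes
trial_starts <- function(cfg) {
  cfg$gap_length_vols +
    (seq_len(cfg$n_trials_per_run) - 1L) *
    (cfg$trial_length_vols + cfg$gap_length_vols)
}

# the session's trial table implied by a config
sim_trial_table <- function(cfg) {
  starts <- trial_starts(cfg)
  tr <- cfg$intervolume_time
  ids <- integer(0); runs <- integer(0); sv <- integer(0); ev <- list()
  for (r in seq_len(cfg$n_runs) - 1L) {
    for (t in seq_len(cfg$n_trials_per_run) - 1L) {
      ids <- c(ids, r * cfg$n_trials_per_run + t)
      runs <- c(runs, r)
      sv <- c(sv, starts[t + 1L])
      t0 <- starts[t + 1L] * tr
      ev <- c(ev, list(data.frame(
        condition = c("fixation", "stimulation"),
        onset = c(t0, t0 + cfg$stim_onset),
        duration = c(cfg$fixation_duration, cfg$stim_duration))))
    }
  }
  trial_table(ids, runs, sv, sv + cfg$trial_length_vols - 1L,
              status = "accepted", events = ev)
}

#' Simulate a trial-structured awake-NHP session with ground truth
#'
#' Assembles `baseline x bias x (1 + activation + drift + run step) + noise`,
#' then corrupts the geometry volume by volume: a sinusoidal within-trial
#' translation along the phase axis, per-trial affine jitter for every trial
#' after the first, and N/2 ghosts in a seeded subset of inter-trial volumes
#' and in all volumes of `bad_trial_ids`. Independent random streams are used
#' per component, so switching one artefact off leaves the others bit-equal.
#'
#' @param cfg a [sim_config]
#' @return list with elements `series` ([volume_series]), `trials`
#'   ([trial_table]), `sensor` (data frame: time, jaw, body), `truth`
#'   (ground-truth list: `brain_mask`, `activation_map`, `injected_shift1d`,
#'   `injected_affine`, `artefact_volumes` (0-based), `bad_trials`,
#'   `clean_baseline`, `muscle_mask`) and `config`
#' @export
simulate_session <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ph <- make_phantom(cfg$grid, cfg$voxel_size, seed = cfg$seed)
  ctr <- (cfg$grid + 1) / 2
  bias_ctr <- cfg$bias_center %||% ctr
  bias <- if (cfg$bias_strength > 0)
    bias_field(cfg$grid, bias_ctr, cfg$bias_strength, cfg$voxel_size)
  else array(1, cfg$grid)
  baseline <- ph$baseline * bias

  trials <- sim_trial_table(cfg)
  nt_run <- cfg$volumes_per_run
  nt <- cfg$n_runs * nt_run
  tr <- cfg$intervolume_time

  # activation blobs inside the brain
  centers <- cfg$activation_centers %||% list(
    ctr + c(-0.15 * cfg$grid[1], -0.12 * cfg$grid[2], 0),
    ctr + c(0.15 * cfg$grid[1], -0.12 * cfg$grid[2], 0))
  act <- array(FALSE, cfg$grid)
  co <- arrayInd(seq_len(prod(cfg$grid)), cfg$grid)
  for (cc in centers) {
    dmm2 <- ((co[, 1] - cc[1]) * cfg$voxel_size[1])^2 +
      ((co[, 2] - cc[2]) * cfg$voxel_size[2])^2 +
      ((co[, 3] - cc[3]) * cfg$voxel_size[3])^2
    act <- act | array(dmm2 <= cfg$activation_radius_mm^2, cfg$grid)
  }
  act <- act & ph$brain_mask

  # expected BOLD response to the stimulation events, peak-normalised
  reg <- build_regressors(trials, run_lengths = rep(nt_run, cfg$n_runs),
                          intervolume_time = tr,
                          conditions = "stimulation")[, 1]
  if (max(reg) > 0) reg <- reg / max(reg)

  # per-volume intensity modulation
  run_of <- rep(seq_len(cfg$n_runs) - 1L, each = nt_run)
  t_run <- rep((seq_len(nt_run) - 1) * tr, cfg$n_runs)
  drift <- cfg$drift_linear * t_run / (nt_run * tr) +
    cfg$drift_cosine_amplitude * cos(2 * pi * t_run / cfg$drift_cosine_period)
  step <- cfg$run_step_offset * run_of

  # geometric truth
  in_trial <- rep(NA_integer_, nt)      # trial id per volume, NA outside
  for (i in seq_len(nrow(trials))) {
    rows <- trials$run_id[i] * nt_run +
      (trials$start_vol[i]:trials$end_vol[i]) + 1L
    in_trial[rows] <- trials$trial_id[i]
  }
  shift <- rep(0, nt)
  if (cfg$shift_amplitude_mm > 0) {
    for (i in seq_len(nrow(trials))) {
      rows <- which(in_trial == trials$trial_id[i])
      tt <- (seq_along(rows) - 1) * tr
      shift[rows] <- cfg$shift_amplitude_mm *
        sin(2 * pi * tt / cfg$shift_period_s)
    }
  }
  set.seed(cfg$seed + 211L)
  affines <- list()
  first_trial <- trials$trial_id[1]
  for (i in seq_len(nrow(trials))) {
    id <- trials$trial_id[i]
    p <- identity_affine()
    if (id != first_trial) {
      p[1:3] <- runif(3, -1, 1) * cfg$affine_translation_mm
      p[4:6] <- runif(3, -1, 1) * cfg$affine_rotation_rad
      p[7:9] <- 1 + runif(3, -1, 1) * cfg$affine_scale
      p[10:12] <- runif(3, -1, 1) * cfg$affine_shear
    }
    affines[[as.character(id)]] <- p
  }

  # ghost placement
  set.seed(cfg$seed + 101L)
  intertrial <- which(is.na(in_trial))
  n_ghost <- round(cfg$ghost_fraction * length(intertrial))
  ghosted <- sort(sample(intertrial, n_ghost))
  bad_rows <- which(in_trial %in% cfg$bad_trial_ids)
  artefact_rows <- sort(union(ghosted, bad_rows))

  # assemble volumes
  axis <- axis_num(cfg$phase_axis)
  e <- c(0, 0, 0); e[axis] <- 1
  data <- array(0, c(cfg$grid, nt))
  for (v in seq_len(nt)) {
    gain <- 1 + drift[v] + step[v]
    vol <- baseline * gain
    if (cfg$activation_amplitude > 0 && reg[v] > 0)
      vol <- vol + baseline * cfg$activation_amplitude * reg[v] * act
    id <- in_trial[v]
    pj <- if (!is.na(id)) affines[[as.character(id)]] else identity_affine()
    moved <- abs(shift[v]) > 0 || any(pj != identity_affine())
    if (moved) {
      M <- affine_matrix(pj)
      A <- M[1:3, 1:3]
      b <- as.numeric(M[1:3, 4] - A %*% (shift[v] * e))
      vol <- resample_affine(vol, A, b, cfg$voxel_size, order = 3L)
    }
    if (v %in% artefact_rows)
      vol <- inject_ghost(vol, axis, cfg$ghost_amplitude)
    data[, , , v] <- vol
  }
  if (cfg$noise_sd > 0) {
    set.seed(cfg$seed + 307L)
    data <- data + rnorm(length(data),
                         sd = cfg$noise_sd * mean(ph$baseline[ph$brain_mask]))
  }
  series <- volume_series(data, cfg$voxel_size, tr, cfg$phase_axis,
                          run_lengths = rep(nt_run, cfg$n_runs))

  # motion-sensor traces: quiet within trials, noisy bursts between them
  set.seed(cfg$seed + 401L)
  t_global <- (seq_len(nt) - 1) * tr
  inter <- is.na(in_trial)
  jaw <- 0.05 * abs(rnorm(nt)) + inter * (0.8 + 0.3 * abs(rnorm(nt)))
  body <- 0.05 * abs(rnorm(nt)) + inter * (0.6 + 0.3 * abs(rnorm(nt)))
  jaw[artefact_rows] <- jaw[artefact_rows] + 1
  sensor <- data.frame(time = t_global, jaw = jaw, body = body)

  truth <- structure(list(
    brain_mask = ph$brain_mask,
    muscle_mask = ph$muscle_mask,
    activation_map = act,
    injected_shift1d = shift,
    injected_affine = affines,
    artefact_volumes = artefact_rows - 1L,
    bad_trials = as.integer(cfg$bad_trial_ids),
    clean_baseline = baseline
  ), class = "ground_truth")

  log_step("simulate_session",
           list(seed = cfg$seed, grid = cfg$grid, n_runs = cfg$n_runs,
                volumes_per_run = cfg$volumes_per_run))
  list(series = series, trials = trials, sensor = sensor, truth = truth,
       config = cfg)
}

# a config identical to cfg but with all artefacts and noise switched off
clean_config <- function(cfg, keep_noise = FALSE) {
  cfg$shift_amplitude_mm <- 0
  cfg$affine_translation_mm <- 0
  cfg$affine_rotation_rad <- 0
  cfg$affine_scale <- 0
  cfg$affine_shear <- 0
  cfg$ghost_fraction <- 0
  cfg$bad_trial_ids <- integer(0)
  if (!keep_noise) cfg$noise_sd <- 0
  cfg
}
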