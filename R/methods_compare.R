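# The five-analysis comparison harness. Methods 1-5 apply, cumulatively,
# the trial-oriented preprocessing steps and are scored by the proportion of
# suprathreshold voxels for the stimulation - fixation contrast:
#   1 standard: whole-series rigid realignment, no artefact handling
#   2 standard + one-hot artefact regressors (best conventional practice)
#   3 trial concatenation + whole-series rigid realignment
#   4 trial concatenation + 2-step realignment
#   5 method 4 + gap-interpolated 96 s high-pass filtering
# All methods share smoothing, per-run session intercepts, a run-wise
# 128 s model high-pass, grand-mean scaling, and the same t threshold.

#' Default configuration for the method comparison
#'
#' @param brain_roi brain region for the ghost-ratio QC (logical array)
#' @param ghost_roi ghost region; derived from `brain_roi` when `NULL`
#' @param mask counting/fitting mask (defaults to `brain_roi`)
#' @param threshold t threshold for suprathreshold counting
#' @param fwhm_mm spatial smoothing FWHM (mm)
#' @param model_cutoff run-wise model high-pass cutoff (s), applied to data
#'   and condition regressors in every method
#' @param gap_cutoff cutoff (s) of the gap-interpolated filter (method 5)
#' @param ratio_threshold,com_threshold_mm QC flagging thresholds
#' @param conditions,contrast contrast definition over condition columns
#' @param overrides optional manual trial overrides (data frame
#'   `trial_id`, `status`)
#' @param settings a [reg_settings] for all registrations
#' @return a list of class `method_config`
#' @export
method_config <- function(brain_roi, ghost_roi = NULL, mask = NULL,
                          threshold = 3.11, fwhm_mm = c(2, 2, 2),
                          model_cutoff = 128, gap_cutoff = 96,
                          ratio_threshold = "adaptive",
                          com_threshold_mm = 2,
                          conditions = c("stimulation", "fixation"),
                          contrast = c(1, -1),
                          overrides = NULL,
                          settings = reg_settings()) {
  structure(list(brain_roi = brain_roi, ghost_roi = ghost_roi,
                 mask = mask %||% brain_roi, threshold = threshold,
                 fwhm_mm = fwhm_mm, model_cutoff = model_cutoff,
                 gap_cutoff = gap_cutoff, ratio_threshold = ratio_threshold,
                 com_threshold_mm = com_threshold_mm,
                 conditions = conditions, contrast = contrast,
                 overrides = overrides, settings = settings),
            class = "method_config")
}

# shared GLM stage: smooth, run-wise model high-pass on data and condition
# regressors, design with per-run intercepts (+ one-hot artefact columns),
# OLS fit, suprathreshold count
glm_stage <- function(series, regressors, config, artefact_vols = NULL) {
  series <- smooth_spatial(series, config$fwhm_mm)
  series <- highpass(series, filter_settings(cutoff = config$model_cutoff))
  reg <- regressors
  tr <- series$intervolume_time
  for (r in unique(series$run_id)) {
    rows <- which(series$run_id == r)
    reg[rows, ] <- dct_project_out(reg[rows, , drop = FALSE], tr,
                                   config$model_cutoff)
  }
  des <- design_matrix(reg, series$run_id, artefact_vols)
  contrast <- c(config$contrast, rep(0, ncol(des$X) - length(config$contrast)))
  fit <- fit_glm(series, des, contrast, mask = config$mask)
  supra <- count_suprathreshold(fit, config$mask, config$threshold)
  list(fit = fit, count = supra$count, proportion = supra$proportion,
       n_columns = ncol(des$X))
}

# QC flags for the full series
method_flags <- function(series, config) {
  stats <- qc_stats(series, config$brain_roi, config$ghost_roi)
  auto_flag(stats, config$ratio_threshold, config$com_threshold_mm)
}

#' Run one of the five comparison analyses
#'
#' @param series the full (unconcatenated) session [volume_series]
#' @param trials the session [trial_table]
#' @param method integer 1-5
#' @param config a [method_config]
#' @return list: `method`, `count`, `proportion`, `n_columns`, `df`, `fit`
#'   (the `glm_result`)
#' @export
run_method <- function(series, trials, method, config) {
  stopifnot(method %in% 1:5)
  regressors <- build_regressors(trials, unname(run_lengths(series)),
                                 series$intervolume_time, config$conditions)
  out <- if (method %in% 1:2) {
    ra <- realign_rigid6(series, config$settings)
    art <- NULL
    if (method == 2) {
      flags <- method_flags(series, config)
      art <- artefact_rows(series, trials, flags)
    }
    glm_stage(ra$series, regressors, config, art)
  } else {
    flags <- method_flags(series, config)
    sel <- reject_trials(trials, flags, unname(run_lengths(series)),
                         config$overrides)
    cc <- concatenate(series, sel)
    reg <- select_regressor_rows(regressors, cc$index)
    if (method == 3) {
      ra <- realign_rigid6(cc$series, config$settings)
      glm_stage(ra$series, reg, config)
    } else {
      ra <- realign_2step(cc$series, cc$index$kept$trial_id,
                          config$settings)
      ser <- ra$series
      if (method == 5)
        ser <- gap_filtered_highpass(ser, cc$index,
                                     filter_settings(config$gap_cutoff))
      glm_stage(ser, reg, config)
    }
  }
  log_step("run_method", list(method = method, count = out$count,
                              proportion = out$proportion))
  c(list(method = method, df = out$fit$df), out)
}

# 1-based rows treated as artefact-affected for method 2: every flagged
# volume, every volume of a trial containing a flagged volume, and all
# inter-trial volumes
artefact_rows <- function(series, trials, flags) {
  rl <- unname(run_lengths(series))
  offs <- c(0L, cumsum(rl))
  runs <- sort(unique(series$run_id))
  in_trial <- rep(FALSE, n_volumes(series))
  trial_art <- integer(0)
  for (i in seq_len(nrow(trials))) {
    r <- match(trials$run_id[i], runs)
    rows <- offs[r] + (trials$start_vol[i]:trials$end_vol[i]) + 1L
    in_trial[rows] <- TRUE
    if (any(flags[rows])) trial_art <- c(trial_art, rows)
  }
  sort(unique(c(which(flags), trial_art, which(!in_trial))))
}

#' Run all requested methods on one session, sharing intermediate stages
#'
#' @param series,trials the session
#' @param config a [method_config]
#' @param methods subset of 1:5
#' @return data frame: `method`, `count`, `proportion`, `df`, `n_columns`
#' @export
compare_methods <- function(series, trials, config, methods = 1:5) {
  regressors <- build_regressors(trials, unname(run_lengths(series)),
                                 series$intervolume_time, config$conditions)
  flags <- if (any(methods >= 2)) method_flags(series, config) else NULL
  ra_full <- if (any(methods <= 2)) realign_rigid6(series, config$settings)
             else NULL
  cc <- reg_cc <- ra2 <- NULL
  if (any(methods >= 3)) {
    sel <- reject_trials(trials, flags, unname(run_lengths(series)),
                         config$overrides)
    cc <- concatenate(series, sel)
    reg_cc <- select_regressor_rows(regressors, cc$index)
    if (any(methods >= 4))
      ra2 <- realign_2step(cc$series, cc$index$kept$trial_id,
                           config$settings)
  }
  rows <- lapply(methods, function(m) {
    res <- switch(as.character(m),
      "1" = glm_stage(ra_full$series, regressors, config),
      "2" = glm_stage(ra_full$series, regressors, config,
                      artefact_rows(series, trials, flags)),
      "3" = glm_stage(realign_rigid6(cc$series, config$settings)$series,
                      reg_cc, config),
      "4" = glm_stage(ra2$series, reg_cc, config),
      "5" = glm_stage(
        gap_filtered_highpass(ra2$series, cc$index,
                              filter_settings(config$gap_cutoff)),
        reg_cc, config))
    data.frame(method = m, count = res$count,
               proportion = res$proportion, df = res$fit$df,
               n_columns = res$n_columns)
  })
  do.call(rbind, rows)
}

#' Seed-averaged method comparison on simulated sessions
#'
#' @param cfg a [sim_config]; its seed field is replaced by each entry of
#'   `seeds`
#' @param seeds integer vector of simulation seeds
#' @param methods subset of 1:5
#' @param config_fn function(sim) -> [method_config]; the default counts
#'   within the ground-truth brain mask and uses it as the QC brain region
#' @return data frame with one row per seed x method
#' @export
method_comparison_study <- function(cfg, seeds = 1:10, methods = 1:5,
                                    config_fn = NULL) {
  config_fn <- config_fn %||% function(sim)
    method_config(brain_roi = sim$truth$brain_mask)
  rows <- lapply(seeds, function(s) {
    cfg$seed <- s
    sim <- simulate_session(cfg)
    out <- compare_methods(sim$series, sim$trials, config_fn(sim), methods)
    out$seed <- s
    out
  })
  do.call(rbind, rows)
}
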