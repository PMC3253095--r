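# YAML-configured orchestration of the full processing chain:
# simulate -> qc -> select -> concat -> realign -> tfilter -> extract -> glm
# (-> compare). Every stage materialises its outputs (NIfTI/TSV/JSON) so any
# intermediate can be inspected, and every stage logs its parameters.

PIPELINE_KEYS <- c("out_dir", "seed", "log", "input", "simulate", "qc",
                   "select", "realign", "tfilter", "extract", "glm",
                   "compare")

#' Load, default and validate a pipeline configuration
#'
#' Unknown top-level keys are rejected before anything runs. Defaults:
#' gap-filter cutoff 96 s, model cutoff 128 s, smoothing 2 mm, t threshold
#' 3.11, adaptive QC thresholds.
#'
#' @param path YAML file, or a list with the same structure
#' @return validated configuration list of class `pipeline_config`
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$out_dir)) stop("out_dir is required")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  defaults <- list(
    qc = list(ratio_threshold = "adaptive", com_threshold_mm = 0.3),
    select = list(overrides = NULL),
    realign = list(mode = "2step"),
    tfilter = list(cutoff = 96),
    extract = list(strength = 1, threshold_frac = 0.28, mode = "3d"),
    glm = list(threshold = 3.11, fwhm_mm = 2, model_cutoff = 128,
               conditions = c("stimulation", "fixation"),
               contrast = c(1, -1)))
  for (k in names(defaults))
    cfg[[k]] <- modifyList(defaults[[k]], cfg[[k]] %||% list())
  if (!is.numeric(cfg$tfilter$cutoff) || cfg$tfilter$cutoff <= 0)
    stop("tfilter cutoff must be a positive number of seconds")
  if (!is.null(cfg$input)) {
    for (f in unlist(cfg$input))
      if (!file.exists(f)) stop("input file does not exist: ", f)
  } else if (is.null(cfg$simulate)) {
    cfg$simulate <- list()
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full pipeline described by a configuration
#'
#' Stages run in order and write their outputs under `out_dir`; with
#' `resume = TRUE` a stage whose outputs already exist is skipped. The
#' consolidated step log lands in `out_dir/log.jsonl`.
#'
#' @param config a `pipeline_config` (or path/list accepted by
#'   [validate_config()])
#' @param resume skip stages whose outputs are already on disk
#' @return the output directory, invisibly
#' @export
run_pipeline <- function(config, resume = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  set_log_file(cfg$log %||% file.path(out, "log.jsonl"))
  on.exit(set_log_file(NULL))
  p <- function(...) file.path(out, ...)
  stage <- function(name, outputs, fn) {
    if (resume && all(file.exists(p(outputs)))) return(invisible(NULL))
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  truth_mask <- NULL
  if (!is.null(cfg$simulate)) {
    stage("simulate", c("series.nii.gz", "trials.tsv"), function() {
      sim_args <- cfg$simulate
      sim_args$seed <- cfg$seed
      sim <- simulate_session(do.call(sim_config, sim_args))
      write_volume_series(sim$series, p("series.nii.gz"))
      write_trial_table(sim$trials, p("trials.tsv"))
      write.table(sim$sensor, p("sensor.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      write_volume3d(sim$truth$brain_mask, sim$series$voxel_size,
                     p("truth_brain_mask.nii.gz"))
      write_volume3d(sim$truth$activation_map, sim$series$voxel_size,
                     p("truth_activation.nii.gz"))
      jsonlite::write_json(
        list(artefact_volumes = sim$truth$artefact_volumes,
             bad_trials = sim$truth$bad_trials,
             injected_shift1d = sim$truth$injected_shift1d,
             injected_affine = lapply(sim$truth$injected_affine, as.list)),
        p("truth.json"), auto_unbox = TRUE, digits = NA)
    })
    series_path <- p("series.nii.gz")
    trials_path <- p("trials.tsv")
    mask_path <- p("truth_brain_mask.nii.gz")
  } else {
    series_path <- cfg$input$series
    trials_path <- cfg$input$trials
    mask_path <- cfg$input$brain_mask
  }
  series <- read_volume_series(series_path)
  trials <- read_trial_table(trials_path)
  brain_roi <- array(as.logical(RNifti::readNifti(mask_path) > 0),
                     dim(series$data)[1:3])

  stage("qc", "qc.tsv", function() {
    stats <- qc_stats(series, brain_roi)
    flags <- auto_flag(stats, cfg$qc$ratio_threshold,
                       cfg$qc$com_threshold_mm)
    stats$flag <- flags
    write.table(stats, p("qc.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  })
  qc <- read.delim(p("qc.tsv"))

  stage("select", "trials_selected.tsv", function() {
    overrides <- if (!is.null(cfg$select$overrides))
      read.delim(cfg$select$overrides) else NULL
    sel <- reject_trials(trials, qc$flag, unname(run_lengths(series)),
                         overrides)
    write_trial_table(sel, p("trials_selected.tsv"))
  })
  sel <- read_trial_table(p("trials_selected.tsv"))

  stage("concat", c("concat.nii.gz", "index.json"), function() {
    cc <- concatenate(series, sel)
    write_volume_series(cc$series, p("concat.nii.gz"))
    write_concat_index(cc$index, p("index.json"))
  })
  concat <- read_volume_series(p("concat.nii.gz"))
  index <- read_concat_index(p("index.json"))

  stage("realign", c("realigned.nii.gz", "transforms.json"), function() {
    if (identical(cfg$realign$mode, "rigid6")) {
      ra <- realign_rigid6(concat)
      write_volume_series(ra$series, p("realigned.nii.gz"))
      jsonlite::write_json(as.data.frame(ra$params), p("transforms.json"),
                           digits = NA)
    } else {
      ra <- realign_2step(concat, index$kept$trial_id)
      write_volume_series(ra$series, p("realigned.nii.gz"))
      write_transforms(ra$transforms, p("transforms.json"))
    }
  })
  realigned <- read_volume_series(p("realigned.nii.gz"))

  stage("tfilter", "filtered.nii.gz", function() {
    filt <- gap_filtered_highpass(realigned, index,
                                  filter_settings(cfg$tfilter$cutoff))
    write_volume_series(filt, p("filtered.nii.gz"))
  })
  filtered <- read_volume_series(p("filtered.nii.gz"))

  stage("extract", c("mask.nii.gz", "brain.nii.gz"), function() {
    ex <- extract_brain(realigned,
                        extraction_params(
                          strength = cfg$extract$strength,
                          threshold_frac = cfg$extract$threshold_frac,
                          mode = cfg$extract$mode))
    write_volume3d(ex$mask, realigned$voxel_size, p("mask.nii.gz"))
    write_volume_series(ex$series, p("brain.nii.gz"))
  })
  mask <- array(as.logical(RNifti::readNifti(p("mask.nii.gz")) > 0),
                dim(series$data)[1:3])

  stage("glm", c("tmap.nii.gz", "glm.tsv"), function() {
    mc <- method_config(
      brain_roi = brain_roi, mask = mask,
      threshold = cfg$glm$threshold, fwhm_mm = cfg$glm$fwhm_mm,
      model_cutoff = cfg$glm$model_cutoff,
      conditions = cfg$glm$conditions, contrast = cfg$glm$contrast)
    reg <- build_regressors(trials, unname(run_lengths(series)),
                            series$intervolume_time, cfg$glm$conditions)
    reg <- select_regressor_rows(reg, index)
    res <- glm_stage(filtered, reg, mc)
    write_volume3d(res$fit$t, series$voxel_size, p("tmap.nii.gz"))
    write.table(data.frame(count = res$count,
                           proportion = res$proportion,
                           df = res$fit$df,
                           threshold = cfg$glm$threshold),
                p("glm.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  })

  if (!is.null(cfg$compare)) {
    stage("compare", "compare.tsv", function() {
      sim_args <- cfg$simulate %||% list()
      seeds <- cfg$compare$seeds %||% cfg$seed
      methods <- cfg$compare$methods %||% 1:5
      tab <- method_comparison_study(do.call(sim_config, sim_args),
                                     seeds = seeds, methods = methods)
      write.table(tab, p("compare.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    })
  }
  invisible(out)
}
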