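# Per-volume QC statistics (ghost ratio, centre-of-mass shift),
# semi-automatic flagging with manual overrides, whole-trial rejection, and
# concatenation of the accepted trial epochs.

#' Centre-of-mass shift of every volume relative to a reference volume
#'
#' The intensity-weighted centroid in mm (voxel position times voxel size),
#' minus the centroid of the reference volume. An apparent-motion metric:
#' B0-induced shifts and ghosts both displace the centroid.
#'
#' @param series a [volume_series]
#' @param reference_index 0-based index of the reference volume
#' @param mask optional logical mask restricting the centroid computation
#' @return numeric matrix, one row per volume, columns x/y/z in mm
#' @export
com_shift <- function(series, reference_index = 0L, mask = NULL) {
  nt <- n_volumes(series)
  if (reference_index < 0 || reference_index >= nt)
    stop("reference_index out of range")
  d <- dim(series$data)[1:3]
  co <- arrayInd(seq_len(prod(d)), d)
  sel <- if (is.null(mask)) seq_len(prod(d)) else which(mask)
  pos <- sweep(co[sel, , drop = FALSE], 2, series$voxel_size, `*`)
  cen <- function(v) {
    w <- as.numeric(v)[sel]
    s <- sum(w)
    if (s == 0) stop("all-zero volume: centroid undefined")
    colSums(pos * w) / s
  }
  cents <- t(vapply(seq_len(nt),
                    function(i) cen(series$data[, , , i]), numeric(3)))
  out <- sweep(cents, 2, cents[reference_index + 1L, ], `-`)
  colnames(out) <- c("x", "y", "z")
  out
}

#' Brain-to-ghost intensity ratio of one volume
#'
#' Mean intensity over a predefined brain region divided by the mean over
#' the region outside the brain most affected by N/2 ghosting. Higher is
#' cleaner; a ghost raises the denominator and lowers the ratio.
#'
#' @param volume 3D array
#' @param brain_roi,ghost_roi disjoint non-empty logical masks
#' @return scalar ratio (the denominator is stabilised with
#'   `eps = 1e-12 * max(volume)`)
#' @export
ghost_ratio <- function(volume, brain_roi, ghost_roi) {
  if (!any(brain_roi) || !any(ghost_roi)) stop("ROIs must be non-empty")
  if (any(brain_roi & ghost_roi)) stop("ROIs must be disjoint")
  eps <- 1e-12 * max(volume)
  mean(volume[brain_roi]) / (mean(volume[ghost_roi]) + eps)
}

#' Default ghost region: the N/2 footprint of the brain outside the brain
#'
#' The brain mask circularly shifted by half the field of view along the
#' phase axis, minus the brain mask itself: where the ghost of the brain
#' lands when it does not overlap brain tissue.
#'
#' @param brain_mask logical 3D mask
#' @param phase_axis phase-encode axis (label or number)
#' @return logical mask; errors if the footprint is empty
#' @export
default_ghost_roi <- function(brain_mask, phase_axis) {
  if (!any(brain_mask)) stop("brain mask is empty")
  a <- axis_num(phase_axis)
  roi <- circshift3d(brain_mask, a, dim(brain_mask)[a] %/% 2L) & !brain_mask
  if (!any(roi))
    stop("ghost footprint is empty (brain fills the field of view)")
  roi
}

#' Per-volume QC statistics for a series
#'
#' @param series a [volume_series]
#' @param brain_roi brain region for the ghost ratio
#' @param ghost_roi ghost region; derived via [default_ghost_roi()] if `NULL`
#' @param reference_index 0-based reference volume for the CoM shift
#' @return object of class `qc_stats`: data frame with columns `volume`
#'   (0-based), `run_id`, `ghost_ratio`, `com_x`, `com_y`, `com_z`
#' @export
qc_stats <- function(series, brain_roi, ghost_roi = NULL,
                     reference_index = 0L) {
  if (is.null(ghost_roi))
    ghost_roi <- default_ghost_roi(brain_roi, series$phase_axis)
  nt <- n_volumes(series)
  gr <- vapply(seq_len(nt), function(i)
    ghost_ratio(series$data[, , , i], brain_roi, ghost_roi), numeric(1))
  cs <- com_shift(series, reference_index)
  out <- data.frame(volume = seq_len(nt) - 1L, run_id = series$run_id,
                    ghost_ratio = gr, com_x = cs[, 1], com_y = cs[, 2],
                    com_z = cs[, 3])
  class(out) <- c("qc_stats", "data.frame")
  log_step("qc_stats", list(n_volumes = nt,
                            reference_index = reference_index))
  out
}

#' Flag artefact-affected volumes from QC statistics
#'
#' A volume is flagged when its ghost ratio falls below the threshold or its
#' CoM deviates from the run's median CoM by more than `com_threshold_mm`.
#' The adaptive ratio threshold is `median - 3 * MAD` of the ghost ratios
#' within each run, a robust stand-in for a manually tuned per-session
#' threshold. Median-centring the CoM keeps the criterion valid even when
#' the nominal reference volume is itself artefact-affected.
#'
#' @param stats a `qc_stats` data frame
#' @param ratio_threshold positive scalar, or `"adaptive"` (default)
#' @param com_threshold_mm CoM deviation threshold in mm
#' @return logical vector, one flag per volume
#' @export
auto_flag <- function(stats, ratio_threshold = "adaptive",
                      com_threshold_mm = 0.3) {
  if (com_threshold_mm <= 0) stop("com_threshold_mm must be positive")
  if (identical(ratio_threshold, "adaptive")) {
    # spread floored at 2% of the run median: ROI means are near noiseless,
    # so unflooded MAD would flag physically meaningless sub-percent wobble,
    # while a visible ghost drops the ratio by tens of percent
    thr <- stats::ave(stats$ghost_ratio, stats$run_id, FUN = function(x)
      median(x) - 3 * max(mad(x), 0.02 * median(x)))
  } else {
    if (!is.numeric(ratio_threshold) || ratio_threshold <= 0)
      stop("ratio_threshold must be positive or \"adaptive\"")
    thr <- rep(ratio_threshold, nrow(stats))
  }
  dev <- function(x) x - stats::ave(x, stats$run_id, FUN = median)
  com_norm <- sqrt(dev(stats$com_x)^2 + dev(stats$com_y)^2 +
                     dev(stats$com_z)^2)
  flags <- stats$ghost_ratio < thr | com_norm > com_threshold_mm
  log_step("auto_flag", list(ratio_threshold = ratio_threshold,
                             com_threshold_mm = com_threshold_mm,
                             n_flagged = sum(flags)))
  flags
}

#' Reject whole trials from per-volume flags, with manual overrides
#'
#' Any trial containing at least one flagged volume is marked
#' `auto_flagged`; single-volume excision is deliberately not offered, since
#' movement that degrades one volume also perturbs the field for the rest of
#' the trial. Manual overrides are applied last and win.
#'
#' @param trials a [trial_table]
#' @param flags per-volume logical vector over the session (same order as
#'   the series the trials refer to)
#' @param run_lengths per-run volume counts of that series
#' @param manual_overrides optional data frame with columns `trial_id`,
#'   `status`
#' @return the trial table with updated `status`
#' @export
reject_trials <- function(trials, flags, run_lengths,
                          manual_overrides = NULL) {
  offs <- c(0L, cumsum(as.integer(run_lengths)))
  if (length(flags) != offs[length(offs)])
    stop("flags length must equal the series length")
  runs <- sort(unique(trials$run_id))
  for (i in seq_len(nrow(trials))) {
    r <- match(trials$run_id[i], runs)
    rows <- offs[r] + (trials$start_vol[i]:trials$end_vol[i]) + 1L
    if (any(flags[rows]) && trials$status[i] == "accepted")
      trials$status[i] <- "auto_flagged"
  }
  if (!is.null(manual_overrides) && nrow(manual_overrides)) {
    for (j in seq_len(nrow(manual_overrides))) {
      k <- match(manual_overrides$trial_id[j], trials$trial_id)
      if (is.na(k)) stop("override references unknown trial_id ",
                         manual_overrides$trial_id[j])
      st <- manual_overrides$status[j]
      if (!st %in% TRIAL_STATUSES) stop("unknown override status: ", st)
      trials$status[k] <- st
    }
  }
  log_step("reject_trials",
           list(n_auto_flagged = sum(trials$status == "auto_flagged"),
                n_overrides = if (is.null(manual_overrides)) 0L
                              else nrow(manual_overrides)))
  trials
}

#' Concatenate the accepted trial epochs of a series
#'
#' Keeps exactly the volumes of accepted trials, in original order, and
#' records the bijection between concatenated and original indices together
#' with the removed volumes and their acquisition times (the gap metadata
#' that later drives gap interpolation and regressor row selection).
#'
#' @param series a [volume_series]
#' @param trials a [trial_table] validated against the series
#' @return list with `series` (the concatenated [volume_series]) and `index`
#'   (a `concat_index`: `kept` data frame with `run_id`, `orig_vol` (0-based),
#'   `trial_id`, `acq_time`; `gaps` data frame with `run_id`, `orig_vol`,
#'   `acq_time`; `run_lengths` of the original series)
#' @export
concatenate <- function(series, trials) {
  validate_trials(trials, series)
  acc <- trials[trials$status == "accepted", , drop = FALSE]
  if (nrow(acc) == 0) stop("no accepted trials to concatenate")
  rl <- run_lengths(series)
  runs <- as.integer(names(rl))
  offs <- c(0L, cumsum(rl))
  keep_rows <- integer(0)
  trial_of <- integer(0)
  for (i in order(acc$run_id, acc$start_vol)) {
    r <- match(acc$run_id[i], runs)
    rows <- offs[r] + (acc$start_vol[i]:acc$end_vol[i]) + 1L
    keep_rows <- c(keep_rows, rows)
    trial_of <- c(trial_of, rep(acc$trial_id[i], length(rows)))
  }
  kept <- data.frame(run_id = series$run_id[keep_rows],
                     orig_vol = orig_index(keep_rows, series),
                     trial_id = trial_of,
                     acq_time = series$acq_time[keep_rows])
  gap_rows <- setdiff(seq_len(n_volumes(series)), keep_rows)
  gaps <- data.frame(run_id = series$run_id[gap_rows],
                     orig_vol = orig_index(gap_rows, series),
                     acq_time = series$acq_time[gap_rows])
  index <- structure(list(kept = kept, gaps = gaps,
                          run_lengths = as.integer(rl)),
                     class = "concat_index")
  out <- replace_data(series, series$data[, , , keep_rows, drop = FALSE],
                      keep = keep_rows)
  log_step("concatenate", list(n_kept = length(keep_rows),
                               n_removed = length(gap_rows)))
  list(series = out, index = index)
}

# session-global 1-based row -> 0-based within-run original index
orig_index <- function(rows, series) {
  rl <- run_lengths(series)
  offs <- c(0L, cumsum(rl))
  r <- findInterval(rows - 1L, offs[-length(offs)], rightmost.closed = FALSE)
  as.integer(rows - 1L - offs[r])
}

#' Write a concatenation index to JSON
#' @param index a `concat_index`
#' @param path output path
#' @export
write_concat_index <- function(index, path) {
  jsonlite::write_json(list(kept = index$kept, gaps = index$gaps,
                            run_lengths = index$run_lengths),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a concatenation index from JSON
#' @param path file path
#' @export
read_concat_index <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(kept = as.data.frame(obj$kept),
                 gaps = as.data.frame(obj$gaps),
                 run_lengths = as.integer(obj$run_lengths)),
            class = "concat_index")
}
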