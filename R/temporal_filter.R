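# High-pass filtering of concatenated trial data. Removed epochs are first
# bridged by linear interpolation between per-trial anchor images (the
# voxelwise average of the last two volumes of one trial and of the first
# two volumes of the next), the evenly sampled runs are filtered one by one
# by projecting out low-frequency discrete-cosine components, and the
# interpolated samples are discarded again.

#' Filter settings
#' @param cutoff high-pass cutoff period in seconds (components with period
#'   above this are removed); default 96
#' @param anchor_pair_size number of volumes averaged into each gap anchor
#' @return list of class `filter_settings`
#' @export
filter_settings <- function(cutoff = 96, anchor_pair_size = 2L) {
  stopifnot(cutoff > 0, anchor_pair_size >= 1)
  structure(list(cutoff = cutoff,
                 anchor_pair_size = as.integer(anchor_pair_size)),
            class = "filter_settings")
}

# non-constant DCT basis vectors with period > cutoff, N samples at spacing TR
dct_basis <- function(n, tr, cutoff) {
  k_max <- floor(2 * n * tr / cutoff)
  if (k_max < 1) return(NULL)
  n0 <- 0:(n - 1)
  vapply(seq_len(k_max), function(k) cos(pi * k * (2 * n0 + 1) / (2 * n)),
         numeric(n))
}

# project the low-frequency DCT span out of the columns of Y (n x v)
dct_project_out <- function(Y, tr, cutoff) {
  X <- dct_basis(nrow(Y), tr, cutoff)
  if (is.null(X)) return(Y)
  # DCT-II vectors are orthogonal with squared norm n/2
  Y - X %*% (crossprod(X, Y) / (nrow(Y) / 2))
}

#' Reconstitute the original per-run time grid by linear gap interpolation
#'
#' For each within-run gap between consecutive accepted trials, anchor
#' images are the voxelwise mean of the preceding trial's last two volumes
#' (placed at the midpoint of their acquisition times) and of the following
#' trial's first two volumes; each missing volume is the straight line
#' through the two anchors evaluated at its original acquisition time.
#' Leading/trailing within-run gaps are filled by constant extension of the
#' nearest anchor. Single-volume trials use that volume as both anchor
#' members.
#'
#' @param concat the concatenated [volume_series]
#' @param index the `concat_index` from [concatenate()]
#' @param settings a [filter_settings]
#' @return a [volume_series] on the full original per-run grid
#' @export
interpolate_gaps <- function(concat, index, settings = filter_settings()) {
  if (nrow(index$gaps) == 0 && nrow(index$kept) == n_volumes(concat) &&
      sum(index$run_lengths) == n_volumes(concat))
    return(concat)
  d3 <- dim(concat$data)[1:3]
  runs <- sort(unique(c(index$kept$run_id, index$gaps$run_id)))
  rl <- index$run_lengths
  tr <- concat$intervolume_time
  m <- settings$anchor_pair_size
  pieces <- vector("list", length(runs))
  for (ri in seq_along(runs)) {
    r <- runs[ri]
    n <- rl[ri]
    krows <- which(index$kept$run_id == r)
    if (length(krows) == 0) stop("run ", r, " has no accepted trials")
    kept_r <- index$kept[krows, ]
    full <- array(0, c(d3, n))
    full[, , , kept_r$orig_vol + 1L] <- concat$data[, , , krows]
    # per-trial anchors, in within-run order
    ids <- unique(kept_r$trial_id)
    anchors <- lapply(ids, function(id) {
      sel <- krows[kept_r$trial_id == id]
      k <- min(m, length(sel))
      head_sel <- sel[seq_len(k)]
      tail_sel <- sel[length(sel) - seq_len(k) + 1L]
      list(
        first = list(img = vol_mean(concat$data, head_sel),
                     t = mean(concat$acq_time[head_sel])),
        last = list(img = vol_mean(concat$data, tail_sel),
                    t = mean(concat$acq_time[tail_sel]))
      )
    })
    starts <- vapply(ids, function(id)
      min(kept_r$orig_vol[kept_r$trial_id == id]), numeric(1))
    ends <- vapply(ids, function(id)
      max(kept_r$orig_vol[kept_r$trial_id == id]), numeric(1))
    ord <- order(starts)
    ids <- ids[ord]; anchors <- anchors[ord]
    starts <- starts[ord]; ends <- ends[ord]
    missing <- setdiff(0:(n - 1L), kept_r$orig_vol)
    for (v in missing) {
      t_v <- v * tr
      after <- findInterval(v, starts)    # trial preceding the gap, 0 if none
      if (after == 0) {
        full[, , , v + 1L] <- anchors[[1]]$first$img
      } else if (after == length(ids) && v > ends[after]) {
        full[, , , v + 1L] <- anchors[[after]]$last$img
      } else {
        a <- anchors[[after]]$last
        b <- anchors[[after + 1L]]$first
        w <- (t_v - a$t) / (b$t - a$t)
        full[, , , v + 1L] <- (1 - w) * a$img + w * b$img
      }
    }
    pieces[[ri]] <- full
  }
  data <- abind4(pieces)
  volume_series(data, concat$voxel_size, tr, concat$phase_axis,
                run_lengths = rl)
}

vol_mean <- function(data, sel) {
  if (length(sel) == 1) return(data[, , , sel])
  apply(data[, , , sel, drop = FALSE], 1:3, mean)
}

#' Run-wise high-pass filter by discrete-cosine projection
#'
#' Per run and voxel, the `K = floor(2 N TR / cutoff)` non-constant
#' discrete-cosine components with period above the cutoff are projected
#' out. The constant (run mean) component is retained; between-run intensity
#' steps are left for the per-run intercepts of the GLM. The projection is
#' zero-phase, linear and idempotent.
#'
#' @param series an evenly sampled [volume_series]
#' @param settings a [filter_settings]
#' @return the filtered [volume_series]
#' @export
highpass <- function(series, settings = filter_settings()) {
  tr <- series$intervolume_time
  if (settings$cutoff <= 2 * tr) {
    warning("cutoff <= 2 TR leaves no basis vectors; returning input")
    return(series)
  }
  d <- dim(series$data)
  Y <- matrix(series$data, prod(d[1:3]), d[4])
  for (r in unique(series$run_id)) {
    rows <- which(series$run_id == r)
    Y[, rows] <- t(dct_project_out(t(Y[, rows, drop = FALSE]), tr,
                                   settings$cutoff))
  }
  log_step("highpass", list(cutoff = settings$cutoff))
  replace_data(series, array(Y, d))
}

#' Drop the interpolated samples again
#'
#' @param filtered a [volume_series] on the full original grid
#' @param index the `concat_index`
#' @return the concatenated [volume_series] holding exactly the kept volumes
#' @export
drop_interpolated <- function(filtered, index) {
  if (n_volumes(filtered) != sum(index$run_lengths))
    stop("series length does not match the index run lengths")
  offs <- c(0L, cumsum(index$run_lengths))
  runs <- sort(unique(c(index$kept$run_id, index$gaps$run_id)))
  r <- match(index$kept$run_id, runs)
  rows <- offs[r] + index$kept$orig_vol + 1L
  replace_data(filtered, filtered$data[, , , rows, drop = FALSE],
               keep = rows)
}

#' Gap-interpolated high-pass filtering of a concatenated series
#'
#' `drop_interpolated(highpass(interpolate_gaps(...)))`: the filter sees an
#' evenly sampled series free of concatenation steps, and only the genuine
#' samples are kept afterwards. On gap-free input this equals [highpass()]
#' exactly.
#'
#' @param concat the concatenated [volume_series]
#' @param index the `concat_index`
#' @param settings a [filter_settings]
#' @return the filtered concatenated [volume_series]
#' @export
gap_filtered_highpass <- function(concat, index,
                                  settings = filter_settings()) {
  cont <- interpolate_gaps(concat, index, settings)
  filt <- highpass(cont, settings)
  out <- drop_interpolated(filt, index)
  log_step("gap_filtered_highpass", list(cutoff = settings$cutoff))
  out
}
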