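# Regressor construction, design assembly consistent with concatenation,
# spatial smoothing, and a per-run-session OLS GLM with t-maps and
# suprathreshold counting.

#' Canonical double-gamma haemodynamic response function
#'
#' Peak delay 6 s, undershoot delay 16 s, unit dispersions, undershoot ratio
#' 1/6, 32 s support; sampled at `dt` and peak-normalised to 1.
#'
#' @param dt sampling interval in seconds
#' @return numeric kernel sampled at `0, dt, 2dt, ... <= 32`
#' @export
canonical_hrf <- function(dt) {
  stopifnot(dt > 0)
  t <- seq(0, 32, by = dt)
  h <- dgamma(t, shape = 6, scale = 1) - dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

#' Build condition regressors on the original (pre-concatenation) grid
#'
#' Event boxcars are laid out per run on a fine grid (`dt = TR/16`),
#' convolved with the canonical HRF, and sampled at the volume acquisition
#' times. Regressors are always built before any concatenation; removing
#' volumes later removes the same rows from data and model.
#'
#' @param trials a [trial_table] carrying condition events
#' @param run_lengths per-run volume counts of the original series
#' @param intervolume_time TR in seconds
#' @param conditions condition labels to build, in column order
#' @return numeric matrix, one row per original volume, one column per
#'   condition
#' @export
build_regressors <- function(trials, run_lengths, intervolume_time,
                             conditions) {
  tr <- intervolume_time
  fine <- tr / 16
  hrf <- canonical_hrf(fine)
  ev_list <- lapply(seq_len(nrow(trials)), function(i) {
    ev <- trials$events[[i]]
    if (nrow(ev) == 0) return(NULL)
    cbind(ev, run_id = trials$run_id[i])
  })
  all_ev <- do.call(rbind, ev_list)
  out <- matrix(0, sum(run_lengths), length(conditions),
                dimnames = list(NULL, conditions))
  if (is.null(all_ev) || nrow(all_ev) == 0) return(out)
  missing <- setdiff(conditions, unique(all_ev$condition))
  if (length(missing))
    stop("unknown condition(s): ", paste(missing, collapse = ", "))
  runs <- seq_along(run_lengths) - 1L
  at <- 0L
  for (ri in seq_along(run_lengths)) {
    n <- run_lengths[ri]
    grid_n <- ceiling(n * tr / fine) + 1L
    tgrid <- (seq_len(grid_n) - 1) * fine
    for (ci in seq_along(conditions)) {
      ev <- all_ev[all_ev$run_id == runs[ri] &
                     all_ev$condition == conditions[ci], , drop = FALSE]
      if (nrow(ev) == 0) next
      box <- numeric(grid_n)
      for (j in seq_len(nrow(ev)))
        box[tgrid >= ev$onset[j] &
              tgrid < ev$onset[j] + ev$duration[j]] <- 1
      conv <- convolve(box, rev(hrf), type = "open")[seq_len(grid_n)]
      # sample at volume acquisition times
      vol_t <- (seq_len(n) - 1) * tr
      out[at + seq_len(n), ci] <- conv[round(vol_t / fine) + 1]
    }
    at <- at + n
  }
  out * fine   # approximate continuous convolution (integral scaling)
}

#' Select regressor rows consistent with a concatenation
#'
#' @param regressors matrix with one row per original volume
#' @param index the `concat_index` from [concatenate()]
#' @return the rows at `index$kept`, in order
#' @export
select_regressor_rows <- function(regressors, index) {
  if (nrow(regressors) != sum(index$run_lengths))
    stop("regressor length does not match the original series length")
  offs <- c(0L, cumsum(index$run_lengths))
  runs <- sort(unique(c(index$kept$run_id, index$gaps$run_id)))
  r <- match(index$kept$run_id, runs)
  regressors[offs[r] + index$kept$orig_vol + 1L, , drop = FALSE]
}

#' Spatial Gaussian smoothing of every volume
#'
#' @param series a [volume_series]
#' @param fwhm_mm per-axis FWHM in mm (length 3, recycled); 0 is the
#'   identity
#' @return the smoothed [volume_series]
#' @export
smooth_spatial <- function(series, fwhm_mm = c(2, 2, 2)) {
  fwhm_mm <- rep_len(fwhm_mm, 3)
  stopifnot(all(fwhm_mm >= 0))
  if (all(fwhm_mm == 0)) return(series)
  sigma_vox <- fwhm_to_sigma(fwhm_mm) / series$voxel_size
  out <- series$data
  for (v in seq_len(n_volumes(series)))
    out[, , , v] <- smooth3d(series$data[, , , v], sigma_vox)
  log_step("smooth_spatial", list(fwhm_mm = fwhm_mm))
  replace_data(series, out)
}

#' Assemble a design matrix
#'
#' Columns: condition regressors, optional one-hot artefact regressors (one
#' column per artefact-affected volume), and one intercept per run
#' (between-run intensity steps are session effects).
#'
#' @param regressors condition regressor matrix aligned to the series rows
#' @param run_id per-volume run label
#' @param artefact_vols optional 1-based row indices to model with one-hot
#'   columns
#' @return list of class `design_matrix`: `X`, `names`, `condition_cols`
#' @export
design_matrix <- function(regressors, run_id, artefact_vols = NULL) {
  n <- length(run_id)
  stopifnot(nrow(regressors) == n)
  X <- regressors
  nms <- colnames(regressors)
  if (!is.null(artefact_vols) && length(artefact_vols)) {
    A <- matrix(0, n, length(artefact_vols))
    A[cbind(artefact_vols, seq_along(artefact_vols))] <- 1
    X <- cbind(X, A)
    nms <- c(nms, paste0("artefact_", artefact_vols))
  }
  runs <- sort(unique(run_id))
  R <- vapply(runs, function(r) as.numeric(run_id == r), numeric(n))
  X <- cbind(X, R)
  nms <- c(nms, paste0("run_", runs))
  colnames(X) <- nms
  structure(list(X = X, names = nms,
                 condition_cols = seq_len(ncol(regressors))),
            class = "design_matrix")
}

#' Fit a voxelwise OLS GLM and compute the contrast t-map
#'
#' Optionally grand-mean scales the whole dataset so the within-mask grand
#' mean is 100, then fits `y = X b` per voxel by ordinary least squares and
#' forms `t = c'b / sqrt(s2 c'(X'X)^- c)`. Voxels with residual variance
#' below `1e-12` times the grand mean get `t = 0` and a degenerate flag.
#' Rank-deficient designs are handled by pseudo-inverse with a warning.
#'
#' @param series a [volume_series]
#' @param design a [design_matrix] (or plain matrix) with as many rows as
#'   the series has volumes
#' @param contrast numeric contrast vector over the design columns
#' @param mask logical 3D mask of voxels to fit (default: all)
#' @param grand_mean_scale scale the in-mask grand mean to 100 (default)
#' @return list of class `glm_result`: `t` (3D array, 0 outside mask),
#'   `beta` (columns x voxels matrix), `sigma2` (3D array), `df`,
#'   `degenerate` (3D logical), `mask`, `contrast`
#' @export
fit_glm <- function(series, design, contrast, mask = NULL,
                    grand_mean_scale = TRUE) {
  X <- if (inherits(design, "design_matrix")) design$X else design
  d <- dim(series$data)
  if (nrow(X) != d[4]) stop("design rows must equal the series length")
  if (length(contrast) != ncol(X))
    stop("contrast length must equal the number of design columns")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  Y <- t(matrix(series$data, prod(d[1:3]), d[4])[which(mask), , drop = FALSE])
  gm <- mean(Y)
  if (grand_mean_scale && gm != 0) Y <- Y * (100 / gm)
  rk <- qr(X)$rank
  if (rk < ncol(X)) {
    warning("rank-deficient design (rank ", rk, " of ", ncol(X),
            "); using pseudo-inverse")
    sv <- svd(X)
    keep <- sv$d > max(sv$d) * 1e-10
    XtXinv <- sv$v[, keep, drop = FALSE] %*%
      (t(sv$v[, keep, drop = FALSE]) / sv$d[keep]^2)
  } else {
    XtXinv <- chol2inv(chol(crossprod(X)))
  }
  beta <- XtXinv %*% crossprod(X, Y)
  df <- nrow(X) - rk
  if (df <= 0) stop("no residual degrees of freedom")
  res <- Y - X %*% beta
  rss <- colSums(res^2)
  sigma2 <- rss / df
  cvc <- as.numeric(t(contrast) %*% XtXinv %*% contrast)
  gm_now <- mean(Y)
  degen <- sigma2 < 1e-12 * abs(gm_now)
  tv <- as.numeric(crossprod(contrast, beta)) / sqrt(sigma2 * cvc)
  tv[degen | !is.finite(tv)] <- 0
  tmap <- array(0, d[1:3])
  tmap[which(mask)] <- tv
  s2map <- array(NA_real_, d[1:3])
  s2map[which(mask)] <- sigma2
  dmap <- array(FALSE, d[1:3])
  dmap[which(mask)] <- degen
  log_step("fit_glm", list(n_columns = ncol(X), df = df,
                           grand_mean_scale = grand_mean_scale))
  structure(list(t = tmap, beta = beta, sigma2 = s2map, df = df,
                 degenerate = dmap, mask = mask, contrast = contrast),
            class = "glm_result")
}

#' Count suprathreshold voxels of a t-map
#'
#' @param result a `glm_result` (or a plain 3D t-map array)
#' @param mask logical mask over which to count
#' @param threshold t threshold (the conventional single-voxel height
#'   threshold for p < 0.001 uncorrected is 3.11)
#' @return list: `count` (in-mask voxels with `t > threshold`), `proportion`
#'   (count / in-mask voxels)
#' @export
count_suprathreshold <- function(result, mask, threshold = 3.11) {
  tmap <- if (inherits(result, "glm_result")) result$t else result
  if (!any(mask)) stop("empty mask")
  count <- sum(tmap[mask] > threshold)
  list(count = count, proportion = count / sum(mask))
}
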