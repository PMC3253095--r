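# VolumeSeries: a 4D functional series with voxel geometry, timing, run
# membership and the phase-encode axis. Stored in double precision whatever
# the on-disk datatype, since filtering and resampling need it.

#' Construct a volume series
#'
#' @param data 4D numeric array (x, y, z, t)
#' @param voxel_size length-3 voxel size in mm, all positive
#' @param intervolume_time time between consecutive volumes in seconds
#' @param phase_axis phase-encode axis, one of `"x"`, `"y"`, `"z"`; the axis
#'   along which B0 perturbations appear as apparent shifts and along which
#'   the N/2 ghost is displaced
#' @param run_lengths integer vector of volumes per run; alternatively supply
#'   `run_id` directly
#' @param run_id optional per-volume 0-based run label (non-decreasing)
#' @return an object of class `volume_series`
#' @export
volume_series <- function(data, voxel_size, intervolume_time,
                          phase_axis = "y", run_lengths = NULL,
                          run_id = NULL) {
  if (length(dim(data)) != 4L)
    stop("volume data must be 4-dimensional (x, y, z, t)")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive values (mm)")
  if (!is.numeric(intervolume_time) || length(intervolume_time) != 1L ||
      intervolume_time <= 0)
    stop("intervolume_time must be a positive scalar (s)")
  nt <- dim(data)[4]
  if (is.null(run_id)) {
    if (is.null(run_lengths)) run_lengths <- nt
    if (sum(run_lengths) != nt)
      stop("run_lengths must sum to the number of volumes")
    run_id <- rep(seq_along(run_lengths) - 1L, run_lengths)
  }
  run_id <- as.integer(run_id)
  if (length(run_id) != nt) stop("run_id must have one entry per volume")
  if (any(diff(run_id) < 0)) stop("run_id must be non-decreasing along time")
  acq_time <- stats::ave(rep(0, nt), run_id,
                         FUN = function(x) (seq_along(x) - 1)) *
    intervolume_time
  structure(list(
    data = array(as.double(data), dim(data)),
    voxel_size = as.double(voxel_size),
    intervolume_time = as.double(intervolume_time),
    phase_axis = match.arg(phase_axis, c("x", "y", "z")),
    run_id = run_id,
    acq_time = as.double(acq_time)
  ), class = "volume_series")
}

#' @export
print.volume_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<volume_series> %dx%dx%d voxels x %d volumes, %d run(s)\n",
    d[1], d[2], d[3], d[4], length(unique(x$run_id))))
  cat(sprintf("  voxel %.3g x %.3g x %.3g mm, TR %.3g s, phase axis %s\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$intervolume_time, x$phase_axis))
  invisible(x)
}

#' Number of volumes in a series
#' @param series a `volume_series`
#' @export
n_volumes <- function(series) dim(series$data)[4]

#' Volumes per run of a series
#' @param series a `volume_series`
#' @return named integer vector, one entry per run in order
#' @export
run_lengths <- function(series) {
  tab <- table(series$run_id)
  stats::setNames(as.integer(tab), names(tab))
}

# Replace the data array, keeping (or subsetting) metadata
replace_data <- function(series, data, keep = NULL) {
  out <- series
  out$data <- data
  if (!is.null(keep)) {
    out$run_id <- series$run_id[keep]
    out$acq_time <- series$acq_time[keep]
  }
  stopifnot(dim(data)[4] == length(out$run_id))
  out
}

#' Read a 4D NIfTI series with its JSON sidecar
#'
#' The sidecar (``<path minus extension>.json`` unless given) must provide
#' `intervolume_time` (s) and `phase_axis`, and may provide `runs` as a vector
#' of per-run volume counts. Several files may be given, each holding one or
#' more runs of the same session; they are concatenated in order.
#'
#' @param path one or more NIfTI-1 file paths (.nii or .nii.gz)
#' @param sidecar optional explicit sidecar path(s)
#' @return a [volume_series]
#' @export
read_volume_series <- function(path, sidecar = NULL) {
  if (is.null(sidecar)) sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (length(sidecar) != length(path))
    stop("need one sidecar per NIfTI file")
  parts <- lapply(seq_along(path), function(i) {
    img <- RNifti::readNifti(path[i])
    if (length(dim(img)) != 4L)
      stop("expected a 4-dimensional NIfTI file: ", path[i])
    vox <- attr(img, "pixdim")[1:3]
    if (any(vox <= 0)) stop("non-positive voxel size in ", path[i])
    if (!file.exists(sidecar[i]))
      stop("missing sidecar with timing metadata: ", sidecar[i])
    meta <- jsonlite::read_json(sidecar[i], simplifyVector = TRUE)
    if (is.null(meta$intervolume_time))
      stop("sidecar lacks intervolume_time: ", sidecar[i])
    if (is.null(meta$phase_axis))
      stop("sidecar lacks phase_axis: ", sidecar[i])
    runs <- meta$runs %||% dim(img)[4]
    list(data = array(as.double(img), dim(img)), vox = vox,
         tr = meta$intervolume_time, phase = meta$phase_axis, runs = runs)
  })
  tr <- parts[[1]]$tr
  phase <- parts[[1]]$phase
  vox <- parts[[1]]$vox
  for (p in parts) {
    if (!isTRUE(all.equal(p$tr, tr)) || p$phase != phase)
      stop("inconsistent timing metadata across files")
    if (!isTRUE(all.equal(p$vox, vox, tolerance = 1e-5)))
      stop("inconsistent voxel geometry across files")
  }
  data <- do.call(function(...) abind4(list(...)), lapply(parts, `[[`, "data"))
  runs <- unlist(lapply(parts, `[[`, "runs"))
  volume_series(data, vox, tr, phase, run_lengths = runs)
}

# bind 4D arrays along the 4th dimension
abind4 <- function(lst) {
  d <- dim(lst[[1]])[1:3]
  nt <- sum(vapply(lst, function(a) dim(a)[4], 1L))
  out <- array(0, c(d, nt))
  at <- 0L
  for (a in lst) {
    out[, , , at + seq_len(dim(a)[4])] <- a
    at <- at + dim(a)[4]
  }
  out
}

#' Write a volume series as NIfTI plus JSON sidecar
#' @param series a [volume_series]
#' @param path output .nii/.nii.gz path; the sidecar is written next to it
#' @return `path`, invisibly
#' @export
write_volume_series <- function(series, path) {
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$voxel_size, series$intervolume_time)
  RNifti::writeNifti(img, path)
  meta <- list(intervolume_time = series$intervolume_time,
               phase_axis = series$phase_axis,
               runs = as.integer(unname(run_lengths(series))))
  jsonlite::write_json(meta, sub("\\.nii(\\.gz)?$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a 3D mask or image as NIfTI
#' @param vol 3D array (logical masks are written as uint8)
#' @param voxel_size length-3 mm voxel size
#' @param path output path
#' @export
write_volume3d <- function(vol, voxel_size, path) {
  dtype <- if (is.logical(vol)) "uint8" else "auto"
  img <- RNifti::asNifti(array(if (is.logical(vol)) as.integer(vol) else vol,
                               dim(vol)))
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}
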