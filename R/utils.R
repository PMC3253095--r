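# Shared numeric helpers: Gaussian smoothing, FWHM conversion, array shifts,
# binary morphology built on the 6-neighbourhood.

#' Convert a full width at half maximum to a Gaussian sigma
#' @param fwhm full width at half maximum (any length unit)
#' @return sigma in the same unit
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# 1D Gaussian kernel, truncated at 3 sigma, unnormalised
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  exp(-x^2 / (2 * sigma^2))
}

# Convolve a 3D array along one axis with a renormalised truncated Gaussian.
# Rows of the convolution matrix are renormalised so a constant image stays
# constant and interior intensity is conserved.
smooth_axis <- function(vol, axis, sigma) {
  if (sigma <= 0) return(vol)
  d <- dim(vol)
  n <- d[axis]
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - r):min(n, i + r)
    w <- k[j - i + r + 1L]
    K[i, j] <- w / sum(w)
  }
  perm <- c(axis, setdiff(1:3, axis))
  v <- aperm(vol, perm)
  dv <- dim(v)
  v <- K %*% matrix(v, n)
  dim(v) <- dv
  aperm(v, order(perm))
}

#' Smooth a 3D volume with an anisotropic Gaussian
#' @param vol 3D array
#' @param sigma_vox per-axis sigma in voxels (length 3, recycled)
#' @return smoothed array of the same dimension
#' @export
smooth3d <- function(vol, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  for (a in 1:3) vol <- smooth_axis(vol, a, sigma_vox[a])
  vol
}

# Integer circular shift of a 3D array along one axis
circshift3d <- function(vol, axis, by) {
  n <- dim(vol)[axis]
  by <- ((by %% n) + n) %% n
  if (by == 0) return(vol)
  idx <- c((n - by + 1L):n, 1L:(n - by))
  switch(axis, vol[idx, , , drop = FALSE], vol[, idx, , drop = FALSE],
         vol[, , idx, drop = FALSE])
}

# Non-circular integer shift padding with FALSE/0
shift_pad <- function(vol, axis, by, fill = FALSE) {
  out <- array(fill, dim(vol))
  n <- dim(vol)[axis]
  if (abs(by) >= n) return(out)
  src <- if (by >= 0) 1:(n - by) else (1 - by):n
  dst <- if (by >= 0) (1 + by):n else 1:(n + by)
  ix <- function(a, i) switch(a, vol[i, , , drop = FALSE],
                              vol[, i, , drop = FALSE],
                              vol[, , i, drop = FALSE])
  if (axis == 1) out[dst, , ] <- ix(1, src)
  if (axis == 2) out[, dst, ] <- ix(2, src)
  if (axis == 3) out[, , dst] <- ix(3, src)
  out
}

# 6-neighbourhood dilation/erosion of a logical 3D array
dilate6 <- function(m) {
  out <- m
  for (a in 1:3) out <- out | shift_pad(m, a, 1L) | shift_pad(m, a, -1L)
  out
}
erode6 <- function(m) !dilate6(!m)

# Morphological closing with the 1-voxel 6-ball
close6 <- function(m) erode6(dilate6(m))

# Fill interior holes: background components not touching the array border.
# Faces along singleton axes are ignored so per-slice (nx x ny x 1) filling
# works in-plane.
fill_holes3d <- function(m) {
  lab <- c_label3d(!m, dim(m))
  d <- dim(m)
  border <- integer(0)
  if (d[1] > 1) border <- c(border, lab[c(1, d[1]), , ])
  if (d[2] > 1) border <- c(border, lab[, c(1, d[2]), ])
  if (d[3] > 1) border <- c(border, lab[, , c(1, d[3])])
  border <- unique(border[border > 0])
  m | (lab > 0 & !(lab %in% border))
}

# Largest / seed-containing connected component of a logical array
select_component <- function(m, center = NULL) {
  lab <- c_label3d(m, dim(m))
  if (max(lab) == 0L) return(m & FALSE)
  if (!is.null(center)) {
    ci <- round(center)
    target <- lab[ci[1], ci[2], ci[3]]
    if (target == 0L) {
      # nearest labelled voxel to the seed
      idx <- which(lab > 0L)
      co <- arrayInd(idx, dim(m))
      d2 <- (co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 +
        (co[, 3] - center[3])^2
      target <- lab[idx[which.min(d2)]]
    }
  } else {
    target <- which.max(tabulate(lab[lab > 0L]))
  }
  lab == target
}

# axis label <-> number
axis_num <- function(axis) {
  if (is.numeric(axis)) return(as.integer(axis))
  match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
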