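# R-level wrappers around the compiled resampler. The sampling map takes an
# output-grid position p (centre-of-volume mm coordinates) to the input-space
# position q = A p + b at which the source volume is interpolated.

#' Resample a 3D volume through an affine sampling map
#'
#' @param vol 3D array
#' @param A 3x3 linear part of the sampling map (output mm -> input mm)
#' @param b length-3 offset of the sampling map (mm)
#' @param voxel_size length-3 voxel size in mm
#' @param order interpolation order: 1 (trilinear) or 3 (cubic spline,
#'   Catmull-Rom)
#' @param background value for points outside the field of view
#' @return resampled 3D array on the same grid
#' @export
resample_affine <- function(vol, A, b, voxel_size, order = 3L,
                            background = 0) {
  stopifnot(length(dim(vol)) == 3L, order %in% c(1L, 3L))
  c_resample_affine(as.double(vol), dim(vol), A, as.double(b),
                    as.double(voxel_size), as.integer(order), background)
}

# Resample through the *correction* map of an estimated affine: the output
# (reference-space) image samples the moving image at M^-1 p.
resample_by_params <- function(vol, params, voxel_size, order = 3L) {
  m <- inv_map(affine_matrix(params))
  resample_affine(vol, m$A, m$b, voxel_size, order = order)
}

# Translate a volume: output(x) = vol(x + shift_mm) (sampling map offset)
translate_volume <- function(vol, shift_mm, voxel_size, order = 3L) {
  resample_affine(vol, diag(3), shift_mm, voxel_size, order = order)
}

# MSD cost between ref and vol pulled through the sampling map, scored over
# a fixed interior margin of the output grid
msd_cost <- function(vol, ref, A, b, voxel_size, order = 1L,
                     margin = c(2L, 2L, 1L)) {
  c_msd_affine(as.double(vol), as.double(ref), dim(vol), A, as.double(b),
               as.double(voxel_size), 0, as.integer(order),
               as.integer(margin))
}
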