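# Spatial transform parameterisation. A 12-parameter affine is
# (tx, ty, tz, rx, ry, rz, sx, sy, sz, hxy, hxz, hyz): translations in mm,
# intrinsic rotations about x then y then z in radians, axis scales, and
# unit upper-triangular shears. The homogeneous matrix is T R Z S acting in
# centre-of-volume mm coordinates, mapping moving-image coordinates to
# reference coordinates.

AFFINE_NAMES <- c("tx", "ty", "tz", "rx", "ry", "rz",
                  "sx", "sy", "sz", "hxy", "hxz", "hyz")

#' Identity affine parameter vector
#' @return named length-12 numeric vector
#' @export
identity_affine <- function() {
  stats::setNames(c(0, 0, 0, 0, 0, 0, 1, 1, 1, 0, 0, 0), AFFINE_NAMES)
}

#' Build the 4x4 homogeneous matrix of a 12-parameter affine
#' @param p named or positional length-12 parameter vector
#'   (translations mm, rotations rad, scales, shears); matrix = T R Z S
#' @return 4x4 matrix mapping moving to reference mm coordinates
#' @export
affine_matrix <- function(p) {
  p <- as.numeric(p)
  stopifnot(length(p) == 12L)
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Z <- diag(p[7:9])
  S <- rbind(c(1, p[10], p[11]), c(0, 1, p[12]), c(0, 0, 1))
  A <- Rx %*% Ry %*% Rz %*% Z %*% S
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- p[1:3]
  M
}

# inverse map split into linear part + offset for the resampler
inv_map <- function(M) {
  Mi <- solve(M)
  list(A = Mi[1:3, 1:3], b = Mi[1:3, 4])
}

#' Bundle per-volume shifts and per-trial affines into a transform set
#'
#' @param shift1d per-volume shift in mm along the phase axis (0 at each
#'   trial's first volume)
#' @param affines named list (by trial id) of 12-parameter vectors
#' @param trial_of per-volume trial id
#' @param phase_axis the shift axis label
#' @param reference identifier of the registration reference
#' @return an object of class `transform_set`
#' @export
transform_set <- function(shift1d, affines, trial_of, phase_axis,
                          reference = "mean of first accepted trial") {
  stopifnot(length(shift1d) == length(trial_of))
  structure(list(shift1d = as.numeric(shift1d), affines = affines,
                 trial_of = as.integer(trial_of), phase_axis = phase_axis,
                 reference = reference),
            class = "transform_set")
}

#' Write a transform set to JSON
#' @param tf a [transform_set]
#' @param path output path
#' @export
write_transforms <- function(tf, path) {
  obj <- list(reference = tf$reference, phase_axis = tf$phase_axis,
              shift1d = tf$shift1d, trial_of = tf$trial_of,
              affines = lapply(tf$affines, function(p)
                as.list(stats::setNames(as.numeric(p), AFFINE_NAMES))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transform set from JSON
#' @param path file path written by [write_transforms()]
#' @return a [transform_set]
#' @export
read_transforms <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  affines <- lapply(obj$affines, function(a)
    stats::setNames(as.numeric(unlist(a)[AFFINE_NAMES]), AFFINE_NAMES))
  transform_set(obj$shift1d, affines, obj$trial_of, obj$phase_axis,
                obj$reference)
}
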