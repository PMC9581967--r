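#' Particle poses (ZYZ Euler angles plus 2D shift)
#'
#' A pose links the 3D reference frame to a particle image: the reference
#' volume is rotated by the intrinsic ZYZ rotation
#' `R = Rz(psi) %*% Ry(tilt) %*% Rz(rot)` (a point at position `p` in the
#' reference appears at `R %*% p` in the rotated volume), projected along +z,
#' and the projected image content is then translated by `(shift_x, shift_y)`
#' Angstrom. Angles are degrees.
#'
#' Worked example: `pose(90, 0, 0)` rotates the reference by 90 degrees about
#' z, so the reference +x axis maps to +y; `pose(0, 90, 0)` maps +z to +x
#' (tilt about y); composing `pose(90, 90, 0)` gives
#' `Ry(90) %*% Rz(90)`, which maps +x to +y to itself? No: +x -> (Rz) +y ->
#' (Ry) +y. See `pose_matrix()` for the matrices.
#'
#' @param rot,tilt,psi Euler angles (degrees).
#' @param shift_x,shift_y image translation (Angstrom).
#' @return `pose()` returns a one-row data.frame with columns
#'   `rot, tilt, psi, shift_x, shift_y`; `poses()` binds several.
#' @export
pose <- function(rot = 0, tilt = 0, psi = 0, shift_x = 0, shift_y = 0) {
  v <- c(rot, tilt, psi, shift_x, shift_y)
  if (!all(is.finite(v))) stop("pose: non-finite pose parameters")
  data.frame(rot = rot, tilt = tilt, psi = psi,
             shift_x = shift_x, shift_y = shift_y)
}

#' @rdname pose
#' @param ... poses (one-row data.frames) or data.frames of poses.
#' @export
poses <- function(...) do.call(rbind, list(...))

deg2rad <- function(d) d * pi / 180

rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

rot_x <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' Rotation matrix of a pose
#'
#' `R = Rz(psi) %*% Ry(tilt) %*% Rz(rot)`; orthonormal with det +1.
#'
#' @param rot,tilt,psi Euler angles in degrees, or a one-row pose data.frame
#'   as first argument.
#' @return 3x3 rotation matrix.
#' @export
pose_matrix <- function(rot, tilt = NULL, psi = NULL) {
  if (is.data.frame(rot)) {
    p <- rot
    return(rot_z(p$psi[1]) %*% rot_y(p$tilt[1]) %*% rot_z(p$rot[1]))
  }
  rot_z(psi) %*% rot_y(tilt) %*% rot_z(rot)
}

#' Euler angles from a rotation matrix
#'
#' Inverse of [pose_matrix()]; returns `c(rot, tilt, psi)` in degrees with
#' `tilt` in `[0, 180]`. At the gimbal degeneracy (`tilt` = 0 or 180) `rot`
#' is set to 0 and the full in-plane angle assigned to `psi`.
#'
#' @param R 3x3 rotation matrix.
#' @export
matrix_to_euler <- function(R) {
  tilt <- acos(max(-1, min(1, R[3, 3])))
  if (abs(sin(tilt)) < 1e-10) {
    # Rz(psi +/- rot) only
    ang <- atan2(R[2, 1], R[1, 1]) * 180 / pi
    if (R[3, 3] > 0) return(c(rot = 0, tilt = 0, psi = ang))
    return(c(rot = 0, tilt = 180, psi = -ang))
  }
  rot <- atan2(R[3, 2], -R[3, 1])
  psi <- atan2(R[2, 3], R[1, 3])
  c(rot = rot * 180 / pi, tilt = tilt * 180 / pi, psi = psi * 180 / pi)
}

#' Geodesic angle between two orientations
#'
#' The rotation angle (degrees) of `Ra %*% t(Rb)` — the natural metric on
#' SO(3) for alignment-error measurements.
#'
#' @param a,b one-row pose data.frames or 3x3 rotation matrices.
#' @export
angular_distance <- function(a, b) {
  Ra <- if (is.matrix(a)) a else pose_matrix(a)
  Rb <- if (is.matrix(b)) b else pose_matrix(b)
  tr <- sum(diag(Ra %*% t(Rb)))
  acos(max(-1, min(1, (tr - 1) / 2))) * 180 / pi
}

#' Alignment error modulo helical symmetry
#'
#' A helical segment aligned to a symmetry-equivalent lattice position is not
#' an alignment error. Returns the minimum geodesic angle between `a` and
#' `b` composed with `Rz(k * twist)` over `k in -k_max .. k_max`. With
#' `c2 = TRUE` the dimer's two-fold axis (along the radial x direction of the
#' unit frame) is also taken as an invariance of the filament, adding the
#' branch `Rz(k * twist) %*% Rx(180)`.
#'
#' @param a,b poses (one-row data.frames).
#' @param twist helical twist (degrees per unit).
#' @param k_max number of symmetry offsets to try either side.
#' @param c2 include the C2 (dimer two-fold) branch.
#' @export
angular_distance_helical <- function(a, b, twist, k_max = 4, c2 = FALSE) {
  Ra <- pose_matrix(a)
  Rb <- pose_matrix(b)
  d <- min(vapply(-k_max:k_max, function(k) {
    angular_distance(Ra, Rb %*% rot_z(k * twist))
  }, numeric(1)))
  if (c2) {
    d2 <- min(vapply(-k_max:k_max, function(k) {
      angular_distance(Ra, Rb %*% rot_z(k * twist) %*% rot_x(180))
    }, numeric(1)))
    d <- min(d, d2)
  }
  d
}

# Validate a pose data.frame.
check_poses <- function(p, n = NULL) {
  need <- c("rot", "tilt", "psi", "shift_x", "shift_y")
  if (!all(need %in% names(p)))
    stop("poses must have columns ", paste(need, collapse = ", "))
  if (!all(vapply(p[need], function(col) all(is.finite(col)), logical(1))))
    stop("poses contain non-finite values")
  if (!is.null(n) && nrow(p) != n)
    stop("expected ", n, " poses, got ", nrow(p))
  invisible(p)
}
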