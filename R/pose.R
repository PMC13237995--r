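#' Six degree-of-freedom rigid pose
#'
#' A rigid transform decomposed into three translations and three rotations
#' in a joint-coordinate-system style convention: flexion--extension (FE)
#' about the medial--lateral axis, abduction--adduction (AA, positive =
#' varus) about the anterior--posterior axis, and internal--external (IE)
#' rotation about the proximal--distal axis. Translations are medial--lateral
#' (ML), anterior--posterior (AP) and proximal--distal (PD), in mm; rotations
#' in degrees.
#'
#' The working frame has +x medial, +y anterior, +z proximal.
#'
#' @param AP_mm,PD_mm,ML_mm translations in mm.
#' @param FE_deg,AA_deg,IE_deg rotations in degrees.
#' @return an object of class `rigid_pose`.
#' @export
rigid_pose <- function(AP_mm = 0, PD_mm = 0, ML_mm = 0,
                       FE_deg = 0, AA_deg = 0, IE_deg = 0) {
  p <- list(AP_mm = AP_mm, PD_mm = PD_mm, ML_mm = ML_mm,
            FE_deg = FE_deg, AA_deg = AA_deg, IE_deg = IE_deg)
  stopifnot(all(vapply(p, function(v) is.numeric(v) && length(v) == 1 && is.finite(v), TRUE)))
  structure(p, class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat(sprintf("rigid_pose: AP %+.3f PD %+.3f ML %+.3f mm | FE %+.3f AA %+.3f IE %+.3f deg\n",
              x$AP_mm, x$PD_mm, x$ML_mm, x$FE_deg, x$AA_deg, x$IE_deg))
  invisible(x)
}

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

rot_x <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3, 3, byrow = TRUE)
}
rot_y <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3, 3, byrow = TRUE)
}
rot_z <- function(a) {
  c <- cos(a); s <- sin(a)
  matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

#' Convert a rigid pose to a 4x4 homogeneous transform
#'
#' Rotations are applied in the fixed order FE -> AA -> IE about the
#' reference (tibial) frame axes: the rotation matrix is
#' `Rz(IE) %*% Ry(AA) %*% Rx(FE)` with x the medial--lateral axis, y the
#' anterior--posterior axis and z the proximal--distal axis. A constant AA
#' therefore tilts the moving body about the fixed coronal (AP) axis at
#' every flexion angle, so a varus offset means the same joint-space
#' asymmetry throughout the arc. The translation column is (ML, AP, PD).
#'
#' @param pose a [rigid_pose()].
#' @return a 4x4 numeric matrix.
#' @seealso [matrix_to_pose()] for the inverse.
#' @export
pose_to_matrix <- function(pose) {
  stopifnot(inherits(pose, "rigid_pose"))
  R <- rot_z(deg2rad(pose$IE_deg)) %*%
       rot_y(deg2rad(pose$AA_deg)) %*%
       rot_x(deg2rad(pose$FE_deg))
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- c(pose$ML_mm, pose$AP_mm, pose$PD_mm)
  m
}

#' Recover a rigid pose from a 4x4 homogeneous transform
#'
#' Inverse of [pose_to_matrix()]; valid away from the AA = +/-90 deg gimbal
#' singularity, far outside the anatomical range used here.
#'
#' @param m a 4x4 homogeneous rigid transform.
#' @return a [rigid_pose()].
#' @export
matrix_to_pose <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == c(4, 4)))
  R <- m[1:3, 1:3]
  # R = Rz(c) Ry(b) Rx(a): R[3,1] = -sin b
  b <- asin(max(-1, min(1, -R[3, 1])))
  a <- atan2(R[3, 2], R[3, 3])
  cc <- atan2(R[2, 1], R[1, 1])
  rigid_pose(AP_mm = m[2, 4], PD_mm = m[3, 4], ML_mm = m[1, 4],
             FE_deg = rad2deg(a), AA_deg = rad2deg(b), IE_deg = rad2deg(cc))
}

#' Apply a homogeneous transform to 3D points
#'
#' @param m 4x4 transform.
#' @param pts n x 3 matrix of points (or a length-3 vector).
#' @return n x 3 matrix of transformed points.
#' @export
transform_points <- function(m, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  sweep(pts %*% t(m[1:3, 1:3]), 2, m[1:3, 4], "+")
}

pose_as_vector <- function(pose) {
  c(AP_mm = pose$AP_mm, PD_mm = pose$PD_mm, ML_mm = pose$ML_mm,
    FE_deg = pose$FE_deg, AA_deg = pose$AA_deg, IE_deg = pose$IE_deg)
}

vector_as_pose <- function(v) {
  rigid_pose(AP_mm = v[["AP_mm"]], PD_mm = v[["PD_mm"]], ML_mm = v[["ML_mm"]],
             FE_deg = v[["FE_deg"]], AA_deg = v[["AA_deg"]], IE_deg = v[["IE_deg"]])
}
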