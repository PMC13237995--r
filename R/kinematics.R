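#' Flexion pose series
#'
#' Ordered sequence of (flexion angle, femur-relative-to-tibia rigid pose)
#' frames for one subject, e.g. a weight-bearing lunge from 0 to 100 degrees.
#'
#' @param flexion_deg numeric vector of flexion angles.
#' @param poses list of [rigid_pose()] of the same length.
#' @param subject_id subject label.
#' @return an object of class `flexion_series`.
#' @export
flexion_series <- function(flexion_deg, poses, subject_id = "subject") {
  stopifnot(length(flexion_deg) == length(poses), length(poses) >= 2,
            all(is.finite(flexion_deg)))
  if (anyDuplicated(flexion_deg))
    stop("duplicate flexion angles in series")
  o <- order(flexion_deg)
  structure(list(flexion_deg = flexion_deg[o], poses = poses[o],
                 subject_id = subject_id),
            class = "flexion_series")
}

#' @export
print.flexion_series <- function(x, ...) {
  cat(sprintf("flexion_series '%s': %d frames, %.1f to %.1f deg\n",
              x$subject_id, length(x$flexion_deg),
              min(x$flexion_deg), max(x$flexion_deg)))
  invisible(x)
}

series_matrix <- function(series) {
  m <- t(vapply(series$poses, pose_as_vector, numeric(6)))
  cbind(flexion_deg = series$flexion_deg, m)
}

kin_columns <- c("flexion_deg", "AP_mm", "PD_mm", "ML_mm",
                 "FE_deg", "AA_deg", "IE_deg")

#' Write a flexion series to the canonical CSV layout
#'
#' Columns: flexion_deg, AP_mm, PD_mm, ML_mm, FE_deg, AA_deg, IE_deg.
#' @param series a [flexion_series()].
#' @param path output CSV path.
#' @export
write_series <- function(series, path) {
  utils::write.csv(as.data.frame(series_matrix(series)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Load a flexion series from CSV
#'
#' Expects the 7 canonical columns (see [write_series()]); rows may be in
#' any order and are sorted by flexion angle. Rows with missing or
#' non-finite values, and duplicated flexion angles, are rejected.
#'
#' @param path CSV file path.
#' @param subject_id subject label to attach.
#' @return a [flexion_series()].
#' @export
load_series <- function(path, subject_id = basename(path)) {
  df <- utils::read.csv(path)
  if (nrow(df) == 0) stop("empty kinematics file: ", path)
  missing_cols <- setdiff(kin_columns, names(df))
  if (length(missing_cols) > 0)
    stop("kinematics CSV missing columns: ", paste(missing_cols, collapse = ", "))
  bad <- which(!stats::complete.cases(df[kin_columns]) |
                 rowSums(!sapply(df[kin_columns], is.finite)) > 0)
  if (length(bad) > 0)
    stop("malformed kinematics row(s): ", paste(bad, collapse = ", "))
  poses <- lapply(seq_len(nrow(df)), function(i)
    rigid_pose(AP_mm = df$AP_mm[i], PD_mm = df$PD_mm[i], ML_mm = df$ML_mm[i],
               FE_deg = df$FE_deg[i], AA_deg = df$AA_deg[i],
               IE_deg = df$IE_deg[i]))
  flexion_series(df$flexion_deg, poses, subject_id)
}

#' Standing alignment parameters
#'
#' @param hka_deg hip-knee-ankle mechanical-axis deviation in degrees,
#'   positive = varus; must satisfy |hka| < 30.
#' @param posterior_slope_deg native tibial posterior slope in degrees.
#' @return an object of class `standing_alignment`.
#' @export
standing_alignment <- function(hka_deg = 0, posterior_slope_deg = 0) {
  stopifnot(is.finite(hka_deg), abs(hka_deg) < 30,
            is.finite(posterior_slope_deg))
  structure(list(hka_deg = hka_deg,
                 posterior_slope_deg = posterior_slope_deg),
            class = "standing_alignment")
}

#' Varus-valgus correction of flexion kinematics
#'
#' Shifts the abduction--adduction (AA) rotation of every frame by the
#' negative of the standing HKA angle, removing the standing coronal
#' deformity from the recorded motion. All other degrees of freedom are
#' left untouched, so applying the correction with `hka` and then with
#' `-hka` is the identity.
#'
#' @param series a [flexion_series()].
#' @param alignment a [standing_alignment()].
#' @return the corrected [flexion_series()].
#' @export
correct_varus_valgus <- function(series, alignment) {
  series$poses <- lapply(series$poses, function(p) {
    p$AA_deg <- p$AA_deg - alignment$hka_deg
    p
  })
  series
}

#' Resample a flexion series at given flexion angles
#'
#' Per-DOF linear interpolation between bracketing frames; requested angles
#' must lie within the observed flexion range (no extrapolation).
#'
#' @param series a [flexion_series()].
#' @param angles flexion angles (deg) to sample at.
#' @return a [flexion_series()] on the requested grid.
#' @export
resample_series <- function(series, angles) {
  rng <- range(series$flexion_deg)
  if (any(angles < rng[1] - 1e-9 | angles > rng[2] + 1e-9))
    stop(sprintf("requested angles outside observed range [%.1f, %.1f]",
                 rng[1], rng[2]))
  m <- series_matrix(series)
  out <- sapply(2:7, function(j)
    stats::approx(m[, 1], m[, j], xout = angles, rule = 1)$y)
  out <- matrix(out, nrow = length(angles))
  colnames(out) <- kin_columns[-1]
  poses <- lapply(seq_along(angles), function(i) vector_as_pose(out[i, ]))
  flexion_series(angles, poses, series$subject_id)
}
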