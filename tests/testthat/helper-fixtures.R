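# Shared fixtures, built in code. The heavier cohort fixture is memoised so
# several test files can share one computation.

.fixture_env <- new.env(parent = emptyenv())

fixture_knee <- function(varus = 3, seed = 1) {
  key <- sprintf("knee_%s_%s", varus, seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_knee(
      subject_spec(kinematic_varus_amplitude_deg = varus, seed = seed))
  .fixture_env[[key]]
}

# square planar contour on the z = 0 plane, side `side`, lower-left at
# (x0, y0)
square_contour <- function(x0 = 0, y0 = 0, side = 10) {
  planar_contour(plane3d(c(0, 0, 0), c(0, 0, 1)),
                 list(cbind(c(0, side, side, 0) + x0,
                            c(0, 0, side, side) + y0)))
}

circle_contour <- function(r, n = 128, center = c(0, 0)) {
  planar_contour(plane3d(c(0, 0, 0), c(0, 0, 1)),
                 list(sweep(ellipse_polygon(r, r, n), 2, center, "+")))
}

# independent ray-parity point-in-mesh used as a cross-section area oracle;
# deliberately separate from the package's cut/chaining code path
oracle_points_in_mesh <- function(pts, mesh, dir = c(0.1, 0.2, 1)) {
  dir <- dir / sqrt(sum(dir^2))
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  crossings <- integer(nrow(pts))
  for (k in seq_len(nrow(a))) {
    h <- c(dir[2] * e2[k, 3] - dir[3] * e2[k, 2],
           dir[3] * e2[k, 1] - dir[1] * e2[k, 3],
           dir[1] * e2[k, 2] - dir[2] * e2[k, 1])
    det <- sum(e1[k, ] * h)
    if (abs(det) < 1e-12) next
    s <- sweep(pts, 2, a[k, ], "-")
    u <- (s %*% h) / det
    q <- cbind(s[, 2] * e1[k, 3] - s[, 3] * e1[k, 2],
               s[, 3] * e1[k, 1] - s[, 1] * e1[k, 3],
               s[, 1] * e1[k, 2] - s[, 2] * e1[k, 1])
    vv <- (q %*% dir) / det
    tt <- (q %*% e2[k, ]) / det
    hit <- u >= 0 & vv >= 0 & (u + vv) <= 1 & tt > 0
    crossings <- crossings + hit
  }
  crossings %% 2 == 1
}

# The acceptance-style cohort: 8 knees, injected kinematic varus uniform in
# [0.7, 7.0] deg, full tibial + MB + GB_full planning. Memoised.
acceptance_cohort <- function() {
  if (!is.null(.fixture_env$cohort)) return(.fixture_env$cohort)
  cohort <- generate_cohort(8, subject_spec(), c(0.7, 7.0), seed = 42L)
  res <- lapply(cohort, function(knee) {
    kin <- correct_varus_valgus(knee$kinematics, knee$alignment)
    tp <- optimize_tibial_placement(
      knee$tibia_mesh, knee$tray_catalog, knee$landmarks, knee$alignment,
      tibial_constraints(),
      sa_config(seed = split_seed(42L, knee$spec$subject_id, "sa")))
    mb <- build_mb_plan(knee$femur_mesh, knee$landmarks,
                        knee$femoral_component_mesh)
    mb_prof <- gap_profile(knee$femoral_component_mesh, mb$component_pose,
                           kin, tp$resection_plane, "MB")
    gb <- optimize_gb(mb, kin, tp$resection_plane,
                      knee$femoral_component_mesh,
                      gb_config(strategy = "GB_full",
                                seed = split_seed(42L, knee$spec$subject_id,
                                                  "gb")))
    list(subject_id = knee$spec$subject_id,
         injected_varus = knee$spec$kinematic_varus_amplitude_deg,
         tibial = tp, mb_profile = mb_prof, gb = gb)
  })
  .fixture_env$cohort <- res
  res
}
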