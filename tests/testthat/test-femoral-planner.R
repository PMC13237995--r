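mb_fixture <- function(knee = fixture_knee()) {
  list(knee = knee,
       kin = correct_varus_valgus(knee$kinematics, knee$alignment),
       plane = build_resection_plane(knee$tibia_mesh, knee$landmarks,
                                     knee$alignment),
       mb = build_mb_plan(knee$femur_mesh, knee$landmarks,
                          knee$femoral_component_mesh))
}

test_that("the MB plan restores the joint line with thickness-matched cuts", {
  knee <- fixture_knee()
  mb <- build_mb_plan(knee$femur_mesh, knee$landmarks,
                      knee$femoral_component_mesh, 9, 9)

  # distal plane: 9 mm above the most distal condyle point, normal along
  # the mechanical axis
  most_distal <- min(knee$femur_mesh$vertices[, 3])
  expect_equal(sum(mb$distal_plane$point * mb$distal_plane$normal),
               most_distal + 9, tolerance = 1e-9)
  expect_equal(mb$distal_plane$normal, c(0, 0, 1), tolerance = 1e-9)

  # posterior plane parallel to the TEA
  tea <- knee$landmarks$medial_epicondyle - knee$landmarks$lateral_epicondyle
  expect_lt(abs(sum(mb$posterior_plane$normal * tea / sqrt(sum(tea^2)))),
            1e-9)

  # zero-offset component shell seats at the identity pose
  expect_lt(max(abs(unlist(mb$component_pose))), 1e-6)

  # zero thickness: planes tangent to the condyles
  mb0 <- build_mb_plan(knee$femur_mesh, knee$landmarks,
                       knee$femoral_component_mesh, 0, 0)
  expect_equal(sum(mb0$distal_plane$point * mb0$distal_plane$normal),
               most_distal, tolerance = 1e-9)

  expect_error(build_mb_plan(knee$femur_mesh, list(),
                             knee$femoral_component_mesh), "landmark")
})

test_that("rotating the TEA rotates the posterior resection with it", {
  knee <- fixture_knee()
  lm <- knee$landmarks
  rot <- pose_to_matrix(rigid_pose(IE_deg = 3))
  lm$medial_epicondyle <- drop(transform_points(rot, lm$medial_epicondyle))
  lm$lateral_epicondyle <- drop(transform_points(rot, lm$lateral_epicondyle))
  mb <- build_mb_plan(knee$femur_mesh, lm, knee$femoral_component_mesh)
  ref <- build_mb_plan(knee$femur_mesh, knee$landmarks,
                       knee$femoral_component_mesh)
  ang <- acos(sum(mb$posterior_plane$normal * ref$posterior_plane$normal))
  expect_equal(ang * 180 / pi, 3, tolerance = 1e-6)
})

test_that("gaps are symmetric for balanced frames and shift with the pose", {
  f <- mb_fixture()
  zero_frame <- rigid_pose(PD_mm = 22)
  g <- compute_gaps(f$knee$femoral_component_mesh, rigid_pose(), zero_frame,
                    f$plane)
  expect_equal(g[["d_m_mm"]], g[["d_l_mm"]], tolerance = 1e-9)

  # frame with 3 deg varus, 46 mm spacing: |d_l - d_m| ~ 2.4 mm
  varus_frame <- rigid_pose(PD_mm = 22 + 23 * sin(3 * pi / 180), AA_deg = 3)
  gv <- compute_gaps(f$knee$femoral_component_mesh, rigid_pose(),
                     varus_frame, f$plane)
  expect_equal(abs(gv[["d_l_mm"]] - gv[["d_m_mm"]]), 46 * sin(3 * pi / 180),
               tolerance = 0.2)

  # translating the component along the plane normal moves both gaps equally
  shift <- rigid_pose(PD_mm = 2 / f$plane$normal[3], AP_mm = 0)
  gs <- compute_gaps(f$knee$femoral_component_mesh, shift, varus_frame,
                     f$plane)
  expect_equal(unname(gs - gv), c(2, 2), tolerance = 0.01)

  one_sided <- tri_mesh(matrix(c(1, 0, 0, 2, 0, 0, 1, 1, 0), 3, 3,
                               byrow = TRUE), matrix(1:3, 1))
  expect_error(compute_gaps(one_sided, rigid_pose(), zero_frame, f$plane),
               "condyle")
})

test_that("the gap-difference loss evaluates the mean absolute asymmetry", {
  prof <- function(dm, dl) {
    df <- data.frame(flexion_deg = seq_along(dm) * 10, d_m_mm = dm,
                     d_l_mm = dl)
    class(df) <- c("gap_profile", "data.frame")
    df
  }
  expect_equal(gap_loss(prof(c(2, 2), c(2, 2))), 0)
  expect_equal(gap_loss(prof(c(3, 2), c(1, 4))), 2)
  expect_equal(gap_loss(prof(-3, 1)), 2)   # magnitudes, not signed values
  expect_error(gap_loss(prof(numeric(0), numeric(0))), "empty")

  # invariant to relabeling the compartments
  set.seed(12)
  dm <- runif(11, 5, 12); dl <- runif(11, 5, 12)
  expect_equal(gap_loss(prof(dm, dl)), gap_loss(prof(dl, dm)))
  # common nonnegative offset leaves the loss unchanged while gaps stay >= 0
  expect_equal(gap_loss(prof(dm + 2, dl + 2)), gap_loss(prof(dm, dl)),
               tolerance = 1e-12)
})

test_that("gap balancing on a symmetric knee stays at the MB pose", {
  knee <- generate_knee(subject_spec(kinematic_varus_amplitude_deg = 0,
                                     native_posterior_slope_deg = 0,
                                     hka_varus_deg = 0))
  f <- mb_fixture(knee)
  gb <- optimize_gb(f$mb, f$kin, f$plane, knee$femoral_component_mesh,
                    gb_config(strategy = "GB_full", seed = 2,
                              max_evals = 600))
  expect_lt(gb$loss_mm, 0.05)
  expect_lt(max(abs(unlist(gb$delta_from_mb)[4:6])), 0.6)
  expect_lte(gb$loss_mm, gb$mb_loss_mm)
})

test_that("gap balancing strongly reduces asymmetry and respects bounds and seeds", {
  f <- mb_fixture(fixture_knee(varus = 3))
  gb <- optimize_gb(f$mb, f$kin, f$plane, f$knee$femoral_component_mesh,
                    gb_config(strategy = "GB_full", seed = 7))
  expect_lt(gb$loss_mm, 0.5)                      # from ~2.45 mm at MB
  expect_lte(gb$loss_mm, gb$mb_loss_mm)
  d <- unlist(gb$delta_from_mb)
  bounds <- gb_config()$bounds[c("AP_mm", "PD_mm", "ML_mm",
                                 "FE_deg", "AA_deg", "IE_deg")]
  expect_true(all(abs(d) <= bounds + 1e-6))

  gb2 <- optimize_gb(f$mb, f$kin, f$plane, f$knee$femoral_component_mesh,
                     gb_config(strategy = "GB_full", seed = 7))
  expect_identical(gb$delta_from_mb, gb2$delta_from_mb)
})

test_that("reduced-range strategies balance their target angles but not the arc", {
  f <- mb_fixture(fixture_knee(varus = 3))
  standing <- optimize_gb(f$mb, f$kin, f$plane,
                          f$knee$femoral_component_mesh,
                          gb_config(strategy = "GB_standing", seed = 3,
                                    max_evals = 800))
  prof <- standing$gap_profile
  at0 <- abs(abs(prof$d_l_mm[1]) - abs(prof$d_m_mm[1]))
  expect_lt(at0, 0.1)                              # balanced where optimized
  full <- optimize_gb(f$mb, f$kin, f$plane, f$knee$femoral_component_mesh,
                      gb_config(strategy = "GB_full", seed = 3))
  expect_gt(gap_loss(prof), gap_loss(full$gap_profile))
})

test_that("recovered corrections track injected varus across the cohort range", {
  # With spherical condyles a tibia-fixed varus offset is corrected by a
  # combination of component varus-valgus and internal-external rotation;
  # the total rotational correction tracks the injected deformity ~1:1 and
  # the varus-valgus share carries most of it (see the methods vignette).
  injected <- c(1, 3, 5, 7)
  rec <- vapply(injected, function(v) {
    f <- mb_fixture(fixture_knee(varus = v))
    gb <- optimize_gb(f$mb, f$kin, f$plane, f$knee$femoral_component_mesh,
                      gb_config(strategy = "GB_full", seed = 11))
    d <- gb$delta_from_mb
    sqrt(d$AA_deg^2 + d$IE_deg^2 + d$FE_deg^2)
  }, 0)
  fit <- stats::lm(rec ~ injected)
  expect_equal(unname(stats::coef(fit)[2]), 1.06, tolerance = 0.12)
  expect_gt(stats::cor(rec, injected), 0.99)
})

test_that("insert recommendation picks the largest thickness that fits", {
  prof <- function(mins) {
    df <- data.frame(flexion_deg = seq_along(mins), d_m_mm = mins,
                     d_l_mm = mins + 1)
    class(df) <- c("gap_profile", "data.frame")
    df
  }
  expect_equal(recommend_insert(prof(c(12, 10.4, 11)), c(9, 10, 11, 12)),
               list(insert_mm = 10, flagged = FALSE))
  expect_equal(recommend_insert(prof(8), c(9, 10, 11, 12)),
               list(insert_mm = 9, flagged = TRUE))
  expect_equal(recommend_insert(prof(c(11, 11)), c(9, 10, 11, 12)),
               list(insert_mm = 11, flagged = FALSE))
  expect_error(recommend_insert(prof(10), numeric(0)), "empty")
})

test_that("paired strategy comparison gives exact signed-rank p-values and Holm", {
  mk <- function(subject, strategy, gd) {
    data.frame(subject_id = subject, strategy = strategy,
               flexion_deg = rep(c(0, 10, 20), each = length(subject)),
               d_m_mm = 8, d_l_mm = 8 + rep(gd, 3))
  }
  set.seed(99)
  subj <- sprintf("s%d", 1:8)
  base <- runif(8, 0.2, 0.9)

  identical_tbl <- rbind(mk(subj, "A", base), mk(subj, "B", base))
  cmp0 <- compare_strategies(identical_tbl, "A", "B")
  expect_true(all(cmp0$p_holm == 1))
  expect_false(any(cmp0$significant))

  # uniformly ~2 mm worse, with distinct per-subject magnitudes so the
  # exact signed-rank distribution applies (no tied differences)
  worse <- rbind(mk(subj, "A", base), mk(subj, "B", base + 2 + (1:8) / 50))
  cmp <- compare_strategies(worse, "A", "B")
  # uniform-direction n = 8: exact two-sided p = 2/2^8
  expect_equal(cmp$p_value, rep(0.0078125, 3))
  # Holm with three tied raw p-values: all adjusted to 3 * p
  expect_equal(cmp$p_holm, rep(3 * 0.0078125, 3))
  expect_true(all(abs(cmp$effect_size) == 1))

  unpaired <- rbind(mk(subj, "A", base), mk(subj[-1], "B", base[-1] + 2))
  expect_error(compare_strategies(unpaired, "A", "B"), "unpaired")
})
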