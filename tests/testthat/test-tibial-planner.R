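test_that("the resection plane sits 8 mm under the lateral plateau with the native slope", {
  knee <- fixture_knee()
  lm <- knee$landmarks

  flat <- build_resection_plane(knee$tibia_mesh, lm, standing_alignment(0, 0))
  expect_equal(flat$point, lm$lateral_plateau - c(0, 0, 8))
  expect_equal(flat$normal, c(0, 0, 1))

  sloped <- build_resection_plane(knee$tibia_mesh, lm,
                                  standing_alignment(0, 5))
  expect_equal(acos(sum(sloped$normal * c(0, 0, 1))) * 180 / pi, 5,
               tolerance = 1e-9)
  expect_equal(sloped$normal[1], 0)  # no coronal tilt
  # posterior drop: the plane surface is lower behind than in front
  z_on_plane <- function(y) {
    # solve n . ((x, y, z) - p0) = 0 for z at the plane point's x
    p0 <- sloped$point; n <- sloped$normal
    p0[3] - n[2] * (y - p0[2]) / n[3]
  }
  expect_lt(z_on_plane(-25), z_on_plane(0))
  expect_equal(z_on_plane(0) - z_on_plane(-25), 25 * tan(5 * pi / 180),
               tolerance = 1e-9)

  shallow <- build_resection_plane(knee$tibia_mesh, lm,
                                   standing_alignment(0, 0),
                                   tibial_constraints(resection_depth_mm = 0))
  expect_equal(shallow$point, lm$lateral_plateau)

  expect_error(build_resection_plane(knee$tibia_mesh,
                                     list(), knee$alignment),
               "lateral_plateau")
})

test_that("PCI follows the penalized coverage formula on hand geometry", {
  res <- square_contour(0, 0)                       # A_T = 100
  expect_equal(compute_pci(res, res), 100)

  inner <- planar_contour(res$plane,
                          list(cbind(c(0, 10, 10, 0), c(0, 0, 6, 6))))
  expect_equal(compute_pci(inner, res), 60)         # containment: area ratio

  # overlap 90, overhang 10, A_T 100 -> 80%
  shifted <- planar_contour(res$plane,
                            list(cbind(c(1, 11, 11, 1), c(0, 0, 10, 10))))
  expect_equal(compute_pci(shifted, res), 80)

  expect_error(compute_pci(res, planar_contour(res$plane,
    list(cbind(c(0, 1e-6, 1e-6), c(0, 0, 1e-6))))), "zero-area")
})

test_that("PCI is at most 100, with equality only for identical contours", {
  set.seed(3)
  res <- square_contour(0, 0)
  for (i in 1:10) {
    imp <- square_contour(runif(1, -3, 3), runif(1, -3, 3),
                          side = runif(1, 6, 12))
    expect_lte(compute_pci(imp, res), 100)
  }
  bigger <- square_contour(-1, -1, side = 12)
  expect_lt(compute_pci(bigger, res), 100)
})

test_that("a larger resection never raises PCI when the overlap is fixed", {
  imp <- square_contour(2, 2, side = 6)             # fully inside both
  small <- square_contour(0, 0, side = 10)
  large <- square_contour(0, 0, side = 14)
  expect_gt(compute_pci(imp, small), compute_pci(imp, large))
})

test_that("component rotation against the Insall line is the signed atan2 angle", {
  knee <- fixture_knee()
  plane <- build_resection_plane(knee$tibia_mesh, knee$landmarks,
                                 standing_alignment(0, 0))
  expect_equal(insall_rotation_of(rigid_pose(), knee$landmarks, plane), 0,
               tolerance = 1e-9)
  expect_equal(insall_rotation_of(rigid_pose(IE_deg = 5), knee$landmarks,
                                  plane), 5, tolerance = 1e-9)
  set.seed(8)
  for (yaw in runif(5, -40, 40))
    expect_equal(insall_rotation_of(rigid_pose(IE_deg = yaw),
                                    knee$landmarks, plane), yaw,
                 tolerance = 1e-6)
  bad <- knee$landmarks
  bad$insall_anterior <- bad$insall_posterior
  expect_error(insall_rotation_of(rigid_pose(), bad, plane), "degenerate")
})

test_that("concentric circular implant lands centered with the area-ratio PCI", {
  # convex symmetric toy: optimum PCI = (r_i/r_t)^2 * 100, at the center
  tibia <- mesh_prism(ellipse_polygon(30, 30, 48), -40, 0)
  tray <- mesh_prism(ellipse_polygon(24, 24, 48), 0, 9)
  lm <- list(lateral_plateau = c(-15, 0, 0),
             insall_posterior = c(0, -30, 0), insall_anterior = c(0, 40, 0))
  plan <- optimize_tibial_placement(tibia, list(size_1 = tray), lm,
                                    standing_alignment(0, 0),
                                    tibial_constraints(resection_depth_mm = 8),
                                    sa_config(seed = 5))
  analytic <- (24 / 30)^2 * 100
  expect_true(plan$feasible)
  expect_equal(plan$pci_percent, analytic, tolerance = 0.02)
  expect_lte(plan$overhang_mm, 2)
  expect_lte(abs(plan$in_plane_pose[["rotation_deg"]]), 5)
  expect_gte(plan$pci_percent, plan$start_pci_percent)

  # near-greedy annealing (temperature ~ 0) also reaches the optimum
  cold <- optimize_tibial_placement(tibia, list(size_1 = tray), lm,
                                    standing_alignment(0, 0),
                                    tibial_constraints(resection_depth_mm = 8),
                                    sa_config(initial_temperature = 1e-6,
                                              seed = 6))
  expect_equal(cold$pci_percent, analytic, tolerance = 0.02)
})

test_that("tibial placement respects both constraints and the seed", {
  knee <- fixture_knee()
  p1 <- optimize_tibial_placement(knee$tibia_mesh, knee$tray_catalog,
                                  knee$landmarks, knee$alignment,
                                  tibial_constraints(), sa_config(seed = 3))
  p2 <- optimize_tibial_placement(knee$tibia_mesh, knee$tray_catalog,
                                  knee$landmarks, knee$alignment,
                                  tibial_constraints(), sa_config(seed = 3))
  expect_true(p1$feasible)
  expect_lte(p1$overhang_mm, 2 + 1e-9)
  expect_lte(abs(p1$in_plane_pose[["rotation_deg"]]), 5)
  expect_lte(p1$pci_percent, 100)
  expect_gte(p1$pci_percent, p1$start_pci_percent)
  expect_identical(p1$in_plane_pose, p2$in_plane_pose)
  expect_identical(p1$pci_percent, p2$pci_percent)

  expect_error(optimize_tibial_placement(knee$tibia_mesh, list(),
                                         knee$landmarks, knee$alignment),
               "empty")
})

test_that("an oversized catalog yields an explicit infeasibility result", {
  knee <- fixture_knee()
  huge <- list(size_1 = mesh_prism(ellipse_polygon(80, 55, 48), 0, 9))
  plan <- optimize_tibial_placement(knee$tibia_mesh, huge, knee$landmarks,
                                    knee$alignment, tibial_constraints(),
                                    sa_config(seed = 2))
  expect_false(plan$feasible)
})
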