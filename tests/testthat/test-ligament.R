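test_that("the piecewise force law matches hand evaluations at the knots", {
  expect_equal(ligament_force(-0.01, 2500), 0)
  # at the toe/linear junction both branches agree: 0.25 k (2e1)^2/e1 = k e1
  expect_equal(ligament_force(0.06, 2500, 0.03), 75)
  expect_equal(0.25 * 2500 * 0.06^2 / 0.03, 2500 * 0.03)
  expect_equal(ligament_force(0.09, 3000, 0.03), 3000 * (0.09 - 0.03))
  expect_equal(ligament_force(0.09, 3000, 0.03), 180)
})

test_that("the force law is continuous, C1 and nondecreasing for all bundles", {
  eps1 <- 0.03
  for (k in c(2500, 3000, 2000)) {
    knot <- 2 * eps1
    expect_equal(ligament_force(knot, k, eps1), k * eps1, tolerance = 1e-14)
    h <- 1e-9
    expect_equal(ligament_force(knot + h, k, eps1),
                 ligament_force(knot - h, k, eps1), tolerance = 1e-6)
    # one-sided slopes both equal k at the junction
    slope_lo <- (ligament_force(knot, k, eps1) -
                   ligament_force(knot - 1e-7, k, eps1)) / 1e-7
    slope_hi <- (ligament_force(knot + 1e-7, k, eps1) -
                   ligament_force(knot, k, eps1)) / 1e-7
    expect_equal(slope_lo, k, tolerance = 1e-3)
    expect_equal(slope_hi, k, tolerance = 1e-3)
    eps <- seq(-0.05, 0.2, by = 1e-3)
    f <- ligament_force(eps, k, eps1)
    expect_true(all(f >= 0))
    expect_true(all(diff(f) >= 0))
  }
})

test_that("free paths equal the Euclidean distance exactly", {
  sph <- mesh_sphere(c(0, 0, 0), 1, n_lat = 12, n_lon = 24)
  w <- wrapping_path_length(c(-2, 0, 5), c(2, 0, 5), list(sph))
  expect_identical(w$length_mm, 4)
  # obstacle present but not blocking: still exactly the straight line
  w2 <- wrapping_path_length(c(-25, 3, 1), c(25, -4, 2), list(sph))
  expect_identical(w2$length_mm,
                   sqrt(sum((c(25, -4, 2) - c(-25, 3, 1))^2)))
  expect_identical(wrapping_path_length(c(0, 0, 0), c(50, 0, 0))$length_mm, 50)
})

test_that("a blocked path wraps the sphere along the tangent-arc-tangent geodesic", {
  sph <- mesh_sphere(c(0, 0, 0), 1, n_lat = 12, n_lon = 24)
  w <- wrapping_path_length(c(-2, 0, 0), c(2, 0, 0), list(sph))
  analytic <- 2 * sqrt(3) + (pi - 2 * acos(1 / 2))
  expect_equal(w$length_mm, analytic, tolerance = 0.01 * analytic)
  expect_gte(w$length_mm, 4)  # never shorter than the chord

  expect_error(wrapping_path_length(c(0, 0, 0), c(2, 0, 0), list(sph)),
               "inside")
})

test_that("ligament sweeps track the construction and need a 0-degree frame", {
  knee <- fixture_knee()
  kin <- correct_varus_valgus(knee$kinematics, knee$alignment)
  bundle <- default_ligament_bundles(knee$landmarks)$aMCL

  # zero relative motion: constant length at all angles
  frozen <- kin
  frozen$poses <- rep(kin$poses[1], length(kin$poses))
  sw0 <- sweep_lengths(bundle, knee, frozen)
  expect_lt(diff(range(sw0$length_mm)), 1e-9)
  expect_equal(sw0$strain, rep(0, nrow(sw0)))
  expect_equal(sw0$force_N, rep(0, nrow(sw0)))

  # unobstructed attachments: lengths reproduce the generating geometry
  sw <- sweep_lengths(bundle, knee, kin)
  direct <- vapply(seq_along(kin$poses), function(i) {
    fa <- drop(transform_points(pose_to_matrix(kin$poses[[i]]),
                                bundle$femoral_attachment))
    sqrt(sum((fa - bundle$tibial_attachment)^2))
  }, 0)
  expect_equal(sw$length_mm, direct, tolerance = 0.01)
  expect_equal(sw$strain[1], 0)     # 0-degree reference
  expect_equal(sw$force_N[1], 0)

  no0 <- resample_series(kin, seq(10, 100, 10))
  expect_error(sweep_lengths(bundle, knee, no0), "0-degree")
})

test_that("native and implanted modes agree for zero-offset implant shells", {
  knee <- fixture_knee()
  kin <- correct_varus_valgus(knee$kinematics, knee$alignment)
  bundle <- default_ligament_bundles(knee$landmarks)$iLCL
  nat <- sweep_lengths(bundle, knee, kin, implanted = FALSE)
  imp <- sweep_lengths(bundle, knee, kin, implanted = TRUE)
  expect_equal(imp$length_mm, nat$length_mm, tolerance = 1e-6)
})

test_that("the tension protocol adds model forces to the side baselines", {
  mk_sweep <- function(strain) {
    df <- data.frame(flexion_deg = seq(0, 100, 10), length_mm = 100,
                     strain = strain,
                     force_N = ligament_force(strain, 2500))
    class(df) <- c("ligament_sweep", "data.frame")
    df
  }
  zero <- list(aMCL = mk_sweep(rep(0, 11)), pMCL = mk_sweep(rep(0, 11)),
               iLCL = mk_sweep(rep(0, 11)))
  prot <- build_tension_protocol(zero)
  expect_true(all(prot$applied_N[prot$bundle != "iLCL"] == 130))
  expect_true(all(prot$applied_N[prot$bundle == "iLCL"] == 100))

  # aMCL strain 0.09 at 70 degrees: applied = 130 + 2500*(0.09-0.03) = 280
  st <- rep(0, 11); st[8] <- 0.09
  prot2 <- build_tension_protocol(list(aMCL = mk_sweep(st)))
  expect_equal(prot2$applied_N[prot2$flexion_deg == 70], 280)

  # slack bundle applies the bare baseline
  prot3 <- build_tension_protocol(list(iLCL = mk_sweep(rep(-0.02, 11))),
                                  baseline_lateral_N = 100)
  expect_true(all(prot3$applied_N == 100))
  expect_true(all(prot3$applied_N >= prot3$baseline_N))
})
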