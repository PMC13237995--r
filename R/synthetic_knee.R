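#' Parametric synthetic-knee subject specification
#'
#' Defines the geometry, deformity and motion of one synthetic subject.
#' Femoral condyles are modeled as two equal spherical caps, the tibial
#' plateau as a slightly dished elliptical slab; implant meshes are
#' zero-offset shells of the articular surfaces plus catalog trays. The
#' kinematics emulate a weight-bearing lunge with a constant injected
#' varus (abduction--adduction) offset and small smooth internal-rotation
#' and rollback excursions.
#'
#' @param subject_id subject label.
#' @param condyle_radius_mm femoral condyle sphere radius.
#' @param condyle_spacing_mm medial-to-lateral condyle center distance.
#' @param plateau_width_mm,plateau_depth_mm tibial plateau ellipse axes (ML, AP).
#' @param native_posterior_slope_deg native tibial posterior slope.
#' @param hka_varus_deg standing hip-knee-ankle deviation (positive = varus);
#'   enters every kinematic frame and is removed by [correct_varus_valgus()].
#' @param kinematic_varus_amplitude_deg residual varus injected into every
#'   flexion frame (remains after HKA correction); drives gap asymmetry.
#' @param flexion_range_deg length-2 flexion range, within 0--100 deg.
#' @param frame_step_deg flexion step between frames; must divide the range.
#' @param seed integer seed (noise phase; cohort reproducibility).
#' @param distal_thickness_mm,posterior_thickness_mm femoral component
#'   condylar thicknesses (resection depths match them).
#' @param baseplate_thickness_mm tibial tray thickness.
#' @param noise_amplitude_deg amplitude of an optional zero-mean smooth
#'   varus perturbation over the flexion arc (default 0 = deterministic
#'   asymmetry).
#' @return an object of class `subject_spec`.
#' @export
subject_spec <- function(subject_id = "synthetic",
                         condyle_radius_mm = 22,
                         condyle_spacing_mm = 46,
                         plateau_width_mm = 75,
                         plateau_depth_mm = 50,
                         native_posterior_slope_deg = 5,
                         hka_varus_deg = 2,
                         kinematic_varus_amplitude_deg = 3,
                         flexion_range_deg = c(0, 100),
                         frame_step_deg = 10,
                         seed = 1L,
                         distal_thickness_mm = 9,
                         posterior_thickness_mm = 9,
                         baseplate_thickness_mm = 9,
                         noise_amplitude_deg = 0) {
  lens <- c(condyle_radius_mm, condyle_spacing_mm, plateau_width_mm,
            plateau_depth_mm, frame_step_deg, distal_thickness_mm,
            posterior_thickness_mm, baseplate_thickness_mm)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all lengths and the frame step must be positive")
  if (condyle_spacing_mm >= plateau_width_mm)
    stop("condyle spacing must be smaller than the plateau width")
  if (length(flexion_range_deg) != 2 ||
      flexion_range_deg[1] < 0 || flexion_range_deg[2] > 100 ||
      flexion_range_deg[1] >= flexion_range_deg[2])
    stop("flexion range must lie within [0, 100] with lo < hi")
  span <- diff(flexion_range_deg)
  if (abs(span / frame_step_deg - round(span / frame_step_deg)) > 1e-9)
    stop("frame_step_deg must divide the flexion range")
  structure(list(
    subject_id = subject_id,
    condyle_radius_mm = condyle_radius_mm,
    condyle_spacing_mm = condyle_spacing_mm,
    plateau_width_mm = plateau_width_mm,
    plateau_depth_mm = plateau_depth_mm,
    native_posterior_slope_deg = native_posterior_slope_deg,
    hka_varus_deg = hka_varus_deg,
    kinematic_varus_amplitude_deg = kinematic_varus_amplitude_deg,
    flexion_range_deg = flexion_range_deg,
    frame_step_deg = frame_step_deg,
    seed = as.integer(seed),
    distal_thickness_mm = distal_thickness_mm,
    posterior_thickness_mm = posterior_thickness_mm,
    baseplate_thickness_mm = baseplate_thickness_mm,
    noise_amplitude_deg = noise_amplitude_deg), class = "subject_spec")
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Names of landmarks expressed in the femoral (moving) frame
#'
#' All other landmarks are expressed in the tibial (fixed) frame.
#' @export
femoral_landmark_names <- c("hip_center", "medial_epicondyle",
                            "lateral_epicondyle", "aMCL_origin",
                            "pMCL_origin", "iLCL_origin",
                            "distal_condyle_medial", "distal_condyle_lateral")

#' Catalog of tibial tray meshes for a subject
#'
#' Elliptical trays with the plateau's ML:AP aspect ratio in four ML widths.
#' Each tray lives in its component frame with the underside contour at
#' z = 0 and the body extruded upward by the baseplate thickness.
#'
#' @param spec a [subject_spec()].
#' @param widths_mm tray medial--lateral widths.
#' @return named list of [tri_mesh()] trays.
#' @export
tibial_tray_catalog <- function(spec, widths_mm = c(58, 62, 66, 70)) {
  ratio <- spec$plateau_width_mm / spec$plateau_depth_mm
  out <- lapply(widths_mm, function(w) {
    poly <- ellipse_polygon(w / 2, w / 2 / ratio, n = 48)
    mesh_prism(poly, 0, spec$baseplate_thickness_mm,
               frame_name = "tibial_component")
  })
  names(out) <- sprintf("size_%d", seq_along(widths_mm))
  out
}

condyle_centers <- function(spec) {
  s <- spec$condyle_spacing_mm / 2
  list(medial = c(s, 0, 0), lateral = c(-s, 0, 0))
}

make_femur_mesh <- function(spec, n_lat = 16, n_lon = 32, frame = "femur") {
  cc <- condyle_centers(spec)
  merge_meshes(
    mesh_sphere(cc$medial, spec$condyle_radius_mm, n_lat, n_lon, frame),
    mesh_sphere(cc$lateral, spec$condyle_radius_mm, n_lat, n_lon, frame))
}

make_tibia_mesh <- function(spec) {
  poly <- ellipse_polygon(spec$plateau_width_mm / 2,
                          spec$plateau_depth_mm / 2, n = 48)
  mesh_prism(poly, -80, 0, dish_mm = 1.5, frame_name = "tibia")
}

make_landmarks <- function(spec) {
  s <- spec$condyle_spacing_mm / 2
  r <- spec$condyle_radius_mm
  epi <- s + r + 2          # epicondyles clear the condylar spheres
  pw <- spec$plateau_width_mm / 2
  list(
    # femoral frame
    hip_center = c(0, 0, 400),
    medial_epicondyle = c(epi, 0, 4),
    lateral_epicondyle = c(-epi, 0, 4),
    aMCL_origin = c(epi, 6, 2),
    pMCL_origin = c(epi, -8, 2),
    iLCL_origin = c(-epi, -2, 2),
    distal_condyle_medial = c(s, 0, -r),
    distal_condyle_lateral = c(-s, 0, -r),
    # tibial frame (ligament insertions sit just outside the plateau slab)
    ankle_center = c(0, 0, -380),
    lateral_plateau = c(-spec$plateau_width_mm / 4, 0, 0),
    insall_posterior = c(0, -spec$plateau_depth_mm / 2, 0),
    insall_anterior = c(0, spec$plateau_depth_mm / 2 + 15, -15),
    aMCL_insertion = c(pw + 1.5, 5, -62),
    pMCL_insertion = c(pw + 1.0, -8, -78),
    iLCL_insertion = c(-(pw + 2.5), -5, -32)
  )
}

# femur-in-tibia pose at one flexion angle; AA carries the full coronal
# offset (standing HKA + injected kinematic varus + optional smooth noise)
lunge_pose <- function(theta, spec, noise_phase = 0) {
  aa <- spec$hka_varus_deg + spec$kinematic_varus_amplitude_deg +
    spec$noise_amplitude_deg * sin(2 * pi * theta / 100 + noise_phase)
  r <- spec$condyle_radius_mm
  s <- spec$condyle_spacing_mm
  rigid_pose(
    AP_mm = -3 * sin(deg2rad(theta) / 2),          # mild posterior rollback
    PD_mm = r + (s / 2) * abs(sin(deg2rad(aa))),   # tight condyle touches plateau
    ML_mm = 0,
    FE_deg = theta,
    AA_deg = aa,
    IE_deg = 0.5 * theta / 100)                    # small internal rotation drift
}

#' Generate a complete synthetic knee
#'
#' Builds bone and implant meshes, anatomical landmarks and lunge
#' kinematics from a [subject_spec()]. Deterministic for a fixed seed.
#'
#' @param spec a [subject_spec()].
#' @return an object of class `synthetic_knee` with fields `femur_mesh`,
#'   `tibia_mesh`, `femoral_component_mesh`, `tibial_component_mesh`
#'   (middle catalog size), `tray_catalog`, `landmarks`, `kinematics`,
#'   `alignment` and `spec`.
#' @export
generate_knee <- function(spec) {
  stopifnot(inherits(spec, "subject_spec"))
  noise_phase <- with_seed(spec$seed, stats::runif(1, 0, 2 * pi))
  angles <- seq(spec$flexion_range_deg[1], spec$flexion_range_deg[2],
                by = spec$frame_step_deg)
  kin <- flexion_series(angles,
                        lapply(angles, lunge_pose, spec = spec,
                               noise_phase = noise_phase),
                        subject_id = spec$subject_id)
  catalog <- tibial_tray_catalog(spec)
  structure(list(
    femur_mesh = make_femur_mesh(spec),
    tibia_mesh = make_tibia_mesh(spec),
    femoral_component_mesh = make_femur_mesh(spec, n_lat = 12, n_lon = 24,
                                             frame = "femoral_component"),
    tibial_component_mesh = catalog[[ceiling(length(catalog) / 2)]],
    tray_catalog = catalog,
    landmarks = make_landmarks(spec),
    kinematics = kin,
    alignment = standing_alignment(
      hka_deg = spec$hka_varus_deg,
      posterior_slope_deg = spec$native_posterior_slope_deg),
    spec = spec), class = "synthetic_knee")
}

#' @export
print.synthetic_knee <- function(x, ...) {
  cat(sprintf("synthetic_knee '%s': varus amplitude %.2f deg, HKA %.2f deg, %d frames\n",
              x$spec$subject_id, x$spec$kinematic_varus_amplitude_deg,
              x$spec$hka_varus_deg, length(x$kinematics$flexion_deg)))
  invisible(x)
}

#' Generate a cohort of synthetic knees with varied deformity
#'
#' Kinematic varus amplitudes are drawn uniformly from `varus_range_deg`;
#' per-subject seeds are derived from `seed` so the cohort is reproducible.
#'
#' @param n number of subjects (>= 1).
#' @param base a [subject_spec()] providing all other parameters.
#' @param varus_range_deg length-2 range of injected varus amplitudes (deg).
#' @param seed integer cohort seed.
#' @return list of [generate_knee()] results.
#' @export
generate_cohort <- function(n, base = subject_spec(),
                            varus_range_deg = c(0.7, 7.0), seed = 1L) {
  stopifnot(n >= 1, length(varus_range_deg) == 2,
            varus_range_deg[1] <= varus_range_deg[2])
  amps <- with_seed(seed,
                    stats::runif(n, varus_range_deg[1], varus_range_deg[2]))
  lapply(seq_len(n), function(i) {
    sp <- base
    sp$subject_id <- sprintf("%s_%02d", base$subject_id, i)
    sp$kinematic_varus_amplitude_deg <- amps[i]
    sp$seed <- as.integer((as.numeric(seed) * 1000 + i) %% 2147483629)
    generate_knee(sp)
  })
}

#' Export a synthetic knee to disk (STL + JSON + CSV)
#'
#' Writes the four meshes as ASCII STL, the landmark map as JSON (mm) and
#' the kinematics in the canonical CSV layout.
#'
#' @param knee a [generate_knee()] result.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
export_knee <- function(knee, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stl(knee$femur_mesh, file.path(dir, "femur.stl"), "femur")
  write_stl(knee$tibia_mesh, file.path(dir, "tibia.stl"), "tibia")
  write_stl(knee$femoral_component_mesh,
            file.path(dir, "femoral_component.stl"), "femoral_component")
  write_stl(knee$tibial_component_mesh,
            file.path(dir, "tibial_component.stl"), "tibial_component")
  jsonlite::write_json(knee$landmarks, file.path(dir, "landmarks.json"),
                       auto_unbox = FALSE, digits = NA)
  write_series(knee$kinematics, file.path(dir, "kinematics.csv"))
  invisible(dir)
}
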