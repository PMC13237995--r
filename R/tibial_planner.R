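#' Constraints on tibial component placement
#'
#' Defaults follow standard surgical limits: component rotation within
#' +/- 5 degrees of the Insall line, overhang at most 2 mm, resection
#' 8 mm below the lateral plateau, matching the native posterior slope.
#'
#' @param rotation_limit_deg rotation band around the Insall line (deg).
#' @param overhang_limit_mm maximum allowed boundary overhang (mm).
#' @param resection_depth_mm cut depth below the lateral plateau (mm).
#' @param match_native_slope tilt the cut by the native posterior slope?
#' @return an object of class `tibial_constraints`.
#' @export
tibial_constraints <- function(rotation_limit_deg = 5,
                               overhang_limit_mm = 2,
                               resection_depth_mm = 8,
                               match_native_slope = TRUE) {
  stopifnot(rotation_limit_deg >= 0, overhang_limit_mm >= 0,
            resection_depth_mm >= 0)
  structure(list(rotation_limit_deg = rotation_limit_deg,
                 overhang_limit_mm = overhang_limit_mm,
                 resection_depth_mm = resection_depth_mm,
                 match_native_slope = isTRUE(match_native_slope)),
            class = "tibial_constraints")
}

#' Simulated-annealing configuration for tibial placement
#'
#' @param max_iterations iteration budget (default 200).
#' @param initial_temperature starting temperature (default 5, in PCI
#'   percentage points).
#' @param cooling_rate geometric cooling factor per iteration.
#' @param proposal_sd_translation_mm,proposal_sd_rotation_deg Gaussian
#'   proposal standard deviations.
#' @param size_change_prob probability a move also switches catalog size.
#' @param seed RNG seed.
#' @return an object of class `sa_config`.
#' @export
sa_config <- function(max_iterations = 200, initial_temperature = 5,
                      cooling_rate = 0.97,
                      proposal_sd_translation_mm = 1,
                      proposal_sd_rotation_deg = 1,
                      size_change_prob = 0.1, seed = 1L) {
  stopifnot(max_iterations >= 1, initial_temperature > 0,
            cooling_rate > 0, cooling_rate < 1)
  structure(list(max_iterations = as.integer(max_iterations),
                 initial_temperature = initial_temperature,
                 cooling_rate = cooling_rate,
                 proposal_sd_translation_mm = proposal_sd_translation_mm,
                 proposal_sd_rotation_deg = proposal_sd_rotation_deg,
                 size_change_prob = size_change_prob,
                 seed = as.integer(seed)), class = "sa_config")
}

#' Build the tibial resection plane
#'
#' The plane passes `resection_depth_mm` below the lateral plateau landmark
#' along the tibial (proximal--distal) axis, is tilted posteriorly by the
#' native slope about the medial--lateral axis when requested, and carries
#' no coronal tilt.
#'
#' @param tibia tibial [tri_mesh()] (frame reference only).
#' @param landmarks landmark map containing `lateral_plateau`.
#' @param alignment a [standing_alignment()] (source of the native slope).
#' @param constraints a [tibial_constraints()].
#' @return a [plane3d()] with the normal pointing proximally.
#' @export
build_resection_plane <- function(tibia, landmarks, alignment,
                                  constraints = tibial_constraints()) {
  lp <- landmarks[["lateral_plateau"]]
  if (is.null(lp)) stop("missing landmark: lateral_plateau")
  slope <- if (constraints$match_native_slope)
    alignment$posterior_slope_deg else 0
  s <- deg2rad(slope)
  plane3d(point = lp - c(0, 0, constraints$resection_depth_mm),
          normal = c(0, -sin(s), cos(s)))
}

#' Penalized tibial coverage index (PCI)
#'
#' PCI = (overlap(A_I, A_T) - Sub(A_I, A_T)) / area(A_T) x 100, where A_I is
#' the region enclosed by the implant underside, A_T the tibial resection
#' surface, and Sub(A_I, A_T) the implant area hanging beyond the resection.
#' Bounded above by 100 (equality iff the contours coincide); negative for
#' gross malposition.
#'
#' @param implant_contour,resection_contour coplanar [planar_contour()]s.
#' @return PCI in percent.
#' @export
compute_pci <- function(implant_contour, resection_contour) {
  a_t <- contour_area(resection_contour)
  if (a_t <= 1e-9) stop("zero-area resection contour")
  ar <- polygon_areas(implant_contour, resection_contour)
  (ar$overlap_mm2 - ar$a_minus_b_mm2) / a_t * 100
}

# In-plane placement frame on the resection: origin at the resection
# centroid, AP axis = projected Insall direction, ML axis perpendicular.
placement_frame <- function(resection_contour, landmarks) {
  ia <- landmarks[["insall_anterior"]]; ip <- landmarks[["insall_posterior"]]
  if (is.null(ia) || is.null(ip)) stop("missing Insall line landmarks")
  b <- resection_contour$basis
  d3 <- ia - ip
  ap <- c(sum(d3 * b$u), sum(d3 * b$v))
  L <- sqrt(sum(ap^2))
  if (L < 1e-9) stop("degenerate Insall line (zero in-plane projection)")
  ap <- ap / L
  loop <- resection_contour$loops[[1]]
  list(center = colMeans(loop), ap = ap, ml = c(ap[2], -ap[1]))
}

# place an implant underside polygon (component-frame 2D: x = ML, y = AP)
# at (x, y, rot) in the placement frame; returns a planar_contour on the
# resection plane
place_implant_contour <- function(implant_poly2d, resection_contour, frame,
                                  x_mm, y_mm, rot_deg) {
  phi <- atan2(frame$ap[2], frame$ap[1]) - pi / 2 + deg2rad(rot_deg)
  R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  ctr <- frame$center + x_mm * frame$ml + y_mm * frame$ap
  placed <- sweep(implant_poly2d %*% t(R), 2, ctr, "+")
  planar_contour(resection_contour$plane, list(placed),
                 basis = resection_contour$basis)
}

# underside contour of a tray mesh (component frame, underside at z = 0),
# as a 2D polygon with x = ML, y = AP
tray_underside_polygon <- function(tray) {
  zs <- range(tray$vertices[, 3])
  cut <- cut_mesh_by_plane(tray, plane3d(c(0, 0, mean(zs)), c(0, 0, 1)))
  if (length(cut$loops) != 1) stop("tray cross-section is not a single loop")
  cut$loops[[1]]  # basis for +z normal is (x, y)
}

#' Signed rotation of a component AP axis relative to the Insall line
#'
#' Projects both the component's anterior axis and the Insall line onto the
#' resection plane and returns the signed angle between them (deg, positive
#' counter-clockwise about the plane normal).
#'
#' @param pose the component pose (a [rigid_pose()]) in the tibial frame;
#'   the component AP axis is its rotated +y axis.
#' @param landmarks landmark map with `insall_anterior`, `insall_posterior`.
#' @param plane the resection [plane3d()].
#' @return signed angle in degrees.
#' @export
insall_rotation_of <- function(pose, landmarks, plane) {
  ia <- landmarks[["insall_anterior"]]; ip <- landmarks[["insall_posterior"]]
  if (is.null(ia) || is.null(ip)) stop("missing Insall line landmarks")
  if (sqrt(sum((ia - ip)^2)) < 1e-9) stop("degenerate Insall line")
  b <- plane_basis(plane)
  proj2 <- function(v3) c(sum(v3 * b$u), sum(v3 * b$v))
  ap_axis <- pose_to_matrix(pose)[1:3, 2]
  a <- proj2(ap_axis); i <- proj2(ia - ip)
  if (sqrt(sum(a^2)) < 1e-9 || sqrt(sum(i^2)) < 1e-9)
    stop("degenerate in-plane projection")
  rad2deg(atan2(a[1] * i[2] - a[2] * i[1], sum(a * i))) * -1
}

#' Optimize tibial component placement by simulated annealing
#'
#' Searches in-plane translation, rotation about the Insall line and catalog
#' size for the placement maximizing the penalized coverage index (PCI).
#' Rotation is clamped to the constraint band; candidates whose boundary
#' overhang exceeds the limit are rejected outright (objective -Inf), so the
#' 2 mm rule acts as a hard constraint on top of the overhang-area penalty
#' already inside the PCI.
#'
#' @param tibia tibial [tri_mesh()].
#' @param implant_catalog named list of tray [tri_mesh()]es (underside at
#'   z = 0 in their component frame).
#' @param landmarks landmark map (`lateral_plateau`, Insall line points).
#' @param alignment a [standing_alignment()].
#' @param constraints a [tibial_constraints()].
#' @param sa an [sa_config()].
#' @return an object of class `tibial_plan` with fields `in_plane_pose`
#'   (x_mm, y_mm, rotation_deg), `chosen_size_id`, `pci_percent`,
#'   `overhang_mm`, `resection_plane`, `resection_contour`,
#'   `implant_contour`, `feasible`, `start_pci_percent`.
#' @export
optimize_tibial_placement <- function(tibia, implant_catalog, landmarks,
                                      alignment,
                                      constraints = tibial_constraints(),
                                      sa = sa_config()) {
  if (length(implant_catalog) == 0) stop("empty implant catalog")
  plane <- build_resection_plane(tibia, landmarks, alignment, constraints)
  resection <- cut_mesh_by_plane(tibia, plane)
  if (length(resection$loops) == 0) stop("resection plane misses the tibia")
  resection$loops <- resection$loops[which.max(
    vapply(resection$loops, function(L) abs(shoelace_area(L)), 0))]
  frame <- placement_frame(resection, landmarks)
  polys <- lapply(implant_catalog, tray_underside_polygon)
  size_ids <- names(polys)
  if (is.null(size_ids)) size_ids <- sprintf("size_%d", seq_along(polys))

  evaluate <- function(st, step = 0.2) {
    if (abs(st$rot) > constraints$rotation_limit_deg + 1e-12)
      return(list(pci = -Inf, overhang = Inf))
    ic <- place_implant_contour(polys[[st$size]], resection, frame,
                                st$x, st$y, st$rot)
    ov <- max_overhang_distance(ic, resection, step = step)
    if (ov > constraints$overhang_limit_mm)
      return(list(pci = -Inf, overhang = ov, contour = ic))
    list(pci = compute_pci(ic, resection), overhang = ov, contour = ic)
  }

  with_seed(sa$seed, {
    mid <- ceiling(length(polys) / 2)
    cur <- list(x = 0, y = 0, rot = 0, size = mid)
    cur_e <- evaluate(cur)
    if (!is.finite(cur_e$pci)) {
      # centered start infeasible: try other sizes, then jittered restarts
      for (sz in order(-vapply(polys, function(p) abs(shoelace_area(p)), 0))) {
        cand <- list(x = 0, y = 0, rot = 0, size = sz)
        ce <- evaluate(cand)
        if (is.finite(ce$pci)) { cur <- cand; cur_e <- ce; break }
      }
      tries <- 0
      while (!is.finite(cur_e$pci) && tries < 50) {
        cand <- list(x = stats::rnorm(1, 0, 3), y = stats::rnorm(1, 0, 3),
                     rot = stats::runif(1, -constraints$rotation_limit_deg,
                                        constraints$rotation_limit_deg),
                     size = sample.int(length(polys), 1))
        ce <- evaluate(cand)
        if (is.finite(ce$pci)) { cur <- cand; cur_e <- ce }
        tries <- tries + 1
      }
      if (!is.finite(cur_e$pci))
        return(structure(list(feasible = FALSE,
                              resection_plane = plane,
                              resection_contour = resection),
                         class = "tibial_plan"))
    }
    start_pci <- evaluate(list(x = 0, y = 0, rot = 0, size = mid))$pci
    best <- cur; best_e <- cur_e
    temp <- sa$initial_temperature
    for (it in seq_len(sa$max_iterations)) {
      prop <- cur
      prop$x <- prop$x + stats::rnorm(1, 0, sa$proposal_sd_translation_mm)
      prop$y <- prop$y + stats::rnorm(1, 0, sa$proposal_sd_translation_mm)
      prop$rot <- prop$rot + stats::rnorm(1, 0, sa$proposal_sd_rotation_deg)
      prop$rot <- max(-constraints$rotation_limit_deg,
                      min(constraints$rotation_limit_deg, prop$rot))
      if (length(polys) > 1 && stats::runif(1) < sa$size_change_prob)
        prop$size <- sample(setdiff(seq_along(polys), prop$size), 1)
      pe <- evaluate(prop)
      delta <- pe$pci - cur_e$pci
      if (is.finite(pe$pci) &&
          (delta > 0 || stats::runif(1) < exp(delta / temp))) {
        cur <- prop; cur_e <- pe
        if (cur_e$pci > best_e$pci) { best <- cur; best_e <- cur_e }
      }
      temp <- temp * sa$cooling_rate
    }
    final <- evaluate(best, step = 0.05)  # fine overhang measurement
    structure(list(
      feasible = TRUE,
      in_plane_pose = c(x_mm = best$x, y_mm = best$y, rotation_deg = best$rot),
      chosen_size_id = size_ids[best$size],
      pci_percent = final$pci,
      overhang_mm = final$overhang,
      start_pci_percent = start_pci,
      resection_plane = plane,
      resection_contour = resection,
      implant_contour = final$contour), class = "tibial_plan")
  })
}

#' @export
print.tibial_plan <- function(x, ...) {
  if (!x$feasible) {
    cat("tibial_plan: no feasible placement found\n")
    return(invisible(x))
  }
  cat(sprintf(
    "tibial_plan: size %s, PCI %.1f%%, rotation %+.2f deg vs Insall, overhang %.2f mm\n",
    x$chosen_size_id, x$pci_percent, x$in_plane_pose[["rotation_deg"]],
    x$overhang_mm))
  invisible(x)
}
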