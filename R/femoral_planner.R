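#' Morphology-based (measured-resection) femoral reference plan
#'
#' Constructs the MB plan: the distal cut is perpendicular to the femoral
#' mechanical axis (hip center to knee center) at a depth equal to the
#' distal component thickness below the most distal condyle point; the
#' posterior cut is parallel to the transepicondylar axis (TEA) at a depth
#' equal to the posterior thickness; the component pose seats the
#' bone-facing surfaces on both cuts, restoring the native articular
#' surface for thickness-matched resections.
#'
#' @param femur femoral [tri_mesh()] (femoral frame).
#' @param landmarks landmark map with `hip_center`, `medial_epicondyle`,
#'   `lateral_epicondyle`.
#' @param component femoral component [tri_mesh()] (component frame:
#'   x medial, y anterior, z proximal).
#' @param distal_thickness_mm,posterior_thickness_mm component thicknesses.
#' @return an object of class `femoral_mb_plan` with `component_pose`,
#'   `distal_plane`, `posterior_plane` and the thicknesses.
#' @export
build_mb_plan <- function(femur, landmarks, component,
                          distal_thickness_mm = 9,
                          posterior_thickness_mm = 9) {
  need <- c("hip_center", "medial_epicondyle", "lateral_epicondyle")
  miss <- need[!need %in% names(landmarks)]
  if (length(miss) > 0)
    stop("missing landmark(s): ", paste(miss, collapse = ", "))
  hip <- landmarks$hip_center
  me <- landmarks$medial_epicondyle
  le <- landmarks$lateral_epicondyle
  knee <- (me + le) / 2

  unit <- function(v) v / sqrt(sum(v^2))
  axis <- unit(hip - knee)                       # mechanical axis, proximal
  tea <- unit(me - le)                           # medial direction
  ml <- unit(tea - sum(tea * axis) * axis)       # in-plane medial axis
  ap <- c(axis[2] * ml[3] - axis[3] * ml[2],     # anterior = axis x ml
          axis[3] * ml[1] - axis[1] * ml[3],
          axis[1] * ml[2] - axis[2] * ml[1])
  n_post <- -ap

  fv <- femur$vertices
  d_dist <- fv %*% axis
  p_distal <- fv[which.min(d_dist), ]
  distal_plane <- plane3d(p_distal + axis * distal_thickness_mm, axis)

  d_post <- fv %*% n_post
  p_post <- fv[which.max(d_post), ]
  posterior_plane <- plane3d(p_post - n_post * posterior_thickness_mm, n_post)

  # component rotation: (x, y, z) component axes -> (ml, ap, axis)
  Rc <- cbind(ml, ap, axis)
  cv <- component$vertices
  cvR <- cv %*% t(Rc)
  # translation from three orthogonal seating constraints:
  # distal surface on the restored joint line, posterior surface on the
  # restored posterior condyle, ML centered on the epicondylar midpoint
  t_axis <- sum(p_distal * axis) - min(cvR %*% axis)
  t_post <- max(d_post) - max(cvR %*% n_post)
  ctr_c <- colMeans(cvR)
  t_ml <- sum(knee * ml) - sum(ctr_c * ml)
  t_vec <- axis * t_axis + n_post * t_post + ml * t_ml
  m <- diag(4); m[1:3, 1:3] <- Rc; m[1:3, 4] <- t_vec

  structure(list(component_pose = matrix_to_pose(m),
                 distal_plane = distal_plane,
                 posterior_plane = posterior_plane,
                 distal_thickness_mm = distal_thickness_mm,
                 posterior_thickness_mm = posterior_thickness_mm),
            class = "femoral_mb_plan")
}

# split component vertices into medial/lateral condyles by the sign of the
# component-frame ML coordinate; exact-midline vertices belong to neither
condyle_partition <- function(component, tol = 1e-9) {
  x <- component$vertices[, 1]
  med <- component$vertices[x > tol, , drop = FALSE]
  lat <- component$vertices[x < -tol, , drop = FALSE]
  if (nrow(med) == 0 || nrow(lat) == 0)
    stop("empty condyle partition: component not split by its midplane")
  list(medial = med, lateral = lat)
}

#' Medial and lateral joint gaps at one flexion frame
#'
#' Composes the femur-in-tibia frame pose with the component-in-femur pose,
#' then returns the minimum signed distance from each condyle's vertices to
#' the tibial resection plane. Positive = gap, negative = penetration
#' (never clamped).
#'
#' @param component femoral component [tri_mesh()].
#' @param pose component pose in the femoral frame (a [rigid_pose()]).
#' @param frame_pose femur-in-tibia pose for the frame (a [rigid_pose()]).
#' @param tibial_plane the resection [plane3d()] (normal proximal).
#' @return named vector `c(d_m_mm, d_l_mm)`.
#' @export
compute_gaps <- function(component, pose, frame_pose, tibial_plane) {
  part <- condyle_partition(component)
  m <- pose_to_matrix(frame_pose) %*% pose_to_matrix(pose)
  c(d_m_mm = min(point_plane_distance(transform_points(m, part$medial),
                                      tibial_plane)),
    d_l_mm = min(point_plane_distance(transform_points(m, part$lateral),
                                      tibial_plane)))
}

# precompute per-frame plane coefficients in the femoral frame so that
# candidate component poses only require one vertex transform
frame_plane_coeffs <- function(series, tibial_plane) {
  A <- matrix(0, 3, length(series$poses))
  b <- numeric(length(series$poses))
  for (i in seq_along(series$poses)) {
    mf <- pose_to_matrix(series$poses[[i]])
    A[, i] <- t(mf[1:3, 1:3]) %*% tibial_plane$normal
    b[i] <- sum((mf[1:3, 4] - tibial_plane$point) * tibial_plane$normal)
  }
  list(A = A, b = b)
}

colmin <- function(m) do.call(pmin, lapply(seq_len(nrow(m)), function(i) m[i, ]))

gaps_for_series_fast <- function(part, pose, series, coeffs) {
  mp <- pose_to_matrix(pose)
  vm <- transform_points(mp, part$medial)
  vl <- transform_points(mp, part$lateral)
  d_m <- colmin(vm %*% coeffs$A) + coeffs$b
  d_l <- colmin(vl %*% coeffs$A) + coeffs$b
  data.frame(flexion_deg = series$flexion_deg, d_m_mm = d_m, d_l_mm = d_l)
}

#' Per-frame gap profile of a component pose over a flexion series
#'
#' @param component femoral component [tri_mesh()].
#' @param pose component pose in the femoral frame.
#' @param series a (varus-valgus corrected) [flexion_series()].
#' @param tibial_plane the resection [plane3d()].
#' @param strategy_label label attached to the profile (e.g. "MB",
#'   "GB_full").
#' @return a `gap_profile`: data.frame (flexion_deg, d_m_mm, d_l_mm) with a
#'   `strategy` attribute.
#' @export
gap_profile <- function(component, pose, series, tibial_plane,
                        strategy_label = "MB") {
  part <- condyle_partition(component)
  df <- gaps_for_series_fast(part, pose, series,
                             frame_plane_coeffs(series, tibial_plane))
  attr(df, "strategy") <- strategy_label
  class(df) <- c("gap_profile", "data.frame")
  df
}

#' Mean absolute medial--lateral gap difference (the GB loss)
#'
#' loss = (1/n) * sum_i | |d_l| - |d_m| |_i over the frames of a profile:
#' zero iff the gap magnitudes match at every frame.
#'
#' @param profile a [gap_profile()] (any data.frame with `d_m_mm`, `d_l_mm`).
#' @return loss in mm.
#' @export
gap_loss <- function(profile) {
  if (nrow(profile) == 0) stop("empty gap profile")
  mean(abs(abs(profile$d_l_mm) - abs(profile$d_m_mm)))
}

#' Configuration for gap-balance (GB) femoral pose optimization
#'
#' @param strategy which flexion frames drive the loss: the full series,
#'   standing only (0 deg), or standing plus 90 deg.
#' @param bounds named per-DOF half-widths of the search box around the MB
#'   pose (mm for AP/PD/ML, deg for FE/AA/IE).
#' @param sigma0 initial CMA-ES step size (mixed mm/deg scale).
#' @param max_evals CMA-ES evaluation budget.
#' @param lambda CMA-ES population size (NULL = default heuristic).
#' @param seed RNG seed.
#' @param insert_catalog_mm available insert thicknesses, ascending.
#' @param tie_break_weight weight of a tiny quadratic pull toward the MB
#'   pose added to the search objective only; it resolves directions the
#'   gap-difference loss is indifferent to (e.g. pure proximal--distal
#'   shifts move both gaps equally) in favor of the anatomical reference.
#'   The reported `loss_mm` is always the plain mean gap difference.
#' @return an object of class `gb_config`.
#' @export
gb_config <- function(strategy = c("GB_full", "GB_standing", "GB_standing_90"),
                      bounds = c(AP_mm = 3, PD_mm = 3, ML_mm = 3,
                                 FE_deg = 3, AA_deg = 8, IE_deg = 5),
                      sigma0 = 1, max_evals = 1800, lambda = NULL,
                      seed = 1L,
                      insert_catalog_mm = c(8, 9, 10, 11, 12, 14),
                      tie_break_weight = 1e-4) {
  strategy <- match.arg(strategy)
  stopifnot(all(bounds > 0), !is.unsorted(insert_catalog_mm),
            length(insert_catalog_mm) >= 1, tie_break_weight >= 0)
  structure(list(strategy = strategy, bounds = bounds, sigma0 = sigma0,
                 max_evals = max_evals, lambda = lambda,
                 seed = as.integer(seed),
                 insert_catalog_mm = insert_catalog_mm,
                 tie_break_weight = tie_break_weight),
            class = "gb_config")
}

strategy_frames <- function(series, strategy) {
  switch(strategy,
         GB_full = series,
         GB_standing = {
           keep <- which.min(series$flexion_deg)  # single standing frame
           series$flexion_deg <- series$flexion_deg[keep]
           series$poses <- series$poses[keep]
           series
         },
         GB_standing_90 = resample_series(series,
                                          c(min(series$flexion_deg), 90)))
}

transform_plane <- function(plane, m) {
  plane3d(transform_points(m, plane$point),
          drop(m[1:3, 1:3] %*% plane$normal))
}

#' Gap-balance optimization of the femoral component pose (CMA-ES)
#'
#' Starting from the MB pose, searches a bounded 6-DOF pose delta that
#' minimizes the mean absolute medial--lateral gap difference over the
#' frames selected by the strategy (full series, 0 deg only, or 0 and 90
#' deg). Candidates outside the search box are clamped and penalized; the
#' result never has a higher loss than the MB pose itself.
#'
#' @param mb a [build_mb_plan()] result.
#' @param kinematics varus-valgus corrected [flexion_series()].
#' @param tibial_plane the tibial resection [plane3d()].
#' @param component femoral component [tri_mesh()].
#' @param config a [gb_config()].
#' @return an object of class `gb_plan`: `optimized_pose`, `delta_from_mb`
#'   (both [rigid_pose()]), `loss_mm`, `mb_loss_mm`, `gap_profile` (full
#'   series), `recommended_insert_mm`, `insert_flagged`, `distal_plane`,
#'   `evals`.
#' @export
optimize_gb <- function(mb, kinematics, tibial_plane, component,
                        config = gb_config()) {
  part <- condyle_partition(component)
  frames <- strategy_frames(kinematics, config$strategy)
  coeffs <- frame_plane_coeffs(frames, tibial_plane)
  mb_mat <- pose_to_matrix(mb$component_pose)
  dof <- c("AP_mm", "PD_mm", "ML_mm", "FE_deg", "AA_deg", "IE_deg")
  bounds <- config$bounds[dof]

  loss_of <- function(delta) {
    dm <- pose_to_matrix(rigid_pose(AP_mm = delta[1], PD_mm = delta[2],
                                    ML_mm = delta[3], FE_deg = delta[4],
                                    AA_deg = delta[5], IE_deg = delta[6]))
    m <- mb_mat %*% dm
    vm <- transform_points(m, part$medial)
    vl <- transform_points(m, part$lateral)
    d_m <- colmin(vm %*% coeffs$A) + coeffs$b
    d_l <- colmin(vl %*% coeffs$A) + coeffs$b
    mean(abs(abs(d_l) - abs(d_m)))
  }
  objective <- function(delta)
    loss_of(delta) + config$tie_break_weight * sum(delta^2)

  loss0 <- loss_of(numeric(6))
  res <- cma_es(objective, x0 = numeric(6), sigma0 = config$sigma0,
                lower = -bounds, upper = bounds,
                max_evals = config$max_evals, lambda = config$lambda,
                stop_fitness = 1e-4, seed = config$seed)
  res$value <- loss_of(res$par)  # report the plain gap-difference loss
  if (!is.finite(res$value) || res$value > loss0) {
    res$par <- numeric(6)  # elitism: never worse than the MB start
    res$value <- loss0
  }
  delta <- rigid_pose(AP_mm = res$par[1], PD_mm = res$par[2],
                      ML_mm = res$par[3], FE_deg = res$par[4],
                      AA_deg = res$par[5], IE_deg = res$par[6])
  opt_mat <- mb_mat %*% pose_to_matrix(delta)
  opt_pose <- matrix_to_pose(opt_mat)
  prof <- gap_profile(component, opt_pose, kinematics, tibial_plane,
                      strategy_label = config$strategy)
  ins <- recommend_insert(prof, config$insert_catalog_mm)
  structure(list(
    optimized_pose = opt_pose,
    delta_from_mb = delta,
    loss_mm = res$value,
    mb_loss_mm = loss0,
    gap_profile = prof,
    recommended_insert_mm = ins$insert_mm,
    insert_flagged = ins$flagged,
    distal_plane = transform_plane(mb$distal_plane,
                                   opt_mat %*% solve(mb_mat)),
    evals = res$evals), class = "gb_plan")
}

#' @export
print.gb_plan <- function(x, ...) {
  d <- x$delta_from_mb
  cat(sprintf(
    "gb_plan: loss %.3f mm (MB %.3f mm), delta AA %+.2f deg IE %+.2f deg FE %+.2f deg, insert %g mm%s\n",
    x$loss_mm, x$mb_loss_mm, d$AA_deg, d$IE_deg, d$FE_deg,
    x$recommended_insert_mm, if (x$insert_flagged) " (flagged)" else ""))
  invisible(x)
}

#' Recommend a tibial insert thickness from a gap profile
#'
#' Picks the largest catalog thickness not exceeding the smallest gap seen
#' over the profile (either compartment, any frame). If every catalog entry
#' is too thick, the thinnest is returned with a warning flag.
#'
#' @param profile a [gap_profile()].
#' @param catalog_mm ascending insert thicknesses.
#' @return list with `insert_mm` and logical `flagged`.
#' @export
recommend_insert <- function(profile, catalog_mm) {
  if (length(catalog_mm) == 0) stop("empty insert catalog")
  min_gap <- min(c(profile$d_m_mm, profile$d_l_mm))
  fits <- catalog_mm[catalog_mm <= min_gap + 1e-9]
  if (length(fits) == 0)
    list(insert_mm = catalog_mm[1], flagged = TRUE)
  else
    list(insert_mm = max(fits), flagged = FALSE)
}

holm_correct <- function(p) stats::p.adjust(p, method = "holm")

#' Paired per-angle comparison of two planning strategies
#'
#' At each flexion angle, compares the absolute medial--lateral gap
#' difference between two strategies across subjects with the paired
#' Wilcoxon signed-rank test (exact when there are no ties), then applies
#' the Holm--Bonferroni correction across angles. The effect size is the
#' matched-pairs rank-biserial correlation.
#'
#' @param profiles long data.frame with columns `subject_id`, `strategy`,
#'   `flexion_deg`, `d_m_mm`, `d_l_mm` (see [gap_profiles_table()]).
#' @param strategy_a,strategy_b the two strategy labels to compare.
#' @param alpha significance level applied to adjusted p-values.
#' @return data.frame: flexion_deg, mean_a, mean_b, statistic, p_value,
#'   p_holm, effect_size, significant.
#' @export
compare_strategies <- function(profiles, strategy_a, strategy_b,
                               alpha = 0.05) {
  need <- c("subject_id", "strategy", "flexion_deg", "d_m_mm", "d_l_mm")
  stopifnot(all(need %in% names(profiles)))
  profiles$gd <- abs(abs(profiles$d_l_mm) - abs(profiles$d_m_mm))
  a <- profiles[profiles$strategy == strategy_a, ]
  b <- profiles[profiles$strategy == strategy_b, ]
  angles <- sort(unique(a$flexion_deg))
  if (!setequal(angles, unique(b$flexion_deg)))
    stop("strategies were evaluated on different angle grids")
  rows <- lapply(angles, function(th) {
    aa <- a[a$flexion_deg == th, ]
    bb <- b[b$flexion_deg == th, ]
    subj <- sort(unique(aa$subject_id))
    if (!setequal(subj, unique(bb$subject_id)) ||
        nrow(aa) != length(subj) || nrow(bb) != length(subj))
      stop("unpaired input: subjects differ between strategies at angle ", th)
    xa <- aa$gd[match(subj, aa$subject_id)]
    xb <- bb$gd[match(subj, bb$subject_id)]
    d <- xa - xb
    if (all(d == 0)) {
      v <- NA_real_; p <- 1; r <- 0
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(xa, xb, paired = TRUE,
                           exact = !any(duplicated(abs(d[d != 0])))))
      v <- unname(wt$statistic); p <- wt$p.value
      dd <- d[d != 0]
      rk <- rank(abs(dd))
      tot <- sum(rk)
      r <- (sum(rk[dd > 0]) - sum(rk[dd < 0])) / tot
    }
    data.frame(flexion_deg = th, mean_a = mean(xa), mean_b = mean(xb),
               statistic = v, p_value = p, effect_size = r)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- holm_correct(out$p_value)
  out$significant <- out$p_holm < alpha
  out[, c("flexion_deg", "mean_a", "mean_b", "statistic", "p_value",
          "p_holm", "effect_size", "significant")]
}

#' Stack gap profiles of several subjects/strategies into a long table
#'
#' @param profiles list of [gap_profile()]s.
#' @param subject_ids subject label per profile.
#' @return long data.frame usable by [compare_strategies()].
#' @export
gap_profiles_table <- function(profiles, subject_ids) {
  stopifnot(length(profiles) == length(subject_ids))
  do.call(rbind, Map(function(p, id) {
    data.frame(subject_id = id,
               strategy = attr(p, "strategy"),
               flexion_deg = p$flexion_deg,
               d_m_mm = p$d_m_mm, d_l_mm = p$d_l_mm)
  }, profiles, subject_ids))
}
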