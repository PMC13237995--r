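#' Collateral ligament bundle definition
#'
#' Attachment pair plus the nonlinear-spring material constants. Default
#' stiffnesses follow the values used for the three bundles modeled here:
#' aMCL 2500 N, pMCL 3000 N, iLCL 2000 N, with strain constant
#' epsilon_1 = 0.03.
#'
#' @param name one of "aMCL", "pMCL", "iLCL".
#' @param femoral_attachment,tibial_attachment 3D points; the femoral point
#'   is expressed in the femoral (moving) frame, the tibial point in the
#'   tibial (fixed) frame.
#' @param stiffness_k_N ligament stiffness k (N); defaults by bundle name.
#' @param eps1 strain constant epsilon_1 (> 0).
#' @return an object of class `ligament_bundle`.
#' @export
ligament_bundle <- function(name, femoral_attachment, tibial_attachment,
                            stiffness_k_N = NULL, eps1 = 0.03) {
  name <- match.arg(name, c("aMCL", "pMCL", "iLCL"))
  if (is.null(stiffness_k_N))
    stiffness_k_N <- c(aMCL = 2500, pMCL = 3000, iLCL = 2000)[[name]]
  stopifnot(stiffness_k_N > 0, eps1 > 0,
            length(femoral_attachment) == 3, length(tibial_attachment) == 3)
  structure(list(name = name,
                 femoral_attachment = as.numeric(femoral_attachment),
                 tibial_attachment = as.numeric(tibial_attachment),
                 stiffness_k_N = stiffness_k_N, eps1 = eps1),
            class = "ligament_bundle")
}

#' The three default bundles of a knee's landmark map
#' @param landmarks landmark map containing `aMCL_origin`, `aMCL_insertion`,
#'   etc.
#' @return named list of [ligament_bundle()]s.
#' @export
default_ligament_bundles <- function(landmarks) {
  mk <- function(nm) ligament_bundle(nm, landmarks[[paste0(nm, "_origin")]],
                                     landmarks[[paste0(nm, "_insertion")]])
  list(aMCL = mk("aMCL"), pMCL = mk("pMCL"), iLCL = mk("iLCL"))
}

#' Piecewise nonlinear ligament force
#'
#' f = 0.25 k eps^2 / eps1   for 0 <= eps <= 2 eps1 (toe region),
#' f = k (eps - eps1)        for eps > 2 eps1 (linear region),
#' f = 0                     for eps < 0 (slack).
#' Continuous and once-differentiable at eps = 2 eps1 (value k eps1,
#' slope k). Vectorized over `strain`.
#'
#' @param strain engineering strain(s) eps.
#' @param k ligament stiffness (N).
#' @param eps1 strain constant (> 0), default 0.03.
#' @return force(s) in N.
#' @export
ligament_force <- function(strain, k, eps1 = 0.03) {
  stopifnot(eps1 > 0, k > 0)
  ifelse(strain < 0, 0,
         ifelse(strain <= 2 * eps1,
                0.25 * k * strain^2 / eps1,
                k * (strain - eps1)))
}

#' Shortest wrapping path length between two points around mesh obstacles
#'
#' Returns the length of the shortest obstacle-avoiding polyline from
#' `origin` to `insertion`. When the straight segment clears every obstacle
#' the Euclidean distance is returned exactly. Otherwise a visibility graph
#' is built over obstacle surface vertices (pushed outward by a small
#' clearance offset) connected along mesh edges, plus endpoint-to-surface
#' edges; the shortest graph path is then tightened by iterative
#' rope-shortening with re-projection to the offset surface.
#'
#' @param origin,insertion 3D endpoints (must lie outside all obstacles).
#' @param obstacles list of watertight [tri_mesh()] obstacles.
#' @param offset_mm clearance offset for surface sample points (mm).
#' @param refine number of rope-shortening sweeps.
#' @return list with `length_mm` and the polyline `path` (n x 3).
#' @export
wrapping_path_length <- function(origin, insertion, obstacles = list(),
                                 offset_mm = NULL, refine = 60) {
  origin <- as.numeric(origin); insertion <- as.numeric(insertion)
  straight <- sqrt(sum((insertion - origin)^2))
  if (length(obstacles) == 0)
    return(list(length_mm = straight, path = rbind(origin, insertion)))
  tris <- lapply(obstacles, mesh_triangle_arrays)
  for (tri in tris) {
    if (point_in_mesh(origin, tri)) stop("origin lies inside an obstacle")
    if (point_in_mesh(insertion, tri)) stop("insertion lies inside an obstacle")
  }
  if (segment_clears(origin, insertion, tris))
    return(list(length_mm = straight, path = rbind(origin, insertion)))

  # visibility graph over offset surface vertices
  nodes <- list(origin, insertion)
  edges <- NULL
  weights <- numeric(0)
  n_off <- 2L
  for (ob in obstacles) {
    scale <- max(apply(ob$vertices, 2, function(x) diff(range(x)))) / 2
    off <- if (is.null(offset_mm)) max(0.1, 0.012 * scale) else offset_mm
    vo <- ob$vertices + off * vertex_normals(ob)
    idx0 <- n_off
    nodes <- c(nodes, lapply(asplit(vo, 1), as.numeric))
    n_off <- n_off + nrow(vo)
    me <- mesh_edges_unique(ob)
    keep <- logical(nrow(me))
    for (i in seq_len(nrow(me)))
      keep[i] <- segment_clears(vo[me[i, 1], ], vo[me[i, 2], ], tris)
    me <- me[keep, , drop = FALSE]
    edges <- rbind(edges, me + idx0)
    weights <- c(weights, sqrt(rowSums(
      (vo[me[, 1], , drop = FALSE] - vo[me[, 2], , drop = FALSE])^2)))
    for (ep in 1:2) {
      p <- if (ep == 1) origin else insertion
      vis <- logical(nrow(vo))
      for (i in seq_len(nrow(vo)))
        vis[i] <- segment_clears(p, vo[i, ], tris)
      wi <- which(vis)
      if (length(wi) > 0) {
        edges <- rbind(edges, cbind(ep, wi + idx0))
        weights <- c(weights, sqrt(colSums((t(vo[wi, , drop = FALSE]) - p)^2)))
      }
    }
  }
  if (is.null(edges) || nrow(edges) == 0)
    stop("no unobstructed wrapping path found")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = weights)
  sp <- suppressWarnings(igraph::shortest_paths(g, 1, 2, weights = weights))
  vp <- as.integer(sp$vpath[[1]])
  if (length(vp) < 2) stop("no unobstructed wrapping path found")
  path <- do.call(rbind, nodes[vp])

  path <- tighten_path(path, tris, clearance = 0.02, sweeps = refine)
  list(length_mm = sum(sqrt(rowSums(diff(path)^2))), path = path)
}

# iterative rope-shortening: midpoint smoothing + re-projection to keep a
# small clearance from every obstacle; endpoints fixed
tighten_path <- function(path, tris, clearance = 0.02, sweeps = 60,
                         n_points = 60) {
  # resample to a regular polyline
  seg <- sqrt(rowSums(diff(path)^2))
  s <- c(0, cumsum(seg))
  t <- seq(0, s[length(s)], length.out = n_points)
  P <- sapply(1:3, function(j) stats::approx(s, path[, j], xout = t)$y)
  project <- function(p) {
    for (tri in tris) {
      np <- nearest_point_on_mesh(p, tri)
      inside <- point_in_mesh(p, tri)
      if (inside) {
        dir <- p - np$point
        nd <- sqrt(sum(dir^2))
        p <- if (nd < 1e-12) np$point else
          np$point + (np$point - p) / nd * clearance
      } else if (np$dist < clearance) {
        dir <- (p - np$point) / np$dist
        p <- np$point + dir * clearance
      }
    }
    p
  }
  for (it in seq_len(sweeps)) {
    moved <- 0
    for (i in 2:(n_points - 1)) {
      target <- (P[i - 1, ] + P[i + 1, ]) / 2
      newp <- project(target)
      moved <- moved + sum((newp - P[i, ])^2)
      P[i, ] <- newp
    }
    if (moved < 1e-10) break
  }
  # drop collinear slack: keep endpoints and points where direction turns
  keep <- c(TRUE, vapply(2:(n_points - 1), function(i) {
    a <- P[i, ] - P[i - 1, ]; b <- P[i + 1, ] - P[i, ]
    cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    sqrt(sum(cr^2)) > 1e-9
  }, TRUE), TRUE)
  P[keep, , drop = FALSE]
}

#' Ligament length / strain / force sweep across flexion
#'
#' Computes the wrapping-path length of one bundle at every frame of a
#' flexion series, the engineering strain against the 0-degree reference
#' length, and the nonlinear spring force. The femoral attachment moves
#' with the femur (frame pose); obstacles are the native bones, plus the
#' implant meshes in implanted mode.
#'
#' @param bundle a [ligament_bundle()].
#' @param knee a [generate_knee()] result (meshes + frames).
#' @param kinematics a [flexion_series()]; must contain a 0-degree frame
#'   (strain reference).
#' @param implanted include implant meshes as obstacles?
#' @param component_pose femoral component pose (implanted mode), default
#'   identity.
#' @param wrap_obstacles logical: solve wrapping paths (TRUE) or use
#'   straight-line attachment distance (FALSE, fast screening).
#' @return a `ligament_sweep` data.frame: flexion_deg, length_mm, strain,
#'   force_N; attributes `bundle`, `reference_length_mm`, `mode`.
#' @export
sweep_lengths <- function(bundle, knee, kinematics = knee$kinematics,
                          implanted = FALSE, component_pose = rigid_pose(),
                          wrap_obstacles = TRUE) {
  if (!any(abs(kinematics$flexion_deg) < 1e-9))
    stop("kinematics lack a 0-degree frame; strain reference undefined")
  static_obs <- list(knee$tibia_mesh)
  n <- length(kinematics$flexion_deg)
  len <- numeric(n)
  for (i in seq_len(n)) {
    mf <- pose_to_matrix(kinematics$poses[[i]])
    fa <- drop(transform_points(mf, bundle$femoral_attachment))
    ta <- bundle$tibial_attachment
    if (wrap_obstacles) {
      obs <- c(list(transform_mesh(knee$femur_mesh, mf)), static_obs)
      if (implanted) {
        mc <- mf %*% pose_to_matrix(component_pose)
        obs <- c(obs, list(transform_mesh(knee$femoral_component_mesh, mc)))
      }
      len[i] <- wrapping_path_length(fa, ta, obs)$length_mm
    } else {
      len[i] <- sqrt(sum((fa - ta)^2))
    }
  }
  ref <- len[which(abs(kinematics$flexion_deg) < 1e-9)[1]]
  strain <- (len - ref) / ref
  df <- data.frame(flexion_deg = kinematics$flexion_deg,
                   length_mm = len, strain = strain,
                   force_N = ligament_force(strain, bundle$stiffness_k_N,
                                            bundle$eps1))
  attr(df, "bundle") <- bundle$name
  attr(df, "reference_length_mm") <- ref
  attr(df, "mode") <- if (implanted) "implanted" else "native"
  class(df) <- c("ligament_sweep", "data.frame")
  df
}

#' Rig tension protocol from per-bundle sweeps
#'
#' Applied tension per frame and bundle = side baseline + model force:
#' medial bundles (aMCL, pMCL) ride the 130 N baseline, the lateral bundle
#' (iLCL) the 100 N baseline. Slack frames apply the bare baseline.
#'
#' @param sweeps named list of `ligament_sweep`s (names aMCL/pMCL/iLCL).
#' @param baseline_medial_N,baseline_lateral_N side baselines (N).
#' @return data.frame: flexion_deg, bundle, length_mm, strain, force_N,
#'   baseline_N, applied_N.
#' @export
build_tension_protocol <- function(sweeps, baseline_medial_N = 130,
                                   baseline_lateral_N = 100) {
  stopifnot(length(sweeps) >= 1, !is.null(names(sweeps)))
  rows <- lapply(names(sweeps), function(nm) {
    sw <- sweeps[[nm]]
    base <- if (nm == "iLCL") baseline_lateral_N else baseline_medial_N
    data.frame(flexion_deg = sw$flexion_deg, bundle = nm,
               length_mm = sw$length_mm, strain = sw$strain,
               force_N = sw$force_N, baseline_N = base,
               applied_N = base + sw$force_N)
  })
  out <- do.call(rbind, rows)
  out[order(out$flexion_deg, out$bundle), ]
}
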