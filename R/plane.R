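#' Oriented plane in 3D
#'
#' @param point any point on the plane (mm).
#' @param normal plane normal; normalized internally.
#' @return an object of class `plane3d`.
#' @export
plane3d <- function(point, normal) {
  point <- as.numeric(point); normal <- as.numeric(normal)
  stopifnot(length(point) == 3, length(normal) == 3)
  n <- sqrt(sum(normal^2))
  if (n < 1e-12) stop("plane normal must be non-zero")
  structure(list(point = point, normal = normal / n), class = "plane3d")
}

#' @export
print.plane3d <- function(x, ...) {
  cat(sprintf("plane3d: point (%.3f, %.3f, %.3f), normal (%.4f, %.4f, %.4f)\n",
              x$point[1], x$point[2], x$point[3],
              x$normal[1], x$normal[2], x$normal[3]))
  invisible(x)
}

#' Signed point-to-plane distance
#'
#' Positive on the side the normal points to.
#'
#' @param points n x 3 matrix or length-3 vector.
#' @param plane a [plane3d()].
#' @return numeric vector of signed distances (mm).
#' @export
point_plane_distance <- function(points, plane) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  drop(sweep(points, 2, plane$point, "-") %*% plane$normal)
}

#' Orthonormal in-plane basis (u, v) completing the plane normal
#'
#' Deterministic: u is the normalized projection of the global axis least
#' aligned with the normal.
#' @param plane a [plane3d()].
#' @return list with unit vectors `u`, `v` (u x v = normal).
#' @keywords internal
plane_basis <- function(plane) {
  n <- plane$normal
  ref <- diag(3)[, which.min(abs(n))]
  u <- ref - sum(ref * n) * n
  u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2],   # v = n x u, so that u x v = n
         n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  list(u = u, v = v)
}

#' Planar contour: polygon loops living on a 3D plane
#'
#' @param plane a [plane3d()].
#' @param loops list of k x 2 matrices of in-plane (u, v) coordinates; the
#'   outer loop counter-clockwise.
#' @param basis optional basis from [plane_basis()] (recomputed otherwise).
#' @return an object of class `planar_contour`.
#' @export
planar_contour <- function(plane, loops, basis = plane_basis(plane)) {
  stopifnot(inherits(plane, "plane3d"), is.list(loops))
  loops <- lapply(loops, function(L) {
    L <- as.matrix(L)
    stopifnot(ncol(L) == 2, nrow(L) >= 3)
    if (shoelace_area(L) < 0) L <- L[nrow(L):1, , drop = FALSE]
    L
  })
  structure(list(plane = plane, loops = loops, basis = basis),
            class = "planar_contour")
}

#' @export
print.planar_contour <- function(x, ...) {
  cat(sprintf("planar_contour: %d loop(s), total area %.3f mm^2\n",
              length(x$loops), contour_area(x)))
  invisible(x)
}

#' Total enclosed area of a contour (sum over loops)
#' @param contour a [planar_contour()].
#' @return area in mm^2.
#' @export
contour_area <- function(contour) {
  sum(vapply(contour$loops, function(L) abs(shoelace_area(L)), 0))
}

#' Map in-plane 2D coordinates back to 3D
#' @keywords internal
contour_points_3d <- function(contour, pts2d) {
  b <- contour$basis
  sweep(outer(pts2d[, 1], b$u) + outer(pts2d[, 2], b$v), 2,
        contour$plane$point, "+")
}

#' Cross-section of a closed mesh with a plane
#'
#' Intersects every triangle with the plane and chains the resulting
#' segments into closed loops, returned as 2D polygons in the plane's
#' in-plane basis. Degenerate contacts (vertices exactly on the plane) are
#' handled by nudging the plane by 1e-9 mm.
#'
#' @param mesh a watertight [tri_mesh()].
#' @param plane a [plane3d()].
#' @return a [planar_contour()]; zero loops when the plane misses the mesh.
#' @export
cut_mesh_by_plane <- function(mesh, plane) {
  v <- mesh$vertices
  d <- point_plane_distance(v, plane)
  if (any(abs(d) < 1e-9)) {  # avoid exact vertex contact
    plane <- plane3d(plane$point + plane$normal * 1e-9, plane$normal)
    d <- point_plane_distance(v, plane)
  }
  f <- mesh$faces
  s <- matrix(d[f] > 0, ncol = 3)
  nump <- rowSums(s)
  cross <- which(nump == 1 | nump == 2)
  if (length(cross) == 0) return(planar_contour(plane, list()))

  seg_a <- matrix(0, length(cross), 3)
  seg_b <- matrix(0, length(cross), 3)
  for (ii in seq_along(cross)) {
    tri <- f[cross[ii], ]
    dd <- d[tri]
    pos <- dd > 0
    solo <- if (sum(pos) == 1) which(pos) else which(!pos)
    o <- tri[solo]; p <- tri[-solo]
    t1 <- dd[solo] / (dd[solo] - dd[-solo][1])
    t2 <- dd[solo] / (dd[solo] - dd[-solo][2])
    q1 <- v[o, ] + t1 * (v[p[1], ] - v[o, ])
    q2 <- v[o, ] + t2 * (v[p[2], ] - v[o, ])
    # orient segment so loops come out with consistent winding:
    # keep (q1, q2) if the solo vertex is on the positive side
    if (sum(pos) == 1) { seg_a[ii, ] <- q1; seg_b[ii, ] <- q2 }
    else               { seg_a[ii, ] <- q2; seg_b[ii, ] <- q1 }
  }

  b <- plane_basis(plane)
  to2d <- function(p3) {
    p0 <- sweep(p3, 2, plane$point, "-")
    cbind(p0 %*% b$u, p0 %*% b$v)
  }
  a2 <- to2d(seg_a); b2 <- to2d(seg_b)

  # chain segments into loops; segments are undirected, so walk the
  # endpoint-incidence structure
  key <- function(p) paste(round(p[, 1], 6), round(p[, 2], 6))
  ka <- key(a2); kb <- key(b2)
  keys <- unique(c(ka, kb))
  ia <- match(ka, keys); ib <- match(kb, keys)
  nseg <- length(ia)
  incid <- vector("list", length(keys))
  for (s in seq_len(nseg)) {
    incid[[ia[s]]] <- c(incid[[ia[s]]], s)
    incid[[ib[s]]] <- c(incid[[ib[s]]], s)
  }
  pts <- rbind(a2, b2)  # point of segment s: start = s, end = nseg + s
  used <- rep(FALSE, nseg)
  loops <- list()
  for (start in seq_len(nseg)) {
    if (used[start]) next
    used[start] <- TRUE
    idx_pts <- start            # walk from the start endpoint...
    cur_key <- ib[start]        # ...towards the end endpoint
    idx_pts <- c(idx_pts, nseg + start)
    closed <- FALSE
    repeat {
      cand <- incid[[cur_key]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0) {
        closed <- cur_key == ia[start]
        break
      }
      s <- cand[1]
      used[s] <- TRUE
      if (ia[s] == cur_key) { idx_pts <- c(idx_pts, nseg + s); cur_key <- ib[s] }
      else                  { idx_pts <- c(idx_pts, s);        cur_key <- ia[s] }
    }
    # the walk revisits the starting point as its last vertex; drop it
    n_pts <- length(idx_pts) - 1
    if (closed && n_pts >= 3)
      loops[[length(loops) + 1]] <- pts[idx_pts[seq_len(n_pts)], , drop = FALSE]
  }
  planar_contour(plane, loops, basis = b)
}
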