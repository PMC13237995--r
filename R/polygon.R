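#' Signed polygon area (shoelace)
#' @param p k x 2 matrix; positive for counter-clockwise loops.
#' @return signed area.
#' @keywords internal
shoelace_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

polygon_is_convex <- function(p, tol = 1e-9) {
  k <- nrow(p)
  a <- p[c(2:k, 1), ] - p
  b <- a[c(2:k, 1), ]
  cr <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  all(cr >= -tol * max(abs(cr), 1)) || all(cr <= tol * max(abs(cr), 1))
}

#' Point-in-polygon test (even-odd rule), vectorized over points
#' @keywords internal
points_in_polygon <- function(pts, poly) {
  x <- pts[, 1]; y <- pts[, 2]
  px <- poly[, 1]; py <- poly[, 2]
  k <- nrow(poly)
  inside <- rep(FALSE, length(x))
  j <- k
  for (i in 1:k) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Sutherland-Hodgman: clip `subject` (any simple polygon) by convex `clip`
clip_polygon_convex <- function(subject, clip) {
  if (shoelace_area(clip) < 0) clip <- clip[nrow(clip):1, , drop = FALSE]
  out <- subject
  k <- nrow(clip)
  for (i in 1:k) {
    if (nrow(out) == 0) return(out)
    a <- clip[i, ]; b <- clip[if (i == k) 1 else i + 1, ]
    e <- b - a
    inp <- out
    n <- nrow(inp)
    d <- e[1] * (inp[, 2] - a[2]) - e[2] * (inp[, 1] - a[1])  # >=0 inside (CCW clip)
    keep <- d >= 0
    res <- matrix(0, 0, 2)
    for (j in 1:n) {
      jn <- if (j == n) 1 else j + 1
      if (keep[j]) res <- rbind(res, inp[j, ])
      if (keep[j] != keep[jn]) {
        t <- d[j] / (d[j] - d[jn])
        res <- rbind(res, inp[j, ] + t * (inp[jn, ] - inp[j, ]))
      }
    }
    out <- res
  }
  out
}

contours_coplanar <- function(a, b, tol = 1e-6) {
  abs(sum(a$plane$normal * b$plane$normal)) > 1 - 1e-6 &&
    abs(point_plane_distance(b$plane$point, a$plane)) < tol
}

# express b's outer loop in a's in-plane basis
loop_in_basis_of <- function(a, b) {
  p3 <- contour_points_3d(b, b$loops[[1]])
  p0 <- sweep(p3, 2, a$plane$point, "-")
  cbind(p0 %*% a$basis$u, p0 %*% a$basis$v)
}

outer_loop <- function(contour, what) {
  if (length(contour$loops) == 0) stop(what, " contour is empty")
  if (length(contour$loops) > 1)
    stop(what, " contour has holes/multiple loops; single-loop contours required")
  contour$loops[[1]]
}

#' Overlap and difference areas of two coplanar contours
#'
#' Computes the intersection area and the two set differences of the regions
#' enclosed by two single-loop coplanar contours. At least one of the two
#' polygons must be convex (true of resection cross-sections and implant
#' undersides in this package); the intersection is obtained by
#' Sutherland--Hodgman clipping against the convex one.
#'
#' @param a,b [planar_contour()] objects on the same plane.
#' @return list with `overlap_mm2`, `a_minus_b_mm2`, `b_minus_a_mm2`.
#' @export
polygon_areas <- function(a, b) {
  if (!contours_coplanar(a, b)) stop("contours are not coplanar")
  pa <- outer_loop(a, "first")
  pb <- loop_in_basis_of(a, b)
  if (shoelace_area(pb) < 0) pb <- pb[nrow(pb):1, , drop = FALSE]
  area_a <- abs(shoelace_area(pa))
  area_b <- abs(shoelace_area(pb))
  if (polygon_is_convex(pb)) {
    inter <- clip_polygon_convex(pa, pb)
  } else if (polygon_is_convex(pa)) {
    inter <- clip_polygon_convex(pb, pa)
  } else {
    stop("polygon_areas requires at least one convex contour")
  }
  ov <- if (nrow(inter) >= 3) abs(shoelace_area(inter)) else 0
  list(overlap_mm2 = ov,
       a_minus_b_mm2 = max(0, area_a - ov),
       b_minus_a_mm2 = max(0, area_b - ov))
}

# perpendicular distance from points to a polygon boundary (min over edges)
points_to_polyline_distance <- function(pts, poly) {
  k <- nrow(poly)
  res <- rep(Inf, nrow(pts))
  for (i in 1:k) {
    a <- poly[i, ]; b <- poly[if (i == k) 1 else i + 1, ]
    e <- b - a
    L2 <- sum(e^2)
    t <- if (L2 == 0) rep(0, nrow(pts)) else
      pmin(1, pmax(0, ((pts[, 1] - a[1]) * e[1] + (pts[, 2] - a[2]) * e[2]) / L2))
    dx <- pts[, 1] - (a[1] + t * e[1])
    dy <- pts[, 2] - (a[2] + t * e[2])
    res <- pmin(res, sqrt(dx^2 + dy^2))
  }
  res
}

densify_loop <- function(poly, step) {
  k <- nrow(poly)
  out <- vector("list", k)
  for (i in 1:k) {
    a <- poly[i, ]; b <- poly[if (i == k) 1 else i + 1, ]
    n <- max(1L, ceiling(sqrt(sum((b - a)^2)) / step))
    t <- seq(0, 1, length.out = n + 1)[1:n]
    out[[i]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

#' Maximum overhang distance of an implant contour beyond a resection contour
#'
#' Distance from the farthest implant-boundary point lying outside the
#' resection region to the resection boundary; 0 when the implant is fully
#' contained. Boundaries are densified to `step` mm before measuring.
#'
#' @param implant,resection coplanar [planar_contour()] objects.
#' @param step boundary sampling step (mm).
#' @return overhang distance (mm).
#' @export
max_overhang_distance <- function(implant, resection, step = 0.05) {
  if (!contours_coplanar(implant, resection)) stop("contours are not coplanar")
  pr <- outer_loop(resection, "resection")
  pi2 <- loop_in_basis_of(resection, implant)
  bd <- densify_loop(pi2, step)
  outside <- !points_in_polygon(bd, pr)
  if (!any(outside)) return(0)
  max(points_to_polyline_distance(bd[outside, , drop = FALSE], pr))
}
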