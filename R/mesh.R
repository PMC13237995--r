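#' Triangle mesh container
#'
#' Minimal closed-surface triangle mesh used for bones and implants.
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices, consistently
#'   oriented (outward normals, counter-clockwise seen from outside).
#' @param frame_name name of the anatomical frame the coordinates live in.
#' @return an object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, frame_name = "unspecified") {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(faces), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            min(faces) >= 1, max(faces) <= nrow(vertices))
  structure(list(vertices = vertices, faces = faces, frame_name = frame_name),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces, frame '%s'\n",
              nrow(x$vertices), nrow(x$faces), x$frame_name))
  invisible(x)
}

#' Check that every edge of a mesh is shared by exactly two faces
#'
#' A mesh passing this check bounds a closed volume (possibly with several
#' connected components, e.g. the two femoral condyles).
#'
#' @param mesh a [tri_mesh()].
#' @return logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh a [tri_mesh()].
#' @param m 4x4 homogeneous transform.
#' @return the transformed [tri_mesh()].
#' @export
transform_mesh <- function(mesh, m) {
  mesh$vertices <- transform_points(m, mesh$vertices)
  mesh
}

#' Concatenate meshes into one (disjoint components allowed)
#' @param ... `tri_mesh` objects sharing a frame.
#' @return a single [tri_mesh()].
#' @export
merge_meshes <- function(...) {
  ms <- list(...)
  v <- do.call(rbind, lapply(ms, `[[`, "vertices"))
  off <- cumsum(c(0, vapply(ms, function(m) nrow(m$vertices), 0)))
  f <- do.call(rbind, Map(function(m, o) m$faces + o, ms, off[seq_along(ms)]))
  tri_mesh(v, f, ms[[1]]$frame_name)
}

mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
      a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
      a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' UV-sphere mesh
#'
#' @param center length-3 center (mm).
#' @param radius sphere radius (mm).
#' @param n_lat,n_lon latitude bands / longitude segments.
#' @param frame_name frame label.
#' @return a watertight [tri_mesh()] with outward normals.
#' @export
mesh_sphere <- function(center = c(0, 0, 0), radius = 1,
                        n_lat = 16, n_lon = 32, frame_name = "unspecified") {
  stopifnot(radius > 0, n_lat >= 3, n_lon >= 3)
  # interior ring vertices + two poles
  th <- seq(0, pi, length.out = n_lat + 1)[2:n_lat]          # polar angle
  ph <- seq(0, 2 * pi, length.out = n_lon + 1)[1:n_lon]
  grid <- expand.grid(ph = ph, th = th)
  ring <- cbind(sin(grid$th) * cos(grid$ph),
                sin(grid$th) * sin(grid$ph),
                cos(grid$th))
  v <- rbind(c(0, 0, 1), ring, c(0, 0, -1)) * radius
  v <- sweep(v, 2, center, "+")
  idx <- function(i, j) 1 + (i - 1) * n_lon + ((j - 1) %% n_lon) + 1  # ring i (1..n_lat-1), lon j
  top <- 1L
  bot <- nrow(v)
  f <- vector("list", 2 * n_lon * (n_lat - 1))
  k <- 0
  for (j in 1:n_lon) {                     # polar caps
    k <- k + 1; f[[k]] <- c(top, idx(1, j), idx(1, j + 1))
    k <- k + 1; f[[k]] <- c(bot, idx(n_lat - 1, j + 1), idx(n_lat - 1, j))
  }
  if (n_lat > 2) {
    for (i in 1:(n_lat - 2)) for (j in 1:n_lon) {
      a <- idx(i, j); b <- idx(i, j + 1); cc <- idx(i + 1, j); d <- idx(i + 1, j + 1)
      k <- k + 1; f[[k]] <- c(a, cc, b)
      k <- k + 1; f[[k]] <- c(b, cc, d)
    }
  }
  m <- tri_mesh(v, do.call(rbind, f), frame_name)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Prism mesh: a convex planar polygon extruded along z
#'
#' Caps are triangle fans around an added center vertex; the top center can
#' be depressed to model a slightly dished articular surface.
#'
#' @param poly2d k x 2 matrix, convex polygon, counter-clockwise.
#' @param z_bottom,z_top extrusion limits (mm), `z_bottom < z_top`.
#' @param dish_mm depression of the top-cap center vertex (mm, >= 0).
#' @param frame_name frame label.
#' @return a watertight [tri_mesh()].
#' @export
mesh_prism <- function(poly2d, z_bottom, z_top, dish_mm = 0,
                       frame_name = "unspecified") {
  poly2d <- as.matrix(poly2d)
  k <- nrow(poly2d)
  stopifnot(k >= 3, z_bottom < z_top, dish_mm >= 0)
  ctr <- colMeans(poly2d)
  v <- rbind(cbind(poly2d, z_bottom),                 # 1..k
             cbind(poly2d, z_top),                    # k+1..2k
             c(ctr, z_bottom),                        # 2k+1
             c(ctr, z_top - dish_mm))                 # 2k+2
  cb <- 2L * k + 1L; ct <- 2L * k + 2L
  nxt <- c(2:k, 1)
  f <- rbind(
    cbind(cb, nxt, 1:k),                              # bottom fan (faces -z)
    cbind(ct, k + (1:k), k + nxt),                    # top fan (faces +z)
    cbind(1:k, nxt, k + nxt),                         # side quads
    cbind(1:k, k + nxt, k + (1:k))
  )
  m <- tri_mesh(v, f, frame_name)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Regular 2D ellipse polygon
#' @param a,b semi-axes (mm); `n` vertex count.
#' @return n x 2 counter-clockwise polygon matrix.
#' @export
ellipse_polygon <- function(a, b, n = 64) {
  t <- seq(0, 2 * pi, length.out = n + 1)[1:n]
  cbind(a * cos(t), b * sin(t))
}

#' Write a mesh as ASCII STL
#' @param mesh a [tri_mesh()].
#' @param path output file path.
#' @param name solid name recorded in the file.
#' @export
write_stl <- function(mesh, path, name = "mesh") {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  block <- sprintf(
    "facet normal %.9g %.9g %.9g\n outer loop\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n  vertex %.9g %.9g %.9g\n endloop\nendfacet",
    n[, 1], n[, 2], n[, 3],
    a[, 1], a[, 2], a[, 3], b[, 1], b[, 2], b[, 3], cc[, 1], cc[, 2], cc[, 3])
  writeLines(block, con)
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' Read an ASCII STL file
#'
#' Coincident vertices are merged exactly (string-keyed), so a watertight
#' solid written by [write_stl()] reads back watertight.
#'
#' @param path STL file path.
#' @param frame_name frame label to attach.
#' @return a [tri_mesh()].
#' @export
read_stl <- function(path, frame_name = "unspecified") {
  lines <- readLines(path)
  vl <- grep("^\\s*vertex", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0)
    stop("not a valid ASCII STL file: ", path)
  xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(p)
    as.numeric(p[2:4])))
  key <- apply(xyz, 1, function(r) paste(sprintf("%.9g", r), collapse = ","))
  uk <- !duplicated(key)
  vid <- match(key, key[uk])
  tri_mesh(xyz[uk, , drop = FALSE], matrix(vid, ncol = 3, byrow = TRUE),
           frame_name)
}
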