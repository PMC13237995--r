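# Low-level mesh queries shared by the ligament wrapping solver.

mesh_triangle_arrays <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  list(a = a,
       e1 = v[f[, 2], , drop = FALSE] - a,
       e2 = v[f[, 3], , drop = FALSE] - a)
}

# Moeller-Trumbore, one segment against all triangles of a prepared mesh
segment_hits_triangles <- function(p, q, tri, tol = 1e-9) {
  d <- q - p
  L <- sqrt(sum(d^2))
  if (L < tol) return(FALSE)
  h <- cbind(d[2] * tri$e2[, 3] - d[3] * tri$e2[, 2],
             d[3] * tri$e2[, 1] - d[1] * tri$e2[, 3],
             d[1] * tri$e2[, 2] - d[2] * tri$e2[, 1])
  det <- rowSums(tri$e1 * h)
  ok <- abs(det) > tol
  if (!any(ok)) return(FALSE)
  s <- matrix(p, nrow(tri$a), 3, byrow = TRUE) - tri$a
  u <- rowSums(s * h) / det
  ok <- ok & u >= -tol & u <= 1 + tol
  if (!any(ok)) return(FALSE)
  qv <- cbind(s[, 2] * tri$e1[, 3] - s[, 3] * tri$e1[, 2],
              s[, 3] * tri$e1[, 1] - s[, 1] * tri$e1[, 3],
              s[, 1] * tri$e1[, 2] - s[, 2] * tri$e1[, 1])
  vv <- (qv[, 1] * d[1] + qv[, 2] * d[2] + qv[, 3] * d[3]) / det
  ok <- ok & vv >= -tol & (u + vv) <= 1 + tol
  if (!any(ok)) return(FALSE)
  t <- rowSums(tri$e2 * qv) / det
  any(ok & t > 1e-7 & t < 1 - 1e-7)
}

segment_clears <- function(p, q, tris) {
  for (tri in tris) if (segment_hits_triangles(p, q, tri)) return(FALSE)
  TRUE
}

# parity test: is a point inside a closed mesh?
point_in_mesh <- function(p, tri) {
  d <- c(0.57735027, 0.51449576, 0.63245553)  # irregular ray direction
  h <- cbind(d[2] * tri$e2[, 3] - d[3] * tri$e2[, 2],
             d[3] * tri$e2[, 1] - d[1] * tri$e2[, 3],
             d[1] * tri$e2[, 2] - d[2] * tri$e2[, 1])
  det <- rowSums(tri$e1 * h)
  ok <- abs(det) > 1e-12
  s <- matrix(p, nrow(tri$a), 3, byrow = TRUE) - tri$a
  u <- rowSums(s * h) / det
  ok <- ok & u >= 0 & u <= 1
  qv <- cbind(s[, 2] * tri$e1[, 3] - s[, 3] * tri$e1[, 2],
              s[, 3] * tri$e1[, 1] - s[, 1] * tri$e1[, 3],
              s[, 1] * tri$e1[, 2] - s[, 2] * tri$e1[, 1])
  vv <- (qv[, 1] * d[1] + qv[, 2] * d[2] + qv[, 3] * d[3]) / det
  ok <- ok & vv >= 0 & (u + vv) <= 1
  t <- rowSums(tri$e2 * qv) / det
  sum(ok & t > 0) %% 2 == 1
}

# closest point on a triangle soup to p (Ericson's region test, vectorized
# over triangles); returns list(point, dist)
nearest_point_on_mesh <- function(p, tri) {
  a <- tri$a; ab <- tri$e1; ac <- tri$e2
  n <- nrow(a)
  pp <- matrix(p, n, 3, byrow = TRUE)
  ap <- pp - a
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  bp <- ap - ab
  d3 <- rowSums(ab * bp); d4 <- rowSums(ac * bp)
  cp <- ap - ac
  d5 <- rowSums(ab * cp); d6 <- rowSums(ac * cp)
  va <- d3 * d6 - d5 * d4
  vb <- d5 * d2 - d1 * d6
  vc <- d1 * d4 - d3 * d2
  # default: interior projection
  denom <- va + vb + vc
  denom[denom == 0] <- 1e-30
  v <- vb / denom; w <- vc / denom
  # region corrections
  reg_a <- d1 <= 0 & d2 <= 0
  reg_b <- d3 >= 0 & d4 <= d3
  reg_c <- d6 >= 0 & d5 <= d6
  reg_ab <- !reg_a & !reg_b & vc <= 0 & d1 >= 0 & d3 <= 0
  reg_ac <- !reg_a & !reg_c & vb <= 0 & d2 >= 0 & d6 <= 0
  reg_bc <- !reg_b & !reg_c & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0
  t_ab <- ifelse(d1 - d3 == 0, 0, d1 / (d1 - d3))
  t_ac <- ifelse(d2 - d6 == 0, 0, d2 / (d2 - d6))
  t_bc <- ifelse((d4 - d3) + (d5 - d6) == 0, 0,
                 (d4 - d3) / ((d4 - d3) + (d5 - d6)))
  v[reg_ab] <- t_ab[reg_ab]; w[reg_ab] <- 0
  v[reg_ac] <- 0;            w[reg_ac] <- t_ac[reg_ac]
  v[reg_bc] <- 1 - t_bc[reg_bc]; w[reg_bc] <- t_bc[reg_bc]
  v[reg_a] <- 0; w[reg_a] <- 0
  v[reg_b] <- 1; w[reg_b] <- 0
  v[reg_c] <- 0; w[reg_c] <- 1
  q <- a + v * ab + w * ac
  dd <- rowSums((pp - q)^2)
  i <- which.min(dd)
  list(point = q[i, ], dist = sqrt(dd[i]))
}

# unit outward vertex normals (area-weighted average of face normals)
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], ] - v[f[, 1], ]
  e2 <- v[f[, 3], ] - v[f[, 1], ]
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  vn <- matrix(0, nrow(v), 3)
  for (j in 1:3) {
    agg <- rowsum(fn, f[, j])
    ids <- as.integer(rownames(agg))
    vn[ids, ] <- vn[ids, ] + agg
  }
  len <- sqrt(rowSums(vn^2)); len[len == 0] <- 1
  vn / len
}

mesh_edges_unique <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}
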