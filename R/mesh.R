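#' Triangle surface meshes
#'
#' scaffem uses a minimal triangle-soup-with-shared-vertices representation:
#' a list with `vertices` (n x 3 numeric matrix, mm) and `faces` (m x 3
#' integer matrix, 1-based, counter-clockwise when seen from outside).
#'
#' @param vertices n x 3 numeric matrix of vertex coordinates (mm).
#' @param faces m x 3 integer matrix of 1-based vertex indices.
#' @return An object of class `scaffem_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3L) stop_invalid("vertices must be n x 3")
  if (nrow(faces) > 0 && (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop_invalid("face indices out of range")
  structure(list(vertices = vertices, faces = faces), class = "scaffem_mesh")
}

#' @export
print.scaffem_mesh <- function(x, ...) {
  cat(sprintf("<scaffem_mesh: %d vertices, %d triangles, watertight: %s>\n",
              nrow(x$vertices), nrow(x$faces), is_watertight(x)))
  invisible(x)
}

# undirected edge keys "a_b" with a < b, one per triangle edge instance
mesh_edge_keys <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  lo <- pmin(e[, 1], e[, 2])
  hi <- pmax(e[, 1], e[, 2])
  paste(lo, hi, sep = "_")
}

#' Is a triangle mesh watertight?
#'
#' A mesh is watertight (closed, 2-manifold along edges) when every undirected
#' edge is shared by exactly two triangles.
#'
#' @param mesh a [tri_mesh()].
#' @return logical scalar.
#' @export
is_watertight <- function(mesh) {
  if (nrow(mesh$faces) == 0) return(FALSE)
  all(table(mesh_edge_keys(mesh)) == 2L)
}

#' Euler characteristic V - E + F of a mesh
#' @param mesh a [tri_mesh()].
#' @return integer; 2 for a closed genus-0 surface.
#' @export
euler_characteristic <- function(mesh) {
  v <- length(unique(as.vector(mesh$faces)))
  e <- length(unique(mesh_edge_keys(mesh)))
  f <- nrow(mesh$faces)
  v - e + f
}

#' Enclosed volume of a closed mesh (divergence theorem)
#'
#' Sum of signed tetrahedron volumes det(v1, v2, v3)/6; positive for
#' outward-oriented closed surfaces.
#'
#' @param mesh a [tri_mesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  # scalar triple product a . (b x c)
  cx <- b[, 2] * c3[, 3] - b[, 3] * c3[, 2]
  cy <- b[, 3] * c3[, 1] - b[, 1] * c3[, 3]
  cz <- b[, 1] * c3[, 2] - b[, 2] * c3[, 1]
  sum(a[, 1] * cx + a[, 2] * cy + a[, 3] * cz) / 6
}

# fixed, irrational-ish ray direction avoids hitting edges/vertices of
# axis-aligned geometry exactly
.ray_dir <- c(0.2403254699, 0.5287519196, 0.8140366262)

#' Point-in-mesh test by ray casting
#'
#' Casts a fixed-direction ray from each query point and counts triangle
#' crossings (Moller-Trumbore, vectorized over points per triangle); odd
#' parity means inside. Robust for watertight meshes away from degenerate
#' grazing configurations.
#'
#' @param points n x 3 matrix of query points.
#' @param mesh a watertight [tri_mesh()].
#' @return logical vector of length n.
#' @export
points_in_mesh <- function(points, mesh) {
  p <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(p)
  crossings <- integer(n)
  v <- mesh$vertices
  f <- mesh$faces
  d <- .ray_dir
  eps <- 1e-12
  for (i in seq_len(nrow(f))) {
    v0 <- v[f[i, 1], ]
    e1 <- v[f[i, 2], ] - v0
    e2 <- v[f[i, 3], ] - v0
    h <- c(d[2] * e2[3] - d[3] * e2[2],
           d[3] * e2[1] - d[1] * e2[3],
           d[1] * e2[2] - d[2] * e2[1])
    a <- sum(e1 * h)
    if (abs(a) < eps) next
    s1 <- p[, 1] - v0[1]; s2 <- p[, 2] - v0[2]; s3 <- p[, 3] - v0[3]
    u <- (s1 * h[1] + s2 * h[2] + s3 * h[3]) / a
    q1 <- s2 * e1[3] - s3 * e1[2]
    q2 <- s3 * e1[1] - s1 * e1[3]
    q3 <- s1 * e1[2] - s2 * e1[1]
    vv <- (d[1] * q1 + d[2] * q2 + d[3] * q3) / a
    tt <- (e2[1] * q1 + e2[2] * q2 + e2[3] * q3) / a
    hit <- u >= 0 & u <= 1 & vv >= 0 & (u + vv) <= 1 & tt > 0
    crossings[hit] <- crossings[hit] + 1L
  }
  crossings %% 2L == 1L
}

#' Unsigned distance from points to a triangle mesh surface
#'
#' Exact point-triangle distances, minimized over all triangles (vectorized
#' over points per triangle). Intended for modest mesh sizes (projection of
#' grid-shell nodes, test oracles).
#'
#' @param points n x 3 matrix.
#' @param mesh a [tri_mesh()].
#' @return list with `distance` (length n) and `closest` (n x 3 matrix of
#'   closest surface points).
#' @export
mesh_surface_distance <- function(points, mesh) {
  p <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(p)
  best <- rep(Inf, n)
  closest <- matrix(NA_real_, n, 3)
  v <- mesh$vertices
  f <- mesh$faces
  for (i in seq_len(nrow(f))) {
    res <- .point_triangle(p, v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ])
    better <- res$d2 < best
    if (any(better)) {
      best[better] <- res$d2[better]
      closest[better, ] <- res$cp[better, , drop = FALSE]
    }
  }
  list(distance = sqrt(best), closest = closest)
}

# squared distance + closest point from many points to one triangle
# (Eberly's region decomposition, vectorized)
.point_triangle <- function(p, a, b, c3) {
  ab <- b - a; ac <- c3 - a
  ap1 <- p[, 1] - a[1]; ap2 <- p[, 2] - a[2]; ap3 <- p[, 3] - a[3]
  d1 <- ab[1] * ap1 + ab[2] * ap2 + ab[3] * ap3
  d2 <- ac[1] * ap1 + ac[2] * ap2 + ac[3] * ap3
  bp1 <- p[, 1] - b[1]; bp2 <- p[, 2] - b[2]; bp3 <- p[, 3] - b[3]
  d3 <- ab[1] * bp1 + ab[2] * bp2 + ab[3] * bp3
  d4 <- ac[1] * bp1 + ac[2] * bp2 + ac[3] * bp3
  cp1 <- p[, 1] - c3[1]; cp2 <- p[, 2] - c3[2]; cp3 <- p[, 3] - c3[3]
  d5 <- ab[1] * cp1 + ab[2] * cp2 + ab[3] * cp3
  d6 <- ac[1] * cp1 + ac[2] * cp2 + ac[3] * cp3

  n <- nrow(p)
  u <- numeric(n); w <- numeric(n)  # barycentric: cp = a + u*ab + w*ac
  done <- rep(FALSE, n)

  reg <- d1 <= 0 & d2 <= 0                     # vertex a
  u[reg] <- 0; w[reg] <- 0; done <- done | reg
  reg <- !done & d3 >= 0 & d4 <= d3            # vertex b
  u[reg] <- 1; w[reg] <- 0; done <- done | reg
  reg <- !done & d6 >= 0 & d5 <= d6            # vertex c
  u[reg] <- 0; w[reg] <- 1; done <- done | reg
  vc <- d1 * d4 - d3 * d2
  reg <- !done & vc <= 0 & d1 >= 0 & d3 <= 0   # edge ab
  t1 <- d1 / (d1 - d3)
  u[reg] <- t1[reg]; w[reg] <- 0; done <- done | reg
  vb <- d5 * d2 - d1 * d6
  reg <- !done & vb <= 0 & d2 >= 0 & d6 <= 0   # edge ac
  t2 <- d2 / (d2 - d6)
  u[reg] <- 0; w[reg] <- t2[reg]; done <- done | reg
  va <- d3 * d6 - d5 * d4
  reg <- !done & va <= 0 & (d4 - d3) >= 0 & (d5 - d6) >= 0  # edge bc
  t3 <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
  u[reg] <- 1 - t3[reg]; w[reg] <- t3[reg]; done <- done | reg
  reg <- !done                                  # interior
  denom <- va + vb + vc
  u[reg] <- (vb / denom)[reg]
  w[reg] <- (vc / denom)[reg]

  cpx <- a[1] + u * ab[1] + w * ac[1]
  cpy <- a[2] + u * ab[2] + w * ac[2]
  cpz <- a[3] + u * ab[3] + w * ac[3]
  dx <- p[, 1] - cpx; dy <- p[, 2] - cpy; dz <- p[, 3] - cpz
  list(d2 = dx * dx + dy * dy + dz * dz, cp = cbind(cpx, cpy, cpz))
}

#' Axis-aligned bounding box of a mesh
#' @param mesh a [tri_mesh()].
#' @return 2 x 3 matrix: row 1 minima, row 2 maxima.
#' @export
mesh_bbox <- function(mesh) {
  rbind(apply(mesh$vertices, 2, min), apply(mesh$vertices, 2, max))
}
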