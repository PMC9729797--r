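# Synthetic geometry fixtures: a parametric mandible-segment defect
# surrogate and analytic solver benchmarks. Everything is deterministic for
# fixed parameters; the seed is recorded so downstream artifacts can cite it.

# rounded-rectangle cross-section polygon in the (y, z) plane, CCW seen from
# +x, fixed vertex count 4*(narc+1)
.section_polygon <- function(width, height, fillet, narc = 4) {
  wy <- width / 2; hz <- height / 2
  r <- min(fillet, 0.49 * min(width, height))
  cy <- wy - r; cz <- hz - r
  corners <- rbind(c(cy, cz, 0), c(-cy, cz, 90), c(-cy, -cz, 180), c(cy, -cz, 270))
  pts <- NULL
  for (k in 1:4) {
    th <- (corners[k, 3] + seq(0, 90, length.out = narc + 1)) * pi / 180
    pts <- rbind(pts, cbind(corners[k, 1] + r * cos(th),
                            corners[k, 2] + r * sin(th)))
  }
  pts
}

# signed distance (2D) to the rounded rectangle; negative inside
.section_sdf <- function(y, z, width, height, fillet) {
  wy <- width / 2; hz <- height / 2
  r <- min(fillet, 0.49 * min(width, height))
  qy <- abs(y) - (wy - r)
  qz <- abs(z) - (hz - r)
  my <- pmax(qy, 0); mz <- pmax(qz, 0)
  sqrt(my^2 + mz^2) + pmin(pmax(qy, qz), 0) - r
}

# lateral bowing of the centreline: pure shear in y, volume-preserving
.bow <- function(x, curvature, span) curvature * x^2 / span

# swept closed surface between x-stations xs (each station gets the same
# polygon translated by the bow); returns tri_mesh with end caps
.sweep_mesh <- function(xs, poly, curvature, span) {
  np <- nrow(poly)
  ns <- length(xs)
  verts <- matrix(0, ns * np + 2, 3)
  for (i in seq_len(ns)) {
    rows <- (i - 1) * np + seq_len(np)
    verts[rows, 1] <- xs[i]
    verts[rows, 2] <- poly[, 1] + .bow(xs[i], curvature, span)
    verts[rows, 3] <- poly[, 2]
  }
  c1 <- ns * np + 1L  # cap centre at x = xs[1]
  c2 <- ns * np + 2L
  verts[c1, ] <- c(xs[1], .bow(xs[1], curvature, span), 0)
  verts[c2, ] <- c(xs[ns], .bow(xs[ns], curvature, span), 0)
  faces <- NULL
  nxt <- c(seq_len(np - 1) + 1L, 1L)
  for (i in seq_len(ns - 1)) {
    a <- (i - 1) * np + seq_len(np)
    b <- a[nxt]
    c3 <- i * np + seq_len(np)
    d <- c3[nxt]
    # polygon is CCW seen from +x; outward side normals need (a, d, b), (a, c, d)
    faces <- rbind(faces, cbind(a, b, d), cbind(a, d, c3))
  }
  first <- seq_len(np)
  last <- (ns - 1) * np + seq_len(np)
  faces <- rbind(faces,
                 cbind(c1, first[nxt], first),   # -x cap faces -x
                 cbind(c2, last, last[nxt]))     # +x cap faces +x
  m <- tri_mesh(verts, faces)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Synthetic segmental-defect fixture
#'
#' Generates a curved-prism surrogate of a mandibular body segment with a
#' missing middle section: a swept rounded-rectangle prism of total length
#' `span_mm + 2 * stump_mm`, bowed laterally by `curvature`. The middle
#' `span_mm` is the defect (implant + graft) region; the two ends are
#' residual-bone stumps carrying the cut planes, occlusal (bite) nodes,
#' condyle (support) nodes and eight muscle attachment sites per side.
#'
#' The geometry is deterministic for fixed parameters; `seed` is recorded in
#' the fixture (and in pipeline logs) so runs can be reproduced bit for bit.
#'
#' @param span_mm defect length along x (mm); must be at least 3 unit-cell
#'   pitches of the default 5 mm pore lattice.
#' @param height_mm section height (z, mm).
#' @param width_mm section width (y, mm).
#' @param curvature dimensionless lateral bowing (0 = straight).
#' @param seed non-negative integer, recorded for provenance.
#' @param stump_mm residual-bone length on each side (mm).
#' @param fillet_mm corner fillet radius of the section (mm).
#' @return a `scaffem_fixture` list: `outer_surface`, `defect_region`
#'   ([tri_mesh()]s), `stump_faces` (list `neg`, `pos` of outer-surface
#'   vertex indices on the cut planes), `occlusal_nodes`, `condyle_nodes`,
#'   `muscle_sites` (data.frame name/side/point/direction), `seed`, `params`.
#' @export
make_defect_fixture <- function(span_mm = 40, height_mm = 20, width_mm = 10,
                                curvature = 0.15, seed = 42,
                                stump_mm = 10, fillet_mm = 1.5) {
  if (any(c(span_mm, height_mm, width_mm, stump_mm) <= 0))
    stop_invalid("degenerate fixture dimensions (all must be > 0)")
  if (seed < 0 || seed != round(seed)) stop_invalid("seed must be an integer >= 0")
  pitch <- 5 / sqrt(2) * 2  # unit-cell pitch of the default 5 mm pore lattice
  if (span_mm < 3 * 5) stop_invalid("span_mm must be >= 3 unit-cell pitches")

  poly <- .section_polygon(width_mm, height_mm, fillet_mm)
  L <- span_mm + 2 * stump_mm
  half_span <- span_mm / 2
  dx_target <- 2.5
  seg <- function(a, b) {
    n <- max(2L, ceiling((b - a) / dx_target) + 1L)
    seq(a, b, length.out = n)
  }
  xs <- unique(c(seg(-L / 2, -half_span), seg(-half_span, half_span),
                 seg(half_span, L / 2)))
  outer <- .sweep_mesh(xs, poly, curvature, span_mm)
  xs_def <- xs[xs >= -half_span - 1e-9 & xs <= half_span + 1e-9]
  defect <- .sweep_mesh(xs_def, poly, curvature, span_mm)

  v <- outer$vertices
  eps <- 1e-9
  stump_neg <- which(abs(v[, 1] + half_span) < eps)
  stump_pos <- which(abs(v[, 1] - half_span) < eps)
  condyle <- which(abs(abs(v[, 1]) - L / 2) < eps)
  top_z <- max(v[, 3])
  occl <- which(v[, 3] > top_z - eps &
                  v[, 1] > half_span + eps & v[, 1] < half_span + 0.6 * stump_mm)
  if (!length(occl))  # very short stumps: take the closest top ring
    occl <- which(v[, 3] > top_z - eps & v[, 1] > half_span + eps)

  dirs <- default_muscle_directions()
  frc <- default_muscle_forces()
  sites <- merge(frc, dirs, by = c("name", "side"), sort = FALSE)
  # attachment points: staggered along each stump's lateral faces
  n8 <- 8
  att <- function(side) {
    sgn <- if (side == "left") -1 else 1
    xc <- sgn * (L / 2 - stump_mm * seq(0.15, 0.85, length.out = n8))
    yside <- rep(c(1, -1), length.out = n8) * (width_mm / 2)
    zc <- height_mm * rep(c(0.25, -0.05, 0.2, -0.15), 2)
    cbind(xc, yside + .bow(xc, curvature, span_mm), zc)
  }
  pts <- rbind(att("left"), att("right"))
  ord <- order(match(sites$side, c("left", "right")))
  sites <- sites[ord, ]
  sites$px <- pts[, 1]; sites$py <- pts[, 2]; sites$pz <- pts[, 3]

  structure(list(
    outer_surface = outer, defect_region = defect,
    stump_faces = list(neg = stump_neg, pos = stump_pos),
    occlusal_nodes = occl, condyle_nodes = condyle,
    muscle_sites = sites, seed = as.integer(seed),
    params = list(span = span_mm, height = height_mm, width = width_mm,
                  curvature = curvature, stump = stump_mm, fillet = fillet_mm,
                  length = L)
  ), class = "scaffem_fixture")
}

#' Analytic inside test for fixture geometry
#'
#' Exact point-membership for the parametric swept prism, used for fast
#' voxel classification (the generic mesh-based test [points_in_mesh()] is
#' the independent oracle).
#'
#' @param fixture a [make_defect_fixture()].
#' @param points n x 3 matrix.
#' @param region `"outer"` (whole prism) or `"defect"` (middle section).
#' @return logical vector.
#' @export
fixture_inside <- function(fixture, points, region = c("outer", "defect")) {
  region <- match.arg(region)
  p <- matrix(as.numeric(points), ncol = 3)
  pr <- fixture$params
  xlim <- if (region == "outer") pr$length / 2 else pr$span / 2
  sd <- .section_sdf(p[, 2] - .bow(p[, 1], pr$curvature, pr$span), p[, 3],
                     pr$width, pr$height, pr$fillet)
  abs(p[, 1]) <= xlim & sd <= 0
}

# signed 2D lateral-wall distance (negative inside); used for the cortical
# shell classification in the pipeline
fixture_wall_depth <- function(fixture, points) {
  p <- matrix(as.numeric(points), ncol = 3)
  pr <- fixture$params
  -.section_sdf(p[, 2] - .bow(p[, 1], pr$curvature, pr$span), p[, 3],
                pr$width, pr$height, pr$fillet)
}

#' Slender cantilever benchmark model
#'
#' A straight chain of beam elements along x, clamped at one end, with a
#' unit transverse tip load (-z). Closed-form Euler-Bernoulli tip deflection
#' is `P L^3 / (3 E I)` with `I = pi d^4 / 64`.
#'
#' @param length_mm,diameter_mm beam length and diameter (mm);
#'   `length/diameter >= 20` (slender) is required.
#' @param E Young's modulus (MPa).
#' @param n_elems number of elements along the span.
#' @param tip_load transverse load at the tip (N, along -z).
#' @return an (unassembled) [fe_model()].
#' @export
make_cantilever_benchmark <- function(length_mm = 100, diameter_mm = 2,
                                      E = 110000, n_elems = 20, tip_load = 1) {
  if (length_mm <= 0 || diameter_mm <= 0 || E <= 0)
    stop_invalid("cantilever parameters must be positive")
  if (length_mm / diameter_mm < 20)
    stop_invalid("cantilever must be slender: length/diameter >= 20")
  nodes <- cbind(seq(0, length_mm, length.out = n_elems + 1), 0, 0)
  conn <- data.frame(a = seq_len(n_elems), b = seq_len(n_elems) + 1L,
                     diameter = diameter_mm, mat = "bench", tag = "trabecular")
  mats <- list(bench = material("bench", E, 0.3))
  bcs <- data.frame(kind = "beam", node = 1L, dof = 1:6, value = 0)
  loads <- data.frame(kind = "beam", node = n_elems + 1L,
                      fx = 0, fy = 0, fz = -tip_load)
  fe_model(beam_nodes = nodes, beam_elems = conn, materials = mats,
           loads = loads, bcs = bcs)
}

#' Voxel-block patch test model
#'
#' A cube of `voxel_count^3` voxel elements with a linear displacement field
#' `u = A x` prescribed on every boundary node, imposing an exact constant
#' strain state; any conforming element must reproduce it to machine
#' precision at the interior.
#'
#' @param voxel_count elements per edge (>= 1).
#' @param E,nu material constants (`nu` in (0, 0.5)).
#' @param strain length-6 imposed strain `(exx, eyy, ezz, gxy, gyz, gzx)`
#'   with engineering shear, dimensionless (1e-3 = 1000 microstrain).
#' @param h voxel edge length (mm).
#' @return an (unassembled) [fe_model()].
#' @export
make_patch_test <- function(voxel_count = 2, E = 15000, nu = 0.3,
                            strain = c(1e-3, 0, 0, 0, 0, 0), h = 1) {
  if (voxel_count < 1) stop_invalid("voxel_count must be >= 1")
  if (nu <= 0 || nu >= 0.5) stop_invalid("nu must be in (0, 0.5)")
  n <- as.integer(voxel_count)
  mask <- array(TRUE, dim = c(n, n, n))
  vox <- vox_mesh(mask, origin = c(0, 0, 0), h = h, mat = "patch")
  A <- matrix(c(strain[1], strain[4] / 2, strain[6] / 2,
                strain[4] / 2, strain[2], strain[5] / 2,
                strain[6] / 2, strain[5] / 2, strain[3]), 3, 3)
  xyz <- vox$nodes
  lim <- n * h
  on_bnd <- apply(xyz, 1, function(p) any(abs(p) < 1e-12 | abs(p - lim) < 1e-12))
  ub <- xyz[on_bnd, , drop = FALSE] %*% t(A)
  idx <- which(on_bnd)
  bcs <- data.frame(kind = "vox",
                    node = rep(idx, each = 3),
                    dof = rep(1:3, length(idx)),
                    value = as.vector(t(ub)))
  fe_model(vox = vox, materials = list(patch = material("patch", E, nu)),
           bcs = bcs)
}
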