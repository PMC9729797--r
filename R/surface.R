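# Triangulated union-of-capsules surface for STL export, by surface-nets
# contouring of the capsule-union signed distance field. Produces one
# watertight surface of the union (junction overlaps resolved by the SDF),
# unlike naive per-strut tube meshing.

# sample the capsule-union SDF on a regular grid; only subgrids near each
# strut are evaluated, the rest stays at a large positive value
.capsule_sdf_grid <- function(lattice, h, margin) {
  bb <- rbind(apply(lattice$nodes, 2, min), apply(lattice$nodes, 2, max))
  rmax <- max(lattice$struts$diameter) / 2
  lo <- bb[1, ] - rmax - margin
  hi <- bb[2, ] + rmax + margin
  n <- pmax(2L, ceiling((hi - lo) / h) + 1L)
  gx <- lo[1] + (seq_len(n[1]) - 1) * h
  gy <- lo[2] + (seq_len(n[2]) - 1) * h
  gz <- lo[3] + (seq_len(n[3]) - 1) * h
  FF <- array(1e9, n)
  st <- lattice$struts
  for (s in seq_len(nrow(st))) {
    a <- lattice$nodes[st$a[s], ]; b <- lattice$nodes[st$b[s], ]
    r <- st$diameter[s] / 2
    slo <- pmin(a, b) - r - 2 * h
    shi <- pmax(a, b) + r + 2 * h
    ix <- which(gx >= slo[1] & gx <= shi[1])
    iy <- which(gy >= slo[2] & gy <= shi[2])
    iz <- which(gz >= slo[3] & gz <= shi[3])
    if (!length(ix) || !length(iy) || !length(iz)) next
    pts <- as.matrix(expand.grid(gx[ix], gy[iy], gz[iz]))
    ab <- b - a
    L2 <- max(sum(ab^2), 1e-30)
    t <- pmin(pmax(((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2] +
                      (pts[, 3] - a[3]) * ab[3]) / L2, 0), 1)
    d <- sqrt((pts[, 1] - a[1] - t * ab[1])^2 +
                (pts[, 2] - a[2] - t * ab[2])^2 +
                (pts[, 3] - a[3] - t * ab[3])^2) - r
    sub <- array(d, c(length(ix), length(iy), length(iz)))
    FF[ix, iy, iz] <- pmin(FF[ix, iy, iz], sub)
  }
  list(FF = FF, gx = gx, gy = gy, gz = gz, h = h, n = n)
}

# exact capsule-union SDF at arbitrary points, bbox-pruned per strut;
# points farther than `far` from every strut bbox keep the value `far`
.capsule_sdf_points <- function(points, lattice, far = 1e9) {
  p <- matrix(as.numeric(points), ncol = 3)
  best <- rep(far, nrow(p))
  st <- lattice$struts
  for (s in seq_len(nrow(st))) {
    a <- lattice$nodes[st$a[s], ]; b <- lattice$nodes[st$b[s], ]
    r <- st$diameter[s] / 2
    if (is.finite(far)) {
      lo <- pmin(a, b) - r - far; hi <- pmax(a, b) + r + far
      cand <- which(p[, 1] >= lo[1] & p[, 1] <= hi[1] &
                      p[, 2] >= lo[2] & p[, 2] <= hi[2] &
                      p[, 3] >= lo[3] & p[, 3] <= hi[3])
      if (!length(cand)) next
    } else cand <- seq_len(nrow(p))
    q <- p[cand, , drop = FALSE]
    ab <- b - a
    L2 <- max(sum(ab^2), 1e-30)
    t <- pmin(pmax(((q[, 1] - a[1]) * ab[1] + (q[, 2] - a[2]) * ab[2] +
                      (q[, 3] - a[3]) * ab[3]) / L2, 0), 1)
    d <- sqrt((q[, 1] - a[1] - t * ab[1])^2 +
                (q[, 2] - a[2] - t * ab[2])^2 +
                (q[, 3] - a[3] - t * ab[3])^2) - r
    best[cand] <- pmin(best[cand], d)
  }
  best
}

#' Triangulated surface of the strut capsule union
#'
#' Contours the signed distance field of the union of strut capsules
#' (cylinders with spherical caps) on a regular grid using the surface-nets
#' method: one vertex per boundary cell at the centroid of its edge-crossing
#' points (then projected onto the exact SDF zero level), one quad (two
#' triangles) per sign-changing grid edge. The result is a closed,
#' outward-oriented surface suitable for [write_stl()].
#'
#' `segments_per_circle` controls resolution: the grid cell size is
#' `pi * d_min / segments_per_circle` (the chord length a tube of the
#' smallest strut diameter would get with that many facets). For large
#' lattices the cell size is enlarged so the grid stays below `max_cells`
#' (with a warning); struts thinner than the enlarged cell then come out
#' blobby, which only affects the manufacturing export, not the mechanics.
#'
#' @param lattice a [lattice_model()] with at least one strut.
#' @param segments_per_circle integer >= 6.
#' @param max_cells grid size cap (number of cells).
#' @return a [tri_mesh()].
#' @export
lattice_to_surface <- function(lattice, segments_per_circle = 12,
                               max_cells = 3e6) {
  if (segments_per_circle < 6) stop_invalid("segments_per_circle must be >= 6")
  if (!nrow(lattice$struts)) stop_invalid("empty lattice")
  dmin <- min(lattice$struts$diameter)
  h <- pi * dmin / segments_per_circle
  bb <- rbind(apply(lattice$nodes, 2, min), apply(lattice$nodes, 2, max))
  ext <- bb[2, ] - bb[1, ] + max(lattice$struts$diameter) + 6 * h
  if (prod(ext / h) > max_cells) {
    h_new <- (prod(ext) / max_cells)^(1 / 3)
    warning(sprintf(
      "surface grid capped at %g cells: cell size %.3f -> %.3f mm", max_cells,
      h, h_new))
    h <- h_new
  }
  g <- .capsule_sdf_grid(lattice, h, margin = 2 * h)
  FF <- g$FF
  n <- g$n
  ncell <- n - 1L
  inside <- FF <= 0
  cl <- function(i, j, k) i + (j - 1) * ncell[1] + (k - 1) * (ncell[1] * ncell[2])

  ncl <- prod(ncell)
  cid_all <- pc_all <- vector("list", 3)
  edge_quads <- list()
  grid_coord <- function(idx) cbind(g$gx[idx[, 1]], g$gy[idx[, 2]], g$gz[idx[, 3]])

  for (axis in 1:3) {
    if (axis == 1) {
      cross <- inside[-n[1], , , drop = FALSE] != inside[-1, , , drop = FALSE]
    } else if (axis == 2) {
      cross <- inside[, -n[2], , drop = FALSE] != inside[, -1, , drop = FALSE]
    } else {
      cross <- inside[, , -n[3], drop = FALSE] != inside[, , -1, drop = FALSE]
    }
    idx <- which(cross, arr.ind = TRUE)
    if (!nrow(idx)) next
    idx2 <- idx
    idx2[, axis] <- idx2[, axis] + 1L
    f0 <- FF[idx]; f1 <- FF[idx2]
    t <- f0 / (f0 - f1)
    pc <- grid_coord(idx)
    pc[, axis] <- pc[, axis] + t * g$h
    # the 4 cells sharing this edge: offsets along the other two axes
    b <- axis %% 3 + 1L
    c3 <- b %% 3 + 1L
    cells <- vector("list", 4)
    offs <- list(c(-1L, -1L), c(0L, -1L), c(0L, 0L), c(-1L, 0L))
    for (q in 1:4) {
      ci <- idx
      ci[, b] <- ci[, b] + offs[[q]][1]
      ci[, c3] <- ci[, c3] + offs[[q]][2]
      cells[[q]] <- cl(ci[, 1], ci[, 2], ci[, 3])
    }
    cid_all[[axis]] <- c(cells[[1]], cells[[2]], cells[[3]], cells[[4]])
    pc_all[[axis]] <- rbind(pc, pc, pc, pc)
    # quad orientation: inside at the lower end -> outward normal +axis ->
    # CCW order in the right-handed (b, c3) plane; else reversed
    fwd <- f0 < 0
    quad <- cbind(cells[[1]], cells[[2]], cells[[3]], cells[[4]])
    quad[!fwd, ] <- quad[!fwd, c(1, 4, 3, 2), drop = FALSE]
    edge_quads[[axis]] <- quad
  }
  cid <- unlist(cid_all)
  pc <- do.call(rbind, pc_all)
  acc <- rowsum(cbind(pc, 1), cid)  # one pass: sums + counts per cell
  used <- as.numeric(rownames(acc))
  verts <- acc[, 1:3, drop = FALSE] / acc[, 4]
  quads <- do.call(rbind, edge_quads)
  q <- matrix(match(quads, used), ncol = 4)
  faces <- rbind(q[, c(1, 2, 3)], q[, c(1, 3, 4)])

  # project vertices onto the exact SDF zero level (two Newton steps with a
  # finite-difference gradient): removes the inward bias of crossing centroids
  eps <- h / 20
  far <- 2 * h
  for (it in 1:2) {
    f0 <- .capsule_sdf_points(verts, lattice, far)
    gxv <- (.capsule_sdf_points(verts + matrix(c(eps, 0, 0), nrow(verts), 3, byrow = TRUE), lattice, far) - f0) / eps
    gyv <- (.capsule_sdf_points(verts + matrix(c(0, eps, 0), nrow(verts), 3, byrow = TRUE), lattice, far) - f0) / eps
    gzv <- (.capsule_sdf_points(verts + matrix(c(0, 0, eps), nrow(verts), 3, byrow = TRUE), lattice, far) - f0) / eps
    g2 <- gxv^2 + gyv^2 + gzv^2
    ok <- is.finite(f0) & abs(f0) < h & g2 > 1e-12
    step <- numeric(nrow(verts))
    step[ok] <- pmin(pmax((f0 / pmax(g2, 1e-12))[ok], -h), h)
    verts <- verts - cbind(step * gxv, step * gyv, step * gzv)
  }
  m <- tri_mesh(verts, faces)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}
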