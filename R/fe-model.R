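# FE model container and voxel-grid helpers.

#' Build a voxel continuum mesh from a cell mask
#'
#' Converts a logical 3D array of occupied cubic cells into a hexahedral
#' node/element mesh sharing nodes between adjacent cells.
#'
#' @param mask 3D logical array (cells along x, y, z).
#' @param origin coordinates of the minimum grid node (mm).
#' @param h voxel edge length (mm).
#' @param mat material name per occupied cell: either a single name or a
#'   character array of `dim(mask)`.
#' @return a `scaffem_vox` list: `nodes` (V x 3), `elems` (M x 8, VTK
#'   ordering), `mat` (length M), `h`, `origin`, `dim`, `node_id` (lookup
#'   array), `cell_ijk` (M x 3).
#' @export
vox_mesh <- function(mask, origin, h, mat) {
  stopifnot(length(dim(mask)) == 3)
  nd <- dim(mask) + 1L
  node_needed <- array(FALSE, nd)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop_invalid("empty voxel mask")
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    node_needed[cbind(idx[, 1] + dx, idx[, 2] + dy, idx[, 3] + dz)] <- TRUE
  }
  node_id <- array(0L, nd)
  node_id[node_needed] <- seq_len(sum(node_needed))
  nidx <- which(node_needed, arr.ind = TRUE)
  nodes <- cbind(origin[1] + (nidx[, 1] - 1) * h,
                 origin[2] + (nidx[, 2] - 1) * h,
                 origin[3] + (nidx[, 3] - 1) * h)
  nodes <- nodes[order(node_id[node_needed]), , drop = FALSE]
  # VTK hexahedron ordering: bottom ring CCW then top ring
  off <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
               c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  elems <- matrix(0L, nrow(idx), 8)
  for (a in 1:8) {
    elems[, a] <- node_id[cbind(idx[, 1] + off[a, 1], idx[, 2] + off[a, 2],
                                idx[, 3] + off[a, 3])]
  }
  m <- if (length(mat) == 1) rep(mat, nrow(idx)) else mat[idx]
  structure(list(nodes = nodes, elems = elems, mat = as.character(m),
                 h = h, origin = origin, dim = dim(mask), node_id = node_id,
                 cell_ijk = idx),
            class = "scaffem_vox")
}

# nearest existing vox node to each point; NA when farther than tol
vox_nearest_node <- function(vox, points, tol) {
  p <- matrix(as.numeric(points), ncol = 3)
  n <- nrow(p)
  out <- rep(NA_integer_, n)
  dbest <- rep(Inf, n)
  nd <- dim(vox$node_id)
  fi <- sweep(sweep(p, 2, vox$origin), 2, rep(vox$h, 3), "/")
  base <- floor(fi)
  for (dx in -1:2) for (dy in -1:2) for (dz in -1:2) {
    i <- base[, 1] + 1L + dx
    j <- base[, 2] + 1L + dy
    k <- base[, 3] + 1L + dz
    ok <- i >= 1 & i <= nd[1] & j >= 1 & j <= nd[2] & k >= 1 & k <= nd[3]
    if (!any(ok)) next
    id <- rep(0L, n)
    id[ok] <- vox$node_id[cbind(i[ok], j[ok], k[ok])]
    has <- id > 0L
    if (!any(has)) next
    d <- rep(Inf, n)
    d[has] <- sqrt(rowSums((p[has, , drop = FALSE] -
                              vox$nodes[id[has], , drop = FALSE])^2))
    better <- d < dbest
    out[better] <- id[better]
    dbest[better] <- d[better]
  }
  out[dbest > tol] <- NA_integer_
  out
}

#' Define a finite-element model
#'
#' Combines (any subset of) a voxel continuum mesh, a beam network, grounded
#' springs, nodal loads and displacement constraints into a model ready for
#' [fe_assemble()].
#'
#' Node references in `springs`, `loads` and `bcs` use `kind` (`"vox"` or
#' `"beam"`) plus the node index in that mesh. Beam nodes are rigidly tied
#' (translations) to the nearest voxel node within `tie_tol`; an untied beam
#' node is an assembly error unless the model has no voxel mesh.
#'
#' @param vox a [vox_mesh()] or `NULL`.
#' @param beam_nodes B x 3 node coordinates, or `NULL`.
#' @param beam_elems data.frame `a`, `b` (node indices), `diameter` (mm),
#'   `mat` (material name), `tag`.
#' @param materials named list of [material()] objects.
#' @param springs data.frame `kind`, `node`, `dx`, `dy`, `dz`, `k` (N/mm).
#' @param loads data.frame `kind`, `node`, `fx`, `fy`, `fz` (N).
#' @param bcs data.frame `kind`, `node`, `dof` (1:3 translations, 4:6 beam
#'   rotations), `value` (prescribed displacement mm / rotation rad).
#' @param tie_tol beam-to-voxel tie tolerance (mm); default 1.8 x voxel edge.
#' @return a `scaffem_femodel` list.
#' @export
fe_model <- function(vox = NULL, beam_nodes = NULL, beam_elems = NULL,
                     materials = default_materials(),
                     springs = NULL, loads = NULL, bcs = NULL,
                     tie_tol = NULL) {
  if (is.null(vox) && is.null(beam_nodes))
    stop_invalid("model needs at least one of: voxel mesh, beam network")
  if (!is.null(beam_nodes)) beam_nodes <- matrix(as.numeric(beam_nodes), ncol = 3)
  if (is.null(tie_tol)) tie_tol <- if (!is.null(vox)) 1.8 * vox$h else 0
  structure(list(vox = vox, beam_nodes = beam_nodes, beam_elems = beam_elems,
                 materials = materials, springs = springs, loads = loads,
                 bcs = bcs, tie_tol = tie_tol),
            class = "scaffem_femodel")
}

# resolve (kind, node) to the 3 translational dof ids
.node_tdof <- function(kind, node, nvoxdof, beam_tdof) {
  if (kind == "vox") 3 * (node - 1) + 1:3 else beam_tdof[node, ]
}

#' Assemble the global stiffness system
#'
#' Builds the sparse symmetric stiffness matrix from hexahedral voxel
#' elements (full 2x2x2 Gauss integration), 3D Timoshenko beams and grounded
#' springs, plus the load vector and resolved constraints. Beam nodes are
#' tied to the voxel grid (shared translational DOFs); rotational DOFs stay
#' with the beams.
#'
#' @param fem a [fe_model()].
#' @return a `scaffem_assembly`: the model plus `K` (dgCMatrix, symmetric),
#'   `f`, `ndof`, dof maps, cached per-beam local matrices, and resolved
#'   boundary conditions.
#' @export
fe_assemble <- function(fem) {
  vox <- fem$vox
  nvox <- if (is.null(vox)) 0L else nrow(vox$nodes)
  ndof <- 3L * nvox

  nbeam <- if (is.null(fem$beam_nodes)) 0L else nrow(fem$beam_nodes)
  beam_tdof <- beam_rdof <- NULL
  tie <- NULL
  if (nbeam > 0) {
    beam_tdof <- matrix(0L, nbeam, 3)
    if (!is.null(vox)) {
      tie <- vox_nearest_node(vox, fem$beam_nodes, fem$tie_tol)
      if (anyNA(tie)) {
        bad <- which(is.na(tie))
        stop("assembly error: untied floating strut node(s) ",
             paste(head(bad, 5), collapse = ", "),
             if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5),
             " have no voxel node within ", fem$tie_tol, " mm")
      }
      beam_tdof <- t(vapply(tie, function(n) 3L * (n - 1L) + 1:3, integer(3)))
    } else {
      beam_tdof <- matrix(ndof + seq_len(3 * nbeam), nbeam, 3, byrow = TRUE)
      ndof <- ndof + 3L * nbeam
    }
    beam_rdof <- matrix(ndof + seq_len(3 * nbeam), nbeam, 3, byrow = TRUE)
    ndof <- ndof + 3L * nbeam
  }

  ti <- tj <- tx <- vector("list", 0)
  push <- function(i, j, x) {
    ti[[length(ti) + 1]] <<- as.integer(i)
    tj[[length(tj) + 1]] <<- as.integer(j)
    tx[[length(tx) + 1]] <<- as.numeric(x)
  }

  hex_groups <- NULL
  if (!is.null(vox)) {
    edof <- matrix(0L, nrow(vox$elems), 24)
    for (a in 1:8) edof[, (3 * a - 2):(3 * a)] <-
        cbind(3L * (vox$elems[, a] - 1L) + 1L, 3L * (vox$elems[, a] - 1L) + 2L,
              3L * (vox$elems[, a] - 1L) + 3L)
    hex_groups <- list()
    for (m in unique(vox$mat)) {
      rows <- which(vox$mat == m)
      mt <- fem$materials[[m]]
      if (is.null(mt)) stop_invalid("unknown material: ", m)
      Ke <- hex_stiffness(mt$E, mt$nu, vox$h)
      ed <- edof[rows, , drop = FALSE]
      rr <- rep(1:24, times = 24)
      cc <- rep(1:24, each = 24)
      push(ed[, rr], ed[, cc], rep(as.vector(Ke), each = length(rows)))
      hex_groups[[m]] <- rows
    }
    attr(hex_groups, "edof") <- edof
  }

  beam_cache <- NULL
  if (nbeam > 0 && !is.null(fem$beam_elems) && nrow(fem$beam_elems) > 0) {
    be <- fem$beam_elems
    beam_cache <- vector("list", nrow(be))
    for (s in seq_len(nrow(be))) {
      a <- be$a[s]; b <- be$b[s]
      ax <- beam_axes(fem$beam_nodes[a, ], fem$beam_nodes[b, ])
      mt <- fem$materials[[be$mat[s]]]
      if (is.null(mt)) stop_invalid("unknown material: ", be$mat[s])
      Kl <- beam_stiffness_local(mt$E, mt$nu, be$diameter[s], ax$L)
      Tm <- matrix(0, 12, 12)
      for (blk in 0:3) Tm[blk * 3 + 1:3, blk * 3 + 1:3] <- ax$R
      Kg <- crossprod(Tm, Kl %*% Tm)
      dofs <- c(beam_tdof[a, ], beam_rdof[a, ], beam_tdof[b, ], beam_rdof[b, ])
      push(rep(dofs, times = 12), rep(dofs, each = 12), as.vector(Kg))
      beam_cache[[s]] <- list(Kl = Kl, Tm = Tm, dofs = dofs, L = ax$L,
                              d = be$diameter[s])
    }
  }

  f <- numeric(ndof)
  if (!is.null(fem$loads) && nrow(fem$loads) > 0) {
    for (r in seq_len(nrow(fem$loads))) {
      dofs <- .node_tdof(fem$loads$kind[r], fem$loads$node[r], 3L * nvox, beam_tdof)
      f[dofs] <- f[dofs] +
        c(fem$loads$fx[r], fem$loads$fy[r], fem$loads$fz[r])
    }
  }

  if (!is.null(fem$springs) && nrow(fem$springs) > 0) {
    for (r in seq_len(nrow(fem$springs))) {
      d <- c(fem$springs$dx[r], fem$springs$dy[r], fem$springs$dz[r])
      d <- d / sqrt(sum(d^2))
      Ks <- fem$springs$k[r] * tcrossprod(d)
      dofs <- .node_tdof(fem$springs$kind[r], fem$springs$node[r], 3L * nvox, beam_tdof)
      push(rep(dofs, times = 3), rep(dofs, each = 3), as.vector(Ks))
    }
  }

  K <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(ndof, ndof))
  K <- (K + Matrix::t(K)) / 2  # exact symmetrization of roundoff

  bc_dof <- integer(0); bc_val <- numeric(0)
  if (!is.null(fem$bcs) && nrow(fem$bcs) > 0) {
    for (r in seq_len(nrow(fem$bcs))) {
      kind <- fem$bcs$kind[r]; node <- fem$bcs$node[r]; dof <- fem$bcs$dof[r]
      g <- if (dof <= 3) .node_tdof(kind, node, 3L * nvox, beam_tdof)[dof]
      else {
        if (kind != "beam") stop_invalid("rotational bc on non-beam node")
        beam_rdof[node, dof - 3L]
      }
      bc_dof <- c(bc_dof, g); bc_val <- c(bc_val, fem$bcs$value[r])
    }
    keep <- !duplicated(bc_dof)
    bc_dof <- bc_dof[keep]; bc_val <- bc_val[keep]
  }

  structure(list(fem = fem, K = K, f = f, ndof = ndof,
                 beam_tdof = beam_tdof, beam_rdof = beam_rdof, tie = tie,
                 hex_groups = hex_groups, beam_cache = beam_cache,
                 bc_dof = bc_dof, bc_val = bc_val),
            class = "scaffem_assembly")
}

#' Solve the assembled linear system and recover fields
#'
#' Sparse Cholesky solve of the constrained system; verifies the equilibrium
#' residual (relative norm < 1e-8) and recovers per-element voxel stress and
#' strain (element-centre evaluation), per-node volume-weighted averages,
#' per-strut surface-fiber equivalent stresses and constraint reactions.
#'
#' @param asm a [fe_assemble()] result.
#' @return a `scaffem_field` list: `u` (length ndof), `residual`,
#'   `reactions`, `vox` (`stress6`, `strain6`, `vm_elem`, `eq_strain_elem`,
#'   `vm_node`, `eq_strain_node` in MPa / microstrain) and `beams`
#'   (`end_stress` S x 2, `stress` per strut max, MPa).
#' @export
fe_solve <- function(asm) {
  ndof <- asm$ndof
  free <- setdiff(seq_len(ndof), asm$bc_dof)
  u <- numeric(ndof)
  u[asm$bc_dof] <- asm$bc_val
  Kff <- asm$K[free, free, drop = FALSE]
  rhs <- asm$f[free]
  if (length(asm$bc_dof))
    rhs <- rhs - as.numeric(asm$K[free, asm$bc_dof, drop = FALSE] %*% asm$bc_val)
  sol <- tryCatch(
    Matrix::solve(Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE,
                                   super = TRUE), rhs),
    error = function(e) {
      dg <- Matrix::diag(Kff)
      loose <- head(order(dg), 6)
      stop("singular system (rigid-body mode?): smallest stiffness at free DOFs ",
           paste(free[loose], collapse = ", "),
           "; check constraints and connectivity [", conditionMessage(e), "]")
    })
  u[free] <- as.numeric(sol)
  res <- as.numeric(Kff %*% u[free]) - rhs
  residual <- sqrt(sum(res^2)) / max(sqrt(sum(rhs^2)), 1e-30)
  if (residual > 1e-8)
    warning(sprintf("equilibrium residual %.3g exceeds 1e-8", residual))
  reactions <- as.numeric(asm$K %*% u - asm$f)[asm$bc_dof]

  voxres <- NULL
  vox <- asm$fem$vox
  if (!is.null(vox)) {
    edof <- attr(asm$hex_groups, "edof")
    M <- nrow(vox$elems)
    strain6 <- matrix(0, M, 6)
    stress6 <- matrix(0, M, 6)
    B0 <- hex_B(0, 0, 0, vox$h)
    Ue <- matrix(u[edof], M, 24)
    strain6 <- Ue %*% t(B0)
    for (m in names(asm$hex_groups)) {
      rows <- asm$hex_groups[[m]]
      D <- iso_D(asm$fem$materials[[m]]$E, asm$fem$materials[[m]]$nu)
      stress6[rows, ] <- strain6[rows, , drop = FALSE] %*% t(D)
    }
    vm_elem <- sqrt(0.5 * ((stress6[, 1] - stress6[, 2])^2 +
                             (stress6[, 2] - stress6[, 3])^2 +
                             (stress6[, 3] - stress6[, 1])^2) +
                      3 * (stress6[, 4]^2 + stress6[, 5]^2 + stress6[, 6]^2))
    tm <- (strain6[, 1] + strain6[, 2] + strain6[, 3]) / 3
    dd <- (strain6[, 1] - tm)^2 + (strain6[, 2] - tm)^2 + (strain6[, 3] - tm)^2 +
      2 * ((strain6[, 4] / 2)^2 + (strain6[, 5] / 2)^2 + (strain6[, 6] / 2)^2)
    eq_elem <- sqrt(2 / 3 * dd) * 1e6
    nn <- nrow(vox$nodes)
    acc_vm <- acc_eq <- cnt <- numeric(nn)
    for (a in 1:8) {
      ids <- vox$elems[, a]
      acc_vm <- acc_vm + .accum(ids, vm_elem, nn)
      acc_eq <- acc_eq + .accum(ids, eq_elem, nn)
      cnt <- cnt + .accum(ids, rep(1, M), nn)
    }
    voxres <- list(strain6 = strain6, stress6 = stress6,
                   vm_elem = vm_elem, eq_strain_elem = eq_elem,
                   vm_node = acc_vm / cnt, eq_strain_node = acc_eq / cnt)
  }

  beamres <- NULL
  if (!is.null(asm$beam_cache)) {
    S <- length(asm$beam_cache)
    end_stress <- matrix(0, S, 2)
    end_forces <- vector("list", S)
    for (s in seq_len(S)) {
      bc <- asm$beam_cache[[s]]
      ul <- bc$Tm %*% u[bc$dofs]
      fl <- as.numeric(bc$Kl %*% ul)
      end_stress[s, 1] <- beam_equivalent_stress(bc$d, fl[1], fl[4], fl[5], fl[6])
      end_stress[s, 2] <- beam_equivalent_stress(bc$d, fl[7], fl[10], fl[11], fl[12])
      end_forces[[s]] <- fl
    }
    beamres <- list(end_stress = end_stress,
                    stress = pmax(end_stress[, 1], end_stress[, 2]),
                    end_forces = end_forces)
  }

  structure(list(u = u, residual = residual, reactions = reactions,
                 vox = voxres, beams = beamres),
            class = "scaffem_field")
}

# sum values into bins (base-R tapply-free accumulator)
.accum <- function(ids, vals, n) {
  out <- numeric(n)
  s <- rowsum(vals, ids)
  out[as.integer(rownames(s))] <- s
  out
}

#' Per-node field restricted to elements of given materials
#'
#' Volume-weighted (equal voxels: arithmetic) average of element values over
#' the elements of the requested materials adjacent to each node; nodes not
#' touching such elements are dropped.
#'
#' @param result a [fe_solve()] result with a voxel mesh.
#' @param asm the matching assembly.
#' @param what `"eq_strain"` (microstrain) or `"vm"` (MPa).
#' @param materials character vector of material names, or `NULL` for all.
#' @return numeric vector of node values.
#' @export
nodal_field <- function(result, asm, what = c("eq_strain", "vm"),
                        materials = NULL) {
  what <- match.arg(what)
  vox <- asm$fem$vox
  if (is.null(vox) || is.null(result$vox)) stop_invalid("no voxel field")
  vals <- if (what == "eq_strain") result$vox$eq_strain_elem else result$vox$vm_elem
  rows <- if (is.null(materials)) seq_len(nrow(vox$elems)) else
    which(vox$mat %in% materials)
  if (!length(rows)) stop_invalid("no elements with material ",
                                  paste(materials, collapse = ","))
  nn <- nrow(vox$nodes)
  acc <- cnt <- numeric(nn)
  for (a in 1:8) {
    ids <- vox$elems[rows, a]
    acc <- acc + .accum(ids, vals[rows], nn)
    cnt <- cnt + .accum(ids, rep(1, length(rows)), nn)
  }
  keep <- cnt > 0
  acc[keep] / cnt[keep]
}
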