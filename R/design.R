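# Couples a defect fixture and an implant lattice into a solvable FE design:
# voxel classification (bone / graft / disc / tooth), boundary conditions,
# bite and muscle loading.

#' Masticatory load case
#'
#' @param bite_force occlusal bite force magnitude (N), default 800
#'   (maximum-force bite, worst case), applied along -z on the occlusal
#'   node patch.
#' @param muscles data.frame merging [default_muscle_forces()] and
#'   [default_muscle_directions()]; each row acts as a point force
#'   `force * (dx, dy, dz)` plus a grounded spring of stiffness `stiffness`
#'   at its attachment node.
#' @return a `scaffem_loadcase` list.
#' @export
load_case <- function(bite_force = 800,
                      muscles = merge(default_muscle_forces(),
                                      default_muscle_directions(),
                                      by = c("name", "side"))) {
  if (bite_force <= 0) stop_invalid("bite_force must be > 0")
  structure(list(bite_force = bite_force, muscles = muscles),
            class = "scaffem_loadcase")
}

#' Assemble a defect design (fixture + lattice -> FE inputs)
#'
#' Classifies one cubic voxel grid over the whole fixture:
#' * defect section: graft continuum (voxels outside the strut capsules;
#'   capsule-occupied voxels are carried by the beam elements),
#' * residual stumps: cortical shell (within `cortical_mm` of the lateral
#'   wall) around a cancellous core,
#' * one voxel layer at each free end: articular-disc material between bone
#'   and the fixed condylar support,
#' * an occlusal tooth patch on the +x stump where the bite force acts.
#'
#' Constraints fix the end-face node layers (condylar support); the bite
#' force is distributed over the tooth-patch top nodes; every muscle site
#' contributes a point force and a grounded spring at its nearest voxel
#' node. Strut nodes are tied to the voxel grid during assembly.
#'
#' @param fixture a [make_defect_fixture()].
#' @param lattice implant [lattice_model()] (including fixation).
#' @param voxel_mm voxel edge (mm), default 1.25 (pore/4).
#' @param load a [load_case()].
#' @param materials named list of [material()]s (needs cortical, cancellous,
#'   disc, tooth, ti6al4v).
#' @param cortical_mm cortical shell thickness (mm).
#' @return a `scaffem_design` list with `vox`, `beam_elems`, `springs`,
#'   `loads`, `bcs`, masks and provenance; pass to [run_stage_sweep()].
#' @export
defect_model <- function(fixture, lattice, voxel_mm = 1.25,
                         load = load_case(),
                         materials = default_materials(),
                         cortical_mm = 2) {
  pr <- fixture$params
  bb <- mesh_bbox(fixture$outer_surface)
  h <- voxel_mm
  orig <- bb[1, ] - 1e-9
  nc <- pmax(1L, ceiling((bb[2, ] - bb[1, ]) / h))
  cx <- orig[1] + (seq_len(nc[1]) - 0.5) * h
  cy <- orig[2] + (seq_len(nc[2]) - 0.5) * h
  cz <- orig[3] + (seq_len(nc[3]) - 0.5) * h
  centres <- as.matrix(expand.grid(cx, cy, cz))
  inside <- fixture_inside(fixture, centres, "outer")
  half_span <- pr$span / 2
  in_defect <- inside & abs(centres[, 1]) <= half_span
  in_stump <- inside & !in_defect

  mat <- array("", nc)
  dim(inside) <- dim(in_defect) <- dim(in_stump) <- nc

  # stump classification
  depth <- fixture_wall_depth(fixture, centres)
  end_layer <- abs(centres[, 1]) > pr$length / 2 - 1.2 * h
  tooth_x <- c(half_span, half_span + 0.5 * pr$stump)
  top <- centres[, 3] > pr$height / 2 - (cortical_mm + 0.2 * h)
  in_tooth <- centres[, 1] >= tooth_x[1] & centres[, 1] <= tooth_x[2] & top
  stump_m <- ifelse(end_layer, "disc",
                    ifelse(in_tooth, "tooth",
                           ifelse(depth <= cortical_mm, "cortical", "cancellous")))
  dim(stump_m) <- nc
  mat[in_stump] <- stump_m[in_stump]

  # defect: graft minus strut-capsule voxels
  strut_cells <- capsule_union_contains(centres, lattice)
  dim(strut_cells) <- nc
  mat[in_defect & !strut_cells] <- "graft"
  mask <- inside & !(in_defect & strut_cells)

  vox <- vox_mesh(mask, orig, h, mat)

  # condylar support: outermost node layers at both ends
  xr <- range(vox$nodes[, 1])
  fixed_nodes <- which(vox$nodes[, 1] < xr[1] + 0.01 * h |
                         vox$nodes[, 1] > xr[2] - 0.01 * h)
  bcs <- data.frame(kind = "vox", node = rep(fixed_nodes, each = 3),
                    dof = rep(1:3, length(fixed_nodes)), value = 0)

  # bite: top nodes over the tooth patch
  zr <- max(vox$nodes[, 3])
  bite_nodes <- which(vox$nodes[, 3] > zr - 0.51 * h &
                        vox$nodes[, 1] >= tooth_x[1] &
                        vox$nodes[, 1] <= tooth_x[2])
  if (!length(bite_nodes)) stop_invalid("no occlusal nodes found for bite load")
  loads <- data.frame(kind = "vox", node = bite_nodes, fx = 0, fy = 0,
                      fz = -load$bite_force / length(bite_nodes))

  # muscles: point force + grounded spring at nearest voxel node
  ms <- fixture$muscle_sites
  mm <- merge(ms[, c("name", "side", "px", "py", "pz")], load$muscles,
              by = c("name", "side"))
  att <- vox_nearest_node(vox, as.matrix(mm[, c("px", "py", "pz")]),
                          tol = max(pr$width, 4 * h))
  if (anyNA(att)) stop_invalid("muscle attachment point far from model")
  springs <- data.frame(kind = "vox", node = att,
                        dx = mm$dx, dy = mm$dy, dz = mm$dz, k = mm$stiffness)
  loads <- rbind(loads, data.frame(kind = "vox", node = att,
                                   fx = mm$force * mm$dx,
                                   fy = mm$force * mm$dy,
                                   fz = mm$force * mm$dz))

  be <- lattice$struts
  be$mat <- "ti6al4v"
  structure(list(fixture = fixture, lattice = lattice, vox = vox,
                 beam_elems = be, springs = springs, loads = loads,
                 bcs = bcs, materials = materials, tie_tol = 1.8 * h,
                 voxel_mm = h,
                 counts = list(region = sum(in_defect),
                               graft = sum(mat == "graft"),
                               strut = sum(in_defect & strut_cells)),
                 load = load),
            class = "scaffem_design")
}

#' @export
print.scaffem_design <- function(x, ...) {
  cat(sprintf("<scaffem_design: %d voxels (%d graft), %d struts, %d springs>\n",
              nrow(x$vox$elems), x$counts$graft, nrow(x$beam_elems),
              nrow(x$springs)))
  invisible(x)
}

#' Swap the lattice of a design, re-voxelizing the graft on the same grid
#'
#' Used by the optimizer after strut diameter updates: the voxel grid and
#' all boundary conditions are regenerated deterministically with identical
#' parameters, so statistics stay comparable across iterations.
#'
#' @param design a [defect_model()].
#' @param lattice the updated [lattice_model()].
#' @return a new `scaffem_design`.
#' @export
design_with_lattice <- function(design, lattice) {
  defect_model(design$fixture, lattice, voxel_mm = design$voxel_mm,
               load = design$load, materials = design$materials)
}
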