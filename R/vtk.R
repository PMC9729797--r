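#' Export a solved voxel field as a legacy ASCII VTK unstructured grid
#'
#' Writes the voxel mesh with point data arrays `displacement_mm`,
#' `vm_stress_MPa` and `eq_strain_ue`, plus cell data `material_id`, for
#' inspection in ParaView-style viewers.
#'
#' @param asm a [fe_assemble()] result with a voxel mesh.
#' @param result the matching [fe_solve()] result.
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(asm, result, path) {
  vox <- asm$fem$vox
  if (is.null(vox)) stop_invalid("no voxel mesh to export")
  n <- nrow(vox$nodes)
  m <- nrow(vox$elems)
  u <- matrix(result$u[seq_len(3 * n)], ncol = 3, byrow = TRUE)
  num <- function(x) sprintf("%.9g", x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "scaffem field export",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(paste(num(vox$nodes[, 1]), num(vox$nodes[, 2]),
                   num(vox$nodes[, 3])), con)
  writeLines(sprintf("CELLS %d %d", m, 9 * m), con)
  writeLines(paste(8, vox$elems[, 1] - 1, vox$elems[, 2] - 1,
                   vox$elems[, 3] - 1, vox$elems[, 4] - 1, vox$elems[, 5] - 1,
                   vox$elems[, 6] - 1, vox$elems[, 7] - 1, vox$elems[, 8] - 1),
             con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("12", m), con)  # VTK_HEXAHEDRON
  writeLines(sprintf("POINT_DATA %d", n), con)
  writeLines("VECTORS displacement_mm double", con)
  writeLines(paste(num(u[, 1]), num(u[, 2]), num(u[, 3])), con)
  writeLines(c("SCALARS vm_stress_MPa double 1", "LOOKUP_TABLE default"), con)
  writeLines(num(result$vox$vm_node), con)
  writeLines(c("SCALARS eq_strain_ue double 1", "LOOKUP_TABLE default"), con)
  writeLines(num(result$vox$eq_strain_node), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS material_id int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(factor(vox$mat))), con)
  invisible(path)
}
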