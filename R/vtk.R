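#' Write a mesh and solution fields as a legacy VTK unstructured grid
#'
#' ASCII legacy format; 4-node tets are cell type 10, 10-node tets type 24.
#' Point data may be vectors (nnodes x 3 matrices) or scalars; cell data are
#' per-element scalars.
#'
#' @param mesh An `fe_mesh`.
#' @param file Output path (`.vtk`).
#' @param point_data Named list of per-node fields.
#' @param cell_data Named list of per-element fields.
#' @return Invisibly, the file path.
#' @export
write_vtk <- function(mesh, file, point_data = list(), cell_data = list()) {
  con <- file(file, "w")
  on.exit(close(con))
  nn <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  npe <- ncol(mesh$elems)
  w <- function(...) writeLines(paste0(...), con)
  w("# vtk DataFile Version 3.0")
  w("screwfe unstructured grid")
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS ", nn, " double")
  writeLines(paste(mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  w("CELLS ", ne, " ", ne * (npe + 1))
  writeLines(paste(npe, apply(mesh$elems - 1L, 1, paste, collapse = " ")),
             con)
  w("CELL_TYPES ", ne)
  writeLines(as.character(rep(if (npe == 4L) 10L else 24L, ne)), con)
  if (length(point_data) > 0) {
    w("POINT_DATA ", nn)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) == 3) {
        w("VECTORS ", nm, " double")
        writeLines(paste(v[, 1], v[, 2], v[, 3]), con)
      } else {
        w("SCALARS ", nm, " double 1")
        w("LOOKUP_TABLE default")
        writeLines(as.character(v), con)
      }
    }
  }
  if (length(cell_data) > 0) {
    w("CELL_DATA ", ne)
    for (nm in names(cell_data)) {
      w("SCALARS ", nm, " double 1")
      w("LOOKUP_TABLE default")
      writeLines(as.character(cell_data[[nm]]), con)
    }
  }
  invisible(file)
}

#' Export an assembly solution (displacements, von Mises, axial stress)
#'
#' @param assembly An `assembly`.
#' @param sol An [fe_solve()] solution.
#' @param file Output `.vtk` path.
#' @return Invisibly, the file path.
#' @export
export_solution_vtk <- function(assembly, sol, file) {
  write_vtk(assembly$mesh, file,
            point_data = list(displacement = sol$u),
            cell_data = list(von_mises = sol$vm,
                             axial_stress = sol$stress[, 3],
                             E = assembly$E))
}
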