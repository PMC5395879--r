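#' Export a hexahedral mesh (legacy VTK ASCII)
#'
#' Unstructured-grid file with integer cell data for the tissue region and
#' optional nodal displacement / cell strain fields.
#'
#' @param mesh A mesh with `nodes`, `elems` and optionally `region`.
#' @param path Output `.vtk` path.
#' @param displacements Optional nodal displacement vector (3 per node).
#' @param cell_strain Optional per-element scalar (e.g. max principal
#'   Green-Lagrange strain).
#' @return The path, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, displacements = NULL,
                           cell_strain = NULL) {
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "trachea mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(apply(mesh$nodes, 1, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", ne, 9 * ne), con)
  writeLines(apply(cbind(8L, mesh$elems - 1L), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("12", ne), con)
  if (!is.null(mesh$region) || !is.null(cell_strain)) {
    writeLines(sprintf("CELL_DATA %d", ne), con)
    if (!is.null(mesh$region)) {
      lev <- c("cartilage", "fibrous", "muscle", "mucosa")
      writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
      writeLines(as.character(match(mesh$region, lev)), con)
    }
    if (!is.null(cell_strain)) {
      writeLines(c("SCALARS max_principal_strain double 1",
                   "LOOKUP_TABLE default"), con)
      writeLines(format(cell_strain, digits = 9), con)
    }
  }
  if (!is.null(displacements)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    writeLines("VECTORS displacement double", con)
    um <- matrix(displacements, ncol = 3, byrow = TRUE)
    writeLines(apply(um, 1, paste, collapse = " "), con)
  }
  invisible(path)
}

#' Export a simulation state series as VTK files
#'
#' One file per recorded state, with nodal displacements and per-element
#' maximum principal Green-Lagrange strain.
#'
#' @param result A [run_load_program()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_states_vtk <- function(result, dir, prefix = "state") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mesh <- result$mesh
  paths <- character()
  for (i in seq_along(result$states)) {
    s <- result$states[[i]]
    strain <- element_strains(mesh, s$u)[, 1]
    p <- file.path(dir, sprintf("%s_%03d.vtk", prefix, i - 1))
    write_mesh_vtk(mesh, p, displacements = s$u, cell_strain = strain)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write a collapse curve as delimited text
#'
#' Columns `pressure_cmH2O`, `force_N`, `area_ratio`.
#'
#' @param curve A [area_ratio_curve()] tibble.
#' @param path Output path.
#' @export
write_collapse_curve <- function(curve, path) {
  df <- data.frame(pressure_cmH2O = curve$pressure_cmh2o,
                   force_N = curve$force_n, area_ratio = curve$area_ratio)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the solver step log
#'
#' Tab-separated step log (step, pressure, convergence, iteration count).
#'
#' @param result A [run_load_program()] result.
#' @param path Output path.
#' @export
write_solver_log <- function(result, path) {
  utils::write.table(result$log, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
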