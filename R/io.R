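# Plain-text exporters: legacy VTK meshes/fields, CSV profiles, JSON summaries.

#' Write a mesh with nodal fields to a legacy VTK file
#'
#' ASCII legacy VTK unstructured grid; quadratic meshes are written with
#' their corner connectivity (VTK triangle cells) plus all nodal data, which
#' every VTK reader understands. Element region tags go out as cell data
#' `region` (1 = necrotic, 2 = viable, 3 = healthy).
#'
#' @param mesh A `tumor_mesh`.
#' @param path Output file.
#' @param point_data Named list of nodal vectors (e.g.
#'   `list(pressure_mmHg = P)`).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list()) {
  nn <- nrow(mesh$nodes); nel <- nrow(mesh$elements)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tumorflow mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nn)), con)
  utils::write.table(cbind(mesh$nodes, 0), con, row.names = FALSE,
                     col.names = FALSE)
  writeLines(sprintf("CELLS %d %d", nel, 4 * nel), con)
  utils::write.table(cbind(3L, mesh$elements[, 1:3] - 1L), con,
                     row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("CELL_TYPES %d", nel), con)
  writeLines(as.character(rep(5L, nel)), con)
  writeLines(sprintf("CELL_DATA %d", nel), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(as.integer(mesh$region)), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nn), con)
    for (nmf in names(point_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nmf),
                   "LOOKUP_TABLE default"), con)
      writeLines(format(point_data[[nmf]], digits = 10), con)
    }
  }
  invisible(path)
}

#' Write a radial (r, P, v) profile to CSV
#'
#' @param sol A `radial_flow` solution.
#' @param path Output file.
#' @param dr Sampling step [cm].
#' @return `path`, invisibly.
#' @export
write_radial_profile <- function(sol, path, dr = 1e-3) {
  rr <- seq(0, sol$geometry$Rht, by = dr)
  utils::write.csv(predict(sol, rr, what = "both"), path, row.names = FALSE)
  invisible(path)
}

#' Write a summary list as JSON
#' @param x Named list of scalars/vectors.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
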