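# Minimal VTK-legacy (ASCII) writers for particle snapshots and triangle
# meshes. Only the subset of the format the package emits is implemented.

pad3 <- function(x) {
  if (ncol(x) == 2) cbind(x, 0) else x
}

vtk_data_block <- function(con, data, n) {
  for (nm in names(data)) {
    v <- data[[nm]]
    if (is.matrix(v)) {
      stopifnot(nrow(v) == n)
      writeLines(sprintf("VECTORS %s float", nm), con)
      writeLines(apply(pad3(v), 1, paste, collapse = " "), con)
    } else {
      stopifnot(length(v) == n)
      writeLines(sprintf("SCALARS %s float 1", nm), con)
      writeLines("LOOKUP_TABLE default", con)
      writeLines(format(v, scientific = TRUE), con)
    }
  }
}

#' Write a particle snapshot as a VTK-legacy file
#'
#' @param path Output file.
#' @param pos Particle positions (n x 2 or n x 3).
#' @param point_data Named list of per-particle scalars (vectors) or vector
#'   fields (matrices).
#' @return `path`, invisibly.
#' @export
write_vtk_points <- function(path, pos, point_data = list()) {
  n <- nrow(pos)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "nestedfsi particle snapshot",
               "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", n)), con)
  writeLines(apply(pad3(pos), 1, paste, collapse = " "), con)
  writeLines(sprintf("VERTICES %d %d", n, 2 * n), con)
  writeLines(paste(1, seq_len(n) - 1), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    vtk_data_block(con, point_data, n)
  }
  invisible(path)
}

#' Write a triangle mesh as a VTK-legacy unstructured grid
#'
#' @param path Output file.
#' @param X Node positions (n x 2 or n x 3).
#' @param tri Triangle connectivity (m x 3, 1-based).
#' @param point_data,cell_data Named lists of nodal / per-element fields.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(path, X, tri, point_data = list(),
                           cell_data = list()) {
  n <- nrow(X); m <- nrow(tri)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "nestedfsi solid mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d float", n)), con)
  writeLines(apply(pad3(X), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", m, 4 * m), con)
  writeLines(apply(cbind(3, tri - 1), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(5L, m)), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    vtk_data_block(con, point_data, n)
  }
  if (length(cell_data)) {
    writeLines(sprintf("CELL_DATA %d", m), con)
    vtk_data_block(con, cell_data, m)
  }
  invisible(path)
}

#' Write a nested model as VTK components plus a JSON sidecar
#'
#' One VTK-legacy file per solid mesh and fluid particle set (rest state),
#' plus `model.json` echoing the configuration and the landmark registry
#' with baseline distances.
#'
#' @param model A [build_nested_model()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_model_vtk <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("uterus", "fetal_body", "skull", "brain")) {
    m <- model[[nm]]
    write_vtk_mesh(file.path(dir, sprintf("%s_rest.vtk", nm)), m$X, m$tri)
  }
  for (nm in c("amniotic_fluid", "csf")) {
    f <- model[[nm]]
    write_vtk_points(file.path(dir, sprintf("%s_rest.vtk", nm)), f$pos,
                     point_data = list(density = f$rho, pressure = f$p))
  }
  jsonlite::write_json(
    list(config = unclass(model$config),
         landmarks = as.data.frame(model$landmarks)),
    file.path(dir, "model.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
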