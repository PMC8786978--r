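## Snapshot output: legacy-VTK polydata for meshes, fibers and filaments,
## CSV tables for filaments, linkers and fiber edge lists.

#' Write a triangle mesh as legacy VTK polydata
#'
#' @param mesh a membrane layer.
#' @param path output file.
#' @param scalars optional per-node scalar (e.g. force magnitude).
#' @param name scalar field name.
#' @export
write_vtk_mesh <- function(mesh, path, scalars = NULL, name = "force") {
  con <- file(path, "w")
  on.exit(close(con))
  X <- mesh$X; tri <- mesh$tri
  writeLines(c("# vtk DataFile Version 3.0", "invadosim mesh", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(X))), con)
  utils::write.table(format(X, trim = TRUE), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(sprintf("POLYGONS %d %d", nrow(tri), nrow(tri) * 4L), con)
  utils::write.table(cbind(3L, tri - 1L), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(scalars)) {
    writeLines(c(sprintf("POINT_DATA %d", nrow(X)),
                 sprintf("SCALARS %s float 1", name),
                 "LOOKUP_TABLE default"), con)
    writeLines(format(scalars, trim = TRUE), con)
  }
  invisible(path)
}

#' Write polylines (filaments or fibers) as legacy VTK
#'
#' @param X node matrix.
#' @param lines list of integer index vectors (1-based chains).
#' @param path output file.
#' @export
write_vtk_lines <- function(X, lines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "invadosim lines", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(X))), con)
  utils::write.table(format(X, trim = TRUE), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  sz <- sum(vapply(lines, length, integer(1))) + length(lines)
  writeLines(sprintf("LINES %d %d", length(lines), sz), con)
  for (ln in lines)
    writeLines(paste(c(length(ln), ln - 1L), collapse = " "), con)
  invisible(path)
}

#' Filament snapshot as a data.frame / CSV
#'
#' Columns: filament id, node index within the filament, x, y, z, state.
#'
#' @param net `actin_network`.
#' @param path optional CSV path; when NULL the data.frame is returned
#'   without writing.
#' @return the snapshot data.frame, invisibly when written.
#' @export
filament_snapshot <- function(net, path = NULL) {
  rows <- list()
  for (f in seq_along(net$filaments)) {
    fl <- net$filaments[[f]]
    if (is.null(fl) || !fl$alive) next
    P <- net$X[fl$nodes, , drop = FALSE]
    rows[[length(rows) + 1L]] <- data.frame(
      filament = f, node = seq_along(fl$nodes),
      x = P[, 1], y = P[, 2], z = P[, 3], state = fl$state)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(filament = integer(0), node = integer(0), x = numeric(0),
               y = numeric(0), z = numeric(0), state = integer(0))
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Fiber network edge list as a data.frame / CSV
#'
#' @param ecm `ecm_network`.
#' @param path optional CSV path.
#' @return data.frame with fiber id, node ids, coordinates, intact flag.
#' @export
ecm_snapshot <- function(ecm, path = NULL) {
  sg <- ecm$seg
  out <- data.frame(fiber = sg$fiber, n1 = sg$n1, n2 = sg$n2,
                    x1 = ecm$X[sg$n1, 1], y1 = ecm$X[sg$n1, 2],
                    z1 = ecm$X[sg$n1, 3],
                    x2 = ecm$X[sg$n2, 1], y2 = ecm$X[sg$n2, 2],
                    z2 = ecm$X[sg$n2, 3],
                    intact = sg$intact)
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Reaction-diffusion field snapshot as flat CSV
#'
#' @param field `rd_field`.
#' @param path optional CSV path.
#' @return data.frame with i, j, k and phi1..phi6.
#' @export
rd_snapshot <- function(field, path = NULL) {
  g <- expand.grid(i = seq_len(field$dims[1]),
                   j = seq_len(field$dims[2]),
                   k = seq_len(field$dims[3]))
  for (s in paste0("phi", 1:6)) g[[s]] <- as.numeric(field[[s]])
  if (!is.null(path)) {
    utils::write.csv(g, path, row.names = FALSE)
    return(invisible(g))
  }
  g
}
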