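# Plain-text exports: legacy VTK for meshes/fields (corner-node
# sub-mesh, linear cells, the standard way quadratic poro-meshes are
# visualized) and CSV for scalar histories.

#' Write a mesh and nodal fields to a legacy VTK file
#'
#' Exports the corner-node sub-mesh (linear hexahedra or quadrilaterals)
#' with optional point data, e.g. displacement or chemical potential, for
#' visualization.
#'
#' @param mesh a \code{PoroMesh}.
#' @param file output path (.vtk).
#' @param point_data named list of per-node vectors (length = number of
#'   nodes) or matrices (nodes x components).
#' @return \code{file}, invisibly.
#' @export
write_vtk <- function(mesh, file, point_data = list()) {
  ndim <- if (mesh$dim == 3) 3L else 2L
  corner_local <- if (ndim == 3) c(1, 3, 9, 7, 19, 21, 27, 25)
                  else c(1, 3, 9, 7)
  cells <- mesh$elems[, corner_local, drop = FALSE]
  used <- sort(unique(as.vector(cells)))
  remap <- integer(nrow(mesh$nodes)); remap[used] <- seq_along(used) - 1L
  xyz <- cbind(mesh$nodes[used, , drop = FALSE],
               matrix(0, length(used), 3 - ndim))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "skinphase export", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", length(used), "double")), con)
  utils::write.table(format(xyz, digits = 10), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  ncell <- nrow(cells)
  npc <- ncol(cells)
  writeLines(paste("CELLS", ncell, ncell * (npc + 1)), con)
  utils::write.table(cbind(npc, matrix(remap[cells], ncell, npc)), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(paste("CELL_TYPES", ncell), con)
  writeLines(as.character(rep(if (ndim == 3) 12L else 9L, ncell)), con)
  writeLines(paste("CELL_DATA", ncell), con)
  writeLines(c("SCALARS layer int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(mesh$layer), con)
  if (length(point_data)) {
    writeLines(paste("POINT_DATA", length(used)), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v) && ncol(v) > 1) {
        v3 <- cbind(v[used, , drop = FALSE],
                    matrix(0, length(used), 3 - ncol(v)))
        writeLines(paste("VECTORS", nm, "double"), con)
        utils::write.table(format(v3, digits = 10), con,
                           row.names = FALSE, col.names = FALSE,
                           quote = FALSE)
      } else {
        v <- if (is.matrix(v)) v[used, 1] else v[used]
        writeLines(c(paste("SCALARS", nm, "double 1"),
                     "LOOKUP_TABLE default"), con)
        writeLines(format(v, digits = 10), con)
      }
    }
  }
  invisible(file)
}

#' Write the scalar series of a protocol result to CSV files
#'
#' One CSV per quantity (tensions per layer, apparent stretches,
#' deflection, apex displacement, layer thickness ratios -- whichever the
#' protocol produced) plus a \code{summary.csv} of scalar outputs. All
#' quantities are in mm-N-s-MPa units; tensions in N/mm.
#'
#' @param result a \code{ProtocolResult}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
export_result_csv <- function(result, dir) {
  stopifnot(inherits(result, "ProtocolResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, name)
    utils::write.csv(d, file.path(dir, paste0(name, ".csv")),
                     row.names = FALSE)
  if (!is.null(result$tensions))
    for (nm in names(result$tensions))
      wr(result$tensions[[nm]], paste0("tension_", nm))
  if (!is.null(result$moduli)) {
    m <- as.data.frame(result$moduli)
    m <- cbind(layer = rownames(result$moduli), m)
    wr(m, "moduli_MPa")
  }
  for (nm in c("apparent", "deflection", "apex", "thickness", "decay"))
    if (!is.null(result[[nm]])) wr(result[[nm]], nm)
  if (!is.null(result$summary))
    wr(data.frame(key = names(result$summary),
                  value = unlist(result$summary)), "summary")
  invisible(dir)
}
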