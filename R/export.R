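# Export/import helpers: minimal ASCII VTU writer for meshes and solution
# fields (quadratic tetrahedra, VTK cell type 24) and YAML run configuration.

#' Write a mesh (and optional fields) to an ASCII VTU file
#'
#' @param mesh a `labeled_mesh`.
#' @param path output file path (.vtu).
#' @param point_data named list of per-node scalars or n x 3 matrices.
#' @param cell_data named list of per-element scalars.
#' @return the path, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$nodes); ne <- nrow(mesh$elems)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  num <- function(x) paste(format(x, digits = 9, trim = TRUE,
                                  scientific = FALSE), collapse = " ")
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid>')
  w(sprintf('<Piece NumberOfPoints="%d" NumberOfCells="%d">', n, ne))
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1, num), con)
  w('</DataArray></Points>')
  w('<Cells>')
  w('<DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$elems - 1L, 1, paste, collapse = " "), con)
  w('</DataArray>')
  w('<DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(paste(10L * seq_len(ne), collapse = " "), con)
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(24L, ne), collapse = " "), con)
  w('</DataArray>')
  w('</Cells>')
  cd <- c(list(region = as.integer(factor(mesh$region))), cell_data)
  w('<CellData>')
  for (nm in names(cd)) {
    w(sprintf('<DataArray type="Float64" Name="%s" format="ascii">', nm))
    writeLines(paste(format(as.numeric(cd[[nm]]), digits = 9, trim = TRUE),
                     collapse = " "), con)
    w('</DataArray>')
  }
  w('</CellData>')
  if (length(point_data)) {
    w('<PointData>')
    for (nm in names(point_data)) {
      x <- point_data[[nm]]
      nc <- if (is.matrix(x)) ncol(x) else 1L
      w(sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">',
                nm, nc))
      if (is.matrix(x)) writeLines(apply(x, 1, num), con)
      else writeLines(paste(format(as.numeric(x), digits = 9, trim = TRUE),
                            collapse = " "), con)
      w('</DataArray>')
    }
    w('</PointData>')
  }
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Recognized blocks: `geometry:` ([mandible_params()] arguments),
#' `loading:` (scale), `fixation:` (gap_width), plus `mode`, `scenarios`
#' (`all` or a list of site/material/thickness entries), `levels`, `seed`
#' and `out`.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  scen <- y$scenarios
  if (!is.null(scen) && !identical(scen, "all"))
    scen <- do.call(rbind, lapply(scen, function(s)
      data.frame(site = s$site, material = s$material,
                 thickness = as.numeric(s$thickness))))
  run_config(geometry = if (is.null(y$geometry)) list() else y$geometry,
             scenarios = if (is.null(scen)) "all" else scen,
             scale = if (is.null(y$loading$scale)) 0.2 else y$loading$scale,
             gap_width = if (is.null(y$fixation$gap_width)) 1.2
                         else y$fixation$gap_width,
             mode = if (is.null(y$mode)) "study" else y$mode,
             levels = if (is.null(y$levels)) c(2.0, 1.0, 0.5)
                      else as.numeric(y$levels),
             seed = if (is.null(y$seed)) 1L else y$seed,
             out = y$out)
}
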