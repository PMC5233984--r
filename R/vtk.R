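#' Export grids and fields to legacy VTK
#'
#' Writes ASCII legacy-VTK structured-points files for inspection in
#' ParaView or similar: tissue labels as cell data for a [labeled_grid()],
#' nodal potential as point data for a `potential_field`, and field
#' magnitude plus vector components as cell data for a `field_samples`.
#'
#' @param x A `labeled_grid`, `potential_field` or `field_samples`.
#' @param path Output file path (conventionally `.vtk`).
#' @return Invisibly, `path`.
#' @export
write_vtk <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- function(dims, origin, spacing) {
    cat("# vtk DataFile Version 3.0\n", file = con)
    cat("tcranchan export\nASCII\nDATASET STRUCTURED_POINTS\n", file = con)
    cat(sprintf("DIMENSIONS %d %d %d\n", dims[1], dims[2], dims[3]), file = con)
    cat(sprintf("ORIGIN %g %g %g\n", origin[1], origin[2], origin[3]), file = con)
    cat(sprintf("SPACING %g %g %g\n", spacing, spacing, spacing), file = con)
  }
  wvec <- function(v) {
    writeLines(paste(formatC(v, format = "g", digits = 7), collapse = " "), con)
  }
  if (inherits(x, "labeled_grid")) {
    spec <- x$spec
    hdr(spec$shape + 1L, spec$origin, spec$spacing)
    cat(sprintf("CELL_DATA %d\n", prod(spec$shape)), file = con)
    cat("SCALARS tissue int 1\nLOOKUP_TABLE default\n", file = con)
    writeLines(paste(as.integer(x$labels), collapse = " "), con)
  } else if (inherits(x, "potential_field")) {
    spec <- x$spec
    hdr(spec$shape + 1L, spec$origin, spec$spacing)
    cat(sprintf("POINT_DATA %d\n", prod(spec$shape + 1L)), file = con)
    cat("SCALARS phi double 1\nLOOKUP_TABLE default\n", file = con)
    wvec(as.numeric(x$phi))
  } else if (inherits(x, "field_samples")) {
    spec <- x$spec
    hdr(spec$shape + 1L, spec$origin, spec$spacing)
    cat(sprintf("CELL_DATA %d\n", prod(spec$shape)), file = con)
    cat("SCALARS E_mag double 1\nLOOKUP_TABLE default\n", file = con)
    wvec(as.numeric(x$mag))
    cat("VECTORS E double\n", file = con)
    m <- cbind(as.numeric(x$Ex), as.numeric(x$Ey), as.numeric(x$Ez))
    writeLines(paste(apply(m, 1, function(r)
      paste(formatC(r, format = "g", digits = 7), collapse = " ")),
      collapse = "\n"), con)
  } else {
    stop("no VTK writer for objects of class ", paste(class(x), collapse = "/"))
  }
  invisible(path)
}

#' Per-tissue field summary
#'
#' @param fs A `field_samples`.
#' @return Data frame: tissue, cell count, max and mean |E| (V/m).
#' @export
field_summary <- function(fs) {
  stopifnot(inherits(fs, "field_samples"))
  out <- list()
  for (nm in names(TISSUES)) {
    sel <- fs$labels == TISSUES[[nm]]
    if (!any(sel) || nm == "AIR") next
    out[[nm]] <- data.frame(tissue = nm, n_cells = sum(sel),
                            max_E = max(fs$mag[sel]),
                            mean_E = mean(fs$mag[sel]))
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
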