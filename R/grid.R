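#' Tissue label codes
#'
#' Integer codes used in [labeled_grid()] label arrays. `AIR` is the exterior
#' complement; every cell of a grid carries exactly one label.
#'
#' @format Named integer vector with entries `AIR`, `SCALP`, `SKULL`, `DURA`,
#'   `CSF`, `GM`, `WM`, `GEL`, `ELECTRODE`, `CHANNEL`.
#' @export
TISSUES <- c(
  AIR = 0L, SCALP = 1L, SKULL = 2L, DURA = 3L, CSF = 4L,
  GM = 5L, WM = 6L, GEL = 7L, ELECTRODE = 8L, CHANNEL = 9L
)

#' Default isotropic tissue conductivities (S/m)
#'
#' Literature values for the quasi-static volume-conduction model: scalp
#' 0.465, skull 0.01, dura mater 0.065, CSF 1.65, gray matter 0.276, white
#' matter 0.126, electrode gel 0.30, electrode metal 5.8e7, and a titanium
#' transcranial channel at 7.4e5. `AIR` is non-conducting and is excluded
#' from the discretized system rather than given a conductivity.
#'
#' @return Named numeric vector (S/m) over all conducting tissue labels.
#' @export
default_conductivities <- function() {
  c(
    SCALP = 0.465, SKULL = 0.01, DURA = 0.065, CSF = 1.65,
    GM = 0.276, WM = 0.126, GEL = 0.30,
    ELECTRODE = 5.80e7, CHANNEL = 7.40e5
  )
}

#' Structured grid specification
#'
#' Describes an axis-aligned voxel grid of isotropic spacing. Cell
#' `(i, j, k)` (0-based) occupies the half-open box
#' `[origin + i*spacing, origin + (i+1)*spacing)` per axis.
#'
#' @param origin Numeric 3-vector, position of the grid corner (mm).
#' @param spacing Isotropic cell edge length (mm), > 0.
#' @param shape Integer 3-vector, number of cells per axis (each >= 2).
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(origin, spacing, shape) {
  origin <- as.numeric(origin)
  shape <- as.integer(shape)
  stopifnot(length(origin) == 3, length(shape) == 3)
  if (!is.numeric(spacing) || length(spacing) != 1 || spacing <= 0)
    stop("spacing must be a positive scalar (mm)")
  if (any(shape < 2L)) stop("grid shape components must be >= 2")
  structure(list(origin = origin, spacing = spacing, shape = shape),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d cells, spacing %g mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Labeled voxel grid
#'
#' Container pairing a [grid_spec()] with an integer array of per-cell tissue
#' labels (codes from [TISSUES]).
#'
#' @param spec A `grid_spec`.
#' @param labels Integer array with `dim == spec$shape`.
#' @return Object of class `labeled_grid`.
#' @export
labeled_grid <- function(spec, labels) {
  stopifnot(inherits(spec, "grid_spec"))
  labels <- as.integer(labels)
  if (length(labels) != prod(spec$shape))
    stop("labels length does not match grid shape")
  dim(labels) <- spec$shape
  if (!all(labels %in% TISSUES)) stop("unknown tissue label code in grid")
  structure(list(spec = spec, labels = labels), class = "labeled_grid")
}

#' @export
print.labeled_grid <- function(x, ...) {
  print(x$spec)
  tab <- table(factor(x$labels, levels = TISSUES, labels = names(TISSUES)))
  tab <- tab[tab > 0]
  v <- x$spec$spacing^3
  cat("cell counts (volume mm^3):\n")
  for (nm in names(tab))
    cat(sprintf("  %-9s %9d  (%.1f)\n", nm, tab[[nm]], tab[[nm]] * v))
  invisible(x)
}

#' @export
summary.labeled_grid <- function(object, ...) {
  print(object)
  invisible(object)
}

# cell-center coordinates along one axis (mm)
axis_centers <- function(spec, axis) {
  spec$origin[axis] + (seq_len(spec$shape[axis]) - 0.5) * spec$spacing
}

# full arrays of cell-center coordinates, as three vectors recycled over the
# cell array in column-major order
cell_center_arrays <- function(spec) {
  cx <- axis_centers(spec, 1); cy <- axis_centers(spec, 2); cz <- axis_centers(spec, 3)
  nx <- spec$shape[1]; ny <- spec$shape[2]; nz <- spec$shape[3]
  list(
    x = rep(cx, times = ny * nz),
    y = rep(rep(cy, each = nx), times = nz),
    z = rep(cz, each = nx * ny)
  )
}

# physical bounds of the grid (mm): 3x2 matrix
grid_bounds <- function(spec) {
  cbind(spec$origin, spec$origin + spec$shape * spec$spacing)
}
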