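#' Region-of-interest specification for neuron placement
#'
#' @param center (x, y) of the ROI center on the cortical crown (mm);
#'   `NULL` uses the fold crown under the undisplaced montage, (0, 0).
#' @param radius ROI radius (mm), default 5.
#' @param spacing Tangent-plane lattice spacing between neurons (mm);
#'   the default 0.84 yields about 112 placements on a 5 mm disc.
#' @return Object of class `roi_spec`.
#' @export
roi_spec <- function(center = NULL, radius = 5, spacing = 0.84) {
  if (radius <= 0) stop("ROI radius must be > 0")
  if (spacing <= 0) stop("neuron lattice spacing must be > 0")
  structure(list(center = center, radius = radius, spacing = spacing),
            class = "roi_spec")
}

# rotation matrix mapping e_z onto unit vector n (Rodrigues)
rotation_to <- function(n) {
  n <- n / sqrt(sum(n^2))
  ez <- c(0, 0, 1)
  v <- c(ez[2] * n[3] - ez[3] * n[2],
         ez[3] * n[1] - ez[1] * n[3],
         ez[1] * n[2] - ez[2] * n[1])
  c_ <- sum(ez * n)
  if (abs(c_ + 1) < 1e-12) return(diag(c(1, -1, -1)))   # antipodal
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# scan the grid column through (x, y): returns list(surface = z of CSF/GM
# interface (mm), gm_thickness (mm), cell = c(i,j,k) of the top GM cell) or
# NULL when the column holds no GM
column_cortex <- function(grid, x, y) {
  spec <- grid$spec
  h <- spec$spacing
  i <- floor((x - spec$origin[1]) / h) + 1L
  j <- floor((y - spec$origin[2]) / h) + 1L
  if (i < 1 || j < 1 || i > spec$shape[1] || j > spec$shape[2]) return(NULL)
  col <- grid$labels[i, j, ]
  gm_k <- which(col == TISSUES[["GM"]])
  if (length(gm_k) == 0) return(NULL)
  k_top <- max(gm_k)
  list(surface = spec$origin[3] + k_top * h,
       gm_thickness = length(gm_k) * h,
       cell = c(i, j, k_top))
}

#' Place a neuron perpendicular to the cortical surface
#'
#' Transforms a morphology from its local frame (+z toward the pia) to grid
#' coordinates: the local +z axis is aligned with the outward cortical
#' normal, the soma is set at a fractional depth of the local gray-matter
#' thickness, the apical tree is stretched along its axis so the tip reaches
#' the layer-1 band (top 10% of the GM), and for L5 cells the axon is
#' stretched so landmark `b1` falls on the GM/WM boundary. Stretch factors
#' are recorded on the result.
#'
#' @param m A [morphology()] from [build_pn()] or [read_swc()].
#' @param surface_point Point on the CSF/GM boundary (mm, length 3).
#' @param normal Outward cortical normal at that point (unit 3-vector).
#' @param gm_thickness Local gray-matter thickness (mm).
#' @param depth_frac Somatic depth as a fraction of GM thickness; defaults
#'   to 0.75 for L5 and 0.4 for L3.
#' @return Object of class `placed_neuron`: list with the transformed
#'   `morph`, `soma_depth` (mm), `surface_point`, `normal`, `scale_apical`,
#'   `scale_axon`, `kind`.
#' @export
place_neuron <- function(m, surface_point, normal, gm_thickness,
                         depth_frac = NULL) {
  stopifnot(inherits(m, "morphology"))
  if (is.null(depth_frac))
    depth_frac <- if (identical(m$kind, "L3")) 0.4 else 0.75
  if (gm_thickness <= 0) stop("neuron cannot fit: no gray matter at this point")
  soma_depth <- depth_frac * gm_thickness
  if (soma_depth <= m$comp$diam[1] * 1e-3 / 2)
    stop("neuron cannot fit: GM thinner than the somatic depth")
  comp <- m$comp
  x <- comp$x; y <- comp$y; z <- comp$z
  apical <- comp$part == "apical_dendrite"
  # stretch the apical tree so its tip reaches the middle of the layer-1
  # band (5% GM depth)
  scale_apical <- 1
  if (any(apical)) {
    tip <- max(z[apical])
    target <- soma_depth - 0.05 * gm_thickness
    if (tip > 0) scale_apical <- target / tip
    z[apical] <- z[apical] * scale_apical
  }
  scale_axon <- 1
  axonal <- comp$part == "axon"
  if (any(axonal)) {
    if (identical(m$kind, "L5") && "b1" %in% names(m$landmarks)) {
      z_b1 <- -comp$z[match(m$landmarks[["b1"]], comp$id)]
      target <- gm_thickness - soma_depth            # soma to GM/WM boundary
      if (z_b1 > 0) scale_axon <- target / z_b1
    } else if (identical(m$kind, "L3")) {
      ext <- -min(z[axonal])
      target <- (0.95 - depth_frac) * gm_thickness   # keep terminal inside GM
      if (ext > 0) scale_axon <- target / ext
    }
    z[axonal] <- z[axonal] * scale_axon
  }
  R <- rotation_to(normal)
  pts <- cbind(x, y, z) %*% t(R)
  soma_pos <- surface_point - normal * soma_depth
  comp$x <- pts[, 1] + soma_pos[1]
  comp$y <- pts[, 2] + soma_pos[2]
  comp$z <- pts[, 3] + soma_pos[3]
  out <- m
  out$comp <- comp
  structure(list(morph = out, soma_depth = soma_depth,
                 surface_point = surface_point, normal = normal,
                 gm_thickness = gm_thickness,
                 scale_apical = scale_apical, scale_axon = scale_axon,
                 kind = m$kind),
            class = "placed_neuron")
}

#' @export
print.placed_neuron <- function(x, ...) {
  cat(sprintf("placed_neuron (%s): soma %.2f mm below surface (%.1f, %.1f, %.1f); apical x%.2f, axon x%.2f\n",
              x$kind, x$soma_depth, x$surface_point[1], x$surface_point[2],
              x$surface_point[3], x$scale_apical, x$scale_axon))
  invisible(x)
}

#' Populate the ROI with neurons
#'
#' Places one neuron at each point of a regular square lattice in the ROI
#' tangent plane (row-major order, deterministic), clipped to the ROI disc.
#' Each lattice point is projected onto the CSF/GM surface along z; the
#' local normal is taken from the smoothed-indicator surface normals and the
#' local GM thickness from the grid column.
#'
#' @param grid A [labeled_grid()] head model.
#' @param roi A [roi_spec()].
#' @param kind `"L5"` or `"L3"`.
#' @param params A [morph_params()].
#' @param normals Optional precomputed [surface_normals()] for `grid`.
#' @param jitter Standard deviation (mm) of an optional random lateral
#'   offset added to each lattice point (uses the current RNG state; seed
#'   it for reproducibility). Default 0: fully deterministic placement.
#' @return List of `placed_neuron` objects.
#' @export
populate_roi <- function(grid, roi = roi_spec(), kind = "L5",
                         params = morph_params(), normals = NULL,
                         jitter = 0) {
  stopifnot(inherits(grid, "labeled_grid"), inherits(roi, "roi_spec"))
  ctr <- roi$center
  if (is.null(ctr)) ctr <- c(0, 0)
  if (is.null(normals)) normals <- surface_normals(grid)
  m0 <- build_pn(kind, params)
  s <- roi$spacing
  nsteps <- floor(roi$radius / s)
  offs <- (-nsteps:nsteps) * s
  placed <- list()
  for (oy in offs) for (ox in offs) {      # row-major
    if (ox^2 + oy^2 > roi$radius^2) next
    x <- ctr[1] + ox; y <- ctr[2] + oy
    if (jitter > 0) {
      x <- x + stats::rnorm(1, 0, jitter)
      y <- y + stats::rnorm(1, 0, jitter)
    }
    colinfo <- column_cortex(grid, x, y)
    if (is.null(colinfo)) next
    # normal at the top GM cell of this column
    hit <- which(normals$i == colinfo$cell[1] & normals$j == colinfo$cell[2] &
                   normals$k == colinfo$cell[3])
    n <- if (length(hit) == 1) {
      c(normals$nx[hit], normals$ny[hit], normals$nz[hit])
    } else c(0, 0, 1)
    sp <- c(x, y, colinfo$surface)
    placed[[length(placed) + 1L]] <-
      place_neuron(m0, sp, n, colinfo$gm_thickness)
  }
  if (length(placed) == 0) stop("ROI produced no neuron placements")
  placed
}

#' Placement summary table
#'
#' One row per placed neuron: index, somatic position and depth, local GM
#' thickness, stretch factors, and the coordinates of each landmark.
#'
#' @param neurons List of `placed_neuron` objects (e.g. from
#'   [populate_roi()]).
#' @return Data frame suitable for CSV export.
#' @export
placement_table <- function(neurons) {
  rows <- lapply(seq_along(neurons), function(q) {
    pn <- neurons[[q]]
    comp <- pn$morph$comp
    soma <- comp[1, ]
    out <- data.frame(id = q, kind = pn$kind,
                      soma_x = soma$x, soma_y = soma$y, soma_z = soma$z,
                      soma_depth = pn$soma_depth,
                      gm_thickness = pn$gm_thickness,
                      scale_apical = pn$scale_apical,
                      scale_axon = pn$scale_axon)
    lm <- pn$morph$landmarks
    for (nm in names(lm)) {
      r <- comp[match(lm[[nm]], comp$id), ]
      out[[paste0(nm, "_x")]] <- r$x
      out[[paste0(nm, "_y")]] <- r$y
      out[[paste0(nm, "_z")]] <- r$z
    }
    out
  })
  do.call(rbind, rows)
}
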