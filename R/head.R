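#' Parametric layered-head parameters
#'
#' Describes the simplified slab head: flat scalp/skull/dura layers stacked
#' along z, a CSF-filled gap, and a gray-matter ribbon whose upper surface
#' follows a sinusoidal gyral fold with one crown (a hand-knob-like ridge)
#' centered under the montage origin, white matter filling the remainder.
#'
#' All lengths in mm. `csf` is the CSF thickness above the fold crown; in the
#' troughs the CSF gap widens by twice the fold amplitude. `wm_min` is the
#' minimum white-matter thickness beneath the deepest point of the gray
#' matter. `headroom` is the air gap kept above the scalp for the gel and
#' electrode assemblies.
#'
#' @param scalp,skull,dura,csf,gm Layer thicknesses (mm). Dura defaults to
#'   0.5 mm.
#' @param wm_min Minimum WM thickness (mm).
#' @param fold_amplitude Half peak-to-trough height of the gyral fold (mm).
#' @param fold_wavelength Spatial period of the fold along x (mm).
#' @param lateral_extent Side length of the square lateral domain (mm).
#' @param headroom Air above the scalp surface (mm); must fit gel + electrode.
#' @return Object of class `head_params`.
#' @export
head_params <- function(scalp = 5, skull = 7, dura = 0.5, csf = 2, gm = 2.5,
                        wm_min = 4, fold_amplitude = 2, fold_wavelength = 28,
                        lateral_extent = 84, headroom = 4) {
  p <- list(scalp = scalp, skull = skull, dura = dura, csf = csf, gm = gm,
            wm_min = wm_min, fold_amplitude = fold_amplitude,
            fold_wavelength = fold_wavelength,
            lateral_extent = lateral_extent, headroom = headroom)
  thick <- unlist(p[c("scalp", "skull", "dura", "csf", "gm", "wm_min")])
  if (any(thick < 0)) stop("layer thicknesses must be >= 0")
  if (p$fold_amplitude < 0 || p$fold_wavelength <= 0)
    stop("fold amplitude must be >= 0 and wavelength > 0")
  structure(p, class = "head_params")
}

# total stack height (mm) of a head_params
head_height <- function(head) {
  head$headroom + head$scalp + head$skull + head$dura + head$csf +
    2 * head$fold_amplitude + head$gm + head$wm_min
}

#' Grid specification fitting a parametric head
#'
#' Builds a [grid_spec()] whose lateral extent is centered on (0, 0) — the
#' montage origin and fold crown — and whose height exactly accommodates the
#' head stack plus electrode headroom.
#'
#' @param head A [head_params()] object.
#' @param spacing Isotropic voxel spacing (mm), default 0.5.
#' @return A `grid_spec`.
#' @export
head_grid <- function(head, spacing = 0.5) {
  L <- head$lateral_extent
  H <- head_height(head)
  shape <- c(round(L / spacing), round(L / spacing), ceiling(H / spacing))
  grid_spec(origin = c(-L / 2, -L / 2, 0), spacing = spacing, shape = shape)
}

# z (mm) of the flat scalp top for a head built on `spec`
scalp_top_z <- function(spec, head) {
  spec$origin[3] + spec$shape[3] * spec$spacing - head$headroom
}

#' Build the simplified layered head model
#'
#' Labels every cell of the grid by membership in the head stack: air above
#' the scalp, then scalp, skull, dura, CSF, gray matter and white matter.
#' The CSF/GM interface (and the GM/WM interface below it) follows
#' `z(x) = z_crown + A (cos(2 pi x / W) - 1)`: a ridge running along y whose
#' crown sits at x = 0, directly under the default montage center.
#'
#' @param grid A [grid_spec()]; typically from [head_grid()].
#' @param head A [head_params()] object.
#' @return A [labeled_grid()].
#' @export
build_head_model <- function(grid, head) {
  stopifnot(inherits(grid, "grid_spec"), inherits(head, "head_params"))
  H <- grid$shape[3] * grid$spacing
  need <- c(headroom = head$headroom, scalp = head$scalp, skull = head$skull,
            dura = head$dura, csf = head$csf + 2 * head$fold_amplitude,
            gm = head$gm, wm = head$wm_min)
  cum <- cumsum(need)
  if (any(bad <- cum > H + 1e-9)) {
    stop(sprintf("head layers exceed grid z extent (%.1f mm): layer '%s' does not fit",
                 H, names(need)[which(bad)[1]]))
  }
  cc <- cell_center_arrays(grid)
  z_s <- scalp_top_z(grid, head)
  z_skull <- z_s - head$scalp          # scalp/skull interface
  z_dura <- z_skull - head$skull       # skull/dura interface
  z_csf <- z_dura - head$dura          # dura/CSF interface
  # folded CSF/GM interface
  z_gm <- (z_csf - head$csf) +
    head$fold_amplitude * (cos(2 * pi * cc$x / head$fold_wavelength) - 1)
  z_wm <- z_gm - head$gm
  lab <- rep.int(TISSUES[["AIR"]], length(cc$z))
  z <- cc$z
  lab[z <= z_s] <- TISSUES[["SCALP"]]
  lab[z <= z_skull] <- TISSUES[["SKULL"]]
  lab[z <= z_dura] <- TISSUES[["DURA"]]
  lab[z <= z_csf] <- TISSUES[["CSF"]]
  lab[z <= z_gm] <- TISSUES[["GM"]]
  lab[z <= z_wm] <- TISSUES[["WM"]]
  g <- labeled_grid(grid, lab)
  attr(g, "head") <- head
  g
}

#' Concentric-sphere phantom parameters
#'
#' @param radii Numeric vector of shell outer radii (mm), strictly decreasing
#'   from outermost to innermost; the innermost entry bounds a full ball.
#' @param labels Character vector of tissue label names (see [TISSUES]), one
#'   per shell.
#' @param center Sphere center (mm); default `NULL` places it at the grid
#'   center.
#' @return Object of class `sphere_params`.
#' @export
sphere_params <- function(radii, labels, center = NULL) {
  radii <- as.numeric(radii)
  if (length(radii) < 1) stop("need at least one layer radius")
  if (any(diff(radii) >= 0)) stop("sphere radii must be strictly decreasing")
  if (length(labels) != length(radii)) stop("one label per radius required")
  if (!all(labels %in% names(TISSUES))) stop("unknown tissue label name")
  structure(list(radii = radii, labels = labels, center = center),
            class = "sphere_params")
}

#' Voxelize a concentric-sphere phantom
#'
#' Cells are assigned by center-point membership: a cell belongs to the
#' outermost shell whose outer radius its center lies within; cells outside
#' the largest radius are `AIR`.
#'
#' @param grid A [grid_spec()].
#' @param sphere A [sphere_params()].
#' @return A [labeled_grid()] with attribute `sphere` recording the spec.
#' @export
build_sphere_phantom <- function(grid, sphere) {
  stopifnot(inherits(grid, "grid_spec"), inherits(sphere, "sphere_params"))
  ctr <- sphere$center
  if (is.null(ctr)) ctr <- grid$origin + grid$shape * grid$spacing / 2
  b <- grid_bounds(grid)
  if (any(ctr - sphere$radii[1] < b[, 1] - 1e-9) ||
      any(ctr + sphere$radii[1] > b[, 2] + 1e-9))
    stop("outer sphere radius does not fit inside the grid")
  cc <- cell_center_arrays(grid)
  r <- sqrt((cc$x - ctr[1])^2 + (cc$y - ctr[2])^2 + (cc$z - ctr[3])^2)
  lab <- rep.int(TISSUES[["AIR"]], length(r))
  # assign outermost-in so inner shells overwrite
  for (i in seq_along(sphere$radii)) {
    lab[r <= sphere$radii[i]] <- TISSUES[[sphere$labels[i]]]
  }
  g <- labeled_grid(grid, lab)
  attr(g, "sphere") <- list(radii = sphere$radii, labels = sphere$labels,
                            center = ctr)
  g
}

#' Transcranial channel specification
#'
#' An I-shaped channel is a cylindrical shaft traversing the full skull
#' thickness; a T-shaped channel adds a wider hat disc. The hat diameter
#' defaults to the shaft diameter + 1 mm, and the hat sits by default against
#' the outer (scalp-side) skull table, where it collects current arriving
#' from the gel and funnels it into the shaft; `hat_side = "inner"` places
#' it on the dural table instead. The channel occupies skull cells only —
#' it never breaches the dura.
#'
#' @param shape One of `"NONE"`, `"I"`, `"T"`.
#' @param shaft_diameter Shaft diameter (mm).
#' @param hat_diameter Hat disc diameter (mm); default shaft + 1.
#' @param hat_thickness Hat disc thickness (mm), default 1.
#' @param position Length-2 vector: (x, y) of the channel axis (mm).
#' @param hat_side `"inner"` (default) or `"outer"` skull table.
#' @return Object of class `channel_spec`.
#' @export
channel_spec <- function(shape = c("T", "I", "NONE"), shaft_diameter = 7,
                         hat_diameter = shaft_diameter + 1, hat_thickness = 1,
                         position = c(0, 0), hat_side = c("outer", "inner")) {
  shape <- match.arg(shape)
  hat_side <- match.arg(hat_side)
  if (shape != "NONE") {
    stopifnot(shaft_diameter > 0, hat_diameter >= shaft_diameter,
              hat_thickness > 0, length(position) == 2)
  }
  structure(list(shape = shape, shaft_diameter = shaft_diameter,
                 hat_diameter = hat_diameter, hat_thickness = hat_thickness,
                 position = as.numeric(position), hat_side = hat_side),
            class = "channel_spec")
}

#' Carve a transcranial channel into the skull
#'
#' Relabels skull cells inside the shaft cylinder (and the hat disc, for a
#' T-shaped channel) as `CHANNEL`. Only cells labeled `SKULL` are touched, so
#' the channel traverses the entire skull thickness without breaching the
#' dura, and carving conserves the combined skull + channel cell count.
#'
#' @param grid A [labeled_grid()] containing a skull layer.
#' @param chan A [channel_spec()]; shape `"NONE"` returns the grid unchanged.
#' @return The modified [labeled_grid()].
#' @export
carve_channel <- function(grid, chan) {
  stopifnot(inherits(grid, "labeled_grid"), inherits(chan, "channel_spec"))
  if (chan$shape == "NONE") return(grid)
  cc <- cell_center_arrays(grid$spec)
  r2 <- (cc$x - chan$position[1])^2 + (cc$y - chan$position[2])^2
  skull <- grid$labels == TISSUES[["SKULL"]]
  shaft <- skull & (r2 <= (chan$shaft_diameter / 2)^2)
  if (!any(shaft)) stop("channel axis does not intersect the skull layer")
  sel <- shaft
  if (chan$shape == "T") {
    zs <- cc$z[skull]
    if (chan$hat_side == "inner") {
      z0 <- min(zs)
      in_hat_z <- cc$z <= z0 + chan$hat_thickness
    } else {
      z1 <- max(zs)
      in_hat_z <- cc$z >= z1 - chan$hat_thickness
    }
    sel <- sel | (skull & in_hat_z & (r2 <= (chan$hat_diameter / 2)^2))
  }
  lab <- grid$labels
  lab[sel] <- TISSUES[["CHANNEL"]]
  out <- labeled_grid(grid$spec, lab)
  attributes(out) <- utils::modifyList(attributes(grid),
                                       attributes(out)[c("names", "class")])
  attr(out, "channel") <- chan
  out
}

#' 4x1 HD electrode montage specification
#'
#' One active disc electrode over the target plus four return electrodes on a
#' ring, each sitting on a gel pad of matching radius. A displacement vector
#' translates all five electrode + gel assemblies rigidly in the scalp plane
#' (the implanted channel stays fixed).
#'
#' @param center (x, y) position of the active electrode axis (mm).
#' @param ring_radius Radius to the return electrodes (mm), default 35.
#' @param elec_height,elec_radius Electrode disc dimensions (mm): 1 and 4.
#' @param gel_height,gel_radius Gel pad dimensions (mm): 2 and 4.
#' @param current_mA Injected current at the active electrode (mA), default 1.
#' @param displacement Rigid in-plane shift (mm) of the whole montage.
#' @return Object of class `montage_spec`.
#' @export
montage_spec <- function(center = c(0, 0), ring_radius = 35,
                         elec_height = 1, elec_radius = 4,
                         gel_height = 2, gel_radius = 4,
                         current_mA = 1, displacement = c(0, 0)) {
  stopifnot(length(center) == 2, length(displacement) == 2,
            ring_radius > 0, elec_height > 0, elec_radius > 0,
            gel_height > 0, gel_radius > 0, current_mA > 0)
  structure(list(center = as.numeric(center), ring_radius = ring_radius,
                 elec_height = elec_height, elec_radius = elec_radius,
                 gel_height = gel_height, gel_radius = gel_radius,
                 current_mA = current_mA,
                 displacement = as.numeric(displacement)),
            class = "montage_spec")
}

# assembly centers (5 x 2 matrix, active first) after displacement
montage_centers <- function(montage) {
  c0 <- montage$center + montage$displacement
  ang <- c(0, 0.5, 1, 1.5) * pi
  rbind(c0,
        cbind(c0[1] + montage$ring_radius * cos(ang),
              c0[2] + montage$ring_radius * sin(ang)))
}

#' Place the electrode montage on the scalp
#'
#' Stacks a gel pad and an electrode disc on the (flat) scalp surface for the
#' active electrode and the four returns, relabeling the air cells they
#' occupy, and extracts the exposed top faces of each electrode: the active
#' set carries the injected-current (Neumann) boundary condition and the
#' return set the ground (Dirichlet) condition.
#'
#' @param grid A [labeled_grid()] head model.
#' @param montage A [montage_spec()].
#' @return Object of class `placed_montage`: list with elements `grid`
#'   (relabeled), `active_faces`, `return_faces` (data frames with 0-based
#'   cell indices `i, j, k`, `axis`, `side`), and `montage`.
#' @export
place_montage <- function(grid, montage) {
  stopifnot(inherits(grid, "labeled_grid"), inherits(montage, "montage_spec"))
  spec <- grid$spec
  h <- spec$spacing
  # flat scalp assumed: take the top of the scalp layer
  scalp_cells <- which(grid$labels == TISSUES[["SCALP"]], arr.ind = TRUE)
  if (nrow(scalp_cells) == 0) stop("grid contains no scalp layer")
  k_s <- max(scalp_cells[, 3])                    # top scalp cell layer (1-based)
  z_s <- spec$origin[3] + k_s * h                 # scalp surface z (mm)
  n_gel <- round(montage$gel_height / h)
  n_el <- round(montage$elec_height / h)
  if (k_s + n_gel + n_el > spec$shape[3])
    stop("electrode assembly does not fit below the grid top")
  centers <- montage_centers(montage)
  b <- grid_bounds(spec)
  rmax <- max(montage$gel_radius, montage$elec_radius)
  if (any(centers[, 1] - rmax < b[1, 1]) || any(centers[, 1] + rmax > b[1, 2]) ||
      any(centers[, 2] - rmax < b[2, 1]) || any(centers[, 2] + rmax > b[2, 2]))
    stop("electrode footprint lies off the grid")
  cx <- axis_centers(spec, 1); cy <- axis_centers(spec, 2)
  lab <- grid$labels
  face_sets <- vector("list", 5L)
  for (e in seq_len(5L)) {
    in_gel <- outer((cx - centers[e, 1])^2, (cy - centers[e, 2])^2, "+") <=
      montage$gel_radius^2
    in_el <- outer((cx - centers[e, 1])^2, (cy - centers[e, 2])^2, "+") <=
      montage$elec_radius^2
    gel_k <- k_s + seq_len(n_gel)
    el_k <- k_s + n_gel + seq_len(n_el)
    for (k in gel_k) lab[, , k][in_gel] <- TISSUES[["GEL"]]
    for (k in el_k) lab[, , k][in_el] <- TISSUES[["ELECTRODE"]]
    top <- which(in_el, arr.ind = TRUE)
    face_sets[[e]] <- data.frame(i = top[, 1] - 1L, j = top[, 2] - 1L,
                                 k = max(el_k) - 1L, axis = 3L, side = 1L)
  }
  out <- labeled_grid(spec, lab)
  attributes(out) <- utils::modifyList(attributes(grid),
                                       attributes(out)[c("names", "class")])
  structure(list(grid = out,
                 active_faces = face_sets[[1]],
                 return_faces = do.call(rbind, face_sets[2:5]),
                 montage = montage,
                 scalp_z = z_s),
            class = "placed_montage")
}

#' @export
print.placed_montage <- function(x, ...) {
  cat(sprintf("placed_montage: 1 active + 4 return electrodes, ring %g mm, displacement (%g, %g) mm\n",
              x$montage$ring_radius, x$montage$displacement[1],
              x$montage$displacement[2]))
  cat(sprintf("  active faces: %d, return faces: %d\n",
              nrow(x$active_faces), nrow(x$return_faces)))
  invisible(x)
}

# centroid (mm) of a face set (face centers)
face_centroid <- function(faces, spec) {
  h <- spec$spacing
  fx <- spec$origin[1] + (faces$i + 0.5) * h
  fy <- spec$origin[2] + (faces$j + 0.5) * h
  fz <- spec$origin[3] + (faces$k + 0.5) * h + ifelse(faces$axis == 3L, faces$side * h / 2, 0)
  c(mean(fx), mean(fy), mean(fz))
}

#' Boundary faces of a voxelized sphere near a surface point
#'
#' Finds exterior faces (conducting cell adjacent to air) whose centers lie
#' within `patch_radius` of the surface point `R * direction`, for use as
#' electrode patches on sphere phantoms.
#'
#' @param grid A [labeled_grid()] from [build_sphere_phantom()].
#' @param direction Unit 3-vector from the sphere center to the electrode.
#' @param patch_radius Patch radius (mm), default 2.
#' @return Face data frame (`i, j, k, axis, side`, 0-based cell indices).
#' @export
sphere_surface_faces <- function(grid, direction, patch_radius = 2) {
  spec <- grid$spec
  sph <- attr(grid, "sphere")
  if (is.null(sph)) stop("grid does not carry sphere metadata")
  direction <- direction / sqrt(sum(direction^2))
  target <- sph$center + sph$radii[1] * direction
  lab <- grid$labels
  dims <- spec$shape
  air <- TISSUES[["AIR"]]
  faces <- list()
  shift_pad <- function(arr, d, axis) {
    # neighbor labels with out-of-grid treated as AIR
    idx <- lapply(dims, seq_len)
    out <- array(air, dim = dims)
    src <- idx; dst <- idx
    n <- dims[axis]
    if (d > 0) { dst[[axis]] <- seq_len(n - 1); src[[axis]] <- 2:n }
    else { dst[[axis]] <- 2:n; src[[axis]] <- seq_len(n - 1) }
    out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
    out
  }
  h <- spec$spacing
  for (axis in 1:3) for (side in c(-1L, 1L)) {
    nb <- shift_pad(lab, side, axis)
    sel <- which(lab != air & nb == air, arr.ind = TRUE)
    if (nrow(sel) == 0) next
    fc <- cbind(spec$origin[1] + (sel[, 1] - 0.5) * h,
                spec$origin[2] + (sel[, 2] - 0.5) * h,
                spec$origin[3] + (sel[, 3] - 0.5) * h)
    fc[, axis] <- fc[, axis] + side * h / 2
    d2 <- (fc[, 1] - target[1])^2 + (fc[, 2] - target[2])^2 + (fc[, 3] - target[3])^2
    keep <- d2 <= patch_radius^2
    if (any(keep)) {
      s <- sel[keep, , drop = FALSE]
      faces[[length(faces) + 1L]] <-
        data.frame(i = s[, 1] - 1L, j = s[, 2] - 1L, k = s[, 3] - 1L,
                   axis = axis, side = side)
    }
  }
  if (length(faces) == 0) stop("no boundary faces found near the requested point")
  do.call(rbind, faces)
}
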