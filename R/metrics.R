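#' Outward normals of the cortical (CSF/GM) surface
#'
#' Estimates per-boundary-cell unit normals from the gradient of a smoothed
#' gray-matter indicator. Boundary cells are GM cells with at least one CSF
#' face neighbor; normals point from GM into CSF and their orientation is
#' verified (and corrected) against label adjacency.
#'
#' @param grid A [labeled_grid()] containing GM and CSF.
#' @param smooth_iter Number of 3-cell box-blur passes per axis, default 2.
#' @return Object of class `surface_normals`: data frame with 1-based cell
#'   indices `i, j, k`, linear index `idx`, and unit normal components
#'   `nx, ny, nz`.
#' @export
surface_normals <- function(grid, smooth_iter = 2) {
  stopifnot(inherits(grid, "labeled_grid"))
  sh <- grid$spec$shape
  lab <- grid$labels
  G <- array(as.numeric(lab == TISSUES[["GM"]]), sh)
  shift <- function(A, d, axis) {
    # shift array by d along axis, zero-filled
    out <- array(0, dim(A))
    n <- dim(A)[axis]
    if (abs(d) >= n) return(out)
    src <- lapply(dim(A), seq_len); dst <- src
    if (d > 0) { dst[[axis]] <- (1 + d):n; src[[axis]] <- 1:(n - d) }
    else if (d < 0) { dst[[axis]] <- 1:(n + d); src[[axis]] <- (1 - d):n }
    out[dst[[1]], dst[[2]], dst[[3]]] <- A[src[[1]], src[[2]], src[[3]]]
    out
  }
  for (it in seq_len(smooth_iter)) {
    for (ax in 1:3) G <- (shift(G, -1, ax) + G + shift(G, 1, ax)) / 3
  }
  gx <- (shift(G, -1, 1) - shift(G, 1, 1)) / 2
  gy <- (shift(G, -1, 2) - shift(G, 1, 2)) / 2
  gz <- (shift(G, -1, 3) - shift(G, 1, 3)) / 2
  # note: shift(G, -1, ax)[i] = G[i+1], so these are +central differences
  csf <- lab == TISSUES[["CSF"]]
  gm <- lab == TISSUES[["GM"]]
  nb_csf <- array(0, sh)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  ax_ <- array(0, sh); ay_ <- array(0, sh); az_ <- array(0, sh)
  for (q in 1:6) {
    d <- dirs[q, ]
    axis <- which(d != 0)
    # indicator of "CSF neighbor in direction d"
    nb <- shift(array(as.numeric(csf), sh), -d[axis], axis)
    nb_csf <- nb_csf + nb
    ax_ <- ax_ + nb * d[1]; ay_ <- ay_ + nb * d[2]; az_ <- az_ + nb * d[3]
  }
  sel <- which(gm & nb_csf > 0)
  if (length(sel) == 0) stop("grid has no GM/CSF interface")
  nxv <- gx[sel]; nyv <- gy[sel]; nzv <- gz[sel]
  nrm <- sqrt(nxv^2 + nyv^2 + nzv^2)
  # gradient points toward increasing GM indicator (into GM); outward is -grad
  nxv <- -nxv / nrm; nyv <- -nyv / nrm; nzv <- -nzv / nrm
  # orientation check against adjacency direction (toward CSF neighbors)
  dot <- nxv * ax_[sel] + nyv * ay_[sel] + nzv * az_[sel]
  flip <- which(dot < 0)
  nxv[flip] <- -nxv[flip]; nyv[flip] <- -nyv[flip]; nzv[flip] <- -nzv[flip]
  ijk <- arrayInd(sel, sh)
  structure(data.frame(idx = sel, i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                       nx = nxv, ny = nyv, nz = nzv),
            class = c("surface_normals", "data.frame"))
}

#' Radial/tangential decomposition of the field on the cortical surface
#'
#' On each cortical boundary cell, the radial component is the projection of
#' E on the surface normal, signed so that positive means the field is
#' directed inward (into the cortex); the tangential component is the
#' magnitude of the cross product with the normal. The decomposition is
#' norm-preserving: `Er^2 + Et^2 = |E|^2`.
#'
#' @param fs A `field_samples` from [compute_efield()].
#' @param normals A `surface_normals` on the same grid.
#' @return Data frame (class `decomposed_field`) with cell indices, signed
#'   `Er` (V/m, positive inward) and tangential magnitude `Et` (V/m).
#' @export
decompose_field <- function(fs, normals) {
  stopifnot(inherits(fs, "field_samples"), inherits(normals, "surface_normals"))
  idx <- normals$idx
  Ex <- fs$Ex[idx]; Ey <- fs$Ey[idx]; Ez <- fs$Ez[idx]
  # outward normal; positive radial = directed inward
  Er <- -(Ex * normals$nx + Ey * normals$ny + Ez * normals$nz)
  cx <- normals$ny * Ez - normals$nz * Ey
  cy <- normals$nz * Ex - normals$nx * Ez
  cz <- normals$nx * Ey - normals$ny * Ex
  Et <- sqrt(cx^2 + cy^2 + cz^2)
  structure(data.frame(idx = idx, i = normals$i, j = normals$j, k = normals$k,
                       Er = Er, Et = Et, mag = fs$mag[idx]),
            class = c("decomposed_field", "data.frame"))
}

#' Peak field and focality volumes
#'
#' Finds the peak field magnitude over a tissue region and the volumes where
#' the magnitude strictly exceeds 50/60/70/80% of that peak. Under strict
#' inequality a perfectly uniform field yields zero volumes. Ties at the
#' peak resolve to the lowest linear cell index.
#'
#' @param fs A `field_samples`.
#' @param region Character vector of tissue label names, default `"GM"`.
#' @return Object of class `focality_report`: `peak` (V/m), `location` (mm),
#'   `cell` (1-based indices), and `volumes` — named vector `Vol_50` ...
#'   `Vol_80` (mm^3).
#' @export
focality_volumes <- function(fs, region = "GM") {
  stopifnot(inherits(fs, "field_samples"))
  codes <- TISSUES[region]
  sel <- which(fs$labels %in% codes)
  if (length(sel) == 0) stop("focality region is empty")
  mags <- fs$mag[sel]
  pk_local <- which.max(mags)
  peak <- mags[pk_local]
  cell <- arrayInd(sel[pk_local], fs$spec$shape)
  loc <- fs$spec$origin + (as.numeric(cell) - 0.5) * fs$spec$spacing
  v <- fs$spec$spacing^3
  fracs <- c(0.5, 0.6, 0.7, 0.8)
  if (min(mags) == peak) {
    # exactly uniform field: no cell exceeds any fraction of its own peak in
    # a meaningful sense; all volumes are zero by convention
    vols <- rep(0, length(fracs))
  } else {
    vols <- vapply(fracs, function(p) sum(mags > p * peak) * v, numeric(1))
  }
  names(vols) <- paste0("Vol_", fracs * 100)
  structure(list(peak = peak, cell = as.integer(cell), location = loc,
                 volumes = vols, region = region,
                 spacing = fs$spec$spacing),
            class = "focality_report")
}

#' @export
print.focality_report <- function(x, ...) {
  cat(sprintf("focality_report (%s): peak |E| = %.4g V/m at (%.1f, %.1f, %.1f) mm\n",
              paste(x$region, collapse = "+"), x$peak,
              x$location[1], x$location[2], x$location[3]))
  cat("  ", paste(sprintf("%s = %.2f mm^3", names(x$volumes), x$volumes),
                  collapse = ", "), "\n")
  invisible(x)
}
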