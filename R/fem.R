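#' Solver configuration
#'
#' @param rtol Relative residual tolerance of the conjugate-gradient solve,
#'   default 1e-9.
#' @param maxit Maximum CG iterations.
#' @param precond Preconditioner: `"mg"` (geometric multigrid V-cycle,
#'   default), `"ssor"` (symmetric Gauss-Seidel) or `"jacobi"`.
#' @return Object of class `solver_config`.
#' @export
solver_config <- function(rtol = 1e-9, maxit = 50000L,
                          precond = c("mg", "ssor", "jacobi")) {
  precond <- match.arg(precond)
  if (!is.numeric(rtol) || rtol <= 0) stop("rtol must be > 0")
  structure(list(rtol = rtol, maxit = as.integer(maxit), precond = precond),
            class = "solver_config")
}

.tcc <- new.env(parent = emptyenv())

# 8x8 trilinear element stiffness on the unit cube (grad N_a . grad N_b),
# 2x2x2 Gauss quadrature; corner a has index 1 + ax + 2 ay + 4 az.
element_stiffness_ref <- function() {
  if (!is.null(.tcc$K_ref)) return(.tcc$K_ref)
  gp <- 0.5 + c(-1, 1) / (2 * sqrt(3))
  corners <- as.matrix(expand.grid(ax = 0:1, ay = 0:1, az = 0:1))
  K <- matrix(0, 8, 8)
  shape1d <- function(a, x) if (a == 1) x else 1 - x
  dshape1d <- function(a) if (a == 1) 1 else -1
  for (gx in gp) for (gy in gp) for (gz in gp) {
    G <- matrix(0, 8, 3)     # gradients of the 8 basis functions
    for (c in 1:8) {
      a <- corners[c, ]
      G[c, 1] <- dshape1d(a[1]) * shape1d(a[2], gy) * shape1d(a[3], gz)
      G[c, 2] <- shape1d(a[1], gx) * dshape1d(a[2]) * shape1d(a[3], gz)
      G[c, 3] <- shape1d(a[1], gx) * shape1d(a[2], gy) * dshape1d(a[3])
    }
    K <- K + (G %*% t(G)) / 8
  }
  .tcc$K_ref <- K
  K
}

# per-cell conductivity vector (S/m), 0 for AIR
sigma_cells <- function(grid, sigma) {
  lab <- as.integer(grid$labels)
  out <- numeric(length(lab))
  for (nm in names(sigma)) out[lab == TISSUES[[nm]]] <- sigma[[nm]]
  out
}

# 27 stencil shifts for a node lattice of dims nn (1-based linear indexing)
stencil_shifts <- function(nn) {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  as.integer(d[, 1] + nn[1] * (d[, 2] + nn[2] * d[, 3]))
}

# Assemble the banded trilinear-FEM stiffness matrix over non-air cells.
# Returns list(B [N x 27], shifts, nn, N). Lengths converted to meters so
# that with sigma in S/m the entries are in siemens.
assemble_banded <- function(grid, sigma) {
  spec <- grid$spec
  nn <- spec$shape + 1L
  N <- prod(nn)
  h_m <- spec$spacing * 1e-3
  K_ref <- element_stiffness_ref()
  sig <- sigma_cells(grid, sigma)
  act <- which(sig > 0)
  if (length(act) == 0) stop("grid contains no conducting cells")
  sig <- sig[act]
  nx <- spec$shape[1]; ny <- spec$shape[2]
  ci <- (act - 1L) %% nx
  cj <- ((act - 1L) %/% nx) %% ny
  ck <- (act - 1L) %/% (nx * ny)
  corners <- as.matrix(expand.grid(ax = 0:1, ay = 0:1, az = 0:1))
  nid <- vector("list", 8L)
  for (a in 1:8) {
    nid[[a]] <- 1 + (ci + corners[a, 1]) +
      nn[1] * ((cj + corners[a, 2]) + nn[2] * (ck + corners[a, 3]))
  }
  shifts <- stencil_shifts(nn)
  # band index for offset d (components in -1:1)
  band_of <- function(d) (d[1] + 1) + 3 * (d[2] + 1) + 9 * (d[3] + 1) + 1
  B <- matrix(0, N, 27L)
  scl <- sig * h_m
  for (a in 1:8) {
    rows <- nid[[a]]
    for (b in 1:8) {
      m <- band_of(corners[b, ] - corners[a, ])
      idx <- rows + (m - 1) * N
      B[idx] <- B[idx] + scl * K_ref[a, b]
    }
  }
  list(B = B, shifts = shifts, nn = nn, N = N)
}

# Connected components of highly conductive (metal) cells, as 1-based node
# index sets. These carry near-rigid potential modes whose global shifts
# converge slowly under multigrid alone; the solver deflates them with an
# exact small coarse correction.
metal_node_sets <- function(grid) {
  lab <- grid$labels
  sh <- grid$spec$shape
  metal <- lab == TISSUES[["CHANNEL"]] | lab == TISSUES[["ELECTRODE"]]
  if (!any(metal)) return(list())
  ind <- which(metal, arr.ind = TRUE)
  lo <- pmax(apply(ind, 2, min) - 1L, 1L)
  hi <- pmin(apply(ind, 2, max) + 1L, sh)
  sub <- metal[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  dims <- dim(sub)
  comp <- array(0, dims)
  comp[sub] <- seq_len(sum(sub))
  # label propagation: each metal cell takes the minimum label among its
  # 6-neighborhood until a fixed point
  repeat {
    prev <- comp
    for (ax in 1:3) {
      n <- dims[ax]
      idx <- lapply(dims, seq_len)
      for (d in c(-1L, 1L)) {
        src <- idx; dst <- idx
        if (d > 0) { dst[[ax]] <- 2:n; src[[ax]] <- 1:(n - 1) }
        else { dst[[ax]] <- 1:(n - 1); src[[ax]] <- 2:n }
        nb <- array(0, dims)
        nb[dst[[1]], dst[[2]], dst[[3]]] <- comp[src[[1]], src[[2]], src[[3]]]
        upd <- sub & nb > 0 & (nb < comp)
        comp[upd] <- nb[upd]
      }
    }
    if (identical(comp, prev)) break
  }
  nn <- sh + 1L
  out <- list()
  for (cid in unique(comp[sub])) {
    cells <- which(comp == cid, arr.ind = TRUE)
    ci <- cells[, 1] + lo[1] - 2L   # 0-based full-grid cell indices
    cj <- cells[, 2] + lo[2] - 2L
    ck <- cells[, 3] + lo[3] - 2L
    nodes <- integer(0)
    for (az in 0:1) for (ay in 0:1) for (ax in 0:1) {
      nodes <- c(nodes, 1 + (ci + ax) + nn[1] * ((cj + ay) + nn[2] * (ck + az)))
    }
    out[[length(out) + 1L]] <- unique(nodes)
  }
  out
}

# 1-based node ids of the 4 nodes of each face (faces: 0-based cell i,j,k,
# axis 1..3, side +/-1); returns integer vector of length 4 * nrow(faces)
face_node_ids <- function(faces, nn) {
  base <- cbind(faces$i, faces$j, faces$k)
  out <- integer(0)
  for (axis in unique(faces$axis)) for (side in unique(faces$side)) {
    sel <- faces$axis == axis & faces$side == side
    if (!any(sel)) next
    bb <- base[sel, , drop = FALSE]
    bb[, axis] <- bb[, axis] + (side > 0)
    free <- setdiff(1:3, axis)
    for (o1 in 0:1) for (o2 in 0:1) {
      p <- bb
      p[, free[1]] <- p[, free[1]] + o1
      p[, free[2]] <- p[, free[2]] + o2
      out <- c(out, 1 + p[, 1] + nn[1] * (p[, 2] + nn[2] * p[, 3]))
    }
  }
  out
}

#' Solve the quasi-static volume-conduction equation
#'
#' Discretizes `div(sigma grad phi) = 0` with node-based trilinear finite
#' elements on the voxel grid (air cells excluded; exterior boundaries are
#' naturally insulated) and solves the symmetric positive-definite system
#' with preconditioned conjugate gradients.
#'
#' Boundary conditions: a total current `current_A` is distributed uniformly
#' over the Neumann face set (omit for none), and each Dirichlet set pins the
#' potential on its faces to a fixed value.
#'
#' @param grid A [labeled_grid()].
#' @param sigma Named conductivity vector (S/m), see
#'   [default_conductivities()].
#' @param neumann_faces Face data frame (`i, j, k, axis, side`) carrying the
#'   injected current, or `NULL`.
#' @param current_A Total injected current (A) over `neumann_faces`.
#' @param dirichlet List of `list(faces = <face df>, value = <V>)` sets; at
#'   least one is required (the system is singular otherwise).
#' @param cfg A [solver_config()].
#' @param x0 Optional initial-guess node array (e.g. a previous solution on
#'   the same lattice); the converged answer is unchanged, only the
#'   iteration count.
#' @return Object of class `potential_field`: node potential array `phi` (V,
#'   dimension `shape + 1`), the grid spec, and solver diagnostics `relres`,
#'   `iters`.
#' @export
solve_laplace <- function(grid, sigma = default_conductivities(),
                          neumann_faces = NULL, current_A = 0,
                          dirichlet = list(), cfg = solver_config(),
                          x0 = NULL) {
  stopifnot(inherits(grid, "labeled_grid"))
  if (length(dirichlet) == 0)
    stop("singular system: at least one Dirichlet (ground) face set is required")
  sys <- assemble_banded(grid, sigma)
  B <- sys$B; shifts <- sys$shifts; N <- sys$N; nn <- sys$nn
  mdiag <- which(shifts == 0L)
  b <- numeric(N)
  if (!is.null(neumann_faces)) {
    if (nrow(neumann_faces) == 0) stop("empty Neumann face set")
    ids <- face_node_ids(neumann_faces, nn)
    per_node <- current_A / (4 * nrow(neumann_faces))
    b <- b + tabulate(ids, nbins = N) * per_node
  }
  # Dirichlet elimination (symmetric)
  phi_d <- numeric(N)
  dmask <- logical(N)
  for (set in dirichlet) {
    if (is.null(set$faces) || nrow(set$faces) == 0) stop("empty Dirichlet face set")
    ids <- unique(face_node_ids(set$faces, nn))
    phi_d[ids] <- set$value
    dmask[ids] <- TRUE
  }
  dnodes <- which(dmask)
  if (any(phi_d != 0)) b <- b - banded_matvec(B, shifts, phi_d)
  for (m in 1:27) {
    colbase <- (m - 1) * N
    B[dnodes + colbase] <- 0
    src <- dnodes - shifts[m]
    src <- src[src >= 1 & src <= N]
    B[src + colbase] <- 0
  }
  B[dnodes + (mdiag - 1) * N] <- 1
  b[dnodes] <- phi_d[dnodes]
  # isolated (air-only) nodes: identity rows
  diag_idx <- (mdiag - 1) * N + seq_len(N)
  iso <- which(B[diag_idx] == 0)
  if (length(iso)) {
    B[iso + (mdiag - 1) * N] <- 1
    b[iso] <- 0
  }
  xinit <- if (is.null(x0)) numeric(N) else {
    if (length(x0) != N) stop("x0 has the wrong length for this lattice")
    as.numeric(x0)
  }
  xinit[dnodes] <- phi_d[dnodes]
  res <- if (cfg$precond == "mg") {
    defl <- lapply(metal_node_sets(grid),
                   function(s) setdiff(s, dnodes))
    defl <- defl[lengths(defl) > 0]
    pcg_mg(B, nn, b, xinit, cfg$rtol, cfg$maxit, defl)
  } else {
    pcg_banded(B, shifts, b, xinit, cfg$rtol, cfg$maxit,
               if (cfg$precond == "ssor") 1L else 0L)
  }
  if (!res$converged)
    stop(sprintf("CG did not converge in %d iterations (relative residual %.3e)",
                 res$iters, res$relres))
  phi <- res$x
  dim(phi) <- nn
  structure(list(phi = phi, spec = grid$spec, relres = res$relres,
                 iters = res$iters),
            class = "potential_field")
}

#' Solve the HD-tDCS montage problem
#'
#' Applies the montage boundary conditions — the configured current injected
#' uniformly over the exposed top faces of the active electrode, ground
#' (0 V Dirichlet) on the return-electrode top faces, insulating elsewhere —
#' and solves for the potential.
#'
#' @param placed A `placed_montage` from [place_montage()].
#' @param sigma Named conductivity vector (S/m).
#' @param cfg A [solver_config()].
#' @param x0 Optional initial guess (see [solve_laplace()]).
#' @return A `potential_field`.
#' @export
solve_potential <- function(placed, sigma = default_conductivities(),
                            cfg = solver_config(), x0 = NULL) {
  stopifnot(inherits(placed, "placed_montage"))
  if (nrow(placed$active_faces) == 0 || nrow(placed$return_faces) == 0)
    stop("montage face sets must be non-empty")
  solve_laplace(placed$grid, sigma,
                neumann_faces = placed$active_faces,
                current_A = placed$montage$current_mA * 1e-3,
                dirichlet = list(list(faces = placed$return_faces, value = 0)),
                cfg = cfg, x0 = x0)
}

#' @export
print.potential_field <- function(x, ...) {
  cat(sprintf("potential_field: %d x %d x %d nodes, CG %d iterations, relative residual %.2e\n",
              dim(x$phi)[1], dim(x$phi)[2], dim(x$phi)[3], x$iters, x$relres))
  cat(sprintf("  phi range: [%.4g, %.4g] V\n", min(x$phi), max(x$phi)))
  invisible(x)
}

#' Differentiate the potential to per-cell electric fields
#'
#' Computes `E = -grad phi` (V/m) at each cell from the trilinear
#' interpolant of its 8 nodal potentials (exact cell-average gradient).
#'
#' @param phi A `potential_field`.
#' @param grid The [labeled_grid()] the potential was solved on.
#' @return Object of class `field_samples`: arrays `Ex, Ey, Ez, mag` (V/m)
#'   over cells, plus the label array and grid spec. Cell volume is
#'   `spacing^3` mm^3.
#' @export
compute_efield <- function(phi, grid) {
  stopifnot(inherits(phi, "potential_field"), inherits(grid, "labeled_grid"))
  P <- phi$phi
  nn <- dim(P)
  nx <- nn[1] - 1L; ny <- nn[2] - 1L; nz <- nn[3] - 1L
  h_m <- grid$spec$spacing * 1e-3
  avg_pairs <- function(D, over) {
    # average array D over node pairs along the axes in `over`
    for (ax in over) {
      n <- dim(D)[ax]
      idx1 <- lapply(dim(D), seq_len); idx2 <- idx1
      idx1[[ax]] <- seq_len(n - 1); idx2[[ax]] <- 2:n
      D <- (D[idx1[[1]], idx1[[2]], idx1[[3]], drop = FALSE] +
              D[idx2[[1]], idx2[[2]], idx2[[3]], drop = FALSE]) / 2
    }
    D
  }
  Dx <- P[2:(nx + 1), , , drop = FALSE] - P[1:nx, , , drop = FALSE]
  Dy <- P[, 2:(ny + 1), , drop = FALSE] - P[, 1:ny, , drop = FALSE]
  Dz <- P[, , 2:(nz + 1), drop = FALSE] - P[, , 1:nz, drop = FALSE]
  Ex <- -avg_pairs(Dx, c(2, 3)) / h_m
  Ey <- -avg_pairs(Dy, c(1, 3)) / h_m
  Ez <- -avg_pairs(Dz, c(1, 2)) / h_m
  dim(Ex) <- dim(Ey) <- dim(Ez) <- c(nx, ny, nz)
  mag <- sqrt(Ex^2 + Ey^2 + Ez^2)
  structure(list(Ex = Ex, Ey = Ey, Ez = Ez, mag = mag,
                 labels = grid$labels, spec = grid$spec),
            class = "field_samples")
}

#' @export
print.field_samples <- function(x, ...) {
  gm <- x$labels == TISSUES[["GM"]]
  cat(sprintf("field_samples: %d x %d x %d cells, |E| max %.4g V/m",
              dim(x$mag)[1], dim(x$mag)[2], dim(x$mag)[3], max(x$mag)))
  if (any(gm)) cat(sprintf(" (GM max %.4g V/m)", max(x$mag[gm])))
  cat("\n")
  invisible(x)
}

#' Sample the potential at arbitrary points
#'
#' Trilinear interpolation of the nodal potential within the containing cell.
#'
#' @param phi A `potential_field`.
#' @param points Numeric matrix (n x 3) of positions (mm).
#' @return Numeric vector of potentials (V).
#' @export
sample_potential <- function(phi, points) {
  stopifnot(inherits(phi, "potential_field"))
  points <- matrix(as.numeric(points), ncol = 3)
  spec <- phi$spec
  h <- spec$spacing
  nn <- dim(phi$phi)
  u <- sweep(points, 2, spec$origin) / h
  bad <- which(u[, 1] < 0 | u[, 1] > nn[1] - 1 |
                 u[, 2] < 0 | u[, 2] > nn[2] - 1 |
                 u[, 3] < 0 | u[, 3] > nn[3] - 1)
  if (length(bad))
    stop(sprintf("point(s) outside grid bounds: %s",
                 paste(apply(points[bad, , drop = FALSE], 1,
                             function(p) sprintf("(%g, %g, %g)", p[1], p[2], p[3])),
                       collapse = ", ")))
  i0 <- pmin(floor(u), matrix(rep(nn - 2, each = nrow(u)), ncol = 3))
  f <- u - i0
  P <- phi$phi
  val <- numeric(nrow(points))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (dx * f[, 1] + (1 - dx) * (1 - f[, 1])) *
      (dy * f[, 2] + (1 - dy) * (1 - f[, 2])) *
      (dz * f[, 3] + (1 - dz) * (1 - f[, 3]))
    idx <- 1 + (i0[, 1] + dx) + nn[1] * ((i0[, 2] + dy) + nn[2] * (i0[, 3] + dz))
    val <- val + w * P[idx]
  }
  val
}

#' Sample the electric field at arbitrary points
#'
#' Nearest-cell lookup of the per-cell field vectors.
#'
#' @param fs A `field_samples`.
#' @param points Numeric matrix (n x 3) of positions (mm).
#' @return Matrix (n x 4): `Ex, Ey, Ez, mag` (V/m).
#' @export
sample_efield <- function(fs, points) {
  stopifnot(inherits(fs, "field_samples"))
  points <- matrix(as.numeric(points), ncol = 3)
  spec <- fs$spec
  sh <- spec$shape
  ci <- pmax(pmin(floor(sweep(points, 2, spec$origin) / spec$spacing),
                  matrix(rep(sh - 1, each = nrow(points)), ncol = 3)), 0)
  idx <- 1 + ci[, 1] + sh[1] * (ci[, 2] + sh[2] * ci[, 3])
  cbind(Ex = fs$Ex[idx], Ey = fs$Ey[idx], Ez = fs$Ez[idx], mag = fs$mag[idx])
}

#' Net current through a closed voxel box
#'
#' Independent conservation check: integrates `sigma * E . n` over the
#' surface of an axis-aligned box of cells, using centered differences of
#' cell-mean potentials and harmonic-mean face conductivities (a quadrature
#' independent of the finite-element residual).
#'
#' @param phi A `potential_field`.
#' @param grid The [labeled_grid()] solved on.
#' @param sigma Named conductivity vector (S/m).
#' @param lo,hi 1-based inclusive cell index ranges (3-vectors) of the box.
#' @return Net outward current (A).
#' @export
current_flux_box <- function(phi, grid, sigma, lo, hi) {
  spec <- grid$spec
  sh <- spec$shape
  stopifnot(all(lo >= 1), all(hi <= sh), all(lo <= hi))
  h_m <- spec$spacing * 1e-3
  P <- phi$phi
  # cell-mean potential
  nx <- sh[1]; ny <- sh[2]; nz <- sh[3]
  Pc <- (P[1:nx, 1:ny, 1:nz] + P[2:(nx + 1), 1:ny, 1:nz] +
           P[1:nx, 2:(ny + 1), 1:nz] + P[2:(nx + 1), 2:(ny + 1), 1:nz] +
           P[1:nx, 1:ny, 2:(nz + 1)] + P[2:(nx + 1), 1:ny, 2:(nz + 1)] +
           P[1:nx, 2:(ny + 1), 2:(nz + 1)] +
           P[2:(nx + 1), 2:(ny + 1), 2:(nz + 1)]) / 8
  sig <- sigma_cells(grid, sigma)
  dim(sig) <- sh
  flux <- 0
  face_flux <- function(cin, cout) {
    # cin, cout: matrices of cell indices (n x 3), paired inside/outside
    iin <- cin[, 1] + sh[1] * ((cin[, 2] - 1) + sh[2] * (cin[, 3] - 1))
    iout <- cout[, 1] + sh[1] * ((cout[, 2] - 1) + sh[2] * (cout[, 3] - 1))
    s1 <- sig[iin]; s2 <- sig[iout]
    sf <- ifelse(s1 > 0 & s2 > 0, 2 * s1 * s2 / (s1 + s2), 0)
    En <- -(Pc[iout] - Pc[iin]) / h_m
    sum(sf * En) * h_m^2
  }
  expand_face <- function(axis, at_in, at_out) {
    free <- setdiff(1:3, axis)
    gr <- expand.grid(a = lo[free[1]]:hi[free[1]], b = lo[free[2]]:hi[free[2]])
    cin <- matrix(0L, nrow(gr), 3); cout <- cin
    cin[, free[1]] <- gr$a; cin[, free[2]] <- gr$b; cin[, axis] <- at_in
    cout[, free[1]] <- gr$a; cout[, free[2]] <- gr$b; cout[, axis] <- at_out
    list(cin = cin, cout = cout)
  }
  for (axis in 1:3) {
    if (hi[axis] < sh[axis]) {
      f <- expand_face(axis, hi[axis], hi[axis] + 1L)
      flux <- flux + face_flux(f$cin, f$cout)
    }
    if (lo[axis] > 1) {
      f <- expand_face(axis, lo[axis], lo[axis] - 1L)
      flux <- flux + face_flux(f$cin, f$cout)
    }
  }
  flux
}
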