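# shared fixtures: small geometries, fibers, random trees, and independent
# dense oracles used across the suite

# homogeneous cube of GM, n cells per side, h mm spacing
cube_grid <- function(n = 10L, h = 1, label = "GM") {
  labeled_grid(grid_spec(c(0, 0, 0), h, c(n, n, n)),
               array(TISSUES[[label]], c(n, n, n)))
}

# full-face z-boundary face sets of a cube grid
cube_z_faces <- function(n) {
  ij <- expand.grid(i = 0:(n - 1), j = 0:(n - 1))
  list(bottom = data.frame(i = ij$i, j = ij$j, k = 0L, axis = 3L, side = -1L),
       top = data.frame(i = ij$i, j = ij$j, k = n - 1L, axis = 3L, side = 1L))
}

# straight fiber along z as a morphology with its root at the center (so the
# discretization is exactly symmetric about z = 0): 2n compartments, total
# length L mm, diameter d um, spanning [-L/2, L/2]
straight_fiber <- function(n = 100, L = 1, d = 2) {
  step <- (L / 2) / n
  up <- data.frame(id = seq_len(n), parent = c(0L, seq_len(n - 1)),
                   part = "axon", x = 0, y = 0, z = seq_len(n) * step, diam = d)
  dn <- data.frame(id = n + seq_len(n), parent = c(0L, n + seq_len(n - 1)),
                   part = "axon", x = 0, y = 0, z = -seq_len(n) * step, diam = d)
  root <- data.frame(id = 0L, parent = -1L, part = "axon",
                     x = 0, y = 0, z = 0, diam = d)
  morphology(rbind(root, up, dn),
             c(center = 0L, top = n, bottom = 2L * n), kind = "fiber")
}

# random tree morphology with n compartments (seeded by the caller)
random_tree <- function(n = 30) {
  tab <- data.frame(id = 0L, parent = -1L, part = "soma",
                    x = 0, y = 0, z = 0, diam = runif(1, 5, 20))
  for (q in seq_len(n - 1)) {
    parent <- sample(0:(q - 1), 1)
    prow <- tab[tab$id == parent, ]
    tab <- rbind(tab, data.frame(
      id = q, parent = parent, part = "axon",
      x = prow$x + rnorm(1, 0, 0.05),
      y = prow$y + rnorm(1, 0, 0.05),
      z = prow$z + rnorm(1, 0, 0.08),
      diam = runif(1, 0.8, 4)))
  }
  morphology(tab, c(soma = 0L), kind = "random")
}

# independent dense-matrix steady-state cable solve, built from first
# principles (no shared code with the package's sparse path)
dense_cable_solve <- function(m, e_mV, params = membrane_params()) {
  comp <- m$comp
  n <- nrow(comp)
  pidx <- match(comp$parent, comp$id)
  len_cm <- numeric(n)
  for (r in seq_len(n)) {
    if (is.na(pidx[r])) {
      len_cm[r] <- comp$diam[r] * 1e-3 * 0.1
    } else {
      p <- pidx[r]
      len_cm[r] <- sqrt((comp$x[r] - comp$x[p])^2 + (comp$y[r] - comp$y[p])^2 +
                          (comp$z[r] - comp$z[p])^2) * 0.1
    }
  }
  d_cm <- comp$diam * 1e-4
  rhalf <- 4 * params$R_a * (len_cm / 2) / (pi * d_cm^2)
  A <- matrix(0, n, n)
  for (r in seq_len(n)) {
    if (!is.na(pidx[r])) {
      g <- 1 / (rhalf[r] + rhalf[pidx[r]])
      A[r, r] <- A[r, r] + g
      A[pidx[r], pidx[r]] <- A[pidx[r], pidx[r]] + g
      A[r, pidx[r]] <- A[r, pidx[r]] - g
      A[pidx[r], r] <- A[pidx[r], r] - g
    }
  }
  Gax <- A
  diag(A) <- diag(A) + pi * d_cm * len_cm / params$R_m
  solve(A, -Gax %*% e_mV)[, 1]
}

# small head for fast end-to-end tests: thinner, narrower, coarser
small_head <- function() {
  head_params(scalp = 4, skull = 5, dura = 0.5, csf = 2, gm = 2.5,
              wm_min = 3, fold_amplitude = 2, fold_wavelength = 28,
              lateral_extent = 64, headroom = 4)
}

small_montage <- function(displacement = c(0, 0)) {
  montage_spec(ring_radius = 22, displacement = displacement)
}
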