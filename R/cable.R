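#' Passive membrane parameters
#'
#' @param R_m Specific membrane resistance (Ohm cm^2), default 30000.
#' @param R_a Axial resistivity (Ohm cm), default 150.
#' @param C_m Specific membrane capacitance (uF/cm^2), default 0.75; only
#'   used by the time-domain integrator, not at steady state.
#' @param R_m_part Optional named list of per-part `R_m` overrides, e.g.
#'   `list(iseg = 10000)`.
#' @return Object of class `membrane_params`.
#' @export
membrane_params <- function(R_m = 30000, R_a = 150, C_m = 0.75,
                            R_m_part = list()) {
  stopifnot(R_m > 0, R_a > 0, C_m > 0)
  structure(list(R_m = R_m, R_a = R_a, C_m = C_m, R_m_part = R_m_part),
            class = "membrane_params")
}

#' Electrotonic length constant
#'
#' `lambda = sqrt(d R_m / (4 R_a))` for a cylinder of diameter `d`.
#'
#' @param diam_um Diameter (um).
#' @param params A [membrane_params()].
#' @return Length constant (mm).
#' @export
length_constant <- function(diam_um, params = membrane_params()) {
  d_cm <- diam_um * 1e-4
  sqrt(d_cm * params$R_m / (4 * params$R_a)) * 10   # cm -> mm
}

# conductance structure of a morphology: list(g_edge (S, per non-root
# compartment, to its parent), g_m (S, per compartment), parent index (1-based))
cable_conductances <- function(m, params) {
  comp <- m$comp
  n <- nrow(comp)
  len_cm <- compartment_lengths(m) * 0.1        # mm -> cm
  d_cm <- comp$diam * 1e-4                      # um -> cm
  if (any(len_cm <= 0)) stop("zero-length compartment")
  R_m <- rep(params$R_m, n)
  for (nm in names(params$R_m_part)) {
    R_m[comp$part == nm] <- params$R_m_part[[nm]]
  }
  g_m <- pi * d_cm * len_cm / R_m               # S
  # axial half-resistance of each compartment (Ohm)
  r_half <- 4 * params$R_a * (len_cm / 2) / (pi * d_cm^2)
  pidx <- match(comp$parent, comp$id)           # NA for root
  has_par <- !is.na(pidx)
  g_edge <- numeric(n)
  g_edge[has_par] <- 1 / (r_half[has_par] + r_half[pidx[has_par]])
  list(g_edge = g_edge, g_m = g_m, pidx = pidx, has_par = has_par, n = n)
}

# sparse symmetric system A = G_axial + G_membrane and the axial Laplacian
# action on a vector (for the right-hand side), using Matrix
cable_system <- function(cc) {
  i <- which(cc$has_par)
  j <- cc$pidx[i]
  g <- cc$g_edge[i]
  n <- cc$n
  diag_ax <- numeric(n)
  for (k in seq_along(i)) {
    diag_ax[i[k]] <- diag_ax[i[k]] + g[k]
    diag_ax[j[k]] <- diag_ax[j[k]] + g[k]
  }
  A <- Matrix::sparseMatrix(
    i = c(seq_len(n), i, j), j = c(seq_len(n), j, i),
    x = c(diag_ax + cc$g_m, -g, -g), dims = c(n, n)
  )
  # G_axial v = (A - G_membrane) v; avoids duplicated-index pitfalls at
  # branch points
  lap <- function(v) as.numeric(A %*% v) - cc$g_m * v
  list(A = A, lap = lap)
}

#' Steady-state membrane polarization under extracellular potentials
#'
#' Solves the passive steady-state compartmental system
#' `(G_axial + G_membrane) dV = -G_axial e` with sealed ends, where
#' `G_axial` couples adjacent compartments through series axial
#' conductances and `G_membrane` is the diagonal of membrane leak
#' conductances. `dV` is the transmembrane deviation from rest
#' (depolarization positive, mV); a spatially constant `e` yields zero
#' polarization exactly.
#'
#' @param neuron A [morphology()] or placed neuron.
#' @param e_mV Extracellular potential at each compartment center (mV).
#' @param params A [membrane_params()].
#' @return Object of class `polarization_profile`: data frame `id, part,
#'   dV_mV` with attribute `landmarks` (named vector of landmark dV, mV).
#' @export
steady_state_polarization <- function(neuron, e_mV, params = membrane_params()) {
  m <- as_morphology(neuron)
  if (length(e_mV) != nrow(m$comp))
    stop("e_mV must have one value per compartment")
  if (anyNA(e_mV) || any(!is.finite(e_mV))) stop("non-finite extracellular potential")
  cc <- cable_conductances(m, params)
  if (any(!cc$has_par & seq_len(cc$n) != 1L))
    stop("disconnected tree: non-root compartment without parent")
  sys <- cable_system(cc)
  rhs <- -sys$lap(e_mV)
  dv <- as.numeric(Matrix::solve(sys$A, rhs))
  make_profile(m, dv)
}

# accept either a bare morphology or a placed neuron
as_morphology <- function(x) {
  if (inherits(x, "placed_neuron")) x$morph else x
}

# assemble a polarization_profile data frame (id, part, landmark, dV_mV)
make_profile <- function(m, dv) {
  lmcol <- rep(NA_character_, nrow(m$comp))
  lmv <- numeric(0)
  if (length(m$landmarks)) {
    pos <- match(m$landmarks, m$comp$id)
    lmcol[pos] <- names(m$landmarks)
    lmv <- dv[pos]
    names(lmv) <- names(m$landmarks)
  }
  prof <- data.frame(id = m$comp$id, part = m$comp$part, landmark = lmcol,
                     dV_mV = dv)
  structure(prof, landmarks = lmv, kind = m$kind,
            class = c("polarization_profile", "data.frame"))
}

#' Polarization under a uniform extracellular field
#'
#' Convenience wrapper for [steady_state_polarization()] with
#' `e_i = -E . x_i`: with positions in mm and the field in V/m the
#' extracellular potential comes out directly in mV.
#'
#' @param m A [morphology()] or placed neuron.
#' @param E Field vector (V/m), length 3.
#' @param params A [membrane_params()].
#' @return A `polarization_profile`.
#' @export
uniform_field_polarization <- function(m, E, params = membrane_params()) {
  stopifnot(length(E) == 3)
  ctr <- compartment_centers(as_morphology(m))
  e_mV <- -(ctr[, 1] * E[1] + ctr[, 2] * E[2] + ctr[, 3] * E[3])
  steady_state_polarization(m, e_mV, params)
}

#' Somatic coupling constant
#'
#' The somatic polarization (mV) per unit local field (mV/mm, numerically
#' equal to V/m), in mm — the standard sub-threshold sensitivity measure.
#'
#' @param profile A `polarization_profile` with a `soma` landmark.
#' @param localE Local field magnitude at the soma (V/m), > 0.
#' @return Object of class `coupling_result`: list with `k_mm`, `dV_soma_mV`,
#'   `localE`.
#' @export
coupling_constant <- function(profile, localE) {
  stopifnot(inherits(profile, "polarization_profile"))
  if (!is.numeric(localE) || localE <= 0)
    stop("localE must be a positive field magnitude (V/m)")
  lm <- attr(profile, "landmarks")
  if (is.null(lm) || !("soma" %in% names(lm)))
    stop("profile lacks a soma landmark")
  structure(list(k_mm = lm[["soma"]] / localE, dV_soma_mV = lm[["soma"]],
                 localE = localE),
            class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("coupling_result: k = %.4f mm (soma %+.4f mV at %.3f mV/mm)\n",
              x$k_mm, x$dV_soma_mV, x$localE))
  invisible(x)
}

#' Time-domain verification integrator
#'
#' Backward-Euler integration of the passive compartmental system
#' `C dV/dt = -(G_axial + G_membrane) V - G_axial e` from rest, provided as
#' an independent check that the steady-state linear solve is the correct
#' long-time limit.
#'
#' @param neuron A [morphology()] or placed neuron.
#' @param e_mV Extracellular potential per compartment center (mV).
#' @param params A [membrane_params()].
#' @param dt Time step (ms).
#' @param t_end End time (ms); defaults to 10 membrane time constants.
#' @return A `polarization_profile` at `t_end`.
#' @export
integrate_polarization <- function(neuron, e_mV, params = membrane_params(),
                                   dt = 0.25, t_end = NULL) {
  m <- as_morphology(neuron)
  if (length(e_mV) != nrow(m$comp))
    stop("e_mV must have one value per compartment")
  tau_ms <- params$R_m * params$C_m * 1e-3      # Ohm cm^2 * uF/cm^2 -> ms
  if (is.null(t_end)) t_end <- 10 * tau_ms
  cc <- cable_conductances(m, params)
  sys <- cable_system(cc)
  len_cm <- compartment_lengths(m) * 0.1
  d_cm <- m$comp$diam * 1e-4
  C_F <- params$C_m * 1e-6 * pi * d_cm * len_cm  # F
  # with V in mV and t in ms both sides are in amperes
  Msys <- sys$A + Matrix::Diagonal(cc$n, C_F / (dt * 1e-3) * 1e0)
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Msys))
  rhs_drive <- -sys$lap(e_mV)
  v <- numeric(cc$n)
  nstep <- ceiling(t_end / dt)
  cdt <- C_F / (dt * 1e-3)
  for (s in seq_len(nstep)) {
    v <- as.numeric(Matrix::solve(ch, cdt * v + rhs_drive))
  }
  make_profile(m, v)
}

#' @export
print.polarization_profile <- function(x, ...) {
  cat(sprintf("polarization_profile (%s): %d compartments, dV range [%.4g, %.4g] mV\n",
              attr(x, "kind"), nrow(x), min(x$dV_mV), max(x$dV_mV)))
  lm <- attr(x, "landmarks")
  if (length(lm))
    cat("  landmarks (mV):",
        paste(sprintf("%s %+.4g", names(lm), lm), collapse = ", "), "\n")
  invisible(x)
}
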