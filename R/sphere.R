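#' Analytic surface potential of a two-electrode conducting sphere
#'
#' Closed-form Legendre series for the potential on a homogeneous conducting
#' sphere of radius `R` and conductivity `sigma`, with a point current
#' source (+I) and sink (-I) on its surface and an insulated boundary
#' elsewhere:
#' `phi(P) = I / (4 pi sigma R) * sum_{n>=1} (2n+1)/n [P_n(cos gA) - P_n(cos gB)]`
#' where `gA`, `gB` are the angles from the sample point to the source and
#' sink. The potential is defined up to an additive constant (remove means
#' before comparing with a numerical solution).
#'
#' Interior sample points are handled exactly through the `(r/R)^n` factor
#' of the interior solution, so voxel cell centers just below the surface
#' can be compared directly.
#'
#' @param points Matrix (n x 3) of sample positions (mm), on or inside the
#'   surface.
#' @param center Sphere center (mm).
#' @param radius Sphere radius (mm).
#' @param source_dir,sink_dir Unit vectors from the center to the source and
#'   sink electrodes.
#' @param current_A Electrode current (A), default 1e-3.
#' @param sigma Conductivity (S/m).
#' @param n_terms Number of terms for `method = "series"`; ignored by the
#'   default exact evaluation.
#' @param method `"closed"` (default) evaluates the series exactly through
#'   the Legendre generating functions
#'   `sum r^n P_n = 1/sqrt(1 - 2 r c + r^2) - 1` and
#'   `sum r^n P_n / n = log(2 / (1 - r c + sqrt(1 - 2 r c + r^2)))`;
#'   `"series"` sums `n_terms` terms explicitly (the truncation error decays
#'   slowly, about `n^-1/2`, so this mode exists for cross-checking).
#' @return Potential (V) at each sample point.
#' @export
sphere_surface_potential <- function(points, center, radius, source_dir,
                                     sink_dir, current_A = 1e-3, sigma,
                                     n_terms = 200,
                                     method = c("closed", "series")) {
  method <- match.arg(method)
  points <- matrix(as.numeric(points), ncol = 3)
  u <- sweep(points, 2, center)
  r <- sqrt(rowSums(u^2))
  u <- u / r
  rho <- pmin(r / radius, 1)
  a <- source_dir / sqrt(sum(source_dir^2))
  b <- sink_dir / sqrt(sum(sink_dir^2))
  ca <- pmin(pmax(u %*% a, -1), 1)
  cb <- pmin(pmax(u %*% b, -1), 1)
  R_m <- radius * 1e-3
  closed <- function(x) {
    q <- sqrt(pmax(1 - 2 * rho * x + rho^2, 0))
    2 * (1 / q - 1) + log(2 / (1 - rho * x + q))
  }
  series <- function(x) {
    p_prev <- rep(1, length(x))       # P_0
    p_cur <- x                        # P_1
    rp <- rho                         # rho^n
    acc <- 3 * rp * p_cur             # (2n+1)/n at n = 1
    for (n in 1:(n_terms - 1)) {
      p_next <- ((2 * n + 1) * x * p_cur - n * p_prev) / (n + 1)
      rp <- rp * rho
      acc <- acc + (2 * (n + 1) + 1) / (n + 1) * rp * p_next
      p_prev <- p_cur
      p_cur <- p_next
    }
    acc
  }
  f <- if (method == "closed") closed else series
  current_A / (4 * pi * sigma * R_m) * (f(as.numeric(ca)) - f(as.numeric(cb)))
}

# closed-form limit of the series (for testing the oracle itself), from the
# generating functions sum P_n = 1/(2 s) - 1 and sum P_n/n = -log(s (1 + s))
# with s = sin(g/2):
# sum (2n+1)/n P_n(cos g) = 1/s - 2 - log(s (1 + s))
sphere_series_closed_form <- function(cosg) {
  s <- sqrt((1 - cosg) / 2)       # sin(g/2)
  1 / s - 2 - log(s * (1 + s))
}
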