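# the analytic two-electrode sphere solution is the oracle for the FEM
# validation; check it against independent mathematics before trusting it

test_that("explicit series summation converges to the closed-form evaluation", {
  R <- 30; sigma <- 0.5
  ctr <- c(0, 0, 0)
  cth <- seq(-0.9, 0.9, length.out = 24)
  pts <- cbind(sqrt(1 - cth^2) * R, 0, cth * R)
  f <- function(method, n) sphere_surface_potential(
    pts, ctr, R, c(0, 0, 1), c(0, 0, -1), current_A = 1e-3, sigma = sigma,
    n_terms = n, method = method)
  vc <- f("closed", 0)
  v1 <- f("series", 500)
  v2 <- f("series", 8000)
  scale <- max(abs(vc))
  # truncation error decays slowly (~ 1/sqrt(n)); 8000 terms reach ~1%
  expect_lt(max(abs(v2 - vc)) / scale, 0.02)
  expect_lt(max(abs(v2 - vc)), max(abs(v1 - vc)))
  # surface closed form agrees with the independently derived identity
  cf <- 1e-3 / (4 * pi * sigma * R * 1e-3) *
    (tcranchan:::sphere_series_closed_form(cth) -
       tcranchan:::sphere_series_closed_form(-cth))
  expect_equal(vc, cf, tolerance = 1e-10)
})

test_that("near a surface electrode the potential approaches the half-space point source", {
  # close to the source the potential behaves as I / (2 pi sigma s), s the
  # arc distance
  R <- 30; sigma <- 0.5
  gam <- c(0.01, 0.02, 0.03)
  pts <- cbind(sin(gam) * R, 0, cos(gam) * R)
  v <- sphere_surface_potential(pts, c(0, 0, 0), R, c(0, 0, 1), c(0, 0, -1),
                                current_A = 1e-3, sigma = sigma)
  s_m <- gam * R * 1e-3
  approx <- 1e-3 / (2 * pi * sigma * s_m)
  expect_equal(v, approx, tolerance = 0.05)
})

test_that("interior evaluation decays with depth and is antisymmetric", {
  R <- 30; sigma <- 0.3
  p_surf <- cbind(20, 0, sqrt(R^2 - 400) - 0.01)
  p_deep <- p_surf / 2
  f <- function(p) sphere_surface_potential(p, c(0, 0, 0), R, c(0, 0, 1),
                                            c(0, 0, -1), 1e-3, sigma)
  expect_gt(abs(f(p_surf)), abs(f(p_deep)))
  # swapping source and sink negates the potential
  g <- function(p) sphere_surface_potential(p, c(0, 0, 0), R, c(0, 0, -1),
                                            c(0, 0, 1), 1e-3, sigma)
  expect_equal(f(p_surf), -g(p_surf), tolerance = 1e-12)
})
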