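test_that("spatially constant extracellular potential produces zero polarization", {
  m <- build_pn("L5")
  n <- nrow(m$comp)
  p0 <- steady_state_polarization(m, rep(3.7, n))
  expect_lt(max(abs(p0$dV_mV)), 1e-10)
  pz <- steady_state_polarization(m, rep(0, n))
  expect_lt(max(abs(pz$dV_mV)), 1e-12)
  expect_lt(max(abs(uniform_field_polarization(m, c(0, 0, 0))$dV_mV)), 1e-12)
})

test_that("sealed-end fiber matches the classical cable closed form", {
  p <- membrane_params()
  d <- 2; L <- 1
  lam <- length_constant(d, p)
  m <- straight_fiber(125, L, d)   # 250 compartments
  E <- 10   # V/m along +z
  prof <- uniform_field_polarization(m, c(0, 0, E), p)
  lm <- attr(prof, "landmarks")
  theory <- E * lam * tanh((L / 2) / lam)
  expect_equal(abs(lm[["top"]]), theory, tolerance = 0.01)
  expect_equal(abs(lm[["bottom"]]), theory, tolerance = 0.01)
  # midpoint polarization vanishes; the two ends are antisymmetric
  expect_lt(abs(lm[["center"]]), 1e-9)
  expect_equal(lm[["top"]], -lm[["bottom"]], tolerance = 1e-9)
  # full antisymmetry of the profile about the center
  n <- 125
  expect_equal(prof$dV_mV[1 + (1:n)], -prof$dV_mV[1 + n + (1:n)],
               tolerance = 1e-9)
})

test_that("sparse steady-state solve matches a dense first-principles oracle", {
  set.seed(7)
  worst <- 0
  for (trial in 1:20) {
    m <- random_tree(sample(10:50, 1))
    e <- rnorm(nrow(m$comp), sd = 2)
    got <- steady_state_polarization(m, e)$dV_mV
    want <- dense_cable_solve(m, e)
    rel <- max(abs(got - want)) / max(abs(want), 1e-12)
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-10)
})

test_that("polarization is linear in the extracellular drive (superposition)", {
  set.seed(11)
  m <- random_tree(40)
  e1 <- rnorm(40); e2 <- rnorm(40)
  p1 <- steady_state_polarization(m, e1)$dV_mV
  p2 <- steady_state_polarization(m, e2)$dV_mV
  p12 <- steady_state_polarization(m, 2 * e1 - 0.5 * e2)$dV_mV
  expect_equal(p12, 2 * p1 - 0.5 * p2, tolerance = 1e-9)
})

test_that("L5 under an inward field: apical tip hyperpolarized, soma depolarized", {
  for (kind in c("L5", "L3")) {
    prof <- uniform_field_polarization(build_pn(kind), c(0, 0, -3))
    lm <- attr(prof, "landmarks")
    expect_lt(lm[["d2"]], 0)
    expect_gt(lm[["soma"]], 0)
  }
})

test_that("somatic polarization decreases as the soma diameter grows", {
  dvs <- vapply(c(10, 15, 20, 25, 30), function(sd_) {
    m <- build_pn("L5", morph_params(soma_diameter = sd_))
    attr(uniform_field_polarization(m, c(0, 0, -3)), "landmarks")[["soma"]]
  }, numeric(1))
  expect_true(all(dvs > 0))
  expect_true(all(diff(abs(dvs)) < 0))
})

test_that("the apical-flattened variant depolarizes the soma more than the tall one", {
  tall <- attr(uniform_field_polarization(build_pn("L5", morph_params(flatness = 1)),
                                          c(0, 0, -3)), "landmarks")[["soma"]]
  flat <- attr(uniform_field_polarization(build_pn("L5", morph_params(flatness = 0.5)),
                                          c(0, 0, -3)), "landmarks")[["soma"]]
  expect_gt(flat, tall)
  expect_gt(tall, 0)
})

test_that("coupling constant is the somatic polarization per unit field", {
  prof <- uniform_field_polarization(build_pn("L5"), c(0, 0, -3))
  lm <- attr(prof, "landmarks")
  k <- coupling_constant(prof, 3)
  expect_equal(k$k_mm, lm[["soma"]] / 3)
  # definitional check: 0.0784 mV at 1 mV/mm is a 0.0784 mm constant
  fake <- prof
  attr(fake, "landmarks")["soma"] <- 0.0784
  expect_equal(coupling_constant(fake, 1)$k_mm, 0.0784)
  # scale invariance: doubling dV and the field leaves k unchanged
  prof2 <- uniform_field_polarization(build_pn("L5"), c(0, 0, -6))
  expect_equal(coupling_constant(prof2, 6)$k_mm, k$k_mm, tolerance = 1e-9)
  expect_error(coupling_constant(prof, 0), "positive")
})

test_that("backward-Euler integration converges to the steady state", {
  m <- build_pn("L3")
  ctr <- compartment_centers(m)
  e <- -(ctr[, 3] * -3)
  ss <- steady_state_polarization(m, e)
  ti <- integrate_polarization(m, e, dt = 0.2)   # 10 membrane time constants
  expect_lt(max(abs(ti$dV_mV - ss$dV_mV)) / max(abs(ss$dV_mV)), 1e-3)
})

test_that("drive vector length and tree connectivity are validated", {
  m <- build_pn("L5")
  expect_error(steady_state_polarization(m, c(1, 2, 3)), "one value per")
  expect_error(steady_state_polarization(m, rep(NA_real_, nrow(m$comp))),
               "finite")
})
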