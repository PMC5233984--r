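test_that("surface normals on a flat slab point straight up and have unit length", {
  head <- head_params(fold_amplitude = 0, lateral_extent = 20, wm_min = 3)
  g <- build_head_model(head_grid(head, 0.5), head)
  sn <- surface_normals(g)
  expect_gt(nrow(sn), 0)
  nrm <- sqrt(sn$nx^2 + sn$ny^2 + sn$nz^2)
  expect_equal(nrm, rep(1, nrow(sn)), tolerance = 1e-6)
  # away from the lateral grid rim (where the smoothed indicator is clipped)
  h <- g$spec$spacing
  x <- g$spec$origin[1] + (sn$i - 0.5) * h
  y <- g$spec$origin[2] + (sn$j - 0.5) * h
  interior <- abs(x) < 7 & abs(y) < 7
  expect_true(all(sn$nz[interior] > 0.99))
})

test_that("sphere-phantom normals agree with the exact radial direction", {
  g <- build_sphere_phantom(grid_spec(c(0, 0, 0), 0.5, c(60, 60, 60)),
                            sphere_params(c(13, 10), c("CSF", "GM")))
  sn <- surface_normals(g)
  ctr <- attr(g, "sphere")$center
  h <- g$spec$spacing
  rx <- g$spec$origin[1] + (sn$i - 0.5) * h - ctr[1]
  ry <- g$spec$origin[2] + (sn$j - 0.5) * h - ctr[2]
  rz <- g$spec$origin[3] + (sn$k - 0.5) * h - ctr[3]
  rn <- sqrt(rx^2 + ry^2 + rz^2)
  cosang <- (sn$nx * rx + sn$ny * ry + sn$nz * rz) / rn
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  expect_lt(stats::quantile(ang, 0.95), 5)
  expect_lt(mean(ang), 5)
})

test_that("missing GM/CSF interface raises an error", {
  g <- cube_grid(6, 1, "WM")
  expect_error(surface_normals(g), "interface")
})

test_that("radial/tangential decomposition handles the canonical angles", {
  head <- head_params(fold_amplitude = 0, lateral_extent = 12, wm_min = 3)
  g <- build_head_model(head_grid(head, 1), head)
  sn <- surface_normals(g)
  sn$nx <- 0; sn$ny <- 0; sn$nz <- 1    # exact slab normals
  mock_fs <- function(E) {
    sh <- g$spec$shape
    structure(list(Ex = array(E[1], sh), Ey = array(E[2], sh),
                   Ez = array(E[3], sh),
                   mag = array(sqrt(sum(E^2)), sh),
                   labels = g$labels, spec = g$spec),
              class = "field_samples")
  }
  # parallel to the normal, |E| = 2, pointing outward (+z) -> Er = -2 (inward
  # positive), Et = 0
  d <- decompose_field(mock_fs(c(0, 0, 2)), sn)
  expect_equal(d$Er, rep(-2, nrow(d)), tolerance = 1e-6)
  expect_equal(d$Et, rep(0, nrow(d)), tolerance = 1e-6)
  # inward-directed field is positive
  d2 <- decompose_field(mock_fs(c(0, 0, -2)), sn)
  expect_true(all(d2$Er > 1.99))
  # perpendicular: Er = 0, Et = 2
  d3 <- decompose_field(mock_fs(c(2, 0, 0)), sn)
  expect_equal(d3$Er, rep(0, nrow(d3)), tolerance = 1e-6)
  expect_equal(d3$Et, rep(2, nrow(d3)), tolerance = 1e-6)
  # 45 degrees: |Er| = Et = 1/sqrt(2)
  d4 <- decompose_field(mock_fs(c(1, 0, 1) / sqrt(2)), sn)
  expect_equal(abs(d4$Er), rep(1 / sqrt(2), nrow(d4)), tolerance = 1e-6)
  expect_equal(d4$Et, rep(1 / sqrt(2), nrow(d4)), tolerance = 1e-6)
  # Pythagorean identity on a skew field
  d5 <- decompose_field(mock_fs(c(0.3, -1.1, 0.7)), sn)
  expect_equal(d5$Er^2 + d5$Et^2, d5$mag^2, tolerance = 1e-9)
})

test_that("focality volumes follow the strict-threshold hand count", {
  sh <- c(4L, 2L, 2L)
  labels <- array(TISSUES[["WM"]], sh)
  labels[, 1, 1] <- TISSUES[["GM"]]     # four unit-volume GM cells
  mag <- array(0, sh)
  mag[, 1, 1] <- c(1.0, 0.6, 0.55, 0.4)
  fs <- structure(list(
    Ex = array(0, sh), Ey = array(0, sh), Ez = array(0, sh),
    mag = mag, labels = labels,
    spec = grid_spec(c(0, 0, 0), 1, sh)), class = "field_samples")
  rep_ <- focality_volumes(fs, "GM")
  expect_equal(rep_$peak, 1.0)
  expect_equal(unname(rep_$volumes), c(3, 1, 1, 1))
  # uniform field over the region: strict inequality gives zero volumes
  fs$mag[, 1, 1] <- 2
  rep_u <- focality_volumes(fs, "GM")
  expect_equal(unname(rep_u$volumes), c(0, 0, 0, 0))
  # empty region errors
  expect_error(focality_volumes(fs, "CSF"), "empty")
})

test_that("focality volumes are nested and scale-invariant", {
  set.seed(42)
  sh <- c(10L, 10L, 4L)
  fs <- structure(list(
    Ex = array(0, sh), Ey = array(0, sh), Ez = array(0, sh),
    mag = array(runif(prod(sh)), sh),
    labels = array(TISSUES[["GM"]], sh),
    spec = grid_spec(c(0, 0, 0), 0.5, sh)), class = "field_samples")
  r1 <- focality_volumes(fs, "GM")
  v <- r1$volumes
  expect_true(all(diff(v) <= 0))
  fs$mag <- fs$mag * 7.3
  r2 <- focality_volumes(fs, "GM")
  expect_equal(r2$volumes, v)
})

test_that("peak field on the channel-free head sits at the gyral crown", {
  head <- small_head()
  g <- build_head_model(head_grid(head, 1), head)
  pm <- place_montage(g, small_montage())
  pf <- solve_potential(pm)
  fs <- compute_efield(pf, pm$grid)
  foc <- focality_volumes(fs, "GM")
  # peak within a few mm of the crown axis, in the upper half of the GM band
  expect_lt(sqrt(sum(foc$location[1:2]^2)), 6)
  gm_k <- which(apply(pm$grid$labels == TISSUES[["GM"]], 3, any))
  expect_gt(foc$cell[3], mean(range(gm_k)))
})
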