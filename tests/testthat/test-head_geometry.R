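test_that("grid_spec validates its invariants", {
  expect_error(grid_spec(c(0, 0, 0), 0, c(4, 4, 4)), "spacing")
  expect_error(grid_spec(c(0, 0, 0), 1, c(1, 4, 4)), ">= 2")
  g <- grid_spec(c(-1, -1, 0), 0.5, c(4, 6, 8))
  expect_identical(g$shape, c(4L, 6L, 8L))
})

test_that("head model labels every cell and layers have the right thickness", {
  head <- small_head()
  g <- build_head_model(head_grid(head, 0.5), head)
  # partition: label counts sum to the total cell count
  expect_identical(sum(table(g$labels)), length(g$labels))
  expect_true(all(g$labels %in% TISSUES))
  # dura measures 0.5 mm in z (one 0.5 mm cell) everywhere in a flat layer
  kprof <- apply(g$labels == TISSUES[["DURA"]], 3, any)
  expect_identical(sum(kprof), 1L)
  # crown column: CSF thickness equals the configured value
  spec <- g$spec
  i <- floor((0 - spec$origin[1]) / spec$spacing) + 1
  col <- g$labels[i, i, ]
  expect_equal(sum(col == TISSUES[["CSF"]]) * spec$spacing, head$csf)
  expect_equal(sum(col == TISSUES[["GM"]]) * spec$spacing, head$gm)
})

test_that("zero fold amplitude yields a flat GM/CSF boundary", {
  head <- head_params(fold_amplitude = 0, lateral_extent = 20, wm_min = 3)
  g <- build_head_model(head_grid(head, 0.5), head)
  gm_top <- apply(g$labels == TISSUES[["GM"]], c(1, 2), function(col) max(which(col)))
  expect_true(all(gm_top == gm_top[1, 1]))
})

test_that("layers that do not fit raise a configuration error naming the layer", {
  head <- small_head()
  grid <- grid_spec(c(-30, -30, 0), 0.5, c(120, 120, 20))  # 10 mm tall
  expect_error(build_head_model(grid, head), "skull|csf|dura")
})

test_that("fold crown apex lies beneath the montage center", {
  head <- small_head()
  g <- build_head_model(head_grid(head, 0.5), head)
  gm <- which(g$labels == TISSUES[["GM"]], arr.ind = TRUE)
  k_max <- max(gm[, 3])
  crown_x <- g$spec$origin[1] + (gm[gm[, 3] == k_max, 1] - 0.5) * g$spec$spacing
  expect_lte(min(abs(crown_x)), head$fold_wavelength / 4)
  expect_lte(abs(mean(range(crown_x))), 1)
})

test_that("sphere phantom shells match analytic volumes within 5%", {
  radii <- c(20, 17, 14, 11)
  labs <- c("SCALP", "SKULL", "CSF", "GM")
  g <- build_sphere_phantom(grid_spec(c(0, 0, 0), 1, c(44, 44, 44)),
                            sphere_params(radii, labs))
  outer_r <- radii
  inner_r <- c(radii[-1], 0)
  for (q in seq_along(labs)) {
    vol <- sum(g$labels == TISSUES[[labs[q]]]) * 1
    expect_equal(vol, 4 * pi / 3 * (outer_r[q]^3 - inner_r[q]^3),
                 tolerance = 0.05)
  }
})

test_that("sphere phantom validates radii", {
  expect_error(sphere_params(c(10, 12), c("GM", "WM")), "decreasing")
  expect_error(
    build_sphere_phantom(grid_spec(c(0, 0, 0), 1, c(10, 10, 10)),
                         sphere_params(20, "GM")),
    "fit")
})

test_that("channel carving respects shape, extent and conservation", {
  head <- small_head()
  g0 <- build_head_model(head_grid(head, 0.5), head)
  skull_before <- sum(g0$labels == TISSUES[["SKULL"]])

  # NONE is the identity
  expect_identical(carve_channel(g0, channel_spec("NONE"))$labels, g0$labels)

  # T hat diameter defaults to shaft + 1
  chT <- channel_spec("T", 7)
  expect_equal(chT$hat_diameter, 8)

  gT <- carve_channel(g0, chT)
  chan <- gT$labels == TISSUES[["CHANNEL"]]
  expect_gt(sum(chan), 0)
  # carving is confined to former skull cells and conserves skull + channel
  expect_identical(sum(gT$labels == TISSUES[["SKULL"]]) + sum(chan),
                   skull_before)
  changed <- which(gT$labels != g0$labels)
  expect_true(all(g0$labels[changed] == TISSUES[["SKULL"]]))

  # I-shaped shaft traverses the entire skull thickness
  gI <- carve_channel(g0, channel_spec("I", 7))
  skull_k <- which(apply(g0$labels == TISSUES[["SKULL"]], 3, any))
  chan_k <- which(apply(gI$labels == TISSUES[["CHANNEL"]], 3, any))
  expect_identical(min(chan_k), min(skull_k))
  expect_identical(max(chan_k), max(skull_k))

  # hat occupies more cells than the shaft alone at the hat level
  gI7 <- carve_channel(g0, channel_spec("I", 7))
  expect_gt(sum(gT$labels == TISSUES[["CHANNEL"]]),
            sum(gI7$labels == TISSUES[["CHANNEL"]]))

  # axis that misses the skull errors
  expect_error(carve_channel(g0, channel_spec("I", 2, position = c(500, 0))),
               "skull")
})

test_that("montage placement creates five assemblies with exact dimensions", {
  head <- small_head()
  g <- build_head_model(head_grid(head, 0.5), head)
  pm <- place_montage(g, small_montage())
  h <- g$spec$spacing
  el <- sum(pm$grid$labels == TISSUES[["ELECTRODE"]])
  gel <- sum(pm$grid$labels == TISSUES[["GEL"]])
  # each disc: pi r^2 h within voxelization error; 5 assemblies
  disc_cells <- sum(outer(tcranchan:::axis_centers(g$spec, 1)^2,
                          tcranchan:::axis_centers(g$spec, 2)^2, "+") <= 16)
  expect_identical(el, 5L * disc_cells * as.integer(round(1 / h)))
  expect_identical(gel, 5L * disc_cells * as.integer(round(2 / h)))
  expect_equal(nrow(pm$active_faces), disc_cells)
  expect_equal(nrow(pm$return_faces), 4 * disc_cells)
})

test_that("rigid displacement shifts all face-set centroids equally", {
  head <- small_head()
  g <- build_head_model(head_grid(head, 0.5), head)
  pm0 <- place_montage(g, small_montage(c(0, 0)))
  pm5 <- place_montage(g, small_montage(c(5, 0)))
  c0a <- tcranchan:::face_centroid(pm0$active_faces, g$spec)
  c5a <- tcranchan:::face_centroid(pm5$active_faces, g$spec)
  expect_equal(c5a - c0a, c(5, 0, 0), tolerance = 1e-10)
  c0r <- tcranchan:::face_centroid(pm0$return_faces, g$spec)
  c5r <- tcranchan:::face_centroid(pm5$return_faces, g$spec)
  expect_equal(c5r - c0r, c(5, 0, 0), tolerance = 1e-10)
  # undisplaced active electrode axis is over the channel axis (origin)
  expect_equal(c0a[1:2], c(0, 0), tolerance = 1e-10)
})

test_that("electrode footprint off the grid raises an error", {
  head <- small_head()
  g <- build_head_model(head_grid(head, 0.5), head)
  expect_error(place_montage(g, montage_spec(ring_radius = 40)), "off the grid")
})

test_that("geometry construction is deterministic (bitwise)", {
  head <- small_head()
  g1 <- carve_channel(build_head_model(head_grid(head, 0.5), head),
                      channel_spec("T", 5))
  g2 <- carve_channel(build_head_model(head_grid(head, 0.5), head),
                      channel_spec("T", 5))
  expect_identical(g1$labels, g2$labels)
})
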