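test_that("parametric morphologies carry the expected landmark sets", {
  l5 <- build_pn("L5")
  expect_setequal(names(l5$landmarks),
                  c("d1", "d2", "d3", "d4", "soma", "iseg", "b1", "b2",
                    "terminal"))
  l3 <- build_pn("L3")
  expect_setequal(names(l3$landmarks),
                  c("d1", "d2", "d3", "soma", "iseg", "mid", "terminal"))
  expect_error(build_pn("L2"), "kind")
})

test_that("morphologies are rooted trees", {
  for (kind in c("L5", "L3")) {
    m <- build_pn(kind)
    comp <- m$comp
    expect_identical(sum(comp$parent == -1L), 1L)
    expect_identical(comp$parent[1], -1L)
    # |edges| = |compartments| - 1 and every parent precedes its child
    expect_identical(sum(comp$parent >= 0), nrow(comp) - 1L)
    expect_true(all(comp$parent[-1] < comp$id[-1]))
    expect_true(all(comp$diam > 0))
    expect_true(all(tcranchan:::compartment_lengths(m) > 0))
  }
})

test_that("morphology constructor validates tree structure and landmarks", {
  bad <- data.frame(id = 0:1, parent = c(-1L, 5L), part = "axon",
                    x = 0, y = 0, z = c(0, 1), diam = 1)
  expect_error(morphology(bad), "parent")
  two_roots <- data.frame(id = 0:1, parent = c(-1L, -1L), part = "axon",
                          x = 0, y = 0, z = c(0, 1), diam = 1)
  expect_error(morphology(two_roots), "root|parent")
  ok <- data.frame(id = 0:1, parent = c(-1L, 0L), part = "axon",
                   x = 0, y = 0, z = c(0, 1), diam = 1)
  expect_error(morphology(ok, landmarks = c(soma = 7L)), "landmark")
})

test_that("SWC round trip preserves structure and landmark coordinates", {
  m <- build_pn("L5")
  path <- withr::local_tempfile(fileext = ".swc")
  write_swc(m, path)
  m2 <- read_swc(path)
  expect_identical(nrow(m2$comp), nrow(m$comp))
  expect_identical(m2$comp$parent, m$comp$parent)
  expect_identical(m2$comp$part, m$comp$part)
  expect_equal(m2$comp[, c("x", "y", "z")], m$comp[, c("x", "y", "z")],
               tolerance = 1e-6)
  expect_equal(m2$comp$diam, m$comp$diam, tolerance = 1e-6)
})

test_that("a minimal three-point SWC file parses with correct parents", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("# comment",
               "1 1 0 0 0 10 -1",
               "2 3 10 0 0 1 1",
               "3 3 -10 0 0 1 1"), path)
  m <- read_swc(path)
  expect_identical(nrow(m$comp), 3L)
  expect_identical(m$comp$parent, c(-1L, 0L, 0L))
  expect_identical(m$comp$part, c("soma", "basal_dendrite", "basal_dendrite"))
  expect_equal(m$comp$x, c(0, 0.01, -0.01))   # um -> mm
  expect_equal(m$comp$diam, c(20, 2, 2))      # radius -> diameter
})

test_that("malformed SWC files raise parse errors naming the line", {
  path <- withr::local_tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 10 -1", "2 3 1 0 0 1 9"), path)
  expect_error(read_swc(path), "line 2")
  writeLines(c("1 1 0 0 0 10 -1", "2 3 1 0 0 1"), path)
  expect_error(read_swc(path), "line 2")
  # cycle: 2 -> 3 -> 2 unreachable from root
  writeLines(c("1 1 0 0 0 10 -1", "2 3 1 0 0 1 3", "3 3 2 0 0 1 2"), path)
  expect_error(read_swc(path), "line")
})

test_that("placement on a flat slab is translation plus scaling", {
  m <- build_pn("L5")
  pn <- place_neuron(m, c(3, -2, 10), c(0, 0, 1), gm_thickness = 2.5)
  # no rotation: x/y offsets preserved up to the apical/axon z-scaling
  soma <- pn$morph$comp[1, ]
  expect_equal(c(soma$x, soma$y), c(3, -2))
  expect_equal(soma$z, 10 - 0.75 * 2.5)
  # apical tip reaches the layer-1 band (top 10% of GM)
  ap <- pn$morph$comp$part == "apical_dendrite"
  tip_depth <- 10 - max(pn$morph$comp$z[ap])
  expect_lt(tip_depth, 0.1 * 2.5)
  expect_gt(tip_depth, 0)
})

test_that("placed L5 axon crosses the GM/WM boundary at b1; L3 stays in GM", {
  head <- small_head()
  g <- build_head_model(head_grid(head, 0.5), head)
  sn <- surface_normals(g)
  ci <- tcranchan:::column_cortex(g, 0, 0)
  sp <- c(0, 0, ci$surface)
  pn5 <- place_neuron(build_pn("L5"), sp, c(0, 0, 1), ci$gm_thickness)
  b1 <- pn5$morph$comp[match(pn5$morph$landmarks[["b1"]], pn5$morph$comp$id), ]
  boundary_z <- ci$surface - ci$gm_thickness
  expect_lt(abs(b1$z - boundary_z), g$spec$spacing)
  # L5 axon crosses into WM exactly once before the bend
  ax <- pn5$morph$comp[pn5$morph$comp$part == "axon", ]
  expect_gt(sum(ax$z < boundary_z), 0)
  # all L3 compartments carry the GM label
  pn3 <- place_neuron(build_pn("L3"), sp, c(0, 0, 1), ci$gm_thickness)
  ctr <- compartment_centers(pn3$morph)
  h <- g$spec$spacing
  idx <- floor(sweep(ctr, 2, g$spec$origin) / h) + 1
  labs <- g$labels[cbind(idx[, 1], idx[, 2], idx[, 3])]
  expect_true(all(labs == TISSUES[["GM"]]))
})

test_that("a neuron cannot be placed in absent gray matter", {
  m <- build_pn("L5")
  expect_error(place_neuron(m, c(0, 0, 5), c(0, 0, 1), gm_thickness = 0),
               "cannot fit")
})

test_that("ROI lattice population matches the target density", {
  head <- small_head()
  g <- build_head_model(head_grid(head, 0.5), head)
  sn <- surface_normals(g)
  # 0.84 mm spacing on a 5 mm disc: about 112 neurons
  pop <- populate_roi(g, roi_spec(radius = 5, spacing = 0.84), "L5",
                      normals = sn)
  expect_gte(length(pop), round(112 * 0.95))
  expect_lte(length(pop), round(112 * 1.05))
  # radius -> 0 yields exactly the central neuron
  pop1 <- populate_roi(g, roi_spec(radius = 1e-6, spacing = 1), "L5",
                       normals = sn)
  expect_identical(length(pop1), 1L)
  # doubling the spacing reduces the count
  pop2 <- populate_roi(g, roi_spec(radius = 5, spacing = 1.68), "L5",
                       normals = sn)
  expect_lt(length(pop2), length(pop))
})

test_that("placement table reports landmarks and stretch factors", {
  head <- small_head()
  g <- build_head_model(head_grid(head, 0.5), head)
  sn <- surface_normals(g)
  pop <- populate_roi(g, roi_spec(radius = 2, spacing = 1), "L5", normals = sn)
  tab <- placement_table(pop)
  expect_identical(nrow(tab), length(pop))
  expect_true(all(c("soma_depth", "scale_apical", "b1_z", "d2_z") %in%
                    names(tab)))
  # apical tip above the soma, axon boundary landmark below it
  expect_true(all(tab$d2_z > tab$soma_z))
  expect_true(all(tab$b1_z < tab$soma_z))
  # seeded jitter perturbs placements reproducibly
  set.seed(5)
  j1 <- populate_roi(g, roi_spec(radius = 2, spacing = 1), "L5",
                     normals = sn, jitter = 0.2)
  set.seed(5)
  j2 <- populate_roi(g, roi_spec(radius = 2, spacing = 1), "L5",
                     normals = sn, jitter = 0.2)
  expect_identical(placement_table(j1), placement_table(j2))
  expect_false(identical(placement_table(j1)$soma_x, tab$soma_x))
})

test_that("placement records scale factors and is deterministic", {
  head <- small_head()
  g <- build_head_model(head_grid(head, 0.5), head)
  sn <- surface_normals(g)
  p1 <- populate_roi(g, roi_spec(radius = 2, spacing = 1), "L5", normals = sn)
  p2 <- populate_roi(g, roi_spec(radius = 2, spacing = 1), "L5", normals = sn)
  expect_identical(lapply(p1, function(x) x$morph$comp),
                   lapply(p2, function(x) x$morph$comp))
  expect_true(all(vapply(p1, function(x) x$scale_apical, numeric(1)) > 0))
})
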