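test_that("homogeneous slab with fixed top/bottom potentials is linear in z", {
  n <- 10L
  g <- cube_grid(n, 1)
  f <- cube_z_faces(n)
  pf <- solve_laplace(g, c(GM = 0.276),
                      dirichlet = list(list(faces = f$bottom, value = 0),
                                       list(faces = f$top, value = 1)),
                      cfg = solver_config(rtol = 1e-10, precond = "ssor"))
  zlin <- rep((0:n) / n, each = (n + 1)^2)
  expect_lt(max(abs(as.numeric(pf$phi) - zlin)), 1e-6)
  expect_lte(pf$relres, 1e-10)
})

test_that("reported residual honors the configured tolerance", {
  n <- 8L
  g <- cube_grid(n, 1)
  f <- cube_z_faces(n)
  for (pc in c("mg", "ssor", "jacobi")) {
    pf <- solve_laplace(g, c(GM = 0.276),
                        dirichlet = list(list(faces = f$bottom, value = 0),
                                         list(faces = f$top, value = 1)),
                        cfg = solver_config(rtol = 1e-9, precond = pc))
    expect_lte(pf$relres, 1e-9)
  }
})

test_that("a system without Dirichlet nodes is rejected as singular", {
  g <- cube_grid(6, 1)
  expect_error(solve_laplace(g, c(GM = 0.276), dirichlet = list()), "singular")
})

test_that("non-convergence at the iteration cap reports the residual", {
  n <- 8L
  g <- cube_grid(n, 1)
  f <- cube_z_faces(n)
  expect_error(
    solve_laplace(g, c(GM = 0.276),
                  dirichlet = list(list(faces = f$bottom, value = 0),
                                   list(faces = f$top, value = 1)),
                  cfg = solver_config(rtol = 1e-12, maxit = 1L,
                                      precond = "jacobi")),
    "did not converge.*residual")
})

test_that("electric field of a linear potential is uniform and exact", {
  n <- 8L
  g <- cube_grid(n, 1)
  f <- cube_z_faces(n)
  pf <- solve_laplace(g, c(GM = 1),
                      dirichlet = list(list(faces = f$bottom, value = 0),
                                       list(faces = f$top, value = 1)),
                      cfg = solver_config(rtol = 1e-11, precond = "ssor"))
  fs <- compute_efield(pf, g)
  # 1 V across n mm: |Ez| = 1000/n V/m, pointing -z
  expect_equal(as.numeric(fs$Ez), rep(-1000 / n, n^3), tolerance = 1e-6)
  expect_lt(max(abs(fs$Ex)), 1e-4)
  expect_lt(max(abs(fs$Ey)), 1e-4)
  # constant potential -> zero field
  pf0 <- pf
  pf0$phi[] <- 0.7
  fs0 <- compute_efield(pf0, g)
  expect_equal(max(fs0$mag), 0)
})

test_that("solution scales linearly with the injected current", {
  head <- small_head()
  g <- build_head_model(head_grid(head, 1), head)
  pm1 <- place_montage(g, small_montage())
  pm2 <- pm1
  pm2$montage$current_mA <- 2
  cfg <- solver_config(rtol = 1e-10)
  pf1 <- solve_potential(pm1, cfg = cfg)
  pf2 <- solve_potential(pm2, cfg = cfg)
  expect_equal(as.numeric(pf2$phi), 2 * as.numeric(pf1$phi),
               tolerance = 1e-6)
})

test_that("swapping source and sink negates the potential (reciprocity)", {
  # homogeneous cube, two electrode patches: +I at A with B grounded, then
  # -I at B... realized by exchanging the roles and negating the current
  n <- 10L
  g <- cube_grid(n, 1)
  ij <- expand.grid(i = 1:3, j = 1:3)
  fA <- data.frame(i = ij$i, j = ij$j, k = n - 1L, axis = 3L, side = 1L)
  fB <- data.frame(i = ij$i + 5L, j = ij$j + 5L, k = n - 1L, axis = 3L, side = 1L)
  cfg <- solver_config(rtol = 1e-11, precond = "ssor")
  pfAB <- solve_laplace(g, c(GM = 0.3), neumann_faces = fA, current_A = 1e-3,
                        dirichlet = list(list(faces = fB, value = 0)), cfg = cfg)
  pfBA <- solve_laplace(g, c(GM = 0.3), neumann_faces = fA, current_A = -1e-3,
                        dirichlet = list(list(faces = fB, value = 0)), cfg = cfg)
  expect_equal(as.numeric(pfAB$phi), -as.numeric(pfBA$phi), tolerance = 1e-7)
})

test_that("trilinear sampling is exact for multilinear potentials and at nodes", {
  n <- 6L
  g <- cube_grid(n, 1)
  f <- cube_z_faces(n)
  pf <- solve_laplace(g, c(GM = 1),
                      dirichlet = list(list(faces = f$bottom, value = 0),
                                       list(faces = f$top, value = 1)),
                      cfg = solver_config(rtol = 1e-11, precond = "ssor"))
  pts <- rbind(c(2, 3, 4), c(0.25, 5.5, 1.75), c(3.3, 0.01, 5.99))
  expect_equal(sample_potential(pf, pts), pts[, 3] / n, tolerance = 1e-7)
  # node-exact
  expect_equal(sample_potential(pf, rbind(c(2, 2, 2))), pf$phi[3, 3, 3])
  # cell center of a multilinear field equals the mean of its 8 nodes
  pf$phi <- array(outer(outer(0:n, 0:n), 0:n) + 1, dim(pf$phi))  # xyz product
  ctr <- rbind(c(2.5, 2.5, 2.5))
  expect_equal(sample_potential(pf, ctr), mean(pf$phi[3:4, 3:4, 3:4]))
  expect_error(sample_potential(pf, rbind(c(-1, 0, 0))), "outside")
})

test_that("raising channel conductivity strictly raises the GM peak field", {
  head <- small_head()
  cfg <- solver_config(rtol = 1e-9)
  peaks <- vapply(c(0.01, 7.4e5), function(sig_chan) {
    g <- build_head_model(head_grid(head, 1), head)
    g <- carve_channel(g, channel_spec("T", 7))
    pm <- place_montage(g, small_montage())
    sig <- default_conductivities()
    sig[["CHANNEL"]] <- sig_chan
    pf <- solve_potential(pm, sig, cfg)
    fs <- compute_efield(pf, pm$grid)
    focality_volumes(fs, "GM")$peak
  }, numeric(1))
  expect_gt(peaks[2], peaks[1])
})

test_that("net current through a box around the active electrode is 1 mA", {
  head <- small_head()
  g <- build_head_model(head_grid(head, 1), head)
  pm <- place_montage(g, small_montage())
  pf <- solve_potential(pm)
  spec <- g$spec
  # box: laterally +/- 8 mm around the center, from mid-scalp to above
  ctr <- round((0 - spec$origin[1:2]) / spec$spacing)
  kmid <- max(which(apply(pm$grid$labels == TISSUES[["SCALP"]], 3, any))) - 2L
  lo <- c(ctr[1] - 8, ctr[2] - 8, kmid)
  hi <- c(ctr[1] + 8, ctr[2] + 8, spec$shape[3])
  flux <- current_flux_box(pf, pm$grid, default_conductivities(), lo, hi)
  expect_equal(flux, 1e-3, tolerance = 0.02)
})
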