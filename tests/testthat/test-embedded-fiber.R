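test_that("fiber paths validate their polylines", {
  expect_error(fiber_path(rbind(c(0, 0, 0), c(0, 0, 0)), 1, 1), "distinct")
  expect_error(fiber_path(rbind(c(0, 0, 0), c(1, 0, 0)), -1, 1))
  p <- fiber_path(rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12)), 0.5, 1000)
  expect_equal(path_length(p), 17)
})

test_that("fibers are split at element boundaries with exact length bookkeeping", {
  mesh <- box_mesh(c(0, 1, 2), 0:1, 0:1)
  f <- fiber_path(rbind(c(0, 0.5, 0.5), c(2, 0.5, 0.5)), 1, 1)
  segs <- segment_fibers(mesh, f)
  expect_length(segs, 2)
  expect_setequal(vapply(segs, `[[`, 1L, "element"), 1:2)
  expect_equal(sum(vapply(segs, `[[`, 1, "length")), 2)
  # natural endpoint coordinates agree with the affine map
  s1 <- segs[[which(vapply(segs, `[[`, 1L, "element") == 1L)]]
  expect_equal(s1$xi_m, c(-1, 0, 0), tolerance = 1e-8)
  expect_equal(s1$xi_n, c(1, 0, 0), tolerance = 1e-8)
  # a fiber wholly inside one element stays one segment
  g <- fiber_path(rbind(c(0.1, 0.2, 0.3), c(0.8, 0.7, 0.9)), 1, 1)
  sg <- segment_fibers(mesh, g)
  expect_length(sg, 1)
  expect_equal(sg[[1]]$xi_m, 2 * c(0.1, 0.2, 0.3) - 1, tolerance = 1e-8)
  expect_equal(sg[[1]]$length, path_length(g))
  # points outside the mesh are reported
  out <- fiber_path(rbind(c(0.5, 0.5, 0.5), c(0.5, 0.5, 5)), 1, 1)
  expect_error(segment_fibers(mesh, out), "unlocatable")
})

test_that("fiber strain row projects the host strain onto the fiber axis", {
  xc <- cube_coords()
  mesh <- unit_cube()
  seg_x <- segment_fibers(mesh, fiber_path(rbind(c(0, .5, .5), c(1, .5, .5)), 1, 1))[[1]]
  Bp <- fiber_strain_row(xc, seg_x)
  sm <- strain_matrix(xc, (seg_x$xi_m + seg_x$xi_n) / 2)
  expect_equal(as.numeric(Bp), as.numeric(sm$B[1, ]), tolerance = 1e-12)
  # diagonal fiber under pure gamma_xy carries strain gxy / 2
  seg_d <- segment_fibers(mesh, fiber_path(rbind(c(0, 0, .5), c(1, 1, .5)), 1, 1))[[1]]
  u_gxy <- rep(0, 24); u_gxy[seq(1, 24, 3)] <- xc[, 2]
  expect_equal(sum(fiber_strain_row(xc, seg_d) * u_gxy), 0.5, tolerance = 1e-12)
  # volumetric strain gives unit fiber strain for any direction
  set.seed(5)
  u_vol <- as.numeric(t(xc))
  for (r in 1:5) {
    d <- runif(3, 0.1, 1); d <- d / sqrt(sum(d^2))
    p0 <- c(0.2, 0.2, 0.2)
    sgs <- segment_fibers(mesh, fiber_path(rbind(p0, p0 + 0.5 * d), 1, 1))
    expect_equal(sum(fiber_strain_row(xc, sgs[[1]]) * u_vol), 1, tolerance = 1e-10)
  }
})

test_that("fiber stiffness integrates to the analytic bar EA/L", {
  mesh <- unit_cube(); xc <- cube_coords()
  seg <- segment_fibers(mesh, fiber_path(rbind(c(0, .5, .5), c(1, .5, .5)), 1, 1))[[1]]
  kf <- fiber_stiffness(xc, seg)
  expect_equal(kf, t(kf))
  u_str <- rep(0, 24); u_str[seq(1, 24, 3)] <- xc[, 1]
  expect_equal(quad_energy(kf, u_str), 1)       # EA/L * (dL)^2 with EA = L = 1
  expect_equal(fiber_stiffness(xc, seg, E = 0), matrix(0, 24, 24))
  # two collinear half-segments equal the full segment
  s1 <- segment_fibers(mesh, fiber_path(rbind(c(0, .5, .5), c(.5, .5, .5)), 1, 1))[[1]]
  s2 <- segment_fibers(mesh, fiber_path(rbind(c(.5, .5, .5), c(1, .5, .5)), 1, 1))[[1]]
  expect_equal(fiber_stiffness(xc, s1) + fiber_stiffness(xc, s2), kf,
               tolerance = 1e-10)
})

test_that("superposition is additive and scales linearly in fiber count", {
  xc <- cube_coords()
  km <- element_stiffness(xc, elastic_matrix(pcu()))
  expect_equal(superpose(km), km)
  seg <- segment_fibers(unit_cube(),
                        fiber_path(rbind(c(0, .5, .5), c(1, .5, .5)), 0.1, 1000))[[1]]
  kf <- fiber_stiffness(xc, seg)
  k3 <- superpose(km, list(kf, kf, kf))
  expect_equal(k3, km + 3 * kf)
})

test_that("an embedded axial fiber adds the voxel rule-of-mixtures stiffness", {
  # unit-cell compression: effective axial modulus Em + (A/Acell) Ef
  mat <- isotropic_material(57, 0.43)
  fib <- fiber_path(rbind(c(0, .5, .5), c(1, .5, .5)), area = 0.2, E = 1000)
  model <- fe_model(unit_cube(), mat, fibers = list(fib))
  h <- homogenize(model)
  expect_equal(h$constants$EL, 57 + 0.2 * 1000, tolerance = 1e-2)
})

test_that("global reinforced stiffness keeps symmetry, PSD and 6 rigid modes", {
  mesh <- box_mesh(c(0, 1, 2), 0:1, 0:1)
  fib <- fiber_path(rbind(c(0, .3, .6), c(2, .7, .4)), 0.3, 5000)
  K <- as.matrix(assemble(fe_model(mesh, pcu(), fibers = list(fib))))
  expect_equal(K, t(K), tolerance = 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6)
  expect_gt(min(ev), -1e-9 * max(ev))
})

test_that("energies are invariant when mesh, fibers and loads rotate together", {
  set.seed(21)
  mesh <- box_mesh(c(0, 1, 2), 0:1, 0:1)
  fib <- fiber_path(rbind(c(0.1, 0.4, 0.5), c(1.9, 0.6, 0.5)), 0.2, 3000)
  u <- runif(3 * nrow(mesh$nodes), -1, 1)
  K0 <- assemble(fe_model(mesh, pcu(), fibers = list(fib)))
  e0 <- as.numeric(u %*% (K0 %*% u))
  R <- random_rotation()
  mesh_r <- hex_mesh(mesh$nodes %*% t(R), mesh$elements)
  fib_r <- fiber_path(fib$points %*% t(R), fib$area, fib$E)
  ur <- as.numeric(R %*% matrix(u, 3))
  Kr <- assemble(fe_model(mesh_r, pcu(), fibers = list(fib_r)))
  er <- as.numeric(ur %*% (Kr %*% ur))
  expect_equal(er, e0, tolerance = 1e-8)
})
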