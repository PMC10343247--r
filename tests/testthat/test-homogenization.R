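test_that("assembly reduces to the element stiffness and blocks for disjoint parts", {
  mesh <- unit_cube()
  model <- fe_model(mesh, pcu())
  K <- as.matrix(assemble(model))
  conn <- mesh$elements[1, ]
  dofs <- as.integer(rbind(3 * conn - 2, 3 * conn - 1, 3 * conn))
  expect_equal(K[dofs, dofs],
               element_stiffness(mesh$nodes[conn, ], elastic_matrix(pcu())),
               tolerance = 1e-12)
  # two disconnected elements: 12 rigid modes
  nodes2 <- rbind(mesh$nodes, mesh$nodes + matrix(c(5, 0, 0), 8, 3, byrow = TRUE))
  mesh2 <- hex_mesh(nodes2, rbind(conn, conn + 8L))
  K2 <- as.matrix(assemble(fe_model(mesh2, pcu())))
  ev <- eigen(K2, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 12)
})

test_that("periodic homogenization recovers a homogeneous medium exactly", {
  model <- fe_model(box_mesh(0:3, 0:3, 0:3), pcu())
  h <- homogenize(model)
  expect_equal(h$constants$EL, 57, tolerance = 1e-3)
  expect_equal(h$constants$ET, 57, tolerance = 1e-3)
  expect_equal(h$constants$vLT, 0.43, tolerance = 1e-6)
  expect_equal(h$constants$GLT, shear_modulus(57, 0.43), tolerance = 1e-3)
})

test_that("macro-strain solves satisfy the affine and strain-average theorems", {
  model <- fe_model(box_mesh(0:2, 0:2, 0:2), pcu())
  K <- assemble(model)
  # zero macro strain: zero displacement
  u0 <- solve_macro_strain(model, rep(0, 6), K = K)
  expect_equal(max(abs(u0)), 0, tolerance = 1e-12)
  # homogeneous material: exact affine field for a mixed macro strain
  eps <- c(0.01, -0.004, 0.002, 0.006, -0.003, 0.008)
  u <- solve_macro_strain(model, eps, K = K)
  Emat <- braidfe:::voigt_to_tensor(eps)
  pin <- model$mesh$nodes[which.min(rowSums(model$mesh$nodes^2)), ]
  u_aff <- t(Emat %*% t(sweep(model$mesh$nodes, 2, pin)))
  expect_equal(u, as.numeric(t(u_aff)), tolerance = 1e-10)
  # volume-average strain equals the imposed macro strain
  expect_equal(average_strain(model, u), eps, tolerance = 1e-10)
  # and for a heterogeneous (fiber-reinforced) cell too
  fib <- fiber_path(rbind(c(0, 1, 1), c(2, 1, 1)), 0.5, 50000)
  mf <- fe_model(box_mesh(0:2, 0:2, 0:2), pcu(), fibers = list(fib))
  uf <- solve_macro_strain(mf, c(1, 0, 0, 0, 0, 0))
  expect_equal(average_strain(mf, uf), c(1, 0, 0, 0, 0, 0), tolerance = 1e-10)
})

test_that("non-periodic meshes are rejected with offender coordinates", {
  mesh <- box_mesh(0:1, 0:1, 0:1)
  mesh$nodes[2, 2] <- 0.31               # break the face-to-face match
  m <- hex_mesh(mesh$nodes, mesh$elements)
  expect_error(solve_macro_strain(fe_model(m, pcu()), c(1, 0, 0, 0, 0, 0)),
               "not periodic")
})

test_that("micro cell satisfies the Hill condition and symmetry diagnostics", {
  h <- homogenize_rvc(build_rvc("micro"), "embedded")
  expect_lt(h$asymmetry, 1e-6)
  # macro energy eps C eps equals volume-averaged micro energy per case
  for (j in 1:6) {
    expect_equal(h$case_energy[j], h$C[j, j], tolerance = 1e-6)
  }
  expect_equal(h$S %*% h$C, diag(6), tolerance = 1e-8)
})

test_that("micro-cell moduli respect mixture bounds and match the bridging axial modulus", {
  f <- kevlar(); m <- pcu()
  vf <- 0.70
  h <- homogenize_rvc(build_rvc("micro", params = bridging_params(vf)), "embedded")
  k <- h$constants
  # embedded-reinforcement convention: matrix fills the cell, fibers overlay,
  # so the Voigt cap uses the full matrix volume plus Vf of fiber
  for (mod in c(k$EL, k$ET, k$EZ)) {
    expect_gte(mod, m$E * 0.999)
    expect_lte(mod, vf * f$E11 + m$E + 1e-6)
  }
  for (g in c(k$GLT, k$GLZ, k$GTZ)) {
    expect_gte(g, m$G * 0.999)
    expect_lte(g, vf * f$G12 + m$G + 1e-6)
  }
  # cross-method consistency with the bridging model's axial modulus
  br <- bundle_constants(f, m, bridging_params(vf))
  expect_lt(abs(k$EL - br$E11) / br$E11, 0.015)
})

test_that("meso cells: bounds, interior ordering, and top/bottom mirror symmetry", {
  top <- homogenize_rvc(build_rvc("top"), "embedded")
  bot <- homogenize_rvc(build_rvc("bottom"), "embedded")
  int <- homogenize_rvc(build_rvc("interior"), "embedded")
  m <- pcu(); f <- kevlar()
  for (h in list(top, bot, int)) {
    for (mod in unlist(h$constants[c("EL", "ET", "EZ")])) {
      expect_gte(mod, m$E * 0.999)
      expect_lte(mod, 0.7 * f$E11 + m$E)
    }
  }
  # the interior cell's vertical interlock dominates the vertical stiffness
  expect_gt(int$constants$ET, 3 * top$constants$ET)
  expect_gt(int$constants$ET, 3 * bot$constants$ET)
  # bottom is the z-mirror of top: identical constants
  for (nm in names(top$constants)) {
    expect_equal(bot$constants[[nm]], top$constants[[nm]], tolerance = 1e-6)
  }
})

test_that("the multiscale chain matches the fiber-embedded pipeline on meso cells", {
  ch <- multiscale_chain(labels = "interior")
  emb <- homogenize_rvc(build_rvc("interior"), "embedded")
  for (nm in c("EL", "ET", "EZ", "GLT", "GLZ", "GTZ")) {
    expect_equal(ch$interior$constants[[nm]], emb$constants[[nm]],
                 tolerance = 0.05)
  }
  expect_lt(abs(ch$interior$constants$vLT - emb$constants$vLT), 0.05)
  # all-matrix chain: zero fiber content returns the matrix at every level
  m0 <- fe_model(build_rvc("top")$mesh, pcu())
  h0 <- homogenize(m0, axes = c(L = 1, T = 3, Z = 2))
  expect_equal(h0$constants$EL, 57, tolerance = 1e-3)
  expect_equal(h0$constants$ET, 57, tolerance = 1e-3)
})

test_that("bundle material extracted from the micro cell is transversely isotropic", {
  h <- homogenize_rvc(build_rvc("micro"), "embedded")
  b <- as_bundle_material(h)
  expect_equal(b$G23, b$E22 / (2 + 2 * b$v23))
  expect_equal(h$constants$ET, h$constants$EZ, tolerance = 1e-8)
  expect_equal(b$E11, h$constants$EL)
})
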