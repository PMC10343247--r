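test_that("shape functions interpolate and partition unity", {
  sf <- hex_shape_functions(c(0, 0, 0))
  expect_equal(sf$N, rep(1 / 8, 8))
  for (i in 1:8) {
    sfi <- hex_shape_functions(braidfe:::HEX_CORNERS[i, ])
    expect_equal(sfi$N, as.numeric(seq_len(8) == i))
  }
  set.seed(7)
  for (r in 1:10) {
    xi <- runif(3, -1.4, 1.4)   # outside the cube is allowed for searches
    sf <- hex_shape_functions(xi)
    expect_equal(sum(sf$N), 1, tolerance = 1e-15)
    expect_equal(colSums(sf$dN), c(0, 0, 0), tolerance = 1e-15)
  }
})

test_that("strain matrix maps displacements to engineering strain", {
  xc <- cube_coords()
  sm <- strain_matrix(xc, c(0.3, -0.2, 0.5))
  expect_equal(sm$detJ, 1 / 8)                 # affine unit cube
  # rigid translation is strain-free
  u_rigid <- rep(c(0.3, -1.2, 0.7), 8)
  expect_equal(as.numeric(sm$B %*% u_rigid), rep(0, 6), tolerance = 1e-14)
  # uniform stretch u = x e_x
  u_str <- rep(0, 24); u_str[seq(1, 24, 3)] <- xc[, 1]
  expect_equal(as.numeric(sm$B %*% u_str), c(1, 0, 0, 0, 0, 0), tolerance = 1e-13)
  # inverted element reports its degeneracy
  bad <- xc; bad[, 1] <- -bad[, 1]
  expect_error(strain_matrix(bad, c(0, 0, 0)), "Jacobian")
})

test_that("isotropic elastic matrix has the closed-form entries", {
  expect_equal(elastic_matrix(isotropic_material(1, 0)),
               diag(c(1, 1, 1, 0.5, 0.5, 0.5)))
  D <- elastic_matrix(pcu())
  expect_equal(D[1, 1], 57 * 0.57 / (1.43 * 0.14))   # 162.29 MPa
  expect_equal(D, t(D))
  expect_gt(min(eigen(D, symmetric = TRUE, only.values = TRUE)$values), 0)
  # uniaxial strain: sigma_y / sigma_x = v / (1 - v)
  s <- D %*% c(1, 0, 0, 0, 0, 0)
  expect_equal(s[2] / s[1], 0.43 / 0.57)
  expect_error(elastic_matrix(isotropic_material(1, 0.5 - 1e-13)), "incompressible")
  # matches the inverse-compliance route
  expect_equal(D, stiffness_matrix(pcu()), tolerance = 1e-12)
})

test_that("element stiffness is symmetric with six rigid modes and zero row sums", {
  set.seed(11)
  xc <- cube_coords() + matrix(runif(24, -0.08, 0.08), 8, 3)
  k <- element_stiffness(xc, elastic_matrix(pcu()))
  expect_equal(k, t(k))
  ev <- eigen(k, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6)
  expect_gt(min(ev), -1e-10 * max(ev))
  expect_lt(max(abs(rowSums(k))), 1e-8 * max(abs(k)))
})

test_that("element energy is invariant under rigid rotation of geometry and loads", {
  set.seed(3)
  xc <- cube_coords() + matrix(runif(24, -0.05, 0.05), 8, 3)
  D <- elastic_matrix(pcu())
  u <- runif(24, -1, 1)
  e0 <- quad_energy(element_stiffness(xc, D), u)
  for (r in 1:3) {
    R <- random_rotation()
    xr <- xc %*% t(R)
    ur <- as.numeric(R %*% matrix(u, 3, 8))
    er <- quad_energy(element_stiffness(xr, D), ur)
    expect_equal(er, e0, tolerance = 1e-10)
  }
})

test_that("a distorted patch reproduces a linear displacement field exactly", {
  mesh <- distorted_cube_mesh()
  model <- fe_model(mesh, pcu())
  K <- assemble(model)
  A <- matrix(c(0.01, 0.004, -0.002,
                0.003, -0.008, 0.005,
                -0.001, 0.002, 0.006), 3, 3, byrow = TRUE)
  u_exact <- as.numeric(t(mesh$nodes %*% t(A)))
  on_bnd <- apply(mesh$nodes, 1, function(p) any(abs(p) < 1e-12 | abs(p - 2) < 1e-12))
  fixed <- as.integer(outer(1:3, which(on_bnd), function(a, n) 3 * (n - 1) + a))
  free <- setdiff(seq_len(model$n_dof), fixed)
  u <- u_exact
  u[free] <- as.numeric(Matrix::solve(K[free, free], -K[free, fixed] %*% u_exact[fixed]))
  expect_lt(max(abs(u - u_exact)), 1e-9)
})

test_that("mesh refinement is consistent on affine elements", {
  # 2x1x1 two-element bar vs a single 2-long element under an end load
  D <- elastic_matrix(isotropic_material(10, 0))
  tip <- function(mesh) {
    model <- fe_model(mesh, isotropic_material(10, 0))
    K <- assemble(model)
    fixed_nodes <- which(mesh$nodes[, 1] < 1e-12)
    fixed <- as.integer(outer(1:3, fixed_nodes, function(a, n) 3 * (n - 1) + a))
    free <- setdiff(seq_len(model$n_dof), fixed)
    end_nodes <- which(mesh$nodes[, 1] > max(mesh$nodes[, 1]) - 1e-12)
    f <- numeric(model$n_dof)
    f[3 * (end_nodes - 1) + 1] <- 1 / length(end_nodes)
    u <- numeric(model$n_dof)
    u[free] <- as.numeric(Matrix::solve(K[free, free], f[free]))
    max(u[3 * (end_nodes - 1) + 1])
  }
  u2 <- tip(box_mesh(c(0, 1, 2), 0:1, 0:1))
  u1 <- tip(box_mesh(c(0, 2), 0:1, 0:1))
  expect_equal(u2, u1, tolerance = 1e-10)
  expect_equal(u1, 2 / 10, tolerance = 1e-10)   # PL/EA
})

test_that("mesh constructors validate connectivity and duplicates", {
  expect_error(hex_mesh(cube_coords(), matrix(c(1:7, 99), 1)), "out of range")
  nodes <- rbind(cube_coords(), cube_coords()[1, ] + 1e-12)
  expect_error(hex_mesh(nodes, matrix(1:8, 1)), "duplicate")
  m <- box_mesh(c(0, 0.5, 1), 0:1, 0:1)
  expect_equal(nrow(m$elements), 2)
  expect_equal(mesh_bbox(m), rbind(c(0, 0, 0), c(1, 1, 1)))
})
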