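# Global assembly, periodic boundary conditions and RVC homogenization.
#
# Periodic constraints are imposed by master-slave elimination: every node on
# a periodic max-face is tied to its image on the min-face, with the
# displacement difference fixed to macro-strain times the face offset.  The
# constraints are satisfied exactly and the reduced system stays symmetric
# positive definite once one master corner is pinned.

#' Finite-element model
#'
#' Bundles a mesh, per-element constitutive matrices and embedded fibers into
#' one object ready for assembly.
#'
#' @param mesh A `hex_mesh`.
#' @param material Default material for all elements (`elastic_material`).
#' @param fibers List of [fiber_path()] objects to embed (segmented here).
#' @param element_D Optional list (length = number of elements) of 6x6
#'   constitutive matrices overriding `material` per element.
#' @return Object of class `fe_model`.
#' @export
fe_model <- function(mesh, material, fibers = list(), element_D = NULL) {
  stopifnot(inherits(mesh, "hex_mesh"))
  m <- nrow(mesh$elements)
  D0 <- if (inherits(material, "isotropic_material")) {
    elastic_matrix(material)
  } else {
    stiffness_matrix(material)
  }
  if (!is.null(element_D)) stopifnot(length(element_D) == m)
  segs <- list()
  for (p in fibers) segs <- c(segs, segment_fibers(mesh, p))
  seg_by_elem <- split(segs, vapply(segs, `[[`, 1L, "element"))
  vol <- 0
  for (e in seq_len(m)) {
    vol <- vol + element_volume(mesh$nodes[mesh$elements[e, ], , drop = FALSE])
  }
  structure(list(mesh = mesh, D0 = D0, element_D = element_D,
                 segments = segs, seg_by_elem = seg_by_elem,
                 volume = vol, n_dof = 3L * nrow(mesh$nodes)),
            class = "fe_model")
}

element_D_of <- function(model, e) {
  if (is.null(model$element_D)) model$D0 else model$element_D[[e]]
}

#' Assemble the global sparse stiffness matrix
#'
#' Element matrices (matrix stiffness plus superposed embedded-fiber
#' contributions) are accumulated into a symmetric sparse matrix.  Before any
#' constraints the matrix has exactly six rigid-body modes per connected
#' component.
#'
#' @param model An [fe_model()].
#' @return Sparse symmetric `n_dof` x `n_dof` stiffness (N/mm).
#' @export
assemble <- function(model) {
  mesh <- model$mesh
  m <- nrow(mesh$elements)
  nt <- 576L * m
  ii <- integer(nt); jj <- integer(nt); xx <- numeric(nt)
  pos <- 0L
  for (e in seq_len(m)) {
    conn <- mesh$elements[e, ]
    coords <- mesh$nodes[conn, , drop = FALSE]
    k <- element_stiffness(coords, element_D_of(model, e))
    fs <- model$seg_by_elem[[as.character(e)]]
    if (!is.null(fs)) {
      k <- superpose(k, lapply(fs, function(s) fiber_stiffness(coords, s)))
    }
    dofs <- as.integer(rbind(3L * conn - 2L, 3L * conn - 1L, 3L * conn))
    idx <- pos + seq_len(576L)
    ii[idx] <- rep(dofs, times = 24L)
    jj[idx] <- rep(dofs, each = 24L)
    xx[idx] <- as.numeric(k)
    pos <- pos + 576L
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(model$n_dof, model$n_dof))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

# Map every node to its canonical periodic master (all periodic coordinates
# folded to the min face) and record the offset to the master.
periodic_map <- function(mesh, periodic = c(TRUE, TRUE, TRUE), tol = 1e-8) {
  nodes <- mesh$nodes
  bb <- mesh_bbox(mesh)
  folded <- nodes
  for (a in 1:3) {
    if (!periodic[a]) next
    on_max <- abs(nodes[, a] - bb[2, a]) < tol
    folded[on_max, a] <- bb[1, a]
  }
  key <- function(x) apply(round(x / (10 * tol)), 1, paste, collapse = ",")
  master <- match(key(folded), key(nodes))
  if (anyNA(master)) {
    bad <- which(is.na(master))
    stop("mesh is not periodic: no image node for node(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " at coordinates ",
         paste(apply(nodes[utils::head(bad, 5), , drop = FALSE], 1,
                     function(r) sprintf("(%g,%g,%g)", r[1], r[2], r[3])),
               collapse = " "))
  }
  list(master = master, offset = nodes - nodes[master, , drop = FALSE])
}

voigt_to_tensor <- function(eps) {
  matrix(c(eps[1], eps[6] / 2, eps[5] / 2,
           eps[6] / 2, eps[2], eps[4] / 2,
           eps[5] / 2, eps[4] / 2, eps[3]), 3, 3)
}

#' Solve a unit-cell problem under an imposed macroscopic strain
#'
#' Applies periodic tie constraints (`u_slave = u_master + eps_bar . dx`),
#' pins one master corner against rigid translation, and solves.  The
#' returned vector is the total displacement field (macroscopic part
#' included).
#'
#' @param model An [fe_model()].
#' @param macro_strain Length-6 macroscopic strain, Voigt order
#'   (x, y, z, yz, zx, xy) with engineering shears.
#' @param K Optional pre-assembled stiffness from [assemble()].
#' @param periodic Logical length 3: which axes are periodic.
#' @return Numeric displacement vector of length `n_dof` (mm).
#' @export
solve_macro_strain <- function(model, macro_strain, K = NULL,
                               periodic = c(TRUE, TRUE, TRUE)) {
  if (is.null(K)) K <- assemble(model)
  mesh <- model$mesh
  n <- nrow(mesh$nodes)
  pm <- periodic_map(mesh, periodic)
  E <- voigt_to_tensor(macro_strain)
  g_nodes <- pm$offset %*% t(E)
  g <- as.numeric(t(g_nodes))                       # dof-ordered (x1,y1,z1,...)

  masters <- sort(unique(pm$master))
  # pin the master closest to the min corner
  bbmin <- mesh_bbox(mesh)[1, ]
  d2 <- rowSums((mesh$nodes[masters, , drop = FALSE] -
                 matrix(bbmin, length(masters), 3, byrow = TRUE))^2)
  pin <- masters[which.min(d2)]
  free_cols <- setdiff(masters, pin)
  col_of <- integer(n); col_of[free_cols] <- seq_along(free_cols)

  keep <- col_of[pm$master] > 0L                    # nodes whose master is free
  rows <- rep(3L * (seq_len(n) - 1L), each = 3L) + rep(1:3, n)
  cols <- rep(3L * (col_of[pm$master] - 1L), each = 3L) + rep(1:3, n)
  mask <- rep(keep, each = 3L)
  T_ <- Matrix::sparseMatrix(i = rows[mask], j = cols[mask], x = 1,
                             dims = c(3L * n, 3L * length(free_cols)))
  Kr <- Matrix::forceSymmetric(Matrix::crossprod(T_, K %*% T_))
  fr <- -as.numeric(Matrix::crossprod(T_, K %*% g))
  ur <- tryCatch(as.numeric(Matrix::solve(Kr, fr)),
                 error = function(e) stop("periodic unit-cell solve failed: ",
                                          conditionMessage(e)))
  as.numeric(T_ %*% ur) + g
}

#' Volume-averaged stress of a displacement field
#'
#' Gauss-point average of the matrix stress plus the axial stress carried by
#' embedded fiber segments, divided by the cell volume.
#'
#' @param model An [fe_model()].
#' @param u Displacement vector from [solve_macro_strain()].
#' @return Length-6 stress in Voigt order (MPa).
#' @export
average_stress <- function(model, u) {
  mesh <- model$mesh
  q <- gauss_rule(2)
  s_tot <- numeric(6)
  for (e in seq_len(nrow(mesh$elements))) {
    conn <- mesh$elements[e, ]
    coords <- mesh$nodes[conn, , drop = FALSE]
    dofs <- as.integer(rbind(3L * conn - 2L, 3L * conn - 1L, 3L * conn))
    ue <- u[dofs]
    D <- element_D_of(model, e)
    for (g in seq_along(q$weights)) {
      sm <- strain_matrix(coords, q$points[g, ])
      s_tot <- s_tot + as.numeric(D %*% (sm$B %*% ue)) * sm$detJ * q$weights[g]
    }
    fs <- model$seg_by_elem[[as.character(e)]]
    if (!is.null(fs)) {
      for (s in fs) {
        for (gp in c(-1, 1) / sqrt(3)) {
          fk <- fiber_kinematics(coords, s$xi_m, s$xi_n, gp)
          d <- fk$cosines
          tv <- c(d[1]^2, d[2]^2, d[3]^2, d[2] * d[3], d[3] * d[1], d[1] * d[2])
          eps_p <- sum((tv %*% fk$B) * ue)
          s_tot <- s_tot + s$E * s$area * eps_p * fk$h * tv
        }
      }
    }
  }
  s_tot / model$volume
}

#' Volume-averaged strain of a displacement field
#'
#' @inheritParams average_stress
#' @return Length-6 strain in Voigt order (engineering shears).
#' @export
average_strain <- function(model, u) {
  mesh <- model$mesh
  q <- gauss_rule(2)
  e_tot <- numeric(6)
  for (e in seq_len(nrow(mesh$elements))) {
    conn <- mesh$elements[e, ]
    coords <- mesh$nodes[conn, , drop = FALSE]
    dofs <- as.integer(rbind(3L * conn - 2L, 3L * conn - 1L, 3L * conn))
    ue <- u[dofs]
    for (g in seq_along(q$weights)) {
      sm <- strain_matrix(coords, q$points[g, ])
      e_tot <- e_tot + as.numeric(sm$B %*% ue) * sm$detJ * q$weights[g]
    }
  }
  e_tot / model$volume
}

#' Homogenize a unit-cell model
#'
#' Solves the six unit macroscopic strain cases under periodic boundary
#' conditions; column j of the effective stiffness is the volume-averaged
#' stress under unit strain j.  The raw stiffness must be symmetric to
#' `sym_tol` (relative) and is then symmetrized.
#'
#' @param model An [fe_model()].
#' @param axes Axis-role map passed to [engineering_constants()].
#' @param periodic Logical length 3.
#' @param label Name carried into the result.
#' @param sym_tol Maximum tolerated relative asymmetry of the raw stiffness.
#' @return Object of class `homogenized_elasticity` with the 6x6 stiffness
#'   `C` (MPa), compliance `S`, engineering `constants`, and diagnostics.
#' @export
homogenize <- function(model, axes = c(L = 1, T = 2, Z = 3),
                       periodic = c(TRUE, TRUE, TRUE), label = "cell",
                       sym_tol = 1e-6) {
  K <- assemble(model)
  C <- matrix(0, 6, 6)
  energies <- numeric(6)
  for (j in 1:6) {
    eps <- numeric(6); eps[j] <- 1
    u <- solve_macro_strain(model, eps, K = K, periodic = periodic)
    C[, j] <- average_stress(model, u)
    energies[j] <- as.numeric(u %*% (K %*% u)) / model$volume
  }
  asym <- max(abs(C - t(C))) / max(abs(C))
  if (asym > sym_tol) {
    stop("homogenized stiffness asymmetric beyond tolerance: relative asymmetry ",
         signif(asym, 3))
  }
  C <- (C + t(C)) / 2
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    stop("homogenized stiffness not positive definite; eigenvalues: ",
         paste(signif(ev, 4), collapse = ", "))
  }
  S <- solve(C)
  structure(list(C = C, S = S,
                 constants = engineering_constants(S, axes),
                 axes = axes, label = label, asymmetry = asym,
                 case_energy = energies),
            class = "homogenized_elasticity")
}

#' @export
print.homogenized_elasticity <- function(x, ...) {
  cat(sprintf("<homogenized elasticity '%s'> (GPa)\n", x$label))
  k <- x$constants
  cat(sprintf("  EL=%.4g ET=%.4g EZ=%.4g vLT=%.3g GLT=%.4g GLZ=%.4g GTZ=%.4g\n",
              k$EL / 1000, k$ET / 1000, k$EZ / 1000, k$vLT,
              k$GLT / 1000, k$GLZ / 1000, k$GTZ / 1000))
  invisible(x)
}

#' Transversely isotropic material from a homogenized cell
#'
#' Reads the fiber-axis constants from the homogenized compliance (fiber axis
#' assumed along x) and enforces the transverse-isotropy identity for `v23`.
#'
#' @param h A `homogenized_elasticity`.
#' @param name Material label.
#' @return A `trans_iso_material`.
#' @export
as_bundle_material <- function(h, name = "homogenized bundle") {
  S <- h$S
  E11 <- 1 / S[1, 1]; E22 <- 1 / S[2, 2]
  G12 <- 1 / S[6, 6]; G23 <- 1 / S[4, 4]
  trans_iso_material(E11 = E11, E22 = E22, v12 = -S[2, 1] * E11,
                     v23 = E22 / (2 * G23) - 1, G12 = G12, G23 = G23,
                     name = name)
}
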