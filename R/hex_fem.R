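# Eight-node isoparametric hexahedral element kernel.
#
# Node ordering follows the standard counter-clockwise bottom face then top
# face convention; natural coordinates of the corners are the rows of
# HEX_CORNERS.  Strain Voigt order is (ex, ey, ez, gyz, gzx, gxy) with
# engineering shears.

HEX_CORNERS <- rbind(
  c(-1, -1, -1), c(1, -1, -1), c(1, 1, -1), c(-1, 1, -1),
  c(-1, -1,  1), c(1, -1,  1), c(1, 1,  1), c(-1, 1,  1))

#' Trilinear shape functions of the 8-node hexahedron
#'
#' @param xi Numeric length-3 natural coordinates (xi, eta, zeta); values
#'   outside `[-1,1]^3` are permitted (used by embedding searches).
#' @return List with `N` (length 8, sums to 1) and `dN` (8x3 gradients with
#'   respect to the natural coordinates; columns sum to 0).
#' @export
hex_shape_functions <- function(xi) {
  stopifnot(length(xi) == 3)
  a <- 1 + HEX_CORNERS[, 1] * xi[1]
  b <- 1 + HEX_CORNERS[, 2] * xi[2]
  c_ <- 1 + HEX_CORNERS[, 3] * xi[3]
  N <- a * b * c_ / 8
  dN <- cbind(HEX_CORNERS[, 1] * b * c_,
              a * HEX_CORNERS[, 2] * c_,
              a * b * HEX_CORNERS[, 3]) / 8
  list(N = N, dN = dN)
}

#' Tensor-product Gauss rule on the parent cube
#'
#' @param n Points per direction (1 or 2; default 2, exact for affine
#'   elements).
#' @return List with `points` (n^3 x 3) and `weights` (sum to 8).
#' @export
gauss_rule <- function(n = 2) {
  g1 <- switch(as.character(n),
               "1" = list(x = 0, w = 2),
               "2" = list(x = c(-1, 1) / sqrt(3), w = c(1, 1)),
               stop("only 1- and 2-point rules are provided"))
  pts <- as.matrix(expand.grid(g1$x, g1$x, g1$x))
  colnames(pts) <- NULL
  w <- apply(as.matrix(expand.grid(g1$w, g1$w, g1$w)), 1, prod)
  list(points = pts, weights = w)
}

#' Strain-displacement matrix of a hexahedral element
#'
#' @param coords 8x3 matrix of element node coordinates (mm).
#' @param xi Natural coordinates of the evaluation point.
#' @return List with `B` (6x24), `detJ` (Jacobian determinant, parent-to-
#'   physical), `J` (3x3 Jacobian, rows d/dxi of x) and `dNdx` (8x3).
#' @export
strain_matrix <- function(coords, xi) {
  sf <- hex_shape_functions(xi)
  J <- t(sf$dN) %*% coords              # J[a, b] = d x_b / d xi_a
  detJ <- det(J)
  if (!is.finite(detJ) || detJ <= 0) {
    stop("non-positive Jacobian determinant (", signif(detJ, 4),
         "): inverted or degenerate element")
  }
  dNdx <- sf$dN %*% t(solve(J))         # d N_i / d x_b
  B <- matrix(0, 6, 24)
  ix <- seq(1, 24, by = 3)
  B[1, ix]     <- dNdx[, 1]
  B[2, ix + 1] <- dNdx[, 2]
  B[3, ix + 2] <- dNdx[, 3]
  B[4, ix + 1] <- dNdx[, 3]; B[4, ix + 2] <- dNdx[, 2]   # gyz
  B[5, ix]     <- dNdx[, 3]; B[5, ix + 2] <- dNdx[, 1]   # gzx
  B[6, ix]     <- dNdx[, 2]; B[6, ix + 1] <- dNdx[, 1]   # gxy
  list(B = B, detJ = detJ, J = J, dNdx = dNdx)
}

#' Isotropic elastic matrix
#'
#' The 6x6 constitutive matrix of an isotropic solid,
#' `D = E(1-v)/((1+v)(1-2v))` times the unit pattern with off-diagonal
#' `v/(1-v)` and shear diagonal `(1-2v)/(2(1-v))`.
#'
#' @param mat An `isotropic_material`.
#' @return 6x6 symmetric positive definite matrix (MPa).
#' @export
elastic_matrix <- function(mat) {
  stopifnot(inherits(mat, "isotropic_material"))
  v <- mat$v
  if (abs(v - 0.5) < 1e-12) stop("v = 0.5: incompressible material, singular elastic matrix")
  f <- mat$E * (1 - v) / ((1 + v) * (1 - 2 * v))
  D <- diag(6)
  D[1:3, 1:3][diag(3) == 0] <- v / (1 - v)
  diag(D)[4:6] <- (1 - 2 * v) / (2 * (1 - v))
  f * D
}

#' Element stiffness of an 8-node hexahedron
#'
#' Full 2x2x2 Gauss integration of `t(B) D B |J|`.
#'
#' @param coords 8x3 node coordinates (mm).
#' @param D 6x6 constitutive matrix (MPa), e.g. from [elastic_matrix()] or
#'   [stiffness_matrix()].
#' @return 24x24 symmetric positive semi-definite stiffness (N/mm).
#' @export
element_stiffness <- function(coords, D) {
  q <- gauss_rule(2)
  k <- matrix(0, 24, 24)
  for (g in seq_along(q$weights)) {
    sm <- strain_matrix(coords, q$points[g, ])
    k <- k + crossprod(sm$B, D %*% sm$B) * (sm$detJ * q$weights[g])
  }
  (k + t(k)) / 2
}

#' Hexahedral mesh
#'
#' @param nodes n x 3 matrix of node coordinates (mm).
#' @param elements m x 8 integer matrix of 1-based connectivity in the
#'   standard bottom-then-top corner order.
#' @param validate Check connectivity, duplicate nodes and Jacobians.
#' @return Object of class `hex_mesh` with fields `nodes`, `elements`.
#' @export
hex_mesh <- function(nodes, elements, validate = TRUE) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  elements <- as.matrix(elements); storage.mode(elements) <- "integer"
  stopifnot(ncol(nodes) == 3, ncol(elements) == 8)
  m <- structure(list(nodes = nodes, elements = elements),
                 class = "hex_mesh")
  if (validate) {
    if (min(elements) < 1 || max(elements) > nrow(nodes)) {
      stop("connectivity indices out of range")
    }
    key <- apply(round(nodes / 1e-9), 1, paste, collapse = ",")
    if (anyDuplicated(key)) stop("duplicate nodes within 1e-9 mm")
    q <- gauss_rule(2)
    for (e in seq_len(nrow(elements))) {
      xc <- nodes[elements[e, ], , drop = FALSE]
      for (g in seq_along(q$weights)) {
        sf <- hex_shape_functions(q$points[g, ])
        if (det(t(sf$dN) %*% xc) <= 0) {
          stop("element ", e, " has non-positive Jacobian at a quadrature point")
        }
      }
    }
  }
  m
}

#' @export
print.hex_mesh <- function(x, ...) {
  bb <- apply(x$nodes, 2, range)
  cat(sprintf("<hex_mesh> %d nodes, %d elements, bbox %s mm\n",
              nrow(x$nodes), nrow(x$elements),
              paste(sprintf("%.3g", bb[2, ] - bb[1, ]), collapse = " x ")))
  invisible(x)
}

#' Structured hexahedral grid from a coordinate mapping
#'
#' Builds an (nx x ny x nz)-element mesh on the unit parameter cube and maps
#' node parameters through `map`, merging coincident mapped nodes.
#'
#' @param nx,ny,nz Element counts per parametric direction.
#' @param map Function taking an n x 3 matrix of parameters in `[0,1]^3` and
#'   returning n x 3 physical coordinates; default identity (unit cube).
#' @param validate Passed to [hex_mesh()].
#' @return A `hex_mesh`.
#' @export
grid_mesh <- function(nx, ny, nz, map = NULL, validate = TRUE) {
  u <- seq(0, 1, length.out = nx + 1)
  v <- seq(0, 1, length.out = ny + 1)
  w <- seq(0, 1, length.out = nz + 1)
  par3 <- as.matrix(expand.grid(u = u, v = v, w = w))
  xyz <- if (is.null(map)) par3 else map(par3)
  key <- apply(round(xyz / 1e-9), 1, paste, collapse = ",")
  uniq <- !duplicated(key)
  remap <- match(key, key[uniq])
  nodes <- xyz[uniq, , drop = FALSE]
  idx <- function(i, j, k) i + (nx + 1) * ((j - 1) + (ny + 1) * (k - 1))
  elems <- matrix(0L, nx * ny * nz, 8)
  e <- 0L
  for (k in seq_len(nz)) for (j in seq_len(ny)) for (i in seq_len(nx)) {
    e <- e + 1L
    elems[e, ] <- remap[c(idx(i, j, k),     idx(i + 1, j, k),
                          idx(i + 1, j + 1, k), idx(i, j + 1, k),
                          idx(i, j, k + 1), idx(i + 1, j, k + 1),
                          idx(i + 1, j + 1, k + 1), idx(i, j + 1, k + 1))]
  }
  hex_mesh(nodes, elems, validate = validate)
}

#' Structured grid between coordinate break points
#'
#' Convenience wrapper over [grid_mesh()] for axis-aligned boxes with given
#' node positions along each axis.
#'
#' @param xb,yb,zb Increasing break-point vectors (mm).
#' @return A `hex_mesh` covering `[min, max]` of each axis.
#' @export
box_mesh <- function(xb, yb, zb) {
  stopifnot(all(diff(xb) > 0), all(diff(yb) > 0), all(diff(zb) > 0))
  interp <- function(t, brk) {
    s <- t * (length(brk) - 1)
    i <- pmin(floor(s), length(brk) - 2)
    brk[i + 1] + (s - i) * (brk[i + 2] - brk[i + 1])
  }
  grid_mesh(length(xb) - 1, length(yb) - 1, length(zb) - 1,
            map = function(p) cbind(interp(p[, 1], xb),
                                    interp(p[, 2], yb),
                                    interp(p[, 3], zb)))
}

#' Bounding box of a mesh
#' @param mesh A `hex_mesh`.
#' @return 2x3 matrix, rows min and max (mm).
#' @export
mesh_bbox <- function(mesh) apply(mesh$nodes, 2, range)

# Volume of one element by 2x2x2 quadrature.
element_volume <- function(coords) {
  q <- gauss_rule(2)
  v <- 0
  for (g in seq_along(q$weights)) {
    sf <- hex_shape_functions(q$points[g, ])
    v <- v + det(t(sf$dN) %*% coords) * q$weights[g]
  }
  v
}
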