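#' @importFrom stats uniroot
#' @importFrom utils modifyList
NULL

# Internal unit system is N / mm / MPa.  GPa is accepted only at config
# boundaries and converted on read.  Voigt order throughout the package is
# (x, y, z, yz, zx, xy) with engineering shear strains.

#' Shear modulus of an isotropic solid
#'
#' @param E Young's modulus (MPa).
#' @param v Poisson's ratio; must lie in (-1, 0.5).
#' @return Shear modulus `0.5 * E / (1 + v)` (MPa).
#' @export
#' @examples
#' shear_modulus(57, 0.43)
shear_modulus <- function(E, v) {
  stopifnot(is.numeric(E), is.numeric(v))
  if (any(E <= 0)) stop("Young's modulus must be positive")
  if (any(v <= -1 | v >= 0.5)) {
    stop("Poisson's ratio must lie in (-1, 0.5); got ", paste(v, collapse = ", "))
  }
  0.5 * E / (1 + v)
}

#' Isotropic elastic material
#'
#' @param E Young's modulus (MPa).
#' @param v Poisson's ratio in (-1, 0.5).
#' @param name Optional label.
#' @return Object of class `isotropic_material` with fields `E`, `v` and the
#'   derived shear modulus `G`.
#' @export
#' @examples
#' pcu <- isotropic_material(E = 57, v = 0.43, name = "PCU")
isotropic_material <- function(E, v, name = "isotropic") {
  G <- shear_modulus(E, v)
  structure(list(E = E, v = v, G = G, name = name),
            class = c("isotropic_material", "elastic_material"))
}

#' Transversely isotropic elastic material
#'
#' The distinguished (fiber) axis is the local x axis.  The three transverse
#' constants are tied by the in-plane isotropy identity
#' `G23 = E22 / (2 + 2 * v23)`; `G23` may be omitted and is then derived, or
#' supplied and checked.
#'
#' @param E11 Axial Young's modulus (MPa).
#' @param E22 Transverse Young's modulus (MPa).
#' @param v12 Axial Poisson's ratio.
#' @param v23 Transverse Poisson's ratio.
#' @param G12 Axial shear modulus (MPa).
#' @param G23 Transverse shear modulus (MPa); derived from `E22`, `v23` when `NULL`.
#' @param name Optional label.
#' @return Object of class `trans_iso_material`.
#' @export
#' @examples
#' kevlar <- trans_iso_material(E11 = 128700, E22 = 12870, v12 = 0.3,
#'                              v23 = -0.5, G12 = 12870, name = "Kevlar")
trans_iso_material <- function(E11, E22, v12, v23, G12, G23 = NULL,
                               name = "transversely isotropic") {
  stopifnot(E11 > 0, E22 > 0, G12 > 0)
  if (v23 <= -1 || v23 >= 1) stop("v23 out of range (-1, 1)")
  G23_derived <- E22 / (2 + 2 * v23)
  if (is.null(G23)) {
    G23 <- G23_derived
  } else if (abs(G23 - G23_derived) > 1e-9 * abs(G23)) {
    stop("G23 inconsistent with E22/(2+2*v23): ", G23, " vs ", G23_derived)
  }
  if (G23 <= 0) stop("transverse shear modulus must be positive")
  structure(list(E11 = E11, E22 = E22, v12 = v12, v23 = v23,
                 G12 = G12, G23 = G23, name = name),
            class = c("trans_iso_material", "elastic_material"))
}

#' @export
print.isotropic_material <- function(x, ...) {
  cat(sprintf("<isotropic material '%s'>  E = %g MPa, v = %g, G = %g MPa\n",
              x$name, x$E, x$v, x$G))
  invisible(x)
}

#' @export
print.trans_iso_material <- function(x, ...) {
  cat(sprintf(paste0("<transversely isotropic material '%s'>\n",
                     "  E11 = %g  E22 = %g  G12 = %g  G23 = %g MPa\n",
                     "  v12 = %g  v23 = %g\n"),
              x$name, x$E11, x$E22, x$G12, x$G23, x$v12, x$v23))
  invisible(x)
}

#' Compliance matrix of a material
#'
#' Returns the 6x6 compliance in Voigt order (x, y, z, yz, zx, xy) with
#' engineering shear strains; for transversely isotropic materials the fiber
#' axis is x.
#'
#' @param mat An `elastic_material`.
#' @return 6x6 numeric matrix (1/MPa).
#' @export
compliance_matrix <- function(mat) UseMethod("compliance_matrix")

#' @export
compliance_matrix.isotropic_material <- function(mat) {
  S <- matrix(0, 6, 6)
  S[1:3, 1:3] <- -mat$v / mat$E
  diag(S)[1:3] <- 1 / mat$E
  diag(S)[4:6] <- 1 / mat$G
  S
}

#' @export
compliance_matrix.trans_iso_material <- function(mat) {
  S <- matrix(0, 6, 6)
  S[1, 1] <- 1 / mat$E11
  S[1, 2] <- S[1, 3] <- S[2, 1] <- S[3, 1] <- -mat$v12 / mat$E11
  S[2, 2] <- S[3, 3] <- 1 / mat$E22
  S[2, 3] <- S[3, 2] <- -mat$v23 / mat$E22
  S[4, 4] <- 1 / mat$G23
  S[5, 5] <- S[6, 6] <- 1 / mat$G12
  S
}

#' Stiffness matrix of a material
#'
#' Inverse of [compliance_matrix()], optionally rotated so that the material
#' (fiber) axis aligns with a given direction.
#'
#' @param mat An `elastic_material`.
#' @param axis Unit direction for the material x axis, default `c(1, 0, 0)`.
#' @return 6x6 stiffness matrix (MPa).
#' @export
stiffness_matrix <- function(mat, axis = c(1, 0, 0)) {
  C <- solve(compliance_matrix(mat))
  axis <- axis / sqrt(sum(axis^2))
  if (all(abs(axis - c(1, 0, 0)) < 1e-12)) return(C)
  rotate_stiffness(C, rotation_to_axis(axis))
}

# Rotation taking the global x axis onto `axis` (any orthonormal completion).
rotation_to_axis <- function(axis) {
  a <- axis / sqrt(sum(axis^2))
  helper <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b <- helper - sum(helper * a) * a
  b <- b / sqrt(sum(b^2))
  cb <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  cbind(a, b, cb, deparse.level = 0)
}

# Bond stress-transformation matrix for Voigt order (x,y,z,yz,zx,xy).
bond_matrix <- function(R) {
  i1 <- c(1, 2, 3); p <- rbind(c(2, 3), c(3, 1), c(1, 2))
  M <- matrix(0, 6, 6)
  M[1:3, 1:3] <- R[i1, i1]^2
  for (r in 1:3) for (s in 1:3) {
    M[r, 3 + s] <- 2 * R[r, p[s, 1]] * R[r, p[s, 2]]
  }
  for (r in 1:3) for (s in 1:3) {
    M[3 + r, s] <- R[p[r, 1], s] * R[p[r, 2], s]
  }
  for (r in 1:3) for (s in 1:3) {
    M[3 + r, 3 + s] <- R[p[r, 1], p[s, 1]] * R[p[r, 2], p[s, 2]] +
      R[p[r, 1], p[s, 2]] * R[p[r, 2], p[s, 1]]
  }
  M
}

#' Rotate a 6x6 stiffness matrix
#'
#' @param C 6x6 stiffness in Voigt order (x,y,z,yz,zx,xy).
#' @param R 3x3 rotation matrix whose columns are the material axes expressed
#'   in global coordinates.
#' @return Rotated 6x6 stiffness.
#' @export
rotate_stiffness <- function(C, R) {
  M <- bond_matrix(R)
  M %*% C %*% t(M)
}

#' Engineering constants from a 6x6 compliance matrix
#'
#' Extracts the seven constants reported for fiber bundles and representative
#' volume cells.  `axes` names which coordinate direction plays the roles of
#' the longitudinal (L), transverse (T) and through-width (Z) axes.
#'
#' @param S 6x6 compliance matrix, Voigt order (x,y,z,yz,zx,xy).
#' @param axes Integer vector `c(L =, T =, Z =)` mapping labels to axes 1:3.
#' @return Named list `EL, ET, EZ, vLT, GLT, GLZ, GTZ` (moduli in the units of
#'   1/S).
#' @export
engineering_constants <- function(S, axes = c(L = 1, T = 2, Z = 3)) {
  shear_idx <- function(i, j) {
    k <- sort(c(i, j))
    if (all(k == c(2, 3))) 4L else if (all(k == c(1, 3))) 5L else 6L
  }
  L <- axes[["L"]]; T_ <- axes[["T"]]; Z <- axes[["Z"]]
  list(EL  = 1 / S[L, L],
       ET  = 1 / S[T_, T_],
       EZ  = 1 / S[Z, Z],
       vLT = -S[T_, L] / S[L, L],
       GLT = 1 / S[shear_idx(L, T_), shear_idx(L, T_)],
       GLZ = 1 / S[shear_idx(L, Z), shear_idx(L, Z)],
       GTZ = 1 / S[shear_idx(T_, Z), shear_idx(T_, Z)])
}
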