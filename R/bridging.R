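# Bridging-model micromechanics for matrix-impregnated fiber bundles.
#
# The bridging matrix [A] relates the volume-average stress in the matrix to
# the volume-average stress in the fiber, sigma_m = A sigma_f.  Its nonzero
# entries are closed-form functions of the constituent constants and two
# empirical bridging parameters alpha (in-plane shear) and beta (transverse),
# both conventionally in 0.3-0.6.

#' Bridging parameters
#'
#' @param Vf Fiber volume fraction of the bundle, in (0, 1).
#' @param alpha Bridging parameter controlling the in-plane (axial) shear
#'   modulus, in (0, 1); conventionally 0.3-0.6.
#' @param beta Bridging parameter controlling the transverse modulus, in
#'   (0, 1); conventionally 0.3-0.6.
#' @return Object of class `bridging_params`.
#' @export
bridging_params <- function(Vf = 0.70, alpha = 0.30, beta = 0.30) {
  stopifnot(Vf > 0, Vf < 1, alpha > 0, alpha < 1, beta > 0, beta < 1)
  structure(list(Vf = Vf, alpha = alpha, beta = beta), class = "bridging_params")
}

#' Bridging matrix of a fiber/matrix pair
#'
#' Assembles the 6x6 bridging matrix in Voigt order (x, y, z, yz, zx, xy)
#' with the fiber axis along x: `a11 = Em/E11f`,
#' `a22 = a33 = a44 = beta + (1-beta) Em/E22f`,
#' `a55 = a66 = alpha + (1-alpha) Gm/G12f`, the axial-transverse coupling
#' `a12 = a13 = (S12f - S12m)/(S11f - S11m) (a11 - a22)`, and zeros elsewhere.
#'
#' @param fiber A `trans_iso_material`.
#' @param matrix An `isotropic_material`.
#' @param params A [bridging_params()] object.
#' @return 6x6 numeric matrix of class `bridging_matrix`.
#' @export
bridging_matrix <- function(fiber, matrix, params = bridging_params()) {
  stopifnot(inherits(fiber, "trans_iso_material"),
            inherits(matrix, "isotropic_material"),
            inherits(params, "bridging_params"))
  S11f <- 1 / fiber$E11; S12f <- -fiber$v12 / fiber$E11
  S11m <- 1 / matrix$E;  S12m <- -matrix$v / matrix$E
  a11 <- matrix$E / fiber$E11
  a22 <- params$beta + (1 - params$beta) * matrix$E / fiber$E22
  a66 <- params$alpha + (1 - params$alpha) * matrix$G / fiber$G12
  # identical constituents make both factors vanish; the coupling is zero
  a12 <- if (abs(S11f - S11m) < 1e-15 * abs(S11m)) 0 else {
    (S12f - S12m) / (S11f - S11m) * (a11 - a22)
  }
  A <- diag(c(a11, a22, a22, a22, a66, a66))
  A[1, 2] <- A[1, 3] <- a12
  structure(A, class = c("bridging_matrix", class(A)))
}

#' Full bridging compliance product
#'
#' Assembles the bundle compliance as
#' `S = (Vf Sf + Vm Sm A) (Vf I + Vm A)^-1` and symmetrizes it.  Including the
#' axial-transverse coupling entry a12 makes the raw product nearly symmetric
#' but stiffens the transverse response relative to the per-constant bridging
#' formulas used by [bundle_constants()]; both are exposed so the difference
#' can be inspected.
#'
#' @inheritParams bridging_matrix
#' @param coupled Keep the a12 = a13 coupling entries (default `TRUE`).
#' @return 6x6 symmetric compliance matrix (1/MPa).
#' @export
bridging_compliance <- function(fiber, matrix, params = bridging_params(),
                                coupled = TRUE) {
  A <- unclass(bridging_matrix(fiber, matrix, params))
  if (!coupled) A[1, 2] <- A[1, 3] <- 0
  Vf <- params$Vf; Vm <- 1 - Vf
  Sf <- compliance_matrix(fiber)
  Sm <- compliance_matrix(matrix)
  B <- Vf * diag(6) + Vm * A
  if (rcond(B) < 1e-14) stop("ill-conditioned bridging parameter set: Vf*I + Vm*A is singular")
  S <- (Vf * Sf + Vm * Sm %*% A) %*% solve(B)
  (S + t(S)) / 2
}

#' Elastic constants of a matrix-impregnated fiber bundle
#'
#' Computes the transversely isotropic constants of a fiber bundle from the
#' bridging model.  Each engineering constant is obtained from its own
#' bridging entry,
#' `X = (Vf + Vm a) / (Vf Sf_x + Vm a Sm_x)`,
#' the form under which the axial modulus reduces exactly to the rule of
#' mixtures `Vf E11f + Vm Em`.  The transverse Poisson's ratio is set from the
#' in-plane isotropy identity `v23 = E22/(2 G23) - 1` so every returned bundle
#' satisfies the transverse-isotropy constraint by construction.
#'
#' @inheritParams bridging_matrix
#' @return A `trans_iso_material` for the bundle.
#' @export
#' @examples
#' kevlar <- trans_iso_material(128700, 12870, 0.3, -0.5, 12870)
#' pcu <- isotropic_material(57, 0.43)
#' bundle_constants(kevlar, pcu, bridging_params(Vf = 0.70))
bundle_constants <- function(fiber, matrix, params = bridging_params()) {
  A <- unclass(bridging_matrix(fiber, matrix, params))
  Vf <- params$Vf; Vm <- 1 - Vf
  S11f <- 1 / fiber$E11; S12f <- -fiber$v12 / fiber$E11
  S22f <- 1 / fiber$E22; S44f <- 1 / fiber$G23; S66f <- 1 / fiber$G12
  Em <- matrix$E; Gm <- matrix$G
  S11m <- 1 / Em; S12m <- -matrix$v / Em
  a11 <- A[1, 1]; a22 <- A[2, 2]; a44 <- A[4, 4]; a66 <- A[6, 6]

  EL  <- (Vf + Vm * a11) / (Vf * S11f + Vm * a11 * S11m)
  vLT <- -(Vf * S12f + Vm * a11 * S12m) / (Vf * S11f + Vm * a11 * S11m)
  ET  <- (Vf + Vm * a22) / (Vf * S22f + Vm * a22 / Em)
  GLT <- (Vf + Vm * a66) / (Vf * S66f + Vm * a66 / Gm)
  GTZ <- (Vf + Vm * a44) / (Vf * S44f + Vm * a44 / Gm)

  rom <- Vf * fiber$E11 + Vm * Em
  if (abs(EL - rom) > 1e-3 * rom) {
    stop("bridging identity violated: axial modulus ", EL,
         " deviates from rule of mixtures ", rom)
  }
  trans_iso_material(E11 = EL, E22 = ET, v12 = vLT,
                     v23 = ET / (2 * GTZ) - 1, G12 = GLT, G23 = GTZ,
                     name = sprintf("%s/%s bundle (Vf=%.3g)",
                                    fiber$name, matrix$name, Vf))
}

#' Recover bridging parameters from target bundle constants
#'
#' Inverts the bridging model: the fiber volume fraction is solved in closed
#' form from the rule-of-mixtures axial modulus, then `beta` and `alpha` are
#' found by scalar root-finding so that the bundle transverse and axial shear
#' moduli match the target.
#'
#' @param target A `trans_iso_material` giving the desired `E11`, `E22`, `G12`.
#' @param fiber,matrix Constituents, as in [bridging_matrix()].
#' @return A [bridging_params()] object reproducing the target `EL`, `ET`,
#'   `GLT` through [bundle_constants()] to within 0.5%.
#' @export
backsolve_params <- function(target, fiber, matrix) {
  EL <- target$E11
  if (EL < min(fiber$E11, matrix$E) || EL > max(fiber$E11, matrix$E)) {
    stop("target axial modulus ", EL, " outside constituent range [",
         min(fiber$E11, matrix$E), ", ", max(fiber$E11, matrix$E), "]")
  }
  Vf <- (EL - matrix$E) / (fiber$E11 - matrix$E)
  Vf <- min(max(Vf, 1e-6), 1 - 1e-6)

  root_in_unit <- function(f, what) {
    lo <- f(1e-6); hi <- f(1 - 1e-6)
    if (lo * hi > 0) {
      stop("no ", what, " in (0,1) reproduces the target; attainable range [",
           signif(min(lo, hi), 4), ", ", signif(max(lo, hi), 4), "] around 0")
    }
    uniroot(f, c(1e-6, 1 - 1e-6), tol = 1e-12)$root
  }
  beta <- root_in_unit(function(b) {
    p <- bridging_params(Vf, alpha = 0.5, beta = b)
    bundle_constants(fiber, matrix, p)$E22 - target$E22
  }, "beta")
  alpha <- root_in_unit(function(a) {
    p <- bridging_params(Vf, alpha = a, beta = beta)
    bundle_constants(fiber, matrix, p)$G12 - target$G12
  }, "alpha")
  out <- bridging_params(Vf = Vf, alpha = alpha, beta = beta)
  got <- bundle_constants(fiber, matrix, out)
  errs <- c(EL = abs(got$E11 - target$E11) / target$E11,
            ET = abs(got$E22 - target$E22) / target$E22,
            GLT = abs(got$G12 - target$G12) / target$G12)
  if (any(errs > 5e-3)) {
    stop("back-solved parameters reproduce the target only to ",
         paste(sprintf("%s=%.2g%%", names(errs), 100 * errs), collapse = ", "))
  }
  out
}
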