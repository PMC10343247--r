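# Representative volume cells: the unidirectional micro cell for the fiber
# bundle and the three meso cells (top / interior / bottom) of the braid,
# plus the two prediction pipelines that homogenize them.

#' Default constituent materials
#'
#' Kevlar fiber and PCU matrix constants (MPa internally).
#'
#' @return List with `fiber` (`trans_iso_material`) and `matrix`
#'   (`isotropic_material`).
#' @export
default_materials <- function() {
  list(fiber = trans_iso_material(E11 = 128700, E22 = 12870, v12 = 0.3,
                                  v23 = -0.5, G12 = 12870, G23 = 12870,
                                  name = "Kevlar"),
       matrix = isotropic_material(E = 57, v = 0.43, name = "PCU"))
}

#' Build a representative volume cell
#'
#' `"micro"` is the unidirectional fiber-bundle cell: a rectangular cell of
#' cross-section `a x sqrt(3) a` with one full and four quarter fibers in
#' hexagonal packing, realized as embedded axial bars whose summed area
#' matches the fiber volume fraction `Vf`.  The meso cells follow the braid
#' spacing: a `(width+gap)^2 x layer-pitch` cell holding one longitudinal and
#' one transverse bundle in two sublayers; `"interior"` adds the vertical
#' interlock column, `"bottom"` is the z-mirror of `"top"`.
#'
#' @param label One of `"micro"`, `"top"`, `"interior"`, `"bottom"`.
#' @param materials Constituents, as from [default_materials()].
#' @param params [bridging_params()]; only `Vf` is used here.
#' @param design A [meniscus_design()] supplying bundle width/height/gap.
#' @param refine Mesh subdivisions per region edge (meso cells).
#' @return Object of class `rvc_spec`: mesh, matrix material, embedded bar
#'   paths, oriented bundle regions, periodicity flags and axis-role map.
#' @export
build_rvc <- function(label = c("micro", "top", "interior", "bottom"),
                      materials = default_materials(),
                      params = bridging_params(),
                      design = meniscus_design(), refine = 2) {
  label <- match.arg(label)
  Vf <- params$Vf
  fib <- materials$fiber; mat <- materials$matrix
  if (label == "micro") {
    a <- 1; h <- sqrt(3) * a; len <- 1
    Af <- Vf * a * h / 2                      # one of two full fibers per cell
    bar <- function(y, z, area) fiber_path(rbind(c(0, y, z), c(len, y, z)),
                                           area = area, E = fib$E11,
                                           tag = "micro-fiber")
    bars <- list(bar(0, 0, Af / 4), bar(a, 0, Af / 4),
                 bar(0, h, Af / 4), bar(a, h, Af / 4),
                 bar(a / 2, h / 2, Af))
    mesh <- box_mesh(seq(0, len, length.out = 3),
                     seq(0, a, length.out = 3),
                     seq(0, h, length.out = 4))
    return(structure(list(label = label, mesh = mesh, matrix_material = mat,
                          bars = bars, regions = list(),
                          dims = c(len, a, h), Vf = Vf,
                          periodic = c(TRUE, TRUE, TRUE),
                          axes = c(L = 1, T = 2, Z = 3)),
                     class = "rvc_spec"))
  }

  cxy <- design$fiber_width + design$gap          # in-plane cell pitch
  cz <- design$height / design$n_layers           # layer pitch
  fw <- design$fiber_width; fh <- design$fiber_height
  cap <- cz - 2 * fh                              # matrix cap thickness
  stopifnot(cap > 0)
  lo <- (cxy - fw) / 2; hi <- (cxy + fw) / 2      # bundle band across the cell

  if (label %in% c("top", "interior")) {
    zb <- c(0, fh, 2 * fh, cz)                    # long below, transverse above
    long_z <- c(0, fh); trans_z <- c(fh, 2 * fh)
  } else {                                        # bottom: exact z-mirror
    zb <- c(0, cap, cap + fh, cz)
    trans_z <- c(cap, cap + fh); long_z <- c(cap + fh, cz)
  }
  regions <- list(
    list(box = rbind(c(0, lo, long_z[1]), c(cxy, hi, long_z[2])),
         axis = c(1, 0, 0), tag = "longitudinal"),
    list(box = rbind(c(lo, 0, trans_z[1]), c(hi, cxy, trans_z[2])),
         axis = c(0, 1, 0), tag = "transverse"))
  bars <- list(
    fiber_path(rbind(c(0, cxy / 2, mean(long_z)), c(cxy, cxy / 2, mean(long_z))),
               area = Vf * fw * fh, E = fib$E11, tag = "longitudinal"),
    fiber_path(rbind(c(cxy / 2, 0, mean(trans_z)), c(cxy / 2, cxy, mean(trans_z))),
               area = Vf * fw * fh, E = fib$E11, tag = "transverse"))
  xyb <- c(0, lo, cxy / 2, hi, cxy)
  if (label == "interior") {
    lock_w <- design$gap / 2                      # interlock column footprint
    regions <- c(regions, list(
      list(box = rbind(c(cxy - lock_w, cxy - lock_w, 0), c(cxy, cxy, cz)),
           axis = c(0, 0, 1), tag = "interlock")))
    bars <- c(bars, list(
      fiber_path(rbind(c(cxy - lock_w / 2, cxy - lock_w / 2, 0),
                       c(cxy - lock_w / 2, cxy - lock_w / 2, cz)),
                 area = Vf * lock_w^2, E = fib$E11, tag = "interlock")))
    xyb <- sort(unique(c(xyb, cxy - lock_w)))
  }
  subdiv <- function(b, n) {
    out <- unique(sort(unlist(lapply(seq_len(length(b) - 1), function(i) {
      seq(b[i], b[i + 1], length.out = n + 1)
    }))))
    out
  }
  mesh <- box_mesh(subdiv(xyb, refine), subdiv(xyb, refine), subdiv(zb, refine))
  structure(list(label = label, mesh = mesh, matrix_material = mat,
                 bars = bars, regions = regions,
                 dims = c(cxy, cxy, cz), Vf = Vf,
                 periodic = c(TRUE, TRUE, TRUE),
                 axes = c(L = 1, T = 3, Z = 2)),
            class = "rvc_spec")
}

#' @export
print.rvc_spec <- function(x, ...) {
  cat(sprintf("<rvc_spec '%s'> %g x %g x %g mm, %d bars, %d oriented regions\n",
              x$label, x$dims[1], x$dims[2], x$dims[3],
              length(x$bars), length(x$regions)))
  invisible(x)
}

# Per-element constitutive matrices for the multi-scale route: oriented
# bundle stiffness inside bundle regions, matrix elsewhere.
rvc_element_D <- function(spec, bundle_material) {
  mesh <- spec$mesh
  Dm <- elastic_matrix(spec$matrix_material)
  Dr <- lapply(spec$regions, function(r) stiffness_matrix(bundle_material, r$axis))
  lapply(seq_len(nrow(mesh$elements)), function(e) {
    cen <- colMeans(mesh$nodes[mesh$elements[e, ], , drop = FALSE])
    for (i in seq_along(spec$regions)) {
      b <- spec$regions[[i]]$box
      if (all(cen >= b[1, ] - 1e-9) && all(cen <= b[2, ] + 1e-9)) return(Dr[[i]])
    }
    Dm
  })
}

#' Homogenize a representative volume cell
#'
#' Two pipelines are available.  `"embedded"` is the fiber-embedded matrix
#' route: the whole cell is matrix and the fiber phase enters as embedded
#' axial bars.  `"multiscale"` replaces each bundle region by a homogeneous
#' transversely isotropic solid oriented along the bundle axis, using
#' `bundle_material` (typically from the micro-cell chain).
#'
#' @param spec An [build_rvc()] result.
#' @param method `"embedded"` or `"multiscale"`.
#' @param bundle_material Required for `"multiscale"`.
#' @return A `homogenized_elasticity`.
#' @export
homogenize_rvc <- function(spec, method = c("embedded", "multiscale"),
                           bundle_material = NULL) {
  method <- match.arg(method)
  model <- if (method == "embedded") {
    fe_model(spec$mesh, spec$matrix_material, fibers = spec$bars)
  } else {
    if (is.null(bundle_material)) stop("multiscale route needs a bundle material")
    fe_model(spec$mesh, spec$matrix_material,
             element_D = rvc_element_D(spec, bundle_material))
  }
  homogenize(model, axes = spec$axes, periodic = spec$periodic,
             label = paste(spec$label, method))
}

#' Micro-to-meso multi-scale prediction chain
#'
#' Homogenizes the unidirectional micro cell to get the fiber-bundle
#' constants, assigns them to the bundle domains of the three meso cells, and
#' homogenizes those.
#'
#' @param materials Constituents, as from [default_materials()].
#' @param params [bridging_params()].
#' @param design A [meniscus_design()].
#' @param labels Meso cells to evaluate.
#' @return List with `micro` (`homogenized_elasticity`), `bundle_material`
#'   (`trans_iso_material`) and one `homogenized_elasticity` per meso label.
#' @export
multiscale_chain <- function(materials = default_materials(),
                             params = bridging_params(),
                             design = meniscus_design(),
                             labels = c("top", "interior", "bottom")) {
  micro <- homogenize_rvc(build_rvc("micro", materials, params, design),
                          method = "embedded")
  bundle <- as_bundle_material(micro, name = "micro-FE bundle")
  out <- list(micro = micro, bundle_material = bundle)
  for (lb in labels) {
    out[[lb]] <- homogenize_rvc(build_rvc(lb, materials, params, design),
                                method = "multiscale", bundle_material = bundle)
  }
  out
}

#' Tabulate homogenized constants in the standard seven-column layout
#'
#' @param results Named list of `homogenized_elasticity` (or
#'   `trans_iso_material`) objects.
#' @return Data frame with columns `EL, ET, EZ` (GPa), `vLT`,
#'   `GLT, GLZ, GTZ` (GPa), one row per entry.
#' @export
constants_table <- function(results) {
  row_of <- function(x) {
    k <- if (inherits(x, "homogenized_elasticity")) x$constants
         else list(EL = x$E11, ET = x$E22, EZ = x$E22, vLT = x$v12,
                   GLT = x$G12, GLZ = x$G12, GTZ = x$G23)
    data.frame(EL = k$EL / 1000, ET = k$ET / 1000, EZ = k$EZ / 1000,
               vLT = k$vLT, GLT = k$GLT / 1000, GLZ = k$GLZ / 1000,
               GTZ = k$GTZ / 1000)
  }
  do.call(rbind, c(lapply(results, row_of), list(make.row.names = TRUE)))
}
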