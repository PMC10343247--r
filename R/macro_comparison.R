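# Macro-scale comparison: the braided meniscus versus a pure-matrix meniscus
# under compressive service loads (fixed base, pressure on the wedge top).

# Local corner indices of the six hexahedron faces.
HEX_FACES <- rbind(c(1, 2, 3, 4), c(5, 6, 7, 8),
                   c(1, 2, 6, 5), c(2, 3, 7, 6),
                   c(3, 4, 8, 7), c(4, 1, 5, 8))

# Boundary faces (appearing in exactly one element) with outward normals.
boundary_faces <- function(mesh) {
  m <- nrow(mesh$elements)
  faces <- matrix(0L, 6L * m, 4L)
  elem <- integer(6L * m)
  for (e in seq_len(m)) {
    faces[6L * (e - 1L) + 1:6, ] <- matrix(mesh$elements[e, HEX_FACES], 6, 4)
    elem[6L * (e - 1L) + 1:6] <- e
  }
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  solo <- key %in% names(which(table(key) == 1L))
  faces <- faces[solo, , drop = FALSE]; elem <- elem[solo]
  normals <- t(vapply(seq_len(nrow(faces)), function(i) {
    xc <- mesh$nodes[faces[i, ], , drop = FALSE]
    nrm <- c(crossprod_3(xc[2, ] - xc[1, ], xc[4, ] - xc[1, ]))
    cen_e <- colMeans(mesh$nodes[mesh$elements[elem[i], ], , drop = FALSE])
    if (sum(nrm * (colMeans(xc) - cen_e)) < 0) nrm <- -nrm
    nrm / sqrt(sum(nrm^2))
  }, numeric(3)))
  list(faces = faces, normals = normals, element = elem)
}

crossprod_3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

# Consistent nodal forces for a vertical pressure (force per unit projected
# area) on the given quad faces; returns the force vector and the projected
# (plan) area.
vertical_pressure_load <- function(mesh, faces, pressure) {
  f <- numeric(3L * nrow(mesh$nodes))
  g1 <- c(-1, 1) / sqrt(3)
  area <- 0
  for (i in seq_len(nrow(faces))) {
    conn <- faces[i, ]
    xc <- mesh$nodes[conn, , drop = FALSE]
    for (gu in g1) for (gv in g1) {
      N <- c((1 - gu) * (1 - gv), (1 + gu) * (1 - gv),
             (1 + gu) * (1 + gv), (1 - gu) * (1 + gv)) / 4
      dNu <- c(-(1 - gv), (1 - gv), (1 + gv), -(1 + gv)) / 4
      dNv <- c(-(1 - gu), -(1 + gu), (1 + gu), (1 - gu)) / 4
      dA <- crossprod_3(as.numeric(dNu %*% xc), as.numeric(dNv %*% xc))
      dAz <- abs(dA[3])
      area <- area + dAz
      f[3L * conn] <- f[3L * conn] - pressure * N * dAz
    }
  }
  list(f = f, plan_area = area)
}

#' Macro finite-element model of a meniscus implant
#'
#' @param design A [meniscus_design()].
#' @param materials Constituents, as from [default_materials()].
#' @param params [bridging_params()] supplying the intra-bundle `Vf`.
#' @param reinforced Embed the braided lattice (`FALSE` gives the pure-matrix
#'   implant on the identical mesh).
#' @param resolution Mesh resolution (mm).
#' @return An [fe_model()] with attributes `design` and `reinforced`.
#' @export
macro_model <- function(design = meniscus_design(),
                        materials = default_materials(),
                        params = bridging_params(),
                        reinforced = TRUE, resolution = 1) {
  built <- build_meniscus(design, resolution = resolution)
  fibers <- if (reinforced) {
    lattice_fiber_paths(built$lattice, E = materials$fiber$E11, Vf = params$Vf)
  } else {
    list()
  }
  model <- fe_model(built$mesh, materials$matrix, fibers = fibers)
  attr(model, "design") <- design
  attr(model, "reinforced") <- reinforced
  model
}

#' Run the compressive load cases on a macro model
#'
#' The bottom surface (z = 0) is fully fixed; each total load is applied as a
#' uniform vertical pressure (load divided by the projected area of the wedge
#' top surface) with consistent nodal forces.  The stiffness is factorized
#' once and reused across loads.
#'
#' @param model A [macro_model()].
#' @param loads Numeric vector of total loads (N); default the 400-1400 N
#'   service set.
#' @return Object of class `simulation_result`: data frame `cases` with
#'   columns `load`, `pressure` (MPa), `displacement` (max downward vertical
#'   displacement of the loaded surface, mm), plus the displacement fields.
#' @export
run_load_cases <- function(model, loads = c(400, 600, 800, 1200, 1400)) {
  stopifnot(all(loads >= 0))
  mesh <- model$mesh
  K <- assemble(model)
  zmin <- min(mesh$nodes[, 3])
  fixed_nodes <- which(mesh$nodes[, 3] < zmin + 1e-8)
  fixed <- as.integer(rbind(3L * fixed_nodes - 2L, 3L * fixed_nodes - 1L,
                            3L * fixed_nodes))
  free <- setdiff(seq_len(model$n_dof), fixed)
  bf <- boundary_faces(mesh)
  top <- bf$normals[, 3] > 0.5
  if (!any(top)) stop("no upward-facing loaded surface found")
  unit <- vertical_pressure_load(mesh, bf$faces[top, , drop = FALSE], 1)
  top_nodes <- unique(as.integer(bf$faces[top, ]))
  Kff <- K[free, free]
  fac <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE)
  fields <- list()
  res <- data.frame(load = loads, pressure = NA_real_, displacement = NA_real_)
  for (i in seq_along(loads)) {
    p <- loads[i] / unit$plan_area
    u <- numeric(model$n_dof)
    if (loads[i] > 0) {
      u[free] <- as.numeric(Matrix::solve(fac, (p * unit$f)[free]))
    }
    res$pressure[i] <- p
    res$displacement[i] <- if (loads[i] > 0) max(-u[3L * top_nodes]) else 0
    fields[[i]] <- u
  }
  structure(list(cases = res, fields = fields,
                 tag = if (isTRUE(attr(model, "reinforced"))) "reinforced"
                       else "pure_matrix",
                 plan_area = unit$plan_area, top_nodes = top_nodes),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result '%s'>\n", x$tag))
  print(x$cases, row.names = FALSE)
  invisible(x)
}

#' Deformation-resistance improvement of the reinforced implant
#'
#' Per load, the improvement is `(u_matrix / u_reinforced - 1) * 100`, i.e.
#' the percentage by which the pure-matrix vertical deformation exceeds the
#' reinforced one at equal load; in the linear model the ratio is
#' load-independent and the mean over loads is also reported.
#'
#' @param reinforced,pure_matrix `simulation_result`s on the same load set
#'   and mesh family.
#' @return List with `per_load` (data frame `load`, `improvement_pct`) and
#'   `mean_pct`.
#' @export
improvement_ratio <- function(reinforced, pure_matrix) {
  r <- reinforced$cases; m <- pure_matrix$cases
  if (!isTRUE(all.equal(r$load, m$load))) stop("mismatched load sets")
  nz <- r$load > 0
  pct <- (m$displacement[nz] / r$displacement[nz] - 1) * 100
  list(per_load = data.frame(load = r$load[nz], improvement_pct = pct),
       mean_pct = mean(pct))
}

#' Compare braided and pure-matrix implants
#'
#' Builds both macro models on the same mesh, runs the load set on each and
#' reports the stress-deformation curves plus the improvement ratio.
#'
#' @inheritParams macro_model
#' @param loads Total loads (N).
#' @return List with `reinforced`, `pure_matrix` (`simulation_result`s) and
#'   `improvement` from [improvement_ratio()].
#' @export
compare_meniscus <- function(design = meniscus_design(),
                             materials = default_materials(),
                             params = bridging_params(),
                             loads = c(400, 600, 800, 1200, 1400),
                             resolution = 1) {
  reinf <- run_load_cases(macro_model(design, materials, params,
                                      reinforced = TRUE,
                                      resolution = resolution), loads)
  pure <- run_load_cases(macro_model(design, materials, params,
                                     reinforced = FALSE,
                                     resolution = resolution), loads)
  list(reinforced = reinf, pure_matrix = pure,
       improvement = improvement_ratio(reinf, pure))
}
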