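# Configuration handling and mesh/result writers.

config_schema <- list(
  materials = list(
    fiber = c("name", "E11_GPa", "E22_GPa", "v12", "G12_GPa", "G23_GPa"),
    matrix = c("name", "E_GPa", "v")),
  bridging = c("Vf", "alpha", "beta"),
  geometry = c("length_mm", "width_mm", "height_mm", "inner_length_mm",
               "inner_bulge_mm", "min_thickness_mm", "fiber_width_mm",
               "fiber_height_mm", "gap_mm", "fan_angle_deg",
               "interlock_area_mm2"),
  mesh = c("resolution_mm"),
  loads_N = NULL,
  output_dir = NULL,
  log_level = NULL)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("unknown config key(s) at ", where, ": ", paste(extra, collapse = ", "))
  }
}

#' Read a run configuration
#'
#' Reads a YAML (or JSON) configuration, validates its keys against the
#' published schema, and converts GPa values to the internal MPa unit system.
#' The packaged default configuration reproduces the Kevlar/PCU constituent
#' table and the default braid design.
#'
#' @param path Path to a YAML/JSON config; `NULL` loads the packaged default.
#' @return List with `materials` (constituent objects), `params`
#'   ([bridging_params()]), `design` ([meniscus_design()]), `resolution`,
#'   `loads`, `output_dir`, `log_level`.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml", package = "braidfe")
  }
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  check_keys(raw, names(config_schema), "top level")
  check_keys(raw$materials, names(config_schema$materials), "materials")
  check_keys(raw$materials$fiber, config_schema$materials$fiber, "materials$fiber")
  check_keys(raw$materials$matrix, config_schema$materials$matrix, "materials$matrix")
  check_keys(raw$bridging, config_schema$bridging, "bridging")
  check_keys(raw$geometry, config_schema$geometry, "geometry")
  check_keys(raw$mesh, config_schema$mesh, "mesh")

  dflt <- yaml::read_yaml(system.file("extdata", "default_config.yaml",
                                      package = "braidfe"))
  merge2 <- function(base, upd) {
    if (is.null(upd)) return(base)
    for (k in names(upd)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(upd[[k]])) {
        merge2(base[[k]], upd[[k]])
      } else upd[[k]]
    }
    base
  }
  cfg <- merge2(dflt, raw)
  gpa <- 1000  # GPa -> MPa
  f <- cfg$materials$fiber; m <- cfg$materials$matrix; g <- cfg$geometry
  list(
    materials = list(
      fiber = trans_iso_material(E11 = f$E11_GPa * gpa, E22 = f$E22_GPa * gpa,
                                 v12 = f$v12,
                                 v23 = f$E22_GPa / (2 * f$G23_GPa) - 1,
                                 G12 = f$G12_GPa * gpa, G23 = f$G23_GPa * gpa,
                                 name = f$name),
      matrix = isotropic_material(E = m$E_GPa * gpa, v = m$v, name = m$name)),
    params = bridging_params(Vf = cfg$bridging$Vf, alpha = cfg$bridging$alpha,
                             beta = cfg$bridging$beta),
    design = meniscus_design(length = g$length_mm, width = g$width_mm,
                             height = g$height_mm,
                             inner_length = g$inner_length_mm,
                             inner_bulge = g$inner_bulge_mm,
                             min_thickness = g$min_thickness_mm,
                             fiber_width = g$fiber_width_mm,
                             fiber_height = g$fiber_height_mm,
                             gap = g$gap_mm, fan_angle = g$fan_angle_deg,
                             interlock_area = g$interlock_area_mm2),
    resolution = cfg$mesh$resolution_mm,
    loads = as.numeric(cfg$loads_N),
    output_dir = cfg$output_dir,
    log_level = cfg$log_level)
}

#' Write a mesh (and optional fiber polylines) as legacy VTK
#'
#' ASCII legacy unstructured-grid format; hexahedra are VTK cell type 12 and
#' fiber polylines type 4.  Point data vectors (e.g. displacements) may be
#' attached to the mesh points.
#'
#' @param mesh A `hex_mesh`.
#' @param file Output path.
#' @param point_data Optional named list of per-node scalars (length n) or
#'   3-column matrices (vectors).
#' @param lattice Optional `truss_lattice` or list of [fiber_path()]s
#'   appended as polyline cells.
#' @return `file`, invisibly.
#' @export
write_vtk <- function(mesh, file, point_data = NULL, lattice = NULL) {
  paths <- if (inherits(lattice, "truss_lattice")) {
    lapply(lattice$paths, `[[`, "points")
  } else if (!is.null(lattice)) {
    lapply(lattice, `[[`, "points")
  } else list()
  extra <- if (length(paths)) do.call(rbind, paths) else NULL
  pts <- rbind(mesh$nodes, extra)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "braidfe export", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(pts))), con)
  utils::write.table(pts, con, row.names = FALSE, col.names = FALSE)
  ncell <- nrow(mesh$elements) + length(paths)
  sizes <- 9L * nrow(mesh$elements) +
    sum(vapply(paths, nrow, 1L) + 1L)
  writeLines(sprintf("CELLS %d %d", ncell, sizes), con)
  utils::write.table(cbind(8L, mesh$elements - 1L), con,
                     row.names = FALSE, col.names = FALSE)
  off <- nrow(mesh$nodes)
  for (p in paths) {
    writeLines(paste(c(nrow(p), off + seq_len(nrow(p)) - 1L), collapse = " "), con)
    off <- off + nrow(p)
  }
  writeLines(sprintf("CELL_TYPES %d", ncell), con)
  writeLines(as.character(c(rep(12L, nrow(mesh$elements)),
                            rep(4L, length(paths)))), con)
  if (!is.null(point_data)) {
    writeLines(sprintf("POINT_DATA %d", nrow(pts)), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        v <- rbind(v, matrix(0, nrow(pts) - nrow(v), 3))
        writeLines(sprintf("VECTORS %s double", nm), con)
        utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
      } else {
        v <- c(v, rep(0, nrow(pts) - length(v)))
        writeLines(c(sprintf("SCALARS %s double 1", nm),
                     "LOOKUP_TABLE default"), con)
        writeLines(as.character(v), con)
      }
    }
  }
  invisible(file)
}

#' Write a mesh as an Abaqus input deck (C3D8)
#'
#' @param mesh A `hex_mesh`.
#' @param file Output path.
#' @param elset Element set name.
#' @return `file`, invisibly.
#' @export
write_abaqus_inp <- function(mesh, file, elset = "SOLID") {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("*NODE", con)
  writeLines(sprintf("%d, %.10g, %.10g, %.10g", seq_len(nrow(mesh$nodes)),
                     mesh$nodes[, 1], mesh$nodes[, 2], mesh$nodes[, 3]), con)
  writeLines(sprintf("*ELEMENT, TYPE=C3D8, ELSET=%s", elset), con)
  writeLines(paste0(seq_len(nrow(mesh$elements)), ", ",
                    apply(mesh$elements, 1, paste, collapse = ", ")), con)
  invisible(file)
}

#' Read an Abaqus input deck with C3D8 elements
#'
#' Minimal reader for decks produced by [write_abaqus_inp()] or equivalent:
#' one `*NODE` block and `*ELEMENT` blocks of type C3D8.
#'
#' @param file Path to the `.inp` file.
#' @return A `hex_mesh`.
#' @export
read_abaqus_inp <- function(file) {
  ln <- readLines(file)
  is_kw <- grepl("^\\*", ln)
  node_rows <- integer(0); elem_rows <- integer(0)
  mode <- ""
  for (i in seq_along(ln)) {
    if (is_kw[i]) {
      up <- toupper(ln[i])
      mode <- if (startsWith(up, "*NODE")) "node"
              else if (startsWith(up, "*ELEMENT") && grepl("C3D8", up)) "elem"
              else ""
    } else if (nzchar(trimws(ln[i]))) {
      if (mode == "node") node_rows <- c(node_rows, i)
      if (mode == "elem") elem_rows <- c(elem_rows, i)
    }
  }
  parse_csv <- function(rows) {
    do.call(rbind, lapply(ln[rows], function(s) {
      as.numeric(strsplit(s, ",")[[1]])
    }))
  }
  nd <- parse_csv(node_rows); el <- parse_csv(elem_rows)
  nodes <- matrix(NA_real_, max(nd[, 1]), 3)
  nodes[nd[, 1], ] <- nd[, 2:4]
  hex_mesh(nodes, matrix(as.integer(el[, 2:9]), ncol = 8))
}

#' Write homogenized-constants tables to CSV
#'
#' @param tab Data frame from [constants_table()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_constants_csv <- function(tab, file) {
  utils::write.csv(cbind(model = rownames(tab), tab), file, row.names = FALSE)
  invisible(file)
}
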