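# Parametric generator of the layered braided meniscus lattice and of the
# crescent wedge solid.
#
# The crescent outline is the region between two half-ellipses sharing the
# plan center: an outer ellipse (half axes length/2 x width) and a concave
# inner ellipse (inner_length/2 x inner_bulge).  Radial stations p in [0,1]
# interpolate between them; the wedge thickness tapers linearly from
# min_thickness at the inner edge (p=0) to the full height at the outer edge
# (p=1).  Fiber layers sit at fixed fractions of the local thickness, so
# transverse arcs are flat and longitudinal fibers follow the taper.

#' Parametric design of the braided meniscus
#'
#' Defaults reproduce the designed 32 x 26 x 11 mm implant: five fiber layers
#' in three levels, per-level transverse/longitudinal fiber counts 6/13, 4/12
#' and 2/8, 2 x 1 mm fiber bundles with 2 mm gaps and a ~15 degree fan
#' between longitudinal fibers.
#'
#' @param length,width,height Overall bounding dimensions (mm).
#' @param inner_length,inner_bulge Half-ellipse axes of the concave inner
#'   edge (mm).
#' @param min_thickness Wedge thickness at the inner edge (mm).
#' @param n_layers Number of fiber layers through the height.
#' @param layer_levels Level index (1-3) of each layer, bottom to top.
#' @param transverse_counts,transverse_lengths Per-level arc counts and
#'   target arc lengths (mm).
#' @param longitudinal_counts,longitudinal_lengths Per-level fan counts and
#'   fiber lengths (mm); defaults shorten by 8 mm then 6 mm level to level.
#' @param fiber_width,fiber_height Bundle cross-section (mm).
#' @param gap In-plane gap between parallel bundles (mm).
#' @param fan_angle Nominal angle between adjacent longitudinal fibers (deg).
#' @param interlock_area Cross-section of the interlock braiding yarn (mm^2).
#' @return Object of class `meniscus_design`.
#' @export
meniscus_design <- function(length = 32, width = 26, height = 11,
                            inner_length = 26, inner_bulge = 3,
                            min_thickness = 3,
                            n_layers = 5, layer_levels = c(1, 1, 2, 2, 3),
                            transverse_counts = c(6, 4, 2),
                            transverse_lengths = c(45, 40, 35),
                            longitudinal_counts = c(13, 12, 8),
                            longitudinal_lengths = c(26, 18, 12),
                            fiber_width = 2, fiber_height = 1, gap = 2,
                            fan_angle = 15, interlock_area = 0.5) {
  stopifnot(length > 0, width > 0, height > 0,
            all(transverse_counts >= 0), all(longitudinal_counts >= 0),
            n_layers == base::length(layer_levels),
            min_thickness > 0, min_thickness < height)
  d <- list(length = length, width = width, height = height,
            inner_length = inner_length, inner_bulge = inner_bulge,
            min_thickness = min_thickness,
            n_layers = n_layers, layer_levels = layer_levels,
            transverse_counts = transverse_counts,
            transverse_lengths = transverse_lengths,
            longitudinal_counts = longitudinal_counts,
            longitudinal_lengths = longitudinal_lengths,
            fiber_width = fiber_width, fiber_height = fiber_height,
            gap = gap, fan_angle = fan_angle,
            bundle_area = fiber_width * fiber_height,
            interlock_area = interlock_area)
  structure(d, class = "meniscus_design")
}

#' Uniformly scale a meniscus design
#'
#' Multiplies every dimensional field (lengths, areas as length^2); counts
#' and angles are unchanged.
#'
#' @param design A `meniscus_design`.
#' @param s Scale factor.
#' @return Scaled `meniscus_design`.
#' @export
scale_design <- function(design, s) {
  stopifnot(s > 0)
  lin <- c("length", "width", "height", "inner_length", "inner_bulge",
           "min_thickness", "transverse_lengths", "longitudinal_lengths",
           "fiber_width", "fiber_height", "gap")
  for (f in lin) design[[f]] <- design[[f]] * s
  design$bundle_area <- design$fiber_width * design$fiber_height
  design$interlock_area <- design$interlock_area * s^2
  design
}

# Plan-view point at angular parameter t in [0, pi] and radial station p.
station_xy <- function(d, t, p) {
  a <- d$inner_length / 2 + p * (d$length / 2 - d$inner_length / 2)
  b <- d$inner_bulge + p * (d$width - d$inner_bulge)
  cbind(a * cos(t), b * sin(t))
}

wedge_thickness <- function(d, p) d$min_thickness + (d$height - d$min_thickness) * p

layer_zfrac <- function(d, layer) (layer - 0.5) / d$n_layers

# Radial station band of a level: upper levels sit nearer the (tall) outer edge.
level_p_range <- function(d, level) {
  n_levels <- length(d$transverse_counts)
  c((level - 1) / n_levels, 1)
}

transverse_stations <- function(d, level) {
  n <- d$transverse_counts[level]
  if (n == 0) return(numeric(0))
  r <- level_p_range(d, level)
  r[1] + (seq_len(n) - 0.5) / n * (r[2] - r[1])
}

longitudinal_stations <- function(d, level) {
  n <- d$longitudinal_counts[level]
  if (n == 0) return(numeric(0))
  if (n == 1) return(pi / 2)
  seq(0, pi, length.out = n)
}

# Cumulative arc length of the station-p ellipse on a fine t grid.
station_arclength <- function(d, p, n = 721) {
  t <- seq(0, pi, length.out = n)
  xy <- station_xy(d, t, p)
  s <- c(0, cumsum(sqrt(rowSums(diff(xy)^2))))
  list(t = t, s = s, total = s[n])
}

# t-window of the arc of given target length centered at the apex.
arc_window <- function(d, p, target) {
  al <- station_arclength(d, p)
  if (al$total <= target) return(c(0, pi))
  s1 <- (al$total - target) / 2
  s2 <- s1 + target
  c(stats::approx(al$s, al$t, xout = s1)$y,
    stats::approx(al$s, al$t, xout = s2)$y)
}

transverse_arc_path <- function(d, p, zfrac, target, step = d$gap) {
  w <- arc_window(d, p, target)
  al <- station_arclength(d, p)
  s_lo <- stats::approx(al$t, al$s, xout = w[1])$y
  s_hi <- stats::approx(al$t, al$s, xout = w[2])$y
  npts <- max(8, ceiling((s_hi - s_lo) / step) + 1)
  tt <- stats::approx(al$s, al$t, xout = seq(s_lo, s_hi, length.out = npts))$y
  xy <- station_xy(d, tt, p)
  cbind(xy, zfrac * wedge_thickness(d, p))
}

# End station of the longitudinal fiber launched outward at angle t.
longitudinal_p_end <- function(d, t, level, p_cap = 0.99) {
  r <- level_p_range(d, level)
  p0 <- r[1]
  full <- sqrt(sum((station_xy(d, t, 1) - station_xy(d, t, p0))^2))
  L <- d$longitudinal_lengths[level]
  p_end <- if (full < 1e-9) p0 else p0 + (1 - p0) * min(1, L / full)
  min(p_end, p_cap)
}

longitudinal_path <- function(d, t, level, zfrac, npts = 6) {
  p0 <- level_p_range(d, level)[1]
  p1 <- longitudinal_p_end(d, t, level)
  ps <- seq(p0, p1, length.out = npts)
  xy <- station_xy(d, rep(t, npts), ps)
  cbind(xy, zfrac * wedge_thickness(d, ps))
}

lattice_entry <- function(points, area, tag, level, layer) {
  list(points = points, area = area, tag = tag, level = level, layer = layer)
}

#' Build the fiber lattice of one braid level
#'
#' @param design A [meniscus_design()].
#' @param level Level index in 1..3 (bottom to top).
#' @param layer Layer index the paths are placed at; defaults to the first
#'   layer belonging to the level.
#' @return Object of class `truss_lattice` whose `paths` hold the transverse
#'   arcs and longitudinal fan fibers of the level.
#' @export
build_level <- function(design, level, layer = NULL) {
  stopifnot(level %in% seq_along(design$transverse_counts))
  if (is.null(layer)) layer <- which(design$layer_levels == level)[1]
  zf <- layer_zfrac(design, layer)
  paths <- list()
  for (p in transverse_stations(design, level)) {
    pts <- transverse_arc_path(design, p, zf, design$transverse_lengths[level])
    paths[[length(paths) + 1]] <-
      lattice_entry(pts, design$bundle_area, "transverse", level, layer)
  }
  for (t in longitudinal_stations(design, level)) {
    pts <- longitudinal_path(design, t, level, zf)
    paths[[length(paths) + 1]] <-
      lattice_entry(pts, design$bundle_area, "longitudinal", level, layer)
  }
  structure(list(paths = paths, design = design), class = "truss_lattice")
}

# Interlock U-loops binding layer `layer` to `layer + 1`, placed at the
# lattice crossings of the upper layer's level; loop pitch equals the gap.
interlock_loops <- function(design, layer) {
  lv <- design$layer_levels[layer + 1]
  paths <- list()
  t_st <- longitudinal_stations(design, lv)
  p_st <- transverse_stations(design, lv)
  for (p in p_st) {
    w <- arc_window(design, p, design$transverse_lengths[lv])
    for (t in t_st) {
      if (t < w[1] || t > w[2]) next
      if (p > longitudinal_p_end(design, t, lv)) next
      # arc-tangent spacing of the second leg
      dxy <- station_xy(design, t + 1e-4, p) - station_xy(design, t - 1e-4, p)
      dsdt <- sqrt(sum(dxy^2)) / 2e-4
      dt <- design$gap / dsdt
      t2 <- if (t + dt <= pi) t + dt else t - dt
      z_lo <- layer_zfrac(design, layer) * wedge_thickness(design, p)
      z_up <- layer_zfrac(design, layer + 1) * wedge_thickness(design, p)
      P1 <- station_xy(design, t, p); P2 <- station_xy(design, t2, p)
      pts <- rbind(c(P1, z_up), c(P1, z_lo), c(P2, z_lo), c(P2, z_up))
      paths[[length(paths) + 1]] <-
        lattice_entry(pts, design$interlock_area, "interlock", lv, layer)
    }
  }
  paths
}

#' Hexahedral mesh of the crescent wedge solid
#'
#' Mapped meshing of the (angle x radial x height) parameter block; the
#' bounding box equals length x width x height exactly.
#'
#' @param design A [meniscus_design()].
#' @param resolution Target element edge length (mm).
#' @return A `hex_mesh`.
#' @export
crescent_mesh <- function(design, resolution = 2) {
  arc <- station_arclength(design, 1)$total
  wmax <- design$width - design$inner_bulge
  nu <- max(8, ceiling(arc / resolution))
  nu <- nu + nu %% 2              # even count puts a node row at the apex
  nv <- max(3, ceiling(wmax / resolution))
  nw <- max(2, ceiling(design$height / resolution / 1.5))
  grid_mesh(nu, nv, nw, map = function(par3) {
    # t decreasing with u keeps the (u, v, w) frame right-handed
    t <- pi * (1 - par3[, 1]); p <- par3[, 2]; w <- par3[, 3]
    xy <- station_xy(design, t, p)
    cbind(xy, w * wedge_thickness(design, p))
  })
}

#' Build the full braided meniscus: lattice plus matrix solid
#'
#' Stacks the layer lattices (levels 1,1,2,2,3 bottom to top at defaults),
#' adds the interlock loops between adjacent layers, and meshes the wedge
#' solid so that every fiber path is locatable inside it.
#'
#' @param design A [meniscus_design()].
#' @param resolution Mesh resolution passed to [crescent_mesh()] (mm).
#' @param mesh Build the matrix mesh (set `FALSE` for lattice-only use).
#' @return List with `lattice` (a `truss_lattice`), `mesh` (a `hex_mesh` or
#'   `NULL`) and `design`.
#' @export
build_meniscus <- function(design = meniscus_design(), resolution = 2,
                           mesh = TRUE) {
  paths <- list()
  for (layer in seq_len(design$n_layers)) {
    lev <- design$layer_levels[layer]
    paths <- c(paths, build_level(design, lev, layer)$paths)
  }
  for (layer in seq_len(design$n_layers - 1)) {
    paths <- c(paths, interlock_loops(design, layer))
  }
  lattice <- structure(list(paths = paths, design = design),
                       class = "truss_lattice")
  list(lattice = lattice,
       mesh = if (mesh) crescent_mesh(design, resolution) else NULL,
       design = design)
}

#' @export
print.truss_lattice <- function(x, ...) {
  tags <- vapply(x$paths, `[[`, "", "tag")
  cat("<truss_lattice>", length(x$paths), "paths:",
      paste(sprintf("%s=%d", names(table(tags)), as.integer(table(tags))),
            collapse = ", "), "\n")
  invisible(x)
}

#' Fiber counts of a lattice by tag and level
#'
#' @param lattice A `truss_lattice`.
#' @return Data frame with columns `tag`, `level`, `layer`, `n`.
#' @export
lattice_counts <- function(lattice) {
  df <- data.frame(tag = vapply(lattice$paths, `[[`, "", "tag"),
                   level = vapply(lattice$paths, `[[`, 1, "level"),
                   layer = vapply(lattice$paths, `[[`, 1, "layer"))
  agg <- stats::aggregate(list(n = rep(1L, nrow(df))),
                          by = df[c("tag", "level", "layer")], FUN = sum)
  agg[order(agg$layer, agg$tag), ]
}

#' Bounding box of lattice and solid together
#'
#' @param built Result of [build_meniscus()].
#' @return 2x3 matrix (rows min, max; mm).
#' @export
meniscus_bbox <- function(built) {
  pts <- do.call(rbind, lapply(built$lattice$paths, `[[`, "points"))
  if (!is.null(built$mesh)) pts <- rbind(pts, built$mesh$nodes)
  apply(pts, 2, range)
}

#' Convert lattice paths to embedded fiber paths
#'
#' The effective bar cross-section is the geometric bundle section times the
#' intra-bundle fiber volume fraction, with the bare fiber axial modulus, so
#' the bar carries exactly the fiber phase's axial stiffness while the host
#' mesh provides the matrix.
#'
#' @param lattice A `truss_lattice`.
#' @param E Fiber axial modulus (MPa).
#' @param Vf Intra-bundle fiber volume fraction scaling the areas.
#' @return List of [fiber_path()] objects.
#' @export
lattice_fiber_paths <- function(lattice, E, Vf = 1) {
  lapply(lattice$paths, function(p) {
    fiber_path(p$points, area = p$area * Vf, E = E, tag = p$tag)
  })
}
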