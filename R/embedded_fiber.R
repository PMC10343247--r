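# Embedded bar reinforcement: polyline fibers carried by host hexahedra.
# A fiber contributes axial stiffness only; its end displacements are
# interpolated from the host element's shape functions, so meshes need not
# conform to fiber paths.

#' Fiber path
#'
#' @param points n x 3 matrix of polyline vertices (mm), n >= 2, consecutive
#'   vertices distinct.
#' @param area Cross-sectional area carried by the fiber (mm^2).
#' @param E Axial Young's modulus of the fiber material (MPa).
#' @param tag Optional label (e.g. "transverse", "longitudinal", "interlock").
#' @return Object of class `fiber_path`.
#' @export
fiber_path <- function(points, area, E, tag = "fiber") {
  points <- as.matrix(points); storage.mode(points) <- "double"
  stopifnot(ncol(points) == 3, nrow(points) >= 2, area > 0, E >= 0)
  seg <- diff(points)
  if (any(sqrt(rowSums(seg^2)) < 1e-12)) stop("consecutive path points must be distinct")
  structure(list(points = points, area = area, E = E, tag = tag),
            class = "fiber_path")
}

#' Total length of a fiber path
#' @param path A `fiber_path`.
#' @return Length (mm).
#' @export
path_length <- function(path) sum(sqrt(rowSums(diff(path$points)^2)))

# Newton inversion of the trilinear map; returns natural coords (possibly
# outside [-1,1]^3) or NULL on non-convergence.
inverse_map <- function(coords, p, xi0 = c(0, 0, 0), tol = 1e-12, maxit = 50) {
  xi <- xi0
  for (it in seq_len(maxit)) {
    sf <- hex_shape_functions(xi)
    r <- as.numeric(crossprod(sf$N, coords)) - p
    if (sqrt(sum(r^2)) < tol * (1 + sqrt(sum(p^2)))) return(xi)
    J <- t(sf$dN) %*% coords
    step <- tryCatch(solve(t(J), r), error = function(e) NULL)
    if (is.null(step)) return(NULL)
    xi <- xi - as.numeric(step)
    if (any(abs(xi) > 10)) return(NULL)
  }
  NULL
}

# Axis-aligned bounding boxes of all elements, expanded by `pad`.
element_bboxes <- function(mesh, pad = 1e-6) {
  m <- nrow(mesh$elements)
  lo <- matrix(0, m, 3); hi <- matrix(0, m, 3)
  for (e in seq_len(m)) {
    xc <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
    lo[e, ] <- apply(xc, 2, min) - pad
    hi[e, ] <- apply(xc, 2, max) + pad
  }
  list(lo = lo, hi = hi)
}

# Locate the element containing point p; returns list(element, xi) or NULL.
locate_point <- function(mesh, p, bb = NULL, tol = 1e-8) {
  if (is.null(bb)) bb <- element_bboxes(mesh)
  cand <- which(p[1] >= bb$lo[, 1] & p[1] <= bb$hi[, 1] &
                p[2] >= bb$lo[, 2] & p[2] <= bb$hi[, 2] &
                p[3] >= bb$lo[, 3] & p[3] <= bb$hi[, 3])
  best <- NULL; best_m <- Inf
  for (e in cand) {
    xi <- inverse_map(mesh$nodes[mesh$elements[e, ], , drop = FALSE], p)
    if (is.null(xi)) next
    m <- max(abs(xi))
    if (m <= 1 + tol && m < best_m) { best <- list(element = e, xi = xi); best_m <- m }
  }
  best
}

#' Split a fiber path into element-hosted segments
#'
#' Walks each polyline leg through the mesh, splitting it where it crosses
#' element boundaries (located by bisection on host membership).  The union of
#' segment parameter ranges covers the path exactly, so total embedded length
#' equals the path length; segments shorter than `min_len` are discarded.
#'
#' @param mesh A `hex_mesh`.
#' @param path A [fiber_path()].
#' @param min_len Minimum retained segment length (mm).
#' @return List of embedded segments, each with fields `element`, `xi_m`,
#'   `xi_n` (endpoint natural coordinates), `p_m`, `p_n` (physical endpoints),
#'   `length` (mm), `area`, `E`, `tag`.
#' @export
segment_fibers <- function(mesh, path, min_len = 1e-6) {
  stopifnot(inherits(mesh, "hex_mesh"), inherits(path, "fiber_path"))
  bb <- element_bboxes(mesh)
  # strict tolerance for clean meshes; a loose fallback absorbs the chordal
  # sag of coarsely faceted curved meshes (points just outside all facets)
  loose <- 0.25
  inside <- function(e, p, tol) {
    xi <- inverse_map(mesh$nodes[mesh$elements[e, ], , drop = FALSE], p)
    !is.null(xi) && max(abs(xi)) <= 1 + tol
  }
  out <- list()
  pts <- path$points
  for (s in seq_len(nrow(pts) - 1)) {
    p0 <- pts[s, ]; p1 <- pts[s + 1, ]
    seg_len <- sqrt(sum((p1 - p0)^2))
    at <- function(t) p0 + t * (p1 - p0)
    find_exit <- function(e, t0, tol) {
      if (inside(e, at(1), tol)) return(1)
      lo <- t0; hi <- 1
      for (it in 1:50) {
        mid <- (lo + hi) / 2
        if (inside(e, at(mid), tol)) lo <- mid else hi <- mid
      }
      lo
    }
    t_cur <- 0; guard <- 0
    while (t_cur < 1 - 1e-12) {
      guard <- guard + 1
      if (guard > 500) stop("fiber segmentation failed to advance on leg ", s)
      probe_t <- min(t_cur + 1e-9, 1)
      loc <- locate_point(mesh, at(probe_t), bb)
      if (is.null(loc)) loc <- locate_point(mesh, at(min(t_cur + 1e-4, 1)), bb)
      if (is.null(loc)) loc <- locate_point(mesh, at(probe_t), bb, tol = loose)
      if (is.null(loc)) {
        stop(sprintf("unlocatable fiber point (%.6g, %.6g, %.6g): outside all elements",
                     at(probe_t)[1], at(probe_t)[2], at(probe_t)[3]))
      }
      e <- loc$element
      t_exit <- find_exit(e, t_cur, 1e-8)
      if (t_exit <= t_cur + 1e-12) t_exit <- find_exit(e, t_cur, loose)
      if (t_exit <= t_cur + 1e-12) {
        # point sits exactly on a face of e but the leg immediately leaves it;
        # retry from a host containing a point slightly ahead
        t_cur <- t_cur + 1e-9
        next
      }
      pm <- at(t_cur); pn <- at(t_exit)
      len <- (t_exit - t_cur) * seg_len
      if (len >= min_len) {
        xc <- mesh$nodes[mesh$elements[e, ], , drop = FALSE]
        xi_m <- inverse_map(xc, pm); xi_n <- inverse_map(xc, pn)
        if (is.null(xi_m) || is.null(xi_n)) stop("inverse mapping failed in element ", e)
        out[[length(out) + 1]] <- list(
          element = e,
          xi_m = pmin(pmax(xi_m, -1), 1),
          xi_n = pmin(pmax(xi_n, -1), 1),
          p_m = pm, p_n = pn, length = len,
          area = path$area, E = path$E, tag = path$tag)
      }
      t_cur <- t_exit
    }
  }
  out
}

# Geometry of a fiber line at natural-line coordinate s in [-1, 1]:
# direction cosines, metric h = |dx/ds| and the host B matrix.
fiber_kinematics <- function(coords, xi_m, xi_n, s) {
  xi <- (xi_m + xi_n) / 2 + s * (xi_n - xi_m) / 2
  sm <- strain_matrix(coords, xi)
  dxi <- (xi_n - xi_m) / 2
  dx <- as.numeric(t(sm$J) %*% dxi)      # d x / d s
  h <- sqrt(sum(dx^2))
  list(B = sm$B, h = h, cosines = dx / h)
}

#' Fiber strain row of an embedded segment
#'
#' The axial fiber strain is the projection of the host strain,
#' `eps_p = [l^2, m^2, n^2, m*n, n*l, l*m] %*% eps` in Voigt order
#' (x, y, z, yz, zx, xy), giving a 1x24 row `B' = T B` over the host DOFs.
#'
#' @param coords 8x3 host element node coordinates.
#' @param segment One segment from [segment_fibers()].
#' @param s Position along the segment in natural line coordinates `[-1, 1]`.
#' @return 1x24 numeric row.
#' @export
fiber_strain_row <- function(coords, segment, s = 0) {
  fk <- fiber_kinematics(coords, segment$xi_m, segment$xi_n, s)
  d <- fk$cosines
  T_ <- c(d[1]^2, d[2]^2, d[3]^2, d[2] * d[3], d[3] * d[1], d[1] * d[2])
  matrix(T_, 1, 6) %*% fk$B
}

#' Stiffness contribution of an embedded fiber segment
#'
#' Two-point Gauss integration of `t(B') Ef B' A h` along the segment,
#' added over the host element's 24 DOFs.
#'
#' @param coords 8x3 host element node coordinates.
#' @param segment One segment from [segment_fibers()].
#' @param E Override axial modulus (default: the segment's).
#' @param area Override cross-section area (default: the segment's).
#' @return 24x24 symmetric positive semi-definite matrix.
#' @export
fiber_stiffness <- function(coords, segment, E = segment$E, area = segment$area) {
  gp <- c(-1, 1) / sqrt(3)
  k <- matrix(0, 24, 24)
  for (g in gp) {
    fk <- fiber_kinematics(coords, segment$xi_m, segment$xi_n, g)
    d <- fk$cosines
    T_ <- c(d[1]^2, d[2]^2, d[3]^2, d[2] * d[3], d[3] * d[1], d[1] * d[2])
    Bp <- matrix(T_, 1, 6) %*% fk$B
    k <- k + crossprod(Bp) * (E * area * fk$h)   # unit Gauss weights
  }
  (k + t(k)) / 2
}

#' Superpose fiber stiffness onto the matrix element stiffness
#'
#' @param km 24x24 matrix element stiffness.
#' @param fiber_ks List of 24x24 fiber contributions for the same element.
#' @return 24x24 combined stiffness `km + sum(k_f)`.
#' @export
superpose <- function(km, fiber_ks = list()) {
  Reduce(`+`, fiber_ks, km)
}
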