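#' Elliptical domain boundary
#'
#' @param semi_major,semi_minor semi-axes in mm (major along x).
#' @param n_vertices number of polygon vertices (inscribed; area converges
#'   to the ellipse area as the count grows).
#' @param centre centre of the ellipse.
#' @return a [boundary_curve()].
#' @export
make_ellipse_boundary <- function(semi_major, semi_minor, n_vertices = 128L,
                                  centre = c(0, 0)) {
  stopifnot(semi_major > 0, semi_minor > 0, n_vertices >= 8)
  t <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  boundary_curve(cbind(centre[1L] + semi_major * cos(t),
                       centre[2L] + semi_minor * sin(t)),
                 name = sprintf("ellipse_%g x %g", semi_major, semi_minor))
}

#' Synthetic barrel-field boundary
#'
#' A fixed, deterministic polygon standing in for the outline of the rat
#' posteromedial barrel subfield. Mirroring how the real outline is traced
#' around the barrels, it is constructed as the rounded convex hull
#' (support function plus margin) of the synthetic barreloid row/arc
#' layout mapped to cortical scale: elongated, about 4.6 x 2.6 mm at
#' `scale = 1`, wider on the many-arc (E-row) side, enclosing roughly
#' 7 mm^2. It is synthetic, not a tracing of real tissue.
#'
#' @param scale linear scale factor (area scales with its square).
#' @param n_vertices polygon resolution.
#' @param pitch barrel-to-barrel spacing in mm at scale 1.
#' @param margin outline clearance around the outermost barrel centres,
#'   in mm at scale 1.
#' @return a [boundary_curve()].
#' @export
make_barrelfield_boundary <- function(scale = 1, n_vertices = 96L,
                                      pitch = 0.34, margin = 0.3) {
  stopifnot(scale > 0)
  co <- make_barreloid_coordinates(barreloid_spec(pitch = pitch))
  pts <- cbind(co$p, co$q)
  pts <- sweep(pts, 2L, colMeans(pts))
  hull <- pts[rev(grDevices::chull(pts)), , drop = FALSE]  # CCW
  n <- nrow(hull)
  arc_step <- 2 * pi / n_vertices
  out <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(n)) {
    vp <- hull[if (i == 1L) n else i - 1L, ]
    v0 <- hull[i, ]
    vn <- hull[if (i == n) 1L else i + 1L, ]
    # outward normals of the incoming and outgoing edges (CCW polygon)
    nrm <- function(e) c(e[2L], -e[1L]) / sqrt(sum(e^2))
    a1 <- atan2(nrm(v0 - vp)[2L], nrm(v0 - vp)[1L])
    a2 <- atan2(nrm(vn - v0)[2L], nrm(vn - v0)[1L])
    da <- a2 - a1                    # CCW turn through the convex corner
    if (da < -1e-9) da <- da + 2 * pi
    if (da < 0 || da > 2 * pi - 1e-6) da <- 0  # collinear edges: no arc
    th <- a1 + seq(0, da, by = arc_step)
    if (th[length(th)] < a1 + da) th <- c(th, a1 + da)
    out <- rbind(out, cbind(v0[1L] + margin * cos(th),
                            v0[2L] + margin * sin(th)))
  }
  out <- out[!duplicated(round(out, 9L)), , drop = FALSE]
  boundary_curve(scale * out, name = "synthetic_barrelfield")
}

#' Barreloid layout specification
#'
#' The rat macrovibrissae layout: five rows (A-E) of whiskers plus four
#' interstitial "straddler" whiskers (alpha-delta) between the row ends.
#' The default arc counts sum with the straddlers to N = 41 labelled
#' projections. Only the count and the row/arc ordering semantics matter
#' to the model; the exact geometry is a documented approximation.
#'
#' @param rows row labels, posterior-to-anterior.
#' @param arcs_per_row whiskers per row.
#' @param straddlers labels of the interstitial whiskers (one between each
#'   adjacent row pair, at the arc-0 position).
#' @param pitch nominal whisker spacing in the thalamic reference plane.
#' @param jitter positional noise magnitude as a fraction of `pitch`.
#' @return object of class `barreloid_spec`.
#' @export
barreloid_spec <- function(rows = c("A", "B", "C", "D", "E"),
                           arcs_per_row = c(4L, 4L, 8L, 10L, 11L),
                           straddlers = c("alpha", "beta", "gamma", "delta"),
                           pitch = 1, jitter = 0) {
  stopifnot(length(rows) == length(arcs_per_row),
            length(straddlers) == length(rows) - 1L,
            pitch > 0, jitter >= 0)
  structure(list(rows = rows, arcs_per_row = arcs_per_row,
                 straddlers = straddlers, pitch = pitch, jitter = jitter),
            class = "barreloid_spec")
}

#' Synthetic barreloid coordinates
#'
#' Generates labelled (p, q) positions in the thalamic reference plane
#' (p: anterior-posterior arc axis, q: medial-lateral row axis). Rows are
#' spaced 1.1 pitch apart with a small per-row shear (the row curvature of
#' the real whisker pad), so that within-row neighbours are each label's
#' nearest neighbours; straddlers sit between row ends at the arc-0
#' position. With the default spec this yields exactly 41 labelled points.
#'
#' @param spec a [barreloid_spec()].
#' @param seed RNG seed (used only when `spec$jitter > 0`).
#' @return data.frame with columns `label`, `p`, `q`, and attributes `row`
#'   and `arc` columns for bookkeeping.
#' @export
make_barreloid_coordinates <- function(spec = barreloid_spec(), seed = 1L) {
  pitch <- spec$pitch
  shear <- 0.15 * pitch
  rowsep <- 1.1 * pitch
  recs <- list()
  for (r in seq_along(spec$rows)) {
    n_arc <- spec$arcs_per_row[r]
    recs[[r]] <- data.frame(
      label = paste0(spec$rows[r], seq_len(n_arc)),
      p = (seq_len(n_arc) - 1) * pitch + shear * (r - 1),
      q = -(r - 1) * rowsep,
      row = spec$rows[r], arc = seq_len(n_arc),
      stringsAsFactors = FALSE)
  }
  st <- data.frame(
    label = spec$straddlers,
    p = -pitch + shear * (seq_along(spec$straddlers) - 0.5),
    q = -(seq_along(spec$straddlers) - 0.5) * rowsep,
    row = spec$straddlers, arc = 0L,
    stringsAsFactors = FALSE)
  out <- rbind(do.call(rbind, recs), st)
  if (anyDuplicated(out$label)) stop("duplicate labels in barreloid spec")
  if (spec$jitter > 0) {
    out[, c("p", "q")] <- out[, c("p", "q")] + with_seed(
      seed, matrix(stats::runif(2 * nrow(out), -spec$jitter, spec$jitter),
                   ncol = 2L)) * pitch
  }
  rownames(out) <- NULL
  out
}

#' Map thalamic coordinates affinely into a cortical domain
#'
#' Places the (p, q) coordinate bounding box into the boundary's bounding
#' box, shrunk by `margin` on each side. Used to seed reference
#' tessellations when no real tracing is available.
#'
#' @param coords data.frame with columns p, q (and label).
#' @param boundary target [boundary_curve()].
#' @param margin fraction of the bounding box kept clear on each side.
#' @return N x 2 matrix of cortical (x, y) positions, rownames = labels.
#' @export
map_coords_to_domain <- function(coords, boundary, margin = 0.15) {
  v <- boundary$vertices
  bx <- range(v[, 1L]); by <- range(v[, 2L])
  bx <- bx + margin * diff(bx) * c(1, -1)
  by <- by + margin * diff(by) * c(1, -1)
  pr <- range(coords$p); qr <- range(coords$q)
  x <- bx[1L] + (coords$p - pr[1L]) / diff(pr) * diff(bx)
  y <- by[1L] + (coords$q - qr[1L]) / diff(qr) * diff(by)
  out <- cbind(x = x, y = y)
  rownames(out) <- coords$label
  out
}

#' Reference label map from a Voronoi tessellation of seed points
#'
#' Assigns every hex to its nearest seed point: the rasterization of the
#' Voronoi (Dirichlet) tessellation of the points, clipped to the lattice
#' domain. By construction its Honda delta tends to 0 as the lattice is
#' refined.
#'
#' @param points N x 2 matrix of cortical seed positions (rownames used as
#'   labels if present).
#' @param lattice a `hex_lattice`.
#' @param labels optional character labels (default rownames or 1..N).
#' @return a [label_map()].
#' @export
make_reference_labelmap <- function(points, lattice, labels = NULL) {
  points <- as.matrix(points)
  N <- nrow(points)
  if (is.null(labels)) {
    labels <- if (!is.null(rownames(points))) rownames(points)
              else as.character(seq_len(N))
  }
  v <- lattice$boundary$vertices
  inside <- pracma::inpolygon(points[, 1L], points[, 2L], v[, 1L], v[, 2L])
  if (!all(inside)) {
    warning(sprintf("%d seed point(s) outside the boundary; still assigned",
                    sum(!inside)))
  }
  d2 <- outer(lattice$centres[, 1L], points[, 1L], "-")^2 +
        outer(lattice$centres[, 2L], points[, 2L], "-")^2
  lab <- max.col(-d2, ties.method = "first")
  label_map_from_labels(lab, N, labels, lattice)
}
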