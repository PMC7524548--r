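#' Closed boundary curve for the cortical domain
#'
#' A boundary curve is a simple closed polygon, in mm, that delimits the
#' patch of cortical sheet on which the model runs (the barrel field
#' outline, an ellipse, ...). Vertices are stored open (the closing edge
#' from the last vertex back to the first is implicit).
#'
#' @param vertices two-column numeric matrix (or data.frame) of x, y
#'   coordinates in mm, in order around the outline. A repeated final
#'   vertex equal to the first is dropped.
#' @param name text label for the domain.
#' @return An object of class `boundary_curve` with elements `vertices`
#'   (n x 2 matrix) and `name`.
#' @export
boundary_curve <- function(vertices, name = "domain") {
  v <- as.matrix(vertices)
  if (ncol(v) != 2L || nrow(v) < 3L || !is.numeric(v) || anyNA(v)) {
    stop("vertices must be a numeric n x 2 matrix with n >= 3 and no NAs")
  }
  colnames(v) <- c("x", "y")
  if (isTRUE(all.equal(v[1L, ], v[nrow(v), ], check.attributes = FALSE))) {
    v <- v[-nrow(v), , drop = FALSE]
  }
  if (nrow(v) < 3L) stop("boundary polygon needs at least 3 distinct vertices")
  a <- polygon_area(v)
  if (a == 0) stop("boundary polygon has zero area")
  if (a < 0) v <- v[rev(seq_len(nrow(v))), , drop = FALSE]  # force CCW
  if (polygon_is_self_intersecting(v)) {
    stop("boundary polygon is self-intersecting")
  }
  structure(list(vertices = v, name = name), class = "boundary_curve")
}

#' @export
print.boundary_curve <- function(x, ...) {
  cat(sprintf("<boundary_curve '%s': %d vertices, area %.4f mm^2>\n",
              x$name, nrow(x$vertices), boundary_area(x)))
  invisible(x)
}

# Signed shoelace area; positive for counter-clockwise vertex order.
polygon_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

polygon_centroid <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# O(n^2) segment-pair crossing test; boundaries here have <= a few hundred
# vertices so this is never a bottleneck.
polygon_is_self_intersecting <- function(v) {
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]  # skip edges sharing a vertex
    if (!length(js)) next
    d1 <- cross2(seg[i, 1L], seg[i, 2L], seg[i, 3L], seg[i, 4L], seg[js, 1L], seg[js, 2L]) *
          cross2(seg[i, 1L], seg[i, 2L], seg[i, 3L], seg[i, 4L], seg[js, 3L], seg[js, 4L])
    d2 <- cross2(seg[js, 1L], seg[js, 2L], seg[js, 3L], seg[js, 4L], seg[i, 1L], seg[i, 2L]) *
          cross2(seg[js, 1L], seg[js, 2L], seg[js, 3L], seg[js, 4L], seg[i, 3L], seg[i, 4L])
    if (any(d1 < 0 & d2 < 0)) return(TRUE)
  }
  FALSE
}

#' Enclosed area of a boundary curve
#' @param boundary a [boundary_curve()].
#' @return area in mm^2.
#' @export
boundary_area <- function(boundary) abs(polygon_area(boundary$vertices))

#' The six hex-neighbour unit directions
#'
#' Neighbours of a hex are indexed j = 1..6 at fixed angles pi*(j-1)/3 from
#' the +x axis. All lattice operators (Laplacian, gradient, flux sums) use
#' this ordering.
#'
#' @return a 6 x 2 matrix of unit vectors, row j = (cos, sin) of pi*(j-1)/3.
#' @export
neighbour_directions <- function() {
  th <- pi * (0:5) / 3
  cbind(cos = cos(th), sin = sin(th))
}

# Axial-coordinate offsets matching neighbour_directions() row for row,
# under the centre convention x = d*(q + r/2), y = d*(sqrt(3)/2)*r.
axial_offsets <- function() {
  matrix(c(1L, 0L,  0L, 1L,  -1L, 1L,  -1L, 0L,  0L, -1L,  1L, -1L),
         ncol = 2L, byrow = TRUE)
}

#' Build a hexagonal lattice filling a boundary curve
#'
#' Tiles the plane with a regular triangular grid of spacing `d`, anchored
#' with one hex centre at `anchor` (by default the polygon centroid, axis 1
#' along +x), and keeps every hex whose centre falls inside the boundary
#' polygon. Each retained hex records its six neighbours in the fixed
#' angular order of [neighbour_directions()], with `NA` marking neighbours
#' whose centre lies outside the domain, its area
#' \eqn{\Omega = (\sqrt{3}/2) d^2}, and its Euclidean distance `d_b` to the
#' nearest point of the boundary outline.
#'
#' @param boundary a [boundary_curve()].
#' @param d hex-to-hex centre spacing in mm.
#' @param anchor optional length-2 numeric, the (x, y) of the grid origin
#'   hex; defaults to the polygon centroid. Exposed so that mirrored
#'   domains can anchor the grid on the mirror line.
#' @return An object of class `hex_lattice`: list with `d`, `centres`
#'   (H x 2), `nbr` (H x 6 integer, NA sentinel), `omega`, `edge_len`
#'   (= d/sqrt(3)), `d_b` (length H), `n_hex`, `boundary`, `anchor`.
#' @export
build_lattice <- function(boundary, d, anchor = NULL) {
  stopifnot(inherits(boundary, "boundary_curve"))
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 0) {
    stop("spacing d must be a single positive number")
  }
  omega <- sqrt(3) / 2 * d^2
  if (boundary_area(boundary) < omega) stop("domain too small")
  if (is.null(anchor)) anchor <- polygon_centroid(boundary$vertices)
  v <- boundary$vertices

  # candidate axial range covering the bounding box (one ring of slack)
  xr <- range(v[, 1L]) - anchor[1L]
  yr <- range(v[, 2L]) - anchor[2L]
  ry <- sqrt(3) / 2 * d
  r_rng <- floor(yr[1L] / ry - 1):ceiling(yr[2L] / ry + 1)
  grid <- do.call(rbind, lapply(r_rng, function(r) {
    q_rng <- floor(xr[1L] / d - r / 2 - 1):ceiling(xr[2L] / d - r / 2 + 1)
    cbind(q = q_rng, r = r)
  }))
  cx <- anchor[1L] + d * (grid[, 1L] + grid[, 2L] / 2)
  cy <- anchor[2L] + ry * grid[, 2L]

  inside <- pracma::inpolygon(cx, cy, v[, 1L], v[, 2L], boundary = FALSE)
  keep <- which(inside)
  if (!length(keep)) stop("domain too small")
  grid <- grid[keep, , drop = FALSE]
  centres <- cbind(x = cx[keep], y = cy[keep])

  idx <- new.env(hash = TRUE, size = length(keep))
  keyv <- paste(grid[, 1L], grid[, 2L])
  for (i in seq_along(keyv)) assign(keyv[i], i, envir = idx)
  off <- axial_offsets()
  nbr <- matrix(NA_integer_, nrow = nrow(grid), ncol = 6L)
  for (j in 1:6) {
    kj <- paste(grid[, 1L] + off[j, 1L], grid[, 2L] + off[j, 2L])
    nbr[, j] <- vapply(kj, function(k) {
      val <- idx[[k]]
      if (is.null(val)) NA_integer_ else as.integer(val)
    }, integer(1L), USE.NAMES = FALSE)
  }

  lat <- structure(list(
    d = d, centres = centres, nbr = nbr, omega = omega,
    edge_len = d / sqrt(3), d_b = rep(NA_real_, nrow(centres)),
    n_hex = nrow(centres), boundary = boundary, anchor = as.numeric(anchor)
  ), class = "hex_lattice")
  lat$d_b <- distance_to_boundary(lat, boundary)
  lat
}

#' @export
print.hex_lattice <- function(x, ...) {
  cat(sprintf("<hex_lattice: %d hexes, d = %g mm, area %.4f mm^2 ('%s')>\n",
              x$n_hex, x$d, x$n_hex * x$omega, x$boundary$name))
  invisible(x)
}

#' Distance from each hex centre to the boundary outline
#'
#' @param lattice a [build_lattice()] result (only `centres` is used).
#' @param boundary the boundary the lattice was built from.
#' @return numeric vector of Euclidean point-to-polyline distances in mm.
#' @export
distance_to_boundary <- function(lattice, boundary) {
  p <- lattice$centres
  v <- boundary$vertices
  n <- nrow(v)
  dmin <- rep(Inf, nrow(p))
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1L else i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      di <- sqrt((p[, 1L] - a[1L])^2 + (p[, 2L] - a[2L])^2)
    } else {
      t <- ((p[, 1L] - a[1L]) * ab[1L] + (p[, 2L] - a[2L]) * ab[2L]) / len2
      t <- pmin(1, pmax(0, t))
      di <- sqrt((p[, 1L] - (a[1L] + t * ab[1L]))^2 +
                 (p[, 2L] - (a[2L] + t * ab[2L]))^2)
    }
    dmin <- pmin(dmin, di)
  }
  dmin
}

#' @rdname boundary_io
#' @export
read_boundary_csv <- function(path, name = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("x_mm", "y_mm") %in% names(df))) {
    stop("boundary CSV must have header 'x_mm,y_mm'")
  }
  boundary_curve(cbind(df$x_mm, df$y_mm),
                 name = if (is.null(name)) basename(path) else name)
}

#' Boundary curve file I/O
#'
#' Boundaries round-trip through CSV (`x_mm,y_mm` header) or SVG. The SVG
#' reader takes the first `<path>` or `<polygon>` element; path data may use
#' M/L/H/V/C/Z commands (absolute or relative), with cubic segments
#' flattened to chords at tolerance `tol` (mm, default 0.005). SVG user
#' units are taken as mm.
#'
#' @param path file path.
#' @param boundary a [boundary_curve()] (writers).
#' @param name optional domain name (readers).
#' @param tol chord-flattening tolerance in mm for curved SVG segments.
#' @name boundary_io
#' @export
write_boundary_csv <- function(boundary, path) {
  utils::write.csv(data.frame(x_mm = boundary$vertices[, 1L],
                              y_mm = boundary$vertices[, 2L]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname boundary_io
#' @export
read_boundary_svg <- function(path, name = NULL, tol = 0.005) {
  doc <- xml2::read_xml(path)
  nm <- if (is.null(name)) basename(path) else name
  poly <- xml2::xml_find_first(doc, ".//*[local-name()='polygon']")
  if (!inherits(poly, "xml_missing")) {
    pts <- as.numeric(strsplit(trimws(xml2::xml_attr(poly, "points")),
                               "[,[:space:]]+")[[1L]])
    return(boundary_curve(matrix(pts, ncol = 2L, byrow = TRUE), name = nm))
  }
  pth <- xml2::xml_find_first(doc, ".//*[local-name()='path']")
  if (inherits(pth, "xml_missing")) stop("no <path> or <polygon> element in SVG")
  boundary_curve(flatten_svg_path(xml2::xml_attr(pth, "d"), tol), name = nm)
}

# Minimal SVG path-data interpreter: M/m, L/l, H/h, V/v, C/c, Z/z.
flatten_svg_path <- function(d, tol = 0.005) {
  toks <- regmatches(d, gregexpr("[MmLlHhVvCcZz]|-?[0-9.eE+-]+", d))[[1L]]
  pts <- matrix(numeric(0), ncol = 2L)
  cur <- c(0, 0); start <- c(0, 0); cmd <- ""
  i <- 1L
  num <- function(k) as.numeric(toks[k])
  while (i <= length(toks)) {
    if (grepl("^[A-Za-z]$", toks[i])) { cmd <- toks[i]; i <- i + 1L }
    rel <- cmd %in% c("m", "l", "h", "v", "c")
    base <- if (rel) cur else c(0, 0)
    switch(tolower(cmd),
      m = { cur <- base + c(num(i), num(i + 1L)); i <- i + 2L
            start <- cur; pts <- rbind(pts, cur)
            cmd <- if (cmd == "m") "l" else "L" },
      l = { cur <- base + c(num(i), num(i + 1L)); i <- i + 2L
            pts <- rbind(pts, cur) },
      h = { cur <- c(base[1L] + num(i), cur[2L]); i <- i + 1L
            pts <- rbind(pts, cur) },
      v = { cur <- c(cur[1L], base[2L] + num(i)); i <- i + 1L
            pts <- rbind(pts, cur) },
      c = { p1 <- base + c(num(i), num(i + 1L))
            p2 <- base + c(num(i + 2L), num(i + 3L))
            p3 <- base + c(num(i + 4L), num(i + 5L)); i <- i + 6L
            seg <- flatten_cubic(cur, p1, p2, p3, tol)
            pts <- rbind(pts, seg)
            cur <- p3 },
      z = { cur <- start },
      stop("unsupported SVG path command: ", cmd)
    )
  }
  pts
}

flatten_cubic <- function(p0, p1, p2, p3, tol) {
  # chord count from a bound on the deviation of a cubic from its chord
  dev <- max(sqrt(sum((p1 - p0)^2)), sqrt(sum((p2 - p3)^2)))
  n <- max(2L, min(64L, ceiling(sqrt(dev / max(tol, 1e-9)) * 4)))
  t <- seq(0, 1, length.out = n + 1L)[-1L]
  b <- function(pa, pb, pc, pd) {
    (1 - t)^3 * pa + 3 * (1 - t)^2 * t * pb + 3 * (1 - t) * t^2 * pc + t^3 * pd
  }
  cbind(b(p0[1L], p1[1L], p2[1L], p3[1L]), b(p0[2L], p1[2L], p2[2L], p3[2L]))
}

#' @rdname boundary_io
#' @export
write_boundary_svg <- function(boundary, path) {
  v <- boundary$vertices
  pts <- paste(sprintf("%.6f,%.6f", v[, 1L], v[, 2L]), collapse = " ")
  xml <- paste0(
    '<?xml version="1.0"?>\n<svg xmlns="http://www.w3.org/2000/svg">',
    '<polygon points="', pts, '" fill="none" stroke="black"/></svg>\n')
  writeLines(xml, path)
  invisible(path)
}

#' Export a lattice to CSV
#'
#' Columns: `index, x_mm, y_mm, d_b_mm, n1..n6`; missing neighbours are
#' written as -1.
#'
#' @param lattice a `hex_lattice`.
#' @param path output file.
#' @export
write_lattice_csv <- function(lattice, path) {
  nbr <- lattice$nbr
  nbr[is.na(nbr)] <- -1L
  df <- data.frame(index = seq_len(lattice$n_hex),
                   x_mm = lattice$centres[, 1L], y_mm = lattice$centres[, 2L],
                   d_b_mm = lattice$d_b)
  for (j in 1:6) df[[paste0("n", j)]] <- nbr[, j]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Clip a boundary polygon to a half-plane and mirror it
#'
#' Used by the Fgf8 mirror-duplication experiment: the domain is cut at the
#' vertical line `x = x_cut` (keeping the part with x <= x_cut), and the cut
#' shape is joined with its reflection across that line, producing a single
#' mirror-symmetric polygon with a straight join.
#'
#' @param boundary a [boundary_curve()].
#' @param x_cut x-position of the join line in mm; defaults to 98% of the
#'   way to the right edge, so that the cut removes only a sliver.
#' @return list with `boundary` (the doubled [boundary_curve()]) and
#'   `x_join` (the join line).
#' @export
mirror_boundary <- function(boundary, x_cut = NULL) {
  v <- boundary$vertices
  if (is.null(x_cut)) {
    xr <- range(v[, 1L])
    x_cut <- xr[1L] + 0.98 * diff(xr)
  }
  left <- clip_halfplane_left(v, x_cut)
  if (nrow(left) < 3L) stop("x_cut leaves no domain to mirror")
  # rotate the clipped outline so it runs join-point -> ... -> join-point,
  # with the closing edge being the join segment; the doubled outline is
  # then the path plus its reflection traversed backwards (shared join
  # points dropped), which contains no edge along the join line itself
  n <- nrow(left)
  on_join <- abs(left[, 1L] - x_cut) < 1e-9
  k <- which(on_join & on_join[c(2:n, 1L)])  # edge k -> k+1 lies on the join
  if (length(k) != 1L) {
    stop("x_cut must cross the boundary exactly twice")
  }
  ord <- c(if (k < n) (k + 1L):n else integer(0), if (k > 0L) 1L:k)
  path <- left[ord, , drop = FALSE]          # starts and ends on the join
  interior <- path[-c(1L, nrow(path)), , drop = FALSE]
  mirrored <- cbind(2 * x_cut - interior[, 1L], interior[, 2L])
  seq_all <- rbind(path, mirrored[rev(seq_len(nrow(mirrored))), , drop = FALSE])
  out <- boundary_curve(seq_all[!duplicated(round(seq_all, 9L)), , drop = FALSE],
                        name = paste0(boundary$name, "+mirror"))
  list(boundary = out, x_join = x_cut)
}

# Sutherland-Hodgman against the half-plane x <= x_cut.
clip_halfplane_left <- function(v, x_cut) {
  n <- nrow(v)
  out <- matrix(numeric(0), ncol = 2L)
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1L else i + 1L, ]
    ain <- a[1L] <= x_cut; bin <- b[1L] <= x_cut
    if (ain) out <- rbind(out, a)
    if (xor(ain, bin)) {
      t <- (x_cut - a[1L]) / (b[1L] - a[1L])
      out <- rbind(out, c(x_cut, a[2L] + t * (b[2L] - a[2L])))
    }
  }
  out
}
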