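#' Winner-take-all label map and region geometry
#'
#' Labels each hex with the projection whose connection density is maximal
#' (ties broken by lowest projection index). Hexes whose total connection
#' density is below 1e-12 fall back to the argmax of the branching density
#' `a` when supplied, and to projection 1 otherwise. The derived geometry
#' comprises per-region areas (hex count times \eqn{\Omega}), centroids
#' (unweighted means of member hex centres), the adjacency matrix `V`
#' (border length between each pair of regions: shared hex-edge count
#' times the hex edge length), and total border lengths `b` (internal
#' borders plus the border with the domain exterior).
#'
#' @param c H x N matrix of connection densities (or a `sim_state`).
#' @param lattice a `hex_lattice`.
#' @param a optional H x N branching densities for the fallback.
#' @param labels optional character vector of N projection labels.
#' @return object of class `label_map`: list with `label` (per-hex integer),
#'   `labels`, `areas`, `centroids`, `V`, `b`, `n_labels`.
#' @export
label_map <- function(c, lattice, a = NULL, labels = NULL) {
  if (inherits(c, "sim_state")) {
    if (is.null(a)) a <- c$a
    c <- c$c
  }
  N <- ncol(c)
  lab <- max.col(c, ties.method = "first")
  weak <- rowSums(c) <= 1e-12
  if (any(weak)) {
    lab[weak] <- if (!is.null(a)) max.col(a[weak, , drop = FALSE],
                                          ties.method = "first") else 1L
  }
  if (is.null(labels)) labels <- as.character(seq_len(N))
  label_map_from_labels(lab, N, labels, lattice)
}

#' @rdname label_map
#' @param lab per-hex integer label vector in 1..N.
#' @param N number of labels.
#' @export
label_map_from_labels <- function(lab, N, labels, lattice) {
  stopifnot(length(lab) == lattice$n_hex, all(lab >= 1L & lab <= N))
  v <- lattice$edge_len
  areas <- tabulate(lab, N) * lattice$omega
  centroids <- matrix(NA_real_, N, 2L)
  for (i in seq_len(N)) {
    m <- lab == i
    if (any(m)) centroids[i, ] <- colMeans(lattice$centres[m, , drop = FALSE])
  }
  V <- matrix(0, N, N)
  ext <- numeric(N)
  for (j in 1:6) {
    q <- lattice$nbr[, j]
    miss <- is.na(q)
    if (any(miss)) {
      tb <- tabulate(lab[miss], N)
      ext <- ext + tb * v
    }
    ok <- which(!miss)
    li <- lab[ok]
    lj <- lab[q[ok]]
    dif <- li != lj
    if (any(dif)) {
      idx <- (lj[dif] - 1L) * N + li[dif]
      tb <- tabulate(idx, N * N)
      V <- V + matrix(tb, N, N) * v
    }
  }
  dimnames(V) <- list(labels, labels)
  names(areas) <- labels
  rownames(centroids) <- labels
  structure(list(label = lab, labels = labels, areas = areas,
                 centroids = centroids, V = V, b = rowSums(V) + ext,
                 n_labels = N),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  nz <- sum(x$areas > 0)
  cat(sprintf("<label_map: %d/%d regions occupied, total area %.4f mm^2>\n",
              nz, x$n_labels, sum(x$areas)))
  invisible(x)
}

# internal region borders as a list of (pair, vertex matrix): vertices are
# midpoints of shared hex edges, i.e. midpoints between neighbouring centres
internal_borders <- function(map, lattice) {
  out <- list()
  lab <- map$label
  for (j in 1:3) {  # each unordered neighbour pair appears once in j = 1..3
    q <- lattice$nbr[, j]
    ok <- which(!is.na(q))
    p <- ok
    qq <- q[ok]
    dif <- lab[p] != lab[qq]
    if (!any(dif)) next
    p <- p[dif]; qq <- qq[dif]
    i1 <- pmin(lab[p], lab[qq])
    i2 <- pmax(lab[p], lab[qq])
    mid <- (lattice$centres[p, , drop = FALSE] +
            lattice$centres[qq, , drop = FALSE]) / 2
    key <- paste(i1, i2)
    for (k in unique(key)) {
      sel <- key == k
      if (is.null(out[[k]])) {
        out[[k]] <- list(pair = c(i1[sel][1L], i2[sel][1L]),
                         verts = mid[sel, , drop = FALSE])
      } else {
        out[[k]]$verts <- rbind(out[[k]]$verts, mid[sel, , drop = FALSE])
      }
    }
  }
  out
}

honda_objective <- function(z, edges) {
  sc <- vapply(edges, function(e) {
    zi <- z[e$pair[1L], ]
    zj <- z[e$pair[2L], ]
    dz <- sqrt(sum((zi - zj)^2))
    if (dz < 1e-12) return(Inf)
    di <- sqrt((e$verts[, 1L] - zi[1L])^2 + (e$verts[, 2L] - zi[2L])^2)
    dj <- sqrt((e$verts[, 1L] - zj[1L])^2 + (e$verts[, 2L] - zj[2L])^2)
    mean(abs(di - dj)) / dz
  }, numeric(1L))
  mean(sc)
}

#' Voronoi-conformance metric (Honda delta)
#'
#' Measures how far a tessellation departs from a Dirichlet (Voronoi)
#' tessellation. One generator point per region is initialized at the
#' region centroid; for every internal border, each border vertex's
#' deviation is the absolute difference of its distances to the two
#' adjacent generators, normalized by the generator separation; an edge
#' scores the mean deviation of its vertices and delta is the mean over
#' edges. The generator positions are then adjusted by derivative-free
#' local optimization (coordinate-wise Nelder-Mead sweeps) and the
#' minimized delta is returned. For an exact Voronoi pattern delta tends
#' to 0 as the lattice is refined; real barrel fields score about 0.05.
#'
#' @param map a [label_map()].
#' @param lattice the lattice it was computed on.
#' @param max_sweeps upper bound on coordinate-descent refinement sweeps
#'   after the joint quasi-Newton fit; sweeps stop early once a full sweep
#'   improves delta by less than `tol`.
#' @param tol convergence tolerance on delta between sweeps.
#' @param optimize set `FALSE` to evaluate at the centroids only.
#' @return the minimized delta (dimensionless).
#' @export
honda_delta <- function(map, lattice, max_sweeps = 3L, tol = 1e-4,
                        optimize = TRUE) {
  if (sum(map$areas > 0) < 2L) stop("need at least 2 regions")
  edges <- internal_borders(map, lattice)
  if (!length(edges)) stop("no internal borders between regions")
  z <- map$centroids
  regions <- sort(unique(unlist(lapply(edges, `[[`, "pair"))))
  if (!optimize) return(honda_objective(z, edges))

  # each generator is confined to its own region's bounding box (one hex of
  # slack): without this constraint the normalized deviation can be driven
  # to zero on any map by scattering the generators far from the domain
  lo <- z; hi <- z
  for (r in regions) {
    m <- map$label == r
    lo[r, ] <- apply(lattice$centres[m, , drop = FALSE], 2L, min) - lattice$d
    hi[r, ] <- apply(lattice$centres[m, , drop = FALSE], 2L, max) + lattice$d
  }
  z <- pmin(pmax(z, lo), hi)

  # a tessellation-like map has ~3 internal borders per region; far more
  # means a fragmented (disorganized) map whose delta is large regardless,
  # so the optimization budget is cut rather than spent polishing it
  fragmented <- length(edges) > 4L * length(regions)

  # joint quasi-Newton fit over all generator coordinates; the objective is
  # piecewise smooth and averaging over many border vertices keeps the
  # numerical gradient well behaved in practice
  act <- regions
  fit <- stats::optim(as.vector(z[act, , drop = FALSE]), function(par) {
    z2 <- z
    z2[act, ] <- matrix(par, ncol = 2L)
    honda_objective(z2, edges)
  }, method = "L-BFGS-B",
  lower = as.vector(lo[act, , drop = FALSE]),
  upper = as.vector(hi[act, , drop = FALSE]),
  control = list(maxit = if (fragmented) 25L else 200L, factr = 1e4))
  z[act, ] <- matrix(fit$par, ncol = 2L)
  if (fragmented) return(honda_objective(z, edges))

  # derivative-free coordinate refinement (robust to kinks the quasi-Newton
  # step may stall on)
  touch <- lapply(regions, function(r) {
    which(vapply(edges, function(e) r %in% e$pair, logical(1L)))
  })
  edge_score <- function(e, zi, zj) {
    dz <- sqrt(sum((zi - zj)^2))
    if (dz < 1e-12) return(1e6)
    di <- sqrt((e$verts[, 1L] - zi[1L])^2 + (e$verts[, 2L] - zi[2L])^2)
    dj <- sqrt((e$verts[, 1L] - zj[1L])^2 + (e$verts[, 2L] - zj[2L])^2)
    mean(abs(di - dj)) / dz
  }
  prev <- honda_objective(z, edges)
  for (s in seq_len(max_sweeps)) {
    for (ri in seq_along(regions)) {
      r <- regions[ri]
      er <- edges[touch[[ri]]]
      fn <- function(zr) {
        # edges not touching r are constant; the global mean differs from
        # this partial sum by a constant, so the argmin is unchanged.
        # stay inside the region bounding box (quadratic penalty)
        pen <- sum(pmax(0, lo[r, ] - zr)^2 + pmax(0, zr - hi[r, ])^2)
        pen * 1e4 + sum(vapply(er, function(e) {
          zi <- if (e$pair[1L] == r) zr else z[e$pair[1L], ]
          zj <- if (e$pair[2L] == r) zr else z[e$pair[2L], ]
          edge_score(e, zi, zj)
        }, numeric(1L)))
      }
      res <- stats::optim(z[r, ], fn, method = "Nelder-Mead",
                          control = list(maxit = 150L, reltol = 1e-8))
      z[r, ] <- res$par
    }
    cur <- honda_objective(z, edges)
    if (prev - cur < tol) { prev <- min(prev, cur); break }
    prev <- cur
  }
  prev
}

#' Pattern difference between two tessellations
#'
#' \deqn{\eta = \frac{\frac{1}{N}\sum_i |A_i^{sim} - A_i^{ref}| \times
#'   \frac{1}{N}\sum_i \lVert V_i^{sim} - V_i^{ref} \rVert}
#'   {\frac{1}{N}\sum_i \frac{V_i^{sim}}{b_i^{sim}} \cdot
#'    \frac{V_i^{ref}}{b_i^{ref}}}}
#' combining per-region area differences, adjacency-vector differences
#' (Euclidean norm over the N-vector of border lengths), and a normalized
#' adjacency-overlap denominator. Units mm^3. Regions are matched by
#' label; a region absent from one map contributes zero vectors. Returns
#' `Inf` when the maps share no adjacency structure at all.
#'
#' @param sim,ref two [label_map()]s with the same label set.
#' @return eta in mm^3.
#' @export
pattern_difference <- function(sim, ref) {
  labs <- ref$labels
  if (!setequal(labs, sim$labels)) stop("label sets differ between maps")
  N <- length(labs)
  o_s <- match(labs, sim$labels)
  A_s <- sim$areas[o_s]
  A_r <- ref$areas
  V_s <- sim$V[o_s, o_s, drop = FALSE]
  V_r <- ref$V
  b_s <- sim$b[o_s]
  b_r <- ref$b
  term_area <- mean(abs(A_s - A_r))
  term_vdiff <- mean(sqrt(rowSums((V_s - V_r)^2)))
  ns <- ifelse(b_s > 0, 1 / b_s, 0)
  nr <- ifelse(b_r > 0, 1 / b_r, 0)
  term_dot <- mean(rowSums((V_s * ns) * (V_r * nr)))
  if (term_dot == 0) return(Inf)
  term_area * term_vdiff / term_dot
}

#' Connection selectivity
#'
#' \eqn{\mu(x) = \max_i c_i(x) / \sum_j c_j(x)}, the winner's share of the
#' total connection density at each cortical site (set to 1/N where the
#' total is below 1e-12, the no-information convention), and its integral
#' \eqn{\omega = \sum_{hex} \mu\,\Omega} over the domain.
#'
#' @param c H x N matrix of connection densities (or a `sim_state`).
#' @param lattice a `hex_lattice`.
#' @return list with `mu` (per-hex) and `omega` (mm^2).
#' @export
selectivity <- function(c, lattice) {
  if (inherits(c, "sim_state")) c <- c$c
  tot <- rowSums(c)
  mx <- do.call(pmax, c(as.data.frame(c), list(na.rm = FALSE)))
  mu <- ifelse(tot <= 1e-12, 1 / ncol(c), mx / tot)
  list(mu = mu, omega = sum(mu) * lattice$omega)
}

#' Connected components of a label map
#'
#' Counts maximal sets of same-labelled hexes connected through the
#' neighbour table. A well-formed single barrel field has one component
#' per occupied label; a mirror-duplicated field has two.
#'
#' @param map a [label_map()].
#' @param lattice the lattice.
#' @return list with `n_components`, `component` (per-hex component id),
#'   `component_label` (label index of each component), and `sizes` (hex
#'   count per component; callers that regard tiny border slivers as
#'   rasterization artifacts can filter on it).
#' @export
count_components <- function(map, lattice) {
  lab <- map$label
  H <- lattice$n_hex
  comp <- integer(H)
  nc <- 0L
  for (s in seq_len(H)) {
    if (comp[s] != 0L) next
    nc <- nc + 1L
    queue <- s
    comp[s] <- nc
    while (length(queue)) {
      p <- queue[[1L]]
      queue <- queue[-1L]
      nb <- lattice$nbr[p, ]
      nb <- nb[!is.na(nb)]
      nb <- nb[comp[nb] == 0L & lab[nb] == lab[p]]
      comp[nb] <- nc
      queue <- c(queue, nb)
    }
  }
  list(n_components = nc, component = comp,
       component_label = lab[match(seq_len(nc), comp)],
       sizes = tabulate(comp, nc))
}

#' Export metric series to CSV
#' @param metrics data.frame with columns step, delta, eta, omega.
#' @param path output file.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics[, c("step", "delta", "eta", "omega")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Export a label map
#'
#' CSV: columns `index,label` (label as text). SVG: coloured hexes with
#' region labels at centroids.
#'
#' @param map a [label_map()].
#' @param lattice the lattice.
#' @param path output file.
#' @name labelmap_io
#' @export
write_labelmap_csv <- function(map, path) {
  utils::write.csv(data.frame(index = seq_along(map$label),
                              label = map$labels[map$label]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname labelmap_io
#' @export
write_labelmap_svg <- function(map, lattice, path) {
  r <- lattice$edge_len
  th <- pi * (2 * (0:5) + 1) / 6  # hexagon corner angles (flat-side up)
  hx <- r * cos(th)
  hy <- r * sin(th)
  cols <- grDevices::hcl(h = seq(15, 375, length.out = map$n_labels + 1L)[-1L],
                         l = 65, c = 100)
  lines <- c('<?xml version="1.0"?>',
             '<svg xmlns="http://www.w3.org/2000/svg">',
             '<g transform="scale(100,-100)">')
  for (p in seq_along(map$label)) {
    pts <- paste(sprintf("%.5f,%.5f",
                         lattice$centres[p, 1L] + hx,
                         lattice$centres[p, 2L] + hy), collapse = " ")
    lines <- c(lines, sprintf('<polygon points="%s" fill="%s"/>',
                              pts, cols[map$label[p]]))
  }
  for (i in seq_len(map$n_labels)) {
    if (!is.na(map$centroids[i, 1L]) && map$areas[i] > 0) {
      lines <- c(lines, sprintf(
        '<text x="%.5f" y="%.5f" font-size="0.08" transform="scale(1,-1)" text-anchor="middle">%s</text>',
        map$centroids[i, 1L], -map$centroids[i, 2L], map$labels[i]))
    }
  }
  lines <- c(lines, "</g></svg>")
  writeLines(lines, path)
  invisible(path)
}
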