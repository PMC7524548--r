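#' Guidance field specification
#'
#' Describes one molecular guidance gradient over the cortical sheet.
#' `linear` fields vary linearly along orientation `phi`; `offset-logistic`
#' fields are sigmoidal along `phi`, centred at a fraction `offset` of the
#' domain's extent with transition width `width` (fractions of the extent).
#'
#' @param kind one of `"linear"`, `"offset-logistic"`.
#' @param phi gradient orientation in degrees from the +x axis.
#' @param gain overall gain applied after normalization.
#' @param offset centre of the sigmoid as a fraction of the span (only for
#'   `offset-logistic`).
#' @param width sigmoid transition width as a fraction of the span.
#' @param noise_mag uniform noise magnitude (fraction of the field range).
#' @param noise_scale Gaussian smoothing width for the noise, mm.
#' @return object of class `guidance_field_spec`.
#' @export
guidance_field_spec <- function(kind = "linear", phi = 0, gain = 1,
                                offset = 0.5, width = 0.1,
                                noise_mag = 0, noise_scale = 0) {
  kind <- match.arg(kind, c("linear", "offset-logistic"))
  stopifnot(is.finite(gain), noise_mag >= 0, noise_scale >= 0)
  structure(list(kind = kind, phi = phi, gain = gain, offset = offset,
                 width = width, noise_mag = noise_mag,
                 noise_scale = noise_scale),
            class = "guidance_field_spec")
}

new_guidance_field <- function(rho, grad, spec, lattice) {
  structure(list(rho = rho, grad_rho = grad, spec = spec,
                 n_hex = lattice$n_hex),
            class = "guidance_field")
}

#' Construct a guidance field on a lattice
#'
#' The field coordinate \eqn{u = x\cos\phi + y\sin\phi} is min-max
#' normalized to \[0, 1\] over the lattice before the gain is applied, so
#' that gains and interaction strengths are comparable across domains.
#' Linear fields carry their (constant) analytic gradient;
#' offset-logistic fields carry the analytic sigmoid gradient.
#'
#' @param lattice a `hex_lattice`.
#' @param spec a [guidance_field_spec()].
#' @return object of class `guidance_field` with `rho` (per-hex scalar) and
#'   `grad_rho` (H x 2 matrix, units 1/mm).
#' @export
make_guidance_field <- function(lattice, spec) {
  if (lattice$n_hex < 1L) stop("empty lattice")
  phi <- spec$phi * pi / 180
  u <- lattice$centres[, 1L] * cos(phi) + lattice$centres[, 2L] * sin(phi)
  ur <- range(u)
  if (diff(ur) == 0) stop("degenerate lattice extent along phi")
  s <- (u - ur[1L]) / diff(ur)
  if (spec$kind == "linear") {
    rho <- spec$gain * s
    slope <- spec$gain / diff(ur)
    grad <- cbind(x = rep(slope * cos(phi), lattice$n_hex),
                  y = rep(slope * sin(phi), lattice$n_hex))
  } else {
    w <- spec$width
    z <- (s - spec$offset) / w
    sig <- 1 / (1 + exp(-z))
    rho <- spec$gain * sig
    dslope <- spec$gain * sig * (1 - sig) / (w * diff(ur))
    grad <- cbind(x = dslope * cos(phi), y = dslope * sin(phi))
  }
  new_guidance_field(rho, grad, spec, lattice)
}

#' @rdname make_guidance_field
#' @param phi,gain shorthand for a linear [guidance_field_spec()].
#' @export
make_linear_field <- function(lattice, phi = 0, gain = 1) {
  make_guidance_field(lattice, guidance_field_spec("linear", phi = phi,
                                                   gain = gain))
}

#' Add smoothed uniform noise to a guidance field
#'
#' Adds \eqn{(\rho_{max}-\rho_{min})\,U(0,\nu_\rho)} independently per hex,
#' then convolves over the lattice with a 2D Gaussian kernel of standard
#' deviation `sigma_rho` (mm). The kernel is evaluated at hex-centre
#' offsets and renormalized per hex, so hexes near the rim are averaged
#' over their available in-domain neighbourhood without zero-padding bias.
#' The gradient is recomputed numerically with the lattice operator.
#'
#' @param field a `guidance_field`.
#' @param lattice the lattice it lives on.
#' @param nu_rho noise magnitude (>= 0); 0 returns the field unchanged.
#' @param sigma_rho smoothing width in mm; 0 skips smoothing.
#' @param seed RNG seed.
#' @return a new `guidance_field`.
#' @export
add_field_noise <- function(field, lattice, nu_rho, sigma_rho = 0, seed = 1L) {
  stopifnot(nu_rho >= 0, sigma_rho >= 0)
  if (nu_rho == 0) return(field)
  rng <- diff(range(field$rho))
  noise <- with_seed(seed, stats::runif(lattice$n_hex, 0, nu_rho)) * rng
  rho <- field$rho + noise
  if (sigma_rho > 0) {
    rho <- cpp_gauss_smooth(lattice$centres, rho, sigma_rho)
  }
  new_guidance_field(rho, hex_gradient(rho, lattice), field$spec, lattice)
}

#' Mirror a guidance field across a join line
#'
#' For the mirror-duplication (Fgf8 misexpression) experiment: on a domain
#' doubled by reflection across the vertical line `x = x_join`, the field's
#' values on the mirrored half are the reflection of the original half. The
#' original half keeps the formula it has on the single domain (the
#' normalization span is taken from the original-half hexes), so
#' restricting the mirrored field to the original half reproduces the
#' unmirrored field. The gradient is computed with the lattice operator
#' (it is discontinuous across the join).
#'
#' @param field a `guidance_field` built on the original (single) lattice;
#'   only its spec is used.
#' @param duplicated_lattice the doubled lattice (see [mirror_boundary()]).
#' @param x_join the join line.
#' @param tol relative tolerance for the lattice mirror-symmetry check.
#' @return a `guidance_field` on the duplicated lattice.
#' @export
mirror_field <- function(field, duplicated_lattice, x_join, tol = 1e-6) {
  lat <- duplicated_lattice
  check_mirror_symmetric(lat, x_join, tol)
  spec <- field$spec
  phi <- spec$phi * pi / 180
  x <- lat$centres[, 1L]
  y <- lat$centres[, 2L]
  x_eff <- ifelse(x <= x_join, x, 2 * x_join - x)
  u <- x_eff * cos(phi) + y * sin(phi)
  left <- x <= x_join
  ur <- range(u[left])
  s <- (u - ur[1L]) / diff(ur)
  rho <- if (spec$kind == "linear") {
    spec$gain * s
  } else {
    spec$gain / (1 + exp(-(s - spec$offset) / spec$width))
  }
  new_guidance_field(rho, hex_gradient(rho, lat), spec, lat)
}

#' Extend a guidance field over a doubled domain without mirroring
#'
#' The complement of [mirror_field()]: the field formula simply continues
#' across the join (used for the guidance axis orthogonal to the
#' duplication). The normalization span is again taken from the
#' original-half hexes so the original half matches the single-domain
#' field.
#'
#' @inheritParams mirror_field
#' @export
extend_field <- function(field, duplicated_lattice, x_join) {
  lat <- duplicated_lattice
  spec <- field$spec
  phi <- spec$phi * pi / 180
  u <- lat$centres[, 1L] * cos(phi) + lat$centres[, 2L] * sin(phi)
  left <- lat$centres[, 1L] <= x_join
  ur <- range(u[left])
  s <- (u - ur[1L]) / diff(ur)
  rho <- if (spec$kind == "linear") {
    spec$gain * s
  } else {
    spec$gain / (1 + exp(-(s - spec$offset) / spec$width))
  }
  new_guidance_field(rho, hex_gradient(rho, lat), spec, lat)
}

check_mirror_symmetric <- function(lattice, x_join, tol = 1e-6) {
  p <- lattice$centres
  refl <- cbind(2 * x_join - p[, 1L], p[, 2L])
  # every reflected centre must coincide with some centre
  key <- function(m) paste(round(m[, 1L] / (lattice$d * 1e-6)),
                           round(m[, 2L] / (lattice$d * 1e-6)))
  ok <- key(refl) %in% key(p)
  if (mean(ok) < 1 - tol - 1e-12) {
    stop("lattice not symmetric about the join")
  }
  invisible(TRUE)
}

#' Thalamic interaction matrix from barreloid coordinates
#'
#' Each projection's sensitivities to the two cortical guidance fields are
#' read off its barreloid's position in the thalamic reference plane: each
#' coordinate axis is affinely mapped so its extremes land on -2 and +2.
#' The scaling is arbitrary in the model (coordinates carry relative
#' position information only); +/-2 is the conventional range.
#'
#' @param coords data.frame with columns `label`, `p`, `q` (thalamic
#'   coordinates of N labelled barreloid centres).
#' @param lim half-range of the scaled interaction strengths (default 2).
#' @return object of class `interaction_matrix`: list with `gamma` (N x 2
#'   matrix, rownames = labels) and `labels`.
#' @export
scale_interactions <- function(coords, lim = 2) {
  stopifnot(all(c("label", "p", "q") %in% names(coords)), nrow(coords) >= 2)
  if (anyDuplicated(coords$label)) stop("labels must be unique")
  sc <- function(v) {
    r <- range(v)
    if (diff(r) == 0) stop("degenerate axis: all coordinates equal")
    -lim + 2 * lim * (v - r[1L]) / diff(r)
  }
  gamma <- cbind(sc(coords$p), sc(coords$q))
  rownames(gamma) <- coords$label
  colnames(gamma) <- c("rho1", "rho2")
  structure(list(gamma = gamma, labels = as.character(coords$label)),
            class = "interaction_matrix")
}

#' Perturb interaction strengths with uniform noise
#'
#' Adds \eqn{(\gamma_{max}-\gamma_{min})\,U(0,\nu_\gamma)} independently to
#' each entry, the range taken per column. Large magnitudes can swap the
#' ordering of neighbouring projections' strengths, producing topological
#' defects in the emergent map.
#'
#' @param im an [scale_interactions()] result.
#' @param nu_gamma noise magnitude (>= 0).
#' @param seed RNG seed.
#' @return a perturbed `interaction_matrix`.
#' @export
add_gamma_noise <- function(im, nu_gamma, seed = 1L) {
  stopifnot(nu_gamma >= 0)
  if (nu_gamma == 0) return(im)
  g <- im$gamma
  noise <- with_seed(seed, matrix(stats::runif(length(g), 0, nu_gamma),
                                  nrow(g), ncol(g)))
  for (j in seq_len(ncol(g))) {
    g[, j] <- g[, j] + diff(range(im$gamma[, j])) * noise[, j]
  }
  im$gamma <- g
  im
}

#' Boundary fall-off multiplier
#'
#' A sharp logistic function of the distance to the boundary,
#' \eqn{1 / (1 + \exp(100 (d_f - d_b)))} with the 100 in 1/mm: approx 0
#' at the rim, 1/2 at `d_f`, approx 1 deeper than about `d_f + 0.05` mm.
#' Multiplying the guidance vectors by it makes them (and their normal
#' derivative) vanish at the boundary, which the no-flux condition
#' requires.
#'
#' @param d_b distance(s) to the boundary, mm.
#' @param d_f fall-off distance, mm (default 0.1).
#' @return multiplier(s) in (0, 1).
#' @export
boundary_falloff <- function(d_b, d_f = 0.1) {
  1 / (1 + exp(100 * (d_f - d_b)))
}

#' Per-projection guidance vector fields and divergences
#'
#' \eqn{g_i(x) = \mathrm{falloff}(d_b(x)) \sum_j \gamma_{i,j} \nabla
#' \rho_j(x)}. The divergence of each \eqn{g_i} is computed numerically
#' with the lattice flux-sum operator (so the fall-off's effect enters
#' consistently with the solver) and cached: both are static during a run.
#'
#' @param im an [scale_interactions()] result (N x M gamma).
#' @param fields list of M `guidance_field`s on `lattice`.
#' @param lattice a `hex_lattice`.
#' @param d_f boundary fall-off distance, mm.
#' @return object of class `projection_guidance`: list with `gx`, `gy`,
#'   `div_g` (all H x N), `labels`, `gamma`, `d_f`.
#' @export
compute_projection_guidance <- function(im, fields, lattice, d_f = 0.1) {
  gamma <- im$gamma
  if (ncol(gamma) != length(fields)) {
    stop("number of guidance fields must match columns of gamma")
  }
  H <- lattice$n_hex
  N <- nrow(gamma)
  fall <- boundary_falloff(lattice$d_b, d_f)
  gx <- matrix(0, H, N)
  gy <- matrix(0, H, N)
  div_g <- matrix(0, H, N)
  for (i in seq_len(N)) {
    gi <- matrix(0, H, 2L)
    for (j in seq_along(fields)) {
      gi <- gi + gamma[i, j] * fields[[j]]$grad_rho
    }
    gi <- gi * fall
    gx[, i] <- gi[, 1L]
    gy[, i] <- gi[, 2L]
    div_g[, i] <- hex_divergence(gi, lattice)
  }
  structure(list(gx = gx, gy = gy, div_g = div_g,
                 labels = im$labels, gamma = gamma, d_f = d_f),
            class = "projection_guidance")
}

#' Read barreloid coordinates from CSV
#'
#' Expects header `label,p,q`.
#' @param path CSV file.
#' @return data.frame with columns label, p, q.
#' @export
read_coords_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(label = "character"))
  if (!all(c("label", "p", "q") %in% names(df))) {
    stop("coordinates CSV must have header 'label,p,q'")
  }
  df
}

#' @rdname read_coords_csv
#' @param coords data.frame with columns label, p, q.
#' @export
write_coords_csv <- function(coords, path) {
  utils::write.csv(coords[, c("label", "p", "q")], path, row.names = FALSE)
  invisible(path)
}
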