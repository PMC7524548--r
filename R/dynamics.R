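#' @useDynLib barrelmap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# run expr with a temporary RNG state seeded by `seed`; restores the
# caller's .Random.seed so no hidden global state leaks between calls
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Hexagonal-lattice Laplacian
#'
#' Finite-volume estimate of the Laplacian at each hex: the flux of the
#' gradient through the hexagon's six edges, which reduces to
#' \eqn{(2/(3d^2)) \sum_j (f(p_j) - f(p_0))}. Missing neighbours (outside
#' the domain) take the ghost value \eqn{f(p_0)} and so contribute zero
#' flux (no-flux boundary). Exact for polynomials up to degree 2.
#'
#' @param f numeric vector over hexes.
#' @param lattice a `hex_lattice`.
#' @return numeric vector, the Laplacian estimate per hex.
#' @export
hex_laplacian <- function(f, lattice) {
  acc <- numeric(lattice$n_hex)
  for (j in 1:6) {
    q <- lattice$nbr[, j]
    ok <- !is.na(q)
    acc[ok] <- acc[ok] + (f[q[ok]] - f[ok])
  }
  2 / (3 * lattice$d^2) * acc
}

#' Hexagonal-lattice gradient
#'
#' Central estimate \eqn{\nabla f(p_0) \approx (1/(3d)) \sum_j (f(p_j) -
#' f(p_0)) \hat n_j} over the six neighbour directions. Missing neighbours
#' take the ghost value \eqn{f(p_0)}, suppressing the normal component at
#' the rim. Exact for linear fields.
#'
#' @inheritParams hex_laplacian
#' @return H x 2 matrix of gradient components (columns x, y), units 1/mm
#'   per unit of `f`.
#' @export
hex_gradient <- function(f, lattice) {
  dirs <- neighbour_directions()
  gx <- numeric(lattice$n_hex)
  gy <- numeric(lattice$n_hex)
  for (j in 1:6) {
    q <- lattice$nbr[, j]
    ok <- !is.na(q)
    df <- f[q[ok]] - f[ok]
    gx[ok] <- gx[ok] + df * dirs[j, 1L]
    gy[ok] <- gy[ok] + df * dirs[j, 2L]
  }
  cbind(x = gx, y = gy) / (3 * lattice$d)
}

#' Flux-sum term a * div(g) on the lattice
#'
#' Gauss-theorem estimate of \eqn{a(p_0)\,\nabla\!\cdot g(p_0)}: the edge
#' flux of `g` through the hexagon, using the edge-midpoint average
#' \eqn{(g(p_j)+g(p_0))/2}. Missing neighbours use ghost \eqn{g = 0}
#' (guidance vanishes at the boundary by construction).
#'
#' @param a numeric vector over hexes.
#' @param g H x 2 matrix, a vector field over hexes.
#' @param lattice a `hex_lattice`.
#' @return numeric vector per hex.
#' @export
a_divg <- function(a, g, lattice) {
  a * hex_divergence(g, lattice)
}

#' Lattice divergence of a vector field (flux-sum form)
#'
#' @inheritParams a_divg
#' @return numeric vector, \eqn{\nabla \cdot g} per hex.
#' @export
hex_divergence <- function(g, lattice) {
  dirs <- neighbour_directions()
  acc <- numeric(lattice$n_hex)
  for (j in 1:6) {
    q <- lattice$nbr[, j]
    ok <- !is.na(q)
    # ghost g = 0 outside the domain: the p0 contribution always enters
    gqx <- numeric(lattice$n_hex)
    gqy <- numeric(lattice$n_hex)
    gqx[ok] <- g[q[ok], 1L]
    gqy[ok] <- g[q[ok], 2L]
    acc <- acc + (gqx + g[, 1L]) * dirs[j, 1L] + (gqy + g[, 2L]) * dirs[j, 2L]
  }
  acc / (3 * lattice$d)
}

#' Model parameters
#'
#' Parameters of the coupled branching/synaptogenesis dynamics.
#'
#' @param N number of thalamocortical projections.
#' @param alpha synaptic decay rate (1/time).
#' @param beta synaptogenesis rate (1/time).
#' @param k branching nonlinearity exponent (k > 1 for pattern formation).
#' @param D diffusion constant of axon branching (mm^2/time).
#' @param epsilon competition (cross-diffusion) strength.
#' @param trim per-projection multipliers m_i in (0, 1] applied to epsilon
#'   (whisker-trimming manipulation); recycled to length N.
#' @param dt integration time step.
#' @param steps default iteration count for a full run.
#' @return object of class `model_params`.
#' @export
model_params <- function(N, alpha = 3.6, beta = 16.67, k = 3, D = 0.5,
                         epsilon = 1.2, trim = 1, dt = 1e-4, steps = 30000L) {
  stopifnot(N >= 1, alpha >= 0, beta >= 0, k >= 1, D >= 0, epsilon >= 0,
            dt > 0, steps >= 0)
  trim <- rep_len(trim, N)
  if (any(trim <= 0 | trim > 1)) stop("trim multipliers must lie in (0, 1]")
  if (epsilon > 0 && N < 2) stop("competition requires N >= 2 (division by N - 1)")
  structure(list(N = as.integer(N), alpha = alpha, beta = beta, k = k, D = D,
                 epsilon = epsilon, trim = trim, dt = dt,
                 steps = as.integer(steps)),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(paste0("<model_params: N=%d alpha=%g beta=%g k=%g D=%g ",
                     "epsilon=%g dt=%g steps=%d>\n"),
              x$N, x$alpha, x$beta, x$k, x$D, x$epsilon, x$dt, x$steps))
  invisible(x)
}

# effective per-projection competition coefficient epsilon * m_i / (N - 1)
eps_over_n1 <- function(params) {
  if (params$epsilon == 0) return(rep(0, params$N))
  params$epsilon * params$trim / (params$N - 1)
}

#' Rate of change of connection density
#'
#' \eqn{dc_i/dt = -\alpha c_i + \beta (1 - \sum_j c_j) a_i^k}: connections
#' decay at rate alpha and form at rate beta in proportion to a nonlinear
#' function of local branching, gated by the remaining synaptic capacity.
#'
#' @param a_i branching density of projection i (vector over hexes).
#' @param c_i connection density of projection i.
#' @param c_total sum of connection densities over all projections.
#' @param params a [model_params()].
#' @return numeric vector per hex.
#' @export
dc_dt <- function(a_i, c_i, c_total, params) {
  -params$alpha * c_i + params$beta * (1 - c_total) * a_i^params$k
}

#' Divergence of the branching flux (five-term expansion)
#'
#' \deqn{\nabla\cdot J_i = D \nabla^2 a_i - a_i \nabla\cdot g_i
#'   - g_i \cdot \nabla a_i + \frac{\epsilon_i}{N-1} a_i \nabla^2 \hat a_i
#'   + \frac{\epsilon_i}{N-1} \nabla \hat a_i \cdot \nabla a_i}
#' with \eqn{\hat a_i = \sum_{j \ne i} a_j} and \eqn{\epsilon_i = \epsilon
#' m_i}. The five terms are: diffusion, the static guidance modulator,
#' guidance advection, and the two competition (cross-diffusion) terms.
#'
#' @param a_i branching density of projection i.
#' @param a_hat_i summed branching density of all other projections.
#' @param g_i H x 2 guidance vector field for projection i.
#' @param div_g_i lattice divergence of `g_i` (static, cached).
#' @param params a [model_params()].
#' @param lattice a `hex_lattice`.
#' @param trim_i competition multiplier for this projection.
#' @return numeric vector per hex.
#' @export
compute_divJ <- function(a_i, a_hat_i, g_i, div_g_i, params, lattice,
                         trim_i = 1) {
  if (params$epsilon > 0 && params$N < 2) {
    stop("competition requires N >= 2 (division by N - 1)")
  }
  grad_a <- hex_gradient(a_i, lattice)
  out <- params$D * hex_laplacian(a_i, lattice) -
    a_i * div_g_i -
    (g_i[, 1L] * grad_a[, 1L] + g_i[, 2L] * grad_a[, 2L])
  if (params$epsilon > 0) {
    e <- params$epsilon * trim_i / (params$N - 1)
    grad_ah <- hex_gradient(a_hat_i, lattice)
    out <- out + e * (a_i * hex_laplacian(a_hat_i, lattice) +
                      grad_ah[, 1L] * grad_a[, 1L] +
                      grad_ah[, 2L] * grad_a[, 2L])
  }
  out
}

#' Initial simulation state
#'
#' Branching densities start as i.i.d. uniform draws in `(a_lo, a_hi)` per
#' hex and projection; connection densities start at zero. Setting
#' `a_lo == a_hi` gives the deterministic noise-free initial condition.
#'
#' @param lattice a `hex_lattice`.
#' @param params a [model_params()].
#' @param seed integer RNG seed (recorded in the state).
#' @param a_lo,a_hi bounds of the initial uniform distribution.
#' @return object of class `sim_state`: list with `a` (H x N), `c` (H x N),
#'   `step`, `seed`.
#' @export
init_state <- function(lattice, params, seed = 1L, a_lo = 0.2, a_hi = 0.4) {
  stopifnot(a_lo <= a_hi)
  H <- lattice$n_hex
  N <- params$N
  a <- if (a_lo == a_hi) {
    matrix(a_lo, H, N)
  } else {
    with_seed(seed, matrix(stats::runif(H * N, a_lo, a_hi), H, N))
  }
  structure(list(a = a, c = matrix(0, H, N), step = 0L, seed = as.integer(seed)),
            class = "sim_state")
}

#' Full time-derivative of the state
#'
#' Reference (R-level) evaluation of da/dt and dc/dt for all projections;
#' the compiled engine used by [run_simulation()] repeats this arithmetic.
#'
#' @param state a [init_state()] result.
#' @param guidance a [compute_projection_guidance()] result.
#' @param params a [model_params()].
#' @param lattice a `hex_lattice`.
#' @return list with matrices `da` and `dc` (H x N).
#' @export
da_dt <- function(state, guidance, params, lattice) {
  a <- state$a
  c_ <- state$c
  N <- params$N
  a_tot <- rowSums(a)
  c_tot <- rowSums(c_)
  da <- matrix(0, nrow(a), N)
  dc <- matrix(0, nrow(a), N)
  for (i in seq_len(N)) {
    g_i <- cbind(guidance$gx[, i], guidance$gy[, i])
    dci <- dc_dt(a[, i], c_[, i], c_tot, params)
    dJ <- compute_divJ(a[, i], a_tot - a[, i], g_i, guidance$div_g[, i],
                       params, lattice, trim_i = params$trim[i])
    dc[, i] <- dci
    da[, i] <- dJ - dci
  }
  list(da = da, dc = dc)
}

#' Advance the state by RK4 steps
#'
#' Classical fourth-order Runge-Kutta on the coupled (a, c) system, run in
#' compiled code. Raises an error if the integration becomes numerically
#' unstable (non-finite values or |a| exceeding 1e6).
#'
#' @inheritParams da_dt
#' @param n_steps number of steps to take (default 1).
#' @return the advanced `sim_state`.
#' @export
rk4_step <- function(state, guidance, params, lattice, n_steps = 1L) {
  res <- cpp_run(state$a, state$c, guidance$gx, guidance$gy, guidance$div_g,
                 nbr0based(lattice), lattice$d,
                 params$D, params$alpha, params$beta, params$k,
                 eps_over_n1(params), params$dt, as.integer(n_steps))
  if (!res$stable) stop("numerical instability")
  state$a <- res$a
  state$c <- res$c
  state$step <- state$step + res$steps_done
  state
}

# neighbour table as 0-based integers with -1 sentinel, for the C++ engine
nbr0based <- function(lattice) {
  nbr <- lattice$nbr - 1L
  nbr[is.na(nbr)] <- -1L
  nbr
}

#' Per-projection conserved mass
#'
#' \eqn{\sum_{hex} (a_i + c_i) \Omega}; under no-flux boundaries the
#' dynamics conserve this quantity per projection.
#'
#' @param state a `sim_state`.
#' @param lattice a `hex_lattice`.
#' @return numeric vector of length N.
#' @export
projection_mass <- function(state, lattice) {
  colSums(state$a + state$c) * lattice$omega
}

#' Run a full simulation
#'
#' Integrates the model from an initial state, recording a label map and
#' pattern metrics at a fixed snapshot cadence. Numerical instability does
#' not raise an error here: the run is returned flagged `stable = FALSE`
#' with whatever was computed up to the failing step.
#'
#' @param lattice a `hex_lattice`.
#' @param guidance a [compute_projection_guidance()] result.
#' @param params a [model_params()].
#' @param seed RNG seed for the initial state (ignored if `init` given).
#' @param init optional `sim_state` to start from.
#' @param snapshot_every cadence (in steps) of metric evaluation.
#' @param ref_map optional reference [label_map()] for the pattern
#'   difference metric eta.
#' @param compute_delta whether to evaluate the Voronoi-conformance metric
#'   at snapshots (it requires a local optimization, the other metrics
#'   are cheap).
#' @param delta_every evaluate delta only at every `delta_every`-th
#'   snapshot (the final snapshot is always evaluated when
#'   `compute_delta` is on).
#' @param a_lo,a_hi initial-condition bounds, passed to [init_state()].
#' @return object of class `sim_run`: list with final `state`, `metrics`
#'   (data.frame step/delta/eta/omega), `snapshots` (list of per-snapshot
#'   label vectors), `stable`, plus the inputs.
#' @export
run_simulation <- function(lattice, guidance, params, seed = 1L, init = NULL,
                           snapshot_every = 1000L, ref_map = NULL,
                           compute_delta = TRUE, delta_every = 1L,
                           a_lo = 0.2, a_hi = 0.4) {
  state <- if (is.null(init)) {
    init_state(lattice, params, seed, a_lo, a_hi)
  } else init
  nbr0 <- nbr0based(lattice)
  epsv <- eps_over_n1(params)
  steps_left <- params$steps - state$step
  snapshots <- list()
  met <- list()
  stable <- TRUE
  labels <- if (!is.null(guidance$labels)) guidance$labels else NULL
  i_snap <- 0L
  record <- function(st, last) {
    lm <- label_map(st$c, lattice, a = st$a, labels = labels)
    want_delta <- compute_delta &&
      (last || (i_snap - 1L) %% delta_every == 0L)
    delta <- if (want_delta && length(unique(lm$label)) >= 2) {
      tryCatch(honda_delta(lm, lattice), error = function(e) NA_real_)
    } else NA_real_
    eta <- if (!is.null(ref_map)) pattern_difference(lm, ref_map) else NA_real_
    om <- selectivity(st$c, lattice)$omega
    list(step = st$step, label = lm$label,
         metrics = data.frame(step = st$step, delta = delta, eta = eta,
                              omega = om))
  }
  while (steps_left > 0) {
    chunk <- min(snapshot_every, steps_left)
    res <- cpp_run(state$a, state$c, guidance$gx, guidance$gy, guidance$div_g,
                   nbr0, lattice$d, params$D, params$alpha, params$beta,
                   params$k, epsv, params$dt, as.integer(chunk))
    state$a <- res$a
    state$c <- res$c
    state$step <- state$step + res$steps_done
    if (!res$stable) {
      stable <- FALSE
      break
    }
    i_snap <- i_snap + 1L
    snap <- record(state, last = steps_left - chunk <= 0)
    snapshots[[length(snapshots) + 1L]] <- snap[c("step", "label")]
    met[[length(met) + 1L]] <- snap$metrics
    steps_left <- steps_left - chunk
  }
  structure(list(
    state = state,
    metrics = if (length(met)) do.call(rbind, met) else
      data.frame(step = integer(), delta = numeric(), eta = numeric(),
                 omega = numeric()),
    snapshots = snapshots, stable = stable,
    lattice = lattice, guidance = guidance, params = params
  ), class = "sim_run")
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("<sim_run: %d steps on %d hexes, N=%d, %s>\n",
              x$state$step, x$lattice$n_hex, x$params$N,
              if (x$stable) "stable" else "UNSTABLE"))
  if (nrow(x$metrics)) {
    last <- x$metrics[nrow(x$metrics), ]
    cat(sprintf("  final: delta=%.4g eta=%.4g omega=%.4g\n",
                last$delta, last$eta, last$omega))
  }
  invisible(x)
}
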