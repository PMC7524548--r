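#' Run the example simulation
#'
#' The full pipeline under one configuration: build the domain, lattice,
#' guidance and interaction inputs, integrate the model, and score the
#' emergent map against the Voronoi reference tessellation of the
#' barreloid coordinates.
#'
#' @param cfg a `run_config` (default [default_config()]).
#' @param seed RNG seed for the initial state.
#' @param compute_delta,delta_every forwarded to [run_simulation()].
#' @return a `sim_run` with the extra elements `inputs` (see
#'   [build_inputs()]) and `final_map` (the final [label_map()]).
#' @export
run_example <- function(cfg = default_config(), seed = NULL,
                        compute_delta = TRUE, delta_every = 1L) {
  if (is.null(seed)) seed <- cfg$seeds[1L]
  inp <- build_inputs(cfg)
  run <- run_simulation(inp$lattice, inp$guidance, inp$params, seed = seed,
                        snapshot_every = cfg$output$snapshot_cadence,
                        ref_map = inp$ref_map, compute_delta = compute_delta,
                        delta_every = delta_every)
  run$inputs <- inp
  run$final_map <- label_map(run$state$c, inp$lattice, a = run$state$a,
                             labels = inp$im$labels)
  run
}

#' Parameter sweep over D, epsilon and alpha/beta
#'
#' Runs one independent simulation per grid cell (all cells share the
#' lattice, guidance and seed; nothing else is shared, so cells may be
#' evaluated in any order) and records the final pattern metrics plus a
#' stability flag. The alpha/beta ratio is applied by holding beta at its
#' configured value and setting alpha = ratio * beta. Numerically unstable
#' cells are flagged and carry no metric values.
#'
#' @param cfg a `run_config` supplying domain, guidance and base model
#'   parameters.
#' @param D_grid,eps_grid,ab_grid parameter grids. The defaults form the
#'   6 x 6 x 6 grid of the full sweep; pass shorter grids for a reduced
#'   sweep.
#' @param seed RNG seed shared by all cells.
#' @param compute_delta evaluate the Voronoi-conformance metric for stable
#'   cells (one optimization per cell; the dominant cost for large grids).
#' @return data.frame with columns `D`, `epsilon`, `ab_ratio`, `stable`,
#'   `delta`, `eta`, `omega`.
#' @export
parameter_sweep <- function(cfg = default_config(),
                            D_grid = c(0.1, 0.2, 0.5, 1, 2, 5),
                            eps_grid = c(0.2, 0.5, 0.9, 1.2, 1.6, 2.2),
                            ab_grid = 0.216 * 10^seq(-2.5, 2.5, length.out = 6),
                            seed = 1L, compute_delta = TRUE) {
  stopifnot(length(D_grid) >= 1, length(eps_grid) >= 1, length(ab_grid) >= 1)
  inp <- build_inputs(cfg)
  grid <- expand.grid(D = D_grid, epsilon = eps_grid, ab_ratio = ab_grid,
                      KEEP.OUT.ATTRS = FALSE)
  init <- init_state(inp$lattice, inp$params, seed = seed)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    p <- model_params(N = inp$params$N,
                      alpha = grid$ab_ratio[i] * cfg$model$beta,
                      beta = cfg$model$beta, k = cfg$model$k,
                      D = grid$D[i], epsilon = grid$epsilon[i],
                      dt = cfg$model$dt, steps = cfg$model$steps)
    run <- run_simulation(inp$lattice, inp$guidance, p, init = init,
                          snapshot_every = p$steps, ref_map = inp$ref_map,
                          compute_delta = FALSE)
    if (!run$stable || !nrow(run$metrics)) {
      return(data.frame(stable = FALSE, delta = NA_real_, eta = NA_real_,
                        omega = NA_real_))
    }
    lm <- label_map(run$state$c, inp$lattice, a = run$state$a,
                    labels = inp$im$labels)
    delta <- if (compute_delta) {
      tryCatch(honda_delta(lm, inp$lattice), error = function(e) NA_real_)
    } else NA_real_
    data.frame(stable = TRUE, delta = delta,
               eta = pattern_difference(lm, inp$ref_map),
               omega = selectivity(run$state$c, inp$lattice)$omega)
  })
  cbind(grid, do.call(rbind, res))
}

#' Sensitivity analysis of map quality to input perturbations
#'
#' Applies one class of perturbation at a set of magnitudes, over several
#' seeds, and tabulates the final-step pattern metrics. Kinds:
#' \describe{
#'   \item{init-noise}{`magnitude` is the half-width w of the initial
#'     branching distribution a(x, 0) ~ U(0.3 - w, 0.3 + w); w = 0 is the
#'     noise-free control a(x, 0) = 0.3, w = 0.1 the baseline (0.2, 0.4).}
#'   \item{gamma-noise}{uniform noise of magnitude `nu_gamma = magnitude`
#'     added to the interaction strengths (see [add_gamma_noise()]).}
#'   \item{rho-noise}{uniform noise of magnitude `nu_rho = magnitude`
#'     added to every guidance field and smoothed at width `sigma_rho`
#'     (see [add_field_noise()]).}
#'   \item{rho-rotation-gain}{the first guidance field is rotated by
#'     `magnitude` degrees and its gain multiplied by `gain1`, the second
#'     field is left unchanged.}
#' }
#'
#' @param kind perturbation class (see above).
#' @param magnitudes numeric vector of perturbation magnitudes.
#' @param seeds integer vector of seeds (one run per magnitude x seed).
#' @param cfg base `run_config`.
#' @param sigma_rho smoothing width (mm) for `rho-noise`.
#' @param gain1 gain multiplier on field 1 for `rho-rotation-gain`.
#' @param compute_delta evaluate delta at the final step.
#' @return data.frame with columns `kind`, `magnitude`, `seed`, `stable`,
#'   `delta`, `eta`, `omega`.
#' @export
sensitivity_suite <- function(kind, magnitudes, seeds = 1:3,
                              cfg = default_config(), sigma_rho = 0.05,
                              gain1 = 1, compute_delta = TRUE) {
  kind <- match.arg(kind, c("init-noise", "gamma-noise", "rho-noise",
                            "rho-rotation-gain"))
  inp <- build_inputs(cfg)
  rows <- list()
  for (mag in magnitudes) {
    gd <- inp$guidance
    a_lo <- 0.2; a_hi <- 0.4
    if (kind == "init-noise") {
      a_lo <- 0.3 - mag; a_hi <- 0.3 + mag
    } else if (kind == "gamma-noise") {
      # gamma noise reuses the run seed so each seed sees an independent draw
    } else if (kind == "rho-rotation-gain") {
      f1 <- make_guidance_field(inp$lattice, guidance_field_spec(
        "linear", phi = cfg$guidance[[1L]]$phi + mag,
        gain = cfg$guidance[[1L]]$gain * gain1))
      gd <- compute_projection_guidance(inp$im, list(f1, inp$fields[[2L]]),
                                        inp$lattice)
    }
    for (sd in seeds) {
      if (kind == "gamma-noise") {
        im2 <- add_gamma_noise(inp$im, mag, seed = sd + 1000L)
        gd <- compute_projection_guidance(im2, inp$fields, inp$lattice)
      } else if (kind == "rho-noise") {
        flds <- lapply(seq_along(inp$fields), function(j) {
          add_field_noise(inp$fields[[j]], inp$lattice, mag, sigma_rho,
                          seed = sd + 1000L * j)
        })
        gd <- compute_projection_guidance(inp$im, flds, inp$lattice)
      }
      run <- run_simulation(inp$lattice, gd, inp$params, seed = sd,
                            snapshot_every = inp$params$steps,
                            ref_map = inp$ref_map,
                            compute_delta = compute_delta,
                            a_lo = a_lo, a_hi = a_hi)
      m <- if (nrow(run$metrics)) run$metrics[nrow(run$metrics), ] else
        data.frame(delta = NA_real_, eta = NA_real_, omega = NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, magnitude = mag, seed = sd, stable = run$stable,
        delta = m$delta, eta = m$eta, omega = m$omega)
    }
  }
  do.call(rbind, rows)
}

#' Mirror-duplication (Fgf8 misexpression) experiment
#'
#' Ectopic posterior expression of the anterior morphogen is modelled by
#' doubling the domain across a join line (see [mirror_boundary()]) and
#' reflecting the anterior-posterior guidance field at the join while the
#' orthogonal field extends unreflected. The standard model then runs on
#' the doubled domain. The lattice grid is anchored on the join so the hex
#' centres are mirror-symmetric.
#'
#' @param cfg base `run_config`.
#' @param seed RNG seed.
#' @param x_cut join position (mm); default cuts a sliver off the right
#'   edge of the domain (see [mirror_boundary()]).
#' @param compute_delta evaluate delta at the final step.
#' @return list with `run` (the `sim_run`), `map` (final [label_map()]),
#'   `n_components` (contiguous regions; 2N for a full duplication),
#'   `pair_area_cor` (correlation between each projection's area on the
#'   two halves), `x_join`, and `inputs`.
#' @export
fgf8_duplication <- function(cfg = default_config(), seed = 1L,
                             x_cut = NULL, compute_delta = TRUE) {
  inp_single <- build_inputs(cfg)
  mb <- mirror_boundary(inp_single$boundary, x_cut)
  yc <- polygon_centroid(mb$boundary$vertices)[2L]
  lat <- build_lattice(mb$boundary, cfg$lattice$d,
                       anchor = c(mb$x_join, yc))
  f1 <- mirror_field(inp_single$fields[[1L]], lat, mb$x_join)
  f2 <- extend_field(inp_single$fields[[2L]], lat, mb$x_join)
  gd <- compute_projection_guidance(inp_single$im, list(f1, f2), lat)
  params <- inp_single$params
  run <- run_simulation(lat, gd, params, seed = seed,
                        snapshot_every = cfg$output$snapshot_cadence,
                        compute_delta = FALSE)
  lm <- label_map(run$state$c, lat, a = run$state$a,
                  labels = inp_single$im$labels)
  cc <- count_components(lm, lat)
  left <- lat$centres[, 1L] <= mb$x_join
  aL <- tabulate(lm$label[left], lm$n_labels) * lat$omega
  aR <- tabulate(lm$label[!left], lm$n_labels) * lat$omega
  # per-half region counts: barrels at the join touch their mirror image,
  # merging into one component of the full map, so "one barrel per label
  # per half" is the doubling property to measure
  half_components <- function(mask) {
    sub <- lat
    outside <- which(!mask)
    sub$nbr[outside, ] <- NA_integer_
    sub$nbr[sub$nbr %in% outside] <- NA_integer_   # sever cross-join links
    cc_h <- count_components(lm, sub)
    first_hex <- match(seq_len(cc_h$n_components), cc_h$component)
    sum(mask[first_hex] & cc_h$sizes >= 3L)
  }
  comp_left <- half_components(left)
  comp_right <- half_components(!left)
  delta <- if (compute_delta && run$stable) {
    tryCatch(honda_delta(lm, lat), error = function(e) NA_real_)
  } else NA_real_
  list(run = run, map = lm, n_components = cc$n_components,
       components_left = comp_left, components_right = comp_right,
       pair_area_cor = stats::cor(aL, aR), area_left = aL, area_right = aR,
       delta = delta, x_join = mb$x_join, lattice = lat,
       inputs = inp_single)
}

#' Whisker-trimming experiment
#'
#' Sensory deprivation of selected whiskers is modelled by multiplying the
#' competition strength epsilon of the corresponding projections by
#' m in (0, 1]. A control run (m = 1) and the trimmed run use the same
#' seed, so initialization variance cancels out of the area comparison.
#'
#' @param targets character vector of projection labels to trim (e.g.
#'   `"C3"`, or all of row C).
#' @param m the epsilon multiplier, in (0, 1].
#' @param cfg base `run_config`.
#' @param seed shared RNG seed.
#' @param control optional precomputed control `sim_run` (from a previous
#'   call with the same cfg and seed) to avoid re-running m = 1.
#' @param inputs optional precomputed [build_inputs()] result for `cfg`,
#'   reused across calls in an m-grid.
#' @return list with `control`, `trimmed` (both `sim_run`s), `areas`
#'   (data.frame label/control/trimmed/ratio), `target_ratio` (mean area
#'   ratio over the targets), and `targets`.
#' @export
trim_whisker <- function(targets, m, cfg = default_config(), seed = 1L,
                         control = NULL, inputs = NULL) {
  stopifnot(m > 0, m <= 1)
  inp <- if (is.null(inputs)) build_inputs(cfg) else inputs
  labs <- inp$im$labels
  unknown <- setdiff(targets, labs)
  if (length(unknown)) stop("unknown label(s): ", paste(unknown, collapse = ", "))
  trim <- rep(1, inp$params$N)
  trim[match(targets, labs)] <- m
  p_trim <- model_params(N = inp$params$N, alpha = cfg$model$alpha,
                         beta = cfg$model$beta, k = cfg$model$k,
                         D = cfg$model$D, epsilon = cfg$model$epsilon,
                         trim = trim, dt = cfg$model$dt,
                         steps = cfg$model$steps)
  if (is.null(control)) {
    control <- run_simulation(inp$lattice, inp$guidance, inp$params,
                              seed = seed, snapshot_every = inp$params$steps,
                              compute_delta = FALSE)
  }
  trimmed <- run_simulation(inp$lattice, inp$guidance, p_trim, seed = seed,
                            snapshot_every = p_trim$steps,
                            compute_delta = FALSE)
  lm_c <- label_map(control$state$c, inp$lattice, a = control$state$a,
                    labels = labs)
  lm_t <- label_map(trimmed$state$c, inp$lattice, a = trimmed$state$a,
                    labels = labs)
  areas <- data.frame(label = labs, control = unname(lm_c$areas),
                      trimmed = unname(lm_t$areas))
  areas$ratio <- ifelse(areas$control > 0, areas$trimmed / areas$control, NA)
  tgt <- areas[areas$label %in% targets, ]
  list(control = control, trimmed = trimmed, areas = areas,
       target_ratio = sum(tgt$trimmed) / sum(tgt$control),
       targets = targets, map_control = lm_c, map_trimmed = lm_t,
       inputs = inp)
}

#' Labels of a whisker row, including its interstitial straddler
#'
#' Row trimming includes the straddler whisker at the row's arc-0 end
#' (alpha with row A, beta with B, gamma with C, delta with D).
#'
#' @param row row letter, one of A-D (E has no straddler of its own).
#' @param labels available projection labels.
#' @return character vector of labels in the row.
#' @export
row_labels <- function(row, labels) {
  strad <- c(A = "alpha", B = "beta", C = "gamma", D = "delta")
  out <- c(grep(paste0("^", row, "[0-9]+$"), labels, value = TRUE),
           intersect(strad[row], labels))
  if (!length(out)) stop("no labels found for row ", row)
  out
}

#' Compare metric samples from two experimental conditions
#'
#' Paired (default) or unpaired two-sample t-test on per-seed metric
#' values. Identical samples are reported as t = 0, p = 1 (no evidence of
#' difference) rather than the undefined 0/0 statistic.
#'
#' @param a,b numeric vectors of per-seed metric values.
#' @param paired use the paired test (requires equal lengths).
#' @return list with `statistic`, `p.value`, `df`, `method`.
#' @export
compare_runs <- function(a, b, paired = TRUE) {
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 samples per group")
  if (paired && length(a) != length(b)) {
    stop("paired comparison needs equal sample sizes")
  }
  if (isTRUE(all.equal(a, b)) ||
      (paired && stats::sd(a - b) == 0) ||
      (!paired && stats::sd(a) == 0 && stats::sd(b) == 0 &&
       mean(a) == mean(b))) {
    return(list(statistic = 0, p.value = 1,
                df = if (paired) length(a) - 1L else length(a) + length(b) - 2L,
                method = if (paired) "paired t-test" else "two-sample t-test"))
  }
  tt <- stats::t.test(a, b, paired = paired, var.equal = !paired)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), method = tt$method)
}

#' Interaction matrix for the 1D-reproduction test
#'
#' For the reduced setting in which N projections order themselves along
#' one axis under M offset sigmoidal gradients: the thalamic counterpart
#' of each cortical field is sampled at N equispaced 1D positions and each
#' column is scaled to the conventional +/-2 range.
#'
#' @param N number of projections.
#' @param offsets sigmoid centres as fractions of the axis (length M).
#' @param width sigmoid width as a fraction of the axis.
#' @param labels optional projection labels.
#' @return an `interaction_matrix` with an N x M gamma.
#' @export
make_1d_interactions <- function(N, offsets = c(0.25, 0.5, 0.75),
                                 width = 0.1, labels = NULL) {
  if (is.null(labels)) labels <- paste0("P", seq_len(N))
  p <- seq(0, 1, length.out = N)
  gamma <- vapply(offsets, function(o) {
    v <- 1 / (1 + exp(-(p - o) / width))
    r <- range(v)
    -2 + 4 * (v - r[1L]) / diff(r)
  }, numeric(N))
  rownames(gamma) <- labels
  structure(list(gamma = gamma, labels = labels),
            class = "interaction_matrix")
}
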