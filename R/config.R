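#' Default run configuration
#'
#' The defaults are the example-simulation conditions: the standard domain
#' at hex spacing d = 0.03 mm, two linear guidance gradients at 0 and 84
#' degrees with unit gain, the synthetic 41-whisker barreloid layout, and
#' model parameters alpha = 3.6, beta = 16.67, k = 3, D = 0.5,
#' epsilon = 1.2, dt = 1e-4, 30000 steps.
#'
#' @return a nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    domain = list(source = "synthetic-barrelfield", scale = 1,
                  semi_major = 2, semi_minor = 1, path = NULL),
    lattice = list(d = 0.03),
    guidance = list(
      list(kind = "linear", phi = 0, gain = 1),
      list(kind = "linear", phi = 84, gain = 1)
    ),
    coords = list(source = "synthetic", jitter = 0, path = NULL),
    model = list(alpha = 3.6, beta = 16.67, k = 3, D = 0.5, epsilon = 1.2,
                 dt = 1e-4, steps = 30000L),
    seeds = 1L,
    output = list(path = NULL, snapshot_cadence = 1000L,
                  formats = c("csv", "svg"))
  ), class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML file and merges it over [default_config()]: absent fields
#' take their defaults, unknown keys raise a warning naming the key.
#' Referenced input files must exist at load time.
#'
#' @param path YAML file, or `NULL` for the pure defaults.
#' @return a validated `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user, prefix = "")
  }
  validate_config(cfg)
}

merge_config <- function(base, user, prefix = "") {
  for (k in names(user)) {
    full <- if (prefix == "") k else paste0(prefix, ".", k)
    if (!k %in% names(base) && prefix != "guidance") {
      warning("unknown config key: ", full)
      next
    }
    if (k == "guidance") {
      base[[k]] <- user[[k]]  # list of field specs replaces wholesale
    } else if (is.list(base[[k]]) && is.list(user[[k]]) &&
               !is.null(names(base[[k]]))) {
      base[[k]] <- merge_config(base[[k]], user[[k]], prefix = full)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

validate_config <- function(cfg) {
  m <- cfg$model
  for (f in c("alpha", "beta", "k", "D", "epsilon", "dt", "steps")) {
    if (is.null(m[[f]]) || !is.numeric(m[[f]]) || length(m[[f]]) != 1L) {
      stop("invalid or missing model field: ", f)
    }
  }
  if (m$dt <= 0) stop("invalid model field: dt (must be > 0)")
  if (m$steps < 0) stop("invalid model field: steps (must be >= 0)")
  if (m$k < 1) stop("invalid model field: k (must be >= 1)")
  if (any(c(m$alpha, m$beta, m$D, m$epsilon) < 0)) {
    stop("invalid model field: rates must be >= 0")
  }
  if (is.null(cfg$lattice$d) || cfg$lattice$d <= 0) {
    stop("invalid or missing lattice field: d")
  }
  src <- cfg$domain$source
  if (!src %in% c("synthetic-barrelfield", "synthetic-ellipse", "svg", "csv")) {
    stop("invalid domain field: source")
  }
  if (src %in% c("svg", "csv")) {
    if (is.null(cfg$domain$path) || !file.exists(cfg$domain$path)) {
      stop("domain file not found: ", cfg$domain$path)
    }
  }
  if (cfg$coords$source == "csv" &&
      (is.null(cfg$coords$path) || !file.exists(cfg$coords$path))) {
    stop("coordinates file not found: ", cfg$coords$path)
  }
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @param cfg a `run_config`.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Assemble model inputs from a configuration
#'
#' Builds the boundary, lattice, barreloid coordinates, interaction matrix,
#' guidance fields and cached projection guidance a run needs.
#'
#' @param cfg a `run_config` (see [load_config()]).
#' @return list with `boundary`, `lattice`, `coords`, `im`, `fields`,
#'   `guidance`, `params`, `ref_map` (Voronoi reference tessellation of the
#'   coordinates mapped into the domain).
#' @export
build_inputs <- function(cfg) {
  boundary <- switch(cfg$domain$source,
    "synthetic-barrelfield" = make_barrelfield_boundary(cfg$domain$scale),
    "synthetic-ellipse" = make_ellipse_boundary(cfg$domain$semi_major,
                                                cfg$domain$semi_minor),
    "svg" = read_boundary_svg(cfg$domain$path),
    "csv" = read_boundary_csv(cfg$domain$path)
  )
  lattice <- build_lattice(boundary, cfg$lattice$d)
  coords <- if (cfg$coords$source == "synthetic") {
    make_barreloid_coordinates(barreloid_spec(jitter = cfg$coords$jitter))
  } else {
    read_coords_csv(cfg$coords$path)
  }
  im <- scale_interactions(coords)
  fields <- lapply(cfg$guidance, function(g) {
    spec <- guidance_field_spec(
      kind = if (is.null(g$kind)) "linear" else g$kind,
      phi = if (is.null(g$phi)) 0 else g$phi,
      gain = if (is.null(g$gain)) 1 else g$gain,
      offset = if (is.null(g$offset)) 0.5 else g$offset,
      width = if (is.null(g$width)) 0.1 else g$width)
    f <- make_guidance_field(lattice, spec)
    if (!is.null(g$noise_mag) && g$noise_mag > 0) {
      f <- add_field_noise(f, lattice, g$noise_mag,
                           if (is.null(g$noise_scale)) 0 else g$noise_scale,
                           seed = if (is.null(g$noise_seed)) 1L else g$noise_seed)
    }
    f
  })
  guidance <- compute_projection_guidance(im, fields, lattice)
  params <- model_params(N = nrow(im$gamma), alpha = cfg$model$alpha,
                         beta = cfg$model$beta, k = cfg$model$k,
                         D = cfg$model$D, epsilon = cfg$model$epsilon,
                         dt = cfg$model$dt, steps = cfg$model$steps)
  ref_map <- make_reference_labelmap(
    map_coords_to_domain(coords, boundary), lattice, labels = im$labels)
  list(boundary = boundary, lattice = lattice, coords = coords, im = im,
       fields = fields, guidance = guidance, params = params,
       ref_map = ref_map)
}

#' Reduced-cost preset of a configuration
#'
#' Scales the lattice spacing up and the iteration count down for quick
#' qualitative runs (trend checks, smoke tests). Metric values from
#' reduced runs are coarser than full-resolution ones; orderings and
#' qualitative outcomes are what reduced runs are for.
#'
#' @param cfg a `run_config`.
#' @param d_factor multiplier on hex spacing (default 2: one quarter of
#'   the hexes).
#' @param steps iteration count for reduced runs.
#' @return the modified `run_config`.
#' @export
scale_down_config <- function(cfg, d_factor = 2, steps = 7500L) {
  cfg$lattice$d <- cfg$lattice$d * d_factor
  cfg$model$steps <- as.integer(steps)
  cfg$output$snapshot_cadence <-
    max(1L, min(cfg$output$snapshot_cadence, as.integer(steps %/% 8)))
  cfg
}

#' Save a simulation run to a plain-text container
#'
#' Writes a directory with `manifest.json` (version, seed, parameters,
#' input content hash), `config.yaml`, `lattice.csv`, `metrics.csv`,
#' `final_a.csv` / `final_c.csv` (H x N state matrices), per-snapshot
#' label CSVs under `snapshots/`, and the final label map as CSV and SVG.
#' Numeric payloads are written at full precision so containers
#' round-trip bit-exactly.
#'
#' @param run a `sim_run`.
#' @param dir output directory (created if needed).
#' @param cfg optional `run_config` to record.
#' @return `dir`, invisibly.
#' @export
save_run <- function(run, dir, cfg = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "snapshots"), showWarnings = FALSE)
  p <- run$params
  manifest <- list(
    package = "barrelmap",
    version = as.character(utils::packageVersion("barrelmap")),
    seed = run$state$seed, steps = run$state$step, stable = run$stable,
    n_hex = run$lattice$n_hex, N = p$N,
    params = p[c("alpha", "beta", "k", "D", "epsilon", "dt", "steps")],
    input_hash = run_input_hash(run)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(cfg)) save_config(cfg, file.path(dir, "config.yaml"))
  write_lattice_csv(run$lattice, file.path(dir, "lattice.csv"))
  write_metrics_csv(run$metrics, file.path(dir, "metrics.csv"))
  write_state_matrix(run$state$a, file.path(dir, "final_a.csv"))
  write_state_matrix(run$state$c, file.path(dir, "final_c.csv"))
  labels <- if (!is.null(run$guidance$labels)) run$guidance$labels else
    as.character(seq_len(p$N))
  lm <- label_map(run$state$c, run$lattice, a = run$state$a, labels = labels)
  write_labelmap_csv(lm, file.path(dir, "labelmap.csv"))
  write_labelmap_svg(lm, run$lattice, file.path(dir, "labelmap.svg"))
  for (s in run$snapshots) {
    utils::write.csv(data.frame(index = seq_along(s$label), label = s$label),
                     file.path(dir, "snapshots",
                               sprintf("labels_step%06d.csv", s$step)),
                     row.names = FALSE)
  }
  invisible(dir)
}

write_state_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  invisible(path)
}

# content hash of the numeric inputs (guidance + params), md5 over a
# canonical text serialization
run_input_hash <- function(run) {
  tf <- tempfile()
  on.exit(unlink(tf))
  con <- file(tf, "wb")
  serialize(list(gx = run$guidance$gx, gy = run$guidance$gy,
                 params = unclass(run$params),
                 centres = run$lattice$centres), con, version = 2L)
  close(con)
  unname(tools::md5sum(tf))
}

#' Load a saved run container
#'
#' Restores what the `metrics` subcommand needs: the final state matrices,
#' the stored metric series, and the manifest. The lattice is rebuilt from
#' the stored configuration.
#'
#' @param dir container directory written by [save_run()].
#' @return list with `manifest`, `a`, `c`, `metrics`, `config` (if saved),
#'   `inputs` (rebuilt via [build_inputs()] when the config is available).
#' @export
load_run <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  a <- as.matrix(utils::read.csv(file.path(dir, "final_a.csv")))
  c_ <- as.matrix(utils::read.csv(file.path(dir, "final_c.csv")))
  metrics <- utils::read.csv(file.path(dir, "metrics.csv"))
  cfgp <- file.path(dir, "config.yaml")
  cfg <- if (file.exists(cfgp)) load_config(cfgp) else NULL
  inputs <- if (!is.null(cfg)) build_inputs(cfg) else NULL
  list(manifest = manifest, a = unname(a), c = unname(c_),
       metrics = metrics, config = cfg, inputs = inputs)
}
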