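# shared small fixtures, built once per test run

# ~500-hex ellipse (2:1 aspect), the workhorse domain for operator tests
fix_ellipse <- local({
  b <- make_ellipse_boundary(1.0, 0.5, 128)
  lat <- build_lattice(b, 0.06)
  list(boundary = b, lattice = lat)
})

# interior mask: hexes with all 6 neighbours present and well clear of rim
interior_hexes <- function(lattice) {
  rowSums(is.na(lattice$nbr)) == 0L & lattice$d_b > 2 * lattice$d
}

# a small 5-projection guidance setup on the fixture ellipse
fix_guidance5 <- local({
  lat <- fix_ellipse$lattice
  coords <- data.frame(label = paste0("P", 1:5),
                       p = 1:5, q = c(0.1, 0.5, 0.2, 0.8, 0.3))
  im <- scale_interactions(coords)
  f1 <- make_linear_field(lat, 0, 1)
  f2 <- make_linear_field(lat, 84, 1)
  list(im = im, fields = list(f1, f2),
       guidance = compute_projection_guidance(im, list(f1, f2), lat),
       coords = coords)
})

# micro run configuration: 9 whiskers on a small ellipse, few steps;
# for plumbing tests where only mechanics matter, not pattern quality
fix_micro_cfg <- local({
  coords_path <- tempfile(fileext = ".csv")
  co <- expand.grid(row = c("B", "C", "D"), arc = 2:4,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  co <- data.frame(label = paste0(co$row, co$arc),
                   p = co$arc + 0.1 * match(co$row, c("B", "C", "D")),
                   q = -match(co$row, c("B", "C", "D")))
  write_coords_csv(co, coords_path)
  cfg <- default_config()
  cfg$domain$source <- "synthetic-ellipse"
  cfg$domain$semi_major <- 1
  cfg$domain$semi_minor <- 0.5
  cfg$lattice$d <- 0.1
  cfg$coords$source <- "csv"
  cfg$coords$path <- coords_path
  cfg$model$steps <- 300L
  cfg$output$snapshot_cadence <- 100L
  cfg
})

# zero-guidance object for N projections on a lattice
zero_guidance <- function(lattice, N) {
  H <- lattice$n_hex
  structure(list(gx = matrix(0, H, N), gy = matrix(0, H, N),
                 div_g = matrix(0, H, N),
                 labels = as.character(seq_len(N)),
                 gamma = matrix(0, N, 2L), d_f = 0.1),
            class = "projection_guidance")
}
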