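# barrelmap

Self-organization of whisker barrel maps by guided reaction–diffusion on a
hexagonal cortical lattice.

Rodents carry one cortical "barrel" of dense thalamocortical innervation per
facial whisker; the barrels tile primary somatosensory cortex as a
somatotopic map whose borders approximate a Voronoi tessellation. How do
distinct, correctly ordered barrels emerge from axons that arrive as an
undifferentiated bundle, without pre-specified centre points? `barrelmap`
implements a local, self-organizing answer for computational
neuroscientists: for each of *N* thalamocortical projections a branching
density *aᵢ* and connection density *cᵢ* evolve on the cortical sheet *S* as

```
∂cᵢ/∂t = −α cᵢ + β (1 − Σⱼ cⱼ) aᵢᵏ
∂aᵢ/∂t = ∇·( D ∇aᵢ − aᵢ gᵢ(x) + (εᵢ/(N−1)) aᵢ ∇âᵢ ) − ∂cᵢ/∂t ,   âᵢ = Σⱼ≠ᵢ aⱼ
```

with `gᵢ(x) = Σⱼ γᵢⱼ ∇ρⱼ(x)`: diffusion, advection along *M* molecular
guidance gradients ρⱼ with projection-specific interaction strengths γᵢⱼ
(read off each barreloid's thalamic position, scaled to ±2), and
cross-diffusion competition of strength ε. The system runs under no-flux
boundaries on a hexagonal lattice built inside an arbitrary boundary
polygon, integrated by RK4 in compiled code.

The package provides:

* **hex lattice** construction and finite-volume operators (Laplacian,
  gradient, flux-sum divergence; ghost-cell no-flux handling) —
  `build_lattice()`, `hex_laplacian()`, …;
* **guidance fields** (linear / offset-logistic / mirrored, noise and
  smoothing, boundary fall-off) and interaction matrices —
  `make_guidance_field()`, `scale_interactions()`,
  `compute_projection_guidance()`;
* **pattern metrics**: winner-take-all label maps with region geometry,
  Voronoi-conformance (Honda) delta, the mm³ pattern-difference η between
  two tessellations, and connection selectivity μ/ω — `label_map()`,
  `honda_delta()`, `pattern_difference()`, `selectivity()`;
* **synthetic inputs**: the 41-whisker row/arc barreloid layout
  (rows A–E plus straddlers α–δ) and a barrel-field-shaped boundary
  generated as the rounded hull of that layout — no external data needed;
* **in-silico experiments**: parameter sweeps over (D, ε, α/β),
  sensitivity analyses (initial noise, γ noise, field noise,
  rotation/gain), Fgf8-style mirror duplication of the map, and whisker
  trimming via per-projection ε multipliers — `parameter_sweep()`,
  `sensitivity_suite()`, `fgf8_duplication()`, `trim_whisker()`;
* a **CLI** (`exec/barrelmap`) with subcommands `run`, `sweep`,
  `sensitivity`, `fgf8`, `trim`, `metrics`, `synth`, YAML configs, and
  plain-text run containers.

## Worked example

Five projections under three offset guidance gradients on an ellipse — the
reduced setting in which topographic ordering is easiest to see:

```r
library(barrelmap)

lat <- build_lattice(make_ellipse_boundary(1.0, 0.5), d = 0.08)
im  <- make_1d_interactions(5)                      # gamma: 5 x 3, scaled to ±2
fld <- lapply(c(0.25, 0.5, 0.75), function(o)
  make_guidance_field(lat, guidance_field_spec("offset-logistic",
                                               offset = o, width = 0.1)))
gd  <- compute_projection_guidance(im, fld, lat)
p   <- model_params(N = 5, steps = 7500)
st  <- rk4_step(init_state(lat, p, seed = 1), gd, p, lat, p$steps)

lm  <- label_map(st$c, lat, a = st$a, labels = im$labels)
round(lm$areas, 3)
#>    P1    P2    P3    P4    P5
#> 0.227 0.305 0.510 0.299 0.227
lm$labels[order(lm$centroids[, 1])]
#> [1] "P1" "P2" "P3" "P4" "P5"
round(selectivity(st$c, lat)$omega, 3)
#> [1] 1.129
```

The five projections carve the 1.57 mm² ellipse into five contiguous fields
whose left-to-right order `P1 … P5` reproduces the ordering of their
thalamic coordinates — a topographic map with no pre-specified centres. The
selectivity integral ω = 1.13 mm² means the average cortical site gives its
winning projection 72% of its connections (ω ranges from |S|/N = 0.31 for
unselective tissue to |S| = 1.57 for a perfectly selective map).

The full 41-whisker pipeline is one call:

```r
cfg <- scale_down_config(default_config(), d_factor = 2, steps = 70000)
run <- run_example(cfg, seed = 1)     # ~8 min; d = 0.06 mm, 2253 hexes
run$metrics                           # step, delta, eta, omega series
```

Over the run all 41 whiskers come to hold one contiguous field each, the
Voronoi-conformance delta falls (0.41 at step 1000 → ~0.2), the pattern
difference η against the reference tessellation falls monotonically
(5.7 → 0.5 mm³ by step 30000 and further after), and selectivity ω rises
monotonically — the barrel map self-organizes and sharpens.

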