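---
title: "Guided reaction-diffusion models of whisker barrel map formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guided reaction-diffusion models of whisker barrel map formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Rodent primary somatosensory cortex contains one "barrel" of dense
thalamocortical innervation per facial whisker, tiled as a somatotopic map
whose borders closely approximate a Voronoi tessellation. `barrelmap`
simulates how such a map can self-organize from an initially undifferentiated
bundle of axons, using only local interactions, under the guidance of
molecular gradients.

Each of $N$ thalamocortical projections $i$ carries two densities over the
cortical sheet $S$: an axon branching density $a_i(\mathbf{x},t)$ and a
connection (occupied synapse) density $c_i(\mathbf{x},t)$. Synaptogenesis
couples them through a shared, limited synaptic capacity:

$$\frac{\partial c_i}{\partial t}
  = -\alpha c_i + \beta\Big(1 - \sum_{j=1}^{N} c_j\Big) a_i^k ,$$

so connections decay at rate $\alpha$ and form at rate $\beta$ in proportion
to a supralinear function ($k > 1$) of local branching, gated by the
remaining capacity. Branching evolves by a conservation law,

$$\frac{\partial a_i}{\partial t}
  = \nabla\cdot\Big(D\,\nabla a_i - a_i\,\mathbf{g}_i(\mathbf{x})
    + \frac{\epsilon_i}{N-1}\, a_i \nabla \hat a_i\Big)
    - \frac{\partial c_i}{\partial t},
  \qquad \hat a_i = \sum_{j\neq i} a_j,$$

whose flux combines diffusion at rate $D$, advection along a static guidance
field $\mathbf{g}_i = \sum_{j=1}^{M}\gamma_{i,j}\nabla\rho_j$ built from $M$
cortical signalling gradients $\rho_j$, and a cross-diffusion competition
term that pushes a projection's branches away from regions dense in *other*
projections' branches, scaled by $\epsilon_i = \epsilon\, m_i$ (the
per-projection multiplier $m_i \le 1$ models whisker trimming). Because the
flux form conserves each projection's total $a_i + c_i$ under no-flux
boundaries, territory can only be won or lost through competition, never
created.

The interaction strengths $\gamma_{i,j}$ are read off each projection's
barreloid position in a thalamic reference plane, affinely scaled so each
axis spans $[-2, 2]$ (`scale_interactions()`): complementary thalamic and
cortical gradients (in the spirit of EphA4/ephrin-A5 pairs) let *relative*
thalamic position select *relative* cortical position, without
pre-specified centre points.

## Discretization

The sheet is a hexagonal lattice of spacing $d$ built inside an arbitrary
closed boundary polygon (`build_lattice()`): hexes live on a triangular grid
anchored at the polygon centroid (axis 1 along $+x$), a hex belongs to the
domain iff its centre is strictly inside, and each hex stores its six
neighbours in the fixed angular order $\pi(j-1)/3$. Hex area is
$\Omega = (\sqrt3/2)d^2$ and edge length $v = d/\sqrt3$. These conventions
are deterministic, so hex counts are bit-reproducible; they are also
conventions — a different anchoring rule would change the count by a rim
layer at most.

All differential operators are Gauss-theorem (finite-volume) flux sums over
the six edges:

* Laplacian: $(2/(3d^2)) \sum_j (f(p_j) - f(p_0))$ — exact for polynomials
  up to degree 2;
* gradient: $(1/(3d)) \sum_j (f(p_j) - f(p_0))\,\hat n_j$ — exact for
  linear fields;
* divergence of a vector field: the edge-midpoint average flux sum, used
  for $a_i \nabla\cdot \mathbf{g}_i$ and cached once per run since
  $\mathbf{g}_i$ is static.

The five-term expansion of the flux divergence is
$D\nabla^2 a_i - a_i\nabla\cdot\mathbf{g}_i - \mathbf{g}_i\cdot\nabla a_i
+ \tfrac{\epsilon_i}{N-1}(a_i \nabla^2 \hat a_i + \nabla\hat a_i\cdot\nabla a_i)$,
evaluated per hex with $\hat a_i$ obtained as (total) $-\,a_i$ so the cost
is $O(NH)$ per evaluation. Time stepping is classical RK4 (the compiled
engine in `src/kernels.cpp`; `da_dt()` and friends are the exported R
reference implementations, and a test pins the two to each other at
$10^{-12}$).

### No-flux boundaries

Zero flux through the domain edge is enforced by two complementary devices:

* **Ghost cells** for scalars: a missing neighbour takes the centre value,
  so diffusion terms contribute no edge flux. This makes the discrete
  Laplacian *telescoping*: its lattice total is zero to machine precision
  for any field.
* **Guidance fall-off**: $\mathbf{g}_i$ is multiplied by the sharp logistic
  $1/(1+\exp(100(d_f - d_b)))$ of the distance to boundary $d_b$, with
  $d_f = 0.1$ mm, so the advective flux (and its normal derivative) vanish
  at the rim; the ghost guidance vector is $\mathbf{0}$.

### A numerical caveat worth knowing

The diffusion and advection terms, as discretized, balance globally to
round-off (the package tests assert $|\sum \nabla\cdot J\,\Omega| <
10^{-6}\,\sum|\nabla\cdot J|\,\Omega$ with $\epsilon = 0$). The two
competition terms, however, couple *centred* gradient estimates that do not
cancel pairwise across edges, so on rough (random) states their global sum
is only $O(10^{-3})$ relative, shrinking as $O(d^2)$ once the state
smooths. The practical consequence is a small transient mass drift at the
start of a run — about $6\times10^{-4}$ relative over the first 1000 steps
with the example parameters — which is monitored in the test suite rather
than hidden by rescaling. An exactly conservative alternative (flux-form
competition) would depart from the five-term expansion that defines the
model's reference implementation, so it was not adopted.

Instability (non-finite values, or $|a| > 10^6$) is detected each step;
`rk4_step()` raises an error while `run_simulation()` returns the partial
run flagged `stable = FALSE`, which is what the parameter sweep records as
a white (unstable) cell. $a_i$ is not clipped at zero; with RK4 and the
example parameters it stays positive in practice, and $[a_i]^k$ is computed
sign-preservingly for integer $k$.

## Pattern metrics

* **Label map** (`label_map()`): each hex is labelled by the projection with
  maximal connection density (ties to the lowest index; hexes with total
  $c$ below $10^{-12}$ fall back to the branching argmax). Region areas,
  centroids, the border-length adjacency matrix $V$ and total border
  lengths $b$ (internal plus domain-exterior border) derive from it.
* **Voronoi conformance** (`honda_delta()`): one generator per region,
  initialized at the centroid; each internal border vertex scores the
  absolute difference of its distances to the two flanking generators,
  normalized by the generator separation; delta is the mean over borders of
  the mean vertex score, minimized over generator positions (joint
  L-BFGS-B then coordinate Nelder-Mead sweeps). Two implementation details
  matter. First, generators are box-constrained to their region: without
  the constraint the normalized deviation of *any* map can be driven
  toward zero by scattering generators to infinity. Second, the deviation
  of an exact Voronoi tessellation rasterized to the lattice is bounded
  below by the rasterization error, roughly $d/(2\,\text{spacing})$ for
  generator spacing $\text{spacing}$ — which should be kept in mind when
  comparing absolute delta values across resolutions.
  On fragmented (pre-organization) maps with many more than ~3 borders per
  region the optimization budget is cut: such maps score high delta
  regardless, and polishing them is wasted work.
* **Pattern difference** $\eta$ (`pattern_difference()`): the product of the
  mean per-region area difference and the mean adjacency-vector difference,
  divided by the mean normalized adjacency overlap; units mm$^3$. It is
  symmetric in its arguments, zero exactly on identical maps, and scales as
  length$^3$ under uniform rescaling of both maps.
* **Selectivity** $\mu, \omega$ (`selectivity()`): $\mu$ is the winner's
  share of the local connection density ($1/N$ where there is none — the
  continuity convention at $t = 0$); $\omega = \sum \mu\,\Omega$.

## Synthetic inputs

The package runs entirely on synthetic stand-ins for the two external
inputs a histological study would supply:

* `make_barreloid_coordinates()` — the rat macrovibrissae layout: rows A-E
  with arc counts 4, 4, 8, 10, 11 plus the four straddlers
  $\alpha$-$\delta$, 41 labelled points on a sheared row/arc grid (rows 1.1
  pitches apart, 0.15-pitch shear) with optional jitter. Only the count and
  the ordering semantics are contractual; the exact geometry approximates
  published whisker-pad layouts.
* `make_barrelfield_boundary()` — the domain outline is generated as the
  rounded convex hull (hull $\oplus$ disk of 0.3 mm) of that same layout at
  0.34 mm pitch, mirroring how a real barrel-field outline is traced around
  the barrels. It encloses about 7 mm$^2$, comparable to the rat
  posteromedial barrel subfield. An early design used a generic egg-shaped
  oval; because its footprint did not follow the row structure, edge
  projections were systematically squeezed out — a useful reminder that in
  this model the boundary shape is a real constraint, not packaging.
* `make_reference_labelmap()` — the Voronoi tessellation of the coordinates
  mapped affinely into the domain, rasterized to the lattice; it is the
  reference for $\eta$ when no real tracing exists, and its delta is the
  rasterization floor by construction.

What the synthetic stand-ins do *not* emulate: the real barreloid cloud's
row curvature and anisotropic spacing, the real outline's concavities, and
biological variability of either. Metric values obtained on synthetic
inputs are therefore comparable across runs of this package but not
numerically to values computed against real tracings; trends (delta falling
during organization, $\omega$ rising, trimming shrinking a barrel) are the
transferable content.

## Experiments and default conditions

The example conditions are $N = 41$, $\alpha = 3.6$, $\beta = 16.67$,
$k = 3$, $D = 0.5$, $\epsilon = 1.2$, $\gamma \in \pm2$, $\delta t = 10^{-4}$,
30000 steps, two linear gradients at $0°$ and $84°$ with unit gain, initial
$a \sim U(0.2, 0.4)$, $c = 0$. The full-resolution lattice spacing is
$d = 0.03$ mm.

* `parameter_sweep()` — independent runs over $D \times \epsilon \times
  \alpha/\beta$ grids (the full factorial default is $6^3 = 216$ cells;
  $\alpha = \text{ratio}\times\beta$ with $\beta$ fixed). Cells share
  nothing but the initial state, so results are order-independent.
* `sensitivity_suite()` — initial-condition noise width, $\gamma$ noise,
  guidance-field noise (uniform, then Gaussian-smoothed at width
  $\sigma_\rho$ with per-hex kernel renormalization at the rim), and
  rotation/gain changes of $\rho_1$.
* `fgf8_duplication()` — the domain is clipped at a join line (default: a
  sliver off the $+x$ end), reflected, and rejoined into one
  mirror-symmetric polygon; the lattice is anchored on the join so hex
  centres mirror exactly; $\rho_1$ is reflected at the join and $\rho_2$
  extended. The emergent map should contain two mirror-image barrel
  fields: twice as many contiguous regions, with strongly correlated
  half-areas per projection.
* `trim_whisker()` — multiplies $\epsilon$ by $m \in (0,1]$ for the
  targeted projections (both competition terms), using the same seed for
  control and trimmed runs so initialization variance cancels from area
  ratios. Row trimming includes the row's interstitial straddler
  ($\gamma$ with row C).

### Problem sizes used by the shipped checks

Package tests and `scripts/acceptance.R` run reduced configurations chosen
once as this package's study conditions: operator and conservation checks
on a ~500-hex ellipse; the 1D-reproduction test ($N = 5$, $M = 3$ offset
logistic gradients at 1/4, 1/2, 3/4 of the long axis, width 0.1 of span)
on a $1\times0.5$ mm ellipse at $d = 0.08$; the headline self-organization
run on the synthetic barrel field at $d = 0.06$ mm (~2250 hexes, half the
full resolution) for 70000 steps; sweep and perturbation runs at
$d = 0.1$ mm with shortened step counts. Reduced runs are scored on
orderings and qualitative outcomes, which is what they resolve reliably;
absolute metric values at full resolution differ by the rasterization
effects described above.

The 70000-step count deserves a note. Under the evenly spaced synthetic
barreloid grid, competition transiently squeezes some interior whiskers
out of the winner-take-all map before their conserved branching mass
reclaims territory, and the last fields to recover need well beyond the
canonical 30000 steps to anneal; 70000 steps is the count at which the
shipped checks find every whisker holding one contiguous field. The slow
recapture is a property of the degenerate, regular synthetic coordinates
— with irregular (real) barreloid positions neighbouring projections
differentiate sooner. When counting regions at finite $d$, connected
components below 3 hexes ($\approx 0.009$ mm$^2$ at $d = 0.06$) are
treated as argmax rasterization slivers, not fields. Similarly, the
whisker-trimming and duplication experiments run at coarser spacing and
shorter horizons where their *directional* claims (areas shrink
monotonically with competition loss, the trimmed barrel vanishes below
half strength, row trimming attenuates shrinkage, the mirrored map
duplicates each field) are resolved; the shrinkage magnitudes at that
scale are more severe than full-resolution ones because the trimmed
barrel is still reclaiming territory when scored.

## Known limitations

* The competition discretization is not exactly conservative on rough
  states (see above); mass drift is monitored, not corrected.
* Honda-delta values are resolution-dependent through the rasterization
  floor and the axis-aligned generator constraints make the optimization
  path only approximately rotation-invariant (observed wobble ~0.002).
* The microvibrissae, rhinal whiskers, and any mechanistic transcription
  network behind the gradients are out of scope; guidance fields are
  phenomenological.
* Run containers are plain text (CSV/JSON/YAML/SVG) for portability and
  diff-ability; large binary state formats are deliberately avoided.
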