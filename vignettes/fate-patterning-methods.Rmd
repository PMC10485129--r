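---
title: "Cell fate patterning on cell graphs: model, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell fate patterning on cell graphs: model, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatepattern)
```

# The model

Each cell carries two antagonistic, auto-activating transcription factors,
u and v, whose promoter occupancies follow Boltzmann statistics over the
binding configurations of u, v and an extracellular signal s. In the
specialized model the mutual inhibition is of the blocking type (u and v
can never be bound at the same promoter simultaneously), the signal blocks
u outright and cooperates with v (weight `eta_vs >= 1`). That yields the
occupancies

$$
p_u = \frac{\eta_u u}{D}, \qquad
p_v = \frac{\eta_v v\,(1 + \eta_s \eta_{vs} s)}{D}, \qquad
D = 1 + \eta_v v (1 + \eta_s \eta_{vs} s) + \eta_u u + \eta_s s ,
$$

and per-cell dynamics `du/dt = r_u p_u - gamma_u u` (likewise for v). Every
`eta` is the exponential of a binding energy difference,
`eta = exp(-delta_eps)`; the constructors accept either scale and convert
once. `bindingProbabilities()` also implements the fully general
seven-configuration occupancy (interaction weights `eta_uv`, `eta_us`,
`eta_uvs`); the general partition sum includes the lone signal-bound
configuration (the `eta_s s` term in D), which is required for the
specialized forms above to emerge as the exact `eta_uv = eta_us =
eta_uvs = 0` case.

A single cell at fixed signal has three steady states: silence (0, 0) —
excluded as a fate whenever `eta_v > gamma_v/r_v` — and the two one-hot
plateaus

$$
u^+v^-: u = \frac{r_u}{\gamma_u} - \frac{1+\eta_s s}{\eta_u}, \qquad
u^-v^+: v = \frac{r_v}{\gamma_v} -
  \frac{1+\eta_s s}{\eta_v (1 + \eta_s \eta_{vs} s)} .
$$

Exactly one of the two is linearly stable for each signal level; the
switch happens at the critical signal `criticalSignal()`, where the two
branches merge into a degenerate line (flagged by `steadyStates()` at
relative tolerance 1e-9, since exact equality is measure-zero in floating
point). Negative closed-form branches are reported as absent rather than
clamped — they are not concentrations.

On a tissue the cells couple through `s = A u`, with A one of two kernels:

* **neighbor-mean** — the mean u over the contact neighbors (rows of A sum
  to 1);
* **dispersion** — `A_ij = a q^(d_ij - 1)` for hop distance `d_ij` and
  dispersion `q` in [0, 1], with a normalizing the largest row sum to 1.
  `q = 0` (with the 0^0 = 1 convention) is the raw contact indicator,
  `q = 1` equal weight on every other cell. The emitted quantity is the
  sender's u level: the signal is produced in proportion to u, and the
  analytic signal ceiling below relies on exactly that substitution.

Linearizing the full 2N-dimensional system gives a block Jacobian whose
off-diagonal v-blocks are diagonal (s does not depend on v) and whose
u-blocks carry the kernel through the chain rule; `grnJacobian()`
assembles it analytically and reports the leading eigenvalue. Two printed
signs in the source derivation are corrected here because they contradict
the surrounding algebra and the finite-difference oracle: the lower-left
block couples through the v-on-u derivatives (not a repeat of the
upper-right block), the lower-right decay is `gamma_v` (not `gamma_u`),
and the diagonal v-derivative of `p_v` is positive (auto-activation).

## The stability interval

Requiring both homogeneous tissue states to be unstable confines
`-delta_eps_u` to

$$
-\Delta\varepsilon_v + \ln\!\frac{r_v\gamma_u}{r_u\gamma_v}
  + \ln(1 + \eta_s\eta_{vs}\, s_{min})
\; < \; -\Delta\varepsilon_u \; < \;
-\Delta\varepsilon_v + \ln\!\frac{r_v\gamma_u}{r_u\gamma_v}
  + \ln(1 + \eta_s\eta_{vs}\, s_{max}) .
$$

In a heterogeneous state some cells are silent in u, so `s_min = 0`; the
u plateau is bounded by `r_u/gamma_u` and both kernels have maximal row
sum 1, so `s_max` approaches `r_u/gamma_u` whenever the plateau correction
`(1 + eta_s r_u/gamma_u)/eta_u` is small against it (`signalBounds()`
checks this separation and warns at less than a factor of ten).
`stabilityInterval()` evaluates the general bounds or, by default, this
approximation. Inside the interval only two-type mixtures are stable;
below it the tissue collapses to all-`u-v+`, above it to all-`u+v-`. The
test suite confirms the endpoints against sign changes of the Jacobian's
leading eigenvalue at the corresponding homogeneous states on a periodic
hexagonal fixture (agreement to better than 1% of the interval width).

## Default parameters

The defaults are pinned to the quantitative constraints the model's
benchmark facts impose, rather than chosen freely:

| parameter | default | why |
|---|---|---|
| `r_u = r_v` | 0.1 | production/decay ratio 0.1 sets the concentration scale |
| `gamma_u = gamma_v` | 1 | time unit = one decay time |
| `eta_v` | `exp(6)` = 403.43 | lower interval bound exactly 6 (equal rates, s_min = 0) |
| `eta_s` | 5 | one free split of the constrained product below |
| `eta_vs` | `(exp(1.87)-1)/0.5` = 10.98 | upper bound exactly 7.87: `eta_s*eta_vs*0.1 = exp(1.87)-1` |
| `eta_u` | `exp(6.935)` | interval midpoint; swept in experiments |

Only the product `eta_s * eta_vs` is constrained by the interval width;
the 5 / 10.98 split keeps the separation quality
`(1 + eta_s * 0.1)/eta_u <= 0.0043` over the whole interval (0.0037 at the
lower end), so the interval approximation and the signal ceiling are valid
everywhere the package sweeps. `eta_vs = 10.98 >= 1` respects the
cooperative-activation assumption, and `eta_v = 403 > gamma_v/r_v = 10`
excludes the silent fate.

# Tissues

`discTissue()` emulates an organoid cross-section: equal-radius cells
jammed into a disc. Blue-noise (best-candidate) sampling seeds the
positions; repulsive truss relaxation along the current Delaunay edges,
with rest length 1.25 times the hexagonal-packing spacing, then jams the
packing into a locally even but globally irregular arrangement (a small
over-pressure is what drives the packing toward six contacts per bulk
cell). The contact graph is the Delaunay triangulation (implemented
in-package, Bowyer-Watson) pruned of edges longer than the contact
distance `2 * radius`; hop distances come from breadth-first shortest
paths via igraph.

The cell radius is half the median nearest-neighbor spacing times a
contact factor. In an irregular packing the distances to *touching*
neighbors spread roughly ±10% around that median, so a factor barely
above 1 would disconnect most true contacts; the default factor 1.3 sits
above that spread while staying below the first non-contact Delaunay
shell. With it, 177-cell tissues measure: mean degree 5.35 (range
5.28–5.40 over ten seeds), bulk cells ≈ 5.9 contacts, boundary cells
3–4, always connected. Generation is deterministic per seed, and
disconnected graphs (possible in principle, never observed at the
default factor) trigger a seeded retry and, after five failures, an
error — the data model tolerates infinite distances but the dispersion
kernel at `q = 1` would be ill-posed on them.

Two idealized fixtures support the analytic results: `hexLattice()`
(combinatorial odd-row-offset adjacency; periodic wrapping needs an even
row count, and coincident wrapped neighbors on small tori deduplicate to
simple-graph edges) and `lineGraph()` (a 1-D chain, `d_ij = |i-j|`).

# Dynamics and numerics

The reference integrator is explicit Euler with the signal recomputed from
the current u at every step — the signal is an instantaneous response, not
a dynamic species. Defaults: `dt = 1e-2 * min(1/gamma_u, 1/gamma_v)`
(two orders below the fastest decay scale; the early autocatalytic growth
rate `r_u eta_u` stays below 2/dt across the sweep range, the Euler
stability bound), convergence when the max-norm of the derivative vector
drops below `tol = 1e-8`, step cap 1e7. Halving dt moves converged states
by less than 1e-4 relative (tested). Negative undershoots would be clipped
at 0 and counted; at the default step none occur. Concentrations below
1e-30 are flushed to exact zero: they are twenty-seven orders of magnitude
below the plateau, dynamically dead, and subnormal arithmetic is
pathologically slow. The inner loop is compiled (Rcpp) with a sparse-row
path for contact kernels; a pure-R twin of the update rule serves as the
cross-check oracle in the tests.

Initial conditions emulate a field of nearly unexpressed, slightly noisy
cells: independent uniform draws in `[0.9, 1.1] * c0` for both factors,
`c0 = 1e-3 * r_u/gamma_u`. Silence is a fixed point, so strictly positive
noise is required for the pattern to self-organize; the magnitude is far
below the plateau so no memory of the initial field survives.

Convergence times vary enormously across `-delta_eps_u`: mid-interval runs
on 177 cells take ~3e5 steps, but close to a proportion jump a frustrated
cell pair can creep for millions of steps (critical slowing down). This is
a property of the dynamics, not the integrator. `bisectRatio()` therefore
treats an evaluation that exhausts `max_steps` as informative-but-unreliable:
its dominance count (u > v) steers the bracket, it is flagged in the
trace, and it can never be returned as the final state.

`classifyFates()` labels a converged cell `u+v-` iff
`u > ratio_threshold * v` (default 1 — the steady states are near one-hot,
and labels are insensitive to thresholds across [0.5, 2], tested);
relative ties within 1e-6 become "undecided" and are refused by the PCF.

## Proportions and their jumps

`proportionSweep()` divides the stability interval into `n_grid = 20`
equidistant `-delta_eps_u` values (endpoints included — they demonstrate
the homogeneous limits) and simulates each from the same seeded initial
field. The u-fraction rises monotonically up to stochastic jitter, but in
steps: under nearest-neighbor signaling a cell keeps the `u+v-` fate only
if at most

$$
l^{max} = \left\lfloor |N_G(i)|\, \frac{\gamma_v}{r_v}\,
  \frac{\eta_u - \eta_v}{\eta_v \eta_s \eta_{vs}} \right\rfloor
$$

of its neighbors share it (`lMax()`). Near the interval's ends
`l_max = 0`, so minority cells form a maximal non-adjacent arrangement;
on an ideal six-neighbor lattice the densest such arrangement is exactly
1/3 of the cells (the acceptance suite verifies this by exact independence
number on a 6x6 torus), and on irregular tissues the realized extreme
minority fraction averages ≈ 27%. Proportions between ~0 and ~27% (and
symmetrically 73–100%) are therefore unreachable under nearest-neighbor
signaling — proportion control is quantized by tissue geometry.

`bisectRatio()` finds the `-delta_eps_u` for a target split by bisection,
each evaluation a full steady-state run from the same seeded initial
field, stopping at an exact hit or when the bracket is below resolution
(then the nearest achieved split is returned, flagged). On the 177-cell
tissue the balanced 89:88 split is reached exactly with the `q = 0.5`
dispersion kernel; at `q = 0.1` the count function jumps 88 → 92 for the
tested seed, so 88:89 is the closest balanced split there.

# Pattern quantification

`pairCorrelation()` counts, for every hop distance k, the ordered cell
pairs of equal type and normalizes by the probability of drawing two
same-type cells without replacement:
`rho_u(k) = (|S^u_k|/|S_k|) / (|T^u|(|T^u|-1)/(N(N-1)))`. Ordered-pair
semantics are used consistently in numerator and denominator, so the
ratios equal the unordered convention (the counts themselves differ by a
factor of two; `pairCounts(..., ordered = FALSE)` exposes the other
convention). Distances with no pairs are omitted to avoid 0/0; the
normalization requires at least two cells of each type. Under uniformly
random labeling with fixed counts the expectation is exactly 1 at every
distance (hypergeometric), which the tests verify within Monte Carlo
error. Checkerboards show `rho` below 1 at distance 1; engulfing patterns
show the minority type's `rho` far above 1 at short range and collapsing
to 0 at long range.

# What the synthetic tissues do and do not show

The generator reproduces the contact statistics that drive the model —
equal radii, ~5.4 mean degree, six-neighbor bulk, three-to-four-neighbor
boundary, irregular spacing — and the boundary effect that cells at the
rim receive less dispersed signal, which is what pushes `u+v-` fates
outward at high q. It does not emulate cell division, movement, sorting,
apoptosis, heterogeneous radii, or 3-D geometry; passing tests therefore
validate the signaling-and-decision mechanism on static tissues, not a
full developmental trajectory. Euclidean-distance correlation functions
and time-resolved (diffusing) signals are likewise out of scope; the
kernels are algebraic stand-ins for the range of a secreted molecule.

# Problem sizes used in the shipped checks

The test suite and the acceptance script use the 177-cell tissue for
headline quantities (sweeps over 10 seeds, 20 grid values; 1000–4000
random labelings for the correlation null; bisection at q = 0.5), a
60-cell disc for property checks, and 4x4–6x6 hexagonal fixtures for the
analytic cross-checks. Sweep and bisection runs there cap the integrator
at 2–2.5 million steps (20,000+ decay times): a run still drifting at that
point is one of the critically slow single-cell flips described above,
whose dominance count already equals the eventual steady state to within
one cell. These sizes keep a full run on a single CPU in the minutes range
while matching the tissue scale the model was built around.

# Known limitations

* Near proportion jumps the Euler dynamics exhibit genuine critical
  slowing down; runs there may need the full step budget, and bisection
  may legitimately report a nearest-achievable split instead of an exact
  one.
* The dispersion kernel's normalization is computed once per tissue; it
  is not re-derived if the graph changes (tissues here are static by
  design).
* The Bowyer-Watson triangulation handles the package's point sets
  (jittered packings, small patches) robustly but is not a general-purpose
  computational-geometry library; highly degenerate co-circular inputs
  beyond the shipped fixtures are untested territory.
* `eta_vs` enters only through the product `eta_s * eta_vs` everywhere in
  the analysis; the split is conventional, and experiments that vary one
  without the other cannot be distinguished by this model.
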