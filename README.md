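# fatepattern

Tissues that must split into two cell types — epiblast versus primitive
endoderm in the early mouse embryo, neural versus epidermal progenitors in
*Drosophila* — often decide each cell's fate through a pair of antagonistic
transcription factors coupled to a signal exchanged between cells.
`fatepattern` simulates such a system on irregular two-dimensional tissues
and provides the analytic machinery that explains what the simulations do:
which parameter ranges force a two-type mixture, what cell-type proportions
are reachable, and how the spatial range of the signal moves the pattern
from a checkerboard to one type engulfing the other.

The package is aimed at modelers of developmental patterning who want a
small, fully scriptable system: every tissue, kernel and simulation is
generated in code from a seed, and every analytic claim is available as a
function next to the simulator it describes.

## Model

Each cell i carries concentrations `u_i` and `v_i` of two auto-activating,
mutually inhibiting transcription factors. Promoter occupancy comes from
Boltzmann statistics over binding configurations, giving the coupled ODEs

    du_i/dt = r_u * eta_u u_i / D_i                         - gamma_u u_i
    dv_i/dt = r_v * eta_v v_i (1 + eta_s eta_vs s_i) / D_i  - gamma_v v_i

    D_i = 1 + eta_v v_i (1 + eta_s eta_vs s_i) + eta_u u_i + eta_s s_i

where each `eta = exp(-delta_eps)` is the statistical weight of a binding
configuration and `s_i` is the received signal: either the mean `u` of the
contact neighbors (nearest-neighbor kernel), or a normalized sum of
`q^(d_ij - 1)`-weighted contributions over the whole tissue (dispersion
kernel, graph distance `d_ij`, dispersion `q` in [0, 1]).

Key analytic results exposed as functions:

* `criticalSignal()` — the received-signal value `s*` at which a single
  cell switches between the `u+v-` and `u-v+` fates;
* `stabilityInterval()` — the interval of `-delta_eps_u` in which both
  homogeneous tissue states are unstable, so only two-type patterns
  survive; with the shipped defaults it is `(6, 7.87)`, i.e.
  `eta_u` in `(403.43, 2617.5)`;
* `lMax()` — how many same-fate neighbors a `u+v-` cell tolerates, which
  quantizes the reachable cell-type proportions;
* `grnJacobian()` — the full 2N x 2N linearization on any tissue;
* `pairCorrelation()` — graph-distance pair correlation functions
  `rho_u(k)`, `rho_v(k)` that quantify checkerboard (rho < 1 at k = 1)
  versus engulfing (rho_v high at small k, low at large k) patterns.

## Worked example

```r
library(fatepattern)

p   <- defaultParams()            # r_u/gamma_u = 0.1, interval (6, 7.87)
tis <- discTissue(177, seed = 1)  # irregular disc packing
g   <- contactGraph(tis)          # pruned Delaunay contacts
K   <- neighborMeanKernel(g)

st <- classifyFates(simulateTissue(g, K, p, seed = 7))
st
#> TissueState: 177 cells, t=3024, converged (302350 steps)
#>   fates: 59 u+v-, 118 u-v+, 0 undecided

stabilityInterval(p)
#> StabilityInterval: -delta_eps_u in (6.0000, 7.8700)  [eta_u in (403.43, 2617.57)]
#>   signal range used: [0, 0.1]

sw <- proportionSweep(g, K, p, n_grid = 20, seed = 7)
round(sw@prop_u[1:5], 3)
#> [1] 0.000 0.260 0.260 0.260 0.260
```

The simulation settles into a checkerboard-like mixture (59 of 177 cells
adopt the `u+v-` fate at the interval midpoint). The sweep shows the
homogeneous endpoint followed by the first heterogeneous plateau at 26% —
the minority fraction is pinned near 1/3 by `lMax = 0` geometry, and across
seeds averages about 27%. Replacing the kernel with
`dispersionKernel(g, 0.9)` and bisecting to a balanced ratio
(`bisectRatio(g, K, p, c(88, 89))`) produces an engulfing pattern whose
`pairCorrelation()` shows `rho_v` near 1.9 at distance 1 and 0 beyond
distance 10.

A YAML-driven interface (`readRunConfig()` / `runExperiment()`) and a thin
CLI (`inst/scripts/fatepattern.R`) cover the same workflow end to end and
write per-cell state CSVs plus reproducibility metadata.

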