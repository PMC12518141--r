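---
title: "Ordering kinetics of an active nematic monolayer under an aligning field: models, estimators and design choices"
author: "nemakin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ordering kinetics of an active nematic monolayer under an aligning field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(nemakin)
```

# The physical picture

A confluent monolayer of elongated cells behaves as a two-dimensional active
nematic: each cell defines a headless orientation axis, neighbouring cells
align, and the collective generates extensile dipolar stresses along the
local elongation axis. When a steady shear flow passes over such a layer, the
flow acts as an external aligning field that energetically penalizes
orientations perpendicular to the flow axis. Ordering then emerges from a
competition:

* the **field** pulls the director towards the flow (x) axis,
* the **activity** feeds energy into orientation fluctuations, nucleating
  pairs of +1/2 and -1/2 topological defects,
* **elasticity** relaxes gradients and drives defect annihilation.

Depending on the relative strength of activity and field, the defect count
can decay monotonically, saturate in a defect-laden turbulent steady state,
stay in a disordered isotropic state, or follow a *non-monotonic* three-stage
trajectory: initial ordering, a transient defect-nucleation phase, and a
final coarsening to near-perfect alignment.

Because the field breaks rotational symmetry down to a mirror symmetry, the
aligned state is doubly degenerate: the signed rejection
$\delta n_\perp = \sin\alpha$ (the perpendicular component of the director
with the convention $\alpha \in (-\pi/2, \pi/2]$) can be positive or
negative at equal energy. Domains of either sign are separated by walls
along which the director sweeps either through the flow axis
($\alpha = 0$; "green", low energy) or through the perpendicular orientation
($\alpha = \pm\pi/2$; "red", high energy). Red walls bind defect pairs; their
decay is a signature of the final ordering stage.

# The continuum model

The simulator (`sim_params()`, `sim_init()`, `sim_step()`,
`run_experiment()`) integrates Beris–Edwards Q-tensor dynamics on a periodic
2D grid. The order parameter is the full symmetric traceless $3\times3$
tensor $Q$ (5 degrees of freedom per node, initialized in-plane):

$$(\partial_t + \mathbf{u}\cdot\nabla) Q - S - f_Q = \Gamma_Q H,$$

with the co-rotation term
$S = (\xi D + \Omega)\,\mathcal{Q} + \mathcal{Q}\,(\xi D - \Omega)
 - 2\xi\,\mathcal{Q}\,\mathrm{tr}(QW)$, where
$\mathcal{Q} = Q + I/3$, $W = \nabla\mathbf{u} = D + \Omega$, and $\xi$ the
flow-aligning parameter. The molecular field is
$H = -\left(\delta\mathcal{F}/\delta Q
 - \tfrac{1}{3} I\, \mathrm{tr}\, \delta\mathcal{F}/\delta Q\right)$ with the
free-energy density

$$f = A_0\left\{\tfrac12\left(1 - \tfrac{\nu}{3}\right)\mathrm{tr}Q^2
      - \tfrac{\nu}{3}\mathrm{tr}Q^3
      + \tfrac{\nu}{4}\left(\mathrm{tr}Q^2\right)^2\right\}
      + \tfrac{K}{2}(\nabla Q)^2 - \epsilon_0\, E\!:\!Q\!,\qquad E = e\otimes e,$$

where $e$ is the unit vector of the preferred (flow) axis. The momentum
balance is incompressible Stokes flow with substrate friction,

$$\gamma \mathbf{u} - \eta \nabla^2 \mathbf{u}
  = -\nabla p + \nabla\cdot\Pi, \qquad \nabla\cdot\mathbf{u} = 0,$$

with the elastic stress
$\Pi^{el} = 2\xi\mathcal{Q}(Q\!:\!H) - \xi H\mathcal{Q} - \xi\mathcal{Q}H
 - K\,\partial_a Q\!:\!\partial_b Q + QH - HQ$
and the active stress $\Pi^{act} = -\zeta Q$ (extensile for $\zeta > 0$). An
optional active torque
$f_Q = 2\omega s\,[-Q_{xy}, Q_{xx}; Q_{xx}, Q_{xy}]$ models spontaneous
self-generated rotation of the cells, which breaks the mirror symmetry.

## Parameters and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `A0` | 0.05 | Landau–de Gennes energy scale |
| `nu` | 2.55 | bulk shape factor; favours the isotropic state without field or activity |
| `K` | 0.02 | one-constant elasticity |
| `xi_align` | 0.9 | flow-aligning parameter (deep in the aligning regime) |
| `Gamma` | 0.1 | rotational mobility |
| `zeta` | 0.03 | extensile activity |
| `eta` | 2/3 | film viscosity |
| `gamma_f` | 0.1 | substrate friction |
| `eps0` | 0.5 | aligning-field strength |
| `omega`, `s` | 0, 0 | active-torque magnitude and sense |

All quantities are in simulation (lattice) units; one node is one length
unit and one step of `dt` one time unit. The defaults fix the three
analytic timescales returned by `timescales()`:
$\tau_\zeta = \eta/\zeta = 22.2$ (activity),
$\tau_n = 1/(\Gamma A_0) = 200$ (intrinsic nematic coarsening) and
$\tau_e = 1/(\Gamma \epsilon_0) = 20$ (field). `Gamma` and `eps0` are not
independently identifiable from the remaining printed constants; the pair
(0.1, 0.5) is the unique choice reproducing $\tau_n = 200$ and
$\tau_e = 20$ simultaneously, and is adopted as the package default.

## Numerical scheme and stability

Q is advanced with explicit Euler; derivatives are centred differences on
the periodic grid. The velocity is re-solved every step pseudo-spectrally:
the stress divergence is projected onto divergence-free modes and divided by
$\gamma + \eta k^2$ (`solver_mode = "hydrodynamic"`) or by $\gamma$ alone
(`"overdamped"`). The Nyquist wavenumber is zeroed in the first-derivative
operators so the projected velocity is exactly real; the resulting relative
divergence is at machine precision. Passive runs tolerate `dt` up to ~5
(diffusive limit $\Gamma K = 0.002$ per node²); active runs use `dt = 0.5`–1.
`sim_step()` aborts with a diagnostic if the field norm diverges.

The initial condition is in-plane uniaxial order of amplitude
`init_amplitude` (default 0.1) with i.i.d. uniform director angles, seeded
from `sim_params(seed = ...)` — an orientational quench.

## The phase diagram at desk scale

The package's own scan of $(\zeta, \epsilon_0)$ at $96^2$, `dt = 1`,
reproduces all four regimes of the taxonomy (`classify_regime()`):

* $(\zeta, \epsilon_0) = (0.03, 0.2)$: **monotonic** (field dominates),
* $(0, 0)$: **isotropic** — with $\nu = 2.55$ the order magnitude $|Q|$
  decays to zero; since director *angles* of a vanishing $Q$ still carry
  apparent order, the label keys on the recorded `mean_amplitude`
  falling below `A_low = 0.1`,
* $(0.3, 0.01)$: **active turbulence** (sustained defect density, low order),
* $(0.031, 0.01)$, seed 1: **non-monotonic** — the documented operating
  point: the quench first anneals almost completely, a secondary defect
  wave nucleates and grows to ~90 defects around $t \approx 7000$, then
  annihilates while global order climbs to ~0.8.

The non-monotonic band is narrow in both parameters (between $\zeta = 0.03$,
which barely nucleates, and $\zeta \gtrsim 0.035$, which sustains
oscillatory defect waves indefinitely at desk scale) — at the baseline
$\epsilon_0 = 0.5$ the field quenches activity outright, which is why the
documented operating points sit at weak fields. Regime thresholds
(`S_low = 0.1`, `S_mid = 0.3`, `S_high = 0.6`, `rho_nm = 1.5`,
`N_high_frac = 0.1`, `A_low = 0.1`) are configurable and reported with
every label.

# The analysis chain

## Director extraction

`extract_orientation()` implements the structure-tensor method: the image is
smoothed with a Gaussian of $\sigma = \mathrm{box}/6$ (tying the smoothing
scale to the averaging box; the kernel itself is a free choice), the tangent
$t = (I_y, -I_x)$ is formed from centred-difference gradients, and
$t \otimes t$ is box-averaged. The director is the dominant eigenvector,
`coherence` the eigenvalue difference $n_1 - n_2$, and nodes below $10^{-3}$
of the frame's median coherence are masked rather than interpolated —
orientation is never fabricated in featureless regions. Defaults follow a
130 µm box with 5.2 µm node spacing. Angles are folded into
$(-\pi/2, \pi/2]$, measured from the flow axis; `dual_angle_maps()` derives
the $[0, \pi)$ representation on demand.

## Defect detection and statistics

Two detectors are provided. `detect_defects()` is the image-side method:
charge density
$q = \tfrac{1}{4\pi}(\partial_x Q_{xk}\,\partial_y Q_{yk}
 - \partial_x Q_{yk}\,\partial_y Q_{xk})$ (sum over $k \in \{x, y\}$, unit
order magnitude, node-unit derivatives), thresholded at $|q| > 0.1$ with
every fifth node considered, connected cores merged within
$2 \times \mathrm{box}$. `detect_defects_winding()` is the simulation-side
method: the nematic winding around every grid plaquette is quantized in
units of $\pi$, each $\pm\pi$ plaquette is exactly one $\pm1/2$ defect, and
total charge is exactly zero on a periodic domain. The charge-density
threshold misses smeared annihilating cores on simulated fields, which is
why `run_experiment()` defaults to the winding detector; `winding_number()`
provides the loop oracle used to cross-check both.

`link_trajectories()` performs greedy globally-nearest linking, segregated
by charge (charge is conserved along a worldline), with gap closing and the
4-hour persistence filter. `knn_opposite_distances()` returns, for every
defect, the distances $d_0 \le d_1 \le d_2 \le d_3$ to the nearest opposite-
charge defects, with per-frame means, standard deviations and the per-defect
table (from which medians can be formed — at desk-scale counts of ~10
defects the median tracks the bound-pair population while the mean is
dominated by a few unbound stragglers).

## Strings

`string_maps()` marks a green edge where $|\Delta\alpha_1| > \pi/2$ between
4-neighbours and a red edge where $|\Delta\alpha_2| > \pi/2$; each jump edge
rasterizes to both incident nodes. `measure_strings()` labels components
(8-connectivity), discards components under 3 nodes as border noise, thins
each to a unit-width skeleton (Zhang–Suen, implemented here since no
installed package provides thinning), and measures length as the
minimum-spanning-tree edge length of the 8-neighbour skeleton graph —
orthogonal steps count as one spacing, diagonal steps as $\sqrt2$ (the
diagonal convention is a documented choice). Diagonal neighbour pairs are
not themselves tested for angle jumps, matching the per-axis difference
definition.

A topological note on the bound-pair fixture
(`make_pair_with_string()`): for an isolated $\pm1/2$ pair built from the
standard ansatz, the director at the midpoint always differs from the far
field by exactly $\pi/2$. A pair with far field along the preferred axis is
therefore necessarily joined by a red wall (and flanked by green tails
ending at the cores); the "parallel class" fixture is the same construction
rotated by $\pi/2$ in director space, so its far field is perpendicular to
the axis. Both fixtures assert their wall class by running `string_maps()`
on their own output.

## Correlation functions and scaling

`rejection_and_domains()` produces $\delta n_\perp$ and the signed domain
map; `correlation_function()` computes
$C(\Delta r) = \langle \delta n_\perp(r)\,\delta n_\perp(r + \Delta r\,
\hat e_{axis})\rangle / \langle \delta n_\perp^2\rangle$ along the parallel
(x) or perpendicular (y) axis, averaging over all valid node pairs (masked
nodes are excluded pairwise, never imputed) up to half the domain. The field
is not mean-subtracted, so a uniform bias raises the long-range plateau
(reported as the mean of $C$ over the largest-lag quartile).
`correlation_length()` interpolates the first crossing of $1/e$ — the
conventional reading of the $1/\epsilon$ level — and reports the plateau
when no crossing exists. `growth_exponent()` fits the log–log slope with a
percentile-bootstrap CI over time points; `collapse_error()` quantifies
scaling collapse as the mean squared inter-curve deviation on a common
rescaled-lag grid. `bootstrap_ci()` is a percentile bootstrap of the mean
with 1000 iterations by default, deterministic given a seed and isolated
from the global RNG stream. Phase boundaries between the kinetic stages are
identified operationally as the extrema of the 5-frame moving-median
defect-count series.

# Synthetic data: what it emulates, and what it does not

`make_defect_texture()` builds the standard multi-defect angle ansatz with
exact windings. `make_correlated_rejection_field()` draws $\delta n_\perp$
as a stationary Gaussian field with a separable Gaussian correlation kernel
synthesized spectrally, then verifies its own realized $1/e$ lengths and
rescales the kernel if a draw misses the target by more than 5% — the
contract holds regardless of kernel family. `make_oriented_texture_image()`
renders a phase-contrast-like texture by filtering seeded noise through a
bank of oriented Gabor kernels (carrier perpendicular to the director,
envelope elongated along it; 48 orientation channels blended per pixel) plus
Gaussian sensor noise.

Round-trip resolution floor, enforced in the test suite: median angular
error < 2° on uniform textures; detected defect positions within ~2 box
widths of ground truth (cell-scale textures, wavelength 6 px and streak
length 10 px, localize cores to a few pixels); correlation lengths within
10% at (20, 5) node spacings on a 256² grid.

The generators emulate oriented cellular texture, defect cores, domain
walls and anisotropic correlations. They do **not** emulate cell division
and extrusion, density inhomogeneity, illumination gradients, stitching
artefacts, or the mechanosensitive response of real endothelial layers —
passing tests demonstrate correctness of the estimators on fields with the
assumed statistical structure, not robustness to all properties of real
microscopy data.

# Documented study conditions

The quantitative checks in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R` run these fixed configurations (96² unless noted,
`dt = 1`, seed 1 — the seeds are part of the documented conditions; the
script's `--seed` drives every other stochastic component):

* **Passive growth law**: $\zeta = 0$, $\epsilon_0 = 0.002$, 128²,
  `dt = 2`, overdamped with $\gamma = 10$ — the friction-dominated limit
  appropriate for a substrate-attached monolayer, in which the coarsening
  law is not masked by backflow (with backflow on, the measured parallel
  exponent rises to ~0.65, a real hydrodynamic enhancement). The weak field
  puts saturation at $\tau_e = 5000$, so the fitting window
  $t \in [1000, 5000]$ precedes it; the measured slope is 0.52 (seed 1),
  consistent with diffusive $t^{1/2}$ coarsening.
* **Regime corners**: $(0.03, 0.2)$ monotonic, $(0, 0)$ isotropic,
  $(0.3, 0.01)$ turbulent, each to $t = 900$–1500.
* **Non-monotonic / binding / strings**: $(0.031, 0.01)$ to $t = 8500$
  (binding and taxonomy) and $(0.03, 0.01)$ to $t = 3000$ (a fully
  coarsening cycle for the string decay: red strings vanish by run end
  while green strings persist in the aligned state — green walls are
  zero-crossing lines of $\delta n_\perp$ and survive at zero energy cost).

Problem sizes were chosen so the whole suite completes on a single desktop
core: simulation grids 48²–128², image fixtures 128–192 px, bootstrap 200
iterations in pipeline tests and 1000 where the CI itself is under test.

# Known limitations

* Pure R integration limits practical runs to ~10⁴ steps at 128²; the deep
  coarsening regime with hundreds of persistent bound pairs (large fields
  of view over days of imaging) is out of desk-scale reach, which is why
  the binding diagnostic uses medians over ~10 remaining defects.
* The explicit Euler / pseudo-spectral combination is first-order in time;
  `dt` must respect the advective stability limit in strongly active runs.
* The charge-density detector inherits the unstated normalization of the
  0.1 threshold; it is configurable, and the winding detector provides the
  topologically exact alternative.
* Anti-aliasing of the nonlinear terms is not performed; at the default
  parameters spectral content at the grid scale is strongly damped by
  elasticity, and conservation diagnostics stay at tolerance throughout.
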