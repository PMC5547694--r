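---
title: "Mechanical cell elimination in a growing vertex-model epithelium: model, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanical cell elimination in a growing vertex-model epithelium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`mcevertex` simulates the apical surface of a growing epithelial sheet as a
two-dimensional vertex model. Each cell is a polygon of shared vertices; every
vertex moves down the gradient of the tissue energy

$$U = \sum_\alpha \tfrac12\,(A_\alpha - A_{0,\alpha})^2
    + \sum_{\langle\alpha\beta\rangle} \Lambda_{\alpha\beta}\, l_{\alpha\beta}
    + \sum_\alpha \tfrac{\Gamma_\alpha}{2}\, L_\alpha^2 ,$$

in dimensionless units (lengths in units of $\sqrt{A_0}$, the natural cell
area; energies in units of the area elastic modulus). The three terms are area
elasticity, line tension/adhesion on each cell-cell edge, and contractility of
the cell perimeter. Vertices follow the overdamped dynamics
$\eta\,\dot{r}_i = -\partial U/\partial r_i$ with $\eta = 1$.

Growth is driven by a per-cell cycle clock. When a clock passes its cycle
length $T$ (drawn per cell with 20% uniform jitter around
$\bar T = \log 2/\mu$), the cell enters mitosis: its natural area ramps up
linearly until its actual area has doubled relative to mitosis entry, and the
cell then divides along an axis through its centroid. The axis is the
shortest axis of the vertex-scatter ellipse plus a von Mises deviation with
concentration $\kappa$ (sampled on the doubled angle, because axes have period
$\pi$). Edges shorter than $\theta_{T1}$ are reconnected (T1 rearrangement,
the discrete form of cell intercalation); cells whose area falls below
$\theta_{T2}$ are extruded by collapsing them onto their centroid (T2, the
model's mechanical cell elimination). Tissue-boundary edges carry a tripled
line tension, which keeps the free boundary circular.

The reference parameter set is $\Lambda = 0.14$, $\Gamma = 0.04$,
$\theta_{T1} = 0.1$, $\theta_{T2} = 0.2$, $\kappa = 0$,
$\mu = 3.47\times10^{-3}$ (so $\bar T \approx 200$ time units).

## Fitness, elimination rate and mortality

The tissue fitness is the local exponent of the growth curve,
$\phi_{\mathrm{Tissue}}(t) = \mathrm d\log g(t)/\mathrm dt$, estimated by
centred differences of the median-filtered cell-count series. For a mixed
population it decomposes exactly into the frequency-weighted sum of per-trait
cellular fitnesses $\phi_{\mathrm{Cell},i} = \mathrm d\log g_i/\mathrm dt$.
The elimination rate is $\varepsilon = N_{\mathrm{elim}}/N_{\mathrm{born}}$
per window of fixed tissue-size increment (window size is a config key; the
temporal mean is insensitive to it); mortality and elimination rate are
linked by $m = -\log(1-\varepsilon/2)/T$, since a population that gains one
cell per division and loses $\varepsilon$ per birth multiplies by
$(2-\varepsilon)$ per cycle.

The dependence of $\varepsilon$ on any single mechanical/growth parameter
$\zeta$ is summarised by the Gaussian-type response
$\varepsilon(\zeta) = e^{-\alpha(\zeta-\beta)^2} + \gamma$, fitted by
multi-start nonlinear least squares (`fit_gaussian_response`). A calibrated
response (e.g. `gaussian_response(245, 0.24, 0)` for the line tension) is the
bridge between the mechanical simulator and the competition ODE below.

## Stress tensors

Per-cell stress uses two discrete representations of Cauchy stress, built
from the cell pressure $P_\alpha = -(A_\alpha - A_{0,\alpha})$ and per-cell
edge-tension shares
$T_{ij,\alpha} = \Lambda_{\alpha\beta}/2 + \Gamma_\alpha L_\alpha$:

* **Method A** integrates the linearly interpolated vertex forces around the
  polygon: $\sigma^{(A)} = \mathrm{sym}\,(\oint F \otimes r)/A$, with the
  pressure acting on each vertex along the outward normal of the segment
  joining its two neighbours. The magnitude of that normal is not stated in
  the sources that define this estimator; we scale it by half the segment
  length, which is the unique choice that makes the summed pressure forces
  equal the integral of $P$ over the cell boundary. This convention is
  isolated in one code path and flagged here deliberately.
* **Method B** sums edge dyads:
  $\sigma^{(B)} = -P\,I + \sum_{ij} (T_{ij,\alpha}/A)\,
  r_{ij}\otimes r_{ij}/\lVert r_{ij}\rVert$. The tension entering it is the
  per-cell share (half the whole-edge line tension plus the cell's own
  perimeter term); boundary edges have a single incident cell which carries
  the full tripled tension.

Both are symmetric by construction, rotate covariantly, and agree strongly
with each other and with cell geometry on relaxed pure-population tissues:
stress magnitude ($\sigma_1+\sigma_2$) correlates with cell area, stress
anisotropy ($\sigma_1-\sigma_2$) with shape anisotropy, and the maximum
principal direction with the shape long axis (orientation statistics use
doubled angles; the reported direction correlation is the Fisher-Lee circular
correlation). Method B is the default for per-batch tracking because it is
cheapest; the acceptance analyses can use either.

## Feedback laws

Three stress-dependent regulation modes can be switched on:

* **growth gating** — the cycle clock runs only while the cell's stress
  magnitude is at least $\bar S$, the mean interior stress magnitude of the
  relaxed initial tissue (computed once, before growth starts). Compressed
  cells wait; crowding self-limits at the cost of slower growth.
* **fluidity feedback** — the contractility (default) or line tension of each
  cell obeys $\dot\chi = c\,(S - S_{\mathrm{ref}}) - d\,(\chi - \chi^0)$,
  with $S_{\mathrm{ref}}$ either a fixed set point (self mode) or the mean
  over adjacent cells (neighbour mode); $\chi$ is clipped at zero. Positive
  $c$ suppresses cell-size heterogeneity but amplifies stress heterogeneity,
  negative $c$ the reverse. The restoration rate $d$ is not printed in the
  source material; the default $d = 0.1$ (restoration over ~10 time units,
  i.e. a feedback gain $c/d = 0.02$ at the default $c = 0.002$) keeps the
  regulated parameter within about a quarter of its basal value at the stress
  spreads a growing tissue shows — slower restoration multiplies the gain and
  drives rim-cell contractility past the tissue's stability boundary. The
  drive is applied to interior cells only: rim cells carry the artificial
  tripled boundary tension and sit in a strongly tensile state, and driving
  them destabilises the rim.
* **division alignment** — the cleavage plane lies along the minimum
  principal stress direction (for an isotropic tensor it falls back to the
  geometric shortest axis), which suppresses elimination without slowing
  growth.

## Heritable traits and the competition ODE

In mixed populations each cell carries one of $N$ discrete trait values of
the line tension (default grid: 10 values evenly spanning $[0.06, 0.26]$,
the informative range of the calibrated $\varepsilon(\Lambda)$ response; the
grid is a config key and simulator-vs-ODE comparisons always share it).
Daughters copy the parental trait with probability $q$, otherwise draw
uniformly; heritability is estimated as the offspring-on-parent regression
slope. On an edge between cells with different tensions the effective
coefficient is $\max(\Lambda_\alpha, \Lambda_\beta)$ by default (the mean
rule is available).

The per-trait counts obey $\dot x = Q_q\,\Phi(t)\,x$ with the inheritance
matrix $Q_q$ (diagonal $q + (1-q)/N$, off-diagonal $(1-q)/N$). Three
approximations are implemented:

1. **closed form** (high heritability): descendants cluster, so each trait
   feels its own tension; $\Phi$ is constant and
   $x(t) = e^{Q_q \Phi t} x(0)$ by matrix exponential.
2. **mean field** (low heritability): traits are well mixed and trait $i$
   feels $\tilde\Lambda_i = \Lambda_i \sum_{k\le i} f_k +
   \sum_{k>i} \Lambda_k f_k$; $\Phi$ is recomputed from the frequencies at
   every step. The system is integrated in normalised form (frequencies plus
   log population size, with eliminated-cells-per-cell as an auxiliary
   state), which stays well conditioned over horizons where the raw counts
   would overflow.
3. **uniform limit** ($q \approx 0$): the mean-field tensions frozen at their
   uniform-frequency values, solved in closed form.

Cumulative eliminated cells are accumulated as
$\int \sum_i m_i(t)\,x_i(t)\,\mathrm dt$ with
$m_i = -\log(1-\varepsilon_i/2)/T$ — a derived bookkeeping quantity, not an
independent model assumption. An optional proliferation-adhesion tradeoff
multiplies each trait's proliferation rate by the logistic factor
$1/(1+e^{-10\Lambda})$, under which the stationary trait distribution peaks
at an interior tension value.

## The synthetic initial tissue

`generate_initial_tissue()` builds the ~250-cell starting condition:
approximately Poisson-disk points (best-candidate sampling) in a disk whose
area equals the cell count, a Voronoi tessellation clipped to the disk
(computed by half-plane clipping; every mesh vertex is identified exactly by
its defining generator triple, so the per-cell polygons assemble into a
consistent shared-vertex mesh without coordinate rounding), 15 Lloyd
iterations to regularise cell sizes, rescaling to unit mean area, and a short
mechanical settling (10 Euler steps).

Two properties of this construction deserve emphasis, because they were
design decisions rather than givens:

* **The settling is deliberately short.** At the reference parameters the
  energy's mechanical equilibrium has interior cell areas near 0.55, not 1,
  and rim cells with two or more boundary edges have *no* stable area under
  the tripled rim tension — full equilibration extrudes them. Extrusion is
  exactly the process the growth run must own (and log as T2 events), so the
  generator stops after removing local Voronoi-junction imbalances. The
  returned tissue has unit mean area by construction; the growth dynamics
  then contract it toward mechanical equilibrium over the first few time
  units.
* **Cell-size heterogeneity.** After Lloyd regularisation the interior-cell
  CV of area is below 0.1; rim cells of the disk-clipped tessellation keep
  the all-cell CV near 0.10-0.12 across seeds, and further relaxation raises
  (not lowers) it. Tests therefore assert interior CV < 0.1 and all-cell
  CV < 0.15.

What the generator emulates is a confluent, roughly isotropic, unstressed
epithelium; what it does not emulate is any real tissue's boundary condition
(a basement membrane or neighbouring tissue), pre-existing stress, or cell
size distribution. Conclusions from passing tests are therefore about the
model's internal consistency and its qualitative mechanisms, not about any
particular organism.

## Numerical choices

* **Integration.** Explicit Euler with $\mathrm dt = 0.05$ and $\eta = 1$.
  Between event batches (1 time unit each: clock update, divisions,
  relaxation, T1/T2 sweeps, feedback update) the mesh is relaxed in short
  rounds interleaved with T1 and T2 sweeps. The interleaving is essential: a
  long un-swept gradient descent lets a collapsing edge fling its vertices
  past each other. Per-step displacements are clamped at 0.1 length units for
  the same reason. Energy non-increase under relaxation is asserted in the
  tests.
* **Two relaxation timescales.** Per-vertex drag makes the tissue's uniform
  dilation mode slow down with tissue area: left to itself, a growing tissue
  accumulates global compression and the elimination rate creeps up with
  size, whereas the local (neighbourhood-scale) lag behind each division is
  size-independent and carries the growth-rate dependence of elimination.
  The integrator therefore treats the global mode quasi-statically — every
  ten relaxation steps an exact line search over a uniform scale factor about
  the tissue centroid removes the collective compression (the energy is a
  closed-form function of the scale, so the optimum is the root of a cubic
  and the move strictly decreases energy) — while the local dynamics keep a
  finite viscous budget of 40 Euler steps (2 viscous time units) per clock
  unit. Deeper local budgets flatten or invert the growth-rate dependence of
  the elimination rate; without the global line search the elimination rate
  roughly doubles between 500 and 1,500 cells. Both knobs are config keys
  (`relax_max_steps`, `dilate`).
* **The mitotic ramp.** The duration of the natural-area ramp is unstated in
  the model's sources and the elimination rate is sensitive to it: a ramp of
  $0.1\,\bar T$ pushes the neighbourhood faster than it can relax and roughly
  doubles $\varepsilon$ relative to a $0.25\,\bar T$ ramp. We fix the ramp at
  $0.25\,\bar T$ (a mitotic phase of a quarter cycle), which respects the
  quasi-static description and puts the reference elimination rate inside the
  band implied by the calibrated single-parameter responses.
* **Topological robustness.** Divisions, T1 and T2 are transactional: the
  operation is applied, the local mesh is validated (edge incidence counts,
  positive areas on the remodelled cells), and a geometrically impossible
  event is reverted and retried in a later batch. Cells that transiently
  invert between sweeps carry undefined (NA) stress until they recover or
  are extruded. Extrusions leave vertices where four or more cells meet;
  such rosette vertices cannot take part in T1 rearrangements and, left
  alone, progressively jam the tissue until elimination outruns division —
  `resolve_rosettes()` therefore splits every multi-fold junction back into
  three-fold vertices each batch.
* **T1 details.** The new edge is placed perpendicular to the old one with
  length $1.05\,\theta_{T1}$ so it does not immediately re-trigger. Edges on
  the tissue boundary, edges whose endpoints are not simple three-cell
  junctions, and edges on triangular cells are skipped.
* **T2 details.** Collapse to the area centroid is the minimal
  topology-preserving realisation of "removing" a cell; neighbours absorb
  the collapsed vertices, and a neighbour reduced below three vertices is
  removed in cascade (logged as an elimination of its own).
* **Degenerate inputs.** Constant data in the Gaussian response fit returns
  a flagged degenerate fit; constant values give NA Moran's I; an isotropic
  stress tensor reports orientation 0 with a degenerate flag; ties in the
  regional terciles are broken by first occurrence.
* **Randomness.** One R RNG stream per run, seeded from the config; a run is
  reproduced exactly by seed + config. Derived seeds for sweep replicates are
  fixed integer functions of the base seed.

## Problem sizes used in the bundled analyses

The bundled test-suite and acceptance analyses run the model at sizes a
laptop handles in minutes: stress-geometry correlations on a pure-population
tissue grown 250 → ~1,500-1,600 cells; single-parameter response sweeps to
~420 cells per run; feedback comparisons to 420 cells and heredity
comparisons to 700; ODE horizons to a few thousand time units. These are the
package's chosen demonstration scales — the model itself has no
size-specific assumptions, and all scales are config arguments.

## Known limitations

* Strictly two-dimensional, flat, and apical: no cell height, curvature, or
  basal mechanics; extrusion is area-threshold-based with no apoptosis
  program.
* Free boundary with a tripled-tension rim. Small tissues (a few dozen
  cells) are rim-dominated and can evaporate at the reference parameters;
  growth outpaces rim extrusion from a couple of hundred cells upward, which
  is why demonstrations start at 250 cells.
* The elimination rate's absolute level depends on unprinted quasi-static
  parameters (see above); qualitative orderings across parameters and
  feedback modes are the robust outputs.
* At high contractility ($\Gamma \gtrsim 0.055$ at the reference line
  tension) total collapse of the free-boundary tissue is energetically
  downhill from its compressed steady state, so the contractility response of
  the elimination rate saturates there rather than peaking near
  $\Gamma \approx 0.076$.
* Around divisions, the neighbours' pressure drop and their
  tension-per-area rise nearly cancel in the stress-magnitude trace at this
  package's state point, so the mean neighbourhood stress change per division
  is indistinguishable from zero here (the elimination-side release, about
  $+0.07$, and the local density-CV drop are robust).
* Stress-gated cell cycling slows growth as expected but does not lower the
  elimination rate in this implementation: the mitotic natural-area ramp is
  the compressed cell's rescue (it re-inflates it), and gating denies
  compressed cells that rescue.
* The q = 1 tissue-fitness rise over one or two doublings is smaller than
  the measurement noise of the log-derivative estimator; the fitness-rise
  mechanism is demonstrated by the competition ODE, and the vertex runs show
  it through the selection differential (eliminated cells carry markedly
  higher tension than dividing ones) and the decline of the elimination rate
  with heritability.
* The mean-field competition ODE ignores spatial clustering except through
  the two bracketing approximations; intermediate heritability is only
  bracketed, not predicted.
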