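---
title: "Mesoscopic Brownian dynamics of fibrin protofibril networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscopic Brownian dynamics of fibrin protofibril networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(fibrinbd)
```

## The model

fibrinbd simulates the aggregation of fibrin protofibrils -- the
double-stranded polymers of fibrin monomers that laterally associate into
the fibres of a blood clot -- at the mesoscale: large enough to form a
micrometre network, small enough to retain single-protofibril mechanics.

Each protofibril is a chain of 22 nodal points with a 22.5 nm segment rest
length (half of the 45 nm fibrinogen molecule), giving a 472.5 nm contour.
Node positions obey the overdamped Langevin equation

$$ c\,\dot{\mathbf r}_i = -\frac{\partial W}{\partial \mathbf r_i} +
   \mathbf F_i^{rand}, $$

with Stokes friction $c = 6\pi\mu a$ ($\mu$ = 1.2 mPa s plasma viscosity,
$a$ = 8 nm the characteristic fibrinogen radius) and thermal forcing of
magnitude $\sigma = \sqrt{2 c k_b T}$ at $T$ = 300 K. The total potential
$W$ has five harmonic components:

* **Stretch** $W^S = \sum \tfrac{k^S}{2}(|r_{ij}| - r_0^S)^2$ over bonded
  neighbours, $k^S = 0.01$ N/m, $r_0^S = 22.5$ nm.
* **Bend** $W^B = \sum \tfrac{k^B}{2}(\theta_{ijk} - \pi)^2$ over
  consecutive node triples; default $k^B = 10^{-18}$ J/rad$^2$ (sweep
  0.1--10). This makes the chain a stiff rod: the implied persistence
  length, $r_0^S k^B / k_b T \approx 5\,\mu$m, far exceeds the contour
  length.
* **Torsion** $W^T = \sum \tfrac{k^T}{2}\phi^2$ over consecutive
  quadruples with plane normals $m = r_{ij}\times r_{ik}$,
  $n = r_{ki}\times r_{kl}$; $k^T = 10^{-23}$ J/rad$^2$, energetically
  negligible next to bending but retained for completeness.
* **Aggregation** $W^A = \sum \tfrac{k^A}{2}(|r_{ij}| - 2a)^2$ between
  nodes of different protofibrils within the threshold
  $a_{th} = 2r_0^S = 45$ nm (one fibrinogen length); default
  $k^A = 2\times10^{-3}$ N/m (sweep 0.2--20), representing lateral
  crosslinking of the alpha-C regions.
* **Repulsion**, the same harmonic form with $k^R = 10^{-3}$ N/m, active
  only below the fibrinogen diameter $2a = 16$ nm, a linear stand-in for
  excluded volume.

All five forces are exact analytic gradients of the energies, certified
against a central finite-difference oracle in the test suite.

### Which pairs aggregate: the pairing rule

The pairing rule is the one genuinely open modelling decision, and it
controls both the morphology and the mechanics. Three rules are
implemented (`fibrin_params(aggregation_pairing = ...)`):

* `"persistent"` (default): each node carries at most one aggregation
  bond -- the schematic picture of one crosslink joining two adjacent
  nodal points of neighbouring protofibrils. Free nodes bind greedily
  (closest candidate pair first) within $a_{th}$, and an existing bond
  persists until its length reaches $a_{th}$, at which point it
  dissociates. Bonds are therefore identifiable objects whose number
  $n_{agg}$ can be counted and whose survival $n_{agg}/n_{agg}^0$ is
  meaningful.
* `"nearest"`: the stateless variant -- every step each node re-selects
  its nearest partner. Kept for ablation.
* `"all"`: every inter-fibre pair within the threshold interacts. Kept
  for ablation.

The choice is constrained from two sides. Multiplicity: each bond is
worth up to $\tfrac{k^A}{2}(a_{th}-2a)^2 \approx 200\,k_bT$, so under
`"all"` the attraction per node is unbounded and the energy is minimised
by crushing the network into dense globules -- volume-scaled runs show
median tortuosity above 20, hundreds of partners per node, and an
effective stiffness $\sum k^A$ too large for any affordable time step.
One bond per node bounds the stiffness, lets protofibrils zip
side-by-side into bundles, and reproduces the series energy partition
$W^A/(W^A+W^S) = 1/(1+k^A/k^S)$ expected along an aligned loaded path.
Persistence: under the stateless rule a loaded bond can relax by
swapping to a closer partner, so tension never accumulates -- stretched
networks showed no fibres beyond 5% strain and a pair survival visibly
below 1 even at the baseline $k^A$. With persistent bonds tension is
held until the bond is pulled to $a_{th}$ (a force of
$k^A(a_{th}-2a) \approx 5.8\times10^{-11}$ N at the baseline, far above
typical network tensions, hence survival 1; one tenth of that at the
lowest $k^A$, hence occasional dissociation), and the stretched-fibre
fraction rises with applied strain as observed. Repulsion always acts on
every overlapping pair; it is a contact force and cannot cause collapse.

## Integration

The discrete update follows the overdamped form with an operator split:

1. Euler displacement $\Delta \mathbf r = (\Delta t/c) \mathbf F$ from the
   bend, torsion, aggregation and repulsion forces;
2. thermal kick $\sqrt{2 k_b T \Delta t / c}\,\hat{\jmath}$ per
   coordinate, with $\hat{\jmath}$ standard normal via the Box--Muller
   transform over a seeded xorwow uniform stream (bit-reproducible per
   seed);
3. the stiff stretch term advanced by one classical fourth-order
   Runge--Kutta step of $\dot{\mathbf r} = \mathbf f^S/c$ with the other
   contributions frozen.

Putting the stretch term last and under RK4 moves its stability bound
from the Euler $k^S\Delta t/c < 2$ to the RK4 $< 2.785$; parameter
validation enforces $\Delta t \le 1.4\,c/k^S$ (a factor-2 safety) and
$\Delta t \le 0.5\,c/k_{max}$ over the Euler-integrated constants
(aggregation, repulsion, and the effective bending stiffness
$k^B/(r_0^S)^2$). The conservative default is $\Delta t$ = 2 ns; scaled
production runs use 10 ns, which sits inside both bounds under the
nearest pairing rule and was verified empirically (monotone energy
descent without noise, stationary energies and pair counts with noise
over tens of milliseconds). Tight equilibrium statistics are a stricter
matter: the discrete-time stationary variance of a mode with relaxation
rate $\lambda = k/c$ is biased by a factor $\sim 1/(1 - \lambda\Delta t)$,
so the equipartition checks run at 0.5 ns.

Numerical guards: the cosine of every angle is clamped to $[-1, 1]$;
exactly collinear bending triples get zero bending force (the gradient
limit at the $\theta_0 = \pi$ minimum); degenerate torsion quadruples
(either plane normal vanishing) contribute neither energy nor force;
coincident bonded or interacting nodes raise an error; any non-finite
coordinate aborts the run with the simulated time in the message.
Coordinates are stored unwrapped so contour lengths and tortuosity are
well defined across the periodic boundary; pair search and imaging use a
wrapped view with minimum-image distances. Inter-fibre neighbours come
from a cell list with a 10 nm Verlet skin, rebuilt when any node has
moved half a skin; the cell list is checked exactly against brute-force
enumeration in the tests.

## Protocol

`run_aggregation()` starts from straight rods placed uniformly at random
(positions and sphere-uniform orientations from the seeded generator) at
0.5 mg/ml -- the reference census is 1215 protofibrils in a 3 um box, and
`fibre_count_from_concentration()` scales that count with box volume and
concentration. The run integrates to `t_end`, samples the energy
breakdown and bond count at 0.1 ms cadence, and at `steady_time` freezes
the per-fibre reference contour lengths `l0` and the reference
aggregation-bond set used later for fibre strain and bond survival.
`plateau_time()` declares the steady state where the windowed mean of the
total energy changes by less than 1% between consecutive windows.

`run_stretch()` performs the virtual tensile test: repeated affine
scaling of the z coordinates and box length by
$\xi = 1 + c_s\Delta\tau/L_z$ ($c_s$ = 2.5 mm/s, $\Delta\tau$ = 2 us of
Brownian relaxation per increment; results are insensitive to halving
$c_s$ because the network re-equilibrates within each increment) up to
engineering strain $\epsilon_z = 1.5$, with the cross-section $A$ fixed.
Engineering stress is $\sigma_z = (1/A)\,dW/dL_z$, evaluated by central
differences on the strain grid after moving-averaging $W$ over a strain
window of 0.08 (0.04 gives near-identical curves). The elastic
coefficient is the ordinary least-squares slope of $\sigma_z$ on
$\epsilon_z$ over 0.05--0.15 (`fit_modulus()`, with `tidy()`/`glance()`
methods).

Observables: per-segment axis angles folded into $[0, \pi/2]$ via the
absolute dot product with $e_z$; length-weighted per-fibre means;
orientation probabilities normalised by the spherical band fraction
$\cos\Theta_1 - \cos\Theta_2$ (so an isotropic network has density 1 in
every band and the first $[0, \pi/12]$ band uses $1 - \cos(\pi/12)$).
Orientation shares such as "the percentage at $\langle\theta\rangle \le
45^\circ$" are quoted on this band-density scale
(`aligned_fraction()`): an isotropic network scores exactly 50% there,
which is the natural reference against which alignment under stretch is
judged (a head-count of fibres would give $1-\cos 45^\circ \approx 29\%$
for isotropic rods and is also recorded). Tortuosity is contour over
end-to-end length on unwrapped chains; the stretched-fibre fraction
$n_{(\epsilon \ge 0.05)}/N$ uses the frozen `l0`; the survival ratio
$n_{agg}/n_{agg}^0$ is counted two ways (`bond_survival()`): the default
compares current and steady-state *bond counts*, the `"pairs"` option
tracks the identity of the frozen reference bonds, so a
broken-and-replaced bond registers as dissociation. Projection imaging
(`project_network()`, `stylize()`) rasterises wrapped nodes at 10 nm per
pixel, encodes height as ten luminosity levels per 0.3 um slab (maximum
wins on overlap), then applies a 3x3 Sobel gradient magnitude and a
Gaussian blur (default sigma 2 px; both filter parameters are choices,
as is drawing nodes rather than segments -- a segment-drawing mode
exists but is off by default).

## Problem sizes used by the tests and the acceptance script

The full-scale experiment (1215 fibres, 3 um box, 200 ms, 10 replicas per
condition, a 3x3 parameter grid) is far beyond a desk run. The packaged
analyses therefore use a volume-scaled system chosen once: a 0.85 um box
at 0.5 mg/ml (28 fibres, 616 nodes), $\Delta t$ = 10 ns, runs of 8 ms
with the steady state declared at 7 ms, two baseline and two low-$k^A$
replicas in the acceptance script (two and one in the test suite), and a
1.5 ms plateau-detection window. The stretch speed is scaled with the box
(`c_s` = 2.5 mm/s x L_z0 / 3 um) so that the engineering strain *rate*
`c_s / L_z0` -- the intensive quantity -- matches the full-scale test; at
the full-scale speed the small box leaves the quasi-static regime and
transient tension inflates the early stretched-fibre fraction.
Orientation shares are computed from band counts pooled over replicas
before normalising, avoiding the small-sample bias of per-replica
density ratios. The shorter clock is justified by the
scaled system itself: its total energy flattens within ~5-8 ms
(everything is within a fibre length of everything else, so aggregation
needs no long diffusive search), and once bonds of order $10^2\,k_bT$
have formed the topology is effectively frozen -- running on changes
neither the energy nor the bond count measurably. All intensive
parameters -- concentration, every energy constant, temperature,
viscosity -- are exactly those of the full-scale system.

What the scaled runs do show: the plateau, the conformational statistics
(tortuosity and its decrease with $k^B$, orientation distributions), the
strain-driven alignment and fibre-stretching trends, bond retention at
the baseline $k^A$ and the onset of dissociation at the lowest $k^A$.
What they cannot show: quantities that live on the network scale of the
3 um clot. With a few tens of fibres a percolating force path is thin,
so the stress-strain curve is noisy, the elastic coefficient carries
large replica error, and orientation shares at large strain tend to sit
below the full-scale values (alignment is driven by the few loaded
strands). The generator also idealises real clots: no
branching protofibrils, no polydispersity in length, no solvent flow, no
red cells or platelets, and SEM-style images are node rasterisations, not
electron micrographs of dehydrated fibres.

## Known limitations

* The pairing rule is a modelling judgement; the stateless `"nearest"`
  and non-exclusive `"all"` variants are provided for ablation (the
  latter collapses the network at this scale).
* The aggregation potential is cut off discontinuously at $a_{th}$: the
  energy jumps when a pair enters or leaves the shell. The moving-average
  smoothing of $W$ before differencing absorbs this in the stress curve.
* Euler stability depends on the local bond multiplicity; the packaged
  validation bounds assume the nearest-pairing default. Sweeps to
  $k^A = 20\times10^{-3}$ N/m require a proportionally smaller step.
* At a few tens of fibres the elastic coefficient and the stretched-fibre
  fraction are finite-size limited, as described above: the single
  percolating load path is taut almost from the start (the fraction
  overshoots the full-scale value at small strain) and no further strands
  are recruited as strain grows (it saturates rather than climbing).
* The tortuosity decrease with bending stiffness saturates at the stiff
  end of the sweep in the scaled system: above $k^B \sim 10^{-18}$
  J/rad$^2$ per-fibre bending is dominated by aggregation-forced network
  geometry, not thermal flexing, so the $10^{-18}$ and $10^{-17}$
  conditions are no longer resolved (and can invert within replica
  noise).
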