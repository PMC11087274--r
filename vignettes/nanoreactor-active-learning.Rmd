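---
title: "Nanoreactor active learning: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nanoreactor active learning: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

nanoreactr is a desk-scale implementation of nanoreactor active learning
(NR–AL) for condensed-phase reactive chemistry of C, H, N and O. The idea:
drive small periodic boxes of molecules through extreme, oscillating
temperature and density so that reactions happen; let an ensemble of cheap
interatomic-potential regressors run the dynamics; whenever the committee
disagrees too much about a configuration, stop, label that configuration
with a reference method, add it to the training set, retrain, and repeat.
The training set thus grows exactly where the current model is worst.

This vignette explains the models and the numerical choices. Everything
here is the package's own account of its design; every number quoted is
computed by the package's tests or scripts.

## Units

Angstrom, femtosecond, Kelvin, amu and kcal/mol throughout, with
k~B~ = 0.0019872041 kcal/(mol K). Velocities are A/fs, forces kcal/mol/A,
densities g/cc.

## The sampling engine

**Oscillating schedules.** Temperature and density both follow

$$x(t) = x_\mathrm{start} + \frac{t}{t_\mathrm{max}}
  (x_\mathrm{end} - x_\mathrm{start}) + x_\mathrm{amp}
  \sin^2\!\left(\frac{t}{t_\mathrm{per}}\right),$$

with the sine argument in radians. Schedule parameters are drawn uniformly
from configurable ranges (`schedule_policy()`); densities are clamped
below at 0.05 g/cc before use, since near-vacuum sampling is out of scope.
By default the density schedule of each sampling run starts at the
as-built density of the box (`match_density_start`), so the first step
does not apply a discontinuous compression.

**Dynamics.** Langevin dynamics with the BAOAB splitting: drift and kick
half-steps around an exact Ornstein–Uhlenbeck update. With zero friction
and zero temperature the step reduces exactly to velocity Verlet (the
suite checks agreement with an independent Verlet oracle to 1e-10 over
100 steps, and NVE conservation to better than 1e-4 relative over 10^4
steps on a soft harmonic dimer). The friction constant of the sampling
protocols, 0.01, is interpreted as 0.01 fs^-1. A finite-step caveat worth
knowing: for the stiffest bond vibrations at dt = 0.5 fs the measured
kinetic temperature sits a few percent below the thermostat target — the
standard O(dt^2) BAOAB bias; the thermostat itself is exact in the
free-particle limit. Density control rescales cell and coordinates
uniformly once per step before the force evaluation (fractional
coordinates are preserved exactly); velocities are left unscaled and the
thermostat re-equilibrates kinetic energy.

**Builders.** Random all-carbon boxes use sequential rejection sampling
with a minimum-image distance floor of twice the 1.7 A carbon van der
Waals radius. Pure rejection saturates near a sphere packing fraction of
0.38, while several protocol densities imply fractions well above it, so
when insertion stalls the builder switches to a force-biased relaxation
(gradually grown exclusion diameter, violating pairs pushed apart);
requests beyond random close packing (0.64) are refused. Molecular boxes
place rigid seed molecules (nine seeds: C2, H2, N2, O2, NH3, CH4, CO2,
H2O, C2H2, with idealized geometries) with uniform quaternion rotations
and a 2.0 A inter-molecular floor, falling back to a grid-start rigid-body
relaxation for dense requests such as the 228-atom Miller box in a 12.1 A
cell. Every generated box is re-checked against its distance constraint by
an independent brute-force scan in the tests.

## The toy reference potential

The labeler stand-in is a smooth pairwise reactive potential: per element
pair a Morse well plus a stiff inverse-power core,

$$V(r) = D_e\left[(1 - e^{-a(r - r_0)})^2 - 1\right] +
  \epsilon_c \left(\frac{0.8\,r_0}{r}\right)^{12},$$

multiplied by a cosine switch that takes the interaction smoothly to zero
at 3.2 A. Equilibrium lengths sit near the seed-molecule bond lengths;
well depths are moderate (35–58 kcal/mol), so bonds persist at room
temperature (≳ 50 k~B~T) yet break readily between 1000 and 2500 K. The
core term matters: an unsaturated pairwise well otherwise lets many
neighbors compress pair distances far below r~0~, producing
cluster-collapse configurations with enormous force scales. Forces are the
exact analytic gradient (finite-difference checked at 1e-6 relative).
The potential is a fixture for desk-scale work: it makes no claim of
chemical accuracy, and its "chemistry" (e.g. aggregation under pressure)
is its own.

An external labeler can replace it through the calculator contract
(`calculator()`): any function returning total energy and per-atom forces
for a configuration. For reproducing the original workflow's labeler the
documented settings are periodic unrestricted KS-DFT in CP2K with the
BLYP functional, TZV2P basis, GTH pseudopotentials, D3 dispersion (zero
damping), 600/60 Ry cutoffs and singlet spin for the whole box; a
directory-exchange adapter is the intended integration route (write a
batch of extended-XYZ inputs, read back energies and forces in the same
format as `write_dataset()` archives).

## Descriptors

Atomic environments are encoded by Behler–Parrinello-style symmetry
functions in the ANI variant: element-pair-resolved radial terms
$\sum_j e^{-\eta (r_{ij} - R_s)^2} f_c(r_{ij})$ and
element-triple-resolved angular terms with $(1 + \cos(\theta -
\theta_s))^\zeta$ modulation, both under the cosine cutoff
$f_c(r) = 0.5\cos(\pi r / r_c) + 0.5$. Default cutoffs are 5.2 A (radial)
and 3.5 A (angular). The angle is evaluated as
$\theta = \arccos(0.95 \cos\theta)$, following the reference ANI
implementation, so that angular gradients stay bounded at collinear
geometries. Periodic images are enumerated explicitly, so cells smaller
than twice the cutoff are handled exactly (the public neighbor-list API
errors on such cutoffs unless multi-image handling is requested). Shell
hyperparameters are small, evenly spaced grids by default and fully
configurable; the campaign tests use 16 radial shells on [0.55, 3.1] A
matched to the toy potential's range. Rotation, permutation and locality
invariances are asserted to 1e-10 in the suite.

## The committee

Each of the M = 8 members is a per-element ridge regressor on a hybrid
feature map: the standardized environment vector taken linearly, plus a
small set of random Fourier features (`cos(Wx + b)`, fixed random draws
per member) for nonlinear corrections. Atomic energies sum to the total
energy; forces are the exact analytic negative gradient (the
finite-difference check at 1e-5 relative is part of the acceptance
suite). Because the coefficients enter energies and forces linearly, the
joint weighted energy+force loss is solved in closed form — the
learning-rate annealing fields of `train_config()` are satisfied
trivially rather than iteratively.

Design choices that emerged as necessary, all exposed in
`train_config()`:

- **Linear-first features.** The radial descriptor block is itself an
  RBF expansion of the local pair distribution, so linear terms express
  near-pairwise energetics and — crucially — extrapolate additively
  across system sizes. The random Fourier block is penalized orders of
  magnitude harder (`cos_penalty`), acting as a correction prior.
- **Robust row weighting.** Force rows are down-weighted by
  $1/(1 + (f/f_0)^2)$ with $f_0$ = 100 kcal/mol/A, and energy rows
  analogously on a per-atom scale, so the extreme labels of hot,
  compressed configurations inform the fit without wrecking the
  near-equilibrium region.
- **Energy calibration.** A shared self-atomic-energy baseline (least
  squares of total energy on composition) is removed before fitting, and
  each member's per-element offsets are re-pinned on the full dataset
  after fitting. Committee energy disagreement then reflects geometry,
  not the calibration drift of weakly-constrained fits; per-member bias
  columns are penalized hard for the same reason.
- **Channel hygiene.** Descriptor channels that are essentially constant
  over the training data are excluded rather than rescaled by a tiny
  standard deviation, which would otherwise amplify them explosively on
  unseen systems.

Training uses the 16-block split: members validate and test on two
distinct held-out blocks each and train on the remaining 14 (so at least
16 samples are required).

## Selection

Query-by-committee uncertainty: `epsilon_E` is the population standard
deviation of member total energies divided by sqrt(N) (kcal/mol per
sqrt(atom)); `epsilon_F` is the maximum over atoms of the Euclidean norm
of per-component member force standard deviations (a mean-over-atoms
switch is provided). A configuration is selected when either channel
strictly exceeds its threshold; the final thresholds are 1.85 and 6.92 in
the units above, and per generation they ramp linearly from 50% to 100%
of those values (exploitation early, exploration late). Note the
normalization: correlated per-atom energy disagreement enters epsilon_E
amplified by sqrt(N), so the energy channel effectively demands per-atom
committee agreement a factor sqrt(N) tighter than the naive reading.

## The campaign and its desk-scale conditions

One generation: train on the current dataset; draw fresh boxes and
schedules; run nanoreactor MD with the member-mean force, monitoring
uncertainty every `monitor_interval` steps (default 25, the midpoint of
the 5–50-step protocol range; the campaign tests use 10); on first
exceedance stop and keep that configuration; label all flagged
configurations; append. Labels whose maximum force component exceeds
3000 kcal/mol/A are dropped, as one drops non-converged reference
calculations. If the model drives the system into numerical blow-up
before the monitor catches it, the last finite configuration is kept as
the flagged structure. Convergence: the mean simulation time of a
generation (flag time, or t_max for unflagged runs) reaches a target —
50 ps at protocol scale, minutes-of-CPU scale here.

The shipped desk conditions for the end-to-end tests, chosen once and
stated here as the package's own study design: CH4 + H2 boxes of 10–18
atoms at 0.25–0.5 g/cc (these two seeds sit at the toy potential's pair
minima, so freshly packed boxes are near-equilibrium without any
reference-potential relaxation), 24 labeled bootstrap cells, 6
simulations per generation, t_max = 250 fs at dt = 0.5 fs, temperature
schedules from 300–800 K up to 500–2500 K, monitoring every 10 steps,
eight generations under a fixed seed. Under these conditions every
generation-1 simulation is flagged at the very first uncertainty check
(5 fs), while by generation 8 the mean simulation time has grown nearly
tenfold to ~48 fs and the dataset from 24 to 39 labeled configurations —
the qualitative signature of the full-scale workflow, at about four
orders of magnitude less compute. Optional FIRE relaxation of bootstrap cells and simulation
starts (`relax_bootstrap`, `relax_starts`) is available for chemistries
whose templates are far from the labeler's minima, in the spirit of the
minimum-energy initialization used by the case-study protocols.

## Trajectory analysis

Bond perception uses per-element-pair cutoffs r_A + r_B + buffer with a
0.02 A buffer; the carbon radius 0.85 A reproduces the 1.72 A C–C
scanning cutoff, and bonding is strict (`distance < cutoff`). Hydrogen's
radius is set to 0.37 A so that the 0.74 A H–H bond is perceived; N and O
use standard covalent radii; all are configurable. Molecules are
connected components of the bond graph; species are counted by canonical
topology keys (color-aware exact canonical labeling, so equal keys are
exactly isomorphism classes; keys carry a format version). Ring censuses
use a minimum cycle basis per component (Horton candidates, greedy GF(2)
independence) over sizes 3–7, with an optional element filter for
carbon-only analyses. The ignition delay time is the mean over CO, CO2
and H2O of the first time each species' count reaches five molecules,
with an NA sentinel when any species never crosses; the mean is over
species (a replicate-mean is a one-liner on the returned series).

## What the synthetic data does and does not show

The generators emulate the construction rules of the original protocols
(box compositions, densities, separation constraints, schedules) at
10–200 atoms and femtosecond-to-picosecond durations, with a pairwise
toy labeler. Passing tests demonstrate that the machinery — builders,
dynamics, descriptors, committee, selection loop, analysis — behaves as
specified and that the active-learning feedback genuinely extends model
competence. They do not demonstrate chemical realism: the toy potential
has no bond saturation, directionality or charge physics, desk boxes are
far below the 1,000–5,000-atom case studies, and no quantity here should
be compared against real reactive chemistry. Reproducing the published
case-study observables requires the original trained potential and
ns-scale simulations, which are out of scope by design.

## Degenerate inputs and tie-breaks

Cutoff exactly at half the box edge is allowed; beyond it the neighbor
API errors unless multi-image enumeration is requested (internally the
descriptors and toy potential always enumerate images, so small boxes are
exact). Uncertainty exactly at threshold does not select. Single-atom
configurations have zero toy energy and forces. Packing infeasibility
errors deterministically (sphere-packing bound for the carbon box,
attempt/relaxation caps elsewhere); `random_nr_system()` redraws rather
than failing on an unlucky composition. Wrapping never changes
minimum-image distances, and the wrap convention is fractional
coordinates in [0, 1).
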