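# nanoreactr

Desk-scale **nanoreactor active learning** (NR–AL) for condensed-phase
reactive chemistry of C, H, N and O, in R.

The workflow this package implements: small periodic boxes of molecules
are driven through extreme, oscillating temperature and density so that
bonds break and form; the dynamics are run by an **ensemble** of cheap
interatomic-potential regressors; whenever the committee's disagreement
about a configuration exceeds a threshold, the simulation stops, the
configuration is labeled by a reference method, added to the training
set, and the ensemble is retrained. The training set therefore grows
exactly where the current model is worst, and the model's competence —
measured by how long sampling runs survive before being flagged — grows
with it.

Who this is for: people who want a fully inspectable, CPU-scale
implementation of the NR–AL loop (for teaching, method development, or
prototyping selection strategies) rather than a production potential.
The reference labeler here is a built-in smooth pairwise reactive toy
potential; a real electronic-structure labeler can be plugged in through
the calculator contract.

## The pieces

* **Sampling** — Langevin dynamics (BAOAB splitting, dt = 0.5 fs,
  friction 0.01 fs⁻¹) under oscillating schedules
  `x(t) = x_start + (t/t_max)(x_end − x_start) + x_amp · sin²(t/t_per)`
  for both temperature and density (box rescaling each step).
* **Selection** — query-by-committee: `ε_E = popsd(E_members)/√N`
  (kcal mol⁻¹ N⁻¹ᐟ²) and `ε_F` = max over atoms of the norm of
  per-component member force standard deviations (kcal mol⁻¹ Å⁻¹);
  a structure is selected when either strictly exceeds its threshold
  (final values 1.85 and 6.92, ramped 50→100% over generations).
* **Models** — Behler–Parrinello-style symmetry functions (radial cutoff
  5.2 Å, angular 3.5 Å) feeding per-element ridge regressors (linear +
  random-Fourier features) with exact analytic forces, trained by the
  eightfold / 16-block (14/1/1) cross-validation scheme on a joint
  energy+force loss.
* **Builders** — random carbon boxes by sequential rejection sampling
  (3.4 Å minimum distance, with a force-biased relaxation fallback for
  dense requests), and packed molecular boxes from nine seed molecules
  (C2, H2, N2, O2, NH3, CH4, CO2, H2O, C2H2) with 2.0 Å separation.
* **Analysis (MolFind)** — PBC-aware bond perception (cutoff
  r_A + r_B + 0.02 Å; C radius 0.85 Å so C–C bonds at < 1.72 Å),
  connected-component molecules, species census via exact canonical
  topology keys, minimum-cycle-basis ring census (sizes 3–7), species
  tracking, and ignition delay times (mean first time CO, CO2 and H2O
  each reach 5 molecules).

Extended-XYZ is the interchange format throughout; datasets and trained
ensembles serialize to versioned plain-text archives.

## A worked example

A miniature campaign with the built-in toy labeler (this is the exact
configuration exercised by the test suite; about seven CPU-minutes):

```r
library(nanoreactr)
set.seed(42)

pol  <- builder_policy(atom_range = c(10L, 18L),
                       density_range = c(0.25, 0.5),
                       molecules = c("CH4", "H2"))
spol <- schedule_policy(T_start = c(300, 800), T_end = c(500, 2500),
                        T_amp = c(0, 500), rho_start = c(0.25, 0.8),
                        rho_end = c(0.25, 0.8), rho_amp = c(0, 0.2),
                        t_per = c(50, 200), t_max = 250)
cfg <- al_config(bootstrap_cells = 24L, sims_per_generation = 6L,
                 t_max_fs = 250, convergence_target_fs = 250,
                 builder = pol, schedule_policy = spol,
                 md = md_params(dt = 0.5, friction = 0.01,
                                monitor_interval = 10L),
                 train = train_config(lambda = 3e-3, energy_weight = 64),
                 n_members = 8L,
                 desc_params = descriptor_params(
                   elements = c("C", "H"),
                   radial_centers = seq(0.55, 3.1, length.out = 16),
                   radial_eta = 24, angular_sections = 2,
                   angular_centers = 1.5),
                 relax_bootstrap = FALSE, relax_starts = FALSE)

labeler <- toy_potential()
state <- al_state(bootstrap_dataset(cfg, labeler), cfg)
state <- run_until_converged(state, labeler, max_generations = 8L)
tidy(state)
```

```
# A tibble: 8 × 6
  generation n_simulations n_flagged n_labeled mean_sim_time_fs dataset_size
       <int>         <int>     <int>     <int>            <dbl>        <int>
1          1             6         6         0              5             24
2          2             6         6         0              5             24
3          3             6         6         1              5             25
4          4             6         6         6              5             31
5          5             6         6         4             20             35
6          6             6         6         3             15             38
7          7             6         6         0             43.3           38
8          8             6         6         1             47.5           39
```

Read it as the active-learning story: in generation 1 every simulation is
flagged at the very first uncertainty check (5 fs) — the bootstrap model
knows only freshly packed boxes. As flagged (and labelable) hot
configurations accumulate, sampling runs survive longer: by generation 8
the mean simulation time has grown almost tenfold to ~48 fs out of the
250 fs cap. `autoplot(state)` shows the same story graphically, and
`glance(state$ensemble)` summarizes the held-out per-atom energy and
force errors of the committee.

The analysis side works on any extended-XYZ trajectory:

```r
tr <- reaction_toy_trajectory("2H2+O2->2H2O@3", n_frames = 5)
track_species(tr, targets = c("H2", "O2", "H2O"))
ring_census(detect_bonds(hexagonal_sheet(3)))   # -> 3 six-membered rings
```

A command-line front end (`inst/cli/nanoreactor.R`) exposes `build`,
`simulate`, `predict`, `analyze` and `al-run` subcommands over the same
functions.

## Scope

The package implements the sampling/selection/labeling/training loop and
the trajectory analyzer at desk scale. It does not ship a trained
general-purpose potential, does not run electronic-structure labelers
(the adapter contract and the reference settings are documented in the
methods vignette), and makes no claims of chemical realism for the toy
potential — see `vignettes/nanoreactor-active-learning.Rmd` for the full
account of models, choices and limitations.
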