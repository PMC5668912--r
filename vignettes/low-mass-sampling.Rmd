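---
title: "Low-mass molecular dynamics sampling: theory, engine and kinetics pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Low-mass molecular dynamics sampling: theory, engine and kinetics pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmdk)
```

## The method and why it works

Classical MD samples configuration space at a pace set by the fastest
vibrations of the system, which scale as $\sqrt{m}$.  Multiplying **all**
atomic masses by a uniform factor $\lambda < 1$ (the low-mass regime,
conventionally $\lambda = 0.1$) speeds every motion by $\sqrt{1/\lambda}$
without changing the potential-energy surface, the Boltzmann distribution,
or the physical composition of the system: the trajectory is the same
curve through configuration space, traversed faster per integration step.

`lmdk` makes this statement *executable*.  For the velocity-Verlet
propagator the position update with masses $\lambda m$ at time step
$\Delta t$,

$$x_{n+1} = x_n + \Delta t\, v_n + \tfrac{\Delta t^2}{2}\,
  \frac{F(x_n)}{\lambda m}\,c,$$

is algebraically identical to the update with masses $m$ at time step
$\Delta t\sqrt{1/\lambda}$ once initial velocities are mapped by
$v \mapsto v\sqrt{1/\lambda}$ (which also leaves the kinetic energy, and
hence the temperature, invariant).  `verify_time_scaling()` runs both
trajectories and reports the maximum position deviation; on a 10-particle
Lennard-Jones cluster over 1000 steps it is at the $10^{-14}$ Å
floating-point floor.  For $\lambda = 0.1$ the multiplier is
$\sqrt{10} = 3.16$ (3 s.f.): tenfold mass reduction at
$\Delta t = 1$ fs is *numerically* the same simulation as standard masses
at $\Delta t = 3.16$ fs.

Two time conventions circulate for mass-scaled dynamics and
`convert_time()` forces the caller to name one:

* **theoretical** — dimensional analysis with fixed length and energy
  units rescales the time *unit* so that $1/\lambda$ low-mass time units
  equal one standard-mass unit (a factor 10 at $\lambda=0.1$);
* **numerical** — the step-for-step propagator equivalence above, a
  factor $\sqrt{1/\lambda} = 3.16$ at $\lambda = 0.1$.

The two differ and silent defaults would hide that; every analysis axis
in this package uses the numerical convention
(`effective_dt = dt * sqrt(1/lambda)`), which is also the convention
under which the packaged benchmark tables' aggregated simulation times
are internally consistent (20 runs × 500×10⁶ steps × 3.16 fs = 31.6 µs).

## The toy engine and its numerical choices

The engine integrates velocity Verlet in Å / fs / amu / kcal mol⁻¹ units
with the single conversion constant
$c = 4.184\times10^{-4}$ Å fs⁻² per (kcal mol⁻¹ Å⁻¹)/amu and
$k_B = 0.0019872$ kcal mol⁻¹ K⁻¹.  Functional forms are harmonic bonds
and angles ($\tfrac12 k(\cdot - \cdot_0)^2$), AMBER-style cosine torsions
$\tfrac{V_n}{2}(1+\cos(n\phi-\gamma))$ and 12-6 Lennard-Jones pairs.
Forces are the exact negative gradient (checked against central finite
differences to ~10⁻¹⁰ relative in the test suite).

* **SHAKE / RATTLE.**  Pair-distance constraints are enforced after the
  drift by mass-weighted corrections along the pre-drift bond vectors,
  iterated to a relative tolerance of 10⁻⁸ (default) with at most 500
  sweeps; velocities receive the matching correction plus a RATTLE
  projection after the second half-kick.  Non-convergence is an *error
  carrying the step index*, never a silent pass — the observable toy-scale
  analogue of constrained integrators failing when the time step grows
  too large.
* **Berendsen thermostat.**  Weak coupling rescales velocities each step
  by $\sqrt{1 + (\Delta t/\tau_T)(T_0/T - 1)}$ with
  $T = 2\,\mathrm{KE}/(N_\mathrm{dof} k_B)$ and
  $N_\mathrm{dof} = 3N - n_\mathrm{constraints}$.  In equivalence tests
  $\tau_T$ must scale with $\sqrt{1/\lambda}$ like every other time;
  `verify_time_scaling()` therefore runs NVE.
* **Initial velocities** are drawn from the Maxwell–Boltzmann
  distribution at the target temperature from a recorded seed (a direct
  draw replaces a gradual heating protocol; with the same seed the draws
  for masses $m$ and $\lambda m$ are exactly related by the
  $\sqrt{1/\lambda}$ mapping, which several tests exploit).
* **Frame grid.**  `run_simulation()` saves exactly
  `floor(n_steps/save_interval)` frames at steps
  `save_interval, 2·save_interval, …`; the step-0 conformation is not a
  frame.  Identical (system, config, seed) gives bitwise-identical
  trajectories.
* No periodic boundaries, barostat or Ewald electrostatics: toy systems
  are finite clusters and chains, and constant-pressure production
  simulation is out of scope.

## Native-state metric

`superpose()` computes the unweighted least-squares rigid fit (Kabsch,
SVD-based) with reflections forbidden (determinant forced to +1);
`select_cab()` picks Cα plus Cβ atoms residue by residue, glycines
contributing only Cα.  `cab_rmsd_series()` fits every saved frame
independently.  `classify_native()` calls a conformation native when its
CαβRMSD is **≤** a cutoff (inclusive).  The conventional cutoff for the
CLN025/chignolin β-hairpins is 1.96 Å — wide enough to admit
crystal-structure-like conformations (the NMR/crystal CαβRMSD gap is
1.95 Å) while excluding native-like misfolds — but it is always a
parameter, so sensitivity analyses are one argument away.  When a
multi-model PDB supplies the reference, the first model is used unless
the caller selects another.

## Folding kinetics pipeline

For each of $N$ independent simulations the *individual* native-state
population is the fraction of saved frames classified native;
`aggregate_population()` reports the mean, the sample SD ($N-1$
denominator) and $SE = SD/\sqrt{N}$, in percent.  This convention
reproduces every (SD, SE) pair in the packaged benchmark tables up to
their independent integer rounding (the check is interval-based: the
printed SDs are themselves rounded, so the test asks whether *some*
unrounded SD consistent with the printed one yields the printed SE).

First-passage folding times come from `first_passage()`: the time of the
first saved frame at or below the cutoff, on the effective
(standard-mass-credited) time axis; runs that never fold contribute
their full duration as right-censored records.  `estimate_folding_time()`
implements a two-step convention:

1. all $N$ full-length runs folded → Kaplan–Meier (restricted mean with
   Greenwood 95% CI, via the survival package) *and* the closed-form
   exponential MLE $\hat\tau = \text{total exposure}/\text{events}$; if
   the two means agree within 1% relative (an operationalisation of
   "identical"), the exponential fit is selected;
2. censored full-length sets use the exponential fit (its CI from the
   normal approximation on $\log\hat\tau$, sd $1/\sqrt{d}$ — a
   convention, since no canonical choice exists);
3. shortened sets in which half or more of the runs did not fold are
   *discarded* with an error: their confidence interval would be overly
   wide.

With no censoring the restricted KM mean is algebraically the sample
mean, which is also the exponential MLE, so the "disagreement" branch of
step 1 can only trigger on inconsistent inputs; it is kept as a guard.

Two-state behaviour ($D \rightleftharpoons N$) is diagnosed by
`ln_nonnative_regression()`: under first-order kinetics
$\ln([D]/[D]_0) = -k_f\,t = -t/\tau_f$, so the log of the
not-yet-folded fraction is linear in time.  With only $N=20$ replicates
the empirical survival is a coarse staircase; the recovery tests place
the 10-point regression grid at observed event times (a probability-plot
style grid), under which $r^2 > 0.9$ in ≥90% of seeded replicates at
$\tau = 100$ ns.  Note that *no* estimator based on 20 events can pin
$\tau$ itself within 30% more than ~84% of the time (the exponential MLE
is Gamma(20)-distributed), so point-accuracy claims are asserted through
CI coverage (~95%, verified by simulation) rather than fixed relative
error.

Population curves from different conditions are compared with
`curve_ttest()`, the pooled-variance unpaired Student test
($df = n_a + n_b - 2$, two-tailed) on the aggregated means at matched
step-count checkpoints — the variant that reproduces the published
comparisons from the printed curves.  Two of the four packaged
comparisons (the 22-point chignolin curves) were originally computed from
unrounded populations; from the integer-rounded printed means the
recomputed P values (0.4924, 0.0297) agree with the published ones
(0.4788, 0.0299) within the band induced by ±0.5 rounding of every mean,
and the acceptance tests assert exactly that consistency.

## Synthetic generators: what they emulate, and what not

`simulate_two_state()` draws a continuous-time two-state Markov chain
with exponential waiting times (rates $k_f$, $k_u$), starting in $D$,
and emits one RMSD per saved frame uniformly from U(1.0, 1.9) Å (native)
or U(2.5, 8.0) Å (nonnative) — mimicking folded β-hairpin conformations
observed around 1.5 Å while staying ≥0.05 Å clear of the 1.96 Å cutoff
so classification is unambiguous.  Both the emitted series and the exact
transition times are returned, making the (one-save-interval, upward)
discretisation bias of first-passage estimates measurable instead of
hidden.  What the generator does *not* emulate: RMSD autocorrelation
within a state, re-crossing dynamics near the cutoff, and non-exponential
(multi-state) kinetics — so passing tests validate the estimators, not
any claim about real trajectories.

`build_double_well()` is the desk-scale stand-in for a folding
landscape: a four-bead chain (default mass 12 amu, bonds 600
kcal mol⁻¹ Å⁻², angles 120 kcal mol⁻¹ rad⁻²) whose periodicity-2 torsion
creates equal minima at dihedral ±90° separated by the requested barrier
(default 1.5 kcal mol⁻¹) at φ = 0.  The dihedral distance from the
folded minimum maps linearly to a pseudo-RMSD (0 Å folded, 8 Å
extended), so the chain feeds the classification/kinetics pipeline
unchanged.

Two empirical facts about this tiny system shaped the crossing drivers:

* **Weak coupling alone is not ergodic here.**  After the initial
  velocity draw relaxes, the torsional mode decouples from the stiff
  bond/angle modes and barrier crossings stop.
  `double_well_first_crossing(reassign_interval = …)` therefore offers
  periodic Maxwell–Boltzmann velocity reassignment (Andersen-style
  massive collisions).  The thermally-activated-crossing property uses
  reassignment every 2000 steps at 250 K — chosen so
  $k_B T \approx \text{barrier}/3$ — under which all pilot seeds crossed
  within 10⁶ steps.
* **The sampling-acceleration comparison uses common random numbers.**
  For the "low mass crosses in fewer steps at equal Δt" property, each
  seed starts both conditions from the same state with the same normal
  draws, so the initial velocities are related by exactly the
  $\sqrt{1/\lambda}$ mapping and both runs begin on the *same physical
  trajectory*, the low-mass one traversing it ~3.16× faster per step.
  A 3000-step horizon at 500 K makes a third of the seeds informative
  (at least one condition crosses); ties are dropped and a one-sided
  sign test is applied.  This paired design is a standard
  variance-reduction device; an unpaired long-horizon variant has the
  same sign but needs far more seeds for the same power.

## Problem sizes and reproducibility

The test suite runs entirely from generated fixtures: LJ clusters of ~10
particles, 10³–10⁵-step integrations, 20–1000-record survival
simulations, 200-replicate Monte-Carlo recoveries and a 100-seed paired
race — a few seconds end to end, yet each property is asserted at the
tolerance the underlying mathematics supports (10⁻⁸–10⁻¹⁴ for exact
identities, calibrated bands for stochastic recoveries).  All randomness
flows from explicit seeds; CLI invocations write a JSON manifest with
config, seed, version and output checksums, and rerunning with an equal
manifest reproduces byte-identical outputs.

## Known limitations

* The engine is a toy: no PBC/PME/barostat, no hydrogen-mass
  repartitioning, no production forcefields; conclusions about real
  solvated proteins must come from production codes.
* The benchmark tables are integer-rounded transcriptions; analyses that
  need unrounded populations (e.g. exact P-value reproduction) are
  inherently band-limited by that rounding.
* The exponential CI convention and the restricted-mean KM convention
  are stated choices, not claims about any external software's
  internals.
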