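---
title: "Detecting dynamical transitions in protein powders"
author: "powderdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dynamical transitions in protein powders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(powderdyn)
```

## The observable

Protein powders — periodic cells packed with many protein units and a small
amount of interstitial water — are the simulation analogue of solid-state
protein formulations. The central observable is the mean-square fluctuation
(MSF) of protein atoms. For each protein unit independently, every trajectory
frame is rigid-body superposed (Kabsch) onto that unit's frame-0 structure
using its heavy atoms, and

$$\mathrm{MSF}_i = \frac{1}{N_F}\sum_{t=1}^{N_F}
  \left| \mathbf{x}_i(t) - \langle \mathbf{x}_i \rangle \right|^2,$$

with $\langle \mathbf{x}_i \rangle$ the post-alignment mean position. Atomic
values are mass-averaged into residue and protein values; the ensemble MSF is
the unweighted mean over protein units. Errors come from block averaging:
the trajectory is cut into 5 contiguous equal blocks, the MSF recomputed per
block against the same frame-0 reference, and the standard error taken as
$\mathrm{sd}(\text{blocks})/\sqrt{n_\text{blocks}}$.

Two conventions deserve a note, since the defining formula leaves them open:

* The variance is taken about the *mean* aligned position (as the formula
  states), while the superposition target is frame 0. The two reference
  choices agree in the large-$N_F$ limit but not frame-by-frame; we follow
  the formula literally. A consequence is that MSF is exactly invariant
  under frame permutations that keep frame 0 first, and only approximately
  invariant otherwise.
* The rigid fit itself is unweighted over heavy atoms; mass enters only when
  MSF values are averaged. Mass-weighted fitting is available as an option
  (`kabschAlign(weights=)`), but is off by default since only the averaging
  step is defined as mass-weighted.

Periodic boxes are handled by making each protein unit whole (minimum-image
relative to the unit's first atom) before fitting; waters never enter the
MSF. Remainder frames when $N_F$ is not divisible by the block count are
dropped from the tail, keeping blocks equal-length and deterministic.

## The two transitions

Heating a hydrated powder produces two changes in MSF(T):

* **T_low** — the harmonic slope change. Below and above T_low (~160 K) the
  MSF is linear in T, with a larger slope above; in semi-log space both
  regimes are well fit by straight lines. `detectTlow()` searches every
  admissible breakpoint candidate (midpoints between consecutive data
  temperatures; each segment retains at least 3 points), fits two
  *independent* OLS lines per candidate, and keeps the candidate with minimal
  total SSE. Continuity at the breakpoint is deliberately not enforced: the
  enthalpy-based T_D below is defined by the *intersection* of two free
  lines, and the same free-line convention is used here for consistency.
* **T_D** — the protein dynamical transition, the onset of anharmonic
  motion. Two detectors are provided:
  * `detectTdEnthalpy()` fits two free lines to H(T) with the same
    breakpoint search and reports their analytic intersection as T_D; the
    segment slopes are heat capacities and their difference is the jump
    $\Delta C_p$. A transition is declared only when the two-regime test is
    significant (default $\alpha = 0.01$) *and* the intersection lies inside
    the data range; otherwise the single-line result is returned — the
    behaviour of strongly dehydrated powders, whose enthalpy shows a single
    linear regime.
  * `detectTdMsf()` extrapolates the upper harmonic segment beyond the
    fitting cap (210 K) and reports the smallest temperature whose value
    exceeds the extrapolation by more than $k\sigma$
    (with $\sigma = \max(\text{fit residual sd}, \text{point error})$,
    $k = 3$) **and** whose higher temperatures all exceed it too. This
    persistence rule keeps a single noisy point from declaring a transition,
    which matters for weakly hydrated systems where the onset is shallow.

### Significance of the two-regime model

The natural test of "two lines vs one" is an F test with 4 vs 2 parameters.
Applied naively after a breakpoint *search*, however, the test is performed
at the SSE-minimizing candidate, which inflates its size well above the
nominal level. `powderdyn` therefore Bonferroni-adjusts the F-test p-value
by the number of candidates scanned. The adjustment is conservative but
restores type-I control — on curves designed with $\Delta C_p = 0$ the
detector stays below its nominal $\alpha$ (verified over 500 replicates in
the test suite) — and costs nothing in practice: genuine transitions of the
size seen in these systems yield p-values many orders of magnitude below
$\alpha$.

### Fit space for each task

T_low detection defaults to log space, where both harmonic regimes are
straight. For the MSF-based T_D onset the segmented fit is used in *linear*
space: the harmonic segment is linear in T, so its logarithm is concave, and
extrapolating a log-space line beyond the fitting window carries a curvature
model error that degrades onset detection. The linear-space fit extrapolates
the mid segment exactly.

### Residue-level and methyl decompositions

`detectResidueTransitions()` applies both criteria per residue, given
whole-protein T_low and T_D: a two-sample slope test (Welch degrees of
freedom, $\alpha = 0.05$) between the below-T_low line and the T_low–T_D
line, and the persistence rule against the extrapolated mid-segment line,
reporting the mean excess above T_D as the anharmonic amplitude. In these
powders both transitions are collective — every residue shows them at the
shared temperatures — while the amplitude above T_D tracks hydropathy:
hydrophilic residues dominate in hydrated powders, hydrophobic ones in
dehydrated powders. Residues are classified by the bundled Eisenberg
consensus scale with threshold 0 (value > 0 ⇒ hydrophobic), which places
Q, K, D, S, R in the hydrophilic class and L, W, I in the hydrophobic class;
the exact values behind published colour scales are not available, so the
threshold is a package choice. Terminal residues are excluded from class
statistics: their large MSF reflects single-sided bonding, not hydropathy.

`fitMethyl()` captures the methyl-rotor signature: OLS of log(MSF) vs T
below T_low (exponential regime) and plain OLS above (linear regime).

## Metropolis dehydration

Lower-hydration powders are prepared from a hydrated configuration by
removal cycles: pick a water uniformly at random, compute the energy change
$\Delta U$ of removing it (energy without minus energy with, so strongly
bound waters have $\Delta U > 0$), accept with probability
$\min(1, e^{-\beta \Delta U})$, and on acceptance delete the water and apply
a relaxation hook. The hook defaults to a no-op; in full molecular work it
would be an NPT relaxation, which is outside this package's scope and hence
a user-supplied callable (contract: configuration in, configuration out,
water count unchanged). Rejected waters stay in the pool and may be
re-proposed — the alternative (drawing without replacement per cycle) is not
distinguishable from the protocol's description, and re-proposal keeps the
acceptance statistics memoryless. $\beta$ defaults to 300 K, the temperature
at which the dehydration cycles are run. A cap of $10^6$ proposals guards
against non-terminating runs on pathological energy functions.

The hydration level is $h = N_w M_w / (n_p M_p)$ in g water/g protein, with
average molecular masses ($M_w = 18.015$ Da; $M_p$ from average residue
masses plus one water for the termini — 2169.42 Da for the bundled Trp-cage
sequence). The reference composition of 16 Trp-cage units and 771 waters
gives $h = 0.40$ g/g, and inverting the formula at 0.40 g/g returns exactly
771 waters.

Two energy models ship for desk-scale work: `toyEnergy()` (pairwise
Lennard-Jones + Coulomb with a 10 Å cutoff over water–protein and
water–water sites) and `waterBindingEnergy()` (waters tagged with binding
energies; removal costs exactly the tag). Both are deliberately small models
for exercising the protocol, not force fields.

## What the synthetic generators emulate

The generators produce every input the pipeline consumes, with the
statistical structure observed in powder simulations; their defaults are the
study conditions and are not tuned per analysis:

* temperature grid 100–300 K at 10 K spacing (a typical production grid;
  the exact grid of any given study is rarely published);
* T_low = 160 K; T_D = 223 K (`tD = NA` emulates a dehydrated system with
  no transition in range);
* harmonic slopes $5\times10^{-4}$ and $10^{-3}$ Å²/K (ratio 2, the scale
  of the semi-log slope change), intercept 0.01 Å²;
* anharmonic excess quadratic in $(T - T_D)$ with coefficient
  $3\times10^{-4}$ Å²/K². The true functional form above T_D is not known —
  only "nonlinear growth" — so the simplest smooth onset is used, sized so
  the excess is unambiguous two grid steps past T_D;
* 1% relative multiplicative Gaussian noise (consistent with error bars
  comparable to plot symbol sizes);
* methyl branch $0.02\,e^{0.01 T}$ Å² below T_low, continued value- and
  slope-matched linearly above;
* per-residue anharmonic amplitudes from hydropathy ranks (weights 0.5–1.5;
  hydrophilic-heavy in "hydrated" mode, hydrophobic-heavy in "dehydrated"
  mode) with a +0.5 bonus for the termini.

`makeTrajectory()` generates frames whose computed MSF matches designed
per-atom targets (i.i.d. Gaussian displacements of per-axis variance
target/3), optional two-site hopping atoms (occupancy variance
$p(1-p)d^2$), and random per-frame whole-protein rigid motion that the MSF
engine's superposition must remove. All generators are pure functions of
their specification and seed, and restore the caller's RNG state.

What the generators do **not** emulate: correlated atomic motions, realistic
water structure and hydrogen-bond networks, force-field energetics, and time
correlation within a trajectory (frames are independent draws). Passing
tests therefore demonstrate the correctness of the estimators and detectors
under the designed statistical structure, not the physics of any particular
real powder.

## Numerical choices and degenerate inputs

* Breakpoint candidates are midpoints between consecutive data temperatures
  — the data's own resolution; a continuous optimizer would imply precision
  a 10 K grid cannot support. SSE ties break toward the lowest candidate.
  With the kink exactly on a grid point, both adjacent candidates fit
  exactly; recovery is then within one candidate step (±5 K on a 10 K
  grid), which is the attainable resolution. At 1% noise the single-seed
  breakpoint scatters by about one grid step; averaged over 20 seeds the
  design value is recovered within ±5 K.
* The onset temperature from `detectTdMsf()` is quantized to the grid: a
  223 K design on a 10 K grid is reported as 230 K (the first grid point
  above the onset).
* Exact (noise-free) inputs are protected by small relative floors when
  comparing SSEs and deviation bands, so zero-residual fits do not trip on
  round-off.
* Degenerate geometry (collinear or coincident point sets) is rejected by
  the Kabsch fit; empty selections, fewer than 2 frames, fewer points than
  a fit window needs, non-positive values in log space, and non-standard
  residue codes all raise explicit errors.

## Problem sizes used in the tests

The suite runs entirely on synthetic data at deliberately small sizes — up
to 2 protein units, a few thousand frames for law-of-large-numbers checks,
20-seed replicates for recovery statistics, and 500 replicates at a reduced
12-point grid for the type-I study. These sizes make every estimator's
sampling error predictable (tolerances like $3/\sqrt{N_F}$ are stated with
the tests) while keeping the full suite in the minutes range.

## Known limitations

* The breakpoint search fits exactly two segments; curves with more regimes
  (or smooth crossovers) are summarized by their best two-segment split.
* Enthalpy units are taken as given; $\Delta C_p$ is reported in the input's
  own units per K, with no per-gram normalization.
* Triclinic boxes and velocity/force records are out of scope; boxes are
  orthorhombic.
* The dehydration protocol removes waters only (no insertion), and its
  energy models are toys; conclusions about real binding strengths require
  a real force field behind the `energyFn` interface.
* Incoherent neutron-scattering observables (elastic intensities,
  resolution convolution) are not computed, although the MSF produced here
  is the quantity such analyses start from.
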