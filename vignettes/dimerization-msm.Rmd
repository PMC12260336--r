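---
title: "Markov state models of reversible dimerization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov state models of reversible dimerization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimerMSM)
```

## The model

dimerMSM estimates the association/dissociation kinetics of a two-chain
protein system from replica coordinate trajectories. The underlying model
is a Markov state model: conformational space is discretized into
microstates and the dynamics at lag time τ is approximated by a
row-stochastic transition matrix T(τ). Three assumptions matter:

* **Markovianity at the chosen lag.** The discretized process must be
  approximately memoryless at τ. This is a property of the combination of
  features, projection, discretization and lag — not of the underlying
  dynamics alone — and is checked, not assumed: implied timescales should
  be flat in τ and the Chapman–Kolmogorov test should agree within its
  uncertainty bands.
* **Reversibility.** The estimator enforces detailed balance
  π_i T_ij = π_j T_ji, appropriate for equilibrium simulations of a
  reversibly associating dimer. This makes the spectrum real, which PCCA++
  and the kinetic-variance bookkeeping rely on.
* **Adequate sampling.** Every MSM quantity is conditional on the largest
  strongly connected set of the transition-count graph; states visited too
  rarely to connect are excluded and reported via a coverage fraction.

## Features

The feature set is the four inter-monomer domain centre-of-mass distances,
in the fixed order (A.Ntd–B.Ntd, A.Ntd–B.Ctd, A.Ctd–B.Ntd, A.Ctd–B.Ctd),
in nm. COMs are mass-weighted by default (coarse-grained beads carry
masses); a `geometric` switch uses unweighted centres. Terminal-arm beads
(domain `"arm"`) are excluded from domain COMs by default — the domains of
interest are the two Greek-key folds — but the annotation table can
reassign them. Intra-monomer domain distances are deliberately not part of
the default feature set: the object of study is inter-monomer association,
and the rigid-fold assumption makes intra-monomer distances nearly
constant. Whole-monomer COM distance (all beads of a chain, arms included)
drives the event detection and population histograms.

Units are fixed package-wide: nm, ns, K, kJ/mol. PDB coordinates (Å) are
converted on load.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| TICA lag | 5.0 | ns | standard choice for coarse-grained association kinetics; check with `implied_timescales()` |
| kinetic variance cutoff | 0.95 | — | keeps the slow subspace while discarding fast noise directions |
| microstates k | 250 | — | fine enough to resolve basins, coarse enough for well-populated counts |
| MSM lag | 5.0 | ns | same as TICA lag; vary to test robustness |
| macrostates | 6 | — | the metastable decomposition scale of interest |
| temperature | 310 | K | physiological, enters only through k_B·T in ΔG |
| bound / unbound thresholds | 6 / 7 | nm | dimeric (<6 nm) and monomeric (>7 nm) distance conventions |
| contact cutoff / persistence | 0.45 / 0.75 | nm / — | standard residue-contact convention; persistent pairs are reported |

## Numerical choices

* **TICA estimator.** The symmetrized (reversible) covariance pair is
  used: C₀ and C̄_τ are accumulated over both time directions, pooled over
  replicas and never across replica boundaries, with a single pooled mean.
  This guarantees real eigenvalues; fitting on time-reversed data gives
  the identical model. Kinetic variance is defined through squared
  eigenvalues, λᵢ²/Σλⱼ², and components are kept until the cumulative sum
  reaches the cutoff. C₀ directions with eigenvalue below 1e-10 of the
  largest are discarded (constant or collinear features must not break the
  whitening). Lags that are not an integer multiple of the frame interval
  are rounded to the nearest frame with a warning.
* **k-means.** k-means++ seeding from the given seed, Lloyd iterations to
  a relative inertia change of 1e-8 or 200 iterations; an empty cluster is
  re-seeded at the point farthest from its centre; assignment ties break
  to the lowest centre index. For large data sets the centres can be fitted
  on a random subsample (`fit_frames`) and all frames assigned afterwards.
* **Counting.** Sliding-window counts (every frame pair t, t+lag) rather
  than strided counts: this uses all data; the mild count correlation it
  introduces does not bias the transition-probability estimates.
* **Reversible MLE.** The self-consistent iteration on symmetric flux
  variables runs until the maximum relative change falls below 1e-10
  (capped at 1e6 sweeps, a non-convergence error otherwise). The
  stationary distribution is cross-checked against the leading left
  eigenvector.
* **PCCA++.** Dominant right eigenvectors, inner-simplex vertex search by
  successive orthogonalization, membership matrix by the vertex-basis
  linear transform; small negative memberships are clipped and rows
  renormalized. Degenerate eigenvalues are tie-broken by index (logged);
  requesting more macrostates than the positive spectrum supports warns
  with an eigenvalue report. Macrostates are numbered by descending
  stationary weight, since any other numbering is figure- or run-specific.
* **Macro MFPT aggregation.** The macrostate-to-macrostate MFPT is the
  stationary-weighted average of microstate MFPTs over the *crisp* source
  set (fuzzy memberships are kept for reporting only). Single-number MFPTs
  between state groups require some aggregation convention; the
  stationary-weighted one answers "starting at equilibrium within the
  source basin, how long to first reach the target basin".
* **CK uncertainty bands.** Normal approximation to the multinomial
  transition counts: se = sqrt(p(1−p)/N) with N the number of transitions
  leaving the set at the re-estimation lag.
* **Event detection.** Hysteresis: enter bound below the bound threshold,
  enter unbound above the unbound threshold, keep the previous state in
  between (initial in-band frames are "intermediate"). A single-threshold
  detector would chatter whenever the distance hovers near the cutoff;
  with hysteresis two consecutive events always alternate in direction.
* **Kabsch RMSD.** Proper rotations only (determinant-corrected SVD), so
  mirror images are never superposed.

## The synthetic generators

No trajectory data ship with the package; two generators provide inputs
with known statistical structure.

**Markov-jump chains with distance emissions** are the primary test
vehicle. `example_dimer_chain()` is a six-state chain with two designed
basins — four bound states in a mixing ring with two dissociation
gateways, and two unbound encounter states that exchange quickly and can
both associate. Within-basin mixing is faster than basin exit on both
sides, so the bound/unbound split is also the chain's dominant metastable
2-partition — the partition PCCA++ should find. Jump probabilities were
calibrated once, against the exact MFPTs of the resulting matrix, so that
at a 5 ns lag step the planted kinetics are ~58 ns association /
~1391 ns dissociation (a ~24-fold asymmetry, the kinetic signature of a
deamidation-stabilized dimer) for the `"asymmetric"` preset and
~417/~520 ns for the `"symmetric"` (wild-type-like) preset. Emissions are
Gaussian per state with a shared 0.35 nm standard deviation — the
simplest model under which discretization can recover the states —
truncated at zero because distances are nonnegative. Bound-state mean
distances sit below 6 nm and unbound ones above 7 nm, so the threshold
conventions apply unchanged. Replicas start from the stationary
distribution by default (empirical counts are then stationary); a
documented `start = "unbound"` flag reproduces a dissociated start
instead. Whether real replicas would start from identical coordinates is
not knowable from a finished study; the Brownian generator exposes
`identical_start` for both conventions without asserting either.

**The Brownian (overdamped Langevin) dimerization** provides
continuous-space coordinates: two rigid bodies, each two domains of beads,
diffusing (translation + rotation) in a reflecting cubic box, coupled by a
flat-bottom attractive well on their COM separation, starting 8.0 nm
apart. The well's edge is a half-cosine switch of finite width (default
0.5 nm): a discontinuous well has no defined force, and the switch width
bounds the Brownian drift per step. Bodies are rigid because internal
flexibility is not the object of study (an elastic network keeping the
folds intact plays that role in coarse-grained simulations); there is no
solvent, no electrostatics, and no force-field realism. The generator
reproduces the *shape* of association data — reversible binding and
unbinding on separated timescales, geometry-dominated occupancies — not
its energetics.

What passing tests therefore show: the estimators recover known
transition matrices, timescales, partitions and MFPTs from data that are
genuinely Markovian (chains) or genuinely diffusive (toy bodies), at the
replica structure and sample sizes of a realistic protocol. What they do
not show: that any particular molecular system is well described by four
distances, a 5 ns lag, or six macrostates — those remain modelling
decisions to validate per system with the CK and timescale diagnostics.

## Problem sizes

The test suite runs chains of 10⁴–10⁶ steps; pipeline-recovery checks use
10 replicas × 10⁵ frames (10⁶ frames total) with 100 microstates fitted
on a 5×10⁴-frame subsample, which recovers the planted MFPTs to within a
few percent while keeping the whole suite under two minutes. The
acceptance script uses the same sizes. Monte Carlo MFPT cross-checks use
10⁵ sampled paths.

## Known limitations

* No Bayesian/bootstrap uncertainty on MSM quantities (MFPTs are point
  estimates; the CK bands cover only residence probabilities).
* No hidden-Markov or milestoning estimators; discretization error is
  diagnosed (CK, timescales) rather than corrected.
* PCCA++ uses the unoptimized inner-simplex memberships; for strongly
  overlapping basins a subsequent simplex optimization could sharpen
  them.
* The trajectory container is a single documented plain-text format plus
  PDB topology; other MD formats need conversion upstream.
* Committor-based flux analysis assumes the reversible estimator;
  irreversible counts are not supported.
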