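# dimerMSM

Markov state models (MSMs) of reversible protein–protein association,
built for the kind of question raised by βB2-crystallin dimerization: how
fast do two monomers associate, how long does the dimer live, and how do
surface modifications such as deamidation (Q70E/Q162E) shift that balance?
The package estimates these kinetics from multi-replica coordinate
trajectories of a two-chain, two-domain system, and ships synthetic
generators with exactly known kinetics so that every stage of the pipeline
is testable without any simulation data.

## The method

Given replica trajectories with frame interval Δt (ns), the pipeline is:

1. **Featurization** — the four inter-monomer domain centre-of-mass
   distances d(A.Ntd–B.Ntd), d(A.Ntd–B.Ctd), d(A.Ctd–B.Ntd),
   d(A.Ctd–B.Ctd) in nm, plus the whole-monomer COM distance used for
   binding/unbinding analyses.
2. **TICA** — solve the generalized eigenproblem C̄_τ v = λ C₀ v with the
   symmetrized lagged covariance C̄_τ, keeping the smallest set of
   components whose cumulative kinetic variance λᵢ²/Σλⱼ² reaches the
   cutoff (default 95% at lag 5 ns).
3. **Microstates** — k-means (k-means++ seeding, Lloyd iterations; default
   k = 250) on the projected coordinates.
4. **MSM** — sliding-window transition counts at lag τ, restriction to the
   largest strongly connected set, then the maximum-likelihood *reversible*
   transition matrix T via the self-consistent iteration
   x_ij ← (c_ij + c_ji) / (c_i/x_i + c_j/x_j),
   which enforces detailed balance π_i T_ij = π_j T_ji.
5. **Validation** — implied timescales t_i = −τ/ln λ_i across lags and the
   Chapman–Kolmogorov test comparing T(τ)^k against models re-estimated at
   lag kτ.
6. **Macrostates** — PCCA++ groups microstates into metastable sets
   (default 6); stationary free energies follow
   ΔG(S_i) = −k_B T ln Σ_{j∈S_i} π_j (kJ/mol, default 310 K).
7. **Kinetics** — committors q⁺, reactive fluxes
   f_ij = π_i q⁻_i T_ij q⁺_j (transition path theory), and mean first
   passage times from the absorbing-target linear system
   (I − T̃) m = τ·1, aggregated over source macrostates by their
   stationary weights.

Structural observables round out the analysis: binding/unbinding event
detection with hysteresis thresholds (bound < 6 nm, unbound > 7 nm),
distance population fractions, inter-chain residue contact maps
(0.45 nm cutoff, 0.75 persistence filter) and Kabsch-superposed RMSD.

## Worked example

The built-in six-state ground-truth chain emulates an asymmetric
dimerization (association ≈ 58 ns, dissociation ≈ 1391 ns, a ~24-fold
asymmetry of the kind produced by deamidation-stabilized dimers):

```r
library(dimerMSM)
chain <- example_dimer_chain("asymmetric")
labels   <- simulate_markov_chain(chain, n_steps = 20000, n_replicas = 5, seed = 1)
features <- emit_distance_trajectories(labels, chain, seed = 2)
tica <- fit_tica(features, lag_ns = 5, variance_cutoff = 0.95)
proj <- project_tica(tica, features)
disc <- cluster_microstates(proj, k = 60, seed = 3)
msm   <- estimate_msm(disc, lag_ns = 5)
macro <- pcca_plus(msm, 2)
round(mfpt_matrix(msm, macro), 1)
#>       target
#> source S1     S2
#>     S1  0 1314.5
#>     S2 54    0.0
macrostate_free_energies(msm$stationary, macro, temperature_K = 310)
#>   macrostate     weight        dG     ddG
#> 1          1 0.96018342 0.1047256 0.00000
#> 2          2 0.03981658 8.3084455 8.20372
```

Macrostate S1 is the bound (dimeric) basin: it carries 96% of the
stationary weight and sits 8.2 kJ/mol below the unbound basin. The MFPT
matrix reads row → column: dissociation (S1→S2) takes ~1310 ns while
association (S2→S1) takes ~54 ns — the recovered ~24-fold asymmetry. At
this reduced problem size (10⁵ frames) the estimates carry a few percent
of sampling error; the acceptance script below runs the same analysis at
10⁶ frames.

A full config-driven run (tables, models, manifest, figures in
`out/`):

```r
run_pipeline(list(seed = 1, output_dir = "out",
                  simulate = list(chain = "asymmetric", n_replicas = 15,
                                  replica_length_ns = 5000),
                  cluster = list(n_microstates = 250, fit_frames = 5e4),
                  macrostates = list(n = 6)))
```

The same runs from a shell via the thin wrapper
`inst/cli/dimer-msm.R {simulate|report} --config run.yaml`.

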