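# msmbind

Markov state model (MSM) analysis of protein–ligand binding kinetics in R.

Lectins such as galectin-3 recognize β-galactoside ligands (N-acetyl-
lactosamine and its higher-affinity synthetic derivatives) through a
shallow, solvent-exposed carbohydrate recognition domain. Unbiased MD
simulations of such systems produce large ensembles of trajectories in
which the ligand diffuses, forms transient encounter complexes and
eventually settles into the crystallographic pose. `msmbind` implements
the statistical pipeline that turns those trajectories into quantitative
thermodynamics and kinetics, and ships a synthetic-data module so every
stage is testable without access to atomistic trajectory data.

## What it computes

Given per-frame coordinates (or pre-computed features), the pipeline is

1. **Featurization** — binary residue–ligand contact vectors (entry r = 1
   iff the minimum heavy-atom distance to residue r is < 0.5 nm), pocket
   center-of-mass distance, Kabsch superposition RMSD, and a bound-pose
   detector (RMSD < 0.2 nm and pocket distance < 0.5 nm sustained ≥ 100 ns).
2. **tICA** — the generalized eigenproblem `C_tau v = lambda C_0 v` with
   symmetrized lagged covariances; components ranked by kinetic variance
   `lambda^2`.
3. **Microstates** — k-means (k-means++ seeding, Lloyd iterations) in the
   tICA space.
4. **MSM** — sliding-window transition counts on the largest strongly
   connected set, reversible maximum-likelihood transition matrix
   (detailed balance enforced by the symmetric-flow fixed point), implied
   timescales `t_i(tau) = -tau / ln lambda_i(tau)` for lag selection.
5. **Macrostates** — PCCA+ (inner-simplex variant) with the macrostate
   count chosen from the largest implied-timescale gap.
6. **Kinetics** — committor probabilities `q+` (0 on the unbound set, 1 on
   the bound set), transition-path-theory fluxes
   `f_ij = pi_i q-_i T_ij q+_j` with bottleneck pathway decomposition,
   mean first passage times from the linear solve
   `m_i = tau + sum_j T_ij m_j`, and

   - `k_on = 1 / (MFPT_on · C)`, `k_off = 1 / MFPT_off`,
     residence time `= 1 / k_off`,
   - `ΔG = -RT ln(pi_bound / pi_unbound)` with a standard-state
     correction `ΔG0 = ΔG - RT ln(C0 / C)`.
7. **Metadynamics (toy)** — a well-tempered engine on analytic landscapes
   (hills every 500 steps, effective height `h·exp(-V/k_B ΔT)`,
   `ΔT = (γ_b - 1) T`), free-energy read-out
   `F(s) = -(T+ΔT)/ΔT · V(s)`, and ligand-egress timing for residence
   comparisons between landscapes.

The synthetic-data module provides exact ground truth: reversible
Metropolis chains with planted metastable blocks and prescribed
stationary populations, and overdamped Langevin simulations of a ligand
particle in multi-basin landscapes with pseudo-residues for contact
featurization.

## Worked example

```r
library(msmbind)

# a bound-dominant four-state system: unbound (U), two rare
# intermediates, bound (B), with exact stationary populations
spec <- planted_chain_spec(
  20, rep(c("U", "I1", "I2", "B"), each = 5),
  c(U = 0.3527, I1 = 0.0037, I2 = 0.0044, B = 0.6392),
  intra_rate = 0.2, inter_rate = 2e-4)
chain <- build_reversible_chain(spec)
dtraj <- sample_chain(chain, 1e6, seed = 42)

its <- implied_timescales(dtraj, c(1, 2, 5, 10, 20), n_its = 6)
as.integer(choose_n_macro(its))
#> [1] 4

msm <- estimate_reversible(count_transitions(dtraj, 10))
mac <- pcca_plus(msm, 4)
round(100 * sort(mac$populations, decreasing = TRUE), 2)
#> [1] 62.51 36.71  0.44  0.34

A <- which(chain$blocks[msm$active] == "U")
B <- which(chain$blocks[msm$active] == "B")
q <- committor(msm, A, B)
round(committor_macro(q, msm$pi, mac$crisp), 3)
#> [1] 0.540 0.617 0.000 1.000    # unbound = 0, bound = 1 exactly

binding_free_energy(0.6392, 0.3527, temperature = 310.15)$dG
#> [1] -0.3664703                  # kcal/mol from the population ratio
```

The macrostate populations recovered from a single 10^6-step trajectory
agree with the planted 63.92 / 35.27 / 0.44 / 0.37 % split; committors of
the unbound and bound macrostates are exactly 0 and 1 (boundary
conditions of the committor solve), while the two rare intermediates sit
in between, as expected for states exchanging with both endpoints. The
free-energy call evaluates `-RT ln(0.6392/0.3527)` at 310.15 K.

For a continuous end-to-end run (Langevin simulation → contacts → tICA →
k-means → MSM → PCCA+ → TPT → rates):

```r
pl <- run_pipeline(pipeline_config(n_macro = 2L, seed = 3))
print(pl)
```

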