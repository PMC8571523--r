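---
title: "Markov state models of ligand binding: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov state models of ligand binding: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmbind)
```

## The problem

Weak-affinity carbohydrate recognition — a galectin binding
N-acetyllactosamine-type ligands in a solvent-exposed groove — is an
equilibrium between a diffusive unbound state, transient encounter
complexes, and the crystallographic bound pose. Long unbiased MD
trajectories sample this equilibrium, but the raw frames must be turned
into a discrete kinetic model before populations, committors, fluxes,
rates and free energies can be read off. `msmbind` implements that
pipeline and, because atomistic trajectory archives of this kind are
rarely redistributable, a synthetic-data module that plants known
metastable structure so every estimator can be validated against exact
ground truth.

## The model

An MSM is a discrete-state, discrete-lag Markov chain: microstate labels
$s_t$ observed every $\tau$ are modeled by a row-stochastic transition
matrix $T(\tau)$. The pipeline stages and their estimators are:

**Contact featurization.** A frame becomes a binary vector with entry
$r = 1$ iff the minimum heavy-atom distance between ligand and residue
$r$ is strictly below the cutoff (default 0.5 nm). The strict inequality
at exactly the cutoff is a documented convention; the boundary case is
measure-zero for real data. Contacts use the minimum ("nearest
neighbor") distance per residue, not residue centers of mass. No
periodic-image handling is performed: trajectory readers must supply
unwrapped coordinates, and the toy simulator uses reflecting walls, so
images never arise.

**tICA.** With instantaneous covariance $C_0$ and symmetrized lagged
covariance $C_\tau$ (averaged over forward and reverse lagged pairs,
formed within trajectories only), the generalized eigenproblem
$C_\tau v = \lambda C_0 v$ is solved through a Cholesky whitening of
$C_0 + \varepsilon I$, $\varepsilon = \mathrm{ridge} \cdot
\mathrm{tr}(C_0)/d$ (ridge $10^{-6}$ by default — binary contact sets
are often rank-deficient). Components are ranked by kinetic variance
$\lambda^2$ and returned as plain projections without kinetic-map
rescaling: the ranking, not the scaling, is what downstream clustering
consumes. Constant features are dropped with a warning.

**Microstates.** k-means with k-means++ seeding and Lloyd iterations,
deterministic under a recorded seed. Empty clusters are repaired by
reseeding to the worst-fit point so k stays fixed; assignment ties break
to the lowest center index. This is written in-package rather than
delegated because these semantics (seeding, tie-break, repair) are part
of the module contract and are asserted by tests.

**Reversible MSM.** Sliding-window counts at lag $\tau$ are restricted
to the largest strongly connected component (largest by total counts; a
unique stationary distribution requires irreducibility). The
maximum-likelihood reversible $T$ comes from the standard fixed-point on
symmetric flows $x_{ij} \leftarrow (c_{ij}+c_{ji}) / (c_i/x_i +
c_j/x_j)$; every iterate satisfies detailed balance exactly, and
convergence is declared at a maximum relative flow change below
$10^{-10}$. Implied timescales $t_i(\tau) = -\tau/\ln\lambda_i(\tau)$
are reported per lag; the plateau rule (relative change below 0.1 for
the slowest three processes across two successive grid points)
operationalizes the usual visual Markovianity check. The lag grid is
user-chosen; nothing in the estimators depends on a particular grid.

**PCCA+.** The macrostate count is chosen as one plus the position of
the largest ratio $t_i/t_{i+1}$ among the slowest processes.
Memberships come from the inner-simplex algorithm on the
$\pi$-orthonormal right eigenvectors: orthogonal index search locates
the rows spanning the largest simplex, and the inverse of that vertex
matrix maps all rows into the probability simplex. No subsequent
objective optimization is applied (the family of PCCA+ refinements
differs here; the inner-simplex variant is the documented choice). The
linear transform can produce slightly negative memberships; these are
clipped and rows renormalized. Macrostate populations aggregate the
stationary weights of *crisp* (argmax) members — whether fuzzy or crisp
aggregation is intended in published tables is usually unstated, and
crisp is the reproducible choice. Near-degenerate eigenvalues at the cut
raise an error rather than returning an arbitrary simplex.

**Kinetics.** Committors solve the boundary-value linear system (0 on
the source set, 1 on the sink set); for reversible chains the backward
committor is $1 - q^+$. Reactive fluxes $f_{ij} = \pi_i q^-_i T_{ij}
q^+_j$ are decomposed into pathways by iterated widest-path (bottleneck)
extraction on the net-flux digraph, stopping when the undecomposed
remainder falls below 1% of the total flux (configurable). Macrostate
committors are $\pi$-weighted means of member values — again a
reporting convention made explicit. MFPTs solve $m_i = \tau + \sum_j
T_{ij} m_j$, with set-level values weighted by the stationary
distribution restricted to the source set; this includes both direct and
intermediate-mediated routes by construction. Rates follow
$k_{on} = 1/(\mathrm{MFPT}_{on} C)$, $k_{off} =
1/\mathrm{MFPT}_{off}$.

**Free energies.** $\Delta G = -RT\ln(\pi_{bound}/\pi_{unbound})$, with
the natural logarithm (required for kcal/mol magnitudes to come out
right) and $R = 1.9872\times10^{-3}$ kcal/(mol K). The standard-state
correction is implemented as the concentration-ratio term $\Delta G^0 =
\Delta G - RT\ln(C_0/C)$ with $C$ the effective ligand concentration of
the simulation volume. Published tables rarely state their conversion
formula or effective concentration, so printed $\Delta G^0$ values
cannot generally be audited from populations alone; the package reports
both $\Delta G$ and $\Delta G^0$ with the concentration used.

## The synthetic-data generator

Two generators provide ground truth:

* **Planted chains** — `build_reversible_chain()` constructs
  $T_{ij} = q_{ij}\min(1, \pi_j/\pi_i)$ (Metropolis acceptance on a
  block-connectivity graph with symmetric proposals), which satisfies
  detailed balance against the target stationary law *by construction*.
  The default study system plants four blocks with stationary
  populations 35.27 / 0.37 / 0.44 / 63.92 % — an unbound-dominant /
  bound-dominant split with two rare intermediates, the population
  structure characteristic of a weak-affinity lectin ligand — at an
  intra/inter hop-rate ratio of $10^3$, giving three slow exchange
  processes well separated from within-block mixing.
* **Langevin binding simulations** — overdamped dynamics
  $x \leftarrow x - (\Delta t/\gamma)\nabla U + \sqrt{2 k_B T \Delta
  t/\gamma}\,\xi$ in a reflecting box over a sum of radial basins
  (Gaussian wells by default; a harmonic option exists because the
  Boltzmann-variance oracle is exact there). The deepest basin is the
  designated binding site; fixed pseudo-residues ring each basin at
  0.35 nm so a 0.5 nm contact cutoff resolves which basin is occupied.
  Default pipeline conditions (2-D, 3 nm half-box, bound depth
  14 kJ/mol, two 6 kJ/mol intermediates, $k_BT = 2.494$ kJ/mol, eight
  150 000-step trajectories) give multiple binding/unbinding events per
  trajectory.

What the toy data do **not** emulate: atomistic geometry (no internal
ligand/protein degrees of freedom, no orientation-dependent binding),
solvent and electrostatics, anisotropic diffusion, and the sheer
dimensionality of real contact spaces. Passing tests therefore
demonstrate estimator correctness — recovery of planted populations,
timescales, committors, fluxes and rates — not force-field realism.

## Numerical choices worth knowing

* **Integrator stability.** The Euler–Maruyama step must resolve the
  stiffest feature it sees. For a harmonic well of spring constant $k$,
  the discrete stationary variance is inflated by $1/(1 - k\Delta
  t/2\gamma)$, so variance tests run at $\Delta t \ll \gamma/k$. The
  same constraint applies to *bias* features in metadynamics: hills of
  height $h$ and width $w$ add local curvature $\approx h/w^2$, and the
  double-well reconstruction runs at $\Delta t = 0.001$ ps with
  $h = 0.5$ kJ/mol precisely because coarser steps sample the hill-scale
  wiggles with a systematic error that accumulates in the deposited
  bias (observed as a slowly growing barrier deficit; diagnosed against
  the analytic barrier, fixed by the smaller step, not by loosening the
  check).
* **Well-tempered metadynamics.** Hills deposit every 500 steps with
  effective height $h\exp(-V(s)/k_B\Delta T)$, $\Delta T =
  (\gamma_b-1)T$, $\gamma_b = 6$; the free energy is read out as
  $F(s) = -(T+\Delta T)/\Delta T \cdot V(s)$, min-shifted, which is
  invariant to any additive constant in the bias. Bias and gradient are
  accumulated on a fixed grid (tails truncated at $6w$) and linearly
  interpolated; an optional late-stage checkpoint average
  (`n_average`) damps the residual fluctuation of the instantaneous
  read-out.
* **Egress dwell window.** The detector requires the distance CV to stay
  beyond the unbound threshold for a dwell window (default
  10 deposition intervals) to suppress recrossing noise. In the toy
  systems the free diffusion constant $k_BT/\gamma$ carries the walker
  across the whole box within a single deposition interval, so the
  comparative egress studies pass `dwell =` one interval; with the
  default window every run in a closed box is censored. Real
  (atomistic-scale) CV series should keep the longer default.
* **Two-state rate reporting.** On the toy landscapes the unbound bulk
  is diffusive rather than metastable, and PCCA+ may split it at higher
  macrostate counts; comparative thermodynamics between landscapes
  (parent-like vs derivative-like) therefore use the two-macrostate
  reduction, which is also the natural frame for
  $k_{on}/k_{off}$.
* **Problem sizes.** Tests and the acceptance script use $10^6$-step
  discrete chains, $10^5$ first-passage samples, $10^7$-step
  metadynamics runs and 10-seed egress ensembles — sizes at which every
  stochastic assertion has comfortable margin on a single CPU while the
  whole suite stays under a minute.

## Known limitations

* Error bars: only a simple whole-trajectory bootstrap
  (`bootstrap_mfpt()`) is provided; no Bayesian transition-matrix
  posterior.
* No Chapman–Kolmogorov test; Markovianity validation rests on
  implied-timescale flatness.
* The committor/backward-committor identity $q^- = 1 - q^+$ is used
  throughout and assumes the reversible estimator; feeding a
  non-reversible matrix through `tpt_flux()` would silently assume
  reversibility.
* PCCA+ without post-optimization can yield memberships slightly outside
  the simplex before clipping; on well-separated systems (the intended
  regime) clipping is inconsequential, and the adjusted-Rand tests
  confirm exact block recovery at coupling ratios of $10^{-3}$.
* The metadynamics engine is 1–2 CVs on analytic landscapes by design;
  it is a testbed for the bias protocol and read-out, not a replacement
  for atomistic biased sampling.
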