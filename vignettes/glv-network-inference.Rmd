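---
title: "Inferring stability-constrained microbial interaction networks from longitudinal relative abundances"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring stability-constrained microbial interaction networks from longitudinal relative abundances}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`glvnet` describes a community of $n$ taxa by the generalized
Lotka–Volterra (gLV) system

$$ y'(t) = \mathrm{diag}(y(t))\,\bigl(r + A\,y(t)\bigr), $$

where $y(t)$ is the vector of abundances, $r$ the intrinsic growth rates,
and $A$ the interaction matrix: $a_{ij}$ is the per-capita influence of
taxon $j$ on the growth of taxon $i$ (facilitation when positive,
inhibition when negative; the diagonal is self-limitation). Abundances
here are relative (proportions from 16S sequencing). Fitting gLV directly
to proportions is an approximation — it implicitly treats total microbial
load as constant — and we adopt it deliberately rather than re-litigate
it; its compositional consequences are handled explicitly below.

The central assumption is that the observed community hovers around an
**asymptotically stable interior equilibrium** $\bar y$ determined by the
data. At an interior equilibrium,

$$ \mathrm{diag}(\bar y)(r + A\bar y) = 0
   \quad\Longleftrightarrow\quad r = -A\bar y, $$

which eliminates $r$ analytically: the inverse problem is a search over
$A$ alone, with the equilibrium condition satisfied exactly by
construction. Local stability is governed by the Jacobian
$J = \mathrm{diag}(r + A\bar y) + \mathrm{diag}(\bar y)A$ (the first term
vanishes at interior equilibria but is kept so boundary points are
handled); admissibility requires the spectral abscissa
$\max_j \Re\,\lambda_j(J)$ to lie below $-m$ with a margin $m = 10^{-6}$,
because floating-point eigenvalues near zero are sign-unreliable — a
strictly zero margin would accept numerically marginal spectra.

This feasibility problem is nonconvex and deliberately multi-solution:
many networks describe the same stable equilibrium. The package therefore
returns an **ensemble** of admissible $(A, r)$ pairs found by repeated
Monte-Carlo-sampled direct search, and distills the ensemble into a
consensus signed network.

# The objective and the search

Each restart minimizes a scalar merit function over the entries of $A$:

$$ f(A) \;=\; \mathrm{WMSE}(A)
   \;+\; \max\bigl(0,\ \alpha(J) + m\bigr)^2
   \;+\; \lambda \sum_{i \ne j} |a_{ij}|, $$

* **Stability hinge.** $\alpha(J)$ is the spectral abscissa; the squared
  hinge is zero exactly on the admissible set.
* **Trajectory misfit** (when longitudinal observations are supplied).
  For each subject the gLV model is integrated by fixed-step RK4
  (step 0.5 weeks) from the subject's initial state through the sampled
  weeks, and predicted compositions are compared with observed ones in
  **centered-log-ratio (clr) space**, weighted by the inverse of the
  log-scale variance model $\sigma^2_{ik} = c_v^2 + 1/(D\,p_{ik})$ with
  multiplicative-noise coefficient of variation $c_v = 0.1$ and read
  depth $D = 10^4$ by default. The clr scale is what the noise model
  dictates: sequencing noise is multiplicative, and per-sample
  renormalization spreads a common-mode error across all taxa that clr
  residuals cancel exactly. Weights are evaluated at the per-week group
  mean composition, not at the individual observation, so weighting is
  not correlated with the error it standardizes. Without observations the
  objective reduces to the stability-plus-sparsity feasibility problem.
* **Sparsity.** A small $\ell_1$ penalty ($\lambda = 0.005$ on the WMSE
  scale) regularizes entries the data do not constrain; consensus
  networks are expected to be sparse.

Two nuisance blocks are estimated jointly with $A$, as extra rows of the
search matrix, each penalized by its squared standardized deviation:

* a log-scale refinement of $\bar y$ within the standard errors of its
  estimate — pinning the equilibrium at a few-percent-biased estimate
  otherwise creates per-capita growth misfits that the optimizer absorbs
  into spurious edges from quasi-static taxa (which act as free
  growth-rate knobs);
* log-scale deviations of each subject's latent initial state from its
  noisy week-3 observation — seeding each trajectory with a noisy start
  is an errors-in-variables problem whose signature is inflated
  mean-reversion (spurious edges that help slow taxa shed their start
  error).

The minimizer is a **compass (coordinate pattern) search**: coordinates
are polled cyclically in row-major order, $+$step before $-$step; the
first improving poll is accepted and polling continues with the next
coordinate; the step halves after a full improvement-free cycle and the
search stops below step $10^{-3}$ (or after `max_iters` moves and
contractions, default 20,000). Diagonal entries are constrained
nonpositive (self-limitation): without that bias, randomly sampled
matrices are almost never Hurwitz-stable as $n$ grows. Initial matrices
draw off-diagonals uniformly from $[-1, 1]$ and diagonals from
$[-1, 0]$. Polls with non-finite objectives (diverging forward
simulations) are rejected and the search continues; starting matrices
whose objective is non-finite have their off-diagonals halved until it
is.

The hot loop is compiled (RcppArmadillo); a pure-R implementation of the
identical algorithm (`glv_objective()`, `direct_search()`) serves as a
readable reference and cross-check.

# Compositional gauge

Purely compositional trajectories cannot distinguish $A$ from
$A + \mathbf{1}c^{\top}$: adding a constant to a column (with the implied
$r$) shifts every taxon's per-capita growth equally and leaves all
predicted compositions unchanged. Every solution is therefore reported in
its sparse gauge representative — each column's off-diagonal median is
subtracted (`l1_gauge()`), the $\ell_1$-minimal member of the gauge
class. For a sparse true network whose columns have at most two
mixed-sign interactions among at least six entries the true matrix is the
unique representative; for three-taxon communities the representative
halves each column's single interaction and mirrors it (sign preserved),
which is the best any compositional method can do at $n = 3$.

# Ensemble acceptance, stability selection, and consensus

A solution is **accepted** when its stability penalty is exactly zero
(spectral abscissa below $-m$), its equilibrium residual max-norm is
below $10^{-8}$, and — when trajectories are fitted — its full-data
objective is within 25% of the best accepted objective, keeping the
consensus on the global basin. Near-misses are retained in the ensemble
but flagged unaccepted. With data, each restart fits a random 80% subset
of subjects, so the restart ensemble doubles as a stability-selection
loop: interactions driven by the noise of particular animals lose sign
agreement across the ensemble, real interactions keep it.

The **consensus network** contains the ordered pair $j \to i$ when the
median of $a_{ij}$ over accepted solutions has magnitude at least
`strength_floor` (0.05) and at least `sign_support` (80%) of solutions
agree with the median's sign. Edge weight is the absolute median, support
the agreement fraction. Diagonals (self-limitation) are reported in a
separate table, never as graph edges. Two consensus networks are compared
edge-key by edge-key into losses, gains, sign flips, and weight changes.

# The synthetic cohorts

Because the method is exercised entirely on synthetic data with known
ground truth, the generator is a first-class module. A scenario fixes the
taxon set (the seven phyla Actinobacteria, Bacteroidetes, Cyanobacteria,
Firmicutes, Proteobacteria, Tenericutes, Verrucomicrobia), a
stability-verified ground-truth matrix $A$ and equilibrium $\bar y$, a
starting composition, and the study design: 12 mice per group sampled
weekly from 3 to 15 weeks of age. The forward model integrates the gLV
dynamics per mouse from a lognormally perturbed start (sd 0.5 on the log
scale — inter-animal variability at weaning is large), applies mean-one
lognormal process noise (sd 0.1) to each weekly composition, splits
phyla across representative order-level lineages, and draws multinomial
reads at depth 10,000, so every sample column sums exactly to the depth
and the whole dataset is reproducible from its seed.

The two presets differ exactly in the designed treatment contrast: the
untreated community has a Proteobacteria hub (edges to Actinobacteria,
Bacteroidetes and Verrucomicrobia, plus a reciprocal Bacteroidetes
influence) that the treated community lacks, while the treated community
gains a positive Firmicutes → Verrucomicrobia influence; a positive
Bacteroidetes → Verrucomicrobia edge and a negative
Firmicutes → Bacteroidetes edge are shared.

Preset numbers encode an identifiability analysis, not biology alone:

* A relative-abundance gLV forces rare taxa to relax slowly (rate
  $\bar y_i |a_{ii}|$ per week), so the large developmental transients
  are carried by the abundant, fast phyla, and slow rare phyla start at
  their steady level. Edge sources are always phyla that actually vary
  (through the transient or through inter-animal scatter).
* Starting compositions were solved numerically (damped Newton on the
  noiseless flow) so that each taxon's week-11–15 window mean equals its
  equilibrium — otherwise the window-mean estimator is biased for slow
  taxa and the bias propagates into spurious interactions.
* Bacteroidetes and Firmicutes self-limitation rates are split (−1.5
  vs −0.6) so the two dominant phyla's transients are not collinear;
  with equal rates, compositional data cannot attribute interactions
  between them reliably.
* Interaction magnitudes are 0.45–0.6, diagonals −0.6 to −1.5, on the
  equilibrium (proportion) scale. These values are fixtures chosen once,
  not estimates of any real community.

What passing recovery tests on these data does **not** show: performance
under model misspecification (real dynamics are not gLV), under
time-varying perturbations (antibiotic kill dynamics are out of scope),
at realistic phylum compositions more skewed than these, or at $n$ much
larger than 7. The generator's noise is observation-only; dynamical
(process) noise feeding back into the trajectories would weaken the
inference further.

# Numerical choices and degenerate inputs

* Simulation (`simulate_glv()`): adaptive stiff-capable `lsoda` with
  absolute tolerance $10^{-9}$, relative $10^{-7}$; negative excursions
  below $10^{-10}$ in magnitude are clipped to zero (trajectories from
  nonnegative starts are nonnegative analytically); $|y| > 10^6$ aborts
  with the failure time — divergent parameterizations are routine during
  inference sampling and are rejected, not fatal.
* Inside the objective, fixed-step RK4 (0.5 weeks) replaces the adaptive
  solver: deterministic cost, bit-reproducible, and accurate to far below
  the noise floor at gLV rates of order 1/week.
* Zeros in count tables are replaced by a detection floor
  ($10^{-4}$ after normalization, renormalized) so equilibria are
  interior; the stability analysis and the elimination $r = -A\bar y$
  both require $\bar y > 0$. All-zero samples become uniform floor
  columns rather than errors.
* The equilibrium's standard errors come from subject-level window means
  (subjects, not samples, are the independent replicates), floored at
  $10^{-3}$ relative.
* Determinism: all randomness flows through configured integer seeds;
  ensembles, generated datasets, and whole pipeline runs are
  byte-reproducible.

# Known limitations

* Identified structure is conditional on the stable-equilibrium premise
  and the constant-total-load approximation; edges should be read as
  influences on relative, not absolute, abundance.
* At three taxa the compositional gauge is irreducibly ambiguous; edge
  signs survive, magnitudes are halved and mirrored.
* At the study's noise level the consensus retains a few spurious
  interactions at the detection-floor scale (supports above 0.8). In our
  own two-condition contrast this masks part of the designed qualitative
  difference: of the three Proteobacteria hub-edge losses only one
  appears as a clean loss (the others surface as a sign flip or weight
  change), and the treated group's Firmicutes → Verrucomicrobia gain
  appears as a threefold weight increase over a floor-scale artifact
  rather than a new edge. Contrast claims at or near `strength_floor`
  should not be trusted; claims about edges at 3–10× the floor are
  robust in our recovery runs.
* Problem sizes used throughout (7 taxa, 12 subjects, 13 weeks, 200
  restarts) keep a full two-group analysis within minutes on one core;
  they were chosen as the point where recovery saturates on the presets.

# Relation to the module surface

`community_model`/`simulate_glv`/`glv_rhs` define and integrate the
dynamics; `stability_matrix`/`spectral_abscissa`/`assess_stability`
implement the equilibrium stability analysis; `read_abundance`,
`aggregate_taxa`, `relative_abundance`, `estimate_equilibrium` handle
tables and the data-determined equilibrium; `make_scenario`/
`generate_dataset` are the synthetic study; `infer_ensemble`/
`consensus_network`/`compare_networks` are the inference layer; and
`run_pipeline()` chains everything from a seeded config. The numbered
scripts under `analysis/` narrate the full study; `scripts/acceptance.R`
recomputes the headline quantities from scratch.
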