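---
title: "Multicellular reservoir computing: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multicellular reservoir computing: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcreservoir)
```

## The model

`mcreservoir` simulates a community of cells arranged on a 3D voxel grid
(one cell per voxel) that is used as a *reservoir computer*: a fixed,
randomly wired dynamical system whose state is read out by a trained linear
model to approximate a temporal Boolean function of a binary input stream.
Nothing inside the reservoir is ever trained or rewired — different target
functions only retrain the readout.

Each cell runs a random Boolean network (RBN) over `N = 1 + 2E + N_r`
binary genes: one input signal gene, a receptor and a secreter gene for
each of the `E` extracellular signalling molecules (ESMs), and `N_r`
reservoir genes. The community contains `S` distinct strains (independently
generated topologies and truth tables); each cell is assigned a strain
uniformly at random.

### Wiring

Edges are assigned randomly and uniformly under three constraints: the
input gene and the receptor genes have no incoming edges, secreter genes
have no outgoing edges, and the total edge count is exactly
`2 (N - 1 - E)`, which fixes the mean in-degree of the regulated
(secreter + reservoir) genes at exactly 2. Together with unbiased
Bernoulli(0.5) truth-table outputs this places every strain at the critical
wiring point where Boolean networks are most capable computationally.
`round(L (E + N_r))` of the edges (round-half-to-even, so the count is
deterministic and unbiased) originate at the input gene and go to distinct
regulated genes; `L` is therefore both the fraction of input-wired genes
and the fraction of input edges. The remaining edges draw sources uniformly
from the non-secreter genes other than the input gene and targets uniformly
from the regulated genes. Self-edges on regulated genes are allowed;
duplicate (source, target) pairs are resampled. Per-gene in-degrees `k_i`
are whatever the random assignment produces (only the mean is pinned);
truth tables have `2^{k_i}` entries and an in-degree-0 gene holds a
constant random value.

### Communication

Cells communicate through ESM concentrations obtained from the steady state
of a screened diffusion equation per molecule,

    0 = beta * Laplacian(C) - alpha * C + eta / V_c,

discretised with the 7-point finite-difference Laplacian on unit voxels
(`V_c = 1`; units are internal to the simulation and cancel in every
threshold, which is defined relatively). Domain walls are zero-flux
(Neumann) via ghost-voxel reflection, except the input wall (the `x = 0`
face), which is a Dirichlet boundary for the input molecule only: held at
100000 when the current signal bit is 1 (a source) and at 0 otherwise (a
sink). Solving to steady state every step encodes the assumption that
diffusion is much faster than gene regulation. The effective interaction
distance is `lambda = sqrt(beta / alpha)`; the standard parameters
`alpha = 1/45`, `beta = 5` give `lambda = 15`. Secretion is leaky:
`eta_basal = 1` when a secreter gene is OFF, `eta_active = 5` when ON.

A receptor turns ON when the ESM concentration *in the cell's own voxel*
is at least `theta` times the *basal reference concentration* — the
numerically computed steady concentration in the voxel of a lone cell
secreting at the basal rate at the domain centre. The input threshold is
calibrated per run so that exactly the first `I` cell layers sense the
active input wall: the field from an active wall with no interior sources
decays monotonically with depth, and the threshold is placed at the
geometric mean of the layer-`I` and layer-`I+1` centre concentrations
(maximising the relative margin on both sides against floating-point
noise; for `I = depth` it is `1 - 1e-6` times the last layer's value). The
model only specifies that the signal must penetrate `I` layers; the
geometric-mean placement is this package's choice of a maximally robust
threshold.

### The timestep

Each step applies, in this exact order: (1) per-cell ESM secretion rates
are set from the *current* secreter gene states; (2) the input wall's
Dirichlet value is set from the current signal bit; (3) all steady-state
fields are solved; (4) input and receptor genes are updated by thresholding
the fields; (5) secreter and reservoir genes are updated from their truth
tables, reading the *new* input/receptor values and the *old*
secreter/reservoir values. The ordering matters: a receptor that flips in
step (4) influences regulated genes within the same step.

### Readout

A run lasts `T` timesteps (default 1000; `v_1 = 0`, all concentrations and
environment-facing genes start at 0, all other genes i.i.d.
Bernoulli(0.5)). The first `T_W = 100` warm-up steps are excluded so
initial-state transients do not enter training. Covariates are the
reservoir-gene states of all cells in the `O` output layers (farthest from
the input wall), read at `t + d`; the delay `d` lets information propagate
across layers before it is read (the three-layer community needs `d = 2`:
with a short `lambda` each hop to the next layer costs one step). The
targets are the objective outputs on windows ending at `t`. Rows are split
75/25 (test size `floor(n/4)`, unstratified) and an L1-penalised linear
regression is fitted with the penalty chosen by 5-fold cross-validation on
the training rows; continuous predictions are binarised at 0.5 (targets
are 0/1 and symmetric; the model reports only hard accuracy). Binary
covariates share a scale, so no standardisation; the coordinate-descent
convergence threshold is kept loose (`1e-4`) because the decision rule is
a 0.5 cut, far coarser than the fit tolerance. Accuracy is the fraction of
correctly predicted held-out rows: 50% is the floor for a balanced target
(a random guess), 100% the ceiling.

## Numerical choices

* **Solver.** The discrete operator `alpha I - beta Lap_h` is symmetric
  positive definite for `alpha > 0`, so each molecule's system is solved by
  a sparse Cholesky factorization (Matrix package). Within a run the
  operator never changes; it is factorised once and reused. The per-step
  ESM evaluation goes further: the fields are linear in the secretion
  rates, so the solver precomputes the cell-to-cell Green matrix (the
  field of a unit source at each cell, evaluated at every cell voxel) and
  each step reduces to one small matrix product per molecule. The
  full-field and Green-matrix paths agree to solver precision and are
  cross-checked in the tests against an independently coded dense solve.
* **Domain.** The simulation box is the cell bounding box plus a `margin`
  (default 1) of empty voxels on every non-input wall, so that reflecting
  Neumann walls do not sit flush against cells and inflate their local
  concentrations; the input wall stays flush so layer 1 touches the
  source. The margin is a config parameter recorded in outputs.
* **Determinism.** The master seed spawns independent substreams for
  strain construction, strain assignment, initial states, the input
  signal and the readout split, so any component can be varied while the
  others are held fixed; `(config, seed)` reproduces a run bit-exactly.
* **Degenerate readouts.** A constant training target (or a degenerate
  lasso fit) falls back to the constant model, whose accuracy is still
  evaluated on the held-out rows.

## Sensitivity analysis

The sensitivity pipeline draws Latin hypercube samples over the eight
varied parameters — `L`, `N_r`, `C`, `S`, `I`, `lambda`, `E`, `theta` —
(one draw per equal-width interval per dimension, orders shuffled
independently), maps each to a cube-community configuration, simulates it,
and computes partial rank correlation coefficients (PRCC) of each
parameter against test accuracy: all columns and the output are
rank-transformed (average ranks on ties; only monotone structure is kept),
each parameter's ranks and the output's ranks are regressed by OLS on all
*other* parameters' ranks, and the PRCC is the Pearson correlation of the
two residual vectors. p-values use the t-statistic with `n - k - 1`
degrees of freedom. On small instances the residual route is verified
against partial correlations obtained by inverting the Spearman
correlation matrix.

Mapping choices: integer parameters are sampled continuously and rounded;
cell counts are snapped to the nearest admissible cube (the geometry
requires it) and `I` is clamped to the resulting depth, exactly as a
bounded design forces; `lambda` is varied directly and converted to
`alpha = beta / lambda^2` at fixed `beta = 5`. The PRCC uses the values
actually simulated (post-snap), since those produced the accuracies.
Replicate accuracies enter as separate rows by default — averaging first
is available and recorded in the result — because the estimand (monotone
association) is the same either way and separate rows keep the per-run
noise visible to the p-values.

## Study conditions and scale

The shipped study defaults are the package's chosen conditions:

* **Proof of concept**: cube community in which every layer senses the
  input and every layer is read out (`I = O = depth`, `d = 0`), `N_r = 24`,
  `E = 5`, standard communication constants, median and parity at
  `w = 3, 5, 7, 9` versus a single-cell control. Two fixed parameters are
  not pinned by the published protocol and were chosen once: `S = 8`
  strains (the strain-count optimum observed in the layered analysis) and
  `L = 0.5` (the midpoint of the sensitivity range; `L` trades
  input-information bandwidth against internal recurrence). Desk scale
  uses a `5^3` community, `T = 600` and 10 replicates per condition; the
  full-size protocol is `12^3`, `T = 1000`, 100 replicates.
* **Layered community**: three stacked square layers, `I = 1`, `O = 1`,
  `d = 2`, with one-at-a-time sweeps of `N_r`, `C`, `S`, `E`.
* **Sensitivity**: desk scale draws 150 LHS samples with `C` capped at
  `6^3` and `N_r` at 100 and runs one replicate per set at the full
  simulation length `T = 1000` (the full design is 10000 sets of 5
  replicates over `C` up to `15^3`, `N_r` up to 500). The full length is
  retained here because the PRCC's resolution is limited by readout test
  noise — at `T = 1000` each accuracy rests on 223 held-out rows
  (binomial noise ≈ 3%), whereas shorter runs leave the parameter signal
  below the noise floor. Even so, with 150 samples over reduced ranges
  the PRCC point estimates carry sampling error of roughly ±0.1 and the
  weakly correlated parameters (`I`, `lambda`, `E`, `theta`) are within
  noise of zero; the strong ordering (`L` first, `N_r` second, `C` and
  `S` positive) is the reproducible structure.

## What the generator does and does not emulate

The synthetic communities reproduce the mechanism — critical RBNs,
steady-state screened diffusion, thresholded leaky signalling, layered
input penetration — under idealised conditions: no cell division, death or
motility, no molecular noise in secretion or sensing, identical
communication constants for all molecules, perfectly synchronous updates,
and one cell per voxel on a regular grid. Passing tests therefore show
that the *computational framework* behaves as specified, not that a wet
biological community would achieve the same accuracies; receptor
heterogeneity, stochastic expression and asynchrony would all erode the
reservoir's effective memory.

## Known limitations

* Steady-state diffusion only; no transient dynamics within a step.
* The lasso readout is a linear model on binary covariates; tasks whose
  reservoir representation is not linearly separable are invisible to it
  even if the information is present.
* With the standard communication constants and `theta = 11.5`, a large
  community's pooled basal secretion can saturate receptors (always above
  threshold), in which case ESM channels carry little information and
  accuracy rests on the input gene and internal dynamics — consistent
  with communication-knockout observations in homogeneous-input
  communities.
* Exhaustive task enumeration is limited to `w <= 4`; larger windows are
  sampled.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(C = 27, N_r = 10, E = 2, S = 3, T = 300, T_W = 50,
                  task = task_spec("parity", 3), seed = 1)
row <- run_single(cfg)
row[, c("task", "C", "N_r", "accuracy")]

sens <- run_sensitivity_study(n_samples = 30,
  ranges = sensitivity_ranges(C_max = 4^3, Nr_max = 40, I_max = 4),
  T = 200, seed = 1)
as.data.frame(sens$prcc)
```
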