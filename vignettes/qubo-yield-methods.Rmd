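---
title: "QUBO models for reaction yield prediction and condition search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{QUBO models for reaction yield prediction and condition search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quboyield)
```

## The model

A reaction setup is encoded as a vector `x` whose entries mark the presence
(1) or absence (0) of discrete choices — a ligand, a base, an additive, a
solvent, a temperature bin — and, optionally, a reaction segment carrying
fingerprint bits or a product-minus-reactant fingerprint difference with
entries in {−1, 0, 1}. The predicted yield is a quadratic form

    y = x' Q x

so the diagonal of `Q` holds per-choice contributions and the off-diagonal
cells hold pairwise interactions. Maximising the yield over conditions is
then minimising `−x' Q x` over binary vectors — a quadratic unconstrained
binary optimization (QUBO) instance that annealing hardware, or the
bundled simulated annealer, solves directly.

Internally every `QuboMatrix` is stored in *single-count upper-triangular*
form: the energy is `offset + Σ_{i≤j} Q[i,j] x_i x_j`, with each pair
coefficient counted once. The familiar symmetric table display, in which a
pair coefficient appears in both mirror cells, is produced by
`symmetricMatrix()` and is presentation-only — evaluating the bilinear
form on the symmetric display would double-count the interactions. The
triangular convention is the one under which the worked two-condition
example (substrate −192 ‰, additive 256 ‰, pair 16 ‰, prediction 80 ‰)
is internally consistent, and it matches common QUBO-solver conventions.

## Two routes to Q

**Learned quadratic model** (`mlQuboModel()`, `trainMlQubo()`). `Q` is an
unconstrained n×n real parameter, initialised as `0.01·N(0,1)` and fitted
by full-batch Adam on the RMSE between `x' Q x` and the standardized
yield. Defaults follow the standard recipe for this model family: 200
epochs, learning rate 1e-3, an ensemble of 5 members each drawing its own
80:10:10 train/validation/test split, and per-member selection of the
epoch checkpoint with the lowest validation RMSE. Predictions average the
members and invert the target standardization. No symmetry constraint is
imposed during training; symmetrisation happens only at export
(`exportTriangular()` folds `Q[i,j]+Q[j,i]` into the upper triangle, which
preserves the bilinear form exactly).

Two numerical points deserve note:

* *Target standardization and the intercept.* Standardizing targets
  subtracts a constant, but a quadratic form has no intercept: it is
  pinned to 0 at `x = 0`. On one-hot condition encodings this is harmless
  — each slot's bits sum to one on every row, so constants lie in the
  model span — but on arbitrary binary vectors a standardized target is
  not exactly representable. Parameter-recovery experiments therefore use
  one-hot designs, the model's intended input class.
* *Optimizer floor.* Constant-step Adam on an RMSE loss stalls at a
  residual proportional to the step size. `mlTrainConfig(lrDecay = )`
  decays the step geometrically across epochs; with `lrDecay = 1e-3` the
  fit on noiseless in-class data reaches ~1e-5 standardized RMSE. The
  default (`lrDecay = 1`, constant step) reproduces the standard recipe.

**Binary-coded least-squares model** (`enumerateTerms()`, `fitDau()`).
Every observed condition value, and every cross-slot pair of values
co-occurring in the data, owns a 10-bit code whose decoded value
`Σ 2^k b_k − 512` is its yield contribution in per-mille; the 1024 codes
cover the integers [−512, 511], giving ≈1 ‰ granularity over a 1000 ‰
yield range. Yields are multiplied by 1000 to match. The prediction for a
row is the sum of its singleton and pair contributions, and expanding the
summed squared error with `b² = b` turns least-squares fitting itself into
a QUBO over all code bits — `buildLsqQubo()` returns that matrix plus the
constant making `energy + constant = SSE` an identity, which the test
suite verifies exhaustively on small instances. Fitting uses exact
enumeration up to 24 bits (deterministic small fits) and the annealer
beyond. The fit uses all supplied rows; pairs unobserved at fit time carry
no variables and contribute zero at prediction, with a warning.
Predictions are reported raw (they can leave [0, 1000] ‰); clamping is
presentation-only.

## Solvers

`bruteForceMinimize()` enumerates up to 2^24 states in Gray-code order
with O(n) incremental energy updates and breaks ties by the
lexicographically smallest bit vector — it is the exact oracle throughout
the test suite. `annealQubo()` is single-bit-flip Metropolis under a
geometric inverse-temperature schedule with independent restarts; it
keeps the `topM` distinct lowest-energy states, recomputes their energies
exactly before reporting, and is fully deterministic in `(seed, sweeps,
restarts)`. A wall-clock `budgetSeconds` mode exists for parity with
hardware annealers whose run time is specified in seconds, but the
default fixed-sweep mode is what tests rely on, precisely because a time
budget is not reproducible. Default temperatures scale with the largest
absolute coefficient (`beta` from 0.1/|c|max to 100/|c|max), so acceptance
starts near-free and ends frozen regardless of the instance's scale. On
seeded 10-variable random instances the annealer matches the exact
minimum on at least 95 of 100 instances (the suite checks this).

## Constraints and condition search

Cardinality rules — exactly one base, one to four reagents, at most two
solvents — are embedded as squared affine penalties that vanish exactly on
feasible assignments. `at_most_k` adds `⌈log2(k+1)⌉` slack bits whose
binary weights have the top weight clamped so the encodable slack range is
exactly [0, k]; `at_least_one` is the complement-count form. The search
QUBO (`buildSearchQubo()`) negates the conditional yield matrix and adds
these penalties; the default penalty weight `2·max|Q|·n` is a cheap
dominance bound and the function warns when a user-supplied weight falls
below the instance's energy span. Because a penalty weight can never be
proven dominant for the annealer's excursions, `searchTopK()`
double-enforces feasibility with a hard filter on returned assignments,
dedupes over slack bits, and ranks by predicted yield with ties broken by
the lexicographically smallest bit vector so that rankings are
solver-independent.

Per-reaction inference uses the conditional reduction
(`reduceConditional()`): fixing the reaction segment (values in
{−1, 0, 1}) folds fixed-fixed terms into a constant and fixed-free terms
into the free diagonal, yielding `Q_cond` over the binary condition bits
with energies preserved exactly. `countSpace()` counts feasible
combinations by the binomial product formula; for the 111-reagent
(choose 1–4) × 24-solvent (choose 0–2) example this evaluates to
1,871,327,836.

## Active learning

`runActiveLearning()` reproduces the iterative acquisition experiment:
100 seeded points, 9 iterations of 50 added points (to 550), five
independent folds, retraining from scratch each iteration so folds stay
comparable. Strategies: uniform random; strategic (the 50 highest
predicted yields, ties by index); adaptive (at iteration i of n,
`round(i/n · 50)` strategic picks — round half up — then random picks).
The model is scored before each selection by the top-k overlap between
its predicted ranking and the grid's true ranking, so the recorded
history has `iters + 1` entries starting with the seed-set model. Pool
yields are never read before their batch is revealed.

## The synthetic generator

`generateGrid()` emits a full-factorial screen with a planted quadratic
surface: per-value singleton effects `N(0, 0.10)`, cross-slot pair
effects `N(0, 0.03)`, base yield 0.30, well noise `N(0, 0.02)`, clipped
to [0, 1]. The default 15×4×3×20 shape (3,600 wells) mirrors a standard
C–N cross-coupling screen; the effect and noise scales were chosen once
as plausible for isothermal HTE plates (replicate noise of a few percent,
condition effects up to tens of percent) and are not tuned per test. The
skewed variant draws each well's base yield from Beta(α, β) (defaults
2 and 8, population skewness ≈ 0.86) to emulate screens where most
reactions perform poorly. `generateReaxysLike()` emits sparse
literature-style records — one condition set per reaction, 1–4 reagents,
0–2 solvents, a fingerprint whose active bits correlate with planted
reagent profiles, a temperature in [20, 150] °C.

What the generator does *not* emulate: real chemistry (no structure
–activity relationships, no mechanism), heteroscedastic or systematic
measurement error, label noise in condition records, and any
non-quadratic yield surface beyond the [0, 1] clip. A passing recovery
test therefore shows that the estimators and solvers are correct on
in-class data, not that the quadratic model suffices for real screens.
Clipping is the only nonlinearity; recovery experiments use parameter
settings (base yield 0.5, effect scales 0.04/0.015) under which the
planted surface stays strictly inside (0, 1), because a clipped surface
leaves the model class and exact recovery is then not a meaningful target.

## Problem sizes and numerical choices in the test suite

The suite runs entirely on synthetic data at deliberately modest sizes:
exhaustive SSE identities on instances up to 20 bits; annealer-oracle
agreement on 100 seeded 10-variable instances; hybrid search equality on
12-bit and 7-bit condition spaces over 20 seeds; learned-model recovery
on a 1,200-well grid; and the active-learning comparison on a 10×4×3×10
grid with ten master seeds of five folds each. Temperature handling
follows quantile binning with the inclusive-median convention (ties to
the lower bin) or LSB-first 8-bit binary codes covering the retained
20–150 °C range. Yields are fractions internally and percentages only in
evaluation reports. All randomness is seeded; every stochastic function
takes an explicit seed and is byte-reproducible.

## Known limitations

* The learned model's matrix is unconstrained, so exported off-diagonals
  mix symmetric and antisymmetric parts; only their sum is meaningful.
* One-hot (bin-based) encodings cannot score unseen condition values; the
  model must be re-dimensioned when the vocabulary grows.
* The binary-coded model allocates 10 bits per term, so its variable
  count is an order of magnitude above the learned model's and it needs
  correspondingly more data before its fit stabilises.
* Penalty search guarantees feasibility only via the output filter; with
  severely under-weighted penalties the annealer may spend its budget in
  infeasible regions and return few feasible states (the diagnostics
  report how many were filtered).
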