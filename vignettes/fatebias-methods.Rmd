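---
title: "Measuring cell plasticity as the proportion of hybrid cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cell plasticity as the proportion of hybrid cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fatebias)
```

## The model

`fatebias` treats differentiation as a continuum rather than a set of
discrete boxes. Its measurement chain has three stages.

**1. Probabilistic annotation.** A classifier trained on a
reference-annotated count matrix assigns every cell a probability simplex
over the reference cell types. The package's statistics consume *only*
this probability matrix, so the classifier is pluggable: probabilities
produced by any external annotator (e.g. a transformer-based label-transfer
tool) can be ingested via `read_probability_table()` and flow through the
rest of the pipeline unchanged.

**2. Fate bias.** For an ordered pair of fates (A, B) and a cell with
probabilities $p_A$, $p_B$, the fate bias is

$$\mathrm{bias}(A \mid B) \;=\; \frac{p_A}{p_A + p_B} \in [0, 1],$$

with 1 definite commitment to A, 0 definite commitment to B, and 0.5 an
equal, *hybrid* state. An equivalent signed difference form,
$(p_A - p_B)/(p_A + p_B) \in [-1, 1]$, is available via
`fate_bias(..., method = "signed")` for audit; we default to the ratio
form because all downstream conventions — a hybrid window centred at 0.5,
a [0, 1] range — are stated on that scale, and the two are an affine map
of one another. Cells with $p_A + p_B = 0$ carry no information about the
pair and are excluded from the denominator (and recorded on the result).

**3. Proportion of hybrid cells.** With $N$ the number of eligible cells
whose bias lies in a closed window and $M$ the eligible total,

$$P_{hc} = N/M.$$

The default hybrid window is $[0.4, 0.6]$; the nested windows
$[0.35, 0.65]$ and $[0.45, 0.55]$ are reported alongside it
(`phc_table()`), which both brackets the estimate and provides a built-in
sanity check: $P_{hc}$ must be monotone over nested windows.

**Assumptions.** (i) Hybrid cells have comparable probabilities for the
two flanking fates and accumulate at transition stages; (ii) the
proportion of such cells measures the plasticity of that transition. Both
are assumptions about the biology, not theorems; the synthetic validation
below tests only that the *pipeline* recovers a known hybrid fraction,
not that hybridness equals plasticity in any particular tissue.

**Eligibility (the denominator M).** By default the eligible population
for pair (A, B) is the cells whose reference label is A or B. This is a
genuine modelling choice — one could include every cell with
$p_A + p_B > 0$ — so `fate_bias()` also accepts an explicit cell list
(`eligible =`). Validation on simulations uses the cells of one topology
edge, because a reference label (e.g. GMP) spans two edges and would mix
transitions.

## The classifier backend

The default backend is deliberately simple and fully inspectable:

- **Features.** One score per gene set: the mean log-normalised expression
  of the set's genes (sets from a GMT file; genes absent from the matrix
  count as zero). This mirrors pathway-masked annotators while remaining
  linear. Without gene sets, the top 200 most variable genes are used
  directly.
- **Model.** Multinomial logistic regression with an L2 (ridge) penalty
  (`glmnet`, `alpha = 0`), fitted at a fixed penalty
  $\lambda = 0.075$ with class-balanced observation weights, features
  left unstandardised.
- **Normalisation.** Per-cell scaling to a library size of 10,000 followed
  by `log1p`; all-zero cells are dropped with a warning; the same recipe is
  applied to queries at prediction time. The trained model is never
  refitted on perturbed or query data.

Three of these choices deserve their rationale:

**Why a fixed, fairly strong ridge penalty?** Window-based hybrid counting
needs a probability scale that varies *smoothly* along the commitment
continuum. A maximally calibrated classifier on a reference whose labels
are a hard threshold of the underlying commitment will drive probabilities
toward 0/1 everywhere except a vanishing sliver around the boundary —
formally correct, but it collapses the hybrid window to nothing and makes
$P_{hc}$ an estimate of label noise rather than of the hybrid population.
The fixed ridge penalty acts as the smoothness dial; $\lambda = 0.075$ was
chosen once, during design, as the value at which the bias-versus-commitment
curve is approximately the identity across the hybrid window on the
synthetic continuum (see validation below), and is not adjusted per
dataset. Cross-validated penalties were examined and rejected for exactly
this reason: CV optimises hard-label deviance and saturates the scale.

**Why unstandardised features?** Gene-set scores are already on a common
scale (mean log-normalised expression). Leaving them unstandardised lets
the physical separation of the classes drive the logit scale: when
programs are far apart, probabilities saturate and $P_{hc} \to 0$, which
is the correct limit for a sharply committed population. Internal
standardisation would erase that dependence.

**Why balanced class weights?** In a branching reference the intermediate
types label more cells than the endpoints (an intermediate flanks two
edges). Unbalanced fitting folds these class priors into the intercepts
and shifts the bias scale off-centre — a cell with genuinely equal
evidence would score bias ≠ 0.5. Balancing removes the prior so that 0.5
means "equal evidence", which is what the hybrid window assumes.

Hard labels (`assign_labels()`) are the per-row argmax with ties broken by
vocabulary order, used only for the overlap matrix and fraction tables.

## The synthetic-data generator

`simulate_branching()` emulates a lineage-negative bone-marrow
differentiation continuum: an HSC-like root branching into GMP-like and
MEP-like intermediates that mature into Pro_NE-like and Pro_Mast-like
endpoints. Each type owns a gene program; a cell on edge (parent → child)
has a fate-mixture weight $w \in [0, 1]$ for the child fate, and the two
flanking programs are blended through a sigmoid activation of $w$
(steepness 4, i.e. near-linear across the hybrid window, committing at the
ends). Counts are negative binomial on the blended means with lognormal
library sizes. A fraction `hybrid_fraction_target` of each edge's cells
receives $w$ uniform in $[0.4, 0.6]$ (ground-truth hybrid cells); the rest
draw $w$ uniformly outside that window. Reference labels follow the
$w \ge 0.5 \Rightarrow$ child rule.

Defaults, fixed once: 2,000 cells; 320 genes with 50 per program; program
step 2.5 log2-fold (typical of curated marker programs); NB dispersion 0.2
(UMI-scale overdispersion); library sizes lognormal with median 5,000 and
sdlog 0.3. These describe a modest but realistic droplet experiment; at
this operating point the measurement chain resolves the hybrid window
(validation below) without being trivially noise-free.

What the generator does **not** emulate: real marker-gene identities,
correlated gene modules beyond the block programs, doublets, ambient RNA,
batch effects, more than two flanking programs per cell, or the full
13-type bone-marrow atlas. Passing the synthetic validation therefore
shows the *pipeline arithmetic and calibration* are sound, not that any
particular biological dataset will yield unbiased $P_{hc}$.

## Validation performed by the package's tests

- **Oracle equivalence.** `fate_bias()`/`phc()` agree exactly with a
  brute-force loop-and-count on randomized probability matrices
  (100 matrices, 200 cells × 5 classes, three windows).
- **Nested-window monotonicity** and **pair-swap symmetry**
  ($\mathrm{bias}(A,B) + \mathrm{bias}(B,A) = 1$; $P_{hc}$ invariant under
  swap for windows symmetric about 0.5) on random and pipeline inputs.
- **Separation limit.** A sharply committed population (program step 6
  log2-fold, activation steepness 8, no planted hybrids) yields
  $P_{hc} = 0$ on every pair through the full pipeline, and held-out
  accuracy ≈ 1.
- **Planted-fraction recovery.** Hybrid fractions of 5%, 10% and 20%
  (2,000 cells, 20 simulations each) are recovered by pipeline $P_{hc}$
  (averaged over the four edges, eligibility = the edge's cells) within
  ±3 percentage points.
- **Knockout directionality.** Zeroing an endpoint's program strictly
  decreases that endpoint's predicted fraction and mean probability;
  knocking out genes with zero counts reproduces the baseline bit-exactly;
  perturbation never mutates the serialized model.

`scripts/acceptance.R` re-runs all of these from scratch under a caller
seed and writes the measured numbers as JSON.

## Numerical choices and degenerate inputs

- Window endpoints are **inclusive** (closed intervals), matching bracket
  notation; windows must satisfy $0 \le lo \le hi \le 1$.
- Probability rows are renormalised when within $10^{-3}$ of summing to 1
  on file ingestion (within $10^{-6}$ for in-memory construction); larger
  deviations, or entries outside $[0,1]$ beyond $10^{-9}$, are errors that
  name the offending cell.
- ECDF threshold fractions use strict `<` at the threshold (default 0.5).
- Overlap matrix rows are normalised by reference-row totals, so they sum
  to 1 by construction; reference types whose diagonal falls below 0.8
  are flagged as fate-flexible.
- `classify_reversal()` calls a perturbation *partially reversed* when its
  value lies in the closed interval between the control and disease
  anchors (either orientation); equality with a bound counts as partially
  reversed so that float noise cannot flip a call; *reversed* means
  strictly beyond the control, away from the disease. The same rule
  applies to ECDF values at probability 0.5.
- Knockouts zero **raw counts before normalisation**, so library-size
  factors are recomputed from post-knockout totals. Zeroing after
  log-normalisation would leave size factors computed from pre-knockout
  totals; ordering is not derivable from the knockout definition itself,
  so it is fixed here and documented. Knockouts are idempotent and fatal
  when no gene of the set is present.
- Simulation, training and the CLI derive all randomness from explicit
  seeds; one global CLI seed fans out to per-stage seeds via
  `derive_seed()` so stages are independently reproducible.

## Known limitations

- $P_{hc}$ depends on the probability scale of the annotator. Two
  annotators with equal hard-label accuracy but different sharpness will
  give different $P_{hc}$; comparisons are meaningful within one trained
  model, not across models. This is inherent to the statistic, not to this
  implementation.
- The default backend is linear in gene-set scores; strongly non-linear
  class boundaries would need a different backend behind the same
  probability-matrix contract.
- The generator plants hybrids on a single edge coordinate; real hybrid
  states may mix more than two programs, where the pairwise bias is only a
  projection.
- Eligibility by reference label mixes transitions that share a type; use
  explicit cell lists when a trajectory assignment is available.
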