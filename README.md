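# fatebias

Quantifying cell plasticity from single-cell type probabilities.

## The problem

During branching differentiation — hematopoiesis being the canonical case —
some cells are not cleanly committed: they sit between two fates, with
comparable evidence for each. Discrete annotation (one label per cell) hides
these *hybrid cells*, yet their prevalence is exactly what changes under
genetic or environmental stress. `fatebias` measures plasticity on a fate
transition as the **proportion of hybrid cells**:

- A probabilistic cell-type classifier, trained on a reference-annotated
  expression matrix, assigns each cell a probability simplex over cell
  types (any external annotator's probability table can be ingested
  instead).
- For an ordered fate pair (A, B), each cell's **fate bias** is

  ```
  bias(A vs B) = Prob.A / (Prob.A + Prob.B)
  ```

  so 1 means definite A, 0 definite B, and 0.5 an equal, hybrid state.
- With N the number of eligible cells whose bias falls in a closed hybrid
  window (default [0.4, 0.6]) and M the eligible total,

  ```
  P_hc = N / M
  ```

  is the plasticity of the transition. Nested windows ([0.35, 0.65],
  [0.45, 0.55]) bracket the estimate.

Around this core the package provides ECDF ambiguity curves per reference
type, row-normalised reference-vs-prediction overlap matrices with
diagonal flagging, in-silico gene-set knockouts (zero a pathway's counts,
re-predict with the *fixed* trained model, compare fractions and P_hc,
call reversal against control/disease anchors), and a branching
negative-binomial simulator with known per-cell fate mixtures so every
stage is testable without external data.

Intended users: computational biologists analysing scRNA-seq
differentiation data who want a number — not a picture — for "how fuzzy is
this fate boundary, and did my perturbation change it?"

## Worked example

Simulate a five-type hematopoietic caricature (HSC → GMP/MEP → Pro_NE /
Pro_Mast) with 10% planted hybrid cells, train the classifier on its own
reference labels, and measure plasticity:

```r
library(fatebias)

sim   <- simulate_branching(config = sim_config(hybrid_fraction_target = 0.1, seed = 42))
model <- fit_classifier(sim$expression, sim$cells, gene_sets = sim$programs, seed = 1)
glance(model)
#>   n_classes n_features feature_kind n_train holdout_accuracy lambda
#> 1         5          5 gene_sets       2000            0.980  0.075

probs <- predict_proba(model, sim$expression)
phc_table(probs, sim$cells)
#>   group window       `HSC vs GMP` `HSC vs MEP` `GMP vs MEP` `GMP vs Pro_NE`
#> 1 sim   [0.35, 0.65]         9.49         9.06            0           11.3
#> 2 sim   [0.4, 0.6]           4.59         5.22            0            7.55
#> 3 sim   [0.45, 0.55]         1.77         1.87            0            3.91
```

The table (percentages) reads like its real-data counterpart: transitions
that share an edge in the topology carry hybrid cells, the unrelated
GMP-vs-MEP contrast is 0%, and nested windows shrink P_hc monotonically.
ECDF curves summarise per-type ambiguity — here ~30% of GMP-labelled cells
have Prob(GMP) below 0.5, while committed types sit entirely below the
threshold:

```r
glance(ecdf_curve(probs, "GMP", sim$cells))
#>   group        n frac_below
#> 1 GMP        475      0.295
#> 2 HSC        484      1
#> ...
```

An in-silico knockout of the Pro_NE program depletes that endpoint and
collapses the GMP-to-Pro_NE hybrid pool; the reversal rule classifies a
perturbed P_hc against control/disease anchors:

```r
res <- perturb_and_repredict(model, sim$expression, sim$programs[["Pro_NE"]],
                             set_name = "Pro_NE_program", cells = sim$cells,
                             pairs = list(c("GMP", "Pro_NE")))
res$fractions          # Pro_NE: 0.140 -> 0
res$phc                # P_hc 0.0755 -> 0
classify_reversal(0.0322, 0.0725, 0.05)
#> [1] "partially_reversed"
```

`autoplot()` methods draw the ECDF curves, overlap heatmap, bias histogram
with the hybrid window shaded, and stacked perturbation bars. A thin
command-line wrapper exposes the same stages:

```sh
Rscript inst/cli/fatebias.R simulate --out sim/ --seed 1
Rscript inst/cli/fatebias.R train --matrix sim/expression.mtx \
  --cells-file sim/expression_cells.tsv --genes-file sim/expression_genes.tsv \
  --cell-table sim/cells.tsv --gmt sim/programs.gmt --out model.rds
```

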