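---
title: "Methods: the drug-target / drug-signature network landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the drug-target / drug-signature network landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(druglandscape)
```

## The model

Drugs relate to genes through two largely disjoint mechanisms. A *drug-target
gene* codes a protein the compound physically binds; a *drug-sensitive*
(signature) gene changes expression when cells are treated with the compound.
`druglandscape` encodes both as layers of one bipartite multigraph: drug and
gene nodes, with a `target` edge for every binding pair and a `sensitive`
edge for every significant expression response. A pair that is both bound
and responsive carries two typed edges, never one weighted edge, so the two
per-gene scores remain independent sums:

* **KDTN(g)** — the number of distinct drugs with a target edge to `g`
  (the gene's degree in the drug-target network, DTN);
* **KDSN(g)** — the number of distinct drugs with a sensitive edge to `g`
  (its degree in the drug-sensitive network, DSN).

Genes are then partitioned by the two scores: **DTG** (KDTN ≥ 1, KDSN = 0,
target-only), **DSG** (KDSN ≥ 1, KDTN = 0, sensitive-only) and **DTSG**
(both ≥ 1). The partition is exhaustive over scored genes and pairwise
disjoint, so the set identities
`|DTG| + |DTSG| = #[KDTN ≥ 1]` and `|DSG| + |DTSG| = #[KDSN ≥ 1]`
hold by construction and are asserted in the tests.

## Signature calling

Sensitive edges come from per-drug differential-expression tables
(gene, linear-scale fold change, p-value and/or adjusted p). A pair is
called sensitive when

```
adjusted p < 0.05   AND   (FC > 2  OR  FC < 0.5)
```

with *strict* inequalities at every boundary — the thresholds are
conventionally printed as strict, and `call_signatures()` honours that
exactly (FC = 2.0, FC = 0.5 and adjusted p = 0.05 are not called). Both
branches are reciprocal two-fold changes on the linear scale; log-scale
inputs must be exponentiated by the caller, and the reader warns when any
FC ≤ 0 sneaks in. When only raw p-values are available,
Benjamini–Hochberg adjustment is applied per drug by default (each
compound's contrast is its own testing family, as in Connectivity-Map-style
profiling) or globally via `signature_config(adjust_scope = "global")`.
Calling is idempotent, order-independent, and monotone in the
configuration: widening the fold-change window or raising the p threshold
can only add calls.

## Degree structure

Both layers show heavy-tailed gene-side degrees. `reverse_cumulative()`
computes the empirical CCDF `P(K ≥ k)` (linear on log-log axes under a power
law); `fit_power_law()` fits the discrete power law

`P(X = x) = x^(-alpha) / zeta(alpha, xmin)`

by maximum likelihood, with the Hurwitz zeta evaluated by direct summation
plus an Euler–Maclaurin tail (accurate to ~1e-12 for 1 < alpha ≤ 8, verified
against `zeta(2) = pi^2/6`). With `xmin = "auto"` the cutoff minimises the
Kolmogorov–Smirnov distance between the empirical tail and the fitted model,
the field-standard recipe; candidate cutoffs are capped at 50
quantile-spread values for large samples. Parameter recovery is part of the
acceptance suite: the median absolute error of `alpha` over 20 seeds at
n = 5,000 stays below 0.1 for alpha in {1.8, 2.5, 3.2}. "Representativeness"
of the dual gene set for a full layer is operationalised as the two-sample
KS distance (`compare_distributions()`), reported rather than thresholded —
there is no canonical pass/fail cutoff. Alternative heavy-tail models
(lognormal, stretched exponential) and likelihood-ratio comparisons are out
of scope.

## m-core peeling

The m-core of a layer is obtained by iteratively deleting gene nodes whose
layer degree is below `m` and drug nodes left with no edges, to a fixed
point; all connected components of the residual are kept (maximality holds
per component), with `largest_only = TRUE` as an alternative mode.

Two readings of the constraint coexist in the source description: "at least
m" in the formal definition and "greater than m" in the prose. We implement
**≥ m** (the formal definition) and expose `strict = TRUE` for the other
reading.

One structural fact deserves honesty: with the degree constraint on **gene
nodes only** (KDTN/KDSN are gene-side degrees), removing a gene can never
reduce another gene's degree — a gene's neighbours are drugs, and a drug
adjacent to a surviving gene is never deleted. The fixed point is therefore
reached in a single pass and a gene's core number equals its layer degree.
That makes a reported m-max smaller than the maximum degree impossible under
this reading; the original analysis most plausibly constrained drug nodes as
well (the classical bipartite k-core), which we expose as
`constrain = "all"` for sensitivity analysis. The implementation keeps the
general iterative algorithm (it is what the classical mode needs anyway),
and the tests verify it against randomized single-deletion peeling and an
exhaustive union-of-satisfying-subsets oracle on small graphs, plus igraph's
`coreness()` in the classical mode.

## Enrichment and TF statistics

`hypergeometric_ora()` is a one-sided upper-tail hypergeometric
over-representation test per term with BH FDR across the tested terms of one
library; libraries are tested independently, and the default universe is the
set of scored genes in the network (the original tool's background choice is
unknowable, so it is configurable). p-values are enumeration-exact: the
suite checks them against exhaustive enumeration of all draws on universes
up to 25 genes at 1e-12. `term_overlap()` does the cross-set accounting
(how many significant terms are shared between DTG/DSG/DTSG), and
`tf_binding_frequency()` computes the mean number of TF sets containing each
gene of a set plus the distinct TFs touching it.

A structural limitation worth knowing: over-representation against a query
set covering most of the universe (a DSG-like set of 8,770 genes out of
9,490) has essentially no power — the smallest attainable p for a 60-gene
term is about 0.009 before FDR correction, so such sets rarely yield
significant terms no matter how strongly a term is planted. The planted-term
power checks therefore use DTG/DTSG-scale sets.

## The synthetic world

`synthetic_spec()` defaults to the landscape the source data describes:
382 drugs, a 9,490-gene universe, 720 target genes and 9,233 sensitive genes
of which 463 are both. Degree exponents are not reported anywhere, so they
were fixed once from the printed degree maxima under the heavy-tail
order-statistic relation `max ≈ n^(1/(alpha-1))`: `alpha_target = 2.3`
(186 ≈ 720^(1/1.3)) and `alpha_sensitive = 3.0` (104 ≈ 9233^(1/2.0)).
Gene-side degrees are drawn from the zeta law truncated at the number of
drugs and each gene is wired to a uniformly sampled set of distinct drugs —
a simple-graph realization of the planted gene-side degree sequence that
needs no rewiring. The number of null expression records per drug (200) is
not stated in any source and was chosen once as a realistic profile size.

Reciprocity between layers ("target hubs are rarely sensitive hubs") is
planted by rank-reversal coupling: on shared genes the sensitive degrees are
assigned in inverse order of the target degrees, blended with a uniform
permutation as `anti_correlation` moves from -1 to 0. Note a ceiling imposed
by ties: at the stated-world exponents most degrees equal 1, and midrank
ties bound the achievable Spearman correlation far above -1 (about -0.3 at
the defaults) regardless of the coupling; the coupling test therefore uses
milder tails (alpha = 1.5, 500 drugs) where ties are rare and the planted
rho ≈ -0.94 is visible.

Clean mode gives planted pairs fold changes in (2.2, 8) or (0.1, 0.45) and
adjusted p in (0, 0.04), and null pairs FC in (0.6, 1.8) — planted calls are
recovered *exactly*, which is what the logic tests assert. Noisy mode
narrows the planted margins and lets null FC reach (0.3, 4), so false calls
occur at the rate set by the p threshold; the statistical tests bound the
false-call rate by the nominal threshold within two standard errors over 100
seeds. What a green synthetic test does **not** establish: robustness to
correlated transcriptome noise, cell-line batch structure, or multi-line
signature unification — none of which the generator emulates.

Determinism is a contract: the same spec and seed produce byte-identical
files (`write_landscape()`), and the full pipeline run
(`run_landscape()`) with a fixed config and seed reproduces identical
summaries and artifacts.

## Numerical and design choices

* Gene/drug identifiers are opaque strings, trimmed and uppercased; no
  online ID resolution (deterministic matching offline).
* Duplicate (drug, gene) rows: silently deduplicated in binary target
  tables, a hard error in signature tables (ambiguous statistics).
* Drug-subnetwork sampling rounds half-up with a floor of one drug and
  returns the subgraph induced on the sampled drugs (genes keep only edges
  to sampled drugs).
* The original visualisation subnetwork is internally inconsistent in its
  source (16 vs 19 drugs, 371 vs 382 dual-set drugs); sampling is therefore
  parameterized (`sample_fraction`, seeded) and no attempt is made to
  reproduce a specific figure.
* The pipeline config schema is strict — unknown keys are errors and all
  violations are reported at once — because silent typos are the dominant
  failure mode of file-driven pipelines.
* The three-dimensional degree-reciprocity view has no defined z-axis in the
  source; `analysis/03` substitutes a joint KDTN × KDSN density table and
  2-D bin plot.

## A minimal run

```{r example, eval = FALSE}
spec <- synthetic_spec(n_drugs = 40, n_genes = 500, n_target_genes = 80,
                       n_sensitive_genes = 300, overlap_fraction = 0.5,
                       null_genes_per_drug = 50, seed = 7)
paths <- write_landscape(generate_landscape(spec), "landscape_data")
summary <- run_landscape(list(target_table = paths[["target"]],
                              signature_table = paths[["signature"]],
                              out_dir = "landscape_run",
                              mcore = list(min_genes = 10)))
summary$partition
```
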