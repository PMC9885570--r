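# druglandscape

Genome-wide landscape analysis of the relationship between **drug-target
genes** (proteins a compound physically binds) and **drug-sensitive /
signature genes** (genes whose expression changes under treatment), built
for systems-biology and drug-repositioning researchers who want the whole
analysis reproducible offline from two input tables.

## The model

Both relationships live in one bipartite multigraph of drug and gene nodes:
a `target` edge per binding pair and a `sensitive` edge per significant
expression response. The sensitive indicator for drug *i* and gene *j* is

```
s_ij = 1  iff  adjusted p < 0.05  and  (FC > 2 or FC < 0.5)      (strict)
```

and each gene is scored by its two layer degrees

```
KDTN(j) = Σ_i t_ij     (distinct drugs binding gene j)
KDSN(j) = Σ_i s_ij     (distinct drugs perturbing gene j)
```

Genes partition into **DTG** (KDTN ≥ 1, KDSN = 0), **DSG** (KDSN ≥ 1,
KDTN = 0) and **DTSG** (both). Downstream analyses: reverse-cumulative
degree distributions with discrete power-law maximum-likelihood fits
(KS-minimising `xmin`), two-sample KS representativeness checks, m-core
peeling of each layer (degree constraint on gene nodes; classical k-core as
an option), hypergeometric over-representation with BH FDR against GMT
libraries, cross-set term-overlap accounting, and TF binding-frequency
summaries. A synthetic-data module plants all of this structure so the whole
pipeline is testable without external databases.

## Worked example

```r
library(druglandscape)

spec <- synthetic_spec(n_drugs = 40, n_genes = 500, n_target_genes = 80,
                       n_sensitive_genes = 300, overlap_fraction = 0.5,
                       null_genes_per_drug = 50, seed = 7)
paths <- write_landscape(generate_landscape(spec), "landscape_data")
summary <- run_landscape(list(target_table = paths[["target"]],
                              signature_table = paths[["signature"]],
                              out_dir = "landscape_run",
                              mcore = list(min_genes = 10)))
```

prints

```
[stage load] start
  target table: 145 pairs / 39 drugs / 80 genes
[stage load] start
[stage signature_calling] start
  402 of 2402 records called sensitive
[stage netbuild] start
[stage degree_stats] start
[stage mcore] start
  enrichment: no annotation libraries supplied, skipped
  tf_analysis: no TF library supplied, skipped
run complete: 40 drugs, 340 genes, partition 40/260/40
```

Reading: of the 2,402 simulated expression records, 402 pass the
adjusted-p/fold-change gate and become sensitive edges; the merged network
has 40 drugs and 340 genes, of which 40 are target-only (DTG), 260
sensitive-only (DSG) and 40 both (DTSG) — exactly the planted partition
(80 target genes, half of them also sensitive). `landscape_run/` then holds
the per-gene score table (`gene_scores.tsv`), the partition GMT, GraphML
networks, CCDF tables and power-law fit summaries, per-layer m-core profiles
and core GMTs, and a machine-readable `run_summary.json` whose counts are
audited against the artifacts in the test suite.

The numbered drivers under `analysis/` run the same stages at the full
stated-world scale (382 drugs, 9,490 genes) and write their tables under
`results/`: `01_simulate.R` → `02_network.R` → `03_distributions.R` →
`04_mcore.R` → `05_enrichment.R`.

## Acceptance script

`scripts/acceptance.R` regenerates the stated-world synthetic landscape from
scratch, runs the complete pipeline on it (signature calling → network
construction → scoring → partition → degree fits → m-core peeling), verifies
the recovered partition against the planted truth, and writes its JSON
output to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
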