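# gemreporter

Expression-driven analysis of genome-scale metabolic models (GEMs) in R:
from a reference metabolic network and cohort transcriptomics to reporter
metabolites, a reporter-enriched subnetwork, topological hub ranking, and
metabolomics validation.

## Who this is for

Systems-biology and disease-omics groups who have (i) a compartmentalized
reference metabolic model, (ii) gene-expression matrices for one or more
cohorts plus a differential-expression table for a two-group contrast
(e.g. hemorrhaged IPH+ vs non-hemorrhaged IPH− atherosclerotic plaque),
and optionally (iii) a metabolomics panel with pooled-QC samples — and who
want to know *which metabolites and pathways* the expression changes point
at, not just which genes moved.

## The statistics at the core

**Reporter metabolites.** For each gene, $Z_g = \Phi^{-1}(1-p_g)$ from the
(optionally direction-transformed) differential-expression p-value. Each
metabolite aggregates its $k$ neighboring enzyme genes — the genes in the
rules of the reactions it participates in — as

$$Z_\text{raw} = \frac{1}{\sqrt{k}}\sum_g Z_g,\qquad
Z_\text{corr} = \frac{Z_\text{raw}-\mu_k}{\sigma_k},\qquad
p_\text{reporter} = 1-\Phi(Z_\text{corr}),$$

with $\mu_k,\sigma_k$ estimated by Monte Carlo from random size-$k$ gene
sets drawn from the model's scored genes (background correction).

**Context-specific extraction.** Binary selection $y_r$ per reaction
maximizing $\sum_r w_r y_r$ (weights from HIGH/MEDIUM/LOW/ABSENT expression
tiers evaluated through the gene rules, OR→max / AND→min) subject to every
metabolic task staying feasible, solved exactly by branch-and-bound; the
result is pruned to flux consistency ($|v_r| \ge \varepsilon$ under
$Sv = 0$).

**Subnetwork and hubs.** On the currency-free bipartite metabolite–reaction
graph, simulated annealing maximizes $S(A) = \sum_{i\in A} s_i/\sqrt{|A|}$;
the major component is ranked by degree, closeness (Wasserman–Faust) and
betweenness, and the top-5 metabolites per criterion are the hub report.

**Metabolomics arm.** QC filters (>20% missing, QC-RSD >50%), batch
correction by QC-median synchronization, Shapiro–Wilk-gated t/Wilcoxon
tests with BH adjustment (calls at adjusted p < 0.1), and a 100,000-run
permutation test for metabolite-category enrichment.

## Worked example

The synthetic scenario plants a hub metabolite (`glutamate[c]`, wired
through glutamine synthesis/hydrolysis and the mitochondrial carrier) whose
adjacent enzyme genes are up-regulated by 2 noise SDs in the case group:

```r
library(gemreporter)
cfg <- pipeline_config(out_dir = "demo_out", seed = 1)
res <- run_pipeline(cfg)
```

The log prints each stage as it lands:

```
model: simulated (95 reactions, seed 1)
classify: ABSENT=52 HIGH=90 MEDIUM=102
extract: kept 81/95 reactions (objective 185.000)
reporter[all]: 65 metabolites, 22 significant at 0.1
reporter[up]: 65 metabolites, 22 significant at 0.1
reporter[down]: 65 metabolites, 4 significant at 0.1
subnetwork: 17 nodes (score 12.379), major component 24 nodes
topology: 16 hub metabolite(s): glutamate[c], glutamate[m], aspartate[c], aspartate[m], glutamine[c]
metabolomics: 109 tested, 17 up / 2 down calls
```

Reading this: the extraction kept 81 of 95 reference reactions (total
expression weight 185); 22 metabolites were significantly associated with
up-regulated genes at p < 0.1; the annealing selected 17 scoring nodes
which, with their bridging reactions, form a 24-node major subnetwork; the
hub report is the union of the top-5 metabolites per centrality criterion
(ties included), led by the glutamate/glutamine module:

```r
head(res$hub_report, 3)
#     metabolite compartment test_type   p_reporter rank_degree rank_closeness rank_betweenness
# 1 glutamate[c]           c       All 4.563017e-14           1              1                1
# 2 glutamate[m]           m       All 5.652352e-07           2              2                2
# 3 aspartate[c]           c       All 6.972154e-05           5              3                5
```

The planted hub is recovered: it is the top-ranked metabolite by degree,
closeness and betweenness, and its up-mode reporter p-value is far below
the 0.1 cutoff. On the metabolomics side, the planted sphingolipid
enrichment is found by the permutation test
(`res$metabolomics$category_tests`: 17 of 23 sphingolipids called up,
permutation p ≈ 1e-5), and the hub metabolite itself is called down,
matching the planted abundance shift.

Every stage also writes TSV/JSON outputs plus `pipeline.log` and the
resolved config into `out_dir`; re-running the same config reproduces them
byte for byte.

A thin command-line wrapper with the same stages lives at
`inst/scripts/gemreporter.R`
(`Rscript gemreporter.R run-all --seed 1 --out demo_out`).

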