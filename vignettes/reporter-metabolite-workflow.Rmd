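---
title: "Reporter metabolites and context-specific metabolic networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reporter metabolites and context-specific metabolic networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemreporter)
```

# The problem

Bulk tissue omics of diseased versus healthy samples (the motivating case is
hemorrhaged, IPH+, versus non-hemorrhaged, IPH−, atherosclerotic plaque)
usually yields a differential-expression table and, if one is lucky, a
metabolomics panel. Neither directly answers the question "*which parts of
metabolism* changed?". A genome-scale metabolic model (GEM) — the catalog of
all reactions a tissue can run, with compartmentalized metabolites and
gene–reaction rules — supplies the missing topology: genes map to reactions,
reactions touch metabolites, and differential expression can be aggregated
along that structure.

`gemreporter` implements that chain end to end:

1. classify genes into expression tiers from cohort matrices,
2. extract a context-specific sub-model from a reference GEM
   (task-constrained selection, tINIT-style),
3. score **reporter metabolites** — metabolites whose neighboring enzyme
   genes are collectively differentially expressed,
4. search for a reporter-enriched subnetwork by simulated annealing,
5. rank hub metabolites by degree, closeness and betweenness centrality,
6. validate against a metabolomics panel (QC filtering, batch correction,
   differential abundance, category permutation tests).

A synthetic-data module generates a toy GEM with a planted hub metabolite and
matching expression/metabolomics data, so the entire pipeline is testable
without any external download.

# Models and procedures

## Expression tiers

Let $X$ be a genes × samples log-scale matrix. $Q_1$ and $Q_3$ are the 25%
and 75% quantiles (type-7 estimator) of the **pooled** distribution of all
gene × sample values — not per-gene quantiles, since the intent is to place
genes on the array-wide intensity scale. A gene is

* **ABSENT** if its value is strictly below $Q_1$ in strictly more than
  `absent_sample_frac` (default 0.80) of its samples;
* otherwise **HIGH** if its maximum exceeds $Q_3$, **MEDIUM** if the maximum
  lies in $(Q_1, Q_3]$, **LOW** if it is $\le Q_1$.

Two cohorts are never averaged (no cross-platform harmonization is
attempted); each is classified separately and a gene gets its best tier
(HIGH > MEDIUM > LOW > ABSENT). External evidence — strongly differential
genes below `p_adj_force` and detected proteins — forces genes to HIGH. Both
0.001 and 0.01 are defensible forcing thresholds for "strongly differential";
the default is 0.001 and the value is plain configuration, since the two
conventions appear side by side in practice.

Tier scores (default HIGH +5, MEDIUM +1, LOW −2, ABSENT −8) turn a gene rule
into a reaction weight with OR → max (isozymes) and AND → min (complex
subunits). The magnitudes were chosen once so that a single HIGH gene cannot
outweigh two ABSENT partners in a sum; they are configuration, not science.

## Context-specific extraction

Given reaction weights $w_r$ and a set of metabolic tasks (each demanding
net production of stated metabolites at a minimum rate, with stated free
uptakes), the extraction solves

$$\max_{y \in \{0,1\}^n} \sum_r w_r y_r \quad \text{s.t. for each task } t:
\exists v^t: S_{\text{aug}} v^t = 0,\; \text{lb} \le v^t \le \text{ub},\;
|v^t_r| \le M y_r,$$

one flux vector per task inside a single program, so the selected set
satisfies all tasks jointly. $M = 1000$ matches the default bounds. The
binary program is solved exactly by branch-and-bound on the LP relaxation
(most-fractional branching, the feasible full model as the incumbent). The
LP core is a dense two-phase tableau simplex with Dantzig pricing and a
switch to Bland's rule after 2000 pivots, which guarantees termination on
the highly degenerate all-zero right-hand sides that flux balance produces.
Equal-objective optima are disambiguated toward the lexicographically
smallest kept-id set by an id-indexed perturbation of at most $10^{-6}$,
reported in the result, so results are reproducible across platforms.

After selection, kept reactions that cannot carry $|v| \ge \varepsilon$
(default $10^{-4}$) at steady state are pruned in ascending (weight, id)
order; a removal that breaks a task is reverted and the reaction locked in.
Flux-consistency testing maximizes each reaction's own flux, certifying
en passant every reaction active in the returned vertex (a FastCC-style
shortcut that changes nothing about the answer).

Exchange reactions carry empty gene rules and hence weight 0; in the
pipeline they receive a small positive weight (`exchange_weight`, default 1)
so the extracted model keeps its boundaries instead of losing them to the
tie-break perturbation.

## Reporter metabolites

For gene $g$ with (mode-transformed) p-value $p_g$, $Z_g = \Phi^{-1}(1 -
p_g)$. A metabolite with $k$ neighbor genes (the flattened union over the
rules of its reactions; AND/OR structure is deliberately ignored, the
standard convention for this statistic) scores

$$Z_{\text{raw}} = \frac{1}{\sqrt{k}} \sum_{g} Z_g, \qquad
Z_{\text{corr}} = \frac{Z_{\text{raw}} - \mu_k}{\sigma_k}, \qquad
p = 1 - \Phi(Z_{\text{corr}}),$$

where $\mu_k, \sigma_k$ are estimated from `n_background` (default 10000)
random draws of $k$ genes **from the observed gene-score population of the
model**, not from a theoretical normal — this is what makes the statistic
robust to non-uniform p distributions. Directional modes transform two-sided
p-values one-sidedly (up: $p/2$ if the fold change is positive, else
$1-p/2$; down mirrored; zero fold changes get 0.5); a restrict-to-significant
alternative is available, and neither convention is claimed to be uniquely
correct. P-values are clipped to $[10^{-15}, 1-10^{-15}]$ to keep Z finite.
If every gene score is identical, $\sigma_k$ is floored at $10^{-12}$ and
flagged. Significance uses raw $p < 0.1$ with no multiplicity correction —
the statistic is a ranking device, and this mirrors established use.

## Subnetwork search

The bipartite graph joins metabolites and reactions sharing a nonzero
coefficient, after removing 20 currency metabolites (H2O, CO2, O2, H+,
HCO3−, Na+, CoA, Pi, PPi, AMP, ADP, ATP, NAD+, NADH, NADP+, NADPH, PAP,
PAPS, FAD, FADH2) by name in **all** compartments — these cofactors connect
unrelated pathways and would dominate every topological measure. Metabolite
nodes score $\Phi^{-1}(1-p_{\text{reporter}})$ (0 without a record);
reaction nodes get a flat penalty (default −0.1).

Simulated annealing over inclusion vectors maximizes the Ideker-style
aggregate $S(A) = \sum_{i \in A} s_i / \sqrt{|A|}$: toggle one uniformly
chosen node per move, accept uphill always and downhill with probability
$e^{\Delta S/T}$ under geometric cooling (defaults: 20000 iterations,
$T_0 = 1$, rate 0.9995). The chain starts from the single best node, so the
returned best-seen score can never fall below the best single-node score.
Connectivity is *reported*, not enforced: the best state is decomposed into
connected components afterwards.

One consequence of this exact score deserves honesty: adding a
negative-score node always lowers $S$, so the raw optimum contains
metabolites only — and metabolites are pairwise non-adjacent in a bipartite
graph. The reported decomposition therefore also includes *bridge* reaction
nodes adjacent to at least two selected metabolites (`bridge = TRUE`,
exposed as an argument). The annealing state and score are untouched by
this; only the reported component structure gains the connecting reactions,
which is what lets a "major subnetwork plus small satellites" emerge and
gives the centrality stage a connected substrate.

## Topology

On the major component: degree is the incident edge count; closeness uses
the Wasserman–Faust component-size correction
$\frac{r}{n-1}\cdot\frac{r}{\sum d}$ over the $r$ reachable nodes (defined
even on near-disconnected search output; isolated nodes score 0);
betweenness is the raw count of shortest paths through a node, endpoints
excluded, all node pairs of both types. Ranks are competition ("min") ranks
within node type — ranks, not raw values, are what the hub report uses, and
they are invariant to normalization choices. Hubs are the union of the
top-k (default 5) metabolites under each criterion, annotated with their
best reporter record. Centrality is computed on the bipartite graph by
default (a metabolite projection is provided as an option).

## Metabolomics validation

Metabolites missing in more than 20% of samples, or with a relative
standard deviation above 50% across the pooled-QC injections, are excluded
(RSD on QC samples: the QC pool is the repeatability reference; the choice
of sample set for the missingness rule is all samples). Batch correction
multiplies each metabolite's values per batch by global-QC-median /
batch-QC-median — a multiplicative model, because peak-area ratios are
scale-type data — which exactly equalizes per-batch QC medians and is
idempotent; a zero batch median flags the metabolite and leaves it alone.

Differential abundance per metabolite: Shapiro–Wilk at 0.05 in each group;
both normal → Student's t-test (equal variances); otherwise a two-tailed
Wilcoxon rank-sum (exact for small tie-free samples). BH adjustment across
tested metabolites; calls `up`/`down` at adjusted $p < 0.1$ by the sign of
the case-minus-control median difference. Missing values are excluded
pairwise; no imputation is attempted.

Category enrichment: the statistic is the count of direction-matching calls
in a category; the null permutes the call vector over all metabolites with
membership fixed (equivalent under exchangeability to resampling category
labels); $p = (1 + \#\{\text{perm} \ge \text{obs}\})/(1 + n_{\text{perm}})$
with $n_{\text{perm}} = 100000$ by default — the +1 correction never
reports a zero p at finite permutation count. Both tails are reported.

# The synthetic scenario

The generator emulates the study design the pipeline targets, and its
defaults are fixed once:

* a toy GEM over cytosol, mitochondria and the extracellular space with the
  glutamate/glutamine reaction triplet (glutamine synthesis from glutamate,
  hydrolysis back, and the aspartate/glutamate carrier bridging cytosol and
  mitochondria, genes GLUL, GLS, SLC25A12/13), currency metabolites, ten
  background linear pathways (3–6 steps, 1–3 isozymes per step) fed and
  drained through exchanges, and the hub `glutamate[c]` wired to 8 incident
  reactions — well above twice the background median metabolite degree;
* two cohorts on the log2 scale: 16 control + 27 case primary samples and a
  126-sample support cohort; gene baselines spread over (2, 12) so all
  tiers are populated; noise SD σ = 0.5; hub-adjacent genes shifted by
  δ = 1 = 2σ in the case group; the DEG table comes from per-gene t-tests
  with BH (a generator-internal convenience — a real microarray study would
  use a dedicated pipeline, which is out of scope here);
* metabolomics: 109 metabolites (model metabolites plus synthetic lipid,
  sugar and amino acid panels), three batches with log-normal batch
  factors, 35 primary samples (9 control, 26 case) and 11 pooled-QC
  injections, 5% missingness completely at random; planted shifts: the hub
  metabolite down 1/1.8, and 70% of the sphingolipid category up 1.8-fold,
  so exactly one category is enriched by construction.

What the generator does **not** emulate: probe-level microarray noise,
isotope/derivatization chemistry, batch-by-group confounding, missingness
that depends on abundance. Passing tests therefore demonstrate that the
algorithms recover structure they are designed to see under clean
assumptions — not that any real cohort would behave as nicely.

All generators are deterministic given the scenario seed; every derived
artifact records it.

# Numerical choices and degenerate inputs

* LP/MILP: dense two-phase simplex, tolerance $10^{-9}$; branch-and-bound
  integrality tolerance $10^{-6}$, node cap $10^5$; big-M 1000; flux
  threshold $\varepsilon = 10^{-4}$ (conventional constraint-based scales).
* Degenerate quartiles (constant expression matrix) are an explicit error;
  a single-sample matrix is allowed.
* Reporter: $\sigma_k$ floor $10^{-12}$ with a flag; p clipping $10^{-15}$;
  neighbor sets larger than the scored universe are an error.
* Annealing: the empty set scores $-\infty$ and is never accepted; ties in
  $\Delta S = 0$ accept.
* Ties in ranks: competition ranking; ties in extraction: the id-indexed
  perturbation above.
* Wilcoxon: exact for small tie-free samples, normal approximation with tie
  correction otherwise (R's standard switch); zero-variance-equal groups
  give p = 1.

# Problem sizes used by the test suite

The suite validates against oracles at sizes where the oracles are exact
and fast: centralities on 200 random graphs of up to 30 nodes against a
Floyd–Warshall path-counting brute force; extraction on 25 random networks
with 6–8 optional reactions against subset enumeration (steady-state
feasibility on those unit-conversion networks reduces to digraph
reachability, an LP-free oracle); annealing on 7-node paths against the
exhaustive optimum over all 127 subsets; the Monte Carlo background against
exhaustive enumeration on a 12-gene universe; permutation p-values against
the hypergeometric tail at $n_{\text{perm}} = 10^5$; and 20 end-to-end
pipeline runs for planted-hub recovery. Reference-scale inputs (a
5000-reaction human GEM, real cohorts) are intentionally out of reach of
the synthetic scenario; the package treats the reference model as an input
file.

# Known limitations

* The subnetwork score does not enforce connectivity; the bridge-node
  decomposition (above) is a reporting device, not an optimality claim.
* The MILP is exact but a desk-scale solver; thousands of binary variables
  would need a commercial solver behind the same interface.
* Reporter p-values are one-sided by construction; "down" evidence appears
  in the down mode, not as small p in the up mode.
* The metabolomics arm models no imputation and no drift within batches
  (QC-median synchronization is a step-function correction).
* SBML support is a minimal Level-3 dialect (species, reactions,
  reversibility, bounds and gene rules as custom attributes), sufficient
  for round-tripping this package's models, not a general SBML consumer.
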