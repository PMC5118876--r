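---
title: "Discovering conserved tumor immune gene signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering conserved tumor immune gene signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunesig)
```

## The problem

Solid tumors are infiltrated by immune cells whose transcripts are measured
together with those of the malignant cells in bulk expression profiling.
Because infiltrate composition varies between patients while the relative
expression of a cell type's markers does not, genes expressed by the same
immune population form tight co-expression modules whose internal correlation
structure recurs across tumor types. `immunesig` exploits this: it looks for
gene clusters whose membership is stable under resampling within each of
several independent tumor datasets, keeps those enriched for immunity-related
annotation, asks which cluster memberships are *conserved* across all
datasets and across two unrelated clustering algorithms, and qualifies the
survivors as immune gene signatures. Signatures are then interpreted against
a sorted-leukocyte reference panel, collapsed to per-sample metagene scores,
and tested for association with patient survival.

The pipeline is deliberately conservative: a gene only enters a signature if
it co-clusters with the same companions in every dataset under both
algorithms, so the output is small, disjoint, and reproducible.

## Stage by stage

### Probe collapsing

Array platforms measure most genes with several probe sets. Before pattern
extraction, probes annotated with the same gene symbol are averaged — but
only when they agree with each other: within a gene we build the graph whose
edges connect probes with Pearson \(r > 0.4\) (computed across all samples of
the dataset at hand) and merge maximal cliques of that graph, largest clique
first, ties broken lexicographically. The clique rule guarantees that *every*
averaged pair individually satisfies the correlation gate; probes that fail
the gate, lack a symbol, or have zero variance pass through untouched.
Collapsing is per-dataset — probe behavior is platform- and cohort-specific
— and later stages map collapsed identifiers back to original probe ids
before taking cross-dataset unions. An alternative rule (gating each probe on
its mean correlation to a template) would admit pairs below the printed gate,
which is why we did not adopt it.

### Resampling-stable pattern extraction

Per dataset, a reference clustering is produced by the pattern extractor:
average-linkage hierarchical clustering on the distance \(1 - r\), tree cut
at height \(1 - \texttt{corr\_cut}\), clusters below `min_cluster_size`
discarded. The extractor is a pluggable stand-in for any co-expression
pattern finder with this signature; the scientific weight is carried by the
stability protocol around it. That protocol draws 50% of samples without
replacement, re-runs the extractor, matches each resampled cluster to the
reference cluster of maximal Jaccard overlap (ties to the smaller reference
id), and counts, for every gene, how often it lands in each reference
cluster. The canonical setting is 1000 iterations with genes retained at a
count of 750 or more — the boundary is inclusive. Retained clusters are then
tested against immunity-flagged annotation terms with the hypergeometric
test, and clusters with a minimum immune-term \(p < 0.001\) are flagged; the
union of flagged cluster members across datasets is the candidate universe
for everything downstream.

Matching to a *fixed* full-data reference makes the counts well defined;
matching iterations to each other would leave cluster identity floating.
Iteration \(i\) uses a sub-seed derived from `(seed, i)`, so the whole
stream is reproducible and individual iterations are re-runnable.

### Consensus clustering

Within each dataset, the candidate features are consensus-clustered twice —
once with k-means, once with a self-organizing map — following the
subsampling scheme of Monti et al.: for each candidate \(k\), 80% of
features are drawn without replacement 500 times, each draw is clustered,
and the consensus matrix records, for every feature pair, the fraction of
co-sampled draws in which the pair co-clustered (pairs never drawn together
get consensus 0 with a recorded co-sample count of 0; the diagonal is 1).
The consensus partition cuts the average-linkage tree of
\(1 - \text{consensus}\) into \(k\) groups. Cluster consensus is the mean
consensus over within-cluster pairs (1 for singletons, by convention), item
consensus the mean consensus of an item with a cluster's other members.

Feature profiles are z-scored before clustering so that distances reflect
co-expression shape rather than absolute intensity; whether to standardize
is a genuinely open choice and ours is recorded here. The k-means base
clusterer uses k-means++ seeding with 10 restarts; the SOM is a 1×\(k\) line
of nodes trained online with a Gaussian neighborhood decaying over epochs —
a line with exactly \(k\) nodes makes the SOM a partitioner comparable to
k-means, which is how it is used here; larger grids are out of scope. Empty
nodes are re-seeded at the item farthest from its matched node.

The number of clusters is chosen by the consensus-CDF area criterion: with
\(A(k) = \int_0^1 \mathrm{CDF}_k(t)\,dt = 1 - \overline{\text{consensus}}\)
over the upper triangle, the selected \(k\) maximizes the relative increase
\(\Delta(k)\), restricted to candidates whose mean cluster consensus reaches
0.8, ties to the smaller \(k\). No published decision rule accompanies the
consensus methodology beyond inspection, so the rule is applied
mechanically, all summary statistics are surfaced
(`tidy()`, `plot_consensus_summary()`), and `select_k()`'s choice can be
overridden per dataset. Agreement between the two algorithms' partitions is
quantified by the Hubert–Arabie adjusted Rand index.

### Meta-intersection

For one algorithm, with chosen partitions \(B_i, C_j, L_k, O_l, P_m\) over
the five datasets, every element of the Cartesian product
\(B_i \cap C_j \cap L_k \cap O_l \cap P_m\) is computed — the record count
equals \(\prod_d k_d\) exactly (e.g. 6,300 for per-dataset counts
5,5,6,6,7 and 4,704 for 4,4,6,7,7), with empty intersections counted but not
listed. Records with at least ten members survive; the two algorithms'
surviving records are then crossed pairwise, member intersections of at
least ten genes are kept, and identical member sets are de-duplicated. When
the inputs are true partitions the resulting meta-intersections are provably
pairwise disjoint, and the implementation asserts this on every run.
Features a dataset never clustered belong to no cluster there and hence to
no intersection — the conservative reading of the set notation. We
intersect all record pairs rather than matching records one-to-one first;
with true partitions the two constructions coincide after de-duplication.

### Qualification

A meta-intersection becomes a signature if (i) at least half its members
carry at least one annotation term, (ii) it spans at least ten unique gene
symbols, and (iii) Benjamini–Hochberg adjustment of its hypergeometric term
p-values (within the candidate's own term family) leaves an immunity-flagged
term with \(q < 0.05\). The enrichment universe is the candidate universe
the features were drawn from, not the whole array — candidates can only
contain genes from that universe, so a whole-array universe would inflate
enrichment. The annotation-criterion phrase "symbols and titles" is
operationalized as symbols only; a title adds no identification beyond its
symbol. The BH-over-hypergeometric test is a generic replacement for the
DAVID service (whose EASE-adjusted FDR differs slightly); the criteria
themselves are unchanged.

### Cell-type enrichment scores

The reference panel holds sorted leukocyte expression profiles in 18 groups
(114 arrays; see `default_group_sizes()`). For each feature a one-way
group-means model is fitted; for each ordered group pair the contrast
coefficient is the group-mean difference, tested with the pooled residual
variance shared across all contrasts of that feature. The score of feature
\(f\) in group \(g\) sums the coefficients of the significant contrasts:

\[ s_{fg} = \sum_{h \neq g} (\bar x_{fg} - \bar x_{fh}) \,
   \mathbf{1}\!\left[ p_{gh} \le \alpha / \binom{G}{2} \right], \qquad
   \alpha = 0.05 . \]

The Bonferroni family is the 153 unordered pairs within a feature — the
narrowest family consistent with correcting "each pair"; the choice is a
parameter. The pooled-variance model replaces a moderated-variance
(empirical-Bayes) fit, for which no hyperparameters are available; with
\(\ge 3\) replicates per group and 96 residual degrees of freedom the two
are close, and the model is pluggable. Signature profiles are the mean
member scores per group, with a row-standardized copy for display.

### Metagenes and survival

A signature collapses to a per-sample metagene in two steps: probes sharing
a gene symbol are averaged first (so no gene is over-represented), then the
per-gene values and the symbol-less probe values are averaged. Metagene
correlation structure is displayed as an average-linkage dendrogram on
\(1 - r\). Each metagene is tested as a single continuous covariate in a Cox
proportional-hazards model with Efron's approximation for ties (via the
`survival` package); hazard ratios are per unit metagene with Wald 95%
intervals, and ratios above 1 are flagged as inverse ("poor outcome")
associations. The covariate is used raw by default, matching the continuous-
covariate convention; `standardize = TRUE` rescales it for cross-dataset
comparability. Stratified analyses repeat the fit within levels of
categorical stratifiers and within sample-quantile tertiles of continuous
ones (ties to the lower bin — deterministic and order-invariant); strata
without events yield missing-estimate rows rather than errors, and p-values
are star-coded at 0.05/0.01/0.001.

## The synthetic-data module

`simulate_datasets()` plants the structure the analysis assumes: each module
is a single-factor model — gene \(g\) in module \(m\) of dataset \(d\) has
value \(\mu_g + a_g f_{md} + \varepsilon\) with an independent standard-
normal factor per (module, dataset), loadings uniform on \([0.5, 1.5]\)
(heterogeneous but uniformly positive, as in co-expressed immune modules),
and Gaussian noise. Conserved modules appear in every dataset with
*independent* factors — the correlation structure, not the values, is
conserved, mirroring what recurs across tumor types. Private modules are
active in one dataset only; background genes are pure noise; per-gene means
\(\mu_g \sim N(8, 1.5^2)\) put values on a log2-intensity scale. The
defaults (five datasets, 150 samples, three conserved 40-gene modules, two
private modules per dataset, 300 background genes, noise SD 0.6) are the
validation conditions used throughout the tests; noise SD 0.6 against
loadings near 1 gives within-module correlations around 0.5–0.7, typical of
strong co-expression modules.

`simulate_reference_panel()` reproduces the 18-group design with the panel's
published replicate counts (summing to 114 arrays) and elevates marker-gene
means by `effect` (default 3 log2 units) in their own group only.
`simulate_annotation()` gives each conserved module a matching
immunity-flagged term, adds random decoy terms, and assigns symbols to 90%
of genes so the qualification criteria are exercised rather than trivially
satisfied. `simulate_survival()` draws exponential event times with rate
\(\lambda_0 \exp(\sum_m \beta_m z_m)\) on standardized metagenes and
independent exponential censoring — the simplest mechanism satisfying the
non-informative censoring the Cox model assumes. The defaults
(\(\lambda_0 = 0.1\), censoring rate 0.05) give roughly two-thirds events.

What the generator does **not** emulate: probe-level effects and saturation,
batch effects, non-Gaussian marginals, overlapping modules, mixture
composition of bulk samples, and informative censoring. Passing the planted-
truth tests therefore demonstrates that the machinery is correct under the
model's own assumptions — not that real tumor cohorts will yield signatures
of comparable purity. On real data the analyst should expect partial
overlaps, algorithm disagreement (inspect the ARI), and manual review of
`select_k()`'s choice.

## Numerical and engineering choices

* **Determinism.** Every stochastic stage takes an explicit seed, and
  iteration-level sub-seeds are derived arithmetically from it, so identical
  configurations give byte-identical outputs; matrices are written with 17
  significant digits, which round-trips doubles exactly.
* **Degenerate inputs.** Zero-variance probes bypass correlation gating;
  constant features are excluded from pattern extraction and rejected by
  consensus standardization with a named error; zero residual variance in a
  panel contrast degenerates to \(p \in \{0, 1\}\) by whether the means
  differ; singleton consensus clusters score 1 by convention; strata without
  events report missing estimates.
* **Tie-breaks** are always deterministic: largest clique first then
  lexicographic; Jaccard matching to the smaller reference id; `select_k`
  to the smaller \(k\); tertiles to the lower bin.
* **Problem sizes.** The shipped validation configuration runs the stability
  filter at 100 iterations with retention 75 (the same 75% retention ratio
  as the canonical 750/1000) and consensus at 100 resamples with
  \(k \le 8\); at these sizes the whole pipeline, including simulation and
  survival analysis, completes in a few minutes on one core. The canonical
  1000/750 and 500-resample settings remain the documented defaults of the
  individual functions.

## Known limitations

* The pattern extractor is a correlation-tree stand-in; a different extractor
  can change which genes enter the candidate universe. Its `corr_cut`
  default (0.35) is calibrated against the synthetic model, not against any
  tumor cohort.
* The all-pairs meta-intersection can, in principle, emit nested (not just
  disjoint) sets if fed overlapping record lists; with true partitions this
  cannot occur, and the disjointness assertion guards it.
* Cell-type scores are marker-level summaries, not deconvolved proportions;
  signature-to-lineage naming is interpretation, not output.
* Only univariate (optionally stratified) Cox models are provided;
  multivariable adjustment and competing risks are out of scope.
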