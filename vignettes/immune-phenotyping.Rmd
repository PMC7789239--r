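---
title: "Immune microenvironment phenotyping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune microenvironment phenotyping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`timephen` discovers tumor immune microenvironment (TIME) phenotypes from
bulk expression data and carries them through the downstream analyses a
multi-omic subtyping study needs: single-sample enrichment scoring,
consensus clustering with data-driven choice of the number of clusters,
cross-cohort reproducibility testing, a prognostic index, a single-sample
classifier, and companion procedures on methylation, copy-number, mutation
and miRNA data. This vignette records the statistical model behind each
step, the tunable parameters and their defaults, and the design decisions
that were genuinely open.

## ssGSEA scoring

For a sample with expression vector $x$ over $N$ genes and a gene set $S$
($|S| = m$), genes are ordered by decreasing expression and the enrichment
score is

$$\mathrm{ES}(S) = \sum_{i=1}^{N} \left[ P^w_{\mathrm{in}}(i) -
P_{\mathrm{out}}(i) \right],$$

where $P^w_{\mathrm{in}}$ is the in-set empirical CDF weighted by
$\mathrm{rank}^\alpha$ (default $\alpha = 0.25$) and $P_{\mathrm{out}}$ the
unweighted out-of-set CDF. Only ranks enter, so the score is invariant under
any strictly increasing transform of $x$ — log scale, quantile
normalization, and platform-monotone distortions do not change it. Ties get
average ranks and keep stable input order; this matters on discretised data
and is therefore fixed, not incidental. Scores for a collection are
assembled per (set, sample) pair and, by default, divided by the global
range of the raw score matrix (`normalization = "global_range"`), which
preserves every ordering while putting scores on a common scale. Whether to
z-score expression per gene beforehand is left as a flag (`zscore`, default
off): scoring raw log2 data is the more common choice and the default here.

## Consensus phenotyping and PAC

`consensus_phenotypes()` subsamples 80% of samples 500 times, clusters each
subsample, and records for every sample pair the fraction of co-samplings in
which they co-clustered. For each $k$ the consensus matrix is summarised by
the proportion of ambiguous clustering, $\mathrm{PAC} = F(0.9) - F(0.1)$,
the CDF mass of consensus entries that are neither clearly together nor
clearly apart; the selected $k$ minimises PAC, ties going to the smaller
$k$. Final assignments come from average-linkage hierarchical clustering of
$1 - \mathrm{consensus}$, and clusters are named TIME-1, TIME-2, ... in
ascending order of mean enrichment score, so TIME-1 is always the least
infiltrated group.

Two defaults deserve justification because they deviate from the most common
convention in this literature:

* **Base distance.** Immune phenotypes are partly a *level* structure
  (low / intermediate / high infiltration). The correlation distance
  $1 - r$ is invariant to a uniform shift of a sample's score profile, so
  it is blind to exactly that structure; on data whose groups differ mainly
  in level it merges the extremes. The default distance is therefore
  Euclidean (`distance = "pearson"` remains available).
* **Base clusterer.** PAC discriminates between values of $k$ only if the
  base clusterer expresses instability at the wrong $k$. Average-linkage
  trees built on 80% subsamples of well-separated data are nearly
  deterministic at *every* $k$, which collapses PAC to 0 across a range of
  $k$ and lets the smallest-$k$ tie-break win regardless of the truth.
  k-means with random restarts (the default, `base_method = "kmeans"`)
  supplies the needed stochasticity: at the true $k$ restarts agree, at the
  wrong $k$ they land in different local optima, and the PAC curve develops
  the characteristic minimum.

## In-group proportion (IGP) validation

Validation samples are assigned to the nearest discovery centroid under
Pearson correlation; a cluster's IGP is the fraction of its validation
samples whose nearest validation neighbour ($1 - r$ distance) shares the
label. Significance uses a centroid-rotation null: random orthogonal
rotations of the centred centroids, re-assignment, and re-scoring. Two
properties of this null are worth knowing. First, in a low-dimensional
feature space (24 cell-type scores) a small fraction of rotations happens to
align with the real structure, so p-values of the order 0.005–0.02 are the
realistic floor. Second, once a cluster's observed IGP reaches 1 on strongly
clustered data the null saturates — rotated centroids still inherit whole
clusters coherently — and the p-value is uninformative. IGP point values
carry the evidence in that regime. A diagnostic mode
(`validation_labels = ...`) scores user-supplied labels directly with a
label-permutation null; shuffled labels on well-mixed data then give IGP
near 0.5.

## TIME index and survival

Phenotype-related genes are selected per phenotype with limma's moderated
one-vs-rest t-test at |log2 FC| > 1.5 and BH-adjusted p < 0.05, both strict,
and pooled across contrasts by union. The TIME index (TI) of a patient is
the global-range-normalized ssGSEA score of that signature; by construction
it increases with signature expression. An optional directional mode scores
up- and down-regulated subsets separately and takes the difference.
`optimal_cutoff()` scans every admissible split (at least 10% of samples on
each side by default) and returns the cutpoint with the maximal log-rank
chi-square. The reported p-value is not corrected for the cutoff search and
is anticonservative; it is a ranking device, consistent with common usage of
maximally selected statistics, not a calibrated test.

## Single-sample classifier

Centroids are arithmetic means of the training samples' feature vectors, by
default the 24 cell-type scores (a signature-gene expression mode exists for
targeted panels). A new sample is assigned to the centroid with the highest
Pearson correlation over shared features; the margin between the best and
second-best correlation is reported, calls with margin < 0.05 are flagged
low-confidence rather than refused, and exact ties go to the lower phenotype
index with a flag. Pearson invariance makes calls robust to affine rescaling
of the incoming sample. Because correlation removes the profile mean, the
classifier relies on phenotype *shape* differences; this is also why the
synthetic generator plants shaped effects (below).

## Methylation procedures

The global methylation level of a sample is the mean beta-value over a probe
subset (all probes by default; a curated subset can be supplied). The
epigenetically-silenced-gene (ESG) caller applies four rules: drop probes
methylated in normals (mean normal beta > 0.2) or methylated
(beta >= 0.3) in fewer than 10% of tumors; split tumors at beta = 0.3
(the boundary value counts as methylated); call a probe silenced when mean
expression in the unmethylated group exceeds the methylated group by more
than 1.64 SDs of the unmethylated group; call a gene an ESG when strictly
more than half of its surviving probes are silenced — so a single-probe gene
needs exactly its one probe. The 10%-rule reuses the 0.3 cutoff because the
first criterion names none of its own. Probes whose split leaves an empty
group are ineligible and count as not silenced. Raising the SD multiplier
can only remove calls, never add them.

## Copy-number fractions and mutational signatures

FGG (FGL) is the fraction of the genome basis covered by segments with mean
log2(CN/2) strictly above 0.2 (below −0.2); FGA = FGG + FGL identically.
The threshold is a field convention, not a derived constant, and is exposed
as a parameter; the genome basis is a user-supplied chromosome-size table,
autosomes by default. Segments are validated for per-sample
non-overlap and chromosome bounds.

Mutational signatures are extracted from 96-trinucleotide-context counts by
multiplicative-update NMF under generalized Kullback–Leibler divergence with
30 random restarts per rank (seeded, hence reproducible). KL multiplicative
updates converge slowly, so the iteration budget is deliberately high
(`max_iter = 2000`, `tol = 1e-9`). The rank is chosen by the reconstruction-
error elbow anchored at a baseline fit one rank below the scanned range: the
smallest rank whose next signature improves the fit by less than 10% of its
own gain. The Brunet cophenetic correlation is computed and reported per
rank and serves as the fallback selector, but it discriminates poorly when
exposures are continuous mixtures rather than discrete sample groups — the
usual situation for bulk tumor cohorts — which is why it is not the primary
criterion. Near-duplicate extracted signatures (pairwise cosine > 0.98) set
a `rank_floor` flag: the true number of processes lies below the scanned
range. Extracted signatures are cosine-matched against a reference
catalogue and named after their best match at cosine >= 0.8. The packaged
catalogue is a deterministic synthetic stand-in with the standard 96 x 30
layout, intended for pipeline exercise; substitute a real catalogue file for
biological interpretation.

## Immunomodulator screen

The packaged annotation lists 62 immunomodulators in four classes
(12 MHC-I, 11 MHC-II, 27 checkpoint stimulators, 12 checkpoint inhibitors).
Expression differences across phenotypes use the Kruskal–Wallis test with BH
adjustment over the tested list; mutation and copy-number events use
Fisher's exact test on the phenotype x event table (simulated p, then
chi-square, as fallbacks for intractable tables); genes with constant event
status get p = 1 by convention and a flag. The miRNA screen computes
Spearman correlations between every miRNA and candidate target within each
phenotype, adjusts with BH within the phenotype, and retains pairs with
rho <= −0.2, adjusted p < 0.05 *and* a predicted-binding record — the
binding catalogue is consumed as a plain pair file so that database versions
stay pinned by the user.

## The synthetic cohort generator

`simulate_cohort()` produces the full multi-omic bundle with known truth.
Its design choices are the study conditions for every test in the package:

* **Expression.** Gene baselines are drawn once under a fixed internal seed,
  making them a property of gene identity shared across cohorts (as real
  baselines are) — without this, cross-cohort steps such as IGP would face a
  baseline mismatch no real pair of cohorts exhibits. Phenotype effects
  (defaults 0 / 0.8 / 1.6 log2 on marker genes for TIME-1/2/3) are spread
  over the 24 cell-type sets with fixed weights in [0.6, 1.4] so phenotypes
  differ in shape as well as level, and the suppressive sets (Treg, Th17)
  are boosted to 1.6 in TIME-2 and zeroed in TIME-3: the intermediate
  phenotype is suppressive-high, the activated phenotype effector-high —
  the hallmark immune-suppressed versus immune-activated contrast. A
  per-sample infiltration random effect (SD 0.25 log2 units, identical
  across phenotypes) emulates purity and biological heterogeneity; 0.25 is
  roughly a third of the phenotype step, a realistic amount of
  within-subtype spread that leaves the subtypes recoverable. Residual
  noise is gaussian with SD 1.
* **Survival.** Exponential times with per-phenotype hazard multipliers
  2.0 / 1.4 / 1.0 on a baseline hazard of 0.03 per month, administratively
  censored at 120 months.
* **Methylation.** 20 silenced genes with three probes each: beta 0.6–0.95
  in a random 40% methylated subgroup, 0.02–0.15 elsewhere and in normals;
  expression suppressed by 2.5 noise-SDs in the methylated subgroup
  (comfortably past the 1.64-SD calling rule, so recovery failures indicate
  caller defects, not marginal planting). Distractor probes exercise both
  exclusion rules: variably methylated probes without expression linkage,
  and probes methylated in normals.
* **Copy number.** Per sample, a phenotype-dependent number of altered
  autosomes (more in TIME-1, emulating the higher genomic instability of
  immune-poor tumors) with one gained or lost middle segment per altered
  chromosome; neutral segments have mean ~N(0, 0.03).
* **Mutations.** Counts are Poisson draws around a planted
  signatures x exposures product (default two signatures, ~200 mutations
  per sample).
* **miRNA.** Planted regulators subtract 0.8 x (miRNA − mean) from their
  target's expression; the binding table mixes planted pairs with decoys.

What the generator does **not** emulate: microarray batch and platform
effects, normalization artefacts, overlapping marker sets (configurable but
disjoint by default so oracle checks stay exact), copy-number segment noise
structure, sequencing-depth variation, and the correlation between genomic
instability and methylation seen in real tumors. Passing tests therefore
demonstrate algorithmic correctness under the stated statistical structure,
not robustness to real-data artefacts.

Problem sizes in the test-suite and acceptance runs — 150-sample cohorts,
5000 genes, 500 consensus resamples, 10 cohorts for the k-selection check —
were chosen as the smallest sizes at which the planted structure is
comfortably identifiable; they are the package's own testing conditions.

## Known limitations

* PAC selection inherits k-means' restart stochasticity; on degenerate
  single-cluster data the PAC curve has no pronounced minimum and the
  smallest-k tie-break applies (the result is flagged `degenerate`).
* The maximally selected cutoff p-value is anticonservative (no selection
  correction).
* The rotation-null IGP p-value saturates at observed IGP = 1 and has a
  floor around 0.005–0.02 in 24 dimensions; interpret IGP point values.
* The ESG caller assumes beta-values and expression share samples and that
  probe-gene mapping is many-to-one; cross-reactive probes are not modelled.
* KL-NMF is identifiable only up to scaling and permutation; signatures are
  column-normalized and matching to a catalogue is by cosine, so closely
  collinear reference signatures can swap best matches.
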