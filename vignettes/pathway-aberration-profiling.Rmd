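---
title: "Single-sample pathway aberration profiling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-sample pathway aberration profiling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathscape)
```

## The problem

Tumours that share a histological diagnosis can reach malignancy through
different combinations of molecular alterations. Rather than classifying
samples by individual gene markers, `pathscape` characterizes each tumour by
which *pathways* — curated sets of functionally related genes — appear
coherently up- or downregulated in that single sample, relative to a common
reference. The per-sample view matters: pooling a cohort first would average
away exactly the heterogeneity one wants to find. From the per-sample
pathway calls the package builds cohort-level aberration catalogues,
discovers subgroups of samples with similar aberration patterns, and tests
those subgroups for clinical relevance.

The intended input is a genes × samples matrix of log2 expression ratios
against a common reference (two-channel array style; any per-sample
monotone transform of the values gives identical scores), a sample metadata
table, and gene-set collections in GMT format.

## The statistic

For one sample, all measured genes are ranked from most upregulated (rank
1) to most downregulated (rank *n*); missing values are excluded and exact
ties are broken by gene symbol so the order is total and deterministic.
Walking down the list, each gene is labelled 1 if it belongs to the pathway
and 0 otherwise. Plotting the fraction of 1's seen so far against the
fraction of 0's traces an ROC-like step curve; its area is the enrichment
AUC. With member ranks $r_1 < \dots < r_m$ among $n$ genes,

$$\mathrm{AUC} \;=\; \frac{1}{m(n-m)} \sum_{i=1}^{m} \#\{\text{non-members ranked below } r_i\}
\;=\; \frac{mn - \sum_i r_i - m(m-1)/2}{m(n-m)},$$

i.e. the fraction of member/non-member pairs in which the member outranks
the non-member — a rescaled Mann–Whitney statistic. AUC = 1 iff every
member precedes every non-member. The depletion AUC is the same walk
started from the bottom of the list; under the strict total order it equals
one minus the enrichment AUC.

**Empirical confidence.** Significance is assessed against a permutation
null: the gene labels are shuffled — realized, equivalently and more
cheaply, by drawing uniform $m$-subsets of the $n$ positions — $B$ times
(default $B = 1000$), and the one-sided add-one estimate

$$p \;=\; \frac{1 + \#\{b : \mathrm{AUC}_b \ge \mathrm{AUC}_{\mathrm{obs}}\}}{B + 1}
\in \Big[\tfrac{1}{B+1},\, 1\Big]$$

is computed separately for enrichment and depletion. Add-one smoothing is
used because a raw tail fraction can be zero, which the subsequent log
transform cannot accept; it also makes the estimator's null distribution
uniform on its support. Phenotype-label permutation is deliberately not
offered: in a single-sample design there is no phenotype contrast to
permute.

**Combined signed score.** The two confidence scores are combined by taking
the smaller and mapping it to $\log_2$ space for enrichment and $-\log_2$
space for depletion, ties resolving toward enrichment. Enriched pathways
therefore go *negative* and depleted pathways *positive* in the stored
profiles; display layers that want red-high heatmaps can negate. The
pathways × samples matrix of combined values is the sample's *pathway
aberration profile*.

**No multiple-testing correction** is applied anywhere in scoring or in the
subgroup scans. This is a deliberate property of the method — it is
exploratory, and controlling false positives across ~2000 pathways ×
thousands of samples would make it uselessly conservative. Outputs carry a
supplementary Benjamini–Hochberg column clearly separated from the
uncorrected flags.

## Reproducibility of the permutation null

Each (sample, effective-set-size) null stream is seeded from a hash of the
master seed, the sample *identifier* and the effective size $m$. Three
consequences, each covered by a test: results are bit-reproducible given
the master seed; they are invariant to sample column order and to pathway
order; and the null for a given $(n, m)$ is drawn once per sample and
shared by all pathways of that effective size — a pure optimization,
distributionally identical to fresh draws. An exhaustive-enumeration oracle
(`exact_null_pvalue`) validates the Monte-Carlo scheme on small $(n, m)$.

## Calling and frequencies

A pathway is called **enriched** in a sample when its enrichment score is
below `alpha` (default 0.05, the conventional significance threshold used
throughout) and no larger than the depletion score; **depleted** when the
depletion score is below `alpha` and strictly smaller; **neutral**
otherwise — mutually exclusive by construction. Group-level aberration
frequencies are simply the fraction of a group's samples called enriched
(resp. depleted) per pathway.

## Gene-set handling

GMT collections are uppercased (HUGO convention), de-duplicated within
sets, optionally alias-mapped to a canonical namespace, and filtered to
sets with 10–1000 members — the conventional bounds below which a rank
statistic is unstable and above which a "pathway" is too diffuse to
interpret. When a measured-gene universe is supplied, sizes are counted
*after* intersection with it, because the permutation null depends only on
members that are actually measured. Pathway topology is ignored throughout;
a set is just a set. Name-level uniqueness is enforced per collection;
de-duplication of near-identical sets across source databases is left to
the user, since no principled member-level rule exists without curation.

## Subgroup discovery

Samples are clustered on the combined signed profiles with Euclidean
distance and Ward's minimum-variance linkage (`stats::hclust`,
`method = "ward.D2"`; heights are in square-root-of-merge-cost units and
non-decreasing). Cohort-level comparisons cluster mean profiles; subgroups
from different cohorts are compared on feature vectors concatenating their
enrichment- and depletion-frequency profiles.

"Distinct branches of 20–30 samples" is a description, not an algorithm, so
`extract_subgroups` makes it one: descend from the root splitting any
cluster larger than `max_size`; a cluster smaller than `min_size` produced
by a forced split is merged into its nearest sibling. Pure tree information
cannot rank the subgroups inside the sibling branch (their cophenetic
distances to the undersized cluster are all equal to the attachment
height), so the merge goes to the *smallest* sibling subgroup, ties to the
earlier one in dendrogram order — deterministic, and the merged subgroup
may legitimately exceed `max_size`. `k_override` cuts the tree into exactly
*k* clusters instead, the escape hatch for reproducing a stated cluster
count.

## Clinical association testing

Subgroup-versus-rest survival differences use the unweighted Mantel–Cox
log-rank test on Kaplan–Meier product-limit estimators (`survival`
package); `event = FALSE` means right-censored at `time`. Label
associations use the two-sided Fisher exact test (probability-mass
ordering); differential expression between sample groups uses the
two-sided Wilcoxon rank-sum test, exact when both groups have ≤ 12
tie-free values. All scans flag at `alpha` without correction, as above.

## The synthetic cohort generator

`generate_genesets`, `generate_cohort` and `generate_survival` produce
cohorts with known ground truth so that every pipeline stage is testable
without external data. An expression entry is

*cancer baseline* + *planted pathway shift* + Gaussian noise(0, σ),

where each cancer's baseline shifts a sparse random 10% of genes by ±1
(sufficient for cancers to separate in PCA), and a subgroup planted with an
enriched (depleted) pathway has that pathway's member genes shifted by +δ
(−δ). Defaults δ = 1, σ = 1 — a one-noise-sd coherent shift, the regime the
method is meant to detect. Duplicates are near-copies (noise σ/10) sharing
a patient id. Survival times are exponential with rate `base_rate` × the
subgroup's hazard multiplier; censoring times are uniform on (0, c) with c
solved numerically so the expected censored fraction matches the request.
Gaussian noise on the log-ratio scale is consistent with two-channel
log-ratio data.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: probe-level artifacts and normalization
residuals, batch effects, correlated gene–gene noise within pathways,
heavy-tailed outliers, and biologically overlapping pathway definitions
(generated sets are disjoint unless overlap is requested). Planted states
are also pure: one shift per pathway per subgroup, never mixed within a
pathway.

## Validation problem sizes

The test suite and the acceptance script validate at sizes chosen to make
the statistics sharp while keeping a full run comfortably interactive:
AUC-vs-brute-force on all subsets up to n = 8; permutation-vs-exact on a
grid n ≤ 10, m ≤ 4 at B = 5000; null calibration on 2000 simulated
sample–pathway pairs and a 60-sample × 30-pathway null cohort at B = 1000;
planted-signal recovery with 100 samples × 2000 genes and a 50-gene
pathway at δ = 1, σ = 1, B = 1000; subgroup recovery with 3 × 30 samples,
40 pathways and 5 planted aberrations per subgroup at B = 200; survival
power with a hazard-ratio-3, 30-versus-70 design at 20% censoring over 100
replicates, and null calibration over 500.

## Known limitations

- Ranks discard magnitude: a pathway of uniformly small coherent shifts and
  one with a few huge shifts can score alike.
- The permutation null treats genes as exchangeable; correlated expression
  within a pathway makes the null anti-conservative on real data.
- With $B = 1000$ the smallest attainable score is $1/1001$, so profiles
  saturate at $\pm\log_2(1001) \approx \pm 9.97$; raise `B` if finer tail
  resolution is needed.
- The subgroup extraction bounds (20–30) are heuristics for cohorts of a
  few hundred samples; small cohorts collapse to a single subgroup, which
  the survival scan then skips for lack of a comparison group.
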