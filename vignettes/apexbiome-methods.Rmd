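---
title: "Methods and design notes for apexbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for apexbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`apexbiome` analyses 16S rRNA OTU count tables from root-apex cohorts of
apical periodontitis: four groups (HO healthy oral, HT healthy tooth
apex, NRCT untreated diseased apex, RCT failed-root-canal apex), with
healthy oral and tooth samples paired within subject. This vignette
records the statistical conventions the package commits to, the
generative model behind its synthetic cohorts, and the design decisions
taken where the analysis recipe leaves choices open.

## Normalisation

All between-sample comparisons run on counts rarefied to the cohort's
minimum library size: a single draw without replacement per sample
(multivariate hypergeometric), so downstream counts stay integral and
the draw is reproducible from a required `seed`. Averaging over repeated
draws would shrink variance artificially for the rank tests that follow.
Samples below the target depth are dropped with a warning rather than an
error: when the target is the cohort minimum the case cannot arise, but
user-supplied depths can exceed some libraries. Diversity profiles are
computed on rarefied counts by default (`rarefy_depth = NULL` opts out),
since observed richness and Chao1 are strongly depth-dependent.

## Diversity estimators

* Observed richness: features with count > 0.
* Chao1: \(S_{obs} + F_1^2/(2F_2)\) with singletons \(F_1\) and
  doubletons \(F_2\); when \(F_2 = 0\) the bias-corrected fallback
  \(S_{obs} + F_1(F_1-1)/2\) avoids the division by zero.
  Implementations differ in this branch, so it is documented and tested
  explicitly.
* Shannon in natural log (nats), the convention of the standard
  ecological `diversity` function.
* Simpson defaults to the Gini–Simpson form \(1 - \sum p_i^2\); the
  dominance form \(\sum p_i^2\) and the inverse form are exposed through
  `variant` because published tables rarely state which one they use.

Group contrasts of diversity metrics use the same two-sided Wilcoxon
rank-sum machinery as the differential module; a group with fewer than
two samples yields an inconclusive p of 1 with a warning rather than an
error.

## The multi-criterion differential procedure

For a contrast of two groups at OTU or genus level:

1. rarefy to the table minimum; screen features present in fewer than
   `ceiling(0.10 · n_samples)` samples (all samples, not just the two
   groups, so the same feature universe serves every contrast);
2. per feature, a two-sided Wilcoxon rank-sum test on normalised counts
   — exact when the pooled size is ≤ 12 without ties, otherwise the
   normal approximation with midrank tie correction and continuity
   correction. With `paired = TRUE`, subjects present in both groups
   contribute a signed-rank test on their per-subject differences
   (multiple samples of one subject in a group are averaged first;
   subjects lacking either sample are dropped);
3. Storey q-values at fixed \(\lambda = 0.5\):
   \(\hat\pi_0 = \min(1, \#\{p > \lambda\}/(m(1-\lambda)))\), floored at
   \(1/m\) to stay positive, and step-up q-values
   \(q_{(i)} = \min_{j \ge i} \hat\pi_0\, m\, p_{(j)}/j\). The fixed-λ
   estimator is deterministic and adequate at these problem sizes; the
   spline-over-λ variant adds machinery without changing calls
   materially here. With \(\hat\pi_0 = 1\) the q-values coincide exactly
   with Benjamini–Hochberg, which the tests exploit as an oracle;
4. fold change \((\bar x_{hi} + 1)/(\bar x_{lo} + 1)\) of group means of
   rarefied counts with a pseudocount of one read, because zeros
   dominate these tables and a raw ratio would be unstable or undefined;
5. the Q3 filter: the enriched group — interpreted as the group with the
   larger normalised mean, so the filter asks that the *enriched* side
   be non-trivially abundant — must have 75th-percentile abundance
   ≥ 10 reads (OTU level) or ≥ 100 (genus level) at the rarefied depth.
   Quantiles interpolate linearly between order statistics (index
   \(1 + 0.75(n-1)\)).

A feature is significant only when all three criteria hold (q ≤ 0.05,
fold change ≥ 2, Q3 floor). Direction at exactly tied group means is
reported as `up_in_a` by convention and is not meaningful.

## Sample overlap

For each unordered pair, presence sets over raw counts decompose the
union into shared / unique-to-x / unique-to-y fractions (the shared
fraction is the Jaccard index). Abundance is decomposed by pooling both
samples' reads: the three slices (reads in shared features, reads in
features unique to each sample) partition all observed reads, matching
the pie-chart geometry used for such figures; the denominator of the
published abundance fractions is not stated anywhere we know of, so this
partition-forming choice is the default and a Bray–Curtis-style
`min_relative` mode (\(\sum_i \min(p_{xi}, p_{yi})\), remainder split
evenly) is the alternative. Overlap uses un-rarefied presence by
default — presence is depth-sensitive, and users can rarefy first when
depth-standardised presence is wanted. Pairs are categorised O2O
(oral–oral), T2T (tooth–tooth), O2T (oral–tooth).

## Co-occurrence network

Pearson correlations of rarefied counts across *all* samples of the
cohort (the disease signal itself drives the co-variation of interest),
p-values from the t transform with \(n-2\) degrees of freedom, and Holm
adjustment over the distinct pairs by default — the conservative default
of the correlation routine this mirrors; BH is available. The edge rule
applies the threshold to \(|r| > 0.6\), not signed r, because negative
co-occurrences are part of the structure being sought. Zero-variance
features are excluded with a warning. Components come from graph
traversal and k-core indices from iterative minimum-degree peeling
(igraph); a brute-force pruning oracle cross-checks them in the tests.

## Subtypes and concordance

Lesion strings ("4×5 mm", "4x3mm": two millimetre dimensions, mixed
delimiters, optional suffix) parse into dimensions; the maximum
dimension classifies LSA (≥ 5 mm) vs SSA. Diseased samples cluster on
genus-level relative abundances with Bray–Curtis dissimilarity and
complete linkage, cut at k = 2 — distance and linkage are not dictated
by the recipe this package follows, so a standard ecological default was
chosen and both are exposed (`euclidean`/`jaccard`,
`average`/`ward`). Concordance between the 2-cluster assignment and the
binary lesion labels is the best agreement over the two cluster→label
mappings (hence ≥ 0.5 and invariant to letter swaps), with significance
from a label-permutation test using the \((1 + \#\{perm \ge obs\})/(n_{perm}+1)\)
correction; Fisher's exact test on the 2×2 table is the alternative.
The permutation null is discrete, so its p-values are conservative
rather than exactly uniform — the tests check super-uniformity.

The package ships the published clinical annotation table of the 23
untreated patients (`nrct_clinical()`). Scoring its printed cluster and
lesion columns gives 19/23 agreements (accuracy 0.826); the matching
convention behind the originally reported 0.885 is not reconstructable
from the printed rows, so 0.826 is the number this package's machinery
reports and tests against.

## The synthetic cohort generator

No sequence data are deposited for this study design, so the simulator
is the package's test bed. The generative model:

1. one standard-normal score \(z_i\) per OTU (pool of 5,000) fixes the
   rank-abundance backbone shared by all groups;
2. group expected profiles \(w_{gi} \propto \exp(\sigma_g z_i)\), so a
   larger \(\sigma_g\) concentrates mass in the top OTUs; defaults
   \(\sigma = (2.00, 2.12, 2.70, 2.85)\) for HO/HT/NRCT/RCT were
   calibrated once so that group-mean top-100 cumulative fractions land
   near the 72/75/83/85% pattern of the study conditions and reduced
   richness/diversity follows in the diseased groups;
3. planted multiplicative effects on three disjoint OTU sets drawn from
   the 70th–97th percentile abundance band (the selection rule's Q3
   floor discards low-abundance candidates by design, so planted effects
   below the band would be undetectable by construction): 49 "down"
   OTUs ×25 in HO/HT and ×0.02 in NRCT/RCT; 40 "up" OTUs ×40 in NRCT
   and ×0.05 elsewhere; 51 subtype OTUs ×25 in NRCT-B samples only;
4. per-sample Dirichlet perturbation with concentration 300×profile
   (overdispersion typical of 16S data; `Inf` collapses the noise);
   healthy samples additionally carry a log-normal perturbation
   (sd 0.75) split into a within-subject shared component and an
   independent remainder with correlation `paired_subject_effect`
   (default 0.6) — variance-preserving, so pairing strength and
   per-sample noise are decoupled;
5. multinomial sequencing at a depth uniform on 29,604–68,088 reads.

Metadata reproduce the cohort structure: 9 HO subjects each paired with
an HT tooth, one subject contributing a second tooth (10 HT), 23 NRCT
subjects split into subtypes A (9) and B (14) with lesion strings
agreeing with subtype up to a mislabel rate of 4/23 (so perfect
clustering tops out at 19/23 concordance, mirroring the published
table), and 8 RCT subjects. Simulated taxonomy assigns planted OTUs
private genera — key taxa in real cohorts are distinct genera — so
planted structure survives genus aggregation.

What the simulator does **not** emulate: open-reference OTU-picking
artifacts (absolute per-sample richness here is in the hundreds, not
918–4,436 — orderings and dominance are the calibration targets, not
absolute richness), phylogenetic correlation among OTUs, compositional
correlation artifacts beyond what the Dirichlet induces, and any
real-data taxonomy. Passing tests therefore demonstrate that the
machinery recovers known structure under realistic sparsity and
overdispersion, not that it would produce identical numbers on the
original sequencing data.

## Numerical and degenerate-input conventions

* Empty communities error in the diversity estimators; all-zero paired
  differences yield p = 1 with a warning; features constant across both
  groups get p = 1.
* Exact Wilcoxon p-values follow the standard two-sided doubling
  convention capped at 1; hand-checked examples pin this down.
* q-values are clipped to [0, 1]; \(\hat\pi_0\) to \([1/m, 1]\).
* Rarefaction warns and drops under-depth samples; depth must be a
  positive integer.
* Cluster letters are assigned by first appearance over
  lexicographically sorted sample ids, making the partition
  deterministic for a given table.
* All stochastic stages take explicit seeds; `run_pipeline()` derives
  per-stage substreams from one root seed so stages re-run independently
  yet reproducibly.

## Problem sizes in the test suite

The suite exercises full-size cohorts (5,000 OTUs × 50 samples) for the
calibration, recovery and type-I properties — recovery at one fixed
seed, orderings over five seeds, and a 20-seed null for type-I control —
and 800-OTU cohorts for structural unit tests, a balance chosen to keep
the default `testthat` run around a minute while still testing the
package under its intended data scale. Enumeration oracles (rank tests,
k-cores) run exhaustively at the small sizes where enumeration is exact.

## Known limitations

* The Wilcoxon/Storey/fold-change/Q3 recipe treats counts as exchangeable
  after rarefaction; it does not model compositionality (no CLR/ANCOM)
  or covariates, matching the analysis it re-implements.
* Pearson correlations on rarefied counts are sensitive to the planted
  group structure itself; the network describes co-occurrence across the
  whole cohort, not conditional dependence.
* The fixed-λ \(\hat\pi_0\) can exceed the spline estimate on strongly
  non-null p-value sets, making q-values mildly conservative.
* `concordance()` is defined for two clusters and two labels; larger k
  would need a generalised matching.
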