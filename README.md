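# apexbiome

Downstream analysis of 16S rRNA OTU tables from root-apex microbiome
cohort studies of apical periodontitis (AP), for microbiologists and
bioinformaticians comparing the communities of diseased tooth apices
(with and without failed root canal treatment), healthy tooth apices,
and healthy oral mucosa.

Apical periodontitis is an inflammatory lesion at the tooth-root apex of
microbial etiology. Comparing the apex microbiota of diseased teeth
(NRCT: untreated; RCT: failed root canal treatment) against healthy
controls (HT: healthy tooth apex; HO: buccal mucosa) reveals both taxa
that bloom with disease and — once healthy-apex controls are available —
a large set of taxa that disappear. `apexbiome` implements that complete
analysis chain as composable, tibble-returning functions:

- **Core table** — classic tab-separated OTU tables with Greengenes-style
  lineages (`read_otu_table()` / `write_otu_table()`), taxonomic
  aggregation (`aggregate_taxa()`), one-shot rarefaction to a common
  depth (`rarefy()`), and a prevalence screen (`prevalence_filter()`).
- **Diversity** — per-sample richness and diversity: observed OTUs,
  Chao1 (`S_obs + F1²/(2·F2)`, with the bias-corrected fallback
  `S_obs + F1(F1−1)/2` when `F2 = 0`), Shannon `H = −Σ pᵢ ln pᵢ`,
  Gini–Simpson `1 − Σ pᵢ²`; rank-sum group comparisons and cumulative
  dominance curves (`diversity_table()`, `compare_groups()`,
  `dominance_curve()`).
- **Differential abundance** — the multi-criterion selection rule: a
  two-sided Wilcoxon rank-sum test per feature (signed-rank on
  subject-paired samples), Storey q-values with
  `π̂₀ = #{p > λ}/(m(1−λ))`, fold change of pseudocount-stabilised group
  means, and a Q3 filter requiring the enriched group's 75th-percentile
  normalised abundance to reach a level-specific floor (10 at OTU level,
  100 at genus level). A feature is significant only if `q ≤ 0.05`,
  fold change `≥ 2`, and the Q3 floor is met (`differential_analysis()`).
- **Sample overlap** — pairwise shared/unique decompositions of richness
  (Jaccard) and pooled-read abundance, categorised O2O / T2T / O2T
  (`pairwise_overlap()`, `overlap_summary()`).
- **Co-occurrence network** — Pearson correlations across all samples
  with t-transform p-values, Holm (default) or BH adjustment, edges at
  `|r| > 0.6` and adjusted `p < 0.05`, connected components and k-core
  decomposition (`cooccurrence_network()`).
- **Subtypes** — lesion-string parsing with the LSA/SSA ≥ 5 mm rule,
  genus-level hierarchical clustering (Bray–Curtis, complete linkage),
  and cluster–clinical concordance with a permutation test
  (`parse_lesion()`, `hierarchical_subtypes()`, `concordance()`).
- **Synthetic cohorts** — a calibrated generator
  (`simulate_cohort()`, `default_design()`) reproducing the study
  conditions: 50 samples (9 HO / 10 HT / 23 NRCT / 8 RCT), depths in
  29,604–68,088 reads, group-specific dominance, 49 planted
  disease-suppressed and 40 disease-elevated OTUs, NRCT subtypes A/B
  with lesion annotations, and paired HO/HT subjects — so every stage is
  testable against known ground truth.
- **Pipeline** — `run_pipeline()` orchestrates everything into a
  directory of documented TSV outputs plus a manifest, reproducible from
  one seed.

Results are tidy tibbles; fitted objects support `tidy()`, `glance()`
and `autoplot()`.

## Worked example

```r
library(apexbiome)

cohort <- simulate_cohort(default_design(), seed = 42)
cohort$table
#> <otu_table> 5000 features x 50 samples
#>   sample depths: 30448 - 66521 (median 51854)
#>   taxonomy present for 5000 features

# richness comparison between untreated disease and healthy apices
profiles <- diversity_table(cohort$table, seed = 42)
compare_groups(profiles, cohort$metadata, "observed_otus", "NRCT", "HT")
#> # A tibble: 1 × 5
#>   metric        group_a group_b statistic    p_value
#>   <chr>         <chr>   <chr>       <dbl>      <dbl>
#> 1 observed_otus NRCT    HT              0 0.00000719

# multi-criterion differential abundance at OTU level
res <- differential_analysis(cohort$table, cohort$metadata, "NRCT", "HT", seed = 42)
glance(res)
#> # A tibble: 1 × 8
#>   group_a group_b level n_tested n_significant n_up_in_a n_up_in_b   pi0
#> 1 NRCT    HT      otu       1062           111        56        55 0.759

# co-occurrence network over the significant OTUs
net <- cooccurrence_network(cohort$table, res$feature_id[res$significant], seed = 42)
glance(net)
#> # A tibble: 1 × 5
#>   n_nodes n_edges n_negative_edges n_components max_k_core
#> 1     111     175                4           18          5

# concordance of the published clinical table's clusters with lesion size
clin <- nrct_clinical()
concordance(clin[, c("sample_id", "cluster")],
            data.frame(sample_id = clin$sample_id, label = clin$level), seed = 42)
#> # Cluster-label concordance: accuracy 0.826 (permutation p = 0.0019)
#> # mapping: A -> LSA, B -> SSA
```

Reading the output: the rank-sum test finds untreated-disease apices
significantly poorer in OTUs than healthy apices (p ≈ 7e-6 here); of
1,062 OTUs passing the 10% prevalence screen, 111 meet all three
selection criteria, split between disease-elevated (`up_in_a`, NRCT) and
disease-suppressed (`up_in_b`, higher in HT); the network over those
OTUs splits into components dominated by elevated and suppressed OTUs
respectively, with a few negative edges between them; and the printed
clinical table's A/B community clusters agree with the radiographic
LSA/SSA lesion classification for 19 of 23 patients (accuracy 0.826).

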