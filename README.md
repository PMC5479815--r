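# tempoclust

Temporal archetype analysis of stage-series bulk RNA-seq.

Growing organoid cultures are typically profiled at a ladder of time
points (here days 2, 4, 6, 8, 10, 12, 14) in two replicate series, and
the questions are always the same: which genes rise late (receptor-class
programs), which rise early (precursor/signaling programs), which fall as
proliferation gives way to differentiation, and which categories of genes
are over-represented in each temporal class. tempoclust packages that
analysis — quantification, trimming, clustering, cross-replicate
consensus, differential testing, enrichment — as tested, reproducible R
functions, together with a negative-binomial simulator that generates
two-replicate stage series with known truth so every stage of the
pipeline can be validated end to end without any sequencing data.

## What it computes

* **RPKM and trimming** — `compute_rpkm()` applies
  RPKM<sub>gj</sub> = 10⁹ c<sub>gj</sub> / (N<sub>j</sub> ℓ<sub>g</sub>);
  `trim_genes()` keeps genes with day-14 RPKM ≥ 0.2 *and* cross-stage
  RPKM sum > 0.2 (each criterion assignable to either replicate).
* **Temporal archetypes** — `log_normalize()` (log₂(RPKM+1), per-gene
  mean-centered) then `kmeans_cluster()`: seeded multi-restart Lloyd
  K-means (k = 4, 30 restarts, iteration cap 30,000), labeled
  late_rise / early_rise / flat / early_drop by shape matching
  (`label_archetypes()`).
* **Stage dendrogram** — `cluster_stages()` (Euclidean, complete
  linkage); the two-group cut separates early from late stages.
* **Consensus** — `match_clusters()` aligns the replicates' clusters
  (assignment problem over centers, or archetype identity);
  `intersect_clusters()` keeps genes classified consistently in both,
  plus the combined rising set.
* **Differential expression** — `de_test()`: per-gene NB GLM
  (log link, variance μ + φμ², offsets log N<sub>j</sub>), full model
  `~ stage + replicate` vs reduced `~ replicate`, likelihood-ratio test
  on 6 df, BH-adjusted at 0.05. Dispersion by Cox–Reid adjusted profile
  likelihood: genewise, common, or empirical-Bayes shrunk (default).
* **Enrichment** — `enrich()`: one-sided hypergeometric tail
  P(X ≥ k) against GMT categories with a defined background and a
  Benjamini column over tested terms.
* **Pipeline** — `run_pipeline()` chains everything from one seeded
  config and writes a deterministic manifest with the gene-count funnel.

## Worked example

```r
library(tempoclust)

sim <- generate_dataset(sim_config(seed = 1))   # two replicates, known truth
ra <- compute_rpkm(sim$counts_a)
rb <- compute_rpkm(sim$counts_b)

rep <- trim_genes(ra, rb)
#> filter_report: 2000 of 2000 genes kept (day14 RPKM >= 0.2 on A AND stage sum > 0.2 on B)

keep <- rep$kept_ids
ma <- label_archetypes(kmeans_cluster(log_normalize(subset_genes(ra, keep)), seed = 2))
mb <- label_archetypes(kmeans_cluster(log_normalize(subset_genes(rb, keep)), seed = 3))
table(ma$archetype_labels[ma$assignments])
#> early_drop early_rise       flat  late_rise
#>        276        292       1347         85

cons <- intersect_clusters(ma, mb)
#> consensus_result: mapping 1 -> 2, 2 -> 4, 3 -> 1, 4 -> 3
#> shared sizes: flat=1338, early_drop=270, early_rise=287, late_rise=85
#> combined up set: 372 genes

cut_stages(cluster_stages(log_transform(subset_genes(ra, keep))), 2)
#>  d2  d4  d6  d8 d10 d12 d14
#>   1   1   1   1   2   2   2

de <- de_test(subset_genes(sim$counts_a, keep), subset_genes(sim$counts_b, keep))
sum(de$significant)
#> [1] 681

chart <- enrich(cons$shared_sets$late_rise,
                gene_set_collection(sim$gene_sets$categories, keep))
head(chart, 3)
#>                      term  k  K  n    N  p_value benjamini
#> 1 taste_transduction_like 28 50 85 2000 1.49e-27  4.61e-26
#> 2                decoy_22  5 47 85 2000 4.64e-02  7.20e-01
#> 3                decoy_18  5 57 85 2000 9.14e-02  9.44e-01
```

Reading the output: the simulator planted four temporal archetypes in
known proportions plus a category preferentially drawn from late-rise
genes. The pipeline recovers the archetype class sizes, the stage
dendrogram's two-group cut splits days 2–8 from days 10–14, 681 of 2000
genes change significantly across stages (FDR ≤ 0.05), and the planted
category tops the enrichment chart of the consensus late-rise set by
many orders of magnitude — the behaviour expected when a late-activated
transcriptional program (e.g. taste transduction in taste organoids) is
present.

A thin CLI over the same functions ships in
`inst/scripts/tempoclust-cli.R` (subcommands `simulate`, `rpkm`,
`filter`, `cluster`, `consensus`, `de`, `enrich`, `run-all`).

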