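# vlincscope

Discovery and epigenetic profiling of very long intergenic non-coding
RNAs (vlincRNAs) from strand-specific RNA-seq coverage.

vlincRNAs are contiguous intergenic transcribed regions of ~50 kb to
1 Mb with strong cell-type- and cancer-subtype-specific expression.
Because they are absent from standard annotations, they are found by
segmenting pooled strand-specific coverage rather than by transcript
assembly. `vlincscope` is for genomics analysts who want that procedure
— and the downstream expression, chromatin-state and methylation
analyses — as reusable, tested R functions over Bioconductor containers
(`GRanges`, `RleList`, `SummarizedExperiment`).

## The method

Per strand, with pooled per-base coverage as input:

1. remove covered bases overlapping protein-coding genes (same strand);
2. remove bases below the third quartile (Q3) of the covered-base depth
   multiset, and bases in blacklisted regions;
3. merge surviving bases less than 500 bp apart, then merge the
   resulting segments less than 10 kb apart;
4. keep segments >= 50 kb as vlincRNA calls; calls >= 10 kb from any
   gene on either strand form the high-confidence "far-from-genes" set.

Downstream: region x sample counting (htseq-style, ambiguity-discarding),
a minimal-expression filter (>= 100 reads in >= 3 samples, autosomes),
median-of-ratios log2 normalization, hierarchical clustering with the
cluster-purity statistic `purity = (1/N) Σ_c max_l |c ∩ l|`,
subtype-specific ranking by fold change, candidate promoters (±10 kb of
the 5' start), chromatin-state post-processing (merge < 1 kb, keep
>= 400 bp), promoter refinement to the longest overlapping active
region, shuffle-background overlap enrichment with Fisher and
permutation p-values, and 30-bin WGBS methylation metaprofiles
(10 upstream-flank + 10 body + 10 downstream-flank bins).

A synthetic-data generator plants vlincRNAs, subtype-structured
negative-binomial counts, active promoter chromatin and promoter
hypomethylation with full ground truth, so the whole pipeline is
testable offline.

## Worked example

Simulate a cohort at the default study scale (3 x 10 Mb genome, 20
planted vlincRNAs, 4 subtypes x 8 samples), run discovery and the
promoter enrichment:

```r
library(vlincscope)

sim   <- simulateAll(simConfig(seed = 1))
calls <- discoverVlincs(sim$pooled, sim$truth$genes)
evaluateRecovery(calls, sim$truth$vlincs)$recovery_rate
#> [1] 0.95

labels <- setNames(sim$meta$subtype, sim$meta$sample_id)
nl <- normalizeLog(filterMinExpressed(sim$counts))
clusterPurity(hierarchicalClusters(nl$mat, k = 4), labels)
#> [1] 1

act <- activeRegions(sim$chromatin$states, "Active")
ps  <- candidatePromoters(sim$truth$vlincs, sim$truth$layout)
overlapEnrichment(ps, act, sim$truth$layout, n_shuffles = 1000, seed = 1)
#> EnrichmentResult: 85.0% (17/20) observed vs 21.04% mean random (4.2/20)
#>   fold = 4.04; Fisher p = 8.8e-05; permutation p = 0.001 (1000 replicates)
```

Nineteen of the twenty planted transcripts are recovered at Jaccard
>= 0.8; subtype clustering is perfectly pure at k = 4; promoters of
expressed vlincRNAs overlap planted active chromatin four times more
often than shuffled windows do, with the permutation p at its floor of
1/1001. The published-count arithmetic is available directly:

```r
enrichmentFromCounts(n_obs = 79, mean_random = 36, n = 256)
#> EnrichmentResult: 30.9% (79/256) observed vs 14.06% mean random (36.0/256)
#>   fold = 2.19; Fisher p = 7.2e-06; permutation p = NA (0 replicates)
```

A thin command-line wrapper for shell use lives at
`inst/scripts/vlincscope.R` (subcommands `discover`, `compare`,
`enrich`, `simulate`).

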