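# matbin

Composition-based binning and community analysis of metagenome assemblies,
built for the kind of data produced by shotgun sequencing of microbial mat
communities (e.g. thermophilic phototrophic mats): a few dominant
populations, scaffolds from 1 kb to >100 kb, mixed-type environmental
metadata per site, 16S OTU count tables, and protein-family abundance
profiles.

## What it computes

**Oligonucleotide-frequency binning.** Every scaffold gets a "genome
signature": length-normalized frequencies of all DNA words of length
k = 3..6 (5440 features), plus its G+C fraction. For word *w* of length *k*
on a scaffold with *n_k* valid (N-free) windows,

    f_w = count(w) / n_k,        sum over words of length k: f_w = 1.

Scaffolds ≥ 10 kb are clustered by Monte-Carlo consensus k-means: *T*
randomized, independently seeded k-means trials (optionally pooled over a
range of k), summarized by the co-clustering **support matrix**

    S_ij = (# runs where i and j share a cluster) / (# runs).

Bins are connected components of the graph with an edge wherever
S_ij ≥ 0.90, keeping components of ≥ 10 scaffolds; the same edges export to
SIF/GraphML for network display.

**Community ecology statistics.** Gower dissimilarity for mixed
numeric/categorical site variables; PCoA/PCA ordination; envfit-style
fitting of variables onto ordination scores with permutation p-values;
alpha-diversity estimators (Chao1, ACE, Shannon *H'*, reciprocal Simpson
λ⁻¹, Fisher's α solving S = α·ln(1 + N/α)) and analytic (hypergeometric)
rarefaction.

**Functional profiles.** Category × site abundance matrices: relative
abundance, row standardization, PCA across sites, and two-way hierarchical
clustering under both common recipes (Euclidean/complete and
Pearson/average), exported as Newick.

**Synthetic communities.** Order-m Markov genome models with exact target
G+C but distinct higher-order word bias, lognormal scaffold lengths, planted
bin labels, plus generators for OTU counts (log-series / lognormal),
environmental gradients, and grouped functional matrices — so the whole
pipeline is testable end to end without any downloads.

## Worked example

```r
library(matbin)

models <- list(
  sample_genome_model(0.35, markov_order = 2, seed = 1, label = "Chloroflexus-like"),
  sample_genome_model(0.50, markov_order = 2, seed = 2, label = "Chlorobi-like"),
  sample_genome_model(0.65, markov_order = 2, seed = 3, label = "Roseiflexus-like"))
sim <- generate_scaffolds(community_spec(models, n_scaffolds = rep(60, 3), seed = 11))

scaffolds <- filter_scaffolds(sim$records, 10000)
#> filter_scaffolds: kept 124, dropped 56 (min length 10000 bp)

res <- consensus(composition_matrix(scaffolds),
                 consensus_config(k_values = 4, trials_per_k = 100, seed = 17))
res
#> cocluster_result: 124 scaffolds, 100 runs, 3 clusters (support >= 0.90, min size 10), 0 unbinned

summarize_clusters(res, scaffolds)[, c(1:6, 9)]
#>   cluster n_scaffolds median_size_kb mean_gc_pct sd_gc_pct total_sequence_mb             taxon
#> 1       1          46           19.6        65.1     0.330             1.109  Roseiflexus-like
#> 2       2          40           20.6        50.1     0.326             1.000     Chlorobi-like
#> 3       3          38           16.3        34.9     0.379             0.766 Chloroflexus-like
```

The three planted populations are recovered exactly (adjusted Rand index
1.0 against the truth table): each cluster reports its scaffold count,
median size in kb, mean ± SD G+C percent, and total assembled sequence in
Mb — the conventional bin-property table. `support_edges(res)` +
`write_graph_file()` export the network behind it.

Diversity from a simulated log-series OTU sample (α = 12, N = 500):

```r
diversity_report(generate_otu_counts(N = 500, abundance_model = "logseries",
                                     alpha = 12, seed = 5))
#> diversity_report: S_obs 53, chao1 67.0, ACE 65.8, H' 3.254, 1/lambda 17.04, Fisher alpha 14.98
```

Chao1 and ACE estimate the richness the sample missed; λ⁻¹ ≈ 17 is the
effective number of equally-common species; Fisher's α ≈ 15 estimates the
log-series parameter (truth 12) from one finite sample.

A command-line wrapper covering simulate / compose / gcspec / bin /
diversity / envfit / funcprofile / ordinate is installed at
`<library>/matbin/scripts/matbin`.

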