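# devomap

Comparative analysis of developmental time-course transcriptomes and
two-population genomes, built around the question a dense pig
skeletal-muscle atlas poses: when two breeds are sampled at the same 27
developmental stages (embryonic day E33 to postnatal day D180), do their
muscle transcriptomes develop in register — and if not, which breed runs
ahead? The package is for researchers analysing matched multi-stage
expression series of two conditions (breeds, strains, species) with an
accompanying resequencing panel.

## The core method: stage alignment by a maximum trace

1. **Development-associated genes (DAGs).** Gene *g* is a DAG at time
   point *t* when its abundance exceeds 1.0 (RPKM/TPM) **and** its
   within-gene Z score at *t* exceeds 1.5 — the genes that peak at that
   stage.
2. **Mapping scores.** For every stage pair (*i*, *j*) of conditions A
   and B, the shared-DAG count *k* is scored by the upper-tail
   hypergeometric probability over the common gene universe *N*:

       P(i,j) = P(X >= k),  X ~ Hypergeom(N, |DAG_B(j)|, |DAG_A(i)|)
       M(i,j) = -log10( min(1, T_A * T_B * P(i,j)) )

3. **Maximum trace.** Dynamic programming finds the monotone staircase
   path from M(1,1) to M(T_A,T_B) maximizing the summed score:

       S(i,j) = M(i,j) + max{ S(i-1,j), S(i,j-1), S(i-1,j-1) }

   Traceback from the last cell (ties: diagonal, then vertical) gives
   the alignment; per-stage lag is `median(mapped B index) - i`, positive
   when condition B lags.

Around this core the package provides the supporting layers of a full
comparative study: expression summary statistics and classical MDS;
Welch and interaction-regression differential-expression tests with BH
control and phase-specific gene calling; CV-filtered k-means
co-expression modules with figure-of-merit k selection; ceRNA
(lincRNA-miRNA-mRNA) triplet networks from seed matches and correlation
filters (R < -0.5 / R > 0.5, P < 0.05); and a two-population scan:
windowed Weir-Cockerham FST and nucleotide diversity (50 kb windows,
10 kb step, >= 10 SNPs), log2 pi-ratio with empirical-quantile sweep
thresholds, region merging and gene annotation, LD decay, genotype PCA
and a bootstrapped NJ tree. Seeded synthetic-data generators with ground
truth (injected lag, trajectory archetypes, miRNA-target structure,
Balding-Nichols differentiation with injected sweeps) back every stage
with recovery tests.

## Worked example

Simulate two 27-stage time courses in which 60% of 2,000 genes are
shifted two stages later in condition B, then align them:

```r
library(devomap)

cfg <- expr_sim_config(n_genes = 2000, lag_steps = 2, frac_lagged = 0.6,
                       noise_sd = 0.2, seed = 1)
sim <- simulate_expression(cfg)

dags_a <- call_dags(sim$a, gene_stats(sim$a))
dags_b <- call_dags(sim$b, gene_stats(sim$b))
dags_a
#> dag_sets: condition 'A', 27 time points, 49-244 DAGs per point

msm <- mapping_score_matrix(dags_a, dags_b, rownames(sim$a$expr))
msm
#> mapping_score_matrix: 27 x 27, Bonferroni m = 729, universe 2000
#>   score range [0, 87.4]

trace <- maximum_trace(msm)
summ <- summarize_mapping(trace, sim$a$meta, sim$b$meta)
head(summ, 6)
#>   a_index a_timepoint  b_span lag  class
#> 1       1         E33 E33-E45 1.0 B-lags
#> 2       2         E40 E45-E50 1.5 B-lags
#> 3       3         E45 E50-E50 1.0 B-lags
#> 4       4         E50 E50-E60 1.0 B-lags
#> 5       5         E55 E65-E65 2.0 B-lags
#> 6       6         E60 E70-E70 2.0 B-lags
attr(summ, "modal_interior_lag")
#> [1] 2
attr(summ, "class_counts")
#>      A-lags      B-lags synchronous
#>           1          24           2
```

The trace runs above the diagonal: condition A's stages map to later B
stages almost everywhere (24 of 27 "B-lags" calls), and the modal
interior lag recovers the injected two-stage shift exactly. The mapping
summary reads as "A reaches each transcriptional state about two stages
before B" — the developmental-lag signature the method is built to
detect.

The genomic arm works the same way from one seed:

```r
sw  <- data.frame(start = 8e6 + 1, end = 9e6, pop = "B")
g   <- simulate_genotypes(geno_sim_config(sweep_intervals = sw, seed = 1))$genotypes
scan <- sweep_scan(windowed_pi(g, "A", chrom_length = 2e7),
                   windowed_pi(g, "B", chrom_length = 2e7),
                   windowed_fst(g, "A", "B", chrom_length = 2e7))
scan$regions
#>   chrom   start     end pop n_windows
#> 1     1 7990001 9020000   B        99
```

The single called region covers the injected 8-9 Mb sweep and is
attributed to the correct population.

A configuration-driven runner chains the stages
(`run_pipeline(config, stages, out_dir)`, YAML config, TSV outputs, MD5
manifest; a thin command-line wrapper sits in `inst/scripts/run_pipeline.R`).

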