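# motifnet

Finding the target genes of a cis-regulatory promoter motif — and the
co-expression modules they form — directly from expression data and promoter
sequence, without ChIP experiments.

Motif *enrichment* alone identifies few targets for very common motifs: a
5–10 bp motif such as the CCAAT box (NF-Y) or the GC box (Sp1) occurs in more
than half of all human promoters, so almost no gene group is "enriched" for
it. `motifnet` implements a bottom-up alternative for genomicists and systems
biologists: functional motif occurrences pile up close to the transcription
start site (TSS), while chance occurrences spread uniformly over the
promoter, and that positional signal remains informative exactly where
enrichment saturates.

## The method

1. **Co-expression network.** Pairwise partial correlations (pcor) between
   genes are estimated from an expression matrix under a graphical Gaussian
   model, using a shrinkage correlation estimate (identity target, analytic
   intensity) so the matrix stays invertible when genes outnumber samples.
   Pairs with `pcor >= 0.04` (configurable) become network edges.

2. **Position-bias statistic.** Promoters span positions `-M..+N` around the
   TSS with repeat/transposon positions masked. If position `i` is unmasked
   in `k_i` of a group's promoters, and `K = sum(k_i)`, a motif placed
   uniformly on free positions has expected TSS distance and variance

   ```
   E(d) = sum_i (k_i / K) |i|,     V(d) = sum_i (k_i / K) i^2 - E(d)^2
   ```

   For a motif observed `n` times in the group with mean absolute distance
   `mean|x|`, the bias statistic is

   ```
   Z = (E(d) - mean|x|) / sqrt(V(d) / n)
   ```

   which is standard normal under uniform placement; large Z means the motif
   crowds toward the TSS.

3. **Seeded target calling.** Every network gene seeds a group (itself plus
   its direct neighbours). If the seed's promoter contains the motif and the
   group shows either hypergeometric motif enrichment (`p <= p_cutoff`) or
   position bias (`Z >= z_cutoff`), all motif-containing genes of the group
   are called targets.

4. **Permutation FDR.** Free promoter bases are shuffled in place (mask
   geometry kept), the scan and calling are rerun, and the FDR is the mean
   null target count over the observed target count.

5. **Modules.** The target sub-network is partitioned with Markov clustering
   (MCL), and modules are scored for term over-representation and
   TF-binding fold enrichment (exact hypergeometric tails).

Motif scanning uses JASPAR position frequency matrices, log-odds scoring on
both strands, and a per-window p-value threshold computed from the exact
score distribution by dynamic programming (POSSUM-style; default `4^-8`).

A synthetic-data module generates promoters with repeat-like masked blocks,
motif occurrences planted uniformly or TSS-biased, expression drawn from a
block-structured precision matrix, and binding tables with controlled bound
fractions — so every stage can be validated against known ground truth.

## Worked example

A planted study: 3 co-expression modules of 10 genes (within-module
pcor 0.09) among 120 genes, each module gene carrying two TSS-biased CCAAT
boxes in a 20%-masked 1 kb promoter.

```r
library(motifnet)

promoters <- generate_promoters(120, upstream = 1000, downstream = 0,
                                mask_fraction = 0.2, seed = 11)
sim <- generate_expression(module_sizes = rep(10, 3), n_background_genes = 90,
                           n_samples = 5000, within_pcor = 0.09, seed = 12)
ccaat <- pwm_from_consensus("CCAAT")
planted <- plant_motif(promoters, ccaat, genes = names(sim$truth$module_labels),
                       placement = "tss_biased", scale = 50,
                       per_gene_count = 2, seed = 13)

cfg <- nfy_config(pwm_pvalue = 4^-5, n_perm = 10, seed = 14)
run <- run_pipeline(cfg, promoters = planted$promoters, pwm = ccaat,
                    expression = sim$expression)
run
#> <pipeline run>
#>   network: 45 genes, 146 edges; motif in 103 promoters (261 hits)
#>   targets: 35 (bias 35, enrichment 0, both 0); permutation FDR 0.00%
#>   modules: 3 (largest 13)
```

The CCAAT box sits in 103 of 120 promoters (86%), so enrichment calls
nothing — every target comes from the position-bias route, recovering all
30 planted genes plus a handful of network neighbours, at zero permutation
FDR, and MCL reassembles the three planted modules. A binding table scores
like a module row of a ChIP validation:

```r
enr <- binding_fold_enrichment(run$calls$targets$gene,
                               bound = names(sim$truth$module_labels),
                               population = network_nodes(run$network))
dplyr::select(enr, annotated_module, module_size, fold, p_enrich)
#> # A tibble: 1 × 4
#>   annotated_module module_size  fold    p_enrich
#>              <int>       <int> <dbl>       <dbl>
#> 1               30          35  1.29 0.000000941
```

30 of the 35 called targets are truly planted, a 1.29-fold enrichment over
the network-wide planted fraction with an exact hypergeometric upper tail of
9.4e-7.

Every result is an ordinary tibble (or has a `tidy()`/`glance()` method), so
stages chain with the pipe; `plot_position_bias()`, `plot_pcor_distribution()`
and `autoplot()` give quick diagnostic figures. `exec/motifnet` wraps the
same pipeline for shell use (`motifnet run --config cfg.yaml ...`).

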