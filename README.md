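# regland

Melanoma cells switch between two transcriptional states — a
**proliferative** state driven by the lineage factors SOX10 and MITF, and an
**invasive** state marked by SOX9, ZEB1 and AP-1/TEAD activity — without any
underlying genetic change. The switch is written in the regulatory landscape:
thousands of enhancers gain or lose H3K27ac and open chromatin between the
states. `regland` implements the computational pipeline for decoding such
two-state systems from regulatory data, end to end:

1. **Candidate regulatory-region catalog** — merge heterogeneous feature
   tracks; remove regions overlapping insulators (≥ 20 % of the region) or
   coding exons (≥ 80 %); split partially covered regions at blacklist
   boundaries; drop fragments < 30 bp; extend survivors to 1 kb where space
   permits (`build_catalog()`).
2. **Differential activity and gene signatures** — median-of-ratios
   normalization and a per-row negative-binomial Wald test with moment
   dispersion estimates shrunk towards the matrix-wide mean; state
   signatures at |log2FC| ≥ 1 and BH-adjusted p ≤ 0.05; a two-stage region
   caller that adds a pooled binomial support filter (`nb_differential()`,
   `define_signature()`, `differential_regions()`).
3. **Master-regulator discovery** — every motif/track ranks all M catalog
   regions (best-site log-odds PWM scanning; maximum peak score for
   tracks); a foreground region set is scored by the area under its
   cumulative recovery curve over the top 0.25 % of ranks,

   `AUC_f = (1/T) Σ_{x=1..T} recovery_f(x)`, `T = ⌈0.0025·M⌉`,

   normalized across the feature collection to `NES = (AUC − μ)/σ`, with
   hypergeometric p-values (Bonferroni-corrected) and the foreground
   regions inside the cutoff as predicted direct targets
   (`enrich_features()`). Rankings from several score sources are merged
   with the uniform order-statistics `Q = N!·V_N` (`combine_rankings_orderstat()`).
4. **TF → enhancer → gene networks** — regions are assigned to genes by TSS
   distance, differential expression of the gene, and Pearson correlation
   between region activity and gene expression across samples
   (`assign_regions_to_genes()`), with pre-ranked GSEA and hypergeometric
   overlap statistics for validation (`gsea_preranked()`, `target_overlap()`).
5. **Expression-state classification** — Lee–Seung NMF over high-variance
   genes, cluster-specific signed −log10(adj. p) rankings, and
   order-statistics meta-ranking across datasets (`nmf_cluster()`,
   `cluster_gene_ranking()`, `meta_rank()`).
6. **Synthetic data with planted truth** — toy genomes, two-state NB count
   matrices, sequences with embedded motif instances and a planted
   TF → enhancer → gene network, so every stage is testable without
   downloads (`synthetic_dataset()`).

## Worked example

```r
library(regland)

ds <- synthetic_dataset(genome_spec(seed = 7))   # 2 x 10 Mb, 10,000 regions

## score the planted PWM and 50 decoys against the state-A regions
rankings <- lapply(ds$pwms, function(pw)
  rank_regions(scan_pwm(ds$sequences, pw), feature = pw$name,
               tie_seed = stage_seed(7, pw$name)))
enr <- enrich_features(rankings, ds$truth$active_regions_by_state[[1]])
head(enr$results, 3)
#>   feature  kind     auc       nes  k       pvalue         padj n_targets
#> 1    TF_A motif 0.01300 6.3946581 25 7.615070e-26 3.883686e-24        25
#> 2 decoy07 motif 0.00252 0.6372683  5 9.773484e-02 1.000000e+00         5
#> 3 decoy16 motif 0.00248 0.6152936  5 9.773484e-02 1.000000e+00         5
```

The planted regulator ranks first with NES 6.4: its recovery AUC (0.013) is
ten-fold the decoy mean, all 25 regions inside the 0.25 % cutoff are
foreground (`k = 25`), and the Bonferroni-adjusted hypergeometric p-value is
≪ 0.05. The same screen on real data ranks SOX10/E-box motifs on top of the
proliferative regions and AP-1/TEAD on top of the invasive ones.

The demo pipeline composes everything and writes per-stage JSON manifests:

```r
run_pipeline(pipeline_config(seed = 4), "demo_out")
#> demo_out/report.txt:
#>   Catalog: 5060 regions, mean length 1080.8 bp
#>   Differential regions: 207 proliferative / 199 invasive
#>   Signatures: 13 / 12 genes
#>   Top feature: TF_A (NES 3.18)
#>   Assigned regions: 97%
#>   Network 'TF_A': 6 links to 4 genes
```

A thin command-line wrapper over the same functions ships in
`inst/cli/regland` (subcommands `simulate`, `catalog`, `diff`, `enrich`,
`assign`, `classify`, `run`).

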