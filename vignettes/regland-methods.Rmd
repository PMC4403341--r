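---
title: "regland: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{regland: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`regland` decodes two transcriptional cell states — in the motivating
system, the proliferative (SOX10/MITF-high) and invasive (SOX9/ZEB1-high)
states of melanoma — from regulatory genomics data: a genome-wide catalog of
candidate regulatory regions, differential chromatin activity between the
states, motif/track enrichment that nominates master regulators, and
distance- plus correlation-based assignment of enhancers to target genes.
This vignette records the models behind each stage, the tunable parameters
and their defaults, the numerical conventions, and what the synthetic-data
module does and does not emulate.

## The candidate region catalog

All scoring operates on one fixed universe of M candidate regulatory
regions, built from heterogeneous feature tracks (open chromatin, conserved
elements, predicted modules, ...):

1. **Merge**: the union of all tracks; abutting intervals are joined
   (distance-0 join). Internally the package uses `GRanges`; all interfaces
   are 0-based half-open (BED), converted at I/O boundaries.
2. **Remove or split by blacklist**: a region whose overlap with insulator
   elements reaches 20 % of the region's length, or with coding exons 80 %,
   is removed. Smaller overlaps split the region at the blacklist
   boundaries and the covered piece is discarded. Both blacklists are
   evaluated against the pre-split region, removal before splitting. The
   thresholds are expressed as a fraction of the candidate region (not of
   the blacklist element): the removal rule is about the region's identity,
   and only the region-relative reading makes the follow-up split rule
   ("the piece containing the element is dropped") coherent. Both
   fractions are configurable.
3. **Size filter**: fragments shorter than 30 bp are dropped.
4. **Extension**: regions shorter than 1 kb are extended towards 1 kb where
   possible. The deficit is allocated symmetrically first; whatever one
   side cannot absorb (blacklist interval, neighbouring catalog region,
   chromosome end) is taken from the other side; partial extension is
   allowed, and a fully boxed-in region stays as it is. Regions are
   processed left-to-right per chromosome against the already-extended left
   neighbour, and extension stops 1 bp short of the next region. That last
   convention is what makes the construction **idempotent**: rebuilding the
   catalog from its own output changes nothing, because extension never
   creates abutting regions that a re-merge would join.

Every stage is verified, on random toy genomes up to 100 kb, against a
brute-force per-base-pair implementation (boolean coverage arrays), and the
idempotence property is asserted on the composed builder.

## Differential activity and signatures

Counts (ChIP coverage over catalog regions, or RNA-seq gene counts) are
normalized with median-of-ratios size factors. The two-state test is a
per-row negative-binomial Wald test, written as a self-contained stand-in
for an external differential caller so the pipeline has no heavyweight
dependencies; externally produced result tables can be dropped in at the
same interface.

* Dispersion: per-row method of moments within each state
  (`Var = μ + αμ²`), pooled with degrees-of-freedom weights and shrunk 50/50
  towards the matrix-wide mean dispersion. A single-sample group contributes
  no within-group variance and simply inherits the other group's estimate
  plus shrinkage (small-sample mode, used when a singleton cluster is
  contrasted against the rest).
* Fold change: `log2((μ_B + 0.5) / (μ_A + 0.5))` on normalized group means,
  always finite.
* Inference: the Wald statistic is referred to a t distribution with
  **2(n − 2)** degrees of freedom. The doubling credits the information the
  cross-row shrinkage adds to the variance estimate (the same reasoning
  behind moderated tests); with the plain `n − 2` reference the test is
  visibly conservative at the 9-vs-2 design (type-I ≈ 0.025 at α = 0.05),
  with a normal reference slightly liberal (≈ 0.06); the moderated df put
  the empirical type-I error at ≈ 0.04–0.05. BH adjustment across rows.
* Gene signatures: membership at |log2FC| ≥ 1 and adjusted p ≤ 0.05, the
  sign of the fold change assigning the state; the two signatures are
  disjoint by construction.
* Two-stage region caller: stage 1 is the NB test at (adj. p ≤ 0.05,
  |log2FC| ≥ 1); stage 2 pools size-factor-normalized counts within each
  state and requires a direction-concordant binomial deviation from the
  sample-size split at BH q ≤ 0.05, standing in for an external
  differential peak caller. `support_q ≥ 1` disables stage 2 entirely, so
  the degenerate setting reduces exactly to stage 1.

Methylation evidence is aggregated per region: per-CpG Welch t-tests at a
strict α (default 1e-10), then a two-sample t-test on per-sample region
medians for regions with ≥ 2 probes (α = 0.05); regions with fewer probes
are excluded and reported.

## Ranking-and-recovery enrichment

Each feature (motif or track) induces one complete ranking of the M
regions:

* **Motifs** are scored by the best single site: the maximum over windows
  and both strands of the summed `log2(p/q)` log-odds, with `N` bases
  contributing the background expectation of the position. This replaces a
  hidden-Markov CRM scorer deliberately: it is deterministic, exactly
  checkable against a per-window brute force, and sufficient for
  recovery-based ranking; `rank_regions()` accepts any externally computed
  score vector, so a CRM scorer can be plugged in.
* **Tracks** score a region by the maximum score of overlapping peaks
  (1-bp overlap counts), 0 without overlap.
* Ties are broken by a seeded uniform shuffle, recorded on the ranking —
  the recovery statistic is rank-sensitive, so ties must be resolved
  reproducibly but without bias.

For a foreground region set F (e.g. the regions activated in one state),
`recovery(x)` is the fraction of F found within the top x ranks; the score
is the mean of `recovery(x)` over `x = 1..T` with `T = ⌈0.0025·M⌉`
(ceiling; the cutoff fraction is a parameter). AUCs across the feature
collection are standardized to `NES = (AUC − μ)/σ`, with the population
standard deviation by default (σ is a normalizer over the fixed collection,
not an estimate of a larger population; the sample-sd variant is available).
Significance is the hypergeometric upper tail of the foreground count inside
the cutoff, Bonferroni-corrected across the collection. The foreground
regions inside the cutoff, ordered by rank, are the feature's predicted
direct-target regions, and the motif∩track intersection gives the
high-confidence set.

Rankings from several score sources for the same feature (in the original
setting, ten cross-species projections; generally, any replicate sources or
datasets) are merged per region with uniform order statistics:
`Q = N!·V_N`, `V_k = Σ_{i=1..k} (−1)^{i−1} (V_{k−i}/i!) s_{N−k+1}^i` over
the sorted rank ratios — the joint cumulative probability that N uniform
order statistics fall below the observed ratios — and regions are re-ranked
by ascending Q. The recursion is verified against Monte-Carlo joint
probabilities computed from exponential-spacing constructions of uniform
order statistics.

## Enhancer-to-gene assignment and TF networks

A link (region, gene) requires three joint filters:

* **Distance**: the gene's TSS within `max_dist` of the region, measured
  TSS-to-nearest-region-edge by default (midpoint optional). The studied
  grid is 10 kb–2 Mb; 1 Mb is the network default. Gene strand is ignored.
* **Expression**: the gene differential between the states at
  `padj ≤ ge_alpha` (grid 0.05/0.1/1; default 0.1) and |log2FC| ≥ 1 —
  non-differential genes are ignored.
* **Correlation**: Pearson r between the region's activity profile and the
  gene's expression profile across the shared samples, at `corr_min`
  (grid 0–0.7; default 0.3) in absolute or positive-only mode.

A region may link to several genes and vice versa; `closest_only` restricts
each region to its nearest qualifying gene ("closest correlated gene").
Relaxing any threshold can only add links (monotone containment over the
grid, tested), and the closest-only output is a subset of the all-genes
output.

One structural fact matters for interpreting the correlation filter: with a
two-state design of eleven samples, every state-responsive region is
correlated with every state-responsive gene, because both track the state.
The correlation filter therefore separates responsive from unresponsive
genes, but cannot by itself distinguish a region's true target from another
state gene nearby; distance does that. Accordingly the package evaluates
network recovery in closest-correlated-gene mode, which is also the
assignment the original analysis found superior to closest-gene. TF networks
restrict the link table to a factor's predicted direct-target regions;
networks are compared by hypergeometric overlap of their target-gene sets.

Network validation uses a pre-ranked GSEA statistic: running-sum ES with
hit increments ∝ |score|^p (p = 1 default, p = 0 for the unweighted form)
and miss decrements 1/(N − |S|), null by random gene sets of the same size
(1,000 seeded draws), the normalized score dividing by the mean |null ES| of
the same sign. The ES is verified against an explicit position-loop oracle
and against an independent implementation on the weighted form.

## Expression-state classification

Samples are clustered by NMF (Frobenius objective, Lee–Seung multiplicative
updates, best of 10 seeded restarts, ≤ 2,000 iterations or relative error
change < 1e-6), on log2(normalized + 1) expression restricted to genes with
standard deviation strictly above 1 — median centering is deliberately not
applied, as NMF needs non-negative input. k = 3 by default: the two
transcriptional states plus an immune-infiltration-like group that appears
as a third cluster in tumour cohorts. Samples take the argmax row of H. The
reconstruction error is non-increasing across updates (asserted per
iteration in tests). Cluster-specific rankings contrast each cluster
against the rest and score genes by sign(log2FC)·(−log10 adj. p), p floored
at 1e-300; per-dataset rankings merge through the order-statistics Q with
missing genes assigned the worst ratio 1 (conservative).

## The synthetic-data module

The generators emulate the study conditions at desk scale, and their
defaults are fixed: 2 chromosomes × 10 Mb; 10,000 tiled 500-bp regions;
2,000 genes; 9 proliferative-like vs 2 invasive-like samples; NB counts
with baseline mean 100 and dispersion 0.1; planted effects of log2FC 2;
1,000 active regions per state; one planted TF with 200 target regions
carrying sampled instances of a 10-bp high-information motif among the
1,000 state-A foreground regions; 50 Dirichlet-random decoy PWMs.

The planted network uses a geometry chosen to make edge recovery a
well-posed question under the state-correlation confound described above:
the TF's link-carrying regions cluster at 4 enhancer loci (50 regions each)
spread across the genome, each locus regulating the gene nearest its
centre — mirroring the enhancer clusters observed around state genes — and
all other planted differential genes are kept > 1 Mb from the TF's regions.
Planted truth records every active region, TF target, link and differential
gene, and serializes losslessly to JSON.

What the generators do **not** emulate: read-level sequencing noise,
GC/mappability bias, chromatin-domain structure, dispersion trends over the
mean (dispersion is shared), batch effects, and correlated backgrounds.
Passing the planted-truth suites therefore demonstrates the correctness and
calibration of the statistics under the stated model, not performance on
real libraries.

Problem sizes used by the test and acceptance suites (chosen to exercise
the study design while keeping runs desk-sized): the default dataset above
for enrichment, differential and network recovery; 2,000 rows × (9 + 2)
samples for null calibration; 100 random ≤ 100 kb genomes for the per-bp
catalog oracle; 10^6 Monte-Carlo draws for the order-statistics checks; a
30-sample, 500-gene three-cluster matrix for NMF; and a 2 × 10 Mb,
~5,000-region track-built genome for the end-to-end demo pipeline.

## Numerical conventions and edge cases

* Coordinates 0-based half-open externally, `GRanges` internally; region
  IDs are `chrom:start-end` in the external convention.
* `T = ⌈cutoff_frac · M⌉`; all-zero count rows get p = 1 and log2FC = 0;
  empty sequences and sequences shorter than the PWM score −∞; a constant
  feature collection (σ = 0) is rejected rather than normalized.
* One global seed fans out to per-stage seeds by hashing the stage name
  (`stage_seed()`); no stage consumes ambient randomness, generators
  save and restore the RNG state, and pipeline reruns are bit-identical
  (manifests carry no timestamps).
* Percentages print to the nearest integer, with one decimal kept below
  10 % where integer rounding would lose most of the signal.

## Known limitations

The NB stand-in is a two-group Wald test, not a GLM over arbitrary designs;
multi-factor or batch-corrected designs are out of scope. The PWM scanner
scores the best single site, so homotypic clusters of weak sites rank lower
than a CRM scorer would place them. GSEA FDR comes from gene-set
permutation, the only option without replicate-level data. NMF model
selection (choice of k) is not automated; k defaults to 3 and is a
parameter.
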