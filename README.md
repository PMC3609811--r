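# cisRegNet

Reconstruction of cis-transcription-regulation networks from replicate
expression profiles, with a fully seeded synthetic-data generator so the
whole workflow is testable end to end without external downloads.

The package targets the analysis style used for three-group microarray
stress experiments (control plus two exposure durations, three replicate
arrays each): differential genes are called by fluorescence signal ratio,
annotated by gene-set enrichment, and traced back to candidate upstream
regulators through promoter motif discovery, cross-species conservation
filtering, and transcription-factor (TF) database matching; the resulting
TF→target network is ranked by PageRank and spot-checked by qPCR.

## The methods

- **Differential expression.** A gene is called when its
  experimental/control mean intensity ratio is ≤ 0.67 or ≥ 1.5
  (inclusive) *and* a two-sided Welch t-test on log2 intensities gives
  p < 0.05. No multiple-testing correction is applied to the calls (a BH
  column is reported alongside).
- **Enrichment.** For a query of n genes against a set of K genes in a
  universe of N, the one-sided p-value is P(X ≥ k) for
  X ~ Hypergeometric(N, K, n) — equivalently a one-sided Fisher exact
  test; both routes are implemented and cross-checked. Reports follow the
  (K, k, k/K, p) layout with k/K to four decimals.
- **Motif discovery.** Promoters (−3000..+500 around the TSS,
  strand-aware) of differential genes form the positive set; an equal
  number of non-differential promoters (p ≥ 0.9) form the negative set.
  Candidate widths are 8/10/12/14 bp; each frequent seed word is refined
  by a deterministic fixed-point iteration, scored by the log
  likelihood-score ratio (mean best-site log-odds in positives minus
  negatives against the pooled base composition f), and the top 20 motifs
  are kept.
- **Conservation.** A two-state (conserved / non-conserved) HMM over
  multi-species promoter alignments; emissions are binomial in the number
  of species matching the reference per column; the per-position score is
  the forward–backward posterior of the conserved state, and motif
  instances are kept at mean score ≥ 0.8.
- **TF matching.** Discovered PWMs are compared to a database by maximal
  mean per-column Pearson correlation over ungapped offsets and both
  orientations, with an empirical column-shuffle null; matches need
  p ≤ 10⁻⁴ and the top 5 TFs are reported.
- **Network.** TF→target edges from surviving matched instances; core
  genes ranked by PageRank (damping 0.85, dangling mass redistributed
  uniformly); Cytoscape-loadable SIF export.
- **qPCR.** 2^−ΔΔCt relative quantification with group mean ± SD, the
  group/control ratio, and Welch-test significance stars.

## Worked example

```r
library(cisRegNet)
cfg <- simConfig(nGenes = 60, promoterWindow = c(-150, 50),
                 pwmDbSize = 6, noiseSd = 0.1, deFraction = 0.15, seed = 1)
res <- runPipeline(cfg, "run1", pMin = 0.5, nNull = 20000, pMax = 5e-4,
                   maxSeeds = 30, topN = 10)
attr(res$branches$stress7$de, "summary")
#> total    up  down
#>     9     5     4
res$branches$stress7$match$topTfs
#>      tf     p_value similarity motif_id
#> 1 TF006 4.99975e-05  0.9970093     M001
res$qpcr[res$qpcr$gene == "Fadd", ]
#>   gene    group n        rq ratio stars
#> 7 Fadd  control 9 1.00±0.10  1.00
#> 8 Fadd  stress7 9 1.50±0.16  1.50    **
#> 9 Fadd stress21 9 1.94±0.23  1.93    **
```

Nine of the sixty simulated genes carry planted fold changes; all nine are
called (5 up, 4 down). The discovered top motif matches database record
TF006 — the record the generator derived from the planted consensus — at
the empirical p-value floor. The qPCR table recovers the planted folds
(1.63 and 1.96 for the two stress groups) within sampling noise, with the
control ratio pinned at 1.00 by construction.

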