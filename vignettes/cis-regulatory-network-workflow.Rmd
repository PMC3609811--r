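---
title: "From expression profiles to a ranked cis-regulatory network"
author: "cisRegNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From expression profiles to a ranked cis-regulatory network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cisRegNet)
```

## Scope and model

cisRegNet reimplements, as a tested and reusable pipeline, a classic
microarray-era analysis: starting from a genes × samples fluorescence
intensity matrix with a control group and two treatment groups, it calls
differential genes, annotates them by gene-set enrichment, and asks which
transcription factors (TFs) plausibly drive the observed changes by
mining the differential genes' promoters. Because raw chip data for this
kind of study are often not deposited, the package ships a seeded
synthetic-data generator that produces every input the pipeline consumes
— intensities, gene sets, a genome with annotated TSSs, multi-species
promoter alignments, a TF PWM database, and qPCR Ct tables — together
with the ground truth needed to measure recovery.

## Differential expression

Calls combine two criteria, both inclusive: the linear-scale signal ratio
(experimental group mean / control group mean) must be ≤ 0.67 or ≥ 1.5,
and a two-sided Welch t-test on log2 intensities must give p < 0.05.
The Welch test was chosen because the replicate count is small (three
arrays per group) and within-group variances need not be equal; the exact
test behind the published "P < 0.05" of such analyses is typically a
proprietary array-suite score, so a standard, documented test is
preferable. Degenerate genes with zero variance in both groups get p = 1
when the means agree and p = 0 otherwise, so the ratio criterion alone
decides them. No multiple-testing correction enters the calls —
deliberate fidelity to the emulated analysis style — but a
Benjamini–Hochberg column is always reported so users can apply modern
practice. A caveat the tests make explicit: with only three replicates
the Welch–Satterthwaite df approximation is itself approximate, so the
null-uniformity calibration test uses six replicates per group.

## Enrichment

`hypergeomTail()` computes P(X ≥ k) with `phyper`; `fisherEnrichment()`
computes the same quantity independently through `fisher.test` on the
2×2 table, and the suite verifies the two agree to 1e-12 exhaustively for
every table with N ≤ 12. The universe N is a required input: it is the
set of genes on the platform, not the genome, and published tables rarely
state it — which is why printed p-values of such tables are generally not
reproducible while their k/K columns are. Reported k/K is rounded to four
decimals. Because one-sided discrete p-values are super-uniform, the
null-calibration test checks the randomised p-value
u = P(X > k) + U·P(X = k), which is exactly U(0,1) when the tail is
computed correctly.

## Promoters and the negative set

Promoters are −3000..+500 around the TSS (configurable), extracted
strand-aware with 0-based half-open genomic coordinates; minus-strand
sequences are reverse-complemented so position always increases 5'→3'
relative to the gene, and windows are clipped at contig edges with the
stored TSS offset adjusted. "Non-differential" for the negative set is
operationalised as DE p ≥ 0.9 (configurable): the source analyses say
only "p close to 1". In small simulations the p ≥ 0.9 pool (about 10% of
null genes) can be smaller than the positive set, so the examples here
pass `pMin = 0.5`; at platform scale (tens of thousands of genes) the
default is comfortable.

## Discriminative motif discovery

The objective formalises "maximum likelihood score ratio sorting" as the
difference of mean best-site log-odds between the positive and negative
sets — the log of the ratio of per-set likelihood scores under the motif
versus the pooled background composition f. The search is deterministic
by design: seeds are the most frequent w-mers present in at least 20% of
positive sequences (per width, capped at `maxSeeds`); each seed's
exact-occurrence PWM is refined by alternating best-site collection (one
site per positive sequence) with PWM re-estimation under pseudocount
ε = 0.25, stopping when the site set stabilises, when the objective would
decrease, or after `maxIter` rounds — so the accepted objective is
monotone by construction and identical inputs always give identical
output. Near-duplicate candidates (consensus alignment with ≥ w−1
matches in either orientation, any shift) are collapsed; survivors are
ranked by raw score across widths (a per-base-normalised score is
reported as an auxiliary column) and the top 20 kept. Windows containing
ambiguous bases are skipped rather than scored. Scanning covers both
strands; ties break to the smallest offset, then the plus strand.

## Conservation scoring

Real phylogenetic conservation scorers fit a substitution model over a
tree; this package deliberately replaces those emissions with a binomial
model — each of the S non-reference species matches the reference base
with probability `eCons` (0.9) in the conserved state and `eNon` (0.4)
in the non-conserved state — keeping the two-state HMM structure,
self-transitions of 0.99, and the stationary initial distribution. The
per-position score is the forward–backward posterior of the conserved
state, computed in log space, which the suite verifies against
brute-force enumeration of all 2^L state paths for L ≤ 10. Columns
containing gaps or ambiguous bases emit likelihood 1 under both states
(uninformative). An instance is kept when its mean posterior over the
site is ≥ 0.8; whether published analyses used the mean or the minimum
per-base score is typically unstated, so `stat = "min"` is available.

## PWM matching

"Motif comparison" tools differ; here similarity is the maximal mean
per-aligned-column Pearson correlation over all ungapped offsets with
full overlap of the shorter matrix, in both orientations. Zero-variance
(uniform) columns would make the correlation undefined and score 0. The
p-value is empirical: `nNull` random queries are assembled by drawing
columns uniformly from the pooled database columns and scored against a
random same-width segment of a random record;
p = (1 + #{null ≥ s}) / (1 + nNull), so the attainable floor is
1/(nNull+1) and the configuration is rejected unless that floor sits a
decade below the match cutoff (nNull ≥ 10/pMax). Matches need p ≤ 10⁻⁴
and each comparison reports its best five TFs (ties: higher similarity,
then name).

## Network and PageRank

Every surviving (conserved, matched) instance contributes a directed
TF→target edge; multi-edges collapse. PageRank runs on the joint graph
containing both TF and target nodes (damping 0.85, L1 tolerance 1e-10),
with dangling-node mass redistributed uniformly — the suite checks power
iteration against a dense linear solve on random digraphs. The core-gene
report ranks target-role nodes by default (TFs appear as the regulator
column, matching the usual presentation); `includeTfs = TRUE` ranks the
joint graph. All tie-breaks are lexicographic for determinism.

## qPCR

2^−ΔΔCt with the mean control ΔCt as calibrator; group summaries report
mean ± sample SD of RQ and the ratio of group mean RQ to control mean RQ,
which makes the control ratio exactly 1 by definition. Published tables
of this kind sometimes print ratios that are not the quotient of their
printed group means — the per-sample calculation behind them being
unrecoverable — so this package defines the ratio explicitly as above.
Significance stars (* p<0.05, ** p<0.01) come from a two-sided Welch test
on per-sample RQ; `onDdct = TRUE` tests on the ΔΔCt scale instead, which
some practitioners prefer because ΔΔCt is closer to normal.

## The generator and what passing tests mean

The generator's structural defaults follow the emulated study design:
three groups × three replicate arrays, planted linear folds drawn from
[1.5, 3], a −3000..+500 promoter window, eight non-reference species,
nine qPCR samples per group, and the published fold-change table as the
default planted qPCR folds. Intensities are log-normal
(2^(μ + effect + N(0, σ))), which makes planted folds exact on the
group-mean ratio scale; genes are spaced so promoter windows never
overlap (isolating extraction logic); alignments are match/mismatch only
(no indels), because the conservation model is column-based; the
background base composition defaults to uniform but is configurable,
since the discovery background f should be data-derived. None of this
models probe effects, normalisation artefacts, correlated noise, repeat
structure or real phylogeny — so passing recovery tests demonstrate the
pipeline's internal correctness and statistical calibration, not
performance on real chip data.

## Problem sizes and numerical choices

The statistical suites run at deliberately reduced scale chosen up
front: motif recovery uses 50 positive / 50 negative promoters of 300 bp
over 100 generator seeds; the end-to-end suite uses 60 genes, 160 bp
windows, a 6-record PWM database and a 20 000-draw matching null
(p ≤ 5×10⁻⁴, keeping the floor a decade below the cutoff) over 50 seeds.
These sizes preserve every contract being tested while keeping the whole
suite desk-scale. Numerical choices worth knowing: forward–backward is
log-space throughout; PWM pseudocounts keep log-odds finite; empirical
p-values are add-one so never 0; PageRank raises an error rather than
returning an unconverged vector; and every source of randomness flows
from a single integer seed through fixed child-seed streams, so any
reported number is reproducible bit for bit.

## Worked run

```{r, eval = FALSE}
cfg <- simConfig(nGenes = 60, promoterWindow = c(-150, 50),
                 pwmDbSize = 6, noiseSd = 0.1, deFraction = 0.15,
                 seed = 1)
res <- runPipeline(cfg, "run1", pMin = 0.5, nNull = 20000,
                   pMax = 5e-4, maxSeeds = 30, topN = 10)
attr(res$branches$stress7$de, "summary")   # total/up/down calls
res$branches$stress7$match$topTfs          # planted TF at the p floor
res$branches$stress7$coreGenes             # PageRank core-gene table
res$qpcr                                   # 2^-ddCt report with stars
```

## Known limitations

The discovery search is seed-and-refine, not EM with restarts: motifs
that never occur exactly as a frequent w-mer can be missed. Cross-width
ranking compares raw scores, which mildly favours wider motifs. The
conservation emissions ignore phylogenetic correlation between species,
so S species contribute more independent evidence than real genomes
would. The matching null treats database columns as exchangeable, which
is conservative for highly biased databases. Enrichment reports raw
p-values by design; use the BH column when screening many terms.
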