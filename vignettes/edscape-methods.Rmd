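---
title: "Detecting and interpreting RNA editing landscapes with edscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and interpreting RNA editing landscapes with edscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope and model

`edscape` implements a complete desk-scale pipeline for studying
adenosine-to-inosine (A-to-I) RNA editing across developmental stages from
single-cell RNA-seq read evidence: reliable-site detection through a filter
cascade, annotation against transcript models and interval tracks,
stage-wise differential-editing testing, trajectory clustering, and the
association between exon editing rate and exon inclusion (percent spliced
in, PSI). Because the real inputs of such studies are controlled-access
sequencing datasets, the package ships a first-class synthetic-data
generator that plants known truth at every level, so each stage — and the
pipeline end to end — is verifiable hermetically.

The package consumes *pileup-level* evidence: one row per read per
candidate site, carrying the observed allele, base and mapping quality,
read length, the site's 1-based position within the read, sequencing
strand, and the best/second-best alignment hit scores of the read. This is
deliberate: alignment, deduplication and base-quality recalibration are
upstream commodity steps, while everything scientifically distinctive about
editing-site detection operates on per-site read attributes. An adapter
from BAM pileups is an extension point, not a dependency.

# The filter cascade

Stages run in a fixed order and only ever remove sites:

1. **Candidate calling.** A site is a candidate when at least two reads
   carry a non-reference allele with base quality ≥ 25 and mapping quality
   ≥ 20 (both configurable). The best-supported mismatch allele becomes the
   working alternate.
2. **Known-SNP removal.** Candidates at cataloged SNP positions are
   dropped, *except* records whose molecular type is `cDNA` — such records
   are typically editing sites mis-deposited as SNPs, and removing them
   would delete true positives.
3. **Recurrence.** Variant support in at least two individuals is required;
   a site seen in a single sample is more plausibly a rare genomic variant.
   `single_sample = TRUE` disables this (and the two-individual support
   rule below), which is how the genotype-FDR benchmark evaluates
   per-sample calling.
4. **Strand and position bias.** Reads at a site are split into
   reference-supporting and variant-supporting groups and compared by
   two-sided Fisher exact tests on sequencing strand and on read position.
   "Position" needs a dichotomy the underlying procedure leaves open; we
   binarize at the outer 10% of the read on either end (terminal vs
   interior), a conventional chemistry-artifact zone. Per test family the
   threshold is Bonferroni-corrected: α = 0.01 divided by the number of
   sites with a computable p-value in that family. Zero-margin tables give
   `NA` and never remove a site.
5. **Paralog filter.** A variant-supporting read passes when its best
   alignment hit overlaps the site *and* its second-best score is < 95% of
   the best; reads with missing scores count as failures. The site survives
   only if passing reads strictly outnumber failing reads.
6. **Finalization.** Pooled mismatch frequency (high-quality variant reads
   over all high-quality reads, PHRED ≥ 20, pooled across samples) must be
   ≥ 0.1, and at least two individuals must each have ≥ 5 high-quality
   reads including ≥ 2 variant reads. Sites with a second alternate allele
   backed by ≥ 2 high-quality reads are excluded as multi-allelic — a
   noise-tolerant reading of "two or more variants" that one stray read
   cannot trigger. Variant types are collapsed onto canonical editing
   chemistry: `T-to-C` is `A-to-I` observed antisense, `G-to-A` is
   `C-to-U`.

Two decisions here were genuinely open. The ≥ 0.1 mismatch frequency is
computed on reads pooled across samples (the per-individual requirement is
enforced separately); a per-sample reading would conflate the two rules.
And the Bonferroni family is "all sites tested within one test type",
the most conservative interpretation consistent with correcting
"multiple-group comparisons".

# Annotation

Sites are classed `lncRNA_only`, `mRNA_only`, `overlap` (covered by
transcripts of both classes — common where lncRNAs run antisense to mRNA
loci), or `intergenic`. The splice-site label is a distance rule: a site is
splice-associated when within `splice_window_bp` (default 300 bp) of any
annotated exon boundary, measured on genomic coordinates, strand-agnostic.
This replaces score-based splice-annotation databases, which the upstream
study used only as a binary label; the window is a CLI flag and the
stand-in nature is documented output metadata. Repeat class is `Alu`,
`repetitive_nonAlu` or `nonrepetitive`, with Alu taking precedence on
overlapping tracks.

# Differential editing and trajectories

Per-sample editing ratios (high-quality variant / high-quality reads,
reported only at ≥ 5 high-quality reads, `NA` below) form a sites × samples
matrix. Each site is tested by fixed-effects one-way ANOVA across stages on
its non-missing cells; stages contributing fewer than two values are
dropped, and sites left with fewer than two usable stages are reported
untested. P-values are Benjamini–Hochberg adjusted; `q < 0.05` flags a site
differential.

Differential trajectories are clustered on per-site stage-mean curves,
z-scored so *shape*, not amplitude, drives grouping. Distances are
Euclidean and the tree is built with the package's own implementation of
the Lance–Williams recurrence (average linkage by default; single, complete
and Ward.D2 selectable), cut at k = 3, with labels renumbered by decreasing
cluster size. The recurrence implementation is cross-checked in the test
suite against both a naive group-average oracle and `stats::hclust`.

# The synthetic world

The generator's defaults state the simulated world once:

* **Design**: six stages (oocyte, zygote, 2-, 4-, 8-cell, morula) with
  3/2/3/4/11/3 samples. (The motivating study's text says "29 samples" but
  its per-stage counts sum to 26; we follow the per-stage composition.)
* **Sites**: 500 true A-to-I sites versus 150 SNV, 50 strand-artifact,
  50 position-artifact and 50 paralog confounders, all on exons of a
  miniature two-chromosome genome carrying 40 lncRNA and 40 mRNA
  transcripts (some lncRNAs antisense within mRNA loci to create the
  overlap class).
* **Coverage**: Poisson depth, mean 30; variant reads Binomial(depth,
  ratio) — the simplest model consistent with ratio-based filters.
* **Trajectories**: 70% of true sites get one of three piecewise-linear
  stage curves in proportions 0.93/0.06/0.01 — clusters 1 and 2 fall from
  0.60 and 0.35 to 0.05 at the 8-cell stage, cluster 3 rises from 0.05 to
  0.50 there; the rest are flat (non-differential) at Uniform(0.15, 0.5).
  The morula tails (0.06, 0.30, 0.35) are not constrained by the motivating
  figures, which fix only the pre-8-cell monotone run and the 8-cell
  extremum; we chose tails that differ *in shape* between clusters 1 and 2,
  because shape-standardized clustering cannot distinguish two families
  that differ only in amplitude. Per-sample biological jitter is Gaussian,
  sd 0.05.
* **Confounder signatures**: SNVs sit at ratio 0.5 or 1.0 in every sample
  and in the SNP catalog (5% of *true* sites are also cataloged with
  `MOLTYPE=cDNA` to exercise the exemption); strand artifacts put all
  variant reads on one strand; position artifacts confine variant alleles
  to the terminal 10% of reads; paralog sites give 85% of variant reads
  second-best hit scores ≥ 95% of the best.
* **Splice placement**: an mRNA true site lands in a splice window with
  probability 0.3; the lncRNA probability is derived from a planted odds
  ratio, default 2.0.
* **Exon counts**: for every exon hosting a true site, PSI is an affine map
  of a latent variable correlated with the exon's *realized* editing rate
  (ρ = 0.75 for lncRNA exons, 0.43 for mRNA by default); inclusion /
  exclusion reads (mean 200 per exon/sample) are then drawn to match that
  PSI given the effective lengths. Coupling to the realized rather than the
  true rate is what makes the noise-free ρ = 1 limit give per-exon R
  exactly 1, and keeps the recovered correlation an unbiased estimate of ρ
  rather than a binomially attenuated one. 30% of exons also receive a
  4-fold stage trend in total reads so differential-expression calls have
  planted positives.

What a green test does *not* establish: the generator has no sequencing
error model beyond quality scores, no alignment artifacts other than the
planted hit-score signature, no doublets or ambient contamination, no
transcript-level expression model (depth is independent of stage except for
planted DE exons), and the stage curves are smooth and shared within a
family. Recovery results on this world bound behavior under its stated
assumptions, not on arbitrary real data.

# Association statistics

Exon editing rate is ΣG/(ΣG+ΣA) over high-quality reads at the exon's
A-to-I sites, equivalently a depth-weighted mean of per-site ratios. PSI is
(IR/len_inc) / (IR/len_inc + ER/len_exc), `NA` under 10 supporting reads.
Per-exon Pearson correlations across samples (pairs with missing values
dropped; ≥ 3 pairs; `NA` for constant vectors) are compared between exon
groups (transcript class × splice-site status) and against a random
baseline of 10,000 (editing-rate vector, PSI vector) pairings of different
exons under a fixed seed. Group comparisons use the two-sided Mann–Whitney
U test — the underlying study reports such p-values without naming a test,
and we prefer a rank test over a t-test for bounded, skewed correlation
distributions (Welch t is flag-selectable). Note the random baseline is
*not* centered at zero: random exon pairs share the stage structure of
development, so cross-exon correlations are genuinely positive — the
synthetic world reproduces this emergent property.

Enrichment uses 2×2 odds ratios (a·d)/(b·c) with the Haldane–Anscombe 0.5
correction on zero cells and Woolf confidence intervals; chi-square tests
are computed without Yates continuity correction (convention documented in
the output), the DE-exon family uses Fisher's exact test, and every family
is repeated on the non-Alu subset.

`simple_exon_de()` is plumbing, not science: one-way ANOVA per exon on
log1p length-normalized inclusion densities with median-of-ratios size
factors (plain library-size scaling would let strongly DE exons induce
apparent shifts in flat ones — the classic composition bias), BH-corrected.
Externally supplied DE flags pass through untouched and skip the test.

# Benchmarks

`genotype_fdr()` scores single-sample calls against matched DNA genotypes:
a call is false unless the genomic genotype is homozygous reference; sites
without genotype coverage leave the denominator and are reported
separately. `knockdown_fdr()` assumes every A-to-I site surviving an
editing-enzyme (ADAR) knockdown is a false positive and reports
knockdown/control count ratios per repeat class; the generator's
`edit_scale` (≈ 0 for knockdown) produces matched run pairs in which true
editing vanishes but artifacts persist.

# Numerical and degenerate-input conventions

Fisher tests on tables with a zero margin return `NA` and never remove a
site; ANOVA on fewer than two usable stages yields an `NA` (untested)
result rather than an error; constant vectors yield `NA` correlations;
z-scoring a constant curve gives the zero vector; ties in cluster-size
relabeling break by first appearance; `cutree` operates on the package's
own `hclust`-compatible tree (all four linkages are monotone, so no
inversion handling is needed). All randomness flows from a single integer
seed; generator sub-stages use fixed small offsets from it, so every output
file is byte-reproducible.

# Known limitations

Beyond the generator's stated simplifications: the splice-site label is a
distance proxy, not a splicing-impact score; the Bonferroni family and the
terminal-read dichotomy are stated conventions rather than derived optima;
the exon DE stand-in has no dispersion model and should be replaced by
externally computed flags when a count-model pipeline is available; and the
pooled mismatch-frequency reading, while documented, is one of two
defensible interpretations.
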