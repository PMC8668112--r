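# edscape

RNA editing landscapes from single-cell RNA-seq read evidence.

`edscape` is an R package for studying adenosine-to-inosine (A-to-I) RNA
editing across developmental stages — the setting of human early-embryo
studies, where editing rates reprogram sharply at the 8-cell stage (zygotic
genome activation) and editing on long non-coding RNA (lncRNA) exons
associates with exon inclusion. It is written for computational biologists
who have per-site read evidence (pileups) rather than raw BAMs, and who
need every stage of the analysis to be testable without controlled-access
data.

It provides:

* **Reliable-site detection** — a filter cascade over read-level evidence:
  candidate calling (≥ 2 mismatched reads, base quality ≥ 25, mapping
  quality ≥ 20), known-SNP removal with the `cDNA` molecular-type
  exemption, recurrence in ≥ 2 individuals, Fisher exact strand- and
  read-position-bias tests with Bonferroni correction (α = 0.01), a
  paralog filter on best/second-best alignment hit scores (second < 95% of
  best, passing reads must outnumber failing), and finalization (pooled
  mismatch frequency ≥ 0.1, two individuals with ≥ 5 high-quality reads
  and ≥ 2 variant reads, multi-allelic exclusion). Variant types collapse
  antisense observations onto canonical chemistry: editing ratio at a site
  is *HQ variant reads / HQ reads*, and `T-to-C` ≡ `A-to-I`,
  `G-to-A` ≡ `C-to-U`.
* **Annotation** — transcript class (`lncRNA_only` / `mRNA_only` /
  `overlap` / `intergenic`), splice-site proximity (within 300 bp of an
  exon boundary by default), TFBS overlap, and repeat class with Alu
  precedence.
* **Differential editing** — per-site one-way ANOVA of editing ratio
  across stages with Benjamini–Hochberg FDR, and trajectory clustering of
  z-scored stage-mean curves via the Lance–Williams recurrence
  (average/single/complete/Ward linkage).
* **Splicing association** — exon editing rate ΣG/(ΣG+ΣA), percent spliced
  in PSI = (IR/ℓ_inc)/(IR/ℓ_inc + ER/ℓ_exc), per-exon Pearson
  correlations against a 10,000-random-pair baseline, Mann–Whitney group
  comparisons, and chi-square/Fisher enrichment odds ratios
  (Haldane-corrected) with a non-Alu stratum.
* **Benchmarks** — false-discovery rate against matched DNA genotypes, and
  knockdown-based FDR (sites surviving an ADAR knockdown / control sites,
  per repeat class).
* **A synthetic-data generator** — miniature genome, transcript models,
  planted editing trajectories (three families turning at the 8-cell
  stage), SNV / strand / position / paralog confounders, and exon counts
  whose PSI is coupled to editing rate at a configurable correlation —
  so the whole pipeline verifies hermetically.

## Worked example

```r
library(edscape)

cfg  <- sim_config(seed = 42)          # stated defaults: 500 true sites,
sim  <- simulate_dataset(cfg)          # 300 confounders, 26 samples / 6 stages
x    <- call_editing_sites(sim$evidence, sim$annotation$genome, sim$snps)
x
#> <ed_candidates> 800 sites (500 active) across 26 samples
```

All 500 planted editing sites survive the cascade and all 300 confounders
are removed (recall 1.00, empirical FDR 0.00 against the planted truth).
Annotate and test for differential editing:

```r
sites <- annotate_sites(editing_sites(x), sim$annotation)
table(sites$transcript_class)
#> lncRNA_only   mRNA_only     overlap
#>         207         236          57

mat <- build_matrix(sites, sim$design)
res <- anova_stages(mat, sim$design)
#> differential: 360 of 500 sites (72.0%)

cl <- cluster_trajectories(mat[res$site_id[res$is_differential], ],
                           sim$design, k = 3)
cl$curves[cl$curves$cluster == 1]
#>    cluster  stage  mean    sd     n
#> 1:       1 oocyte 0.587 0.088   351
#> 2:       1 zygote 0.447 0.088   351
#> 3:       1  2cell 0.315 0.063   351
#> 4:       1  4cell 0.185 0.049   351
#> 5:       1  8cell 0.058 0.038   351
#> 6:       1 morula 0.084 0.076   351
```

The dominant trajectory cluster falls from an editing ratio of ~0.59 in
oocytes to its minimum 0.058 at the 8-cell stage — the planted
reprogramming signature. Enrichment and editing–PSI coupling:

```r
enr <- enrichment_tests(merge(sites, res[, c("site_id", "is_differential")],
                              by = "site_id"))
enr[enr$subset == "all" &
    enr$comparison %in% c("lncRNA_x_splice", "mRNA_x_splice"),
    c("comparison", "a", "b", "c", "d", "odds_ratio", "p")]
#>         comparison   a   b  c   d odds_ratio        p
#> 1: lncRNA_x_splice 131 133 67 169      2.484 1.26e-06
#> 2:   mRNA_x_splice 102 191 96 111      0.617 9.21e-03

rates <- exon_editing_rate(site_sample_counts(x), sites)
meas  <- exon_measures(sim$exon_counts, rates)
cd    <- correlation_distributions(meas, exon_split_groups(sites),
                                   n_baseline = 10000)
cd$group_means
#>                 group mean_R   n
#> 1: lncRNA_nonsplicing  0.727  52
#> 2:    lncRNA_splicing  0.681  89
#> 3:      mRNA_splicing  0.410  72
#> 4:   mRNA_nonsplicing  0.399  75
# random-pair baseline mean R: 0.26
```

lncRNA sites are enriched on splice windows (OR 2.48; planted OR 2.0) and
mRNA sites depleted; the per-exon editing–PSI correlation recovers the
planted coupling (lncRNA ρ = 0.75 → mean R ≈ 0.70; mRNA ρ = 0.43 → ≈ 0.40)
above a positive random baseline — random exon pairs share developmental
stage structure, so their correlation does not center at zero.

## Command line

```sh
edscape all --config run.cfg --outdir out/        # simulate → … → benchmark
edscape simulate  --config run.cfg --outdir sim/
edscape callsites --evidence sim/evidence.tsv --genome sim/genome.fa \
                  --snps sim/snps.vcf --out sites.tsv
edscape annotate  --sites sites.tsv --gtf sim/annotation.gtf \
                  --alu sim/alu.bed --repeats sim/repeats.bed \
                  --tfbs sim/tfbs.bed
edscape diffedit  --sites sites_annotated.tsv --design sim/design.tsv
edscape benchmark genotype-fdr --sites sites.tsv \
                  --genotypes sim/genotypes.tsv
```

`edscape all` writes every stage's TSV plus `manifest.json` with per-stage
timings and md5 checksums; reruns with the same config and seed are
byte-identical.

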