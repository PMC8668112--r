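# Synthetic-data generator: determinism, planted structure, file round trips.

test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(cluster_proportions = c(0.5, 0.5, 0.5)),
               "sum to 1")
  expect_error(sim_config(n_true_sites = -1), "counts")
  expect_error(sim_config(exon_psi_editing_rho = 1.5))
})

test_that("identical seeds reproduce outputs byte for byte", {
  cfg <- small_config(seed = 7L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, outdir = d1)
  simulate_dataset(cfg, outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }
  # and a different seed changes the evidence
  d3 <- withr::local_tempdir()
  simulate_dataset(small_config(seed = 8L), outdir = d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "evidence.tsv"))),
                         unname(tools::md5sum(file.path(d3, "evidence.tsv")))))
})

test_that("planted class counts equal the configuration exactly", {
  sim <- cached_small_sim()
  cfg <- sim$config
  tab <- table(sim$truth$class)
  expect_equal(unname(tab[["true_edit"]]), cfg$n_true_sites)
  expect_equal(unname(tab[["snv"]]), cfg$n_snv_confounders)
  expect_equal(unname(tab[["strand_artifact"]]), cfg$n_strand_bias_artifacts)
  expect_equal(unname(tab[["position_artifact"]]),
               cfg$n_position_bias_artifacts)
  expect_equal(unname(tab[["paralog"]]), cfg$n_paralog_confounders)
  expect_false(anyDuplicated(sim$truth[, c("chrom", "pos")]) > 0)
})

test_that("trajectory curves turn at the 8-cell stage", {
  cv <- edscape:::trajectory_curves()
  # clusters 1-2 fall monotonically to a minimum at 8-cell
  for (ci in 1:2) {
    expect_true(all(diff(cv[ci, 1:5]) < 0))
    expect_equal(unname(which.min(cv[ci, ])), 5L)
  }
  # cluster 3 rises to a maximum at 8-cell
  expect_true(all(diff(cv[3, 1:5]) > 0))
  expect_equal(unname(which.max(cv[3, ])), 5L)
  # stated amplitudes
  expect_equal(unname(cv[1, c(1, 5)]), c(0.60, 0.05))
  expect_equal(unname(cv[2, c(1, 5)]), c(0.35, 0.05))
  expect_equal(unname(cv[3, c(1, 5)]), c(0.05, 0.50))

  sim <- cached_small_sim()
  rcols <- paste0("ratio_", embryo_stages())
  tr <- sim$truth[sim$truth$class == "true_edit" & !is.na(sim$truth$cluster)]
  rmat <- as.matrix(tr[, rcols, with = FALSE])
  amin <- apply(rmat, 1, which.min)
  amax <- apply(rmat, 1, which.max)
  expect_true(all(amin[tr$cluster %in% 1:2] == 5L))
  expect_true(all(amax[tr$cluster == 3] == 5L))
})

test_that("planted ref alleles match the genome and edits are A-to-I", {
  sim <- cached_small_sim()
  gb <- ref_alleles(sim$annotation$genome, sim$truth$chrom, sim$truth$pos)
  expect_identical(gb, sim$truth$ref)
  te <- sim$truth[sim$truth$class == "true_edit"]
  expect_true(all(paste0(te$ref, te$alt) %in% c("AG", "TC")))
})

test_that("realized editing ratios match truth within binomial error", {
  sim <- cached_small_sim()
  ct <- attr(sim$evidence, "cell_truth")
  ct <- ct[ct$class == "true_edit" & ct$depth > 0, ]
  obs <- ct$n_var / ct$depth
  tol <- 3 * sqrt(pmax(ct$true_ratio * (1 - ct$true_ratio), 1e-6) /
                    ct$depth)
  expect_gt(mean(abs(obs - ct$true_ratio) <= tol + 1e-12), 0.95)
})

test_that("confounder classes carry their designed signatures", {
  sim <- cached_small_sim()
  ev <- merge(sim$evidence,
              sim$truth[, c("chrom", "pos", "class", "ref", "alt")],
              by = c("chrom", "pos"))
  v <- ev[ev$allele == ev$alt]
  # strand artifacts: >=90% of variant reads on a single strand
  sa <- v[v$class == "strand_artifact"]
  frac <- sa[, .(f = max(mean(strand == "+"), mean(strand == "-"))),
             by = "pos"]
  expect_true(all(frac$f >= 0.9))
  # position artifacts: variant alleles confined to terminal 10%
  pa <- v[v$class == "position_artifact"]
  expect_true(all(pa$pos_in_read <= 10 | pa$pos_in_read > 90))
  # paralogs: most variant reads with second-best hit >= 95% of best
  pg <- v[v$class == "paralog"]
  expect_gt(mean(pg$second_hit_score >= 0.95 * pg$best_hit_score), 0.5)
  # snvs present in the emitted catalog, non-cDNA
  snv <- sim$truth[sim$truth$class == "snv"]
  expect_true(all(paste(snv$chrom, snv$pos) %in%
                    paste(sim$snps$chrom, sim$snps$pos)))
  expect_true(all(is.na(sim$snps$moltype[match(paste(snv$chrom, snv$pos),
                                               paste(sim$snps$chrom,
                                                     sim$snps$pos))])))
})

test_that("lncRNA splice-window enrichment realizes the planted odds ratio", {
  # Monte-Carlo over a larger planting for a tight check of the sampled OR
  cfg <- sim_config(seed = 202L, n_true_sites = 500L,
                    n_snv_confounders = 0L, n_strand_bias_artifacts = 0L,
                    n_position_bias_artifacts = 0L,
                    n_paralog_confounders = 0L)
  ors <- vapply(0:2, function(k) {
    cfg2 <- cfg; cfg2$seed <- cfg$seed + k
    ann <- generate_annotation(cfg2)
    tr <- plant_editing_sites(cfg2, ann)
    te <- tr[tr$class == "true_edit"]
    tab <- table(lnc = te$transcript_class == "lncRNA",
                 sp = te$in_splice_window)
    (tab["TRUE", "TRUE"] * tab["FALSE", "FALSE"]) /
      (tab["TRUE", "FALSE"] * tab["FALSE", "TRUE"])
  }, numeric(1))
  expect_gt(mean(ors), 2.0 / 1.5)
  expect_lt(mean(ors), 2.0 * 1.5)
})

test_that("degenerate annotation requests behave", {
  cfg <- sim_config(seed = 3L, n_lncrna = 0L, n_mrna = 0L,
                    n_true_sites = 0L, n_snv_confounders = 0L,
                    n_strand_bias_artifacts = 0L,
                    n_position_bias_artifacts = 0L,
                    n_paralog_confounders = 0L)
  ann <- generate_annotation(cfg)
  expect_length(ann$exons, 0)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_annotation_gtf(ann, path)
  expect_true(file.exists(path))
  cfg_bad <- sim_config(seed = 3L, n_lncrna = 0L, n_mrna = 0L,
                        n_true_sites = 5L)
  expect_error(plant_editing_sites(cfg_bad, ann), "exonic space")
})

test_that("GTF and BED outputs round-trip through rtracklayer", {
  sim <- cached_small_sim()
  d <- withr::local_tempdir()
  write_annotation_gtf(sim$annotation, file.path(d, "ann.gtf"))
  gr <- read_annotation_gtf(file.path(d, "ann.gtf"))
  expect_equal(length(gr), length(sim$annotation$exons))
  expect_setequal(unique(gr$transcript_class), c("lncRNA", "mRNA"))
  ex <- sim$annotation$exons
  expect_equal(sort(GenomicRanges::start(gr)),
               sort(GenomicRanges::start(ex)))
  # every transcript has >= 2 exons by construction
  expect_true(all(table(gr$transcript_id) >= 2))
  rtracklayer::export(sim$annotation$alu, file.path(d, "alu.bed"),
                      format = "bed")
  alu <- rtracklayer::import(file.path(d, "alu.bed"))
  expect_equal(GenomicRanges::start(alu),
               GenomicRanges::start(sim$annotation$alu))
})

test_that("exon PSI coupling hits its limit cases", {
  cfg <- small_config(seed = 55L, psi_count_noise = FALSE,
                      exon_psi_editing_rho = 1, exon_psi_editing_rho_mrna = 1)
  ann <- generate_annotation(cfg)
  truth <- plant_editing_sites(cfg, ann)
  ev <- simulate_read_evidence(cfg, truth)
  ec <- simulate_exon_counts(cfg, truth, ann, evidence = ev)
  px <- attr(ec, "exon_psi")
  # rho = 1, noise-free: PSI is affine in the realized rate -> R exactly 1
  rs <- px[, .(r = suppressWarnings(correlate(rate, psi))), by = "exon_id"]
  rs <- rs[!is.na(rs$r)]
  expect_true(all(abs(rs$r - 1) < 1e-9))

  # rho = 0: mean per-exon R near zero
  cfg0 <- small_config(seed = 56L, n_true_sites = 200L,
                       exon_psi_editing_rho = 0,
                       exon_psi_editing_rho_mrna = 0)
  ann0 <- generate_annotation(cfg0)
  truth0 <- plant_editing_sites(cfg0, ann0)
  ev0 <- simulate_read_evidence(cfg0, truth0)
  ec0 <- simulate_exon_counts(cfg0, truth0, ann0, evidence = ev0)
  px0 <- attr(ec0, "exon_psi")
  rs0 <- px0[, .(r = suppressWarnings(correlate(rate, psi))),
             by = "exon_id"]
  r0 <- rs0$r[!is.na(rs0$r)]
  se <- sd(r0) / sqrt(length(r0))
  expect_lt(abs(mean(r0)), 2.5 * se + 0.02)
})
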