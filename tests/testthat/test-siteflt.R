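# Filter cascade: candidate gates, SNP/cDNA exemption, recurrence, bias
# tests against the enumeration oracle, paralog rules, finalization.

test_that("candidate calling enforces the read-count and quality gates", {
  # 1 qualifying mismatch -> not a candidate
  ev <- make_reads(n_ref = 10, n_var = 1)
  x <- call_candidates(ev, ref_table(ev))
  expect_false(x$sites$pass_candidate[1])

  # 2 mismatches but one below base quality 25 -> not a candidate
  ev <- rbind(make_reads(n_ref = 10, n_var = 1, bq = 30),
              make_reads(n_ref = 0, n_var = 1, bq = 24))
  x <- call_candidates(ev, ref_table(ev))
  expect_false(x$sites$pass_candidate[1])

  # low mapping quality also disqualifies
  ev <- make_reads(n_ref = 10, n_var = 2, mq = 19)
  x <- call_candidates(ev, ref_table(ev))
  expect_false(x$sites$pass_candidate[1])

  # 3 clean mismatches -> candidate with the right alt
  ev <- make_reads(n_ref = 10, n_var = 3, bq = 30, mq = 60)
  x <- call_candidates(ev, ref_table(ev))
  expect_true(x$sites$pass_candidate[1])
  expect_identical(x$sites$alt[1], "G")

  # unknown allele symbol errors
  bad <- make_reads(n_ref = 2, n_var = 2)
  bad$allele[1] <- "N"
  expect_error(call_candidates(bad, ref_table(bad)), "allele")
})

test_that("known-SNP removal honours the cDNA exemption", {
  ev <- rbind(make_reads(pos = 100, n_ref = 5, n_var = 5),
              make_reads(pos = 200, n_ref = 5, n_var = 5),
              make_reads(pos = 300, n_ref = 5, n_var = 5))
  x <- call_candidates(ev, ref_table(ev))
  catalog <- data.table::data.table(
    chrom = "chr1", pos = c(100L, 200L),
    moltype = c(NA_character_, "cDNA"))
  x <- remove_known_snps(x, catalog)
  s <- x$sites
  expect_false(s$pass_snp[s$pos == 100])  # in catalog, no moltype
  expect_true(s$pass_snp[s$pos == 200])   # cDNA-type retained
  expect_true(s$pass_snp[s$pos == 300])   # not in catalog
})

test_that("recurrence requires two individuals unless single-sample", {
  one <- rbind(make_reads(sample_id = "s1", n_ref = 5, n_var = 5),
               make_reads(sample_id = "s2", n_ref = 10, n_var = 0))
  x <- require_recurrence(call_candidates(one, ref_table(one)))
  expect_false(x$sites$pass_recurrence[1])

  two <- rbind(make_reads(sample_id = "s1", n_ref = 5, n_var = 5),
               make_reads(sample_id = "s2", n_ref = 5, n_var = 2))
  x <- require_recurrence(call_candidates(two, ref_table(two)))
  expect_true(x$sites$pass_recurrence[1])

  x <- call_candidates(one, ref_table(one),
                       site_params(single_sample = TRUE))
  x <- require_recurrence(x)
  expect_true(x$sites$pass_recurrence[1])
})

test_that("bias-test p-values match the hypergeometric enumeration oracle", {
  # symmetric table -> p = 1
  ev <- rbind(make_reads(n_ref = 20, n_var = 0, strand = c("+", "-")),
              make_reads(n_ref = 0, n_var = 10, strand = c("+", "-")))
  x <- bias_tests(call_candidates(ev, ref_table(ev)))
  expect_equal(x$sites$p_strand[1], 1.0)

  # fully separated strands: (20,0,0,20)
  ev <- rbind(make_reads(n_ref = 20, n_var = 0, strand = "+"),
              make_reads(n_ref = 0, n_var = 20, strand = "-"))
  x <- bias_tests(call_candidates(ev, ref_table(ev)))
  expect_equal(x$sites$p_strand[1], oracle_fisher_p(20, 0, 0, 20),
               tolerance = 1e-9)

  # all variant reads terminal, all ref interior, 10 vs 10
  ev <- rbind(make_reads(n_ref = 10, n_var = 0, pos_in_read = 50),
              make_reads(n_ref = 0, n_var = 10, pos_in_read = 3))
  x <- bias_tests(call_candidates(ev, ref_table(ev)))
  expect_equal(x$sites$p_position[1], oracle_fisher_p(0, 10, 10, 0),
               tolerance = 1e-9)
  expect_lt(x$sites$p_position[1], 0.01)

  # fisher2x2 agrees with the oracle across random small tables
  set.seed(11)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(1:12, 1)), 2, 2)
    expect_equal(fisher2x2(tab),
                 oracle_fisher_p(tab[1, 1], tab[1, 2], tab[2, 1],
                                 tab[2, 2]),
                 tolerance = 1e-9)
  }
  # zero margin -> NA
  expect_true(is.na(fisher2x2(matrix(c(0, 0, 5, 5), 2, 2))))
})

test_that("Bonferroni bias filter uses the family-size threshold", {
  # 3 sites tested; threshold = 0.01/3. Site A has p_strand ~ 2.2e-4
  # (below), sites B/C are balanced (p = 1, above).
  evA <- rbind(make_reads(pos = 100, n_ref = 12, n_var = 0, strand = "+"),
               make_reads(pos = 100, n_ref = 0, n_var = 12, strand = "-"))
  evB <- make_reads(pos = 200, n_ref = 10, n_var = 10,
                    strand = c("+", "-"))
  evC <- make_reads(pos = 300, n_ref = 10, n_var = 10,
                    strand = c("+", "-"))
  ev <- rbind(evA, evB, evC)
  x <- apply_bias_filter(bias_tests(call_candidates(ev, ref_table(ev))))
  s <- x$sites
  expect_false(s$pass_bias[s$pos == 100])
  expect_true(all(s$pass_bias[s$pos != 100]))

  # NA p-values (zero-margin tables) never remove a site
  x$sites$p_strand[2] <- NA_real_
  x$sites$active <- x$sites$pass_candidate
  x2 <- apply_bias_filter(x)
  expect_true(x2$sites$pass_bias[2])
})

test_that("paralog filter applies the 95% second-hit rule read-wise", {
  # best 100 / second 94 / overlaps -> pass (94 < 95)
  ev <- make_reads(n_ref = 5, n_var = 6, best = 100, second = 94)
  x <- paralog_filter(call_candidates(ev, ref_table(ev)))
  expect_equal(x$sites$n_blat_pass[1], 6L)
  expect_true(x$sites$pass_paralog[1])

  # second = 95 -> fail (not strictly below 95%)
  ev <- make_reads(n_ref = 5, n_var = 6, best = 100, second = 95)
  x <- paralog_filter(call_candidates(ev, ref_table(ev)))
  expect_equal(x$sites$n_blat_fail[1], 6L)
  expect_false(x$sites$pass_paralog[1])

  # best hit not overlapping the site -> fail regardless of scores
  ev <- make_reads(n_ref = 5, n_var = 6, best = 100, second = 10,
                   overlaps = FALSE)
  x <- paralog_filter(call_candidates(ev, ref_table(ev)))
  expect_false(x$sites$pass_paralog[1])

  # 6 pass vs 5 fail -> kept; 5 vs 5 -> dropped (strict majority)
  ev <- rbind(make_reads(n_ref = 5, n_var = 6, best = 100, second = 50),
              make_reads(n_ref = 0, n_var = 5, best = 100, second = 99))
  x <- paralog_filter(call_candidates(ev, ref_table(ev)))
  expect_true(x$sites$pass_paralog[1])
  ev <- rbind(make_reads(n_ref = 5, n_var = 5, best = 100, second = 50),
              make_reads(n_ref = 0, n_var = 5, best = 100, second = 99))
  x <- paralog_filter(call_candidates(ev, ref_table(ev)))
  expect_false(x$sites$pass_paralog[1])

  # missing scores count as failures
  ev <- make_reads(n_ref = 5, n_var = 4, best = 100, second = 50)
  ev$second_hit_score[1:3] <- NA_real_
  x <- paralog_filter(call_candidates(ev, ref_table(ev)))
  expect_equal(x$sites$n_blat_fail[1], 3L)
})

test_that("finalization enforces frequency, support and bi-allelism", {
  # pooled 4/50 = 0.08 < 0.1 -> dropped by frequency
  ev <- rbind(make_reads(sample_id = "s1", n_ref = 23, n_var = 2),
              make_reads(sample_id = "s2", n_ref = 23, n_var = 2))
  x <- finalize_sites(call_candidates(ev, ref_table(ev)))
  expect_equal(x$sites$pooled_freq[1], 4 / 50)
  expect_false(x$sites$pass_frequency[1])

  # two samples with 6 HQ / 3 HQ-var each -> kept on all finalization rules
  ev <- rbind(make_reads(sample_id = "s1", n_ref = 3, n_var = 3),
              make_reads(sample_id = "s2", n_ref = 3, n_var = 3))
  x <- finalize_sites(call_candidates(ev, ref_table(ev)))
  s <- x$sites
  expect_true(s$pass_frequency[1] && s$pass_support[1] &&
                s$pass_biallelic[1])
  expect_equal(s$pooled_freq[1], 0.5)

  # only one strong sample -> support rule fails
  ev <- rbind(make_reads(sample_id = "s1", n_ref = 3, n_var = 5),
              make_reads(sample_id = "s2", n_ref = 3, n_var = 1))
  x <- finalize_sites(call_candidates(ev, ref_table(ev)))
  expect_false(x$sites$pass_support[1])

  # second alternate with >=2 HQ reads -> multi-allelic, dropped
  ev <- make_reads(n_ref = 10, n_var = 10)
  ev2 <- make_reads(n_ref = 0, n_var = 2, alt = "C")
  x <- finalize_sites(call_candidates(rbind(ev, ev2), ref_table(ev)))
  expect_false(x$sites$pass_biallelic[1])
  # ...but a single stray read is tolerated
  ev3 <- make_reads(n_ref = 0, n_var = 1, alt = "C")
  x <- finalize_sites(call_candidates(rbind(ev, ev3), ref_table(ev)))
  expect_true(x$sites$pass_biallelic[1])
})

test_that("variant types collapse antisense pairs onto canonical editing", {
  mk <- function(ref, alt, pos) {
    make_reads(pos = pos, n_ref = 5, n_var = 5, ref = ref, alt = alt)
  }
  ev <- rbind(mk("A", "G", 100), mk("T", "C", 200), mk("G", "A", 300),
              mk("C", "T", 400), mk("A", "C", 500))
  refs <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L, 500L),
                     ref = c("A", "T", "G", "C", "A"))
  x <- finalize_sites(call_candidates(ev, refs))
  s <- x$sites[order(x$sites$pos)]
  expect_equal(s$variant_type,
               c("A-to-G", "T-to-C", "G-to-A", "C-to-T", "A-to-C"))
  expect_equal(s$canonical_type,
               c("A-to-I", "A-to-I", "C-to-U", "C-to-U", "other"))
})

test_that("per-sample editing ratios respect the coverage mask", {
  ev <- rbind(make_reads(sample_id = "s1", n_ref = 6, n_var = 4),
              make_reads(sample_id = "s2", n_ref = 2, n_var = 1))
  x <- finalize_sites(call_candidates(ev, ref_table(ev)))
  ps <- site_sample_counts(x, active_only = FALSE)
  expect_equal(ps$ratio[ps$sample_id == "s1"], 0.4)
  expect_true(is.na(ps$ratio[ps$sample_id == "s2"]))  # 3 HQ reads < 5
})

test_that("the cascade shrinks monotonically and skipping stages relaxes it", {
  sim <- cached_small_sim()
  x <- call_editing_sites(sim$evidence, sim$annotation$genome, sim$snps)
  s <- x$sites
  flags <- c("pass_candidate", "pass_snp", "pass_recurrence", "pass_bias",
             "pass_paralog", "pass_frequency", "pass_support",
             "pass_biallelic")
  surv <- nrow(s)
  for (fl in flags) {
    surv_next <- sum(apply(
      as.data.frame(s)[, flags[seq_len(which(flags == fl))], drop = FALSE],
      1, function(r) all(r %in% c(TRUE, NA))))
    expect_lte(surv_next, surv)
    surv <- surv_next
  }
  expect_equal(sum(s$active), surv)

  n_full <- sum(s$active)
  for (sk in c("snp", "recurrence", "bias", "paralog")) {
    xs <- call_editing_sites(sim$evidence, sim$annotation$genome,
                             sim$snps, skip = sk)
    expect_gte(sum(xs$sites$active), n_full)
  }
})

test_that("the cascade recovers planted truth on the small dataset", {
  sim <- cached_small_sim()
  x <- call_editing_sites(sim$evidence, sim$annotation$genome, sim$snps)
  called <- editing_sites(x, wide_ratios = FALSE)
  m <- merge(called[, c("chrom", "pos")],
             sim$truth[, c("chrom", "pos", "class")],
             by = c("chrom", "pos"), all.x = TRUE)
  recall <- sum(m$class %in% "true_edit") /
    sum(sim$truth$class == "true_edit")
  fdr <- mean(!m$class %in% "true_edit")
  expect_gte(recall, 0.90)
  expect_lte(fdr, 0.10)  # small-n guard; the full-size bound is tested in
                         # the acceptance suite at 0.05
})
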