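## Candidate-to-reliable editing-site filter cascade.
##
## Stages, in order: (1) candidate calling — >=2 mismatched reads with base
## quality >=25 and mapping quality >=20; (2) known-SNP removal, exempting
## catalog records of molecular type cDNA; (3) recurrence — variant support
## in >=2 individuals; (4) strand and read-position bias Fisher tests with
## Bonferroni correction at alpha 0.01; (5) paralog filter on alignment
## best/second-best hit scores (reads pass when the best hit overlaps the
## site and the second-best score is <95 percent of the best; the site is
## kept when passing reads outnumber failing reads); (6) finalization —
## pooled mismatch frequency >=0.1, >=2 individuals with >=5 high-quality
## (PHRED >=20) reads of which >=2 support the variant, multi-allelic sites
## excluded. Every stage only removes sites.

#' Filter-cascade parameters
#'
#' @param min_bq minimum base quality for a mismatched read to count toward
#'   candidacy (default 25).
#' @param min_mq minimum mapping quality (default 20).
#' @param hq_bq base-quality cutoff defining "high-quality" reads used for
#'   editing ratios and finalization (default 20).
#' @param min_freq minimum pooled mismatch frequency (default 0.1).
#' @param alpha per-family significance level for the bias tests before
#'   Bonferroni correction (default 0.01).
#' @param terminal_frac fraction of the read length at either end counted
#'   as "terminal" for the position-bias dichotomy (default 0.1).
#' @param blat_ratio second-best/best score ratio above which a read fails
#'   the paralog criterion (default 0.95).
#' @param min_hq_reads,min_hq_var per-individual finalization support
#'   thresholds (defaults 5 and 2).
#' @param min_support_samples individuals that must meet the support
#'   thresholds (default 2).
#' @param min_coverage high-quality reads required before a per-sample
#'   editing ratio is reported (default 5; below it the ratio is NA).
#' @param single_sample disable the multi-sample requirements (recurrence
#'   and the two-individual support rule), as done when evaluating FDR on a
#'   single sample against matched genotypes.
#' @return List of class `site_params`.
#' @export
site_params <- function(min_bq = 25L, min_mq = 20L, hq_bq = 20L,
                        min_freq = 0.1, alpha = 0.01, terminal_frac = 0.1,
                        blat_ratio = 0.95, min_hq_reads = 5L,
                        min_hq_var = 2L, min_support_samples = 2L,
                        min_coverage = 5L, single_sample = FALSE) {
  p <- as.list(environment())
  if (p$single_sample) p$min_support_samples <- 1L
  structure(p, class = "site_params")
}

#' Call candidate sites from read evidence
#'
#' A position is a candidate when at least two reads carry a non-reference
#' allele with base quality >= `min_bq` and mapping quality >= `min_mq`.
#' The most-supported non-reference allele becomes the working alternate.
#'
#' @param evidence evidence table (see [read_evidence()]).
#' @param ref reference genome (`DNAStringSet`) or data.frame with `chrom`,
#'   `pos`, `ref` giving the reference allele per site.
#' @param params a [site_params()].
#' @return Object of class `ed_candidates` bundling the per-site table
#'   (`$sites`), per-site/sample summaries (`$persample`), the evidence and
#'   the parameters. `$sites$active` tracks survival through the cascade.
#' @export
call_candidates <- function(evidence, ref, params = site_params()) {
  evidence <- data.table::as.data.table(evidence)
  check_columns(evidence, EVIDENCE_COLUMNS, "evidence table")
  if (!all(evidence$allele %in% c("A", "C", "G", "T"))) {
    stop("unknown allele symbol in evidence (expected A/C/G/T)")
  }
  sites <- unique(evidence[, .(chrom, pos)])
  data.table::setorder(sites, chrom, pos)
  sites[, ref := ref_alleles(ref, chrom, pos)]

  ev <- merge(evidence, sites, by = c("chrom", "pos"))
  ev[, qual_mm := allele != ref & base_qual >= params$min_bq &
       map_qual >= params$min_mq]
  ev[, hq := base_qual >= params$hq_bq]

  # working alternate = best-supported qualifying mismatch allele;
  # runner-up allele retained for the multi-allelic exclusion
  alt_counts <- ev[qual_mm == TRUE, .N, by = .(chrom, pos, allele)]
  data.table::setorder(alt_counts, chrom, pos, -N, allele)
  tops <- alt_counts[, .(alt = allele[1], n_alt_qual = N[1],
                         alt2 = if (.N > 1) allele[2] else NA_character_),
                     by = .(chrom, pos)]
  sites <- merge(sites, tops, by = c("chrom", "pos"), all.x = TRUE)
  sites[is.na(n_alt_qual), n_alt_qual := 0L]
  n_mm <- ev[qual_mm == TRUE, .(n_qual_mm = .N), by = .(chrom, pos)]
  sites <- merge(sites, n_mm, by = c("chrom", "pos"), all.x = TRUE)
  sites[is.na(n_qual_mm), n_qual_mm := 0L]

  ev <- merge(ev, sites[, .(chrom, pos, alt, alt2)], by = c("chrom", "pos"))
  ev[, is_ref := allele == ref]
  ev[, is_var := !is.na(alt) & allele == alt]

  persample <- ev[, .(
    n_reads = .N,
    n_var_qual = sum(is_var & base_qual >= params$min_bq &
                       map_qual >= params$min_mq),
    n_hq = sum(hq),
    n_hq_ref = sum(hq & is_ref),
    n_hq_var = sum(hq & is_var)
  ), by = .(chrom, pos, sample_id)]
  hq_alt2 <- ev[!is.na(alt2) & allele == alt2 & hq == TRUE,
                .(n_hq_alt2 = .N), by = .(chrom, pos)]
  sites <- merge(sites, hq_alt2, by = c("chrom", "pos"), all.x = TRUE)
  sites[is.na(n_hq_alt2), n_hq_alt2 := 0L]

  sites[, pass_candidate := n_qual_mm >= 2L]
  sites[, active := pass_candidate]
  data.table::setorder(sites, chrom, pos)

  structure(list(sites = sites, persample = persample, evidence = ev,
                 params = params),
            class = "ed_candidates")
}

#' @export
print.ed_candidates <- function(x, ...) {
  cat(sprintf("<ed_candidates> %d sites (%d active) across %d samples\n",
              nrow(x$sites), sum(x$sites$active),
              length(unique(x$persample$sample_id))))
  invisible(x)
}

#' Remove candidates present in a known-SNP catalog
#'
#' A candidate is removed when its position is in the catalog, unless the
#' record's molecular type is `cDNA` (such records are putative editing
#' sites mis-deposited as SNPs and are retained).
#'
#' @param x an `ed_candidates` object.
#' @param snp_catalog data.table from [read_snp_catalog()] (columns
#'   `chrom`, `pos`, `moltype`).
#' @return The object with `pass_snp` flags set and failing sites
#'   deactivated.
#' @export
remove_known_snps <- function(x, snp_catalog) {
  stopifnot(inherits(x, "ed_candidates"))
  snp_catalog <- data.table::as.data.table(snp_catalog)
  check_columns(snp_catalog, c("chrom", "pos"), "SNP catalog")
  if (!"moltype" %in% names(snp_catalog)) {
    snp_catalog[, moltype := NA_character_]
  }
  hit <- snp_catalog[x$sites, on = c("chrom", "pos")]
  in_cat <- !is.na(hit$moltype) | site_key(hit$chrom, hit$pos) %in%
    site_key(snp_catalog$chrom, snp_catalog$pos)
  exempt <- !is.na(hit$moltype) & hit$moltype == "cDNA"
  x$sites[, pass_snp := ifelse(active, !(in_cat & !exempt), NA)]
  x$sites[, active := active & pass_snp %in% TRUE]
  x
}

#' Require variant support in at least two individuals
#'
#' Keeps a site only when >=2 distinct samples each contribute >=1
#' variant-supporting read passing the candidacy quality gates. Disabled
#' when `single_sample` was set in [site_params()].
#'
#' @param x an `ed_candidates` object.
#' @return The object with `pass_recurrence` flags set.
#' @export
require_recurrence <- function(x) {
  stopifnot(inherits(x, "ed_candidates"))
  if (x$params$single_sample) {
    x$sites[, pass_recurrence := ifelse(active, TRUE, NA)]
    return(x)
  }
  supp <- x$persample[n_var_qual >= 1L, .(n_supp = .N), by = .(chrom, pos)]
  m <- supp[x$sites, on = c("chrom", "pos")]
  ok <- !is.na(m$n_supp) & m$n_supp >= 2L
  x$sites[, pass_recurrence := ifelse(active, ok, NA)]
  x$sites[, active := active & pass_recurrence %in% TRUE]
  x
}

#' Strand and read-position bias tests
#'
#' Reads spanning each active site are split into a reference-supporting
#' and a variant-supporting group; a two-sided Fisher exact test compares
#' the groups on sequencing strand (+/-) and on read position (terminal =
#' within the outer `terminal_frac` of the read on either end, vs
#' interior). Tables with a zero margin give `NA`.
#'
#' @param x an `ed_candidates` object.
#' @return The object with `p_strand` and `p_position` columns filled for
#'   active sites.
#' @export
bias_tests <- function(x) {
  stopifnot(inherits(x, "ed_candidates"))
  tf <- x$params$terminal_frac
  ev <- x$evidence[(is_ref | is_var)]
  ev[, terminal := pos_in_read <= ceiling(tf * read_len) |
       pos_in_read > read_len - ceiling(tf * read_len)]
  counts <- ev[, .(
    rp = sum(is_ref & strand == "+"), rm = sum(is_ref & strand == "-"),
    vp = sum(is_var & strand == "+"), vm = sum(is_var & strand == "-"),
    rt = sum(is_ref & terminal), ri = sum(is_ref & !terminal),
    vt = sum(is_var & terminal), vi = sum(is_var & !terminal)
  ), by = .(chrom, pos)]
  m <- counts[x$sites[, .(chrom, pos, active)], on = c("chrom", "pos")]
  n <- nrow(m)
  p_str <- rep(NA_real_, n)
  p_pos <- rep(NA_real_, n)
  for (i in which(m$active)) {
    if (m$vp[i] + m$vm[i] == 0) {
      warning(sprintf("site %s:%d has no variant-supporting reads",
                      m$chrom[i], m$pos[i]))
      next
    }
    p_str[i] <- fisher2x2(matrix(c(m$rp[i], m$rm[i], m$vp[i], m$vm[i]),
                                 2, 2, byrow = TRUE))
    p_pos[i] <- fisher2x2(matrix(c(m$rt[i], m$ri[i], m$vt[i], m$vi[i]),
                                 2, 2, byrow = TRUE))
  }
  x$sites[, p_strand := p_str[match(site_key(chrom, pos),
                                    site_key(m$chrom, m$pos))]]
  x$sites[, p_position := p_pos[match(site_key(chrom, pos),
                                      site_key(m$chrom, m$pos))]]
  x
}

#' Remove sites with a significant strand or position bias
#'
#' Within each test family the Bonferroni threshold is `alpha` divided by
#' the number of sites with a computable (non-NA) p-value in that family;
#' a site significant in either family is flagged a false positive and
#' removed. `NA` p-values (zero-margin tables) never remove a site.
#'
#' @param x an `ed_candidates` object with [bias_tests()] computed.
#' @param alpha overrides the configured family alpha when given.
#' @return The object with `pass_bias` flags set.
#' @export
apply_bias_filter <- function(x, alpha = NULL) {
  stopifnot(inherits(x, "ed_candidates"))
  if (!"p_strand" %in% names(x$sites)) {
    stop("run bias_tests() before apply_bias_filter()")
  }
  alpha <- alpha %||% x$params$alpha
  act <- x$sites$active
  n_str <- sum(act & !is.na(x$sites$p_strand))
  n_pos <- sum(act & !is.na(x$sites$p_position))
  thr_str <- if (n_str > 0) alpha / n_str else 0
  thr_pos <- if (n_pos > 0) alpha / n_pos else 0
  bad <- (!is.na(x$sites$p_strand) & x$sites$p_strand < thr_str) |
    (!is.na(x$sites$p_position) & x$sites$p_position < thr_pos)
  x$sites[, pass_bias := ifelse(active, !bad, NA)]
  x$sites[, active := active & pass_bias %in% TRUE]
  x
}

#' Paralog filter on alignment hit scores
#'
#' Each variant-supporting read passes when its best hit overlaps the site
#' and its second-best score is < `blat_ratio` times the best score; reads
#' with missing scores count as failures. The site is kept only when
#' passing reads strictly outnumber failing reads.
#'
#' @param x an `ed_candidates` object.
#' @return The object with `n_blat_pass`, `n_blat_fail` and `pass_paralog`
#'   set.
#' @export
paralog_filter <- function(x) {
  stopifnot(inherits(x, "ed_candidates"))
  br <- x$params$blat_ratio
  ev <- x$evidence[is_var == TRUE]
  ev[, pass := !is.na(best_hit_score) & !is.na(second_hit_score) &
       best_hit_overlaps_site %in% TRUE &
       second_hit_score < br * best_hit_score]
  counts <- ev[, .(n_blat_pass = sum(pass), n_blat_fail = sum(!pass)),
               by = .(chrom, pos)]
  m <- counts[x$sites, on = c("chrom", "pos")]
  x$sites[, n_blat_pass := ifelse(is.na(m$n_blat_pass), 0L, m$n_blat_pass)]
  x$sites[, n_blat_fail := ifelse(is.na(m$n_blat_fail), 0L, m$n_blat_fail)]
  x$sites[, pass_paralog := ifelse(active, n_blat_pass > n_blat_fail, NA)]
  x$sites[, active := active & pass_paralog %in% TRUE]
  x
}

#' Finalize reliable editing sites
#'
#' Keeps sites whose pooled mismatch frequency (high-quality variant reads
#' over all high-quality reads, pooled across samples) is >= `min_freq`
#' and which have >= `min_support_samples` individuals with >=
#' `min_hq_reads` high-quality reads including >= `min_hq_var` variant
#' reads; drops multi-allelic sites (a second alternate allele backed by
#' >=2 high-quality reads). Assigns `variant_type` (e.g. `A-to-G`) and
#' `canonical_type` after antisense collapse (`T-to-C` is `A-to-I` read on
#' the opposite strand; `G-to-A` likewise maps to `C-to-U`).
#'
#' @param x an `ed_candidates` object.
#' @return The object with finalization flags, types, pooled frequency and
#'   per-sample editing ratios computed.
#' @export
finalize_sites <- function(x) {
  stopifnot(inherits(x, "ed_candidates"))
  p <- x$params
  pooled <- x$persample[, .(hq_total = sum(n_hq), hq_var = sum(n_hq_var)),
                        by = .(chrom, pos)]
  pooled[, pooled_freq := ifelse(hq_total > 0, hq_var / hq_total, NA_real_)]
  supp <- x$persample[n_hq >= p$min_hq_reads & n_hq_var >= p$min_hq_var,
                      .(n_support_samples = .N), by = .(chrom, pos)]
  m1 <- pooled[x$sites, on = c("chrom", "pos")]
  m2 <- supp[x$sites, on = c("chrom", "pos")]
  x$sites[, pooled_freq := m1$pooled_freq]
  x$sites[, n_support_samples := ifelse(is.na(m2$n_support_samples), 0L,
                                        m2$n_support_samples)]
  x$sites[, pass_frequency := ifelse(active,
                                     !is.na(pooled_freq) &
                                       pooled_freq >= p$min_freq, NA)]
  x$sites[, pass_support := ifelse(active,
                                   n_support_samples >=
                                     p$min_support_samples, NA)]
  x$sites[, pass_biallelic := ifelse(active, n_hq_alt2 < 2L, NA)]
  x$sites[, active := active & pass_frequency %in% TRUE &
            pass_support %in% TRUE & pass_biallelic %in% TRUE]
  x$sites[, variant_type := ifelse(is.na(alt), NA_character_,
                                   paste0(ref, "-to-", alt))]
  x$sites[, canonical_type := data.table::fcase(
    variant_type %in% c("A-to-G", "T-to-C"), "A-to-I",
    variant_type %in% c("C-to-T", "G-to-A"), "C-to-U",
    default = "other")]
  x$persample[, ratio := ifelse(n_hq_ref + n_hq_var >= p$min_coverage,
                                n_hq_var / (n_hq_ref + n_hq_var), NA_real_)]
  x
}

#' Run the whole cascade
#'
#' Applies [call_candidates()], [remove_known_snps()],
#' [require_recurrence()], [bias_tests()] + [apply_bias_filter()],
#' [paralog_filter()] and [finalize_sites()] in order. Stages named in
#' `skip` are left out (their flags stay NA), which only ever enlarges the
#' surviving set.
#'
#' @param evidence evidence table.
#' @param ref reference genome or allele table.
#' @param snp_catalog SNP catalog (NULL skips the SNP stage).
#' @param params a [site_params()].
#' @param skip character subset of
#'   `c("snp", "recurrence", "bias", "paralog", "frequency", "support",
#'   "multiallelic")`.
#' @return A finalized `ed_candidates` object.
#' @export
call_editing_sites <- function(evidence, ref, snp_catalog = NULL,
                               params = site_params(), skip = character()) {
  if (length(skip)) {
    skip <- match.arg(skip, c("snp", "recurrence", "bias", "paralog",
                              "frequency", "support", "multiallelic"),
                      several.ok = TRUE)
  }
  x <- call_candidates(evidence, ref, params)
  if (!"snp" %in% skip && !is.null(snp_catalog)) {
    x <- remove_known_snps(x, snp_catalog)
  }
  if (!"recurrence" %in% skip) x <- require_recurrence(x)
  if (!"bias" %in% skip) {
    x <- bias_tests(x)
    x <- apply_bias_filter(x)
  }
  if (!"paralog" %in% skip) x <- paralog_filter(x)
  x <- finalize_sites(x)
  # optional un-gating of individual finalization rules
  if (length(intersect(skip, c("frequency", "support", "multiallelic")))) {
    s <- x$sites
    keep <- s$pass_candidate
    for (fl in c("pass_snp", "pass_recurrence", "pass_bias",
                 "pass_paralog")) {
      if (fl %in% names(s)) keep <- keep & (is.na(s[[fl]]) | s[[fl]])
    }
    if (!"frequency" %in% skip) keep <- keep & s$pass_frequency %in% TRUE
    if (!"support" %in% skip) keep <- keep & s$pass_support %in% TRUE
    if (!"multiallelic" %in% skip) keep <- keep & s$pass_biallelic %in% TRUE
    x$sites[, active := keep]
  }
  x
}

#' Extract the finalized editing-site table
#'
#' @param x a finalized `ed_candidates` object.
#' @param wide_ratios append one `ratio_<sample>` column per sample
#'   (default TRUE).
#' @return data.table of surviving sites with coordinates, alleles, types,
#'   all filter flags and (optionally) per-sample editing ratios.
#' @export
editing_sites <- function(x, wide_ratios = TRUE) {
  stopifnot(inherits(x, "ed_candidates"))
  out <- x$sites[active == TRUE]
  out <- data.table::copy(out)
  out[, site_id := site_key(chrom, pos)]
  if (wide_ratios && nrow(out)) {
    ps <- x$persample[site_key(chrom, pos) %in% out$site_id,
                      .(chrom, pos, col = paste0("ratio_", sample_id),
                        ratio)]
    ratios <- data.table::dcast(ps, chrom + pos ~ col, value.var = "ratio")
    out <- merge(out, ratios, by = c("chrom", "pos"), all.x = TRUE)
  }
  data.table::setorder(out, chrom, pos)
  out[]
}

#' Per-site, per-sample read-support table
#'
#' High-quality reference/variant read counts and the resulting editing
#' ratio for every candidate site and sample; downstream exon editing
#' rates pool these counts.
#'
#' @param x an `ed_candidates` object (finalized for ratios).
#' @param active_only restrict to surviving sites (default TRUE).
#' @return data.table with `chrom`, `pos`, `sample_id`, read counts and
#'   `ratio`.
#' @export
site_sample_counts <- function(x, active_only = TRUE) {
  stopifnot(inherits(x, "ed_candidates"))
  ps <- x$persample
  if (active_only) {
    keep <- x$sites[active == TRUE, .(chrom, pos)]
    ps <- ps[keep, on = c("chrom", "pos"), nomatch = 0L]
  }
  data.table::copy(ps)[]
}
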