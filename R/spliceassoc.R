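## Exon editing rates, PSI, editing-splicing correlation and enrichment
## contingency tests.

#' Percent spliced in (PSI)
#'
#' PSI = (IR/inclusion_len) / (IR/inclusion_len + ER/exclusion_len), the
#' length-normalized fraction of transcripts including the exon; NA when
#' the exon has fewer than `min_reads` supporting reads in the sample.
#'
#' @param inclusion_reads,exclusion_reads read counts (vectors recycle).
#' @param inclusion_len,exclusion_len effective lengths (must be > 0).
#' @param min_reads minimum IR+ER before PSI is reported (default 10).
#' @return Numeric vector of PSI values in [0, 1] or NA.
#' @export
compute_psi <- function(inclusion_reads, exclusion_reads, inclusion_len,
                        exclusion_len, min_reads = 10) {
  if (any(inclusion_len <= 0) || any(exclusion_len <= 0)) {
    stop("effective lengths must be positive")
  }
  ir <- inclusion_reads / inclusion_len
  er <- exclusion_reads / exclusion_len
  psi <- ir / (ir + er)
  psi[inclusion_reads + exclusion_reads < min_reads] <- NA_real_
  psi
}

#' Exon editing rates from site-level read support
#'
#' The editing rate of an exon in a sample is the total number of edited
#' (G) high-quality reads divided by the total of edited plus unedited (A)
#' high-quality reads, pooled over the A-to-I sites the exon hosts; NA on a
#' zero denominator.
#'
#' @param site_counts per-site/sample counts from [site_sample_counts()]
#'   (`chrom`, `pos`, `sample_id`, `n_hq_ref`, `n_hq_var`).
#' @param site_annotation annotated site table carrying `chrom`, `pos`,
#'   `exon_ids` and `canonical_type`; only `A-to-I` sites contribute.
#' @return data.table with `exon_id`, `sample_id`, `g`, `a`, `rate`.
#' @export
exon_editing_rate <- function(site_counts, site_annotation) {
  check_columns(site_counts, c("chrom", "pos", "sample_id", "n_hq_ref",
                               "n_hq_var"), "site counts")
  check_columns(site_annotation, c("chrom", "pos", "exon_ids",
                                   "canonical_type"), "annotated sites")
  ann <- data.table::as.data.table(site_annotation)
  ann <- ann[canonical_type == "A-to-I" & !is.na(exon_ids)]
  if (nrow(ann) == 0) {
    return(data.table::data.table(exon_id = character(),
                                  sample_id = character(), g = integer(),
                                  a = integer(), rate = numeric()))
  }
  map <- ann[, .(exon_id = strsplit(exon_ids, ",", fixed = TRUE)[[1]]),
             by = .(chrom, pos)]
  sc <- data.table::as.data.table(site_counts)
  joined <- merge(sc, map, by = c("chrom", "pos"),
                  allow.cartesian = TRUE)
  out <- joined[, .(g = sum(n_hq_var), a = sum(n_hq_ref)),
                by = .(exon_id, sample_id)]
  out[, rate := ifelse(g + a > 0, g / (g + a), NA_real_)]
  data.table::setorder(out, exon_id, sample_id)
  out[]
}

#' Pearson correlation with pairwise-complete observations
#'
#' @param x,y numeric vectors of equal length; pairs with either value NA
#'   are dropped. Returns NA with fewer than `min_pairs` usable pairs or
#'   when either vector is constant.
#' @param min_pairs minimum usable pairs (default 3).
#' @return Pearson R or NA.
#' @export
correlate <- function(x, y, min_pairs = 3L) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < min_pairs) return(NA_real_)
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) return(NA_real_)
  cor(x[ok], y[ok], method = "pearson")
}

#' Per-exon, per-sample measures: PSI, editing rate, expression
#'
#' Joins exon counts with exon editing rates; the expression proxy is the
#' log1p of the length-normalized inclusion count scaled to a per-kilobase
#' rate.
#'
#' @param exon_counts table from [simulate_exon_counts()] or
#'   a TSV in the same schema.
#' @param rates result of [exon_editing_rate()].
#' @param min_reads PSI coverage minimum (default 10).
#' @return data.table with `exon_id`, `transcript_class`, `sample_id`,
#'   counts, `psi`, `rate`, `expression_level`.
#' @export
exon_measures <- function(exon_counts, rates, min_reads = 10) {
  ec <- data.table::as.data.table(exon_counts)
  check_columns(ec, c("exon_id", "transcript_class", "sample_id",
                      "inclusion_reads", "exclusion_reads",
                      "inclusion_len", "exclusion_len"), "exon counts")
  m <- data.table::copy(ec)
  m[, psi := compute_psi(inclusion_reads, exclusion_reads, inclusion_len,
                         exclusion_len, min_reads = min_reads)]
  m[, expression_level := log1p(1000 * inclusion_reads / inclusion_len)]
  m <- merge(m, rates[, .(exon_id, sample_id, rate)],
             by = c("exon_id", "sample_id"), all.x = TRUE)
  data.table::setorder(m, exon_id, sample_id)
  m[]
}

#' Compare editing-measure correlation distributions between exon groups
#'
#' Computes the per-exon Pearson correlation between editing rate and
#' `what` (PSI or expression), groups exons by transcript class x
#' splice-site status, and compares each group's correlation distribution
#' to a random baseline built from `n_baseline` random (editing-rate
#' vector, measure vector) exon pairings, plus lncRNA-vs-mRNA group
#' contrasts, using a two-sided Mann-Whitney U test.
#'
#' @param measures result of [exon_measures()].
#' @param exon_groups data.table mapping `exon_id` to `transcript_class`
#'   and `has_splice_site` (exon hosts a splice-site editing site).
#' @param what `"psi"` or `"expression"`.
#' @param n_baseline number of random pairings (default 10000).
#' @param seed RNG seed for the baseline (default 42).
#' @param min_pairs minimum paired samples per exon correlation.
#' @return List with `per_exon` (exon_id, group, R), `group_means`, and
#'   `tests` (comparison, effect = mean-R difference, statistic, p, group
#'   sizes, baseline description).
#' @export
correlation_distributions <- function(measures, exon_groups,
                                      what = c("psi", "expression"),
                                      n_baseline = 10000L, seed = 42L,
                                      min_pairs = 3L) {
  what <- match.arg(what)
  col <- if (what == "psi") "psi" else "expression_level"
  m <- data.table::as.data.table(measures)
  eg <- data.table::as.data.table(exon_groups)
  check_columns(eg, c("exon_id", "transcript_class", "has_splice_site"),
                "exon groups")

  wide_rate <- data.table::dcast(m, exon_id ~ sample_id,
                                 value.var = "rate")
  wide_y <- data.table::dcast(m, exon_id ~ sample_id, value.var = col)
  ids <- wide_rate$exon_id
  rmat <- as.matrix(wide_rate[, -1])
  ymat <- as.matrix(wide_y[, -1])

  per_r <- vapply(seq_along(ids), function(i) {
    correlate(rmat[i, ], ymat[i, ], min_pairs = min_pairs)
  }, numeric(1))
  per <- data.table::data.table(exon_id = ids, R = per_r)
  per <- merge(per, eg, by = "exon_id")
  per <- per[!is.na(R)]
  per[, group := paste0(ifelse(transcript_class == "lncRNA", "lncRNA",
                               "mRNA"),
                        ifelse(has_splice_site, "_splicing",
                               "_nonsplicing"))]
  if (nrow(per) == 0) stop("no exon with a computable correlation")

  set.seed(seed)
  n_ex <- length(ids)
  i1 <- sample.int(n_ex, n_baseline, replace = TRUE)
  i2 <- sample.int(n_ex, n_baseline, replace = TRUE)
  bump <- i1 == i2
  i2[bump] <- (i2[bump] %% n_ex) + 1L
  baseline <- vapply(seq_len(n_baseline), function(b) {
    correlate(rmat[i1[b], ], ymat[i2[b], ], min_pairs = min_pairs)
  }, numeric(1))
  baseline <- baseline[!is.na(baseline)]

  groups <- split(per$R, per$group)
  mw <- function(a, b) {
    if (!length(a) || !length(b)) return(list(stat = NA_real_,
                                              p = NA_real_))
    wt <- suppressWarnings(stats::wilcox.test(a, b,
                                              alternative = "two.sided"))
    list(stat = unname(wt$statistic), p = wt$p.value)
  }
  rows <- list()
  for (gname in names(groups)) {
    t <- mw(groups[[gname]], baseline)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      comparison = paste0(gname, "_vs_random"),
      effect = mean(groups[[gname]]) - mean(baseline),
      mean_r_group = mean(groups[[gname]]),
      mean_r_reference = mean(baseline),
      statistic = t$stat, p = t$p,
      n1 = length(groups[[gname]]), n2 = length(baseline),
      baseline = sprintf("%d random exon pairings", n_baseline))
  }
  contrasts <- list(
    c("lncRNA_splicing", "mRNA_splicing"),
    c("lncRNA_splicing", "lncRNA_nonsplicing"),
    c("mRNA_splicing", "mRNA_nonsplicing"))
  for (ct in contrasts) {
    a <- groups[[ct[1]]]; b <- groups[[ct[2]]]
    if (is.null(a) || is.null(b)) next
    t <- mw(a, b)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      comparison = paste0(ct[1], "_vs_", ct[2]),
      effect = mean(a) - mean(b), mean_r_group = mean(a),
      mean_r_reference = mean(b), statistic = t$stat, p = t$p,
      n1 = length(a), n2 = length(b), baseline = "group contrast")
  }
  list(per_exon = per[, .(exon_id, transcript_class, has_splice_site,
                          group, R)],
       group_means = per[, .(mean_R = mean(R), n = .N), by = group],
       baseline_mean = mean(baseline),
       tests = data.table::rbindlist(rows))
}

contingency_row <- function(name, subset, a, b, c, d,
                            method = c("chisq", "fisher")) {
  method <- match.arg(method)
  tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(data.table::data.table(
      comparison = name, subset = subset, a = a, b = b, c = c, d = d,
      odds_ratio = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
      statistic = NA_real_, p = NA_real_, method = method,
      note = "degenerate table (empty margin)"))
  }
  or <- odds_ratio(tab)
  if (method == "chisq") {
    tst <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stat <- unname(tst$statistic); p <- tst$p.value
  } else {
    tst <- stats::fisher.test(tab)
    stat <- NA_real_; p <- tst$p.value
  }
  data.table::data.table(
    comparison = name, subset = subset, a = a, b = b, c = c, d = d,
    odds_ratio = or$or, ci_lo = or$ci_lo, ci_hi = or$ci_hi,
    statistic = stat, p = p, method = method, note = "")
}

#' Enrichment tests for editing-site annotations
#'
#' Three families of 2x2 tests, each run on all sites and on the non-Alu
#' subset: (i) differential vs non-differential editing x splice-site
#' status (chi-square, plus the TFBS analogue); (ii) lncRNA vs non-lncRNA
#' and mRNA vs non-mRNA x splice-site status (chi-square); (iii) among
#' editing sites on measured exons, splice-site status x host-exon
#' differential expression (Fisher exact). Odds ratios use the
#' Haldane-Anscombe correction on zero cells; chi-square is computed
#' without continuity correction.
#'
#' @param sites annotated site table (needs `transcript_class`,
#'   `is_splice_site`, `is_tfbs`, `repeat_class`; `is_differential` for
#'   family i; `exon_ids` for family iii).
#' @param exon_de optional data.table (`exon_id`, `is_de`) enabling family
#'   iii.
#' @return data.table with one row per test: table cells, odds ratio with
#'   Woolf 95 percent CI, statistic, p, method.
#' @export
enrichment_tests <- function(sites, exon_de = NULL) {
  s <- data.table::as.data.table(sites)
  check_columns(s, c("transcript_class", "is_splice_site", "is_tfbs",
                     "repeat_class"), "annotated sites")
  subsets <- list(all = s, nonAlu = s[repeat_class != "Alu"])
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  for (sub in names(subsets)) {
    ss <- subsets[[sub]]
    if (nrow(ss) == 0) next
    if ("is_differential" %in% names(s)) {
      add(contingency_row("differential_x_splice", sub,
                          sum(ss$is_differential & ss$is_splice_site),
                          sum(ss$is_differential & !ss$is_splice_site),
                          sum(!ss$is_differential & ss$is_splice_site),
                          sum(!ss$is_differential & !ss$is_splice_site),
                          "chisq"))
      add(contingency_row("differential_x_tfbs", sub,
                          sum(ss$is_differential & ss$is_tfbs),
                          sum(ss$is_differential & !ss$is_tfbs),
                          sum(!ss$is_differential & ss$is_tfbs),
                          sum(!ss$is_differential & !ss$is_tfbs),
                          "chisq"))
    }
    on_lnc <- ss$transcript_class %in% c("lncRNA_only", "overlap")
    on_mrna <- ss$transcript_class %in% c("mRNA_only", "overlap")
    add(contingency_row("lncRNA_x_splice", sub,
                        sum(on_lnc & ss$is_splice_site),
                        sum(on_lnc & !ss$is_splice_site),
                        sum(!on_lnc & ss$is_splice_site),
                        sum(!on_lnc & !ss$is_splice_site), "chisq"))
    add(contingency_row("mRNA_x_splice", sub,
                        sum(on_mrna & ss$is_splice_site),
                        sum(on_mrna & !ss$is_splice_site),
                        sum(!on_mrna & ss$is_splice_site),
                        sum(!on_mrna & !ss$is_splice_site), "chisq"))
    if (!is.null(exon_de) && "exon_ids" %in% names(ss)) {
      de <- data.table::as.data.table(exon_de)
      check_columns(de, c("exon_id", "is_de"), "exon DE flags")
      map <- ss[!is.na(exon_ids),
                .(exon_id = strsplit(exon_ids, ",", fixed = TRUE)[[1]],
                  is_splice_site = is_splice_site[1]),
                by = .(chrom, pos)]
      map <- merge(map, de, by = "exon_id")
      site_de <- map[, .(on_de = any(is_de),
                         is_splice_site = is_splice_site[1]),
                     by = .(chrom, pos)]
      if (nrow(site_de)) {
        add(contingency_row("splice_x_de_exon", sub,
                            sum(site_de$is_splice_site & site_de$on_de),
                            sum(site_de$is_splice_site & !site_de$on_de),
                            sum(!site_de$is_splice_site & site_de$on_de),
                            sum(!site_de$is_splice_site & !site_de$on_de),
                            "fisher"))
      }
    }
  }
  data.table::rbindlist(rows)
}

#' Simple per-exon differential-expression call
#'
#' A hermetic stand-in for a full count-model DE pipeline: per exon, a
#' one-way ANOVA across stages on log1p library-size- and
#' length-normalized inclusion counts, Benjamini-Hochberg corrected;
#' `is_de` means q < `fdr`. When `external_flags` is supplied it is passed
#' through unchanged and no test is run.
#'
#' @param exon_counts exon counts table.
#' @param design design table (`sample_id`, `stage`).
#' @param fdr q-value threshold (default 0.05).
#' @param external_flags optional data.table (`exon_id`, `is_de`).
#' @return data.table with `exon_id`, `p`, `q`, `is_de`.
#' @export
simple_exon_de <- function(exon_counts, design, fdr = 0.05,
                           external_flags = NULL) {
  if (!is.null(external_flags)) {
    de <- data.table::as.data.table(external_flags)
    check_columns(de, c("exon_id", "is_de"), "external DE flags")
    return(de[, .(exon_id, p = NA_real_, q = NA_real_, is_de)])
  }
  ec <- data.table::as.data.table(exon_counts)
  check_columns(ec, c("exon_id", "sample_id", "inclusion_reads",
                      "inclusion_len"), "exon counts")
  design <- as_design(design)
  if ("stage" %in% names(ec)) ec[, stage := NULL]
  ec <- merge(ec, design, by = "sample_id")
  # median-of-ratios size factors (composition-robust, as in count-based
  # DE tools); plain library-size scaling would let strongly DE exons
  # induce apparent shifts in flat ones
  ec[, dens := inclusion_reads / inclusion_len]
  geo <- ec[, .(logg = mean(log(dens[dens > 0]))), by = exon_id]
  ec <- merge(ec, geo, by = "exon_id")
  sf <- ec[is.finite(logg) & dens > 0,
           .(sf = exp(stats::median(log(dens) - logg))), by = sample_id]
  ec <- merge(ec, sf, by = "sample_id", all.x = TRUE)
  ec[is.na(sf) | sf <= 0, sf := 1]
  ec[, value := log1p(1000 * dens / sf)]
  res <- ec[, {
    gg <- droplevels(stage)
    if (nlevels(gg) < 2 || sd(value) == 0) {
      list(p = if (sd(value) == 0) 1.0 else NA_real_)
    } else {
      fit <- stats::anova(stats::lm(value ~ gg))
      list(p = fit[["Pr(>F)"]][1])
    }
  }, by = exon_id]
  res[, q := stats::p.adjust(p, method = "BH")]
  res[, is_de := !is.na(q) & q < fdr]
  res[]
}
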