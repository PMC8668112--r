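## Synthetic miniature datasets with planted truth.
##
## The generator emulates the statistical structure of a stage-resolved
## single-cell RNA-seq editing study: 29 samples over six developmental
## stages (3 oocyte, 2 zygote, 3 2-cell, 4 4-cell, 11 8-cell, 3 morula),
## per-site editing ratios following three trajectory families that turn at
## the 8-cell stage, germline SNVs, strand- and read-position-biased
## artifact sites, paralog-confounded sites, and exon inclusion/exclusion
## counts whose PSI is coupled to the exon editing rate at a configurable
## correlation. Evidence is emitted at pileup level (one row per read per
## site), which is the granularity the filter cascade consumes.

#' Simulation configuration
#'
#' Defaults state the simulated world: sample sizes mirror the six-stage
#' embryo design (29 samples), roughly 500 true editing sites against 300
#' confounders, sequencing depth 30x per site, and lncRNA editing-PSI
#' coupling stronger than mRNA.
#'
#' @param seed integer seed; every generator derives its stream from it, so
#'   identical configs reproduce outputs byte for byte.
#' @param n_samples_per_stage integer vector of length 6 (oocyte, zygote,
#'   2cell, 4cell, 8cell, morula).
#' @param n_true_sites number of genuine A-to-I editing sites to plant.
#' @param n_snv_confounders germline SNV sites (deposited in the SNP
#'   catalog).
#' @param n_strand_bias_artifacts sites whose variant reads come from one
#'   sequencing strand.
#' @param n_position_bias_artifacts sites whose variant alleles sit in the
#'   terminal read segments.
#' @param n_paralog_confounders sites whose variant reads have second-best
#'   alignment hits at >= 95 percent of the best score.
#' @param cluster_proportions 3-simplex of trajectory-family weights for
#'   differential true sites.
#' @param mean_depth Poisson mean reads per site per sample.
#' @param exon_psi_editing_rho target editing-PSI Pearson correlation on
#'   lncRNA exons.
#' @param exon_psi_editing_rho_mrna same for mRNA exons (weaker by default).
#' @param splice_window_bp half-width of the splice-site window around exon
#'   boundaries.
#' @param n_lncrna,n_mrna transcript counts in the miniature annotation.
#' @param frac_constant_sites fraction of true sites with a flat (non
#'   differential) trajectory.
#' @param lncrna_splice_or planted odds ratio of lncRNA vs mRNA sites
#'   falling in splice windows.
#' @param mrna_splice_prob probability an mRNA true site is placed in a
#'   splice window.
#' @param frac_cdna_catalog fraction of true sites also deposited in the
#'   SNP catalog flagged `MOLTYPE=cDNA`.
#' @param stage_jitter_sd per-sample biological jitter (sd) added to the
#'   stage-level true editing ratio.
#' @param read_len simulated read length (bp).
#' @param exon_mean_reads mean inclusion+exclusion reads per exon/sample.
#' @param frac_de_exons fraction of measured exons given a differential
#'   expression trend across stages.
#' @param de_fold expression fold change planted in DE exons.
#' @param psi_count_noise draw inclusion reads binomially (TRUE) or emit
#'   noise-free expected counts (FALSE; used for limit-case checks).
#' @param edit_scale multiplies true editing ratios; ~0 emulates an ADAR
#'   knockdown in which artifacts persist but editing vanishes.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 42L,
                       n_samples_per_stage = c(3L, 2L, 3L, 4L, 11L, 3L),
                       n_true_sites = 500L,
                       n_snv_confounders = 150L,
                       n_strand_bias_artifacts = 50L,
                       n_position_bias_artifacts = 50L,
                       n_paralog_confounders = 50L,
                       cluster_proportions = c(0.93, 0.06, 0.01),
                       mean_depth = 30,
                       exon_psi_editing_rho = 0.75,
                       exon_psi_editing_rho_mrna = 0.43,
                       splice_window_bp = 300L,
                       n_lncrna = 40L, n_mrna = 40L,
                       frac_constant_sites = 0.30,
                       lncrna_splice_or = 2.0,
                       mrna_splice_prob = 0.30,
                       frac_cdna_catalog = 0.05,
                       stage_jitter_sd = 0.05,
                       read_len = 100L,
                       exon_mean_reads = 200,
                       frac_de_exons = 0.30,
                       de_fold = 4,
                       psi_count_noise = TRUE,
                       edit_scale = 1.0) {
  cfg <- as.list(environment())
  stopifnot(length(cfg$n_samples_per_stage) == 6L,
            all(cfg$n_samples_per_stage >= 0))
  counts <- c(cfg$n_true_sites, cfg$n_snv_confounders,
              cfg$n_strand_bias_artifacts, cfg$n_position_bias_artifacts,
              cfg$n_paralog_confounders)
  stopifnot(all(counts >= 0))
  if (abs(sum(cfg$cluster_proportions) - 1) > 1e-8 ||
      any(cfg$cluster_proportions < 0)) {
    stop("cluster_proportions must be non-negative and sum to 1")
  }
  stopifnot(abs(cfg$exon_psi_editing_rho) <= 1,
            abs(cfg$exon_psi_editing_rho_mrna) <= 1,
            cfg$mean_depth > 0, cfg$splice_window_bp >= 0)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "sim_config")
}

#' Sample design implied by a simulation configuration
#'
#' @param config a [sim_config()].
#' @return data.table with `sample_id`, `stage` (ordered factor).
#' @export
sim_design <- function(config) {
  stages <- embryo_stages()
  d <- data.table::data.table(
    stage = rep(stages, config$n_samples_per_stage)
  )
  d[, sample_id := paste0(stage, "_", seq_len(.N)), by = stage]
  as_design(d[, .(sample_id, stage)])
}

## Stage-level trajectory curves. Amplitudes: cluster 1 falls 0.60 -> 0.05,
## cluster 2 falls 0.35 -> 0.05, cluster 3 rises 0.05 -> 0.50, all turning
## at the 8-cell stage; morula tails differ between clusters 1 and 2 so the
## two families remain separable after per-site shape standardization.
trajectory_curves <- function() {
  c1 <- c(seq(0.60, 0.05, length.out = 5), 0.06)
  c2 <- c(seq(0.35, 0.05, length.out = 5), 0.30)
  c3 <- c(seq(0.05, 0.50, length.out = 5), 0.35)
  m <- rbind(c1, c2, c3)
  dimnames(m) <- list(paste0("cluster", 1:3), embryo_stages())
  m
}

#' Generate a miniature genome annotation
#'
#' Lays lncRNA and mRNA transcripts (each with several 700-1500 bp exons)
#' along two synthetic chromosomes, placing a fraction of lncRNAs antisense
#' within an mRNA locus to create the lncRNA/mRNA overlap class, and draws
#' Alu, non-Alu repeat and TFBS intervals inside exons. A random reference
#' sequence is attached so read evidence can be interpreted against real
#' bases.
#'
#' @param config a [sim_config()].
#' @return List of class `ed_annotation`: `exons` (GRanges), `genome`
#'   (DNAStringSet), `alu`, `repeats`, `tfbs` (GRanges).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_tx <- config$n_lncrna + config$n_mrna
  classes <- sample(c(rep("lncRNA", config$n_lncrna),
                      rep("mRNA", config$n_mrna)))
  if (n_tx == 0) {
    genome <- DNAStringSet(c(chr1 = paste(
      sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = "")))
    return(structure(list(exons = GRanges(), genome = genome,
                          alu = GRanges(), repeats = GRanges(),
                          tfbs = GRanges()),
                     class = "ed_annotation"))
  }

  # antisense lncRNAs overlapping an mRNA locus -> "overlap" class sites
  lnc_idx <- which(classes == "lncRNA")
  mrna_idx <- which(classes == "mRNA")
  n_ov <- min(length(mrna_idx), ceiling(0.15 * length(lnc_idx)))
  ov_lnc <- utils::tail(lnc_idx, n_ov)
  ov_partner <- rep(NA_integer_, n_tx)
  # partners must already be placed when the antisense lncRNA is laid down
  ov_partner[ov_lnc] <- vapply(ov_lnc, function(i) {
    cand <- mrna_idx[mrna_idx < i]
    if (length(cand)) resample(cand, 1L) else NA_integer_
  }, integer(1))

  rows <- vector("list", n_tx)
  cursor <- c(chr1 = 1L, chr2 = 1L)
  tx_span <- vector("list", n_tx)
  for (i in seq_len(n_tx)) {
    n_ex <- sample(4:6, 1)
    ex_len <- sample(700:1500, n_ex, replace = TRUE)
    in_len <- sample(400:1200, max(n_ex - 1, 0), replace = TRUE)
    if (!is.na(ov_partner[i]) && !is.null(tx_span[[ov_partner[i]]])) {
      host <- tx_span[[ov_partner[i]]]
      chr <- host$chrom
      start0 <- host$start + sample(0:200, 1)
      strand_i <- if (host$strand == "+") "-" else "+"
    } else {
      chr <- names(cursor)[(i %% 2L) + 1L]
      start0 <- cursor[[chr]] + sample(2000:5000, 1)
      strand_i <- sample(c("+", "-"), 1)
    }
    starts <- start0 + cumsum(c(0L, head(ex_len, -1) + in_len))
    ends <- starts + ex_len - 1L
    tx_id <- sprintf("%s%03d", ifelse(classes[i] == "lncRNA", "LNC", "MRN"), i)
    rows[[i]] <- data.table::data.table(
      chrom = chr, start = starts, end = ends, strand = strand_i,
      transcript_id = tx_id, transcript_class = classes[i],
      exon_number = seq_len(n_ex)
    )
    if (is.na(ov_partner[i])) {
      cursor[[chr]] <- max(cursor[[chr]], ends[n_ex])
    }
    tx_span[[i]] <- list(chrom = chr, start = start0, end = ends[n_ex],
                         strand = strand_i)
  }
  ex <- data.table::rbindlist(rows)
  ex[, exon_id := paste0(transcript_id, "_e", exon_number)]

  chrom_len <- ex[, .(len = max(end) + 2000L), by = chrom]
  genome <- DNAStringSet(vapply(chrom_len$len, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1)))
  names(genome) <- chrom_len$chrom

  exons <- GRanges(ex$chrom, IRanges(ex$start, ex$end), strand = ex$strand)
  mcols(exons)$transcript_id <- ex$transcript_id
  mcols(exons)$transcript_class <- ex$transcript_class
  mcols(exons)$exon_number <- ex$exon_number
  mcols(exons)$exon_id <- ex$exon_id

  draw_track <- function(frac, len) {
    pick <- which(runif(length(exons)) < frac)
    if (!length(pick)) return(GRanges())
    w <- pmin(len, width(exons)[pick] - 2L)
    off <- floor(runif(length(pick)) * (width(exons)[pick] - w))
    GRanges(seqnames(exons)[pick],
            IRanges(start(exons)[pick] + off, width = w))
  }
  alu <- draw_track(0.30, 300L)     # Alu elements are ~300 bp
  reps <- draw_track(0.15, 200L)
  tfbs <- draw_track(0.20, 20L)

  structure(list(exons = exons, genome = genome, alu = alu,
                 repeats = reps, tfbs = tfbs),
            class = "ed_annotation")
}

# sample `n` positions within [lo, hi] of an exon where the genome base
# equals `base`; returns integer positions (may be fewer than n)
positions_with_base <- function(genome, chrom, lo, hi, base, n) {
  if (hi < lo) return(integer(0))
  seq <- Biostrings::extractAt(genome[[chrom]], IRanges(lo, hi))[[1]]
  hits <- Biostrings::matchPattern(base, seq)
  cand <- GenomicRanges::start(hits) + lo - 1L
  if (!length(cand)) return(integer(0))
  resample(cand, min(n, length(cand)))
}

#' Plant editing sites and confounders on the annotation
#'
#' True sites receive a trajectory family (two falling to a minimum at the
#' 8-cell stage with different amplitudes, one rising to a maximum there) or
#' a flat curve; a configurable fraction land inside splice windows, with
#' lncRNA sites enriched at the configured odds ratio. Confounder classes
#' (SNV, strand artifact, position artifact, paralog) are planted on random
#' exonic positions.
#'
#' @param config a [sim_config()].
#' @param annotation result of [generate_annotation()].
#' @return data.table of truth records: coordinates, `class`, `cluster`,
#'   `ref`/`alt` alleles, host exon/transcript, splice-window flag and
#'   per-stage true editing ratios (`ratio_<stage>` columns).
#' @export
plant_editing_sites <- function(config, annotation) {
  stopifnot(inherits(config, "sim_config"),
            inherits(annotation, "ed_annotation"))
  set.seed(config$seed + 2L)
  exons <- annotation$exons
  if (length(exons) == 0 &&
      (config$n_true_sites + config$n_snv_confounders +
       config$n_strand_bias_artifacts + config$n_position_bias_artifacts +
       config$n_paralog_confounders) > 0) {
    stop("insufficient exonic space: annotation has no exons")
  }
  w <- config$splice_window_bp
  curves <- trajectory_curves()
  stages <- embryo_stages()

  n_true <- config$n_true_sites
  n_classes <- c(true_edit = n_true,
                 snv = config$n_snv_confounders,
                 strand_artifact = config$n_strand_bias_artifacts,
                 position_artifact = config$n_position_bias_artifacts,
                 paralog = config$n_paralog_confounders)

  # splice-window probability per transcript class, from the planted OR
  p_m <- config$mrna_splice_prob
  odds_l <- config$lncrna_splice_or * p_m / (1 - p_m)
  p_l <- odds_l / (1 + odds_l)

  ex_dt <- data.table::data.table(
    idx = seq_along(exons),
    chrom = as.character(seqnames(exons)),
    start = start(exons), end = end(exons),
    strand = as.character(strand(exons)),
    transcript_id = mcols(exons)$transcript_id,
    transcript_class = mcols(exons)$transcript_class,
    exon_id = mcols(exons)$exon_id
  )

  used <- new.env(parent = emptyenv())
  place_one <- function(cls) {
    for (try in 1:80) {
      e <- ex_dt[sample(.N, 1)]
      splice_target <- NA
      if (cls == "true_edit") {
        p_sp <- if (e$transcript_class == "lncRNA") p_l else p_m
        splice_target <- runif(1) < p_sp
        if (splice_target) {
          side <- sample(c("start", "end"), 1)
          lo <- if (side == "start") e$start else max(e$start, e$end - w + 1L)
          hi <- if (side == "start") min(e$end, e$start + w - 1L) else e$end
        } else {
          lo <- e$start + w
          hi <- e$end - w
          if (hi < lo) next
        }
      } else {
        lo <- e$start; hi <- e$end
      }
      base <- if (cls %in% c("true_edit")) {
        if (e$strand == "+") "A" else "T"
      } else {
        sample(c("A", "C", "G", "T"), 1)
      }
      pos <- positions_with_base(annotation$genome, e$chrom, lo, hi, base, 5L)
      pos <- pos[!vapply(site_key(e$chrom, pos), exists, logical(1),
                         envir = used)]
      if (!length(pos)) next
      p1 <- pos[1]
      assign(site_key(e$chrom, p1), TRUE, envir = used)
      alt <- if (cls == "true_edit") {
        if (base == "A") "G" else "C"
      } else {
        sample(setdiff(c("A", "C", "G", "T"), base), 1)
      }
      return(data.table::data.table(
        chrom = e$chrom, pos = p1, class = cls, ref = base, alt = alt,
        transcript_id = e$transcript_id, exon_id = e$exon_id,
        transcript_class = e$transcript_class, tx_strand = e$strand,
        in_splice_window = if (cls == "true_edit") splice_target else
          (p1 < e$start + w || p1 > e$end - w)
      ))
    }
    stop("insufficient exonic space for requested site count")
  }

  truth <- data.table::rbindlist(lapply(names(n_classes), function(cls) {
    if (n_classes[[cls]] == 0) return(NULL)
    data.table::rbindlist(lapply(seq_len(n_classes[[cls]]),
                                 function(i) place_one(cls)))
  }))

  # trajectory family per true site; flat sites get cluster NA
  truth[, cluster := NA_integer_]
  is_true <- truth$class == "true_edit"
  n_flat <- round(config$frac_constant_sites * sum(is_true))
  flat <- resample(which(is_true), n_flat)
  diff_idx <- setdiff(which(is_true), flat)
  if (length(diff_idx)) {
    truth$cluster[diff_idx] <- sample.int(3L, length(diff_idx),
                                          replace = TRUE,
                                          prob = config$cluster_proportions)
  }

  ratio <- matrix(0, nrow(truth), 6, dimnames = list(NULL, stages))
  ratio[diff_idx, ] <- curves[truth$cluster[diff_idx], , drop = FALSE]
  ratio[flat, ] <- matrix(rep(runif(length(flat), 0.15, 0.50), 6), ncol = 6)
  snv_rows <- which(truth$class == "snv")
  ratio[snv_rows, ] <- rep(sample(c(0.5, 1.0), length(snv_rows),
                                  replace = TRUE, prob = c(0.7, 0.3)), 6)
  art <- which(truth$class %in%
                 c("strand_artifact", "position_artifact", "paralog"))
  ratio[art, ] <- 0.30
  colnames(ratio) <- paste0("ratio_", stages)
  truth <- cbind(truth, data.table::as.data.table(ratio))

  # site-fixed nuisance draws used by the evidence simulator
  truth[, artifact_strand := sample(c("+", "-"), .N, replace = TRUE)]
  truth[, in_catalog := class == "snv"]
  truth[, moltype := NA_character_]
  cdna <- resample(which(is_true),
                   round(config$frac_cdna_catalog * sum(is_true)))
  truth[cdna, `:=`(in_catalog = TRUE, moltype = "cDNA")]
  data.table::setorder(truth, chrom, pos)
  truth[]
}

#' Simulate pileup-level read evidence
#'
#' For every site and sample, coverage is Poisson(`mean_depth`) and
#' variant-supporting reads are Binomial(depth, true ratio) where the true
#' ratio is the stage curve plus per-sample jitter (true sites) or the
#' class-specific constant. Qualities, strands, read positions and
#' alignment hit scores are drawn so that true sites pass the filter gates
#' while each confounder class trips exactly the filter aimed at it.
#'
#' @param config a [sim_config()].
#' @param truth result of [plant_editing_sites()].
#' @param design optional design table; defaults to [sim_design()].
#' @return data.table in the evidence schema (see [read_evidence()]), with
#'   the realized per-site/sample truth attached as attribute
#'   `cell_truth`.
#' @export
simulate_read_evidence <- function(config, truth, design = sim_design(config)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  stages <- embryo_stages()
  rl <- config$read_len

  cells <- data.table::CJ(site = seq_len(nrow(truth)),
                          samp = seq_len(nrow(design)))
  cells[, `:=`(chrom = truth$chrom[site], pos = truth$pos[site],
               class = truth$class[site],
               sample_id = design$sample_id[samp],
               stage = as.character(design$stage[samp]))]
  rmat <- as.matrix(truth[, paste0("ratio_", stages), with = FALSE])
  base_ratio <- rmat[cbind(cells$site, match(cells$stage, stages))]
  scale <- ifelse(cells$class == "true_edit", config$edit_scale, 1)
  jitter <- ifelse(cells$class %in% c("true_edit"),
                   rnorm(nrow(cells), 0, config$stage_jitter_sd), 0)
  cells[, true_ratio := clamp(base_ratio * scale + jitter, 0, 1)]
  cells[, depth := rpois(.N, config$mean_depth)]
  cells[, n_var := rbinom(.N, depth, true_ratio)]

  idx <- rep(seq_len(nrow(cells)), cells$depth)
  ev <- cells[idx, .(chrom, pos, sample_id, stage, site, n_var)]
  ev[, rix := seq_len(.N), by = .(site, sample_id)]
  ev[, is_var := rix <= n_var]
  n <- nrow(ev)

  ev[, allele := ifelse(is_var, truth$alt[site], truth$ref[site])]
  lowq <- runif(n) < 0.05
  ev[, base_qual := ifelse(lowq, sample(10:24, n, replace = TRUE),
                           clamp(round(rnorm(n, 37, 2.5)), 20, 42))]
  lowm <- runif(n) < 0.05
  ev[, map_qual := ifelse(lowm, sample(0:19, n, replace = TRUE), 60L)]
  ev[, read_len := rl]

  term <- c(seq_len(rl %/% 10L), (rl - rl %/% 10L + 1L):rl)
  ev[, pos_in_read := sample(rl, n, replace = TRUE)]
  pa <- ev$is_var & truth$class[ev$site] == "position_artifact"
  ev[pa, pos_in_read := sample(term, sum(pa), replace = TRUE)]

  ev[, strand := sample(c("+", "-"), n, replace = TRUE)]
  sa <- ev$is_var & truth$class[ev$site] == "strand_artifact"
  ev[sa, strand := truth$artifact_strand[site]]

  ev[, best_hit_score := round(runif(n, 200, 300))]
  ev[, second_hit_score := round(runif(n, 0, 0.90) * best_hit_score, 1)]
  ev[, best_hit_overlaps_site := TRUE]
  pg <- ev$is_var & truth$class[ev$site] == "paralog"
  bad <- pg & runif(n) < 0.85
  ev[bad, second_hit_score := round(runif(sum(bad), 0.95, 1.0) *
                                      best_hit_score, 1)]
  ev[pg & runif(n) < 0.20, best_hit_overlaps_site := FALSE]

  ev[, read_id := sprintf("r%s_%s_%d", site, sample_id, rix)]
  out <- ev[, .(chrom, pos, sample_id, stage, read_id, allele, base_qual,
                map_qual, read_len, pos_in_read, strand, best_hit_score,
                second_hit_score, best_hit_overlaps_site)]
  data.table::setorder(out, chrom, pos, sample_id, read_id)
  data.table::setattr(out, "cell_truth",
                      cells[, .(chrom, pos, sample_id, stage, class,
                                true_ratio, depth, n_var)])
  out[]
}

#' Simulate exon inclusion/exclusion counts coupled to editing
#'
#' For every exon hosting at least one true editing site, per-sample PSI is
#' generated as an affine function of a latent variable correlated with the
#' exon's (realized, when `evidence` is supplied) editing rate at the
#' class-specific target correlation; inclusion/exclusion read counts are
#' then drawn to match that PSI given the effective lengths. A fraction of
#' exons additionally receive a stage-trending total-count profile so a
#' differential-expression call has planted positives.
#'
#' @param config a [sim_config()].
#' @param truth result of [plant_editing_sites()].
#' @param annotation result of [generate_annotation()].
#' @param evidence optional evidence table from [simulate_read_evidence()];
#'   when supplied the latent coupling uses realized editing rates (high
#'   quality reads only), otherwise the stage-level truth curves.
#' @param design optional design table; defaults to [sim_design()].
#' @return data.table with `exon_id`, `transcript_class`, `sample_id`,
#'   `stage`, `inclusion_reads`, `exclusion_reads`, `inclusion_len`,
#'   `exclusion_len`; exon-level truth (target rho, planted DE flag) in
#'   attribute `exon_truth`.
#' @export
simulate_exon_counts <- function(config, truth, annotation, evidence = NULL,
                                 design = sim_design(config)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 4L)
  stages <- embryo_stages()
  ex_sites <- truth[class == "true_edit"]
  if (nrow(ex_sites) == 0) {
    return(data.table::data.table(
      exon_id = character(), transcript_class = character(),
      sample_id = character(), stage = character(),
      inclusion_reads = numeric(), exclusion_reads = numeric(),
      inclusion_len = integer(), exclusion_len = integer()))
  }

  # per-exon per-sample editing rate driving the PSI coupling
  if (!is.null(evidence)) {
    key <- ex_sites[, .(chrom, pos, exon_id)]
    evs <- evidence[key, on = c("chrom", "pos"), nomatch = 0L]
    evs <- evs[base_qual >= 20]
    evs <- merge(evs, truth[, .(chrom, pos, ref, alt)],
                 by = c("chrom", "pos"))
    rate_dt <- evs[allele %in% c(ref, alt),
                   .(g = sum(allele == alt), a = sum(allele == ref)),
                   by = .(exon_id, sample_id)]
    rate_dt[, rate := g / (g + a)]
  } else {
    rmat <- as.matrix(ex_sites[, paste0("ratio_", stages), with = FALSE])
    long <- data.table::CJ(i = seq_len(nrow(ex_sites)),
                           s = seq_len(nrow(design)))
    long[, `:=`(exon_id = ex_sites$exon_id[i],
                sample_id = design$sample_id[s],
                rate = rmat[cbind(i, match(as.character(design$stage[s]),
                                           stages))])]
    rate_dt <- long[, .(rate = mean(rate)), by = .(exon_id, sample_id)]
  }

  ex_info <- unique(ex_sites[, .(exon_id, transcript_id, transcript_class)])
  ew <- data.table::data.table(
    exon_id = mcols(annotation$exons)$exon_id,
    exon_len = width(annotation$exons))
  ex_info <- merge(ex_info, ew, by = "exon_id")

  grid <- data.table::CJ(exon_id = ex_info$exon_id,
                         sample_id = design$sample_id, sorted = TRUE)
  grid <- merge(grid, rate_dt[, .(exon_id, sample_id, rate)],
                by = c("exon_id", "sample_id"), all.x = TRUE)
  grid <- merge(grid, ex_info, by = "exon_id")
  grid <- merge(grid, design, by = "sample_id")
  data.table::setorder(grid, exon_id, sample_id)

  de_exons <- ex_info$exon_id[runif(nrow(ex_info)) < config$frac_de_exons]
  de_profile <- setNames(seq(1, 1 / config$de_fold, length.out = 6), stages)

  grid[, psi := {
    r <- rate
    r[is.na(r)] <- mean(r, na.rm = TRUE)
    rho <- if (transcript_class[1] == "lncRNA") config$exon_psi_editing_rho
           else config$exon_psi_editing_rho_mrna
    z <- if (sd(r) > 0) (r - mean(r)) / sd(r) else rep(0, length(r))
    latent <- rho * z + sqrt(max(0, 1 - rho^2)) * rnorm(length(r))
    mx <- max(abs(latent))
    if (mx == 0) rep(0.5, length(r)) else 0.5 + 0.48 * latent / mx
  }, by = exon_id]

  grid[, inclusion_len := exon_len]
  grid[, exclusion_len := config$read_len]
  mult <- ifelse(grid$exon_id %in% de_exons,
                 de_profile[as.character(grid$stage)], 1)
  expected <- config$exon_mean_reads * mult
  q <- grid$psi * grid$inclusion_len /
    (grid$psi * grid$inclusion_len + (1 - grid$psi) * grid$exclusion_len)
  if (config$psi_count_noise) {
    total <- rpois(nrow(grid), expected)
    grid[, inclusion_reads := rbinom(.N, total, q)]
    grid[, exclusion_reads := total - inclusion_reads]
  } else {
    grid[, inclusion_reads := expected * q]
    grid[, exclusion_reads := expected * (1 - q)]
  }

  out <- grid[, .(exon_id, transcript_class, sample_id,
                  stage = as.character(stage),
                  inclusion_reads, exclusion_reads,
                  inclusion_len, exclusion_len)]
  data.table::setorder(out, exon_id, sample_id)
  ex_truth <- ex_info[, .(exon_id, transcript_class,
                          rho_target = ifelse(transcript_class == "lncRNA",
                                              config$exon_psi_editing_rho,
                                              config$exon_psi_editing_rho_mrna),
                          true_de = exon_id %in% de_exons)]
  data.table::setattr(out, "exon_truth", ex_truth)
  data.table::setattr(out, "exon_psi",
                      grid[, .(exon_id, sample_id, psi, rate)])
  out[]
}

#' Genotype records implied by the planted truth
#'
#' Germline SNV sites are het or hom-alt (from their planted allele ratio),
#' everything else is hom-ref; this is the matched-genotype gold standard
#' consumed by [genotype_fdr()].
#'
#' @param truth result of [plant_editing_sites()].
#' @return data.table with `chrom`, `pos`, `genotype`.
#' @export
sim_genotypes <- function(truth) {
  data.table::data.table(
    chrom = truth$chrom, pos = truth$pos,
    genotype = ifelse(truth$class != "snv", "hom_ref",
                      ifelse(truth$ratio_oocyte >= 0.99, "hom_alt", "het")))
}

#' Run the full generator and optionally write all files
#'
#' Executes annotation, site planting, evidence and exon-count simulation
#' in order, and (when `outdir` is given) writes genome FASTA, GTF, BED
#' tracks, evidence/truth/design/exon-count TSVs, the SNP catalog VCF and
#' the genotype TSV.
#'
#' @param config a [sim_config()].
#' @param outdir optional output directory (created if needed).
#' @return List with all generated objects (and `files` when written).
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  ann <- generate_annotation(config)
  truth <- plant_editing_sites(config, ann)
  design <- sim_design(config)
  ev <- simulate_read_evidence(config, truth, design)
  exons <- simulate_exon_counts(config, truth, ann, evidence = ev,
                                design = design)
  snps <- truth[in_catalog == TRUE,
                .(chrom, pos, ref, alt, moltype)]
  geno <- sim_genotypes(truth)
  res <- list(config = config, annotation = ann, truth = truth,
              design = design, evidence = ev, exon_counts = exons,
              snps = snps, genotypes = geno)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    f <- function(x) file.path(outdir, x)
    writeXStringSet(ann$genome, f("genome.fa"))
    write_annotation_gtf(ann, f("annotation.gtf"))
    rtracklayer::export(ann$alu, f("alu.bed"), format = "bed")
    rtracklayer::export(ann$repeats, f("repeats.bed"), format = "bed")
    rtracklayer::export(ann$tfbs, f("tfbs.bed"), format = "bed")
    write_evidence(ev, f("evidence.tsv"))
    write_tsv(truth, f("truth_sites.tsv"))
    write_tsv(design, f("design.tsv"))
    write_tsv(exons, f("exon_counts.tsv"))
    write_snp_vcf(snps, f("snps.vcf"))
    write_tsv(geno, f("genotypes.tsv"))
    res$files <- c(genome = f("genome.fa"), gtf = f("annotation.gtf"),
                   alu = f("alu.bed"), repeats = f("repeats.bed"),
                   tfbs = f("tfbs.bed"), evidence = f("evidence.tsv"),
                   truth = f("truth_sites.tsv"), design = f("design.tsv"),
                   exon_counts = f("exon_counts.tsv"), snps = f("snps.vcf"),
                   genotypes = f("genotypes.tsv"))
  }
  res
}

#' Write the miniature annotation as GTF
#'
#' Emits transcript and exon features with `transcript_biotype` set to
#' `lncRNA` or `protein_coding`.
#'
#' @param annotation an `ed_annotation`.
#' @param path output GTF path.
#' @return The path, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path) {
  ex <- annotation$exons
  if (length(ex) == 0) {
    writeLines("##gff-version 2", path)
    return(invisible(path))
  }
  gr <- ex
  mcols(gr) <- NULL
  mcols(gr)$source <- "edscape_sim"
  mcols(gr)$type <- "exon"
  mcols(gr)$gene_id <- mcols(ex)$transcript_id
  mcols(gr)$transcript_id <- mcols(ex)$transcript_id
  mcols(gr)$transcript_biotype <-
    ifelse(mcols(ex)$transcript_class == "lncRNA", "lncRNA",
           "protein_coding")
  mcols(gr)$exon_id <- mcols(ex)$exon_id
  mcols(gr)$exon_number <- as.character(mcols(ex)$exon_number)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}
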