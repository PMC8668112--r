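# Builders for hand-crafted read evidence and small simulated datasets.

# One block of reads at a single site for one sample. Vectors recycle to
# n_ref + n_var reads; variant reads come first.
make_reads <- function(chrom = "chr1", pos = 100L, sample_id = "s1",
                       stage = "oocyte", n_ref = 10L, n_var = 5L,
                       ref = "A", alt = "G", bq = 35L, mq = 60L,
                       strand = NULL, pos_in_read = NULL, read_len = 100L,
                       best = 100, second = 50, overlaps = TRUE) {
  n <- n_ref + n_var
  if (n == 0) stop("empty read block")
  data.table::data.table(
    chrom = chrom, pos = as.integer(pos), sample_id = sample_id,
    stage = stage,
    read_id = sprintf("%s_%s_%d_%d", chrom, sample_id, pos, seq_len(n)),
    allele = rep(c(alt, ref), c(n_var, n_ref)),
    base_qual = rep_len(bq, n), map_qual = rep_len(mq, n),
    read_len = as.integer(read_len),
    pos_in_read = if (is.null(pos_in_read)) {
      rep_len(as.integer(read_len / 2), n)
    } else rep_len(as.integer(pos_in_read), n),
    strand = if (is.null(strand)) rep_len(c("+", "-"), n)
             else rep_len(strand, n),
    best_hit_score = rep_len(best, n),
    second_hit_score = rep_len(second, n),
    best_hit_overlaps_site = rep_len(overlaps, n)
  )
}

# reference-allele lookup table for hand-built evidence
ref_table <- function(evidence, ref = "A") {
  u <- unique(evidence[, c("chrom", "pos")])
  u$ref <- rep_len(ref, nrow(u))
  u
}

# small-but-complete simulated dataset reused across test files
small_config <- function(seed = 101L, ...) {
  base <- list(seed = seed, n_true_sites = 60L, n_snv_confounders = 20L,
               n_strand_bias_artifacts = 8L,
               n_position_bias_artifacts = 8L, n_paralog_confounders = 8L,
               n_lncrna = 12L, n_mrna = 12L)
  do.call(sim_config, utils::modifyList(base, list(...)))
}

cached_small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(small_config())
    cache
  }
})

# Independent oracles ---------------------------------------------------

# Fisher exact two-sided p by exhaustive enumeration of all tables with
# the observed margins, summing probabilities <= that of the observed
# table (with the conventional 1+1e-7 relative slack for ties).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  if (m + n2 == 0 || k == 0 || k == m + n2 || m == 0 || n2 == 0) {
    return(NA_real_)
  }
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  xs <- lo:hi
  logp <- lchoose(m, xs) + lchoose(n2, k - xs) - lchoose(m + n2, k)
  p <- exp(logp)
  p_obs <- p[xs == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# One-way ANOVA F by direct sum-of-squares decomposition.
oracle_anova_F <- function(values, groups) {
  keep <- !is.na(values)
  values <- values[keep]; groups <- as.character(groups)[keep]
  gm <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  grand <- mean(values)
  ssb <- sum(ns * (gm - grand)^2)
  ssw <- sum((values - gm[groups])^2)
  dfb <- length(gm) - 1
  dfw <- length(values) - length(gm)
  (ssb / dfb) / (ssw / dfw)
}

# Benjamini-Hochberg step-up computed literally from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    rank_i <- which(ord == i)
    q[i] <- min(vapply(rank_i:n, function(j) {
      p[ord[j]] * n / j
    }, numeric(1)), 1)
  }
  q
}

# Naive average-linkage agglomeration: inter-cluster distance recomputed
# every step as the mean of all cross-pair original distances.
oracle_average_linkage_heights <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        dd <- mean(dm[clusters[[i]], clusters[[j]]])
        if (dd < best) { best <- dd; bi <- i; bj <- j }
      }
    }
    heights[step] <- best
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}
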