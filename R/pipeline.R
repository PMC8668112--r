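## Orchestration: simulate -> callsites -> annotate -> diffedit -> splice
## -> benchmark, with structured logging and a manifest of checksums.

#' Default pipeline configuration
#'
#' Plain key-value settings with the published filter defaults: base
#' quality 25, mapping quality 20, pooled mismatch frequency 0.1, bias-test
#' alpha 0.01 with Bonferroni correction, differential-editing FDR 0.05,
#' three trajectory clusters, 10000 baseline pairings.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(seed = 42L, n_true_sites = 500L, n_snv_confounders = 150L,
       n_strand_bias_artifacts = 50L, n_position_bias_artifacts = 50L,
       n_paralog_confounders = 50L, mean_depth = 30,
       exon_psi_editing_rho = 0.75, exon_psi_editing_rho_mrna = 0.43,
       n_lncrna = 40L, n_mrna = 40L,
       min_bq = 25L, min_mq = 20L, min_freq = 0.1, alpha = 0.01,
       fdr = 0.05, k = 3L, linkage = "average", splice_window = 300L,
       baseline_pairs = 10000L, min_psi_reads = 10L,
       single_sample = FALSE)
}

#' Read a key = value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are
#' coerced to numeric or logical where possible. Unknown keys error.
#'
#' @param path configuration file.
#' @return Full configuration list (defaults overridden by the file).
#' @export
read_config <- function(path) {
  cfg <- default_config()
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    cur <- cfg[[key]]
    cfg[[key]] <- if (is.logical(cur)) as.logical(val)
      else if (is.numeric(cur)) as.numeric(val) else val
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

log_msg <- function(logfile, fmt, ...) {
  msg <- sprintf(fmt, ...)
  message("[edscape] ", msg)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
  invisible(msg)
}

#' Run the full pipeline on a synthetic dataset
#'
#' Executes all stages in dependency order, writing every intermediate
#' table under `outdir` and a `manifest.json` recording the configuration,
#' seed, per-stage wall-clock and md5 checksums of all stage outputs.
#' Reruns with an identical configuration reproduce identical checksums.
#'
#' @param config configuration list ([default_config()]) or a path to a
#'   key = value file.
#' @param outdir output directory.
#' @return Invisibly, a list with all in-memory stage results and the
#'   manifest.
#' @export
run_all <- function(config = default_config(), outdir) {
  if (is.character(config)) config <- read_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(outdir, "run.log")
  if (file.exists(logfile)) unlink(logfile)
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- round(tic() - t0, 3)
    log_msg(logfile, "stage %-10s done in %.2fs", name, timings[[name]])
    res
  }
  f <- function(x) file.path(outdir, x)

  sim <- stage("simulate", {
    sc <- sim_config(
      seed = config$seed, n_true_sites = config$n_true_sites,
      n_snv_confounders = config$n_snv_confounders,
      n_strand_bias_artifacts = config$n_strand_bias_artifacts,
      n_position_bias_artifacts = config$n_position_bias_artifacts,
      n_paralog_confounders = config$n_paralog_confounders,
      mean_depth = config$mean_depth,
      exon_psi_editing_rho = config$exon_psi_editing_rho,
      exon_psi_editing_rho_mrna = config$exon_psi_editing_rho_mrna,
      n_lncrna = config$n_lncrna, n_mrna = config$n_mrna,
      splice_window_bp = config$splice_window)
    simulate_dataset(sc, outdir = f("sim"))
  })

  called <- stage("callsites", {
    ev <- read_evidence(f("sim/evidence.tsv"))
    snps <- read_snp_catalog(f("sim/snps.vcf"))
    params <- site_params(min_bq = config$min_bq, min_mq = config$min_mq,
                          min_freq = config$min_freq,
                          alpha = config$alpha,
                          single_sample = config$single_sample)
    x <- call_editing_sites(ev, sim$annotation$genome, snps, params)
    write_tsv(editing_sites(x), f("sites.tsv"))
    write_tsv(site_sample_counts(x), f("site_counts.tsv"))
    x
  })

  annotated <- stage("annotate", {
    ann <- annotate_sites(editing_sites(called, wide_ratios = TRUE),
                          annotation = sim$annotation,
                          splice_window_bp = config$splice_window)
    write_tsv(ann, f("sites_annotated.tsv"))
    ann
  })

  diff <- stage("diffedit", {
    mat <- build_matrix(annotated, sim$design)
    res <- anova_stages(mat, sim$design, fdr = config$fdr)
    write_tsv(res, f("differential.tsv"))
    dm <- mat[res$site_id[res$is_differential], , drop = FALSE]
    cl <- NULL
    if (nrow(dm) >= config$k) {
      cl <- cluster_trajectories(dm, sim$design, k = config$k,
                                 linkage = config$linkage)
      write_tsv(cl$assignments, f("clusters.tsv"))
      write_tsv(cl$curves, f("cluster_curves.tsv"))
    }
    list(matrix = mat, differential = res, clusters = cl)
  })

  splice <- stage("splice", {
    ann2 <- merge(annotated,
                  diff$differential[, .(site_id, is_differential)],
                  by = "site_id", all.x = TRUE)
    ann2[is.na(is_differential), is_differential := FALSE]
    de <- simple_exon_de(sim$exon_counts, sim$design, fdr = config$fdr)
    rates <- exon_editing_rate(site_sample_counts(called), ann2)
    meas <- exon_measures(sim$exon_counts, rates,
                          min_reads = config$min_psi_reads)
    splice_exons <- exon_split_groups(ann2)
    cd <- correlation_distributions(meas, splice_exons, what = "psi",
                                    n_baseline = config$baseline_pairs,
                                    seed = config$seed)
    enr <- enrichment_tests(ann2, exon_de = de[, .(exon_id, is_de)])
    write_tsv(meas, f("exon_measures.tsv"))
    write_tsv(cd$per_exon, f("exon_correlations.tsv"))
    write_tsv(cd$tests, f("correlation_tests.tsv"))
    write_tsv(enr, f("association_tests.tsv"))
    write_tsv(de, f("exon_de.tsv"))
    list(measures = meas, correlations = cd, enrichment = enr, de = de)
  })

  benchres <- stage("benchmark", {
    fdrres <- genotype_fdr(editing_sites(called, wide_ratios = FALSE),
                           sim$genotypes)
    jsonlite::write_json(fdrres, f("benchmark.json"), auto_unbox = TRUE,
                         digits = NA)
    fdrres
  })

  outputs <- list.files(outdir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, c(f("run.log"), f("manifest.json")))
  manifest <- list(
    config = config,
    seed = config$seed,
    versions = list(edscape = as.character(packageVersion("edscape")),
                    R = paste(R.version$major, R.version$minor, sep = ".")),
    timings_sec = timings,
    checksums = as.list(tools::md5sum(sort(outputs)))
  )
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  log_msg(logfile, "pipeline complete; manifest written")
  invisible(list(sim = sim, called = called, annotated = annotated,
                 diff = diff, splice = splice, benchmark = benchres,
                 manifest = manifest))
}

#' Exon-level splice grouping from annotated sites
#'
#' An exon "has a splice-site editing site" when any site assigned to it is
#' splice-annotated; its class is the class of its transcript (overlap
#' sites contribute to both hosting exons via their exon ids).
#'
#' @param annotated annotated site table with `exon_ids`,
#'   `is_splice_site`.
#' @return data.table with `exon_id`, `transcript_class` (lncRNA/mRNA by
#'   exon id prefix), `has_splice_site`.
#' @export
exon_split_groups <- function(annotated) {
  s <- data.table::as.data.table(annotated)
  check_columns(s, c("exon_ids", "is_splice_site"), "annotated sites")
  map <- s[!is.na(exon_ids),
           .(exon_id = strsplit(exon_ids, ",", fixed = TRUE)[[1]],
             is_splice_site = is_splice_site[1]),
           by = .(chrom, pos)]
  out <- map[, .(has_splice_site = any(is_splice_site)), by = exon_id]
  out[, transcript_class := ifelse(grepl("^LNC", exon_id), "lncRNA",
                                   "mRNA")]
  out[, .(exon_id, transcript_class, has_splice_site)]
}
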