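## False-discovery-rate benchmarks for the site caller.

#' FDR of called sites against matched DNA genotypes
#'
#' A called editing site is counted true when the matched genomic genotype
#' is homozygous reference, false otherwise (the mismatch is then a
#' genomic variant, not editing). Sites without genotype coverage are
#' excluded from the denominator and reported separately.
#'
#' @param sites table of called sites (`chrom`, `pos`).
#' @param genotypes table with `chrom`, `pos`, `genotype` in
#'   `hom_ref`/`het`/`hom_alt`/`missing`.
#' @return List: `fdr_percent` (false / (true + false) * 100, NA on empty
#'   overlap), `n_true`, `n_false`, `n_uncovered`.
#' @export
genotype_fdr <- function(sites, genotypes) {
  s <- unique(data.table::as.data.table(sites)[, .(chrom, pos)])
  g <- data.table::as.data.table(genotypes)
  check_columns(g, c("chrom", "pos", "genotype"), "genotype table")
  m <- g[s, on = c("chrom", "pos")]
  covered <- !is.na(m$genotype) & m$genotype != "missing"
  n_true <- sum(covered & m$genotype == "hom_ref")
  n_false <- sum(covered & m$genotype != "hom_ref")
  list(fdr_percent = if (n_true + n_false == 0) NA_real_ else
         100 * n_false / (n_true + n_false),
       n_true = n_true, n_false = n_false,
       n_uncovered = sum(!covered))
}

#' FDR from an editing-enzyme knockdown pair
#'
#' Assuming every A-to-I site still detected after ADAR knockdown is a
#' false positive, the FDR of the caller is the ratio of A-to-I sites
#' detected in the knockdown run to those detected in the control run,
#' reported per repeat class.
#'
#' @param sites_control,sites_knockdown called-site tables from two runs
#'   with identical parameters; `canonical_type` restricts counting to
#'   A-to-I sites when present, and `repeat_class` stratifies the ratio
#'   (absent -> a single `all` class).
#' @return data.table with `repeat_class`, `n_control`, `n_knockdown`,
#'   `fdr_percent` (NA when a class has no control sites).
#' @export
knockdown_fdr <- function(sites_control, sites_knockdown) {
  prep <- function(x) {
    x <- unique(data.table::as.data.table(x), by = c("chrom", "pos"))
    if ("canonical_type" %in% names(x)) x <- x[canonical_type == "A-to-I"]
    if (!"repeat_class" %in% names(x)) x[, repeat_class := "all"]
    x
  }
  ctl <- prep(sites_control)
  kd <- prep(sites_knockdown)
  classes <- sort(unique(c(ctl$repeat_class, kd$repeat_class)))
  out <- data.table::data.table(
    repeat_class = classes,
    n_control = vapply(classes, function(cl) sum(ctl$repeat_class == cl),
                       integer(1)),
    n_knockdown = vapply(classes, function(cl) sum(kd$repeat_class == cl),
                         integer(1)))
  out[, fdr_percent := ifelse(n_control > 0,
                              100 * n_knockdown / n_control, NA_real_)]
  out[]
}
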