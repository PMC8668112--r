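## File formats: evidence/sites/design/exon-count tables are TSV; transcript
## models GTF (1-based, via rtracklayer); interval tracks BED (0-based
## half-open, via rtracklayer); SNP catalogs VCF (via VariantAnnotation) or
## TSV; reference genomes FASTA (via Biostrings).

EVIDENCE_COLUMNS <- c(
  "chrom", "pos", "sample_id", "stage", "read_id", "allele", "base_qual",
  "map_qual", "read_len", "pos_in_read", "strand", "best_hit_score",
  "second_hit_score", "best_hit_overlaps_site"
)

#' Read a per-read evidence table
#'
#' One row per read per candidate site: allele observed, base and mapping
#' quality, read length and 1-based position of the site within the read,
#' sequencing strand, and alignment best/second-best hit scores used by the
#' paralog filter.
#'
#' @param path TSV file path.
#' @return data.table with the evidence schema.
#' @export
read_evidence <- function(path) {
  ev <- data.table::fread(path, sep = "\t", showProgress = FALSE)
  check_columns(ev, EVIDENCE_COLUMNS, sprintf("evidence table '%s'", path))
  ev[, best_hit_overlaps_site := as.logical(best_hit_overlaps_site)]
  ev
}

#' @rdname read_evidence
#' @param evidence data.table in the evidence schema.
#' @export
write_evidence <- function(evidence, path) {
  check_columns(evidence, EVIDENCE_COLUMNS, "evidence table")
  data.table::fwrite(evidence, path, sep = "\t")
  invisible(path)
}

#' Read a sample design table
#'
#' @param path TSV with columns `sample_id` and `stage`.
#' @return data.table with `stage` as a factor ordered by [embryo_stages()]
#'   when all levels are recognized, otherwise by first appearance.
#' @export
read_design <- function(path) {
  d <- data.table::fread(path, sep = "\t", showProgress = FALSE)
  check_columns(d, c("sample_id", "stage"), sprintf("design table '%s'", path))
  as_design(d)
}

as_design <- function(d) {
  d <- data.table::as.data.table(d)
  lv <- if (all(unique(d$stage) %in% embryo_stages())) {
    intersect(embryo_stages(), unique(d$stage))
  } else unique(d$stage)
  d[, stage := factor(stage, levels = lv)]
  d[]
}

#' Read a known-SNP catalog (VCF or TSV)
#'
#' VCF catalogs are parsed with VariantAnnotation; the INFO key `MOLTYPE`
#' carries the molecular type of the record (`cDNA` entries are putative
#' editing sites mis-deposited as SNPs and are exempt from removal). TSV
#' catalogs need columns `chrom`, `pos` and optionally `moltype`.
#'
#' @param path file path ending in `.vcf` or `.tsv`.
#' @return data.table with columns `chrom`, `pos`, `moltype` (NA when
#'   unspecified).
#' @export
read_snp_catalog <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    vcf <- VariantAnnotation::readVcf(path)
    rr <- SummarizedExperiment::rowRanges(vcf)
    mol <- if ("MOLTYPE" %in% names(VariantAnnotation::info(vcf))) {
      as.character(VariantAnnotation::info(vcf)$MOLTYPE)
    } else rep(NA_character_, length(rr))
    dt <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(rr)),
      pos = GenomicRanges::start(rr),
      moltype = mol
    )
  } else {
    dt <- data.table::fread(path, sep = "\t", showProgress = FALSE)
    check_columns(dt, c("chrom", "pos"), sprintf("SNP catalog '%s'", path))
    if (!"moltype" %in% names(dt)) dt[, moltype := NA_character_]
    dt <- dt[, .(chrom = as.character(chrom), pos = as.integer(pos), moltype)]
  }
  unique(dt, by = c("chrom", "pos"))
}

#' Write a minimal SNP catalog VCF
#'
#' @param snps data.table with `chrom`, `pos`, `ref`, `alt`, `moltype`
#'   (NA moltype emits an empty INFO field).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_snp_vcf <- function(snps, path) {
  check_columns(snps, c("chrom", "pos", "ref", "alt"), "SNP table")
  mol <- if ("moltype" %in% names(snps)) snps$moltype else rep(NA, nrow(snps))
  info <- ifelse(is.na(mol), ".", paste0("MOLTYPE=", mol))
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=MOLTYPE,Number=1,Type=String,Description="Molecular type of the catalog record">',
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO"), collapse = "\t"))
  )
  ord <- order(snps$chrom, snps$pos)
  body <- paste(snps$chrom[ord], snps$pos[ord], ".", snps$ref[ord],
                snps$alt[ord], ".", ".", info[ord], sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Look up reference alleles in a genome
#'
#' @param genome a `DNAStringSet` keyed by chromosome, or a data.frame with
#'   columns `chrom`, `pos`, `ref`.
#' @param chrom,pos parallel vectors of 1-based site coordinates.
#' @return Character vector of reference bases.
#' @export
ref_alleles <- function(genome, chrom, pos) {
  if (is(genome, "DNAStringSet")) {
    out <- character(length(chrom))
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      if (!ch %in% names(genome)) {
        stop(sprintf("chromosome '%s' absent from reference genome", ch))
      }
      hits <- Biostrings::extractAt(genome[[ch]], IRanges(pos[idx], pos[idx]))
      out[idx] <- as.character(hits)
    }
    return(out)
  }
  ref_dt <- data.table::as.data.table(genome)
  check_columns(ref_dt, c("chrom", "pos", "ref"), "reference allele table")
  key <- data.table::data.table(chrom = chrom, pos = pos)
  m <- ref_dt[key, on = c("chrom", "pos")]
  if (anyNA(m$ref)) {
    stop("reference allele missing for one or more sites")
  }
  m$ref
}

#' Read transcript models from GTF
#'
#' Exon features must be present; transcript class is taken from the
#' `transcript_biotype` attribute (`lncRNA` vs anything else = mRNA) or a
#' literal `transcript_class` attribute when present.
#'
#' @param path GTF file.
#' @return GRanges of exons with `transcript_id`, `transcript_class`,
#'   `exon_id` metadata columns.
#' @export
read_annotation_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) {
    stop(sprintf("GTF '%s' contains no exon features", path))
  }
  mc <- mcols(gr)
  if (!"transcript_class" %in% names(mc)) {
    bt <- if ("transcript_biotype" %in% names(mc)) mc$transcript_biotype
          else rep("protein_coding", length(gr))
    mcols(gr)$transcript_class <-
      ifelse(bt %in% c("lncRNA", "lincRNA"), "lncRNA", "mRNA")
  }
  if (!"exon_id" %in% names(mcols(gr))) {
    mcols(gr)$exon_id <- paste0(mcols(gr)$transcript_id, "_e",
                                seq_along(gr))
  }
  gr
}

read_bed_track <- function(path) {
  if (file.size(path) == 0) return(GRanges())
  rtracklayer::import(path, format = "bed")
}

write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
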