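## Site annotation: transcript class, splice-site proximity, TFBS overlap,
## repeat class. The splice-site label is a distance-to-exon-boundary rule
## (default window 300 bp), a stand-in for score-based splice annotation
## databases; distances are genomic and strand-agnostic.

#' Annotate editing sites against transcript models and interval tracks
#'
#' Adds four annotation columns plus host-exon ids:
#' `transcript_class` is `lncRNA_only`, `mRNA_only`, `overlap` (covered by
#' both classes) or `intergenic`; `is_splice_site` is TRUE within
#' `splice_window_bp` of any annotated exon boundary; `is_tfbs` marks TFBS
#' overlap; `repeat_class` is `Alu`, `repetitive_nonAlu` or
#' `nonrepetitive`, with Alu taking precedence.
#'
#' @param sites data.table with at least `chrom` and `pos` (e.g. from
#'   [editing_sites()]).
#' @param annotation an `ed_annotation` object, or NULL if file paths are
#'   given.
#' @param gtf,alu_bed,repeats_bed,tfbs_bed file paths used when
#'   `annotation` is NULL (`alu_bed`/`repeats_bed`/`tfbs_bed` optional).
#' @param splice_window_bp splice-site window half-width (default 300).
#' @return A copy of `sites` with annotation columns appended; row order is
#'   preserved and re-annotation is idempotent.
#' @export
annotate_sites <- function(sites, annotation = NULL, gtf = NULL,
                           alu_bed = NULL, repeats_bed = NULL,
                           tfbs_bed = NULL, splice_window_bp = 300L) {
  sites <- data.table::copy(data.table::as.data.table(sites))
  check_columns(sites, c("chrom", "pos"), "sites table")
  if (is.null(annotation)) {
    if (is.null(gtf)) stop("provide either an annotation object or a GTF")
    exons <- read_annotation_gtf(gtf)
    alu <- if (!is.null(alu_bed)) read_bed_track(alu_bed) else GRanges()
    reps <- if (!is.null(repeats_bed)) read_bed_track(repeats_bed)
            else GRanges()
    tfbs <- if (!is.null(tfbs_bed)) read_bed_track(tfbs_bed) else GRanges()
  } else {
    stopifnot(inherits(annotation, "ed_annotation"))
    exons <- annotation$exons
    alu <- annotation$alu
    reps <- annotation$repeats
    tfbs <- annotation$tfbs
  }
  if (length(exons) == 0) stop("annotation contains no exon features")

  gr <- GRanges(sites$chrom, IRanges(sites$pos, sites$pos))
  ov <- findOverlaps(gr, exons, ignore.strand = TRUE)
  cls <- mcols(exons)$transcript_class[subjectHits(ov)]
  on_lnc <- on_mrna <- logical(nrow(sites))
  on_lnc[unique(queryHits(ov)[cls == "lncRNA"])] <- TRUE
  on_mrna[unique(queryHits(ov)[cls == "mRNA"])] <- TRUE
  sites[, transcript_class := data.table::fcase(
    on_lnc & on_mrna, "overlap",
    on_lnc, "lncRNA_only",
    on_mrna, "mRNA_only",
    default = "intergenic")]

  eid <- mcols(exons)$exon_id[subjectHits(ov)]
  ex_map <- data.table::data.table(row = queryHits(ov), exon_id = eid)
  ex_map <- ex_map[, .(exon_ids = paste(sort(unique(exon_id)),
                                        collapse = ",")), by = row]
  sites[, exon_ids := NA_character_]
  sites[ex_map$row, exon_ids := ex_map$exon_ids]

  bpos <- c(start(exons), end(exons))
  bounds <- GRanges(rep(as.character(seqnames(exons)), 2),
                    IRanges(bpos, bpos))
  dtn <- distanceToNearest(gr, bounds, ignore.strand = TRUE)
  # |pos - boundary| in bases (GRanges distance() counts the gap, which is
  # one less than the coordinate difference for non-touching positions)
  dist <- rep(NA_integer_, nrow(sites))
  dist[queryHits(dtn)] <- abs(sites$pos[queryHits(dtn)] -
                                bpos[subjectHits(dtn)])
  sites[, is_splice_site := !is.na(dist) & dist <= splice_window_bp]

  overlaps_any <- function(track) {
    hit <- logical(nrow(sites))
    if (length(track)) {
      hit[unique(queryHits(findOverlaps(gr, track,
                                        ignore.strand = TRUE)))] <- TRUE
    }
    hit
  }
  sites[, is_tfbs := overlaps_any(tfbs)]
  in_alu <- overlaps_any(alu)
  in_rep <- overlaps_any(reps)
  sites[, repeat_class := data.table::fcase(
    in_alu, "Alu",
    in_rep, "repetitive_nonAlu",
    default = "nonrepetitive")]
  sites[]
}
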