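#' Collate per-cell allele counts from a cell-barcoded BAM
#'
#' Optional adapter that performs the per-cell pileup directly from a
#' coordinate-sorted, indexed BAM carrying a cell barcode tag (CB by
#' default), for a supplied list of candidate substitution loci. Reads
#' below the mapping-quality threshold, bases below the base-quality
#' threshold, and reads without the barcode tag are skipped; a read whose
#' base at the locus is neither the reference nor the alternate allele
#' contributes to neither count.
#'
#' @param bam path to an indexed BAM file.
#' @param loci data.frame with `chrom`, `pos`, `ref`, `alt` (e.g. from
#'   [read_site_vcf()]); 1-based positions.
#' @param cells optional cell metadata; counts are restricted to known
#'   barcodes and validated against them.
#' @param cb_tag per-read cell barcode tag (default `"CB"`).
#' @param min_base_quality,min_mapq quality thresholds (defaults 20/30).
#' @return an [allele_count_matrix()].
#' @export
collate_counts_bam <- function(bam, loci, cells = NULL, cb_tag = "CB",
                               min_base_quality = 20L, min_mapq = 30L) {
  for (pkg in c("Rsamtools", "GenomicAlignments"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop("the BAM adapter needs the ", pkg, " package")
  loci$chrom <- normalize_chrom(loci$chrom)
  check_loci(loci$chrom, loci$pos, loci$ref, loci$alt, "locus list")
  rows <- list()
  for (r in seq_len(nrow(loci))) {
    which <- GenomicRanges::GRanges(loci$chrom[r],
                                    IRanges::IRanges(loci$pos[r], width = 1L))
    param <- Rsamtools::ScanBamParam(
      which = which, tag = cb_tag,
      what = c("pos", "cigar", "seq", "qual", "mapq"),
      flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isDuplicate = FALSE))
    hit <- Rsamtools::scanBam(bam, param = param)[[1]]
    if (!length(hit$pos)) next
    cb <- hit$tag[[cb_tag]]
    ok <- !is.na(cb) & !is.na(hit$mapq) & hit$mapq >= min_mapq
    if (!any(ok)) next
    ## lay read bases/qualities onto reference coordinates (handles
    ## indels and clipping), then index the locus column
    seqs <- GenomicAlignments::sequenceLayer(
      Biostrings::DNAStringSet(hit$seq[ok]), hit$cigar[ok])
    quals <- GenomicAlignments::sequenceLayer(
      Biostrings::BStringSet(hit$qual[ok]), hit$cigar[ok])
    off <- loci$pos[r] - hit$pos[ok] + 1L
    inside <- off >= 1L & off <= Biostrings::width(seqs)
    if (!any(inside)) next
    base <- substr(as.character(seqs[inside]), off[inside], off[inside])
    q <- utf8ToInt(paste(substr(as.character(quals[inside]), off[inside],
                                off[inside]), collapse = ""))
    q <- q - 33L
    cb_in <- cb[ok][inside]
    good <- q >= min_base_quality & base %in% c(loci$ref[r], loci$alt[r])
    if (!any(good)) next
    tab <- table(cb_in[good], base[good])
    for (bc in rownames(tab)) {
      rc <- if (loci$ref[r] %in% colnames(tab)) tab[bc, loci$ref[r]] else 0L
      vc <- if (loci$alt[r] %in% colnames(tab)) tab[bc, loci$alt[r]] else 0L
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = bc, chrom = loci$chrom[r], pos = loci$pos[r],
        ref = loci$ref[r], alt = loci$alt[r],
        ref_count = as.integer(rc), var_count = as.integer(vc))
    }
  }
  if (!length(rows)) stop("no counts collated from BAM at the given loci")
  tab <- do.call(rbind, rows)
  if (!is.null(cells))
    tab <- tab[tab$cell_id %in% cells$cell_id, , drop = FALSE]
  allele_count_matrix(tab, cells)
}
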