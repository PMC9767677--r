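#' Read cell metadata
#'
#' Reads the tab-separated cell metadata table. Required columns:
#' `cell_id`, `patient_id`, `lineage`, `subtype`; optional columns:
#' `clonotype_id`, `region`. `lineage` is the major cell class
#' (e.g. T/NK, B/plasma, myeloid, endothelial, epithelial, fibroblast,
#' tumor); `subtype` the finer cluster label. Clonotype ids mark expanded
#' T-cell receptor clones and are expected on T cells only: a clonotype on
#' a non-T lineage triggers a warning, not an error.
#'
#' @param path TSV file with header, or a data.frame already in memory.
#' @return data.frame of class `cell_metadata`, one row per cell.
#' @export
read_cell_metadata <- function(path) {
  tab <- if (is.data.frame(path)) path else
    read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("cell_id", "patient_id", "lineage", "subtype")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("cell metadata is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(tab$cell_id)) {
    dup <- unique(tab$cell_id[duplicated(tab$cell_id)])
    stop("duplicate cell_id(s) in cell metadata: ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  if (any(is.na(tab$lineage) | tab$lineage == ""))
    stop("cell metadata: empty lineage labels")
  if (any(is.na(tab$subtype) | tab$subtype == ""))
    stop("cell metadata: empty subtype labels")
  if (!"clonotype_id" %in% names(tab)) tab$clonotype_id <- NA_character_
  tab$clonotype_id[!is.na(tab$clonotype_id) & tab$clonotype_id == ""] <-
    NA_character_
  if (!"region" %in% names(tab)) tab$region <- NA_character_
  non_t <- !is.na(tab$clonotype_id) &
    !grepl("^T", tab$lineage, ignore.case = TRUE)
  if (any(non_t))
    warning(sum(non_t), " cell(s) carry a clonotype_id on a non-T lineage")
  rownames(tab) <- tab$cell_id
  class(tab) <- c("cell_metadata", "data.frame")
  tab
}

#' Read substitution sites from a VCF
#'
#' Consumes only CHROM/POS/REF/ALT; multi-allelic records are expanded and
#' non-substitution alleles (indels) are dropped. Used both for candidate
#' locus lists and for known-SNP masks.
#'
#' @param path VCF file (uncompressed or bgzipped).
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
read_site_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character()))
  alt_list <- strsplit(fix$ALT, ",", fixed = TRUE)
  n <- lengths(alt_list)
  out <- data.frame(chrom = normalize_chrom(rep(fix$CHROM, n)),
                    pos = as.integer(rep(fix$POS, n)),
                    ref = toupper(rep(fix$REF, n)),
                    alt = toupper(unlist(alt_list)),
                    stringsAsFactors = FALSE)
  out[nchar(out$ref) == 1L & nchar(out$alt) == 1L &
        out$ref %in% BASES & out$alt %in% BASES, , drop = FALSE]
}

#' Read gene annotation intervals with strand
#'
#' Accepts BED6 (strand in column 6; every interval is treated as an exon
#' of the named gene) or GFF3 (records typed `gene` or `exon`; gene name
#' from the `Name`/`gene`/`ID` attribute). Coordinates are returned
#' 1-based inclusive.
#'
#' @param path BED or GFF3 file; format chosen by extension
#'   (`.bed` vs `.gff`/`.gff3`).
#' @return `GRanges` with metadata columns `gene` and `type`.
#' @export
read_gene_annotation <- function(path) {
  gff <- grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE)
  gr <- rtracklayer::import(path)
  GenomeInfoDb::seqlevels(gr) <- normalize_chrom(GenomeInfoDb::seqlevels(gr))
  if (gff) {
    keep <- as.character(gr$type) %in% c("gene", "exon")
    gr <- gr[keep]
    mc <- S4Vectors::mcols(gr)
    gene <- if (!is.null(mc$gene)) mc$gene else
      if (!is.null(mc$Name)) mc$Name else mc$ID
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      gene = as.character(gene), type = as.character(gr$type))
  } else {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      gene = as.character(gr$name), type = "exon")
  }
  if (any(!as.character(BiocGenerics::strand(gr)) %in% c("+", "-")))
    stop("gene annotation: every interval needs a +/- strand")
  gr
}

#' Bundle the masks consumed by the filter cascade
#'
#' @param known_snp_sites data.frame of known-SNP substitution sites
#'   (columns `chrom`, `pos`, `alt`; e.g. from [read_site_vcf()]), or NULL
#'   for no mask (a warning is logged: calls cannot then be screened
#'   against population variation).
#' @param genes gene annotation `GRanges` from [read_gene_annotation()],
#'   or NULL.
#' @param deg_genes_by_cluster optional named list, cluster -> character
#'   vector of its top differentially expressed genes (used only by
#'   [build_mutation_matrix()]).
#' @return object of class `mask_set`.
#' @export
mask_set <- function(known_snp_sites = NULL, genes = NULL,
                     deg_genes_by_cluster = NULL) {
  snp_keys <- character()
  if (!is.null(known_snp_sites) && nrow(known_snp_sites)) {
    snp_keys <- paste(normalize_chrom(known_snp_sites$chrom),
                      as.integer(known_snp_sites$pos),
                      toupper(known_snp_sites$alt), sep = ":")
  } else {
    sc_log("empty SNP mask: calls will not be screened against known SNPs")
  }
  structure(list(snp_keys = unique(snp_keys), genes = genes,
                 deg_genes_by_cluster = deg_genes_by_cluster),
            class = "mask_set")
}

#' Read per-cluster top differentially expressed gene lists
#'
#' @param path TSV with columns `cluster`, `gene`, and optionally `rank`.
#' @param top keep the `top` lowest-ranked genes per cluster (default 100,
#'   the usual size of a per-cluster marker list).
#' @return named list cluster -> character vector of genes.
#' @export
read_deg_lists <- function(path, top = 100L) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cluster", "gene") %in% names(tab)))
    stop("DEG table needs columns 'cluster' and 'gene'")
  if ("rank" %in% names(tab)) tab <- tab[order(tab$cluster, tab$rank), ]
  lapply(split(tab$gene, tab$cluster), function(g) utils::head(unique(g), top))
}

#' Write final calls as TSV and minimal VCF
#'
#' The TSV carries one row per call with locus, patient, top lineage, the
#' enrichment statistics and per-criterion pass flags. The VCF is a
#' minimal VCFv4.2 body with the statistics in INFO.
#'
#' @param calls a calls data.frame (see [call_mutations()]).
#' @param path output path (TSV) or VCF path for `write_calls_vcf`.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  out <- calls
  out$carriers <- vapply(out$carriers, paste, "", collapse = ",")
  if (!is.null(out$carriers_ignored))
    out$carriers_ignored <- vapply(out$carriers_ignored, paste, "",
                                   collapse = ",")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
write_calls_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=scmutcall",
    "##INFO=<ID=PATIENT,Number=1,Type=String,Description=\"Patient id\">",
    "##INFO=<ID=LINEAGE,Number=1,Type=String,Description=\"Top lineage\">",
    "##INFO=<ID=NVAR,Number=1,Type=Integer,Description=\"Variant cells in top lineage\">",
    "##INFO=<ID=NREF,Number=1,Type=Integer,Description=\"Reference cells outside top lineage\">",
    "##INFO=<ID=FISHP,Number=1,Type=Float,Description=\"One-sided Fisher enrichment p\">",
    "##INFO=<ID=EF,Number=1,Type=Float,Description=\"Enrichment factor\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls)) {
    info <- sprintf("PATIENT=%s;LINEAGE=%s;NVAR=%d;NREF=%d;FISHP=%.3g;EF=%s",
                    calls$patient_id, calls$top_group, calls$var_cells_top,
                    calls$ref_cells_other, calls$fisher_p,
                    ifelse(is.infinite(calls$enrichment_factor), "inf",
                           sprintf("%.4g", calls$enrichment_factor)))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", calls$chrom,
                       calls$pos, calls$ref, calls$alt, info), con)
  }
  invisible(path)
}
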