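#' Enumerate candidate mutations from an allele count matrix
#'
#' A locus is a candidate, within a patient, when at least one of that
#' patient's cells holds a variant-supporting read there; a cell carries
#' the candidate when its variant count is >= 1. Candidates are
#' patient-scoped throughout the cascade: the same genomic locus seen in
#' two patients yields two candidate rows.
#'
#' @param acm an [allele_count_matrix()].
#' @param cells cell metadata from [read_cell_metadata()].
#' @return data.frame of class `mutation_candidates`: one row per
#'   (patient, locus), with a `carriers` list-column of carrier cell ids.
#' @export
enumerate_candidates <- function(acm, cells) {
  if (nrow(acm$loci) == 0) stop("empty allele count matrix")
  unknown <- setdiff(colnames(acm$var), cells$cell_id)
  if (length(unknown))
    stop("cells in count matrix but not metadata: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  tri <- Matrix::mat2triplet(acm$var)
  keep <- tri$x >= 1
  i <- tri$i[keep]; j <- tri$j[keep]
  cell_id <- colnames(acm$var)[j]
  patient <- cells[cell_id, "patient_id"]
  grp <- paste(patient, i, sep = "\r")
  carrier_by <- split(cell_id, grp)
  first <- !duplicated(grp)
  key_i <- i[first]; key_p <- patient[first]
  ord <- order(key_p, key_i)
  key_i <- key_i[ord]; key_p <- key_p[ord]
  out <- data.frame(patient_id = key_p,
                    locus = rownames(acm$loci)[key_i],
                    acm$loci[key_i, , drop = FALSE],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$carriers <- unname(carrier_by[paste(key_p, key_i, sep = "\r")])
  out$carriers <- lapply(out$carriers, sort)
  out$carriers_ignored <- rep(list(character()), nrow(out))
  out$n_carriers <- lengths(out$carriers)
  class(out) <- c("mutation_candidates", "data.frame")
  out
}

#' Remove singlet candidates
#'
#' A variant seen in exactly one cell of a patient cannot be distinguished
#' from a one-off error, so it is discarded. Applied per patient.
#'
#' @param candidates candidates from [enumerate_candidates()].
#' @return candidates with >= 2 carrier cells each.
#' @export
remove_singlets <- function(candidates) {
  candidates[lengths(candidates$carriers) >= 2L, , drop = FALSE]
}

#' Remove candidates shared across major cell lineages
#'
#' Somatic mutations are acquired after embryonic differentiation, so a
#' genuine mutation cannot be carried by cells of more than one major
#' lineage; sharing marks a site-specific artifact (or germline variation)
#' and the candidate is dropped.
#'
#' @param candidates candidates table.
#' @param cells cell metadata; every carrier must have a lineage.
#' @return candidates whose carriers all sit in one major lineage.
#' @export
remove_cross_lineage_shared <- function(candidates, cells) {
  n_lin <- vapply(candidates$carriers, function(cc) {
    lin <- cells[cc, "lineage"]
    if (anyNA(lin))
      stop("carrier cell(s) with unknown lineage: ",
           paste(utils::head(cc[is.na(lin)], 5L), collapse = ", "))
    length(unique(lin))
  }, 1L)
  candidates[n_lin == 1L, , drop = FALSE]
}

#' Per-cell binomial allelic filter
#'
#' In the absence of copy-number change, a true heterozygous mutation in
#' an expressed autosomal gene should show roughly equal reference and
#' variant reads in a cell; a strong reference excess suggests a mapping
#' or deep-sequencing artifact. For each carrier cell the one-sided
#' binomial tail P(X <= var | n = ref + var, p = 0.5) is computed; when
#' p < `alpha` the cell's call is ignored. Ignored cells keep their reads
#' and still count as reference-bearing cells downstream. Candidates left
#' with fewer than two credible carriers are dropped.
#'
#' The test is one-sided toward reference excess on purpose: cells with a
#' variant-read excess (allele-specific expression, transcriptional
#' bursts) are biologically expected and must not be discarded.
#'
#' @param candidates candidates table.
#' @param acm the allele count matrix.
#' @param alpha significance level (default 0.05).
#' @return candidates with `carriers` reduced to credible carriers and
#'   `carriers_ignored` holding the cells whose call was ignored.
#' @export
binomial_allelic_filter <- function(candidates, acm, alpha = 0.05) {
  if (!nrow(candidates)) return(candidates)
  for (r in seq_len(nrow(candidates))) {
    cc <- candidates$carriers[[r]]
    cnt <- locus_counts(acm, candidates$locus[r], cc)
    p <- pbinom(cnt$var, cnt$ref + cnt$var, 0.5)
    ign <- p < alpha
    candidates$carriers[[r]] <- cc[!ign]
    candidates$carriers_ignored[[r]] <-
      sort(c(candidates$carriers_ignored[[r]], cc[ign]))
  }
  candidates$n_carriers <- lengths(candidates$carriers)
  candidates[candidates$n_carriers >= 2L, , drop = FALSE]
}

#' Annotate candidates with gene, exonic class and trinucleotide context
#'
#' Fills the reference-orientation trinucleotide context (the variant base
#' with its two flanking reference bases), the overlapping gene and its
#' exonic class, and the transcribed-strand context: when the overlapping
#' gene lies on the minus strand the context is reverse-complemented;
#' loci overlapping genes on both strands get no strand assignment.
#'
#' @param candidates candidates table.
#' @param genome named `DNAStringSet` (or object coercible to one) of
#'   reference contigs; must cover each locus with one base of flank.
#' @param masks a [mask_set()] whose `genes` element supplies annotation
#'   intervals (may be NULL: candidates stay gene-less/strand-less).
#' @return candidates with columns `tri_context`, `gene`, `exonic_class`,
#'   `tx_strand`, `tx_context` added.
#' @export
annotate_candidates <- function(candidates, genome, masks = mask_set()) {
  if (!methods::is(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  names(genome) <- normalize_chrom(names(genome))
  n <- nrow(candidates)
  tri <- character(n)
  for (r in seq_len(n)) {
    chrom <- candidates$chrom[r]; pos <- candidates$pos[r]
    if (!chrom %in% names(genome))
      stop("contig absent from reference: ", chrom)
    if (pos - 1L < 1L || pos + 1L > Biostrings::width(genome[chrom]))
      stop("locus outside reference bounds (need one base of flank): ",
           candidates$locus[r])
    tri[r] <- as.character(Biostrings::subseq(genome[[chrom]],
                                              pos - 1L, pos + 1L))
    if (substr(tri[r], 2, 2) != candidates$ref[r])
      stop("reference base mismatch at ", candidates$locus[r],
           ": genome has ", substr(tri[r], 2, 2))
  }
  candidates$tri_context <- tri
  candidates$gene <- NA_character_
  candidates$exonic_class <- "intergenic"
  candidates$tx_strand <- NA_character_
  if (!is.null(masks$genes) && n > 0) {
    gr <- GenomicRanges::GRanges(candidates$chrom,
                                 IRanges::IRanges(candidates$pos, width = 1L))
    hits <- GenomicRanges::findOverlaps(gr, masks$genes, ignore.strand = TRUE)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      for (r in unique(q)) {
        sub <- s[q == r]
        genes <- sort(unique(masks$genes$gene[sub]))
        candidates$gene[r] <- paste(genes, collapse = ";")
        candidates$exonic_class[r] <-
          if (any(masks$genes$type[sub] == "exon")) "exonic" else "intronic"
        strands <- unique(as.character(BiocGenerics::strand(masks$genes[sub])))
        if (length(strands) == 1L) candidates$tx_strand[r] <- strands
      }
    }
  }
  candidates$tx_context <- ifelse(
    is.na(candidates$tx_strand), NA_character_,
    ifelse(candidates$tx_strand == "-", revcomp(candidates$tri_context),
           candidates$tri_context))
  candidates
}
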