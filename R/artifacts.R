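#' Inject labeled artifacts into a simulated dataset
#'
#' Adds the three artifact modes the cascade is designed to reject, all
#' recorded in a truth label table so tests can verify their removal:
#' \itemize{
#'   \item cross-lineage site-specific errors: variant reads in several
#'     cells of two or more major lineages (removed by
#'     [remove_cross_lineage_shared()]);
#'   \item strand-asymmetric context classes: sets of loci sharing one
#'     (trinucleotide, alt) class whose host genes sit on the plus versus
#'     minus strand at a configured ratio, each locus otherwise looking
#'     like a credible lineage-restricted mutation (removed by
#'     [strand_bias_filter()] when the class is large enough);
#'   \item singlet errors: variant reads in exactly one cell (removed by
#'     [remove_singlets()]).
#' }
#'
#' @param sim a `sim_dataset` from [simulate_dataset()].
#' @param cross_lineage number of cross-lineage artifact loci.
#' @param strand_classes list of class descriptors, each a list with
#'   `context` (trinucleotide, reference orientation), `alt`, `n`
#'   (members), `prob_plus` (probability a member's host gene is on the
#'   plus strand; the strand split is drawn binomially), and optionally
#'   `lineage` (host lineage of the carrier cells, default
#'   `"fibroblast"`), `n_cells` (carrier cells per locus, default 7) and
#'   `label` (truth label, default `"strand_artifact"`).
#' @param singlet number of singlet error loci.
#' @param seed RNG seed for the injection (default: dataset seed + 1).
#' @return the `sim_dataset` with an updated count matrix and an
#'   `artifacts` label table.
#' @export
inject_artifacts <- function(sim, cross_lineage = 0L, strand_classes = list(),
                             singlet = 0L, seed = sim$config$seed + 1L) {
  stopifnot(inherits(sim, "sim_dataset"))
  set.seed(seed)
  cells <- sim$cells
  p1 <- sort(unique(cells$patient_id))[1]
  pcells <- cells[cells$patient_id == p1, ]
  new_counts <- list(); labels <- list()
  used <- sim$used_loci
  note <- function(loc) used <<- rbind(used, data.frame(chrom = loc$chrom,
                                                        pos = loc$pos))
  add_locus_counts <- function(loc, carriers) {
    new_counts[[length(new_counts) + 1L]] <<- simulate_locus_counts(
      pcells$cell_id, sim$gene_rates[[loc$gene]], sim$config$depth_mean,
      carriers, 0, 0, loc, force_carriers = TRUE)
  }
  add_label <- function(loc, type, class = NA_character_,
                        lineage = NA_character_, carriers = character()) {
    labels[[length(labels) + 1L]] <<- data.frame(
      locus = locus_key(loc$chrom, loc$pos, loc$ref, loc$alt),
      chrom = loc$chrom, pos = loc$pos, ref = loc$ref, alt = loc$alt,
      patient_id = p1, type = type, class = class, lineage = lineage,
      n_cells = length(carriers), stringsAsFactors = FALSE)
  }

  for (i in seq_len(cross_lineage)) {
    loc <- draw_locus(sim$genome, sim$genes, used, sim$class_count,
                      class_cap = Inf)
    note(loc)
    lins <- sample(unique(pcells$lineage), 2L)
    carriers <- unlist(lapply(lins, function(l)
      sample(pcells$cell_id[pcells$lineage == l], 3L)))
    add_locus_counts(loc, carriers)
    add_label(loc, "cross_lineage", lineage = paste(lins, collapse = ";"),
              carriers = carriers)
  }

  for (cl in strand_classes) {
    lineage <- if (is.null(cl$lineage)) "fibroblast" else cl$lineage
    n_cells <- if (is.null(cl$n_cells)) 7L else cl$n_cells
    label <- if (is.null(cl$label)) "strand_artifact" else cl$label
    if (sprintf("%s>%s", cl$context, cl$alt) %in% names(sim$class_count))
      warning("artifact class collides with simulated truth class: ",
              cl$context, ">", cl$alt)
    n_plus <- stats::rbinom(1L, cl$n, cl$prob_plus)
    strands <- c(rep("+", n_plus), rep("-", cl$n - n_plus))
    for (s in strands) {
      loc <- draw_locus(sim$genome, sim$genes, used, sim$class_count,
                        class_cap = Inf, strand = s, context = cl$context,
                        alt = cl$alt)
      note(loc)
      carriers <- sample(pcells$cell_id[pcells$lineage == lineage], n_cells)
      add_locus_counts(loc, carriers)
      add_label(loc, label, class = sprintf("%s>%s", cl$context, cl$alt),
                lineage = lineage, carriers = carriers)
    }
  }

  for (i in seq_len(singlet)) {
    loc <- draw_locus(sim$genome, sim$genes, used, sim$class_count,
                      class_cap = Inf)
    note(loc)
    carriers <- sample(pcells$cell_id, 1L)
    add_locus_counts(loc, carriers)
    add_label(loc, "singlet", carriers = carriers)
  }

  if (length(new_counts)) {
    tab <- rbind(acm_to_table(sim$acm), do.call(rbind, new_counts))
    sim$acm <- allele_count_matrix(tab, cells)
  }
  sim$artifacts <- rbind(sim$artifacts, do.call(rbind, labels))
  sim$used_loci <- used
  sim
}

#' Binomially downsample read depth
#'
#' Thins every stored reference and variant count with independent
#' binomial draws at the given retention fraction, emulating shallower
#' sequencing. Entries whose counts both reach zero are dropped. To
#' compare a nested depth series (100%, 50%, 25%, ...), thin the already
#' thinned matrix again so lower depths are subsets of higher ones.
#'
#' @param acm an [allele_count_matrix()].
#' @param fraction retention probability in (0, 1].
#' @param seed RNG seed.
#' @return the thinned `allele_count_matrix`.
#' @export
downsample_counts <- function(acm, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(acm)
  set.seed(seed)
  tab <- acm_to_table(acm)
  tab$ref_count <- stats::rbinom(nrow(tab), tab$ref_count, fraction)
  tab$var_count <- stats::rbinom(nrow(tab), tab$var_count, fraction)
  tab <- tab[tab$ref_count + tab$var_count > 0, , drop = FALSE]
  allele_count_matrix(tab)
}

#' Write every file a simulated dataset exports
#'
#' Emits the formats the pipeline reads: counts TSV, cell metadata TSV,
#' reference FASTA, gene BED6, SNP-mask VCF, DNA-evidence TSV, and the
#' truth/artifact tables as JSON.
#'
#' @param sim a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_counts(sim$acm, fp("counts.tsv"))
  write.table(sim$cells, fp("cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  Biostrings::writeXStringSet(sim$genome, fp("genome.fa"))
  rtracklayer::export(
    GenomicRanges::GRanges(GenomicRanges::seqnames(sim$genes),
                           IRanges::ranges(sim$genes),
                           strand = BiocGenerics::strand(sim$genes),
                           name = sim$genes$gene, score = 0L),
    fp("genes.bed"))
  snp <- sim$masks$snp_keys
  con <- file(fp("snp_mask.vcf"), "w")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (length(snp)) {
    parts <- do.call(rbind, strsplit(snp, ":", fixed = TRUE))
    pos <- as.integer(parts[, 2])
    ref <- vapply(seq_len(nrow(parts)), function(i)
      as.character(Biostrings::subseq(sim$genome[[parts[i, 1]]],
                                      pos[i], pos[i])), "")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", parts[, 1], pos, ref,
                       parts[, 3]), con)
  }
  close(con)
  dna <- sim$dna
  write.table(dna, fp("dna_evidence.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- sim$truth
  truth$assigned_carriers <- NULL
  jsonlite::write_json(list(truth = truth, artifacts = sim$artifacts),
                       fp("truth.json"), digits = NA)
  invisible(dir)
}
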