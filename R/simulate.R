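#' Configuration for the synthetic dataset generator
#'
#' The generator emulates the data regime the caller is built for:
#' several patients of droplet scRNA-seq with seven major cell lineages
#' and finer subtypes; a clonally structured tumor (a truncal clone with
#' two nested subclones); clonal hematopoiesis making subsets of myeloid
#' cells share mutations; expanded CD8+ T-cell clonotypes carrying
#' post-thymic mutations; expression-dependent per-cell coverage with
#' dropout; sequencing error; allelic dropout; and, via
#' [inject_artifacts()], the artifact classes the filter cascade exists
#' to remove.
#'
#' @param seed mandatory RNG seed; the whole dataset is a deterministic
#'   function of the configuration.
#' @param n_patients number of patients (cells and truth loci are drawn
#'   independently per patient).
#' @param lineage_sizes named integer vector of cells per major lineage
#'   per patient.
#' @param tumor_clone_muts mutations per tumor clone; the first clone is
#'   truncal (carried by every tumor cell), later clones are nested
#'   subclones.
#' @param tumor_clone_fractions fraction of tumor cells in each subclone
#'   (disjoint; same length as `tumor_clone_muts` minus one).
#' @param ch_clone_muts mutations per clonal-hematopoiesis myeloid clone.
#' @param ch_clone_fractions fraction of myeloid cells per CH clone
#'   (disjoint).
#' @param clonotype_sizes cell counts of the expanded CD8+ clonotypes;
#'   remaining CD8 cells become singleton clonotypes.
#' @param t_clone_muts post-thymic mutations per expanded clonotype.
#' @param pre_thymic_shared number of mutations shared between the
#'   largest and the smallest expanded clonotype (acquired before thymic
#'   selection; they violate single-clonotype restriction by design).
#' @param expression_meanlog,expression_sdlog log-normal parameters of
#'   the per-gene expression rate (probability a cell yields reads from
#'   the gene), clipped to `[0.25, 0.95]`.
#' @param depth_mean mean Poisson read depth per expressed cell-locus.
#' @param error_rate per-base sequencing error rate (variant reads in
#'   non-carrier cells).
#' @param ado_rate allelic-dropout probability: a carrier cell-locus
#'   expresses one allele only, chosen at random.
#' @param n_background_loci covered loci with no true variant (error-only
#'   candidates when `error_rate > 0`).
#' @param n_snp known heterozygous germline SNP sites (variant in every
#'   cell; also emitted in the SNP mask).
#' @param shared_site_across_patients when TRUE (and `n_patients >= 2`)
#'   one extra truth locus is planted in the first two patients to
#'   exercise the cross-patient mask.
#' @param dna_mode `"complete"`: DNA evidence corroborates every truth
#'   mutation (as if every compartment had been sequenced);
#'   `"tumor_only"`: only tumor-clone mutations are called orthogonally,
#'   so CH and T-clone calls surface as DNA false positives — the regime
#'   a real tumor-exome benchmark operates in.
#' @param dna_depth total DNA pileup depth per locus.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_patients = 1L,
                       lineage_sizes = c(T_NK = 400L, B_plasma = 100L,
                                         myeloid = 250L, endothelial = 80L,
                                         epithelial = 80L, fibroblast = 90L,
                                         tumor = 200L),
                       tumor_clone_muts = c(trunk = 18L, subA = 10L,
                                            subB = 10L),
                       tumor_clone_fractions = c(subA = 0.4, subB = 0.35),
                       ch_clone_muts = c(ch1 = 7L, ch2 = 5L),
                       ch_clone_fractions = c(ch1 = 0.30, ch2 = 0.15),
                       clonotype_sizes = c(40L, 30L, 25L, 20L, 15L),
                       t_clone_muts = 2L,
                       pre_thymic_shared = 0L,
                       expression_meanlog = log(0.65),
                       expression_sdlog = 0.25,
                       depth_mean = 8,
                       error_rate = 1e-3,
                       ado_rate = 0.1,
                       n_background_loci = 30L,
                       n_snp = 4L,
                       shared_site_across_patients = FALSE,
                       dna_mode = c("complete", "tumor_only"),
                       dna_depth = 60L) {
  if (missing(seed)) stop("sim_config: a seed is mandatory")
  stopifnot(all(lineage_sizes >= 0), all(tumor_clone_muts >= 0),
            error_rate >= 0, error_rate <= 1, ado_rate >= 0, ado_rate <= 1,
            depth_mean > 0, sum(tumor_clone_fractions) <= 1,
            sum(ch_clone_fractions) <= 1)
  structure(list(seed = as.integer(seed), n_patients = as.integer(n_patients),
                 lineage_sizes = lineage_sizes,
                 tumor_clone_muts = tumor_clone_muts,
                 tumor_clone_fractions = tumor_clone_fractions,
                 ch_clone_muts = ch_clone_muts,
                 ch_clone_fractions = ch_clone_fractions,
                 clonotype_sizes = as.integer(clonotype_sizes),
                 t_clone_muts = as.integer(t_clone_muts),
                 pre_thymic_shared = as.integer(pre_thymic_shared),
                 expression_meanlog = expression_meanlog,
                 expression_sdlog = expression_sdlog,
                 depth_mean = depth_mean, error_rate = error_rate,
                 ado_rate = ado_rate,
                 n_background_loci = as.integer(n_background_loci),
                 n_snp = as.integer(n_snp),
                 shared_site_across_patients = shared_site_across_patients,
                 dna_mode = match.arg(dna_mode),
                 dna_depth = as.integer(dna_depth)),
            class = "sim_config")
}

## Subtype labels per lineage used by the generator.
SIM_SUBTYPES <- list(
  T_NK = c("CD8_Tem", "CD8_Tex", "CD4_Tconv", "NK"),
  B_plasma = c("B_naive", "plasma"),
  myeloid = c("mono_CD14", "mono_CD16", "macro_TAM1", "macro_TAM2"),
  endothelial = "endo",
  epithelial = "epi_PT",
  fibroblast = "fibro",
  tumor = c("tumor_c1", "tumor_c2"))

## Small hermetic genome: random contigs plus a gene model with both
## strands, so annotation/strand logic is exercised without downloads.
build_sim_genome <- function() {
  contigs <- c(chr1 = 60000L, chr2 = 40000L, MT = 8000L)
  genome <- Biostrings::DNAStringSet(vapply(contigs, function(n)
    paste(sample(BASES, n, replace = TRUE), collapse = ""), ""))
  names(genome) <- names(contigs)
  genes_per_contig <- list(chr1 = 25L, chr2 = 16L, MT = 3L)
  rows <- list()
  k <- 0L
  for (chrom in names(genes_per_contig)) {
    n <- genes_per_contig[[chrom]]
    width <- 1500L; gap <- if (chrom == "MT") 600L else 800L
    start <- 200L
    for (i in seq_len(n)) {
      k <- k + 1L
      rows[[k]] <- data.frame(chrom = chrom, start = start,
                              end = start + width - 1L,
                              gene = sprintf("g%03d", k),
                              strand = if (k %% 2L == 0L) "-" else "+")
      start <- start + width + gap
    }
  }
  tab <- do.call(rbind, rows)
  genes <- GenomicRanges::GRanges(
    tab$chrom, IRanges::IRanges(tab$start, tab$end), strand = tab$strand,
    gene = tab$gene, type = "exon")
  list(genome = genome, genes = genes)
}

## Draw a fresh substitution locus inside a gene, respecting a minimum
## gap to already-used positions and a cap on (trinucleotide, alt) class
## size (so no truth class becomes large enough for the strand test).
draw_locus <- function(genome, genes, used, class_count, min_gap = 10L,
                       class_cap = 9L, strand = NULL, context = NULL,
                       alt = NULL, max_iter = 5000L) {
  pool <- if (is.null(strand)) genes else
    genes[as.character(BiocGenerics::strand(genes)) == strand]
  for (iter in seq_len(max_iter)) {
    g <- pool[sample.int(length(pool), 1L)]
    chrom <- as.character(GenomicRanges::seqnames(g))
    pos <- sample(seq(GenomicRanges::start(g) + 1L,
                      GenomicRanges::end(g) - 1L), 1L)
    if (any(abs(used$pos[used$chrom == chrom] - pos) <= min_gap)) next
    tri <- as.character(Biostrings::subseq(genome[[chrom]], pos - 1L,
                                           pos + 1L))
    if (!is.null(context) && tri != context) next
    ref <- substr(tri, 2L, 2L)
    alt_i <- if (is.null(alt)) sample(setdiff(BASES, ref), 1L) else alt
    if (alt_i == ref) stop("draw_locus: requested alt equals reference base")
    cls <- sprintf("%s>%s", tri, alt_i)
    cnt <- class_count[[cls]]
    if (!is.null(cnt) && cnt >= class_cap) next
    return(list(chrom = chrom, pos = pos, ref = ref, alt = alt_i, tri = tri,
                class = cls,
                gene = g$gene, strand = as.character(BiocGenerics::strand(g))))
  }
  stop("draw_locus: could not place a locus under the constraints")
}

## Simulate the per-cell counts of one locus: Bernoulli expression at the
## gene's rate, Poisson depth, balanced binomial allele sampling for
## carriers with optional allelic dropout, binomial error reads for
## non-carriers. Returns a count-table fragment (covered cells only).
simulate_locus_counts <- function(cell_ids, rate, depth_mean, carriers,
                                  error_rate, ado_rate, locus,
                                  force_carriers = FALSE) {
  n <- length(cell_ids)
  expressed <- stats::rbinom(n, 1L, rate) == 1L
  depth <- stats::rpois(n, depth_mean)
  depth[!expressed] <- 0L
  if (force_carriers) {
    ## artifact injection: the chosen cells must show variant reads
    car_idx <- cell_ids %in% carriers
    depth[car_idx] <- pmax(2L, stats::rpois(sum(car_idx), depth_mean))
  }
  keep <- depth > 0L
  if (!any(keep)) return(NULL)
  ids <- cell_ids[keep]; d <- depth[keep]
  is_car <- ids %in% carriers
  var <- integer(length(ids))
  if (any(is_car)) {
    nc <- sum(is_car)
    ado <- stats::rbinom(nc, 1L, ado_rate) == 1L
    v <- stats::rbinom(nc, d[is_car], 0.5)
    mono_var <- stats::rbinom(nc, 1L, 0.5) == 1L
    v[ado & mono_var] <- d[is_car][ado & mono_var]
    v[ado & !mono_var] <- 0L
    if (force_carriers) v <- pmax(1L, v)
    var[is_car] <- v
  }
  if (any(!is_car) && error_rate > 0)
    var[!is_car] <- stats::rbinom(sum(!is_car), d[!is_car], error_rate)
  data.frame(cell_id = ids, chrom = locus$chrom, pos = locus$pos,
             ref = locus$ref, alt = locus$alt,
             ref_count = d - var, var_count = var,
             stringsAsFactors = FALSE)
}

## Build the per-patient cell table (deterministic subtype split,
## clonotypes on CD8 cells).
sim_cells_one_patient <- function(cfg, patient) {
  rows <- list()
  k <- 0L
  for (lin in names(cfg$lineage_sizes)) {
    n <- cfg$lineage_sizes[[lin]]
    subs <- SIM_SUBTYPES[[lin]]
    if (is.null(subs)) subs <- lin
    st <- rep(subs, length.out = n)[order(rep(seq_along(subs),
                                              length.out = n))]
    for (i in seq_len(n)) {
      k <- k + 1L
      rows[[k]] <- data.frame(
        cell_id = sprintf("%s_c%04d", patient, k), patient_id = patient,
        lineage = lin, subtype = st[i], clonotype_id = NA_character_,
        region = "tumor_core", stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, rows)
  cd8 <- which(grepl("^CD8", cells$subtype))
  cd8 <- sample(cd8)  # random assignment of clones to CD8 cells
  if (sum(cfg$clonotype_sizes) > length(cd8))
    stop("sim_config: expanded clonotype sizes exceed the CD8 cell count")
  at <- 0L
  for (i in seq_along(cfg$clonotype_sizes)) {
    idx <- cd8[(at + 1L):(at + cfg$clonotype_sizes[i])]
    cells$clonotype_id[idx] <- sprintf("%s_clt%02d", patient, i)
    at <- at + cfg$clonotype_sizes[i]
  }
  rest <- cd8[(at + 1L):length(cd8)]
  cells$clonotype_id[rest] <- sprintf("%s_clt_s%03d", patient,
                                      seq_along(rest))
  cells
}

#' Generate a fully labeled synthetic dataset
#'
#' Produces cells, a sparse allele count matrix over the simulated
#' candidate loci, masks (SNP sites and gene annotation), DNA evidence,
#' and a truth table with a per-mutation detectability flag: a truth
#' mutation is flagged detectable when, in the realized counts, it has at
#' least 2 (and at least 5) credible carrier cells in its lineage after
#' the per-cell allelic filter, at least 20 reference cells outside that
#' lineage, passes the Fisher/enrichment thresholds, is patient-unique
#' and is absent from the SNP mask — i.e. exactly the conditions under
#' which the cascade can call it.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset` with elements `cells`, `acm`,
#'   `masks`, `genome`, `genes`, `gene_rates`, `dna`, `truth`,
#'   `artifacts` (empty; see [inject_artifacts()]) and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gb <- build_sim_genome()
  genome <- gb$genome; genes <- gb$genes
  rates <- pmin(0.95, pmax(0.25, stats::rlnorm(
    length(genes), config$expression_meanlog, config$expression_sdlog)))
  names(rates) <- genes$gene

  patients <- sprintf("P%02d", seq_len(config$n_patients))
  cells <- do.call(rbind, lapply(patients, function(p)
    sim_cells_one_patient(config, p)))
  cells <- read_cell_metadata(cells)

  used <- data.frame(chrom = character(), pos = integer())
  class_count <- list()
  note_locus <- function(loc) {
    used <<- rbind(used, data.frame(chrom = loc$chrom, pos = loc$pos))
    class_count[[loc$class]] <<-
      (if (is.null(class_count[[loc$class]])) 0L else
        class_count[[loc$class]]) + 1L
  }

  truth <- list(); counts <- list()
  for (p in patients) {
    pcells <- cells[cells$patient_id == p, ]
    ## clone membership
    tum <- sample(pcells$cell_id[pcells$lineage == "tumor"])
    clone_cells <- list(trunk = tum)
    at <- 0L
    for (cl in names(config$tumor_clone_fractions)) {
      nsub <- floor(config$tumor_clone_fractions[[cl]] * length(tum))
      clone_cells[[cl]] <- tum[(at + 1L):(at + nsub)]
      at <- at + nsub
    }
    mye <- sample(pcells$cell_id[pcells$lineage == "myeloid"])
    at <- 0L
    for (cl in names(config$ch_clone_fractions)) {
      nsub <- floor(config$ch_clone_fractions[[cl]] * length(mye))
      clone_cells[[cl]] <- mye[(at + 1L):(at + nsub)]
      at <- at + nsub
    }
    expanded <- sprintf("%s_clt%02d", p, seq_along(config$clonotype_sizes))
    for (cl in expanded)
      clone_cells[[cl]] <- pcells$cell_id[!is.na(pcells$clonotype_id) &
                                            pcells$clonotype_id == cl]
    ## mutation plan: (clone, origin lineage, clonotype label)
    plan <- list()
    add_mut <- function(clone, lineage, clonotype = NA_character_)
      plan[[length(plan) + 1L]] <<- list(clone = clone, lineage = lineage,
                                         clonotype = clonotype)
    for (cl in names(config$tumor_clone_muts))
      for (i in seq_len(config$tumor_clone_muts[[cl]]))
        add_mut(cl, "tumor")
    for (cl in names(config$ch_clone_muts))
      for (i in seq_len(config$ch_clone_muts[[cl]]))
        add_mut(cl, "myeloid")
    for (cl in expanded)
      for (i in seq_len(config$t_clone_muts))
        add_mut(cl, "T_NK", cl)
    if (config$pre_thymic_shared > 0) {
      for (i in seq_len(config$pre_thymic_shared))
        add_mut("pre_thymic", "T_NK", "pre_thymic")
      clone_cells[["pre_thymic"]] <-
        c(clone_cells[[expanded[1]]],
          clone_cells[[expanded[length(expanded)]]])
    }
    for (m in plan) {
      loc <- draw_locus(genome, genes, used, class_count)
      note_locus(loc)
      carriers <- clone_cells[[m$clone]]
      truth[[length(truth) + 1L]] <- data.frame(
        locus = locus_key(loc$chrom, loc$pos, loc$ref, loc$alt),
        chrom = loc$chrom, pos = loc$pos, ref = loc$ref, alt = loc$alt,
        patient_id = p, clone = m$clone, lineage = m$lineage,
        clonotype = m$clonotype, gene = loc$gene, tri_context = loc$tri,
        gene_strand = loc$strand, n_clone_cells = length(carriers),
        stringsAsFactors = FALSE)
      attr(truth[[length(truth)]], "carriers") <- carriers
      counts[[length(counts) + 1L]] <- simulate_locus_counts(
        pcells$cell_id, rates[[loc$gene]], config$depth_mean, carriers,
        config$error_rate, config$ado_rate, loc)
    }
  }
  truth_carriers <- lapply(truth, attr, "carriers")
  truth <- do.call(rbind, truth)
  truth$assigned_carriers <- truth_carriers

  ## one shared site across the first two patients (fails the
  ## cross-patient mask by design)
  if (config$shared_site_across_patients && config$n_patients >= 2L) {
    loc <- draw_locus(genome, genes, used, class_count)
    note_locus(loc)
    for (p in patients[1:2]) {
      pcells <- cells[cells$patient_id == p, ]
      carriers <- sample(pcells$cell_id[pcells$lineage == "tumor"], 30L)
      truth <- rbind(truth, data.frame(
        locus = locus_key(loc$chrom, loc$pos, loc$ref, loc$alt),
        chrom = loc$chrom, pos = loc$pos, ref = loc$ref, alt = loc$alt,
        patient_id = p, clone = "shared_site", lineage = "tumor",
        clonotype = NA_character_, gene = loc$gene, tri_context = loc$tri,
        gene_strand = loc$strand, n_clone_cells = 30L,
        assigned_carriers = I(list(carriers))))
      counts[[length(counts) + 1L]] <- simulate_locus_counts(
        pcells$cell_id, rates[[loc$gene]], config$depth_mean, carriers,
        config$error_rate, config$ado_rate, loc)
    }
  }

  ## germline SNP sites: heterozygous in every cell, listed in the mask
  snp <- list()
  for (i in seq_len(config$n_snp)) {
    loc <- draw_locus(genome, genes, used, class_count)
    note_locus(loc)
    snp[[i]] <- data.frame(chrom = loc$chrom, pos = loc$pos, ref = loc$ref,
                           alt = loc$alt)
    counts[[length(counts) + 1L]] <- simulate_locus_counts(
      cells$cell_id, rates[[loc$gene]], config$depth_mean, cells$cell_id,
      config$error_rate, 0, loc)
  }
  snp <- if (length(snp)) do.call(rbind, snp) else NULL

  ## covered background loci with no true variant
  for (i in seq_len(config$n_background_loci)) {
    loc <- draw_locus(genome, genes, used, class_count)
    note_locus(loc)
    counts[[length(counts) + 1L]] <- simulate_locus_counts(
      cells$cell_id, rates[[loc$gene]], config$depth_mean, character(),
      config$error_rate, config$ado_rate, loc)
  }

  acm <- allele_count_matrix(do.call(rbind, counts), cells)
  masks <- mask_set(known_snp_sites = snp, genes = genes)

  truth <- annotate_detectability(truth, acm, cells, masks)
  dna <- sim_dna_evidence(truth, config)

  structure(list(cells = cells, acm = acm, masks = masks, genome = genome,
                 genes = genes, gene_rates = rates, dna = dna, truth = truth,
                 artifacts = data.frame(), config = config,
                 used_loci = used, class_count = class_count),
            class = "sim_dataset")
}

## Flag each truth mutation detectable iff the realized counts satisfy
## every callable condition of the cascade (see simulate_dataset docs).
annotate_detectability <- function(truth, acm, cells, masks,
                                   config = call_config()) {
  n <- nrow(truth)
  truth$n_raw_carriers <- integer(n)
  truth$n_credible_carriers <- integer(n)
  truth$ref_cells_other <- integer(n)
  truth$detectable <- logical(n)
  site <- paste(truth$chrom, truth$pos, truth$alt, sep = ":")
  n_pat <- vapply(split(truth$patient_id, site),
                  function(x) length(unique(x)), 1L)
  for (r in seq_len(n)) {
    key <- truth$locus[r]
    if (!key %in% rownames(acm$loci)) next
    pcells <- intersect(colnames(acm$ref),
                        cells$cell_id[cells$patient_id == truth$patient_id[r]])
    cnt <- locus_counts(acm, key, pcells)
    has_var <- cnt$var >= 1
    credible <- has_var & !(pbinom(cnt$var, cnt$ref + cnt$var, 0.5) <
                              config$binom_alpha)
    lin <- cells[pcells, "lineage"]
    in_lin <- lin == truth$lineage[r]
    v_top <- sum(credible & in_lin)
    v_other <- sum(credible & !in_lin)
    ref_cell <- (!has_var & cnt$ref >= 1) | (has_var & !credible)
    r_top <- sum(ref_cell & in_lin)
    r_other <- sum(ref_cell & !in_lin)
    fe <- fisher_enrichment(v_top, r_top, v_other, r_other)
    truth$n_raw_carriers[r] <- sum(has_var)
    truth$n_credible_carriers[r] <- v_top
    truth$ref_cells_other[r] <- r_other
    truth$detectable[r] <-
      v_top >= max(2L, config$min_var_cells) &&
      v_top > v_other &&                    # its lineage is the top group
      r_other >= config$min_ref_cells &&
      fe$fisher_p < config$fisher_alpha &&
      fe$enrichment_factor >= config$min_enrichment &&
      n_pat[site[r]] == 1L &&
      !(site[r] %in% masks$snp_keys)
  }
  truth
}

## Orthogonal DNA evidence consistent with the clone fractions.
sim_dna_evidence <- function(truth, config) {
  frac <- c(trunk = 1.0, config$tumor_clone_fractions,
            config$ch_clone_fractions)
  rows <- lapply(seq_len(nrow(truth)), function(r) {
    cl <- truth$clone[r]
    f <- if (cl %in% names(frac)) frac[[cl]] else 0.3
    called <- config$dna_mode == "complete" || truth$lineage[r] == "tumor"
    v <- if (called) stats::rbinom(1L, config$dna_depth, f / 2) else 0L
    data.frame(patient_id = truth$patient_id[r], chrom = truth$chrom[r],
               pos = truth$pos[r], ref = truth$ref[r], alt = truth$alt[r],
               tumor_var = v, tumor_ref = config$dna_depth - v,
               normal_var = 0L, orthogonal_call = called)
  })
  out <- do.call(rbind, rows)
  out <- out[!duplicated(paste(out$patient_id, out$chrom, out$pos,
                               out$alt)), ]
  read_dna_evidence(out)
}
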