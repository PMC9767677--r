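test_that("group counts pool subtypes within a lineage and break ties", {
  cells <- read_cell_metadata(data.frame(
    cell_id = sprintf("c%02d", 1:40), patient_id = "P1",
    lineage = rep(c("T_NK", "myeloid"), each = 20),
    subtype = rep(c("CD8", "CD4", "mono", "macro"), each = 10)))
  counts <- toy_counts(c(
    lapply(sprintf("c%02d", 1:6), function(id)
      list(id, "chr1", 100, "A", "G", 3, 3)),       # T carriers (2 subtypes)
    lapply(sprintf("c%02d", 7:40), function(id)
      list(id, "chr1", 100, "A", "G", 5, 0))))      # reference cells
  acm <- allele_count_matrix(counts, cells)
  cand <- toy_candidate("P1", "chr1:100:A>G", sprintf("c%02d", 1:6))
  gc <- group_counts(cand, acm, cells, "lineage")
  expect_equal(gc$top_group, "T_NK")
  expect_equal(gc$var_top, 6L)
  expect_equal(gc$ref_top, 14L)      # T cells with reference base only
  expect_equal(gc$var_other, 0L)
  expect_equal(gc$ref_other, 20L)
  expect_false(gc$tie)

  ## tie at 3 carriers each: lexicographically first lineage, flagged
  cand2 <- toy_candidate("P1", "chr1:100:A>G",
                         sprintf("c%02d", c(1:3, 21:23)))
  gc2 <- group_counts(cand2, acm, cells, "lineage")
  expect_equal(gc2$top_group, "T_NK")
  expect_true(gc2$tie)
})

test_that("ignored carriers count as reference cells", {
  cells <- toy_cells()
  acm <- allele_count_matrix(toy_counts(list(
    list("c01", "chr1", 100, "A", "G", 2, 2),
    list("c04", "chr1", 100, "A", "G", 3, 3),
    list("c02", "chr1", 100, "A", "G", 30, 1),   # reference excess
    list("c03", "chr1", 100, "A", "G", 8, 0))), cells)
  cand <- toy_candidate("P1", "chr1:100:A>G", c("c01", "c04"),
                        ignored = "c02")
  gc <- group_counts(cand, acm, cells, "lineage")
  expect_equal(gc$var_top, 2L)               # both kept carriers are T_NK
  expect_equal(gc$ref_other, 2L)             # c02 (ignored) + c03
})

test_that("Fisher enrichment matches full-enumeration oracle on examples", {
  ## exclusively top-group mutation: p = tail sum, factor = +Inf
  fe <- fisher_enrichment(5, 15, 0, 50)
  expect_equal(fe$fisher_p, fisher_oracle(5, 15, 0, 50), tolerance = 1e-12)
  expect_identical(fe$enrichment_factor, Inf)
  ## identical proportions cannot be enriched
  fe2 <- fisher_enrichment(2, 2, 2, 2)
  expect_equal(fe2$enrichment_factor, 1)
  expect_gt(fe2$fisher_p, 0.05)
  ## prevalence-ratio arithmetic, recomputed independently
  fe3 <- fisher_enrichment(10, 20, 1, 200)
  expect_equal(fe3$enrichment_factor, (10 / 30) / (1 / 201))
  expect_equal(fe3$enrichment_factor, 67, tolerance = 0.01)
  ## degenerate all-zero table
  fe4 <- fisher_enrichment(0, 0, 0, 0)
  expect_equal(fe4$fisher_p, 1)
  expect_equal(fe4$enrichment_factor, 0)
})

test_that("Fisher p agrees with enumeration on random tables", {
  set.seed(202)
  for (i in 1:200) {
    tab <- as.integer(sample(0:60, 4, replace = TRUE))
    fe <- fisher_enrichment(tab[1], tab[2], tab[3], tab[4])
    expect_equal(fe$fisher_p, fisher_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-9)
    ## also agrees with the one-sided reference implementation
    ref <- stats::fisher.test(matrix(tab, 2, byrow = TRUE),
                              alternative = "greater")$p.value
    expect_equal(fe$fisher_p, ref, tolerance = 1e-9)
  }
})

test_that("final thresholds enforce all four criteria", {
  base <- data.frame(
    patient_id = "P1", locus = "chr1:100:A>G", chrom = "chr1", pos = 100L,
    ref = "A", alt = "G", fisher_p = 2e-5, enrichment_factor = 6,
    var_cells_top = 5L, ref_cells_other = 25L, stringsAsFactors = FALSE)
  ok <- apply_final_thresholds(base)
  expect_equal(nrow(ok), 1L)

  low_var <- base; low_var$var_cells_top <- 4L
  out <- apply_final_thresholds(low_var)
  expect_equal(nrow(out), 0L)
  expect_false(attr(out, "flags")$pass_min_var)

  ## a site called in two patients fails in both
  shared <- rbind(base, base)
  shared$patient_id <- c("P1", "P2")
  out2 <- apply_final_thresholds(shared)
  expect_equal(nrow(out2), 0L)
  expect_equal(attr(out2, "flags")$pass_patient_unique, c(FALSE, FALSE))

  ## SNP mask
  snp <- data.frame(chrom = "chr1", pos = 100L, alt = "G")
  out3 <- apply_final_thresholds(base, mask_set(known_snp_sites = snp))
  expect_equal(nrow(out3), 0L)
  expect_false(attr(out3, "flags")$pass_snp)

  ## weak enrichment or p above threshold fails
  weak <- base; weak$enrichment_factor <- 4.9
  expect_equal(nrow(apply_final_thresholds(weak)), 0L)
  slak <- base; slak$fisher_p <- 2e-4
  expect_equal(nrow(apply_final_thresholds(slak)), 0L)
})

test_that("raising the min-variant-cells threshold never grows the PASS set", {
  sim <- generous_sim()
  cands <- enumerate_candidates(sim$acm, sim$cells)
  cands <- remove_cross_lineage_shared(remove_singlets(cands), sim$cells)
  cands <- binomial_allelic_filter(cands, sim$acm)
  cands <- compute_enrichment(cands, sim$acm, sim$cells)
  sizes <- vapply(c(2, 5, 10, 20), function(k)
    nrow(apply_final_thresholds(cands, sim$masks,
                                call_config(min_var_cells = k))), 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("strand bias filter removes skewed classes and spares the rest", {
  mk <- function(n, ctx, alt, strands) data.frame(
    patient_id = "P1", locus = sprintf("chr1:%d:%s>%s", seq_len(n) * 100,
                                       substr(ctx, 2, 2), alt),
    chrom = "chr1", pos = seq_len(n) * 100L, ref = substr(ctx, 2, 2),
    alt = alt, tri_context = ctx, tx_strand = strands,
    stringsAsFactors = FALSE)
  skew <- mk(42, "GCA", "G", c(rep("+", 40), rep("-", 2)))
  bal <- mk(19, "TCT", "T", c(rep("+", 10), rep("-", 9)))
  tiny <- mk(3, "ACA", "T", rep("+", 3))
  calls <- rbind(skew, bal, tiny)
  out <- strand_bias_filter(calls)
  cls <- attr(out, "strand_classes")
  expect_true(cls["GCA>G", "removed"])
  ## oracle: two-sided exact binomial tail
  expect_equal(cls["GCA>G", "p"], 2 * binom_cdf_oracle(2, 42),
               tolerance = 1e-12)
  expect_false(cls["TCT>T", "removed"])
  expect_false(cls["ACA>T", "tested"])   # below min class size: untested
  expect_setequal(unique(out$tri_context), c("TCT", "ACA"))
  ## strand-unassignable members fall with their class
  skew2 <- skew
  skew2$tx_strand[1] <- NA
  out2 <- strand_bias_filter(rbind(skew2, bal))
  expect_false(any(out2$tri_context == "GCA"))
})

test_that("proximity clusters are removed per patient, transitively", {
  mk <- function(patient, pos) data.frame(
    patient_id = patient, locus = sprintf("chr1:%d:A>G", pos),
    chrom = "chr1", pos = pos, ref = "A", alt = "G",
    stringsAsFactors = FALSE)
  calls <- rbind(mk("A", 100), mk("A", 103), mk("A", 200), mk("A", 205),
                 mk("B", 102))
  out <- proximity_filter(calls)
  ## 100/103 clustered (gap 3); 200/205 kept (gap 5); patient B untouched
  expect_setequal(out$pos[out$patient_id == "A"], c(200, 205))
  expect_equal(out$pos[out$patient_id == "B"], 102)
  ## transitive chain: 100,104,108 all removed although 100-108 spans 8
  chain <- rbind(mk("C", 100), mk("C", 104), mk("C", 108))
  expect_equal(nrow(proximity_filter(chain)), 0L)
})

test_that("no PASS call has carriers in more than one major lineage", {
  sim <- noise_free_sim()
  calls <- call_mutations(sim$acm, sim$cells, sim$genome, sim$masks)
  n_lin <- vapply(calls$carriers, function(cc)
    length(unique(sim$cells[cc, "lineage"])), 1L)
  expect_true(all(n_lin == 1L))
})
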