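test_that("the generator is deterministic under its seed", {
  cfg <- sim_config(seed = 55)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(acm_to_table(s1$acm), acm_to_table(s2$acm))
  expect_identical(s1$truth$locus, s2$truth$locus)
  expect_identical(s1$dna$tumor_var, s2$dna$tumor_var)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_sim_dataset(s1, d1); write_sim_dataset(s2, d2)
  for (f in c("counts.tsv", "cells.tsv", "genome.fa", "genes.bed",
              "snp_mask.vcf", "dna_evidence.tsv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("an infeasible configuration is rejected", {
  expect_error(sim_config(seed = 1, error_rate = 2), "error_rate")
  expect_error(simulate_dataset(
    sim_config(seed = 1, clonotype_sizes = rep(100L, 10))),
    "exceed the CD8 cell count")
  expect_error(sim_config())
})

test_that("noise-free counts contain no variant reads outside carriers", {
  sim <- noise_free_sim()
  tab <- acm_to_table(sim$acm)
  key <- locus_key(tab$chrom, tab$pos, tab$ref, tab$alt)
  carrier_of <- split(unlist(sim$truth$assigned_carriers),
                      rep(sim$truth$locus, lengths(sim$truth$assigned_carriers)))
  snp_loci <- vapply(strsplit(sim$masks$snp_keys, ":"), function(p)
    paste0(p[1], ":", p[2]), "")
  for (i in which(tab$var_count > 0)) {
    site <- paste0(tab$chrom[i], ":", tab$pos[i])
    expect_true(site %in% snp_loci ||
                  tab$cell_id[i] %in% carrier_of[[key[i]]])
  }
})

test_that("detectable truth mutations really have callable support", {
  sim <- noise_free_sim()
  det <- sim$truth[sim$truth$detectable, ]
  expect_gte(nrow(det), 50)
  expect_true(all(det$n_credible_carriers >= 5))
  expect_true(all(det$ref_cells_other >= 20))
  ## carrier counts in the truth table match a direct matrix scan
  for (r in sample(nrow(sim$truth), 10)) {
    key <- sim$truth$locus[r]
    v <- sim$acm$var[key, ]
    expect_equal(sim$truth$n_raw_carriers[r], sum(v >= 1))
  }
})

test_that("artifact injection is labeled, additive and seeded", {
  sim <- noise_free_sim()
  sim2 <- inject_artifacts(sim, cross_lineage = 25, singlet = 4, seed = 9)
  expect_equal(sum(sim2$artifacts$type == "cross_lineage"), 25L)
  ## labels never leak into the truth mutation list
  expect_length(intersect(sim2$artifacts$locus, sim2$truth$locus), 0)
  ## injected loci gained entries; original entries are untouched
  tab0 <- acm_to_table(sim$acm)
  tab2 <- acm_to_table(sim2$acm)
  orig <- tab2[paste(tab2$chrom, tab2$pos) %in% paste(tab0$chrom, tab0$pos), ]
  rownames(orig) <- NULL
  expect_identical(orig, tab0)
  ## zero-artifact call is the identity
  sim3 <- inject_artifacts(sim)
  expect_identical(acm_to_table(sim3$acm), tab0)
  ## cross-lineage artifacts span >= 2 lineages with >= 2 cells each
  for (loc in sim2$artifacts$locus[sim2$artifacts$type == "cross_lineage"]) {
    v <- sim2$acm$var[loc, ]
    lin <- table(sim2$cells[names(v)[v >= 1], "lineage"])
    expect_gte(length(lin), 2)
    expect_true(all(lin >= 2))
  }
})

test_that("strand-class artifacts land at the configured asymmetry", {
  sim <- cached("strand_sim", {
    s <- simulate_dataset(sim_config(seed = 31, error_rate = 0,
                                     ado_rate = 0))
    inject_artifacts(s, strand_classes = list(
      list(context = "GCA", alt = "G", n = 42, prob_plus = 20 / 21)),
      seed = 32)
  })
  art <- sim$artifacts[sim$artifacts$type == "strand_artifact", ]
  expect_equal(nrow(art), 42L)
  ## all share one (trinucleotide, alt) class in reference orientation
  expect_equal(unique(art$class), "GCA>G")
  ## strand split is binomial around 40:2
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(art$chrom, IRanges::IRanges(art$pos, width = 1)),
    sim$genes, ignore.strand = TRUE)
  strand <- as.character(BiocGenerics::strand(
    sim$genes[S4Vectors::subjectHits(hits)]))
  expect_equal(length(strand), 42L)
  expect_gte(sum(strand == "+"), 35)
  expect_lte(sum(strand == "-"), 7)
})

test_that("a locus shared across patients appears in both matrices", {
  sim <- cached("two_patient", simulate_dataset(
    sim_config(seed = 21, n_patients = 2L, error_rate = 0, ado_rate = 0,
               shared_site_across_patients = TRUE)))
  shared <- sim$truth[sim$truth$clone == "shared_site", ]
  expect_equal(nrow(shared), 2L)
  expect_equal(length(unique(shared$locus)), 1L)
  expect_false(any(shared$detectable))
  key <- shared$locus[1]
  for (p in unique(shared$patient_id)) {
    pcells <- sim$cells$cell_id[sim$cells$patient_id == p]
    expect_gte(sum(sim$acm$var[key, intersect(pcells,
                                              colnames(sim$acm$var))]), 1)
  }
  ## and the pipeline masks it out in both patients
  calls <- call_mutations(sim$acm, sim$cells, sim$genome, sim$masks)
  expect_false(key %in% calls$locus)
  flags <- attr(calls, "flags")
  expect_true(all(!flags$pass_patient_unique[flags$locus == key]))
})

test_that("downsampling thins counts monotonically", {
  sim <- noise_free_sim()
  half <- downsample_counts(sim$acm, 0.5, seed = 8)
  t0 <- acm_to_table(sim$acm); th <- acm_to_table(half)
  expect_lt(sum(th$ref_count) + sum(th$var_count),
            sum(t0$ref_count) + sum(t0$var_count))
  k0 <- paste(t0$cell_id, t0$chrom, t0$pos)
  kh <- paste(th$cell_id, th$chrom, th$pos)
  expect_true(all(kh %in% k0))
  m <- match(kh, k0)
  expect_true(all(th$ref_count <= t0$ref_count[m]))
  expect_true(all(th$var_count <= t0$var_count[m]))
})
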