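options(scmutcall.quiet = TRUE)

## Simulated datasets are shared across test files through a memoising
## cache: each named configuration is generated once per test run.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .sim_cache))
    assign(name, force(expr), envir = .sim_cache)
  get(name, envir = .sim_cache)
}

## Noise-free dataset at the study scale: 1 patient, 1200 cells over the
## 7 major lineages, 60 clonally structured truth mutations.
noise_free_sim <- function() {
  cached("noise_free", simulate_dataset(
    sim_config(seed = 101, error_rate = 0, ado_rate = 0)))
}

## Generous-depth noise-free dataset: deep, well-expressed loci so every
## truth mutation is detectable (for exact-closure properties).
generous_sim <- function() {
  cached("generous", simulate_dataset(
    sim_config(seed = 103, error_rate = 0, ado_rate = 0, depth_mean = 12,
               expression_meanlog = log(0.85), expression_sdlog = 0.1)))
}

## Small hand-built cell table: three lineages, two patients.
toy_cells <- function() {
  read_cell_metadata(data.frame(
    cell_id = sprintf("c%02d", 1:12),
    patient_id = rep(c("P1", "P2"), each = 6),
    lineage = rep(c("T_NK", "myeloid", "tumor"), 4),
    subtype = rep(c("CD8", "mono", "tum1"), 4),
    stringsAsFactors = FALSE))
}

## Hand-built count table for one patient-scoped candidate locus.
toy_counts <- function(rows) {
  do.call(rbind, lapply(rows, function(r)
    data.frame(cell_id = r[[1]], chrom = r[[2]], pos = as.integer(r[[3]]),
               ref = r[[4]], alt = r[[5]], ref_count = as.integer(r[[6]]),
               var_count = as.integer(r[[7]]), stringsAsFactors = FALSE)))
}

## Build a minimal candidates row for direct filter-level tests.
toy_candidate <- function(patient, locus_str, carriers,
                          ignored = character()) {
  parts <- strsplit(locus_str, "[:>]")[[1]]
  out <- data.frame(patient_id = patient, locus = locus_str,
                    chrom = parts[1], pos = as.integer(parts[2]),
                    ref = parts[3], alt = parts[4],
                    stringsAsFactors = FALSE)
  out$carriers <- list(carriers)
  out$carriers_ignored <- list(ignored)
  out$n_carriers <- length(carriers)
  out
}

## Independent oracle: exact binomial lower-tail CDF by direct summation
## of the probability mass function.
binom_cdf_oracle <- function(var, n, p = 0.5) {
  sum(choose(n, 0:var) * p^(0:var) * (1 - p)^(n - (0:var)))
}

## Independent oracle: one-sided Fisher p by full enumeration of all 2x2
## tables with the observed margins, summing the hypergeometric mass of
## tables at least as enriched in the top-left cell.
fisher_oracle <- function(a, b, c, d) {
  m <- a + c          # variant-cell margin
  n_top <- a + b      # top-group margin
  N <- a + b + c + d
  if (N == 0) return(1)
  ks <- max(0, n_top - (N - m)):min(m, n_top)
  mass <- vapply(ks, function(k)
    choose(m, k) * choose(N - m, n_top - k) / choose(N, n_top), 0)
  sum(mass[ks >= a])
}

## Independent oracle for tree recovery: enumerate every unrooted
## topology (n = 4, 5), fit branch lengths by constrained least squares,
## and pick the best-fitting topology.
best_fit_topology <- function(d) {
  taxa <- rownames(d)
  all_tr <- phangorn::allTrees(length(taxa), rooted = FALSE,
                               tip.label = taxa)
  errs <- vapply(all_tr, function(tr) {
    fit <- phangorn::nnls.tree(d, tr)
    sum((as.matrix(cophenetic(fit))[taxa, taxa] - d)^2)
  }, 0)
  all_tr[[which.min(errs)]]
}

same_topology <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
}
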