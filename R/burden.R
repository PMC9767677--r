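#' Per-lineage mutation-burden profile
#'
#' For every (patient, major lineage) group with at least `min_cells`
#' cells — smaller groups lack discriminatory power and are excluded with
#' a log entry — computes the proportion of cells carrying exactly one,
#' two, three, or more than three PASS mutations. Clonally structured
#' populations (tumor cells, clonal-hematopoiesis myeloid cells, expanded
#' T cells) show elevated multi-mutation fractions.
#'
#' @param calls PASS calls from [call_mutations()] (carrier lists used).
#' @param cells cell metadata.
#' @param min_cells minimum group size (default 100).
#' @return data.frame with `patient_id`, `lineage`, `n_cells`,
#'   `prop_1`, `prop_2`, `prop_3`, `prop_gt3`, `prop_0`.
#' @export
burden_profile <- function(calls, cells, min_cells = 100L) {
  per_cell <- table(unlist(calls$carriers))
  nmut <- setNames(rep(0L, nrow(cells)), cells$cell_id)
  nmut[names(per_cell)] <- as.integer(per_cell)
  grp <- paste(cells$patient_id, cells$lineage, sep = "\r")
  rows <- lapply(split(seq_len(nrow(cells)), grp), function(idx) {
    n <- length(idx)
    m <- nmut[cells$cell_id[idx]]
    data.frame(patient_id = cells$patient_id[idx[1]],
               lineage = cells$lineage[idx[1]], n_cells = n,
               prop_1 = sum(m == 1) / n, prop_2 = sum(m == 2) / n,
               prop_3 = sum(m == 3) / n, prop_gt3 = sum(m > 3) / n,
               prop_0 = sum(m == 0) / n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  small <- out$n_cells < min_cells
  if (any(small))
    sc_log("burden_profile: excluding ", sum(small),
           " group(s) under ", min_cells, " cells")
  out[!small, , drop = FALSE]
}
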