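#' Binary mutation-by-subtype matrix for lineage tracing
#'
#' Records, for each PASS mutation, which cell subtypes contain at least
#' `min_carriers` carrier cells. Because mutations are detected through
#' expression, mutations in genes that mark a cluster (its top
#' differentially expressed genes) would pull transcriptionally similar
#' subtypes together; any mutation whose gene appears in any cluster's
#' DEG list is therefore excluded before tree building. All-zero rows are
#' dropped.
#'
#' @param calls PASS calls (annotated with `gene`, carrier lists).
#' @param cells cell metadata (subtype labels).
#' @param deg_lists named list cluster -> top DEG genes, or NULL (a
#'   warning is logged and no exclusion is applied).
#' @param subtypes subtypes to include as columns (default: all subtypes
#'   observed among the carrier cells' metadata).
#' @param min_carriers carrier cells required for presence (default 1).
#' @return binary integer matrix, rows = mutation locus keys, columns =
#'   subtypes; excluded mutations recorded in attribute `"excluded"`.
#' @export
build_mutation_matrix <- function(calls, cells, deg_lists = NULL,
                                  subtypes = NULL, min_carriers = 1L) {
  if (is.null(subtypes)) subtypes <- sort(unique(cells$subtype))
  excluded <- character()
  if (is.null(deg_lists)) {
    sc_log("no DEG lists supplied: expression-marker exclusion skipped")
  } else {
    deg <- unique(unlist(deg_lists))
    genes <- strsplit(ifelse(is.na(calls$gene), "", calls$gene), ";")
    hit <- vapply(genes, function(g) any(g %in% deg), TRUE)
    excluded <- calls$locus[hit]
    calls <- calls[!hit, , drop = FALSE]
  }
  mat <- matrix(0L, nrow = nrow(calls), ncol = length(subtypes),
                dimnames = list(calls$locus, subtypes))
  for (r in seq_len(nrow(calls))) {
    st <- table(cells[calls$carriers[[r]], "subtype"])
    st <- names(st)[st >= min_carriers]
    mat[r, intersect(st, subtypes)] <- 1L
  }
  mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  attr(mat, "excluded") <- excluded
  mat
}

#' Asymmetric-binary (Jaccard) distance between subtypes
#'
#' For two subtypes, the fraction of mutations present in exactly one of
#' them among mutations present in at least one (double absences carry no
#' information and are ignored). Zero when the union is empty.
#'
#' @param mat binary mutation x subtype matrix.
#' @return symmetric subtype x subtype distance matrix with zero diagonal.
#' @export
binary_distance <- function(mat) {
  d <- as.matrix(stats::dist(t(mat > 0), method = "binary"))
  d[is.nan(d)] <- 0  # empty unions: no discordance observed
  d
}

#' Neighbor-joining tree over cell subtypes
#'
#' Standard Saitou-Nei neighbor joining on a subtype distance matrix.
#' Negative branch lengths (a known NJ artifact on non-additive input)
#' are clamped to zero and flagged.
#'
#' @param d square symmetric distance matrix, zero diagonal, >= 3 taxa.
#' @return unrooted `phylo` tree; attribute `"n_clamped"` counts clamped
#'   branches.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  tr <- ape::nj(stats::as.dist(d))
  neg <- tr$edge.length < 0
  if (any(neg)) {
    sc_log("nj_tree: clamping ", sum(neg), " negative branch length(s) to 0")
    tr$edge.length[neg] <- 0
  }
  attr(tr, "n_clamped") <- sum(neg)
  tr
}

#' Bootstrap supports for the subtype tree
#'
#' Resamples mutation rows with replacement `n_reps` times, rebuilding
#' the binary distance and NJ tree each time; the support of each
#' internal edge of the full-data tree is the number of replicates whose
#' tree contains the same bipartition. Resampling indices are drawn
#' explicitly under the given seed, so runs are reproducible.
#'
#' @param mat binary mutation x subtype matrix (>= 1 row).
#' @param n_reps bootstrap replicates (default 100).
#' @param seed RNG seed (default 1).
#' @return the full-data `phylo` tree with `node.label` holding supports
#'   (out of `n_reps`; the root label is empty).
#' @export
bootstrap_support <- function(mat, n_reps = 100L, seed = 1L) {
  if (nrow(mat) < 1) stop("mutation matrix has no rows")
  if (!is.null(rownames(mat)))  # canonical row order: supports do not
    mat <- mat[order(rownames(mat)), , drop = FALSE]  # depend on input order
  ref <- nj_tree(binary_distance(mat))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  idx <- replicate(n_reps, sample.int(nrow(mat), replace = TRUE),
                   simplify = FALSE)
  boots <- lapply(idx, function(i)
    nj_tree(binary_distance(mat[i, , drop = FALSE])))
  supp <- ape::prop.clades(ref, boots, rooted = FALSE)
  supp[is.na(supp)] <- 0L
  ref$node.label <- as.character(supp)
  ref$node.label[1] <- ""  # root of the unrooted representation
  attr(ref, "supports") <- supp
  ref
}

#' Write a subtype tree as Newick with supports as node labels
#'
#' @param tree `phylo` from [bootstrap_support()] or [nj_tree()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_subtype_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
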