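#' Sparse per-cell allele count matrix
#'
#' Container for reference/variant read counts at candidate substitution
#' loci, one row per locus and one column per cell. Counts are stored as
#' two parallel sparse matrices; a (cell, locus) pair with no reads at all
#' is absent rather than stored as zero.
#'
#' @param counts data.frame with columns `cell_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `ref_count`, `var_count`. Each (cell, locus) pair may appear at
#'   most once; duplicates are a validation error (no silent summing).
#' @param cells optional cell metadata (see [read_cell_metadata()]); when
#'   supplied, every `cell_id` in `counts` must be present in it.
#'
#' @return an object of class `allele_count_matrix` with components
#'   `ref` and `var` (loci x cells `dgCMatrix`) and `loci` (data.frame with
#'   `chrom`, `pos`, `ref`, `alt`, rownames = locus keys).
#' @export
allele_count_matrix <- function(counts, cells = NULL) {
  req <- c("cell_id", "chrom", "pos", "ref", "alt", "ref_count", "var_count")
  miss <- setdiff(req, names(counts))
  if (length(miss))
    stop("count table is missing required column(s): ",
         paste(miss, collapse = ", "))
  counts$chrom <- normalize_chrom(counts$chrom)
  counts$pos <- as.integer(counts$pos)
  counts$ref <- toupper(counts$ref); counts$alt <- toupper(counts$alt)
  check_loci(counts$chrom, counts$pos, counts$ref, counts$alt, "count table")
  if (any(counts$ref_count < 0) || any(counts$var_count < 0))
    stop("count table: negative read counts")
  key <- locus_key(counts$chrom, counts$pos, counts$ref, counts$alt)
  pair <- paste(counts$cell_id, key, sep = "\r")
  if (anyDuplicated(pair)) {
    dup <- unique(pair[duplicated(pair)])
    stop("duplicate (cell, locus) rows in count table: ",
         paste(utils::head(sub("\r", " @ ", dup), 5L), collapse = "; "))
  }
  if (!is.null(cells)) {
    unknown <- setdiff(unique(counts$cell_id), cells$cell_id)
    if (length(unknown))
      stop("count table references cell_id(s) absent from cell metadata: ",
           paste(utils::head(unknown, 5L), collapse = ", "))
  }
  keep <- counts$ref_count > 0 | counts$var_count > 0
  counts <- counts[keep, , drop = FALSE]
  key <- key[keep]

  ## canonical order: loci by genomic position, cells by id — so equal
  ## count sets always build byte-identical matrices
  lord <- order(counts$chrom, counts$pos, counts$ref, counts$alt)
  ukey <- unique(key[lord])
  ucell <- sort(unique(as.character(counts$cell_id)))
  i <- match(key, ukey)
  j <- match(counts$cell_id, ucell)
  dm <- list(ukey, ucell)
  ref <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(counts$ref_count),
                              dims = c(length(ukey), length(ucell)),
                              dimnames = dm)
  var <- Matrix::sparseMatrix(i = i, j = j, x = as.numeric(counts$var_count),
                              dims = c(length(ukey), length(ucell)),
                              dimnames = dm)
  loci <- unique(data.frame(chrom = counts$chrom, pos = counts$pos,
                            ref = counts$ref, alt = counts$alt,
                            row.names = NULL))
  rownames(loci) <- locus_key(loci$chrom, loci$pos, loci$ref, loci$alt)
  loci <- loci[ukey, , drop = FALSE]
  structure(list(ref = Matrix::drop0(ref), var = Matrix::drop0(var),
                 loci = loci),
            class = "allele_count_matrix")
}

#' @export
print.allele_count_matrix <- function(x, ...) {
  cat("allele_count_matrix:", nrow(x$loci), "loci x", ncol(x$ref), "cells;",
      length(x$ref@x) + length(x$var@x), "stored counts\n")
  invisible(x)
}

#' @export
dim.allele_count_matrix <- function(x) dim(x$ref)

#' Subset an allele count matrix by loci and/or cells
#'
#' @param x an `allele_count_matrix`.
#' @param loci locus keys (or logical/integer index over rows) to keep.
#' @param cells cell ids (or index over columns) to keep.
#' @return the subset `allele_count_matrix`.
#' @export
acm_subset <- function(x, loci = NULL, cells = NULL) {
  if (!is.null(loci)) {
    x$ref <- x$ref[loci, , drop = FALSE]
    x$var <- x$var[loci, , drop = FALSE]
    x$loci <- x$loci[rownames(x$ref), , drop = FALSE]
  }
  if (!is.null(cells)) {
    x$ref <- x$ref[, cells, drop = FALSE]
    x$var <- x$var[, cells, drop = FALSE]
  }
  x
}

#' Convert an allele count matrix to a long count table
#'
#' Inverse of [allele_count_matrix()]: one row per stored (cell, locus)
#' pair. Writing this table and reading it back reproduces the matrix.
#'
#' @param x an `allele_count_matrix`.
#' @return data.frame with the canonical count-table columns.
#' @export
acm_to_table <- function(x) {
  any_ <- x$ref + x$var  # union of stored entries
  tri <- Matrix::mat2triplet(any_)
  ord <- order(tri$j, tri$i)
  i <- tri$i[ord]; j <- tri$j[ord]
  out <- data.frame(
    cell_id = colnames(x$ref)[j],
    chrom = x$loci$chrom[i],
    pos = x$loci$pos[i],
    ref = x$loci$ref[i],
    alt = x$loci$alt[i],
    ref_count = as.integer(x$ref[cbind(i, j)]),
    var_count = as.integer(x$var[cbind(i, j)]),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read / write the canonical count-table TSV
#'
#' The on-disk format is a tab-separated table with header
#' `cell_id chrom pos ref alt ref_count var_count`.
#'
#' @param path file path.
#' @param cells optional cell metadata for cell-id validation.
#' @return `read_counts` returns an `allele_count_matrix`;
#'   `write_counts` returns `path` invisibly.
#' @export
read_counts <- function(path, cells = NULL) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  allele_count_matrix(tab, cells = cells)
}

#' @rdname read_counts
#' @param x an `allele_count_matrix` to write.
#' @export
write_counts <- function(x, path) {
  write.table(acm_to_table(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

## Per-locus count vectors for one candidate locus restricted to a cell set.
locus_counts <- function(acm, key, cell_ids) {
  list(ref = acm$ref[key, cell_ids], var = acm$var[key, cell_ids])
}
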