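#' @importFrom methods as is
#' @importFrom stats pbinom phyper setNames
#' @importFrom utils read.delim write.table
NULL

BASES <- c("A", "C", "G", "T")

#' Normalize a chromosome/contig name
#'
#' Mitochondrial contigs come under several aliases ("MT", "chrM", "M",
#' "chrMT"); all are mapped to the canonical label "MT" so that
#' mitochondrial loci join and mask correctly across inputs.
#'
#' @param chrom character vector of contig names.
#' @return character vector of normalized names.
#' @export
normalize_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  mito <- chrom %in% c("MT", "chrM", "M", "chrMT", "mt")
  chrom[mito] <- "MT"
  chrom
}

#' Build the canonical locus key "chrom:pos:ref>alt"
#'
#' @param chrom,pos,ref,alt vectors describing substitution loci
#'   (1-based coordinates, VCF convention).
#' @return character vector of keys.
#' @export
locus_key <- function(chrom, pos, ref, alt) {
  sprintf("%s:%d:%s>%s", normalize_chrom(chrom), as.integer(pos),
          toupper(ref), toupper(alt))
}

## Validate substitution loci: single bases, alt != ref, pos >= 1.
check_loci <- function(chrom, pos, ref, alt, what = "locus table") {
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(!ref %in% BASES) || any(!alt %in% BASES))
    stop(what, ": ref/alt must be single bases A/C/G/T (substitutions only)")
  if (any(ref == alt))
    stop(what, ": alt base must differ from ref base")
  if (any(is.na(pos)) || any(pos < 1))
    stop(what, ": positions must be integers >= 1")
  invisible(TRUE)
}

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of DNA strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Shared message channel; suppressible with options(scmutcall.quiet = TRUE)
sc_log <- function(...) {
  if (!isTRUE(getOption("scmutcall.quiet", FALSE)))
    message("[scmutcall] ", ...)
  invisible(NULL)
}
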