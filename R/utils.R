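#' @useDynLib svgt, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats dpois pnorm fisher.test rbinom runif rnorm rpois setNames
#' @importFrom utils head tail
NULL

IUPAC_CHARS <- strsplit("ACGTUMRWSYKVHDBN", "")[[1]]

#' Reverse complement of a nucleotide string
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# fast scalar reverse complement (no S4 dispatch; hot path of the k-mer filter)
revcomp1 <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTacgt", "TGCAtgca", x))))
}

is_dna <- function(x) {
  all(strsplit(toupper(x), "")[[1]] %in% IUPAC_CHARS)
}

#' Phred-scale a p-value or error probability
#' @param p probability in (0, 1].
#' @param cap maximum returned value.
#' @return -10 log10(p), capped.
#' @export
phred <- function(p, cap = Inf) {
  pmin(-10 * log10(pmax(p, .Machine$double.xmin)), cap)
}

svgt_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "svgt_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Convert between 1-based closed (VCF) and 0-based half-open coordinates
#'
#' Internally all intervals are 0-based half-open; VCF positions are 1-based.
#' `vcf_to_internal(pos)` maps a 1-based position to the 0-based index of the
#' same base; `internal_to_vcf(start0)` is its inverse.
#'
#' @param pos 1-based position(s).
#' @param start0 0-based position(s).
#' @return integer vector.
#' @export
vcf_to_internal <- function(pos) as.integer(pos) - 1L

#' @rdname vcf_to_internal
#' @export
internal_to_vcf <- function(start0) as.integer(start0) + 1L

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

log_msg <- function(verbose, ...) {
  if (isTRUE(verbose)) message(sprintf(...))
}
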