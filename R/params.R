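#' Graph construction parameters
#'
#' @param read_length average read length in bases; also the default flank
#'   length and long-node split size.
#' @param flank_length flank node length (defaults to `read_length`).
#' @param min_sv_length minimum SV length to accept when parsing VCFs
#'   (structural variants are conventionally 50 bp+).
#' @return object of class `graph_params`.
#' @export
graph_params <- function(read_length = 150L,
                         flank_length = read_length,
                         min_sv_length = 50L) {
  stopifnot(read_length > 0, flank_length > 0, min_sv_length >= 0)
  structure(list(
    read_length = as.integer(read_length),
    flank_length = as.integer(flank_length),
    min_sv_length = as.integer(min_sv_length)
  ), class = "graph_params")
}

#' Graph alignment parameters
#'
#' Local alignment scoring is affine: a gap of length k scores
#' `gap_open + k * gap_extend`.
#'
#' @param match match score (> 0).
#' @param mismatch mismatch penalty (< 0).
#' @param gap_open gap opening penalty (< 0), charged once per gap.
#' @param gap_extend per-base gap extension penalty (< 0).
#' @param min_overlap_fraction minimum fraction of the read length a read must
#'   overlap a node to support it (the node length caps the threshold).
#' @param kmer_size k used by the unique-kmer read filter.
#' @param max_alignments cap on the number of co-optimal alignments collected
#'   per read (2 are enough to decide uniqueness; more aid diagnostics).
#' @return object of class `alignment_params`.
#' @export
alignment_params <- function(match = 1L, mismatch = -4L,
                             gap_open = -6L, gap_extend = -1L,
                             min_overlap_fraction = 0.10,
                             kmer_size = 16L,
                             max_alignments = 8L) {
  stopifnot(
    match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0,
    min_overlap_fraction > 0, min_overlap_fraction <= 1, kmer_size >= 1
  )
  structure(list(
    match = as.integer(match), mismatch = as.integer(mismatch),
    gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
    min_overlap_fraction = min_overlap_fraction,
    kmer_size = as.integer(kmer_size),
    max_alignments = as.integer(max_alignments)
  ), class = "alignment_params")
}

#' Breakpoint genotyping parameters
#'
#' The expected breakpoint read count is `lambda = depth * (read_length -
#' min_overlap) / read_length`. `eps` is the modelled rate of reads supporting
#' neither haplotype. Confidence filters: more than `min_reads` - 1 reads
#' (strictly "more than one read" at the default), two-sided depth Z-test p >=
#' `depth_p`, genotype quality >= `min_gq`, and a strand-bias Fisher test.
#'
#' The strand filter: with `fisher_verbatim = FALSE` (default) a breakpoint
#' passes when the Phred-scaled Fisher p-value is BELOW `fisher_phred`
#' (high Phred = strong strand bias = fail, the conventional semantics);
#' `fisher_verbatim = TRUE` inverts this to pass on Phred >= `fisher_phred`.
#'
#' @param depth genome-average fold coverage d (> 0).
#' @param read_length average read length l.
#' @param min_overlap minimum supporting overlap m in bases; default 10% of l.
#' @param eps error-read rate epsilon in `[0, 1)`.
#' @param mu haplotype fractions for a heterozygous pair (must sum to 1).
#' @param priors genotype prior: `NULL` for uniform, or a named numeric over
#'   genotype labels (e.g. `c("REF/REF" = .25, "REF/ALT" = .5, "ALT/ALT" = .25)`).
#' @param min_reads minimum read count (pass requires `R >= min_reads`).
#' @param depth_p minimum two-sided Z-test p-value for the depth filter.
#' @param min_gq minimum Phred genotype quality.
#' @param fisher_phred strand-bias Phred threshold.
#' @param fisher_verbatim see Details.
#' @param max_gq cap on reported genotype quality.
#' @return object of class `genotyping_params`.
#' @export
genotyping_params <- function(depth = 30, read_length = 150L,
                              min_overlap = ceiling(0.10 * read_length),
                              eps = 0.01, mu = c(0.5, 0.5), priors = NULL,
                              min_reads = 2L, depth_p = 0.01, min_gq = 10,
                              fisher_phred = 30, fisher_verbatim = FALSE,
                              max_gq = 100) {
  stopifnot(depth > 0, read_length > 0, min_overlap >= 0,
            eps >= 0, eps < 1, length(mu) == 2, abs(sum(mu) - 1) < 1e-9)
  if (min_overlap >= read_length)
    svgt_error("svgt_bad_params", "min_overlap must be smaller than read_length")
  if (!is.null(priors)) {
    if (any(!is.finite(priors)) || all(priors == 0))
      svgt_error("svgt_bad_params", "priors must be finite and not all zero")
  }
  structure(list(
    depth = depth, read_length = as.integer(read_length),
    min_overlap = as.integer(min_overlap), eps = eps, mu = mu,
    priors = priors, min_reads = as.integer(min_reads), depth_p = depth_p,
    min_gq = min_gq, fisher_phred = fisher_phred,
    fisher_verbatim = isTRUE(fisher_verbatim), max_gq = max_gq
  ), class = "genotyping_params")
}

#' Expected breakpoint read count (Poisson mean)
#'
#' `lambda = d * (l - m) / l` for depth d, read length l and minimum
#' supporting overlap m: only reads overlapping the junction by at least m
#' bases on the shorter side can support a breakpoint.
#'
#' @param d genome-average depth (> 0).
#' @param l read length.
#' @param m minimum supporting overlap in bases, `0 <= m < l`.
#' @return the Poisson mean.
#' @export
#' @examples
#' poisson_lambda(30, 150, 15) # 27
poisson_lambda <- function(d, l, m) {
  if (d <= 0) svgt_error("svgt_bad_params", "depth must be positive")
  if (m < 0 || m >= l)
    svgt_error("svgt_bad_params", "min overlap m must satisfy 0 <= m < l")
  d * (l - m) / l
}
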