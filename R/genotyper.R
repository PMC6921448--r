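# Poisson breakpoint genotype-likelihood model and confidence filters.
#
# At a breakpoint with connecting haplotype edges, read counts are modelled as
# Poisson: under a heterozygous pair the per-haplotype counts have means
# lambda * mu_h; under a homozygote the count has mean lambda * (1 - eps);
# reads supporting neither haplotype of the genotype have mean lambda * eps,
# with lambda = d (l - m) / l the expected breakpoint-spanning read count.

#' Heterozygous-genotype read-count likelihood
#'
#' `dpois(R_h1, lambda * mu_h1) * dpois(R_h2, lambda * mu_h2)` for a
#' heterozygous pair (h1 != h2). Computed in log space.
#'
#' @param counts a `breakpoint_counts`.
#' @param h1,h2 haplotype labels (must differ).
#' @param params [genotyping_params()].
#' @param log return the log-likelihood?
#' @return likelihood (or log-likelihood).
#' @export
het_likelihood <- function(counts, h1, h2, params, log = FALSE) {
  stopifnot(h1 != h2)
  lam <- poisson_lambda(params$depth, params$read_length, params$min_overlap)
  ll <- dpois(counts$R_h[[h1]], lam * params$mu[1L], log = TRUE) +
        dpois(counts$R_h[[h2]], lam * params$mu[2L], log = TRUE)
  if (log) ll else exp(ll)
}

#' Homozygous-genotype read-count likelihood
#'
#' `dpois(R_h, lambda * (1 - eps))`.
#'
#' @inheritParams het_likelihood
#' @param h haplotype label.
#' @return likelihood (or log-likelihood).
#' @export
hom_likelihood <- function(counts, h, params, log = FALSE) {
  lam <- poisson_lambda(params$depth, params$read_length, params$min_overlap)
  ll <- dpois(counts$R_h[[h]], lam * (1 - params$eps), log = TRUE)
  if (log) ll else exp(ll)
}

#' Error-read likelihood
#'
#' `dpois(R_not, lambda * eps)` where `R_not` is the number of reads at the
#' breakpoint supporting neither haplotype of the genotype under evaluation.
#' With `eps = 0` and a positive count this is 0 (log -Inf), not an error.
#'
#' @inheritParams het_likelihood
#' @param R_not count of reads supporting neither haplotype; defaults to
#'   `counts$R_neither`.
#' @return likelihood (or log-likelihood).
#' @export
error_likelihood <- function(counts, params, R_not = counts$R_neither,
                             log = FALSE) {
  lam <- poisson_lambda(params$depth, params$read_length, params$min_overlap)
  ll <- dpois(R_not, lam * params$eps, log = TRUE)
  if (log) ll else exp(ll)
}

genotype_pairs <- function(haps) {
  out <- list()
  for (i in seq_along(haps)) for (j in i:length(haps))
    out <- c(out, list(c(haps[i], haps[j])))
  out
}

gt_label <- function(pair) paste(pair, collapse = "/")

#' Genotype posterior over all unordered haplotype pairs
#'
#' For every unordered pair of connecting haplotypes the likelihood is the
#' product of the pair term (heterozygous: per-haplotype Poisson; homozygous:
#' single Poisson at mean `lambda (1 - eps)`) and the error term (Poisson at
#' mean `lambda eps` for the reads supporting neither haplotype of the pair).
#' Posteriors are prior-weighted and normalized; genotype quality is
#' `-10 log10(1 - max posterior)`, capped at `params$max_gq`.
#'
#' @param counts a `breakpoint_counts`.
#' @param params [genotyping_params()]. `params$priors` may be a named vector
#'   over genotype labels (`"REF/ALT"` style); unnamed genotypes get prior 0;
#'   `NULL` means uniform.
#' @return object of class `genotype_likelihoods`: `genotypes` (labels),
#'   `loglik`, `posterior`, `best`, `gq`.
#' @export
genotype_posterior <- function(counts, params) {
  haps <- counts$haplotypes
  if (length(haps) < 2L)
    svgt_error("svgt_bad_counts", "breakpoint must have >= 2 connecting edges")
  pairs <- genotype_pairs(haps)
  labels <- vapply(pairs, gt_label, "")
  loglik <- vapply(pairs, function(pr) {
    supp <- sum(counts$R_h[unique(pr)])
    R_not <- counts$R - supp
    pair_ll <- if (pr[1L] == pr[2L]) {
      hom_likelihood(counts, pr[1L], params, log = TRUE)
    } else {
      het_likelihood(counts, pr[1L], pr[2L], params, log = TRUE)
    }
    pair_ll + error_likelihood(counts, params, R_not = R_not, log = TRUE)
  }, 0.0)
  prior <- if (is.null(params$priors)) {
    rep(1 / length(labels), length(labels))
  } else {
    pr <- params$priors[labels]
    pr[is.na(pr)] <- 0
    if (all(pr == 0)) svgt_error("svgt_bad_params", "priors are all zero")
    as.numeric(pr / sum(pr))
  }
  logpost <- loglik + log(prior)
  logpost[prior == 0] <- -Inf
  m <- max(logpost)
  post <- if (is.finite(m)) exp(logpost - m) else rep(1, length(logpost))
  post <- post / sum(post)
  best <- which.max(post)
  gq <- min(phred(max(1 - post[best], 0), cap = params$max_gq), params$max_gq)
  structure(list(
    genotypes = labels, loglik = setNames(loglik, labels),
    posterior = setNames(post, labels), best = labels[best], gq = gq
  ), class = "genotype_likelihoods")
}

#' Two-sided Z test of breakpoint depth against the genomic average
#'
#' The total breakpoint read count R is compared to its expectation lambda
#' (variance lambda, the normal approximation to the Poisson).
#'
#' @param R total read count at the breakpoint.
#' @param params [genotyping_params()].
#' @return list with `p` and `pass` (p >= `params$depth_p`).
#' @export
depth_test <- function(R, params) {
  lam <- poisson_lambda(params$depth, params$read_length, params$min_overlap)
  if (lam <= 0) svgt_error("svgt_bad_params", "expected depth lambda is zero")
  z <- (R - lam) / sqrt(lam)
  p <- 2 * pnorm(-abs(z))
  list(p = p, pass = p >= params$depth_p)
}

#' Phred-scaled Fisher strand-bias test
#'
#' Two-sided Fisher exact test on a 2x2 allele-by-strand contingency table of
#' breakpoint-overlapping reads; returns `-10 log10(p)`.
#'
#' @param tab 2x2 matrix of non-negative counts (rows: alleles, cols: strands).
#' @return Phred-scaled p-value.
#' @export
fisher_strand_phred <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) svgt_error("svgt_bad_counts", "negative strand counts")
  if (any(dim(tab) != 2L)) svgt_error("svgt_bad_counts", "need a 2x2 table")
  if (sum(tab) == 0) return(0)
  p <- fisher.test(round(tab))$p.value
  phred(p)
}

strand_table <- function(counts) {
  haps <- counts$haplotypes
  if (length(haps) >= 2L) {
    rbind(c(counts$fwd[[haps[1L]]], counts$rev[[haps[1L]]]),
          c(counts$fwd[[haps[2L]]], counts$rev[[haps[2L]]]))
  } else {
    rbind(c(counts$fwd[[haps[1L]]], counts$rev[[haps[1L]]]),
          c(counts$neither_fwd, counts$neither_rev))
  }
}

#' Genotype one breakpoint with confidence filters
#'
#' Computes the genotype posterior, then applies the four confidence tests:
#' (1) more than one read aligned at the breakpoint regardless of allele;
#' (2) depth not significantly different from the genomic average (two-sided
#' Z test p >= 0.01); (3) genotype quality >= 10; (4) the Fisher strand-bias
#' criterion (see [genotyping_params()] for the two semantics). The breakpoint
#' is `passing` iff all four flags are clear; the genotype is reported either
#' way.
#'
#' @param counts a `breakpoint_counts`.
#' @param params [genotyping_params()].
#' @return object of class `breakpoint_genotype`: `likelihoods`, `counts`,
#'   `flags` (named logical: low_reads, bad_depth, low_gq, strand_bias),
#'   `status` ("passing"/"failing"), `fisher_phred`, `depth_p`.
#' @export
genotype_breakpoint <- function(counts, params = genotyping_params()) {
  gl <- genotype_posterior(counts, params)
  dt <- depth_test(counts$R, params)
  fs <- fisher_strand_phred(strand_table(counts))
  fisher_fail <- if (params$fisher_verbatim) fs < params$fisher_phred
                 else fs >= params$fisher_phred
  flags <- c(
    low_reads = counts$R < params$min_reads,
    bad_depth = !dt$pass,
    low_gq = gl$gq < params$min_gq,
    strand_bias = fisher_fail
  )
  structure(list(
    likelihoods = gl, counts = counts, flags = flags,
    status = if (any(flags)) "failing" else "passing",
    fisher_phred = fs, depth_p = dt$p
  ), class = "breakpoint_genotype")
}

#' JSON diagnostic record for a breakpoint genotype
#'
#' @param bpgt a `breakpoint_genotype`.
#' @return JSON string.
#' @export
breakpoint_to_json <- function(bpgt) {
  jsonlite::toJSON(list(
    breakpoint = bpgt$counts$breakpoint,
    R = bpgt$counts$R, R_h = as.list(bpgt$counts$R_h),
    R_neither = bpgt$counts$R_neither,
    loglik = as.list(bpgt$likelihoods$loglik),
    posterior = as.list(bpgt$likelihoods$posterior),
    best = bpgt$likelihoods$best, gq = bpgt$likelihoods$gq,
    flags = as.list(bpgt$flags), status = bpgt$status
  ), auto_unbox = TRUE, digits = NA)
}
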