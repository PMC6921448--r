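# Population-scale helpers: EM genotype priors under HWE, exact HWE
# filtering, SV merging/matching, benchmark metrics, breakpoint deviation.

#' EM estimate of allele frequency from genotype likelihoods
#'
#' Expectation-maximization under Hardy-Weinberg equilibrium: the E-step
#' weights each sample's genotype likelihoods by the HWE priors
#' (p^2, 2pq, q^2); the M-step sets q to the posterior-weighted alternative
#' allele count over 2N. The observed-data log-likelihood is non-decreasing
#' across iterations (asserted).
#'
#' @param lik N x 3 matrix of per-sample likelihoods over (ref/ref, ref/alt,
#'   alt/alt). Rows need not be normalized.
#' @param tol convergence tolerance on |delta q|.
#' @param max_iter iteration cap.
#' @return list with `q` (alt allele frequency), `priors` (named genotype
#'   priors p^2/2pq/q^2), `loglik` (trace), `iterations`.
#' @export
em_allele_frequency <- function(lik, tol = 1e-8, max_iter = 1000L) {
  lik <- as.matrix(lik)
  if (ncol(lik) != 3L) svgt_error("svgt_bad_input", "need an N x 3 likelihood matrix")
  if (any(!is.finite(lik)) || any(lik < 0))
    svgt_error("svgt_bad_input", "likelihoods must be finite and non-negative")
  n <- nrow(lik)
  q <- 0.5
  ll_trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    p <- 1 - q
    pri <- c(p^2, 2 * p * q, q^2)
    w <- sweep(lik, 2L, pri, `*`)
    rs <- rowSums(w)
    ll <- sum(log(pmax(rs, .Machine$double.xmin)))
    if (length(ll_trace) && ll < tail(ll_trace, 1L) - 1e-9)
      svgt_error("svgt_em_decreased", "EM log-likelihood decreased")
    ll_trace <- c(ll_trace, ll)
    post <- w / pmax(rs, .Machine$double.xmin)
    q_new <- sum(post[, 2L] + 2 * post[, 3L]) / (2 * n)
    done <- abs(q_new - q) < tol
    q <- q_new
    if (done) break
  }
  p <- 1 - q
  list(q = q,
       priors = c("REF/REF" = p^2, "REF/ALT" = 2 * p * q, "ALT/ALT" = q^2),
       loglik = ll_trace, iterations = length(ll_trace))
}

# Exact conditional distribution of the heterozygote count given the allele
# counts (log scale), via the standard recurrence between adjacent (same
# parity) heterozygote counts.
hwe_het_distribution <- function(n_ab, n_a, n_genotypes) {
  rare <- min(n_a, 2L * n_genotypes - n_a)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  logp <- numeric(length(hets))
  # recurrence upward from the smallest het count:
  # P(h+2)/P(h) = 4 * n_aa(h) * n_bb(h) / ((h+2) * (h+1))
  for (k in seq_along(hets)[-1L]) {
    h <- hets[k - 1L]
    naa <- (rare - h) / 2
    nbb <- n_genotypes - (h + naa)
    logp[k] <- logp[k - 1L] + log(4 * naa * nbb) - log((h + 2) * (h + 1))
  }
  logp <- logp - max(logp)
  pr <- exp(logp); pr <- pr / sum(pr)
  setNames(pr, hets)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of the heterozygote count given the allele counts
#' (all configurations enumerated; the p-value sums the probabilities of
#' configurations no more likely than the observed one). SVs with p < `alpha`
#' are flagged as HWE-failed.
#'
#' @param hom_ref,het,hom_alt genotype counts.
#' @param alpha pass threshold (default 1e-4).
#' @return list with `p` and `pass` (p >= alpha).
#' @export
hwe_fisher_test <- function(hom_ref, het, hom_alt, alpha = 1e-4) {
  if (any(c(hom_ref, het, hom_alt) < 0))
    svgt_error("svgt_bad_input", "negative genotype counts")
  n <- hom_ref + het + hom_alt
  n_a <- 2L * hom_alt + het
  if (n == 0L || n_a == 0L || n_a == 2L * n)
    return(list(p = 1, pass = TRUE))
  dist <- hwe_het_distribution(het, n_a, n)
  p_obs <- dist[[as.character(het)]]
  p <- sum(dist[dist <= p_obs * (1 + 1e-7)])
  p <- min(p, 1)
  list(p = p, pass = p >= alpha)
}

#' Genotype dosage coding
#'
#' 0 for homozygous-reference and missing genotypes, 1 for heterozygotes,
#' 2 for homozygous alternative.
#'
#' @param gt character vector of VCF-style genotypes.
#' @return integer vector of dosages.
#' @export
gt_dosage <- function(gt) {
  d <- integer(length(gt))
  d[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  d[gt %in% c("1/1", "1|1")] <- 2L
  d
}

interval_overlap <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2))

insertion_seq_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -4),
    gapOpening = 6, gapExtension = 1
  )
  Biostrings::nmatch(aln) / max(nchar(a), nchar(b))
}

#' Are two SV records the same variant (merge relation)?
#'
#' Deletions are the same when their deleted intervals have at least 80%
#' reciprocal overlap. Insertions are the same when their breakpoints are at
#' most 150 bp apart AND their inserted sequences share at least 80% matching
#' bases under local alignment (fraction of the longer sequence). Different
#' types or contigs never match.
#'
#' @param a,b [sv_record()]s.
#' @param recip_overlap reciprocal-overlap threshold.
#' @param ins_dist maximum insertion breakpoint distance (bp).
#' @param ins_identity minimum matching-base fraction for insertions.
#' @return logical flag.
#' @export
same_sv <- function(a, b, recip_overlap = 0.8, ins_dist = 150L,
                    ins_identity = 0.8) {
  if (a$contig != b$contig || a$type != b$type) return(FALSE)
  if (a$type == "deletion") {
    ov <- interval_overlap(a$start, a$end, b$start, b$end)
    return(ov >= recip_overlap * (a$end - a$start) &&
           ov >= recip_overlap * (b$end - b$start))
  }
  if (a$type == "insertion") {
    if (abs(a$start - b$start) > ins_dist) return(FALSE)
    return(insertion_seq_identity(a$alt_seq, b$alt_seq) >= ins_identity)
  }
  # swaps: same replaced span rule as deletions plus alt identity
  ov <- interval_overlap(a$start, a$end, b$start, b$end)
  ov >= recip_overlap * max(1L, a$end - a$start) &&
    ov >= recip_overlap * max(1L, b$end - b$start) &&
    insertion_seq_identity(a$alt_seq, b$alt_seq) >= ins_identity
}

#' Merge per-sample SV calls into a unique SV set
#'
#' Transitive-closure clustering under [same_sv()] (order-invariant); each
#' cluster is represented by its first member in genomic order.
#'
#' @param records list of [sv_record()]s (possibly from several samples).
#' @param ... thresholds passed to [same_sv()].
#' @return list of representative [sv_record()]s; attribute `"cluster"` maps
#'   each input record to its cluster index.
#' @export
merge_svs <- function(records, ...) {
  n <- length(records)
  if (!n) return(records)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (same_sv(records[[i]], records[[j]], ...)) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  # representative = first cluster member in genomic order (input-order
  # invariant), clusters emitted in genomic order of their representatives
  ord <- order(vapply(records, `[[`, "", "contig"),
               vapply(records, `[[`, 0L, "start"),
               vapply(records, `[[`, 0L, "end"))
  reps <- integer(0); rep_root <- integer(0)
  for (i in ord) {
    if (!roots[i] %in% rep_root) {
      reps <- c(reps, i); rep_root <- c(rep_root, roots[i])
    }
  }
  out <- records[reps]
  attr(out, "cluster") <- match(roots, rep_root)
  out
}

#' Split unique SVs into singleton and clustered sets
#'
#' An SV is clustered when any other unique SV lies strictly within `window`
#' bp upstream or downstream (a gap of exactly `window` bp is still a
#' singleton).
#'
#' @param records list of unique [sv_record()]s.
#' @param window proximity window in bp (default 150).
#' @return list with `singleton` and `clustered` record lists.
#' @export
exclude_clustered <- function(records, window = 150L) {
  n <- length(records)
  clustered <- logical(n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- records[[i]]; b <- records[[j]]
    if (a$contig != b$contig) next
    gap <- max(a$start, b$start) - min(a$end, b$end)
    if (gap < window) { clustered[i] <- TRUE; clustered[j] <- TRUE }
  }
  list(singleton = records[!clustered], clustered = records[clustered])
}

#' Do a call and a truth record match for benchmarking?
#'
#' Breakpoints (start and end) must be no more than `bp_dist` apart; deletions
#' must additionally have at least `recip_overlap` reciprocal overlap.
#'
#' @param call,truth [sv_record()]s.
#' @param bp_dist maximum breakpoint distance (default 500).
#' @param recip_overlap deletion reciprocal-overlap threshold (default 0.8).
#' @return logical flag.
#' @export
matches_truth <- function(call, truth, bp_dist = 500L, recip_overlap = 0.8) {
  if (call$contig != truth$contig || call$type != truth$type) return(FALSE)
  if (abs(call$start - truth$start) > bp_dist ||
      abs(call$end - truth$end) > bp_dist) return(FALSE)
  if (call$type == "deletion") {
    ov <- interval_overlap(call$start, call$end, truth$start, truth$end)
    return(ov >= recip_overlap * (call$end - call$start) &&
           ov >= recip_overlap * (truth$end - truth$start))
  }
  TRUE
}

#' Presence/absence benchmarking against a truth set
#'
#' A call with an alternative genotype is a true positive when some truth
#' record with an alternative genotype matches it ([matches_truth()]), and a
#' false positive otherwise. Recall = TP / (number of truth alternative
#' genotypes); precision = TP / (TP + FP); F = their harmonic mean. Genotype
#' concordance over the true positives is reported separately.
#'
#' @param calls,truth lists of [sv_record()]s carrying `genotype` fields
#'   (VCF style, e.g. "0/1"; "0/0" and "./." count as absent).
#' @param ... thresholds passed to [matches_truth()].
#' @return list with `tp`, `fp`, `fn`, `recall`, `precision`, `f_score`,
#'   `gt_concordance`, and the per-call match index `match_idx`.
#' @export
match_to_truth <- function(calls, truth, ...) {
  is_alt <- function(r) gt_dosage(r$genotype) > 0L
  truth_alt <- vapply(truth, is_alt, TRUE)
  call_alt <- vapply(calls, is_alt, TRUE)
  match_idx <- rep(NA_integer_, length(calls))
  used <- logical(length(truth))
  for (i in seq_along(calls)) {
    if (!call_alt[i]) next
    for (j in seq_along(truth)) {
      if (!truth_alt[j] || used[j]) next
      if (matches_truth(calls[[i]], truth[[j]], ...)) {
        match_idx[i] <- j; used[j] <- TRUE; break
      }
    }
  }
  tp <- sum(!is.na(match_idx))
  fp <- sum(call_alt) - tp
  n_truth_alt <- sum(truth_alt)
  recall <- if (n_truth_alt) tp / n_truth_alt else NA_real_
  precision <- if (tp + fp) tp / (tp + fp) else NA_real_
  f <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0)
    2 * recall * precision / (recall + precision) else NA_real_
  conc <- if (tp) {
    mean(vapply(which(!is.na(match_idx)), function(i)
      identical(gt_dosage(calls[[i]]$genotype),
                gt_dosage(truth[[match_idx[i]]]$genotype)), TRUE))
  } else NA_real_
  list(tp = tp, fp = fp, fn = n_truth_alt - tp,
       recall = recall, precision = precision, f_score = f,
       gt_concordance = conc, match_idx = match_idx)
}

#' Breakpoint deviation between a matched call and truth record
#'
#' The pair must match under the long-read comparison rule: breakpoints no
#' more than 500 bp apart and, for deletions, overlap at least 60% of the
#' union length (inclusive). Deviation is the absolute start (and end)
#' position difference; for insertions the inserted-sequence edit distance
#' from global pairwise alignment is also reported.
#'
#' @param call,truth [sv_record()]s.
#' @param bp_dist maximum breakpoint distance.
#' @param union_frac minimum overlap as a fraction of the union length.
#' @return list with `start`, `end` (absolute bp deviations), `deviation`
#'   (their mean) and, for insertions, `seq_edit_distance`.
#' @export
breakpoint_deviation <- function(call, truth, bp_dist = 500L, union_frac = 0.6) {
  if (call$contig != truth$contig || call$type != truth$type)
    svgt_error("svgt_unmatched", "records differ in contig or type")
  if (abs(call$start - truth$start) > bp_dist ||
      abs(call$end - truth$end) > bp_dist)
    svgt_error("svgt_unmatched", "breakpoints more than 500 bp apart")
  if (call$type == "deletion") {
    ov <- interval_overlap(call$start, call$end, truth$start, truth$end)
    un <- max(call$end, truth$end) - min(call$start, truth$start)
    if (ov < union_frac * un)
      svgt_error("svgt_unmatched", "overlap below 60% of the union length")
  }
  ds <- abs(call$start - truth$start)
  de <- abs(call$end - truth$end)
  out <- list(start = ds, end = de, deviation = (ds + de) / 2)
  if (call$type == "insertion") {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(call$alt_seq), Biostrings::DNAString(truth$alt_seq),
      type = "global")
    out$seq_edit_distance <- Biostrings::nedit(aln)
  }
  out
}
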