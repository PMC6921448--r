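# Variant-level genotyping: combine the two breakpoint genotypes of an SV.

#' Pool two breakpoints' counts and re-genotype
#'
#' Element-wise sum of the two `breakpoint_counts` (a read supporting both
#' breakpoints was counted at each, hence contributes twice) re-genotyped with
#' the depth parameter doubled. Commutative.
#'
#' @param c1,c2 `breakpoint_counts` from the two breakpoints of one SV.
#' @param params [genotyping_params()].
#' @return a `genotype_likelihoods` for the pooled counts, with the pooled
#'   `breakpoint_counts` attached as attribute `"counts"`.
#' @export
pool_and_regenotype <- function(c1, c2, params = genotyping_params()) {
  if (!identical(sort(c1$haplotypes), sort(c2$haplotypes)))
    svgt_error("svgt_bad_counts", "breakpoints carry different haplotype sets")
  h <- c1$haplotypes
  pooled <- breakpoint_counts(
    R_h = c1$R_h[h] + c2$R_h[h],
    R_neither = c1$R_neither + c2$R_neither,
    fwd = c1$fwd[h] + c2$fwd[h], rev = c1$rev[h] + c2$rev[h],
    neither_fwd = c1$neither_fwd + c2$neither_fwd,
    neither_rev = c1$neither_rev + c2$neither_rev,
    breakpoint = "pooled"
  )
  p2 <- params
  p2$depth <- 2 * params$depth
  gl <- genotype_posterior(pooled, p2)
  attr(gl, "counts") <- pooled
  gl
}

#' Combine two breakpoint genotypes into an SV genotype
#'
#' Decision tree: (1a) both breakpoints passing with the same genotype ->
#' that genotype, filter PASS; (1b) both passing, different genotypes ->
#' re-genotype on pooled reads with doubled depth, non-PASS
#' ("conflicting_breakpoints"); (2) exactly one passing -> the passing
#' breakpoint's genotype, non-PASS ("one_breakpoint_failing"); (3a) both
#' failing, same genotype -> that genotype, non-PASS ("breakpoints_failing");
#' (3b) both failing, different genotypes -> pooled re-genotype, non-PASS
#' ("breakpoints_failing"). Only branch 1a yields PASS.
#'
#' @param bp1,bp2 `breakpoint_genotype` objects from one SV's graph.
#' @param params [genotyping_params()].
#' @return object of class `sv_genotype`: `gt` (genotype label over
#'   haplotypes), `filter`, `branch`, `gq`, `breakpoints`, `pooled` (or NULL).
#' @export
combine_breakpoints <- function(bp1, bp2, params = genotyping_params()) {
  g1 <- bp1$likelihoods$best; g2 <- bp2$likelihoods$best
  p1 <- bp1$status == "passing"; p2 <- bp2$status == "passing"
  pooled <- NULL
  if (p1 && p2) {
    if (identical(g1, g2)) {
      branch <- "1a"; gt <- g1; filter <- "PASS"
      gq <- min(bp1$likelihoods$gq, bp2$likelihoods$gq)
    } else {
      branch <- "1b"
      pooled <- pool_and_regenotype(bp1$counts, bp2$counts, params)
      gt <- pooled$best; filter <- "conflicting_breakpoints"; gq <- pooled$gq
    }
  } else if (xor(p1, p2)) {
    branch <- "2"
    keep <- if (p1) bp1 else bp2
    gt <- keep$likelihoods$best; filter <- "one_breakpoint_failing"
    gq <- keep$likelihoods$gq
  } else {
    if (identical(g1, g2)) {
      branch <- "3a"; gt <- g1
      gq <- min(bp1$likelihoods$gq, bp2$likelihoods$gq)
    } else {
      branch <- "3b"
      pooled <- pool_and_regenotype(bp1$counts, bp2$counts, params)
      gt <- pooled$best; gq <- pooled$gq
    }
    filter <- "breakpoints_failing"
  }
  structure(list(
    gt = gt, filter = filter, branch = branch, gq = gq,
    breakpoints = list(bp1, bp2), pooled = pooled
  ), class = "sv_genotype")
}

#' Filter label / evaluation status of an SV genotype
#'
#' PASS iff decision-tree branch 1a fired. In `evaluation` mode an SV whose
#' breakpoints failed confidence criteria 1 (read count) or 2 (depth) is
#' reported as homozygous reference, mirroring how such calls are treated in
#' benchmarking; failures of criteria 3/4 only keep their called genotype.
#'
#' @param svgt an `sv_genotype`.
#' @param evaluation apply the criteria-1/2 to-reference rule?
#' @return list with `filter` and `gt` (possibly overridden).
#' @export
variant_filter_status <- function(svgt, evaluation = FALSE) {
  gt <- svgt$gt
  if (evaluation) {
    crit12_fail <- any(vapply(
      svgt$breakpoints,
      function(b) b$flags[["low_reads"]] || b$flags[["bad_depth"]],
      TRUE
    ))
    if (crit12_fail) gt <- ref_genotype(svgt)
  }
  list(filter = svgt$filter, gt = gt)
}

ref_genotype <- function(svgt) {
  haps <- svgt$breakpoints[[1L]]$counts$haplotypes
  ref <- if ("REF" %in% haps) "REF" else haps[1L]
  paste(ref, ref, sep = "/")
}

#' Map a haplotype-pair genotype label to VCF GT notation
#'
#' `"REF"` maps to allele 0, `"ALT"` to 1.
#'
#' @param gt genotype label such as `"REF/ALT"`.
#' @return string such as `"0/1"`.
#' @export
gt_to_vcf <- function(gt) {
  if (is.na(gt)) return("./.")
  al <- strsplit(gt, "/", fixed = TRUE)[[1L]]
  idx <- ifelse(al == "REF", 0L, 1L)
  paste(sort(idx), collapse = "/")
}

#' Genotype one SV record end to end (in-memory reads)
#'
#' Builds the graph, splits long nodes, realigns the given reads, filters
#' them (unique mapping, unique k-mer), counts breakpoint support, genotypes
#' both breakpoints and combines them.
#'
#' @param record an [sv_record()].
#' @param reads named character vector of read sequences near the SV.
#' @param reference reference accessor.
#' @param gparams [graph_params()].
#' @param aparams [alignment_params()].
#' @param tparams [genotyping_params()].
#' @return an `sv_genotype` with attributes `record` and `n_reads`.
#' @export
genotype_sv <- function(record, reads, reference,
                        gparams = graph_params(),
                        aparams = alignment_params(),
                        tparams = genotyping_params()) {
  graph <- build_graph(record, reference, gparams)
  graph <- split_long_nodes(graph, gparams$read_length)
  bps <- enumerate_breakpoints(graph)
  if (length(bps) != 2L)
    svgt_error("svgt_bad_graph",
               sprintf("expected 2 breakpoints, found %d", length(bps)))
  filtered <- if (length(reads)) {
    # the unique-kmer filter is alignment-independent: apply it first so
    # filtered-out reads (e.g. repeat-only reads at TR loci) skip the DP;
    # the retained set equals unique-mapping-then-unique-kmer order
    kt <- table(graph_kmers(graph, aparams$kmer_size))
    has_km <- vapply(reads, has_unique_kmer, TRUE,
                     graph = graph, k = aparams$kmer_size,
                     graph_kmer_table = kt)
    reads_km <- reads[has_km]
    if (length(reads_km)) {
      best_unique_alignments(align_reads(reads_km, graph, aparams))
    } else list()
  } else list()
  bpg <- lapply(bps, function(bp) {
    cnt <- count_breakpoint_support(bp, filtered, graph, aparams)
    genotype_breakpoint(cnt, tparams)
  })
  out <- combine_breakpoints(bpg[[1L]], bpg[[2L]], tparams)
  attr(out, "record") <- record
  attr(out, "n_reads") <- length(filtered)
  out
}
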