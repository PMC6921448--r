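# small configurations keep the module tests fast; the full-scale stated
# world (1 Mb, 100 SVs, 30x) runs in test-acceptance.R

small_cfg <- function(...) {
  simulation_config(reference_length = 60000L, n_sv = 6L, min_gap = 1500L,
                    seed = 5L, ...)
}

test_that("truth simulation is deterministic and honors the configuration", {
  cfg <- small_cfg()
  s1 <- simulate_truth(cfg)
  s2 <- simulate_truth(cfg)
  expect_identical(s1$reference, s2$reference)
  expect_identical(s1$records, s2$records)
  expect_identical(s1$haplotypes[[1L]]$seq, s2$haplotypes[[1L]]$seq)
  # FASTA and VCF bytes are identical under the same seed
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- write_simulation(s1, d1)
  p2 <- write_simulation(s2, d2)
  expect_identical(readLines(p1$fasta), readLines(p2$fasta))
  expect_identical(readLines(p1$vcf), readLines(p2$vcf))
})

test_that("an all-het deletion configuration yields exactly that truth set", {
  cfg <- simulation_config(reference_length = 200000L, n_sv = 20L,
                           type_mix = c(deletion = 1, insertion = 0),
                           genotype_probs = c("0/0" = 0, "0/1" = 1, "1/1" = 0),
                           tr_fraction = 0, seed = 9L)
  sim <- simulate_truth(cfg)
  expect_length(sim$records, 20L)
  expect_true(all(vapply(sim$records, `[[`, "", "type") == "deletion"))
  expect_true(all(vapply(sim$records, `[[`, "", "genotype") == "0/1"))
  # placement leaves every pair more than 150 bp apart (singleton regime)
  out <- exclude_clustered(sim$records, 150L)
  expect_length(out$clustered, 0L)
})

test_that("TR designation rate follows the configured fraction", {
  cfg <- simulation_config(reference_length = 500000L, n_sv = 40L,
                           tr_fraction = 0.5, seed = 13L)
  sim <- simulate_truth(cfg)
  n_tr <- sum(sim$tr_locus)
  expect_gte(n_tr, qbinom(0.005, 40, 0.5))
  expect_lte(n_tr, qbinom(0.995, 40, 0.5))
  # TR loci actually sit in periodic sequence: the 40 bp around the SV start
  # must contain a repeated k-mer
  for (i in which(sim$tr_locus)[1:3]) {
    s <- sim$records[[i]]$start
    win <- substr(sim$reference[[1L]], s - 20L, s + 20L)
    km <- substring(win, 1:(nchar(win) - 7L), 8:nchar(win))
    expect_gt(max(table(km)), 1L)
  }
})

test_that("infeasible placement raises a typed error", {
  expect_error(
    simulate_truth(simulation_config(reference_length = 10000L, n_sv = 50L,
                                     min_gap = 1000L)),
    class = "svgt_placement")
})

test_that("read simulation hits the configured depth and error model", {
  cfg <- small_cfg(error_rate = 0)
  sim <- simulate_truth(cfg)
  bam <- simulate_reads(sim, tempfile())
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    what = c("seq", "flag")))[[1L]]
  n_reads <- length(res$seq)
  hl <- sum(vapply(sim$haplotypes, function(h) nchar(h$seq), 0))
  # d * G / (2l) fragments, two reads each, G summed over both haplotypes
  expect_lt(abs(n_reads - cfg$depth * hl / (2 * 150)) /
              (cfg$depth * hl / (2 * 150)), 0.05)
  # error rate 0: every mapped read is an exact substring of a haplotype
  withr::with_seed(1, idx <- sample(which(!bitwAnd(res$flag, 4L)), 25L))
  haps <- vapply(sim$haplotypes, function(h) h$seq, "")
  for (i in idx) {
    sq <- as.character(res$seq[i])
    if (bitwAnd(res$flag[i], 16L)) sq <- revcomp(sq)
    expect_true(grepl(sq, haps[1L], fixed = TRUE) ||
                grepl(sq, haps[2L], fixed = TRUE))
  }
})

test_that("het deletion breakpoints see roughly lambda/2 reads per haplotype", {
  cfg <- simulation_config(reference_length = 120000L, n_sv = 4L,
                           type_mix = c(deletion = 1, insertion = 0),
                           genotype_probs = c("0/0" = 0, "0/1" = 1, "1/1" = 0),
                           tr_fraction = 0, min_gap = 2000L, seed = 23L)
  sim <- simulate_truth(cfg)
  bam <- simulate_reads(sim, tempfile())
  lam <- poisson_lambda(30, 150, 15)
  counts <- lapply(sim$records, function(rec) {
    reads <- extract_reads(bam, rec, 150L)
    g <- build_graph(rec, sim$reference, graph_params())
    g <- split_long_nodes(g, 150L)
    filt <- best_unique_alignments(align_reads(reads, g))
    count_breakpoint_support(enumerate_breakpoints(g)[[1L]], filt, g)
  })
  for (cn in counts) {
    for (h in c("REF", "ALT")) {
      # Poisson-ish tolerance: mean lambda/2, allow 4 sigma
      expect_lt(abs(cn$R_h[[h]] - lam / 2), 4 * sqrt(lam / 2) + 1)
    }
  }
})

test_that("breakpoint corruption shifts by exactly s and preserves lengths", {
  cfg <- small_cfg()
  sim <- simulate_truth(cfg)
  same <- corrupt_breakpoints(sim$records, 0L, nchar(sim$reference))
  expect_identical(unclass(same)[seq_along(sim$records)],
                   unclass(sim$records)[seq_along(sim$records)])
  withr::with_seed(2, {
    sh <- corrupt_breakpoints(sim$records, 20L, nchar(sim$reference))
  })
  expect_length(sh, length(sim$records))
  for (k in seq_along(sh)) {
    expect_equal(abs(sh[[k]]$start - sim$records[[k]]$start), 20L)
    expect_equal(sh[[k]]$end - sh[[k]]$start,
                 sim$records[[k]]$end - sim$records[[k]]$start)
  }
  # a record near the contig edge is dropped, not mangled (either shift
  # direction leaves no room for the 150 bp flank)
  edge_rec <- list(sv_record("sim1", 155L, 255L, "deletion", id = "edge"))
  withr::with_seed(3, {
    dropped <- corrupt_breakpoints(edge_rec, 50L, 400L)
  })
  expect_length(dropped, 0L)
  expect_equal(attr(dropped, "dropped"), "edge")
})

test_that("junction reads carry exact M/D/I CIGARs in the BAM", {
  cfg <- simulation_config(reference_length = 60000L, n_sv = 2L,
                           type_mix = c(deletion = 1, insertion = 0),
                           genotype_probs = c("0/0" = 0, "0/1" = 0, "1/1" = 1),
                           tr_fraction = 0, min_gap = 5000L, seed = 31L,
                           len_range = c(300L, 400L))
  sim <- simulate_truth(cfg)
  bam <- simulate_reads(sim, tempfile())
  rec <- sim$records[[1L]]
  res <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
    which = GenomicRanges::GRanges(cfg$contig,
                                   IRanges::IRanges(rec$start - 100L,
                                                    rec$end + 100L)),
    what = c("pos", "cigar")))[[1L]]
  delres <- grepl(sprintf("%dD", rec$end - rec$start), res$cigar)
  expect_gt(sum(delres), 10L)  # hom deletion: many junction reads
})
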