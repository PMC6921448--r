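ref <- fixture_reference()
gp <- graph_params(read_length = 150L)
ap <- alignment_params()

test_that("exact node substring aligns with score = match x length", {
  g <- build_graph(fixture_record(ref, "deletion", len = 300L), ref, gp)
  rd <- substr(g$nodes$LF$seq, 11, 90)
  alns <- align_read_to_graph(rd, g, ap)
  expect_equal(alns[[1L]]$score, 80L)
  expect_equal(alns[[1L]]$path, "LF")
  expect_true(is_uniquely_mapped(alns))
})

test_that("junction read picks the ALT edge and matches the linear oracle", {
  g <- build_graph(fixture_record(ref, "deletion", len = 300L), ref, gp)
  altseq <- allele_path_seq(g, "ALT")
  rd <- substr(altseq, 81, 230)   # 70 bases flankL + 80 bases flankR
  alns <- align_read_to_graph(rd, g, ap)
  best <- alns[[which.max(vapply(alns, `[[`, 0L, "score"))]]
  expect_equal(best$path, c("LF", "RF"))
  expect_equal(best$score,
               max(oracle_sw(rd, allele_path_seq(g, "REF")),
                   oracle_sw(rd, altseq)))
  expect_equal(best$mismatches, 0L)
})

test_that("ambiguous reads return co-optimal alignments and fail uniqueness", {
  # two flanks that share a 40 bp cassette: a read inside it maps twice
  cassette <- strrep("ACGT", 10)
  myref <- setNames(paste0(substr(ref[[1L]], 1, 150 - 40), cassette,
                           substr(ref[[1L]], 151, 300), cassette,
                           substr(ref[[1L]], 311, 460)), "chrA")
  rec <- sv_record("chrA", 150, 300, "deletion", id = "amb")
  g <- build_graph(rec, myref, graph_params(read_length = 150L))
  rd <- substr(cassette, 3, 38)
  alns <- align_read_to_graph(rd, g, ap)
  expect_gte(length(alns), 2L)
  sc <- vapply(alns, `[[`, 0L, "score")
  expect_true(sum(sc == max(sc)) >= 2L)
  expect_false(is_uniquely_mapped(alns))
})

test_that("is_uniquely_mapped follows the best-score rule", {
  a <- function(score, start) fake_alignment("LF", 50, score = score,
                                             graph_start = start)
  expect_true(is_uniquely_mapped(list(a(42, 0), a(40, 10), a(17, 20))))
  expect_false(is_uniquely_mapped(list(a(42, 0), a(42, 10))))
  expect_false(is_uniquely_mapped(list()))
})

test_that("unique-kmer filter distinguishes unique from repeated sequence", {
  rec <- fixture_record(ref, "insertion", alt_len = 60L)
  g <- build_graph(rec, ref, gp)
  rd <- substr(rec$alt_seq, 1, 40)
  expect_true(has_unique_kmer(rd, g, 16L))
  # a read living entirely in a tandem repeat tiled through the graph
  trref <- setNames(paste0(substr(ref[[1L]], 1, 100), strrep("ATGGC", 100),
                           substr(ref[[1L]], 101, 400)), "chrR")
  trrec <- sv_record("chrR", 200, 400, "deletion", id = "tr")
  trg <- build_graph(trrec, trref, graph_params(read_length = 100L))
  trread <- strrep("ATGGC", 8)
  expect_false(has_unique_kmer(trread, trg, 16L))
  # brute-force check: every kmer of that read occurs > 1x in the graph
  kt <- table(graph_kmers(trg, 16L))
  rk <- substring(trread, 1:(nchar(trread) - 15L), 16:nchar(trread))
  expect_true(all(kt[rk] > 1L, na.rm = TRUE))
  expect_false(has_unique_kmer("ACGT", g, 16L))  # k > read length
})

test_that("node support uses min(10% read length, node length)", {
  g <- build_graph(fixture_record(ref, "deletion", len = 300L), ref, gp)
  aln <- fake_alignment(c("LF", "RF"), c(15L, 135L), read_length = 150L)
  expect_true(supports_node(aln, "LF", g, ap))   # threshold 15
  aln14 <- fake_alignment(c("LF", "RF"), c(14L, 136L), read_length = 150L)
  expect_false(supports_node(aln14, "LF", g, ap))
  # short node: threshold capped at node length
  sref <- setNames(paste0(substr(ref[[1L]], 1, 150),
                          substr(ref[[1L]], 1000, 1007), substr(ref[[1L]], 151, 300)), "chrS")
  srec <- sv_record("chrS", 150, 158, "swap", alt_seq = "TTTTTTTA", id = "s")
  sg <- build_graph(srec, sref, graph_params(read_length = 150L,
                                             min_sv_length = 0L))
  a8 <- fake_alignment(c("LF", "REFSEQ"), c(142L, 8L), read_length = 150L)
  expect_true(supports_node(a8, "REFSEQ", sg, ap))
})

test_that("edge support needs the edge on the path and both nodes supported", {
  g <- build_graph(fixture_record(ref, "deletion", len = 300L), ref, gp)
  edge_alt <- list(from = "LF", to = "RF")
  straddle <- fake_alignment(c("LF", "RF"), c(75L, 75L))
  expect_true(supports_edge(straddle, edge_alt, g, ap))
  lopsided <- fake_alignment(c("LF", "RF"), c(145L, 5L))
  expect_false(supports_edge(lopsided, edge_alt, g, ap))
  off_path <- fake_alignment(c("LF", "DEL"), c(75L, 75L))
  expect_false(supports_edge(off_path, edge_alt, g, ap))
})

test_that("breakpoint counting is exact bookkeeping", {
  g <- build_graph(fixture_record(ref, "deletion", len = 300L), ref, gp)
  bp <- enumerate_breakpoints(g)[[1L]]  # LF:outgoing
  alns <- c(
    lapply(1:10, function(i) fake_alignment(c("LF", "RF"), c(75L, 75L),
                                            read_id = paste0("alt", i))),
    lapply(1:10, function(i) fake_alignment(c("LF", "DEL"), c(75L, 75L),
                                            read_id = paste0("ref", i))),
    lapply(1:2, function(i) fake_alignment(c("LF", "RF"), c(145L, 5L),
                                           read_id = paste0("nei", i)))
  )
  cn <- count_breakpoint_support(bp, alns, g, ap)
  expect_equal(cn$R, 22L)
  expect_equal(unname(cn$R_h), c(10L, 10L))
  expect_equal(cn$R_neither, 2L)
  expect_equal(cn$R, sum(cn$R_h) + cn$R_neither)
  empty <- count_breakpoint_support(bp, list(), g, ap)
  expect_equal(empty$R, 0L)
})

test_that("a read spanning a short deletion counts at both breakpoints", {
  g <- build_graph(fixture_record(ref, "deletion", len = 60L), ref, gp)
  altseq <- allele_path_seq(g, "ALT")
  rd <- setNames(substr(altseq, 81, 230), "span")  # 70 in LF, 80 in RF
  filt <- best_unique_alignments(align_reads(rd, g, ap))
  bps <- enumerate_breakpoints(g)
  c1 <- count_breakpoint_support(bps[[1L]], filt, g, ap)
  c2 <- count_breakpoint_support(bps[[2L]], filt, g, ap)
  expect_equal(c1$R_h[["ALT"]], 1L)
  expect_equal(c2$R_h[["ALT"]], 1L)
})

test_that("graph DP equals max over allele-path linear alignments", {
  withr::with_seed(4242, {
    for (i in 1:60) {
      smallref <- setNames(paste(sample(c("A", "C", "G", "T"), 300,
                                        replace = TRUE), collapse = ""), "c")
      type <- sample(c("deletion", "insertion", "swap"), 1L)
      len <- sample(10:60, 1L)
      rec <- sv_record("c", 120L, if (type == "insertion") 120L else 120L + len,
                       type,
                       alt_seq = if (type == "deletion") "" else
                         paste(sample(c("A", "C", "G", "T"), sample(10:60, 1L),
                                      replace = TRUE), collapse = ""),
                       id = "p")
      g <- build_graph(rec, smallref, graph_params(read_length = 60L,
                                                   min_sv_length = 0L))
      src <- allele_path_seq(g, sample(c("REF", "ALT"), 1L))
      st <- sample.int(nchar(src) - 30L, 1L)
      rd <- substr(src, st, st + sample(15:30, 1L))
      # mutate a couple of bases
      for (p in sample.int(nchar(rd), 2L)) {
        substr(rd, p, p) <- sample(c("A", "C", "G", "T"), 1L)
      }
      alns <- align_read_to_graph(rd, g)
      gsc <- if (length(alns)) max(vapply(alns, `[[`, 0L, "score")) else 0L
      osc <- max(vapply(c("REF", "ALT"), function(al) {
        ps <- allele_path_seq(g, al)
        max(oracle_sw(rd, ps), oracle_sw(revcomp(rd), ps))
      }, 0))
      expect_equal(gsc, osc)
    }
  })
})

test_that("strand symmetry: reverse complement keeps the best score", {
  g <- build_graph(fixture_record(ref, "insertion", alt_len = 80L), ref, gp)
  withr::with_seed(5, {
    rds <- sample_path_reads(g, "ALT", 10L, 100L, error = 0.02)
  })
  for (rd in rds) {
    s1 <- max(vapply(align_read_to_graph(rd, g), `[[`, 0L, "score"))
    s2 <- max(vapply(align_read_to_graph(revcomp(rd), g), `[[`, 0L, "score"))
    expect_equal(s1, s2)
  }
})

test_that("removing a read never increases any breakpoint count", {
  g <- build_graph(fixture_record(ref, "deletion", len = 200L), ref, gp)
  withr::with_seed(6, {
    rds <- c(sample_path_reads(g, "ALT", 15L, 120L),
             sample_path_reads(g, "REF", 15L, 120L))
  })
  filt <- best_unique_alignments(align_reads(rds, g, ap))
  bps <- enumerate_breakpoints(g)
  full <- lapply(bps, count_breakpoint_support, alignments = filt,
                 graph = g, params = ap)
  drop <- filt[-1L]
  red <- lapply(bps, count_breakpoint_support, alignments = drop,
                graph = g, params = ap)
  for (k in 1:2) {
    expect_true(all(red[[k]]$R_h <= full[[k]]$R_h))
    expect_lte(red[[k]]$R_neither, full[[k]]$R_neither)
    expect_lte(red[[k]]$R, full[[k]]$R)
  }
})

test_that("empty reads raise a typed error", {
  g <- build_graph(fixture_record(ref, "deletion", len = 100L), ref, gp)
  expect_error(align_reads(c(a = ""), g, ap), class = "svgt_empty_read")
})
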