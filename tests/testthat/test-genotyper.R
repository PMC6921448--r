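pp <- genotyping_params(depth = 30, read_length = 150L, min_overlap = 15L,
                        eps = 0.01)

test_that("poisson_lambda is d(l-m)/l", {
  expect_equal(poisson_lambda(30, 150, 15), 27)
  expect_equal(poisson_lambda(30, 150, 0), 30)
  expect_equal(poisson_lambda(35, 150, 15), 31.5)
  expect_error(poisson_lambda(30, 150, 150), class = "svgt_bad_params")
  expect_error(poisson_lambda(0, 150, 15), class = "svgt_bad_params")
})

test_that("het likelihood matches the factorial pmf oracle", {
  p20 <- genotyping_params(depth = 20, read_length = 150L, min_overlap = 0L)
  cn <- breakpoint_counts(c(REF = 10L, ALT = 10L))
  expect_equal(het_likelihood(cn, "REF", "ALT", p20),
               oracle_pois_pmf(10, 10)^2, tolerance = 1e-12)
  # zero counts collapse to exp(-lambda)
  cn0 <- breakpoint_counts(c(REF = 0L, ALT = 0L))
  expect_equal(het_likelihood(cn0, "REF", "ALT", p20), exp(-20),
               tolerance = 1e-12)
  # symmetry in the haplotype labels (mu = 0.5/0.5)
  cns <- breakpoint_counts(c(REF = 7L, ALT = 13L))
  expect_equal(het_likelihood(cns, "REF", "ALT", p20),
               het_likelihood(cns, "ALT", "REF", p20))
})

test_that("hom likelihood matches the oracle and is monotone beyond the mode", {
  cn0 <- breakpoint_counts(c(REF = 0L, ALT = 0L))
  expect_equal(hom_likelihood(cn0, "REF", pp), oracle_pois_pmf(0, 27 * 0.99),
               tolerance = 1e-12)
  p20 <- genotyping_params(depth = 20, read_length = 150L, min_overlap = 0L,
                           eps = 0.05)
  cn <- breakpoint_counts(c(REF = 19L, ALT = 0L))
  expect_equal(hom_likelihood(cn, "REF", p20), oracle_pois_pmf(19, 19),
               tolerance = 1e-12)
  # for fixed count below the mean, likelihood decreases as lambda grows
  lams <- seq(25, 60, by = 5)
  vals <- vapply(lams, function(lam) {
    par <- genotyping_params(depth = lam, read_length = 150L,
                             min_overlap = 0L, eps = 0)
    hom_likelihood(breakpoint_counts(c(REF = 20L, ALT = 0L)), "REF", par)
  }, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("error likelihood handles eps = 0 without exceptions", {
  p0 <- genotyping_params(depth = 30, read_length = 150L, min_overlap = 15L,
                          eps = 0)
  expect_equal(error_likelihood(breakpoint_counts(c(REF = 1L, ALT = 1L), 0L), p0), 1)
  expect_equal(error_likelihood(breakpoint_counts(c(REF = 1L, ALT = 1L), 3L), p0), 0)
  expect_identical(
    error_likelihood(breakpoint_counts(c(REF = 1L, ALT = 1L), 3L), p0, log = TRUE),
    -Inf)
  p05 <- genotyping_params(depth = 20, read_length = 150L, min_overlap = 0L,
                           eps = 0.05)
  expect_equal(error_likelihood(breakpoint_counts(c(REF = 0L, ALT = 0L), 1L), p05),
               exp(-1), tolerance = 1e-12)
})

test_that("genotype posterior picks the oracle argmax and normalizes", {
  cn <- breakpoint_counts(c(REF = 30L, ALT = 0L), 0L)
  gl <- genotype_posterior(cn, pp)
  # independent enumeration with the pmf oracle
  lam <- 27; eps <- 0.01
  lik <- c(
    "REF/REF" = oracle_pois_pmf(30, lam * (1 - eps)) * oracle_pois_pmf(0, lam * eps),
    "REF/ALT" = oracle_pois_pmf(30, lam / 2) * oracle_pois_pmf(0, lam / 2) *
      oracle_pois_pmf(0, lam * eps),
    "ALT/ALT" = oracle_pois_pmf(0, lam * (1 - eps)) * oracle_pois_pmf(30, lam * eps)
  )
  expect_equal(gl$best, names(which.max(lik)))
  expect_equal(gl$best, "REF/REF")
  expect_equal(unname(gl$posterior), unname(lik / sum(lik)), tolerance = 1e-9)
  expect_equal(sum(gl$posterior), 1, tolerance = 1e-12)
})

test_that("a degenerate prior forces its genotype", {
  cn <- breakpoint_counts(c(REF = 30L, ALT = 0L), 0L)
  pd <- genotyping_params(depth = 30, read_length = 150L, min_overlap = 15L,
                          priors = c("REF/ALT" = 1))
  gl <- genotype_posterior(cn, pd)
  expect_equal(gl$best, "REF/ALT")
  expect_equal(unname(gl$posterior["REF/ALT"]), 1)
  expect_error(
    genotyping_params(priors = c("REF/REF" = 0, "REF/ALT" = 0, "ALT/ALT" = 0)),
    class = "svgt_bad_params")
})

test_that("posterior is invariant to uniform prior rescaling", {
  withr::with_seed(11, {
    for (i in 1:20) {
      cn <- breakpoint_counts(setNames(as.integer(rpois(2, 13)), c("REF", "ALT")),
                              rpois(1, 1))
      p1 <- genotyping_params(priors = c("REF/REF" = .2, "REF/ALT" = .3,
                                         "ALT/ALT" = .5))
      p2 <- genotyping_params(priors = c("REF/REF" = 2, "REF/ALT" = 3,
                                         "ALT/ALT" = 5))
      expect_equal(genotype_posterior(cn, p1)$posterior,
                   genotype_posterior(cn, p2)$posterior, tolerance = 1e-12)
      expect_equal(sum(genotype_posterior(cn, p1)$posterior), 1,
                   tolerance = 1e-12)
    }
  })
})

test_that("log-space likelihoods equal the direct-formula oracle", {
  lams <- c(1, 5, 13, 27, 50)
  for (lam in lams) {
    par <- genotyping_params(depth = lam, read_length = 150L, min_overlap = 0L,
                             eps = 0.05)
    for (k in c(0L, 1L, 7L, 40L, 100L)) {
      cn <- breakpoint_counts(c(REF = k, ALT = 0L), R_neither = k)
      expect_equal(hom_likelihood(cn, "REF", par),
                   oracle_pois_pmf(k, lam * 0.95), tolerance = 1e-9)
      expect_equal(error_likelihood(cn, par),
                   oracle_pois_pmf(k, lam * 0.05), tolerance = 1e-9)
      expect_equal(het_likelihood(cn, "REF", "ALT", par),
                   oracle_pois_pmf(k, lam / 2) * oracle_pois_pmf(0, lam / 2),
                   tolerance = 1e-9)
    }
  }
})

test_that("depth test is two-sided around lambda", {
  dt <- depth_test(27L, pp)
  expect_gt(dt$p, 0.9)
  expect_true(dt$pass)
  hi <- depth_test(round(27 + 10 * sqrt(27)), pp)
  expect_lt(hi$p, 0.01)
  expect_false(hi$pass)
  expect_equal(oracle_z_p(round(27 + 10 * sqrt(27)), 27, 27), hi$p,
               tolerance = 1e-12)
  expect_equal(depth_test(27 + 8, pp)$p, depth_test(27 - 8, pp)$p,
               tolerance = 1e-12)
})

test_that("Fisher strand Phred matches the hypergeometric oracle", {
  expect_equal(fisher_strand_phred(rbind(c(10, 10), c(10, 10))), 0)
  tab <- rbind(c(20, 0), c(0, 20))
  expect_equal(fisher_strand_phred(tab), -10 * log10(oracle_fisher_p(tab)),
               tolerance = 1e-6)
  expect_gt(fisher_strand_phred(tab), 30)
  expect_equal(fisher_strand_phred(rbind(c(3, 9), c(11, 2))),
               fisher_strand_phred(rbind(c(11, 2), c(3, 9))))
  expect_error(fisher_strand_phred(rbind(c(-1, 1), c(1, 1))),
               class = "svgt_bad_counts")
})

test_that("breakpoint genotyping applies the four confidence filters", {
  # criterion 1: a single read fails but is still genotyped
  one <- genotype_breakpoint(breakpoint_counts(c(REF = 1L, ALT = 0L)), pp)
  expect_equal(one$status, "failing")
  expect_true(one$flags[["low_reads"]])
  expect_true(one$likelihoods$best %in% c("REF/REF", "REF/ALT", "ALT/ALT"))
  # clean heterozygous counts pass all filters
  het <- genotype_breakpoint(
    breakpoint_counts(c(REF = 13L, ALT = 14L), R_neither = 0L), pp)
  expect_equal(het$status, "passing")
  expect_equal(het$likelihoods$best, "REF/ALT")
  expect_false(any(het$flags))
  # a genotype-quality below 10 trips low_gq
  found <- NULL
  for (r1 in 3:9) for (r2 in 0:3) {
    cn <- breakpoint_counts(c(REF = r1, ALT = r2))
    gl <- genotype_posterior(cn, pp)
    if (gl$gq < 10) { found <- cn; break }
  }
  expect_false(is.null(found))
  bg <- genotype_breakpoint(found, pp)
  expect_true(bg$flags[["low_gq"]])
  expect_equal(bg$status, "failing")
})

test_that("strand-bias semantics: conventional default, verbatim switch", {
  balanced <- breakpoint_counts(c(REF = 14L, ALT = 13L))
  expect_equal(genotype_breakpoint(balanced, pp)$status, "passing")
  ppv <- genotyping_params(depth = 30, read_length = 150L, min_overlap = 15L,
                           fisher_verbatim = TRUE)
  expect_true(genotype_breakpoint(balanced, ppv)$flags[["strand_bias"]])
  biased <- breakpoint_counts(c(REF = 20L, ALT = 20L),
                              fwd = c(REF = 20L, ALT = 0L),
                              rev = c(REF = 0L, ALT = 20L))
  expect_true(genotype_breakpoint(biased, pp)$flags[["strand_bias"]])
  expect_false(genotype_breakpoint(biased, ppv)$flags[["strand_bias"]])
})

test_that("generative-model counts are recovered at high rates", {
  withr::with_seed(2024, {
    n <- 300L
    for (gt in c("REF/ALT", "ALT/ALT")) {
      calls <- vapply(seq_len(n), function(i) {
        genotype_posterior(simulate_counts(gt, pp), pp)$best
      }, "")
      expect_gte(mean(calls == gt), 0.95)
    }
  })
})
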