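# Independent oracles and fixture builders. Every oracle here recomputes the
# quantity from first principles, on a different computational route than the
# package implementation.

# --- Poisson pmf: naive factorial formula (counts <= 170), log-gamma beyond
oracle_pois_pmf <- function(k, lambda) {
  if (lambda == 0) return(as.numeric(k == 0))
  if (k <= 170) {
    lambda^k * exp(-lambda) / factorial(k)
  } else {
    exp(k * log(lambda) - lambda - lgamma(k + 1))
  }
}

# --- plain Gotoh affine local alignment on linear sequences
oracle_sw <- function(read, ref, match = 1, mismatch = -4,
                      gap_open = -6, gap_extend = -1) {
  r <- strsplit(toupper(read), "")[[1L]]
  s <- strsplit(toupper(ref), "")[[1L]]
  m <- length(r); n <- length(s)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)  # gap in read (ref consumed)
  F <- matrix(NEG, m + 1, n + 1)  # gap in ref (read consumed)
  best <- 0
  for (j in 2:(n + 1)) {
    for (i in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend, E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open + gap_extend, F[i - 1, j] + gap_extend)
      sub <- if (r[i - 1] == s[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# --- two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  a_obs <- tab[1, 1]
  lp <- function(a) {
    b <- r1 - a; cc <- c1 - a; d <- N - a - b - cc
    if (b < 0 || cc < 0 || d < 0) return(-Inf)
    lchoose(r1, a) + lchoose(N - r1, cc) - lchoose(N, c1)
  }
  as_all <- 0:min(r1, c1)
  probs <- exp(vapply(as_all, lp, 0))
  probs <- probs / sum(probs)
  p_obs <- probs[as_all == a_obs]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- exact HWE het-count test by direct closed-form enumeration
oracle_hwe_p <- function(hom_ref, het, hom_alt) {
  n <- hom_ref + het + hom_alt
  n_a <- 2 * hom_alt + het
  rare <- min(n_a, 2 * n - n_a)
  if (n == 0 || rare == 0) return(1)
  hets <- seq.int(rare %% 2, rare, by = 2)
  lp <- vapply(hets, function(h) {
    naa <- (rare - h) / 2
    nbb <- n - naa - h
    lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
      h * log(2) - (lchoose(2 * n, rare))
  }, 0)
  probs <- exp(lp - max(lp)); probs <- probs / sum(probs)
  p_obs <- probs[hets == het]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- two-sided normal tail
oracle_z_p <- function(x, mean, var) 2 * pnorm(-abs(x - mean) / sqrt(var))

# --- fixtures -------------------------------------------------------------

fixture_reference <- function(len = 4000L, seed = 101L, contig = "chrT") {
  withr::with_seed(seed, {
    setNames(paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = ""), contig)
  })
}

# a random SV record compatible with fixture_reference
fixture_record <- function(ref, type = c("deletion", "insertion", "swap"),
                           start = 2000L, len = 120L, alt_len = len) {
  type <- match.arg(type)
  contig <- names(ref)
  alt <- if (type == "deletion") "" else
    paste(sample(c("A", "C", "G", "T"), alt_len, replace = TRUE), collapse = "")
  end <- if (type == "insertion") start else start + len
  sv_record(contig, start, end, type, alt_seq = alt, id = paste0("fx_", type))
}

# build a graph_alignment object directly (for support/uniqueness tests)
fake_alignment <- function(path, node_overlap, score = 100L, strand = "+",
                           graph_start = 0L, graph_end = 0L,
                           read_length = 150L, read_start = 1L,
                           read_end = read_length, mismatches = 0L,
                           read_id = "r") {
  structure(list(
    read_id = read_id, score = as.integer(score), strand = strand,
    path = path, node_overlap = setNames(as.integer(node_overlap), path),
    read_start = read_start, read_end = read_end,
    graph_start = graph_start, graph_end = graph_end,
    mismatches = mismatches, read_length = read_length
  ), class = "graph_alignment")
}

# reads sampled from an allele path with optional substitution errors
sample_path_reads <- function(graph, allele, n, read_len, error = 0) {
  pathseq <- allele_path_seq(graph, allele)
  L <- nchar(pathseq)
  starts <- sample.int(L - read_len + 1L, n, replace = TRUE)
  reads <- substring(pathseq, starts, starts + read_len - 1L)
  if (error > 0) {
    for (i in seq_along(reads)) {
      ne <- rbinom(1L, read_len, error)
      if (ne > 0) {
        pos <- sample.int(read_len, ne)
        for (p in pos) {
          old <- substr(reads[i], p, p)
          substr(reads[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        }
      }
    }
  }
  setNames(reads, sprintf("%s_read%03d", allele, seq_len(n)))
}

# draw breakpoint counts from the generative Poisson model for a true genotype
simulate_counts <- function(true_gt, params) {
  lam <- poisson_lambda(params$depth, params$read_length, params$min_overlap)
  haps <- c("REF", "ALT")
  pair <- strsplit(true_gt, "/", fixed = TRUE)[[1L]]
  R_h <- setNames(integer(2), haps)
  if (pair[1L] == pair[2L]) {
    R_h[pair[1L]] <- rpois(1L, lam * (1 - params$eps))
  } else {
    R_h["REF"] <- rpois(1L, lam * params$mu[1L])
    R_h["ALT"] <- rpois(1L, lam * params$mu[2L])
  }
  breakpoint_counts(R_h, R_neither = rpois(1L, lam * params$eps))
}
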