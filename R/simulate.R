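# Fully synthetic truth data: a random reference (optionally with embedded
# tandem-repeat arrays), a diploid sample with known SV genotypes, paired-end
# reads with substitution errors, and optionally breakpoint-shifted input
# VCFs. Reads are placed at their true origin (the mapping layer is
# noise-free by design, so genotyper errors are attributable to the
# genotyper); an aligned, sorted, indexed BAM is produced.

#' Simulation configuration
#'
#' Defaults emulate a typical short-read experiment: 150 bp paired-end reads
#' at 30-fold coverage with 0.5% substitution error and a 400 +/- 50 bp insert
#' on a 1 Mb genome carrying 100 singleton SVs of 50-1000 bp (mixed deletions
#' and insertions, a quarter of loci inside tandem-repeat arrays).
#'
#' @param reference_length genome length in bp.
#' @param contig contig name.
#' @param n_sv number of SVs.
#' @param type_mix named probabilities over `deletion`/`insertion`.
#' @param len_range SV length range (uniform on the log scale).
#' @param genotype_probs named probabilities over "0/0", "0/1", "1/1".
#' @param tr_fraction fraction of SV loci embedded in a tandem-repeat array.
#' @param min_gap minimum distance between consecutive SV spans (singleton
#'   regime; must be > 150 so no two SVs are within 150 bp).
#' @param read_length,depth,error_rate,insert_mean,insert_sd read simulation.
#' @param seed RNG seed; fixed seeds give identical outputs.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(reference_length = 1e6L, contig = "sim1",
                              n_sv = 100L,
                              type_mix = c(deletion = 0.5, insertion = 0.5),
                              len_range = c(50L, 1000L),
                              genotype_probs = c("0/0" = 0.2, "0/1" = 0.4,
                                                 "1/1" = 0.4),
                              tr_fraction = 0.25, min_gap = 1000L,
                              read_length = 150L, depth = 30,
                              error_rate = 0.005,
                              insert_mean = 400, insert_sd = 50,
                              seed = 1L) {
  stopifnot(reference_length > 0, n_sv >= 0, min_gap > 150,
            error_rate >= 0, error_rate <= 1, tr_fraction >= 0, tr_fraction <= 1,
            abs(sum(type_mix) - 1) < 1e-9, abs(sum(genotype_probs) - 1) < 1e-9)
  structure(as.list(environment()), class = "simulation_config")
}

make_tr_array <- function(unit, len) {
  paste(rep(unit, ceiling(len / nchar(unit))), collapse = "") |>
    substr(1L, len)
}

#' Simulate a reference, SV truth set and diploid haplotypes
#'
#' SV spans are placed non-overlapping with at least `min_gap` bp between
#' them. Loci designated as tandem-repeat (TR) get a short-unit repeat array
#' written into the reference around the SV, and the SV length is rounded to
#' a unit multiple (breakpoint-ambiguous by construction). Heterozygous SVs
#' are assigned to a random haplotype.
#'
#' @param config a [simulation_config()].
#' @return object of class `sv_simulation`: `reference` (named character),
#'   `records` (list of [sv_record()] with genotypes), `haplotypes` (two block
#'   tables + sequences), `tr_locus` (logical per SV), `config`.
#' @export
simulate_truth <- function(config = simulation_config()) {
  set.seed(config$seed)
  L <- as.integer(config$reference_length)
  n <- as.integer(config$n_sv)
  types <- if (n) sample(names(config$type_mix), n, replace = TRUE,
                         prob = config$type_mix) else character(0)
  lens <- if (n) as.integer(round(exp(runif(
    n, log(config$len_range[1L]), log(config$len_range[2L]))))) else integer(0)
  spans <- ifelse(types == "deletion", lens, 0L)
  required <- sum(spans) + (n + 1L) * config$min_gap
  if (required > L)
    svgt_error("svgt_placement",
               sprintf("cannot place %d SVs in %d bp (need %d)", n, L, required))
  slack <- L - required
  cuts <- sort(as.integer(runif(n, 0, slack)))
  starts <- config$min_gap * seq_len(n) + c(0L, cumsum(spans)[-n]) + cuts
  refseq <- random_dna(L)

  tr_locus <- if (n) runif(n) < config$tr_fraction else logical(0)
  records <- vector("list", n)
  gts <- if (n) sample(names(config$genotype_probs), n, replace = TRUE,
                       prob = config$genotype_probs) else character(0)
  for (i in seq_len(n)) {
    s <- starts[i]; len <- lens[i]
    if (tr_locus[i]) {
      unit <- random_dna(sample(2:6, 1L))
      len <- max(config$len_range[1L],
                 as.integer(nchar(unit) * round(len / nchar(unit))))
      if (types[i] == "deletion") len <- min(len, spans[i])  # keep placement
      pad <- 75L
      arr_len <- (if (types[i] == "deletion") len else 0L) + 2L * pad
      arr <- make_tr_array(unit, arr_len)
      substr(refseq, s - pad + 1L, s - pad + arr_len) <- arr
    }
    records[[i]] <- if (types[i] == "deletion") {
      sv_record(config$contig, s, s + len, "deletion",
                id = sprintf("sv%03d", i), genotype = gts[i])
    } else {
      alt <- if (tr_locus[i]) {
        # phase-aligned unit so the insertion extends the embedded array
        make_tr_array(substr(refseq, s + 1L, s + nchar(unit)), len)
      } else random_dna(len)
      sv_record(config$contig, s, s, "insertion", alt_seq = alt,
                id = sprintf("sv%03d", i), genotype = gts[i])
    }
  }
  reference <- setNames(refseq, config$contig)
  carriers <- lapply(seq_len(n), function(i) {
    switch(gts[i],
           "0/0" = c(FALSE, FALSE),
           "0/1" = sample(c(TRUE, FALSE)),
           "1/1" = c(TRUE, TRUE))
  })
  haplotypes <- lapply(1:2, function(h) {
    carried <- if (n) vapply(carriers, `[`, TRUE, h) else logical(0)
    build_haplotype(reference, config$contig, records[carried])
  })
  structure(list(reference = reference, records = records,
                 haplotypes = haplotypes, tr_locus = tr_locus,
                 config = config), class = "sv_simulation")
}

# Haplotype = reference with the given (sorted, non-overlapping) SVs applied.
# Returns the sequence plus a block table mapping haplotype intervals to
# reference intervals (type "ref") or inserted sequence (type "ins"); all
# coordinates 0-based half-open.
build_haplotype <- function(reference, contig, records) {
  refseq <- reference[[contig]]
  L <- nchar(refseq)
  ord <- order(vapply(records, `[[`, 0L, "start"))
  records <- records[ord]
  blocks <- list()
  cur_ref <- 0L; cur_hap <- 0L
  add_ref <- function(from, to) {
    if (to > from)
      blocks[[length(blocks) + 1L]] <<- list(
        type = "ref", ref_start = from, ref_end = to,
        hap_start = cur_hap, hap_end = cur_hap + (to - from))
    cur_hap <<- cur_hap + max(0L, to - from)
  }
  add_ins <- function(seq) {
    blocks[[length(blocks) + 1L]] <<- list(
      type = "ins", ref_start = NA_integer_, ref_end = NA_integer_,
      hap_start = cur_hap, hap_end = cur_hap + nchar(seq), seq = seq)
    cur_hap <<- cur_hap + nchar(seq)
  }
  for (r in records) {
    add_ref(cur_ref, r$start)
    if (nzchar(r$alt_seq)) add_ins(r$alt_seq)
    cur_ref <- r$end
  }
  add_ref(cur_ref, L)
  seqs <- vapply(blocks, function(b) {
    if (b$type == "ref") substr(refseq, b$ref_start + 1L, b$ref_end) else b$seq
  }, "")
  tab <- data.frame(
    type = vapply(blocks, `[[`, "", "type"),
    ref_start = vapply(blocks, `[[`, 0L, "ref_start"),
    ref_end = vapply(blocks, `[[`, 0L, "ref_end"),
    hap_start = vapply(blocks, `[[`, 0L, "hap_start"),
    hap_end = vapply(blocks, `[[`, 0L, "hap_end"),
    stringsAsFactors = FALSE
  )
  list(seq = paste(seqs, collapse = ""), blocks = tab)
}

# SAM position + CIGAR for a haplotype interval [s, e), from the block table.
# Returns list(pos (1-based), cigar) or NULL when no base maps (read entirely
# inside inserted sequence).
hap_to_sam <- function(blocks, s, e) {
  idx <- findInterval(s, blocks$hap_start)
  ops <- character(0); lens <- integer(0); pos <- NA_integer_
  prev_ref_end <- NA_integer_
  i <- idx
  while (i <= nrow(blocks) && blocks$hap_start[i] < e) {
    bs <- max(s, blocks$hap_start[i]); be <- min(e, blocks$hap_end[i])
    if (be <= bs) { i <- i + 1L; next }
    if (blocks$type[i] == "ref") {
      rs <- blocks$ref_start[i] + (bs - blocks$hap_start[i])
      if (!is.na(prev_ref_end) && rs > prev_ref_end) {
        ops <- c(ops, "D"); lens <- c(lens, rs - prev_ref_end)
      }
      if (is.na(pos)) pos <- rs + 1L
      ops <- c(ops, "M"); lens <- c(lens, be - bs)
      prev_ref_end <- rs + (be - bs)
    } else {
      ops <- c(ops, "I"); lens <- c(lens, be - bs)
    }
    i <- i + 1L
  }
  if (!any(ops == "M")) return(NULL)
  # leading/trailing I (or D) are not valid CIGAR: soft-clip / drop them
  while (length(ops) && ops[1L] != "M") {
    if (ops[1L] == "I") { ops[1L] <- "S" } else { lens <- lens[-1L]; ops <- ops[-1L] }
    if (length(ops) && ops[1L] == "S") break
  }
  while (length(ops) && ops[length(ops)] != "M") {
    k <- length(ops)
    if (ops[k] == "I") { ops[k] <- "S"; break } else { ops <- ops[-k]; lens <- lens[-k] }
  }
  list(pos = pos, cigar = paste0(lens, ops, collapse = ""))
}

inject_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  l <- nchar(reads[1L])
  nerr <- rbinom(length(reads), l, rate)
  tot <- sum(nerr)
  if (!tot) return(reads)
  idx <- rep(seq_along(reads), nerr)
  pos <- sample.int(l, tot, replace = TRUE)
  old <- substr(reads[idx], pos, pos)
  bases <- c("A", "C", "G", "T")
  new <- vapply(old, function(b) sample(setdiff(bases, b), 1L), "",
                USE.NAMES = FALSE)
  # duplicated (read, pos) pairs: keep the first
  dup <- duplicated(paste(idx, pos))
  idx <- idx[!dup]; pos <- pos[!dup]; new <- new[!dup]
  pieces <- split(seq_along(idx), idx)
  for (k in names(pieces)) {
    r <- as.integer(k)
    for (j in pieces[[k]]) substr(reads[r], pos[j], pos[j]) <- new[j]
  }
  reads
}

#' Simulate paired-end reads and write an aligned, sorted, indexed BAM
#'
#' Fragments are drawn uniformly from each haplotype at depth/2, read pairs
#' taken from the fragment ends (R1 forward, R2 reverse-complemented), and
#' substitution errors applied at the configured rate. Reads are placed in
#' the BAM at their true reference origin with an exact M/I/D/S CIGAR derived
#' from the haplotype block structure; reads entirely inside inserted
#' sequence are recorded as placed-but-unmapped at the insertion anchor.
#'
#' @param sim an `sv_simulation` from [simulate_truth()].
#' @param prefix output path prefix; writes `<prefix>.bam` (+ index).
#' @param sample_name read-group/sample name.
#' @return path to the BAM file.
#' @export
simulate_reads <- function(sim, prefix, sample_name = "SIM") {
  config <- sim$config
  set.seed(config$seed + 1L)
  l <- as.integer(config$read_length)
  sam <- paste0(prefix, ".sam")
  con <- file(sam, "w")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", config$contig,
                       nchar(sim$reference[[config$contig]])),
               sprintf("@RG\tID:%s\tSM:%s", sample_name, sample_name)), con)
  qual <- paste(rep("I", l), collapse = "")
  for (h in 1:2) {
    hap <- sim$haplotypes[[h]]
    hl <- nchar(hap$seq)
    npairs <- round(config$depth / 2 * hl / (2 * l))
    frag <- as.integer(pmax(l, pmin(round(rnorm(npairs, config$insert_mean,
                                                config$insert_sd)),
                                    3L * config$insert_mean)))
    fs <- as.integer(floor(runif(npairs, 0, hl - frag)))  # 0-based fragment start
    r1 <- substr(rep(hap$seq, npairs), fs + 1L, fs + l)
    r2 <- revcomp(substr(rep(hap$seq, npairs), fs + frag - l + 1L, fs + frag))
    r1 <- inject_errors(r1, config$error_rate)
    r2 <- inject_errors(r2, config$error_rate)
    qname <- sprintf("sim_h%d_%06d", h, seq_len(npairs))
    # placement: vectorized fast path for reads inside one reference block,
    # block walk (hap_to_sam) for junction reads, unmapped-at-anchor for
    # reads entirely inside inserted sequence
    place <- function(svec) {
      bi <- findInterval(svec, hap$blocks$hap_start)
      inside <- hap$blocks$type[bi] == "ref" & (svec + l) <= hap$blocks$hap_end[bi]
      pos <- ifelse(inside,
                    hap$blocks$ref_start[bi] + (svec - hap$blocks$hap_start[bi]) + 1L,
                    NA_integer_)
      cigar <- ifelse(inside, sprintf("%dM", l), NA_character_)
      mapped <- inside
      for (i in which(!inside)) {
        p <- hap_to_sam(hap$blocks, svec[i], svec[i] + l)
        if (is.null(p)) {
          # anchor an unmapped read at the nearest reference base to its left
          b <- bi[i]
          while (b > 0L && hap$blocks$type[b] != "ref") b <- b - 1L
          pos[i] <- if (b == 0L) 1L else hap$blocks$ref_start[b] +
            min(svec[i] - hap$blocks$hap_start[b],
                hap$blocks$ref_end[b] - hap$blocks$ref_start[b] - 1L) + 1L
          mapped[i] <- FALSE
        } else {
          pos[i] <- p$pos; cigar[i] <- p$cigar; mapped[i] <- TRUE
        }
      }
      list(pos = pos, cigar = cigar, mapped = mapped)
    }
    p1 <- place(fs)
    p2 <- place(fs + frag - l)
    both <- p1$mapped & p2$mapped
    f1 <- 64L + 1L + ifelse(p1$mapped, 0L, 4L) + ifelse(p2$mapped, 32L, 8L) +
      ifelse(both, 2L, 0L)
    f2 <- 128L + 1L + ifelse(p2$mapped, 16L, 4L) + ifelse(p1$mapped, 0L, 8L) +
      ifelse(both, 2L, 0L)
    tlen <- ifelse(both, p2$pos + l - p1$pos, 0L)
    lines <- c(
      paste(qname, f1, config$contig, p1$pos, ifelse(p1$mapped, 60L, 0L),
            ifelse(p1$mapped, p1$cigar, "*"), "=", p2$pos, tlen, r1, qual,
            sep = "\t"),
      paste(qname, f2, config$contig, p2$pos, ifelse(p2$mapped, 60L, 0L),
            ifelse(p2$mapped, p2$cigar, "*"), "=", p1$pos, -tlen, r2, qual,
            sep = "\t"))
    writeLines(lines, con)
  }
  close(con)
  bam <- Rsamtools::asBam(sam, prefix, overwrite = TRUE, indexDestination = TRUE)
  unlink(sam)
  bam
}

#' Shift SV breakpoints to emulate an imprecise input VCF
#'
#' Each record's breakpoints move by exactly `shift` bp in a random direction
#' (seeded); deletion and swap lengths are preserved (start and end move
#' together). Records whose graph window would leave the contig are dropped
#' and logged in attribute `"dropped"`.
#'
#' @param records list of [sv_record()]s.
#' @param shift non-negative shift in bp.
#' @param contig_length contig length (bounds check).
#' @param flank flank length used downstream (bounds margin).
#' @return list of shifted records.
#' @export
corrupt_breakpoints <- function(records, shift, contig_length,
                                flank = 150L) {
  stopifnot(shift >= 0)
  if (shift == 0) { attr(records, "dropped") <- character(0); return(records) }
  out <- list(); dropped <- character(0)
  for (r in records) {
    d <- sample(c(-1L, 1L), 1L) * as.integer(shift)
    s <- r$start + d; e <- r$end + d
    if (s - flank < 0L || e + flank > contig_length) {
      dropped <- c(dropped, r$id); next
    }
    out <- c(out, list(sv_record(r$contig, s, e, r$type, alt_seq = r$alt_seq,
                                 id = r$id, genotype = r$genotype)))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Write simulation artifacts to disk
#'
#' Writes the reference FASTA (+ faidx index), the truth VCF, the simulated
#' BAM (+ index) and a JSON manifest of all parameters.
#'
#' @param sim an `sv_simulation`.
#' @param dir output directory (created).
#' @param sample_name sample name.
#' @return named list of paths (`fasta`, `vcf`, `bam`, `manifest`).
#' @export
write_simulation <- function(sim, dir, sample_name = "SIM") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$reference), fa)
  Rsamtools::indexFa(fa)
  vcf <- file.path(dir, "truth.vcf")
  gts <- list(lapply(sim$records, function(r) list(
    gt = r$genotype, filter = "PASS", dp = 0L, ad = c(0L, 0L), gq = 0
  )))
  write_genotyped_vcf(sim$records, gts, sample_name, vcf,
                      reference = sim$reference)
  bam <- simulate_reads(sim, file.path(dir, "reads"), sample_name)
  manifest <- file.path(dir, "manifest.json")
  cfg <- sim$config; class(cfg) <- NULL
  jsonlite::write_json(cfg, manifest, auto_unbox = TRUE, digits = NA)
  list(fasta = fa, vcf = vcf, bam = bam, manifest = manifest)
}
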