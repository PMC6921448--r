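# VCF in/out and BAM read extraction. This is the only module that touches
# 1-based VCF coordinates; everything internal is 0-based half-open.

#' Parse candidate SVs from a VCF
#'
#' Accepts sequence-resolved REF/ALT pairs and symbolic `<DEL>` (END or SVLEN
#' in INFO) and `<INS>` (inserted sequence in INFO SEQ) alleles. Multi-allelic
#' records are decomposed into one record per ALT. Records shorter than
#' `params$min_sv_length` and symbolic insertions without a sequence are
#' skipped with a logged reason (attribute `"skipped"`).
#'
#' @param path VCF file.
#' @param params [graph_params()] (supplies the minimum SV length).
#' @return list of [sv_record()]s; attribute `"skipped"` is a data.frame of
#'   rejected records and reasons, attribute `"samples"` the VCF sample names.
#' @export
parse_sv_vcf <- function(path, params = graph_params()) {
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path),
    error = function(e) svgt_error("svgt_bad_vcf", conditionMessage(e))
  )
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  contig <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ids <- names(rr)
  if (is.null(ids)) ids <- sprintf("sv%d", seq_along(rr))
  gt_mat <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)

  records <- list()
  skipped <- data.frame(id = character(0), reason = character(0))
  skip <- function(id, reason) {
    skipped[nrow(skipped) + 1L, ] <<- list(id, reason)
  }
  get_info <- function(field, i) {
    if (!field %in% colnames(info)) return(NA)
    v <- info[[field]][i]
    if (is.list(v) || methods::is(v, "List")) v <- unlist(v)[1L]
    if (length(v) != 1L || is.na(v)) NA else v
  }

  for (i in seq_along(rr)) {
    a <- alt[i]
    rec <- NULL
    if (grepl("^<", a)) {
      svtype <- toupper(get_info("SVTYPE", i))
      if (a %in% c("<DEL>") || identical(svtype, "DEL")) {
        end1 <- suppressWarnings(as.integer(get_info("END", i)))
        if (is.na(end1)) {
          svlen <- suppressWarnings(as.integer(get_info("SVLEN", i)))
          if (!is.na(svlen)) end1 <- pos[i] + abs(svlen)
        }
        if (is.na(end1)) { skip(ids[i], "symbolic DEL without END/SVLEN"); next }
        rec <- tryCatch(
          sv_record(contig[i], pos[i], end1, "deletion", id = ids[i]),
          error = function(e) { skip(ids[i], conditionMessage(e)); NULL })
      } else if (a %in% c("<INS>") || identical(svtype, "INS")) {
        seq <- get_info("SEQ", i)
        if (is.na(seq) || !nzchar(seq)) {
          skip(ids[i], "symbolic INS without inserted sequence"); next
        }
        rec <- tryCatch(
          sv_record(contig[i], pos[i], pos[i], "insertion",
                    alt_seq = as.character(seq), id = ids[i]),
          error = function(e) { skip(ids[i], conditionMessage(e)); NULL })
      } else {
        skip(ids[i], sprintf("unsupported symbolic allele %s", a)); next
      }
    } else {
      # sequence-resolved: strip the common prefix (the VCF padding base)
      ncp <- 0L
      maxp <- min(nchar(ref[i]), nchar(a))
      while (ncp < maxp &&
             substr(ref[i], ncp + 1L, ncp + 1L) == substr(a, ncp + 1L, ncp + 1L))
        ncp <- ncp + 1L
      ref_rest <- substr(ref[i], ncp + 1L, nchar(ref[i]))
      alt_rest <- substr(a, ncp + 1L, nchar(a))
      start0 <- vcf_to_internal(pos[i]) + ncp
      type <- if (!nzchar(alt_rest) && nzchar(ref_rest)) "deletion"
              else if (!nzchar(ref_rest) && nzchar(alt_rest)) "insertion"
              else if (nzchar(ref_rest) && nzchar(alt_rest)) "swap"
              else NA_character_
      if (is.na(type)) { skip(ids[i], "REF equals ALT"); next }
      rec <- tryCatch(
        sv_record(contig[i], start0,
                  if (type == "insertion") start0 else start0 + nchar(ref_rest),
                  type, alt_seq = alt_rest, id = ids[i]),
        error = function(e) { skip(ids[i], conditionMessage(e)); NULL })
    }
    if (is.null(rec)) next
    if (!is.null(gt_mat) && ncol(gt_mat) >= 1L)
      rec$genotype <- as.character(gt_mat[i, 1L])
    if (sv_length(rec) < params$min_sv_length) {
      skip(ids[i], sprintf("SV length %d below minimum %d",
                           sv_length(rec), params$min_sv_length))
      next
    }
    records <- c(records, list(rec))
  }
  attr(records, "skipped") <- skipped
  attr(records, "samples") <- colnames(vcf)
  records
}

#' Estimate read length from a BAM
#'
#' Median sequence length over the first `n` records.
#'
#' @param bam BAM path.
#' @param n number of records to inspect.
#' @return integer read length.
#' @export
estimate_read_length <- function(bam, n = 1000L) {
  bf <- Rsamtools::BamFile(bam, yieldSize = n)
  res <- Rsamtools::scanBam(bf, param = Rsamtools::ScanBamParam(what = "seq"))
  w <- Biostrings::width(res[[1L]]$seq)
  if (!length(w)) svgt_error("svgt_bad_bam", "no reads in BAM")
  as.integer(stats::median(w))
}

#' Extract reads (and their mates) around an SV
#'
#' Fetches all non-duplicate, non-secondary, non-supplementary reads
#' overlapping the window from one read length upstream of the SV start to
#' one read length downstream of its end (inclusive at the window edges),
#' then fetches mates mapped elsewhere by position+name lookup. Each read is
#' returned once; a mate that cannot be retrieved is skipped.
#'
#' @param bam indexed BAM path.
#' @param record an [sv_record()].
#' @param read_length window padding l.
#' @return named character vector of read sequences (names `qname/1|2`),
#'   with attribute `"strand"` (named, "+"/"-" as stored in the BAM).
#' @export
extract_reads <- function(bam, record, read_length = 150L) {
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)))
    svgt_error("svgt_missing_index", sprintf("no index for %s", bam))
  l <- as.integer(read_length)
  win <- GenomicRanges::GRanges(
    record$contig,
    IRanges::IRanges(max(1L, internal_to_vcf(record$start) - l),
                     internal_to_vcf(record$end - 1L) + l)
  )
  what <- c("qname", "flag", "strand", "pos", "seq", "mrnm", "mpos")
  flags <- Rsamtools::scanBamFlag(isDuplicate = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(which = win, what = what, flag = flags)
  )[[1L]]
  n <- length(res$qname)
  if (!n) {
    out <- character(0); attr(out, "strand") <- character(0); return(out)
  }
  second <- bitwAnd(res$flag, 128L) > 0L
  key <- paste0(res$qname, "/", ifelse(second, 2L, 1L))
  seqs <- as.character(res$seq)
  strands <- ifelse(bitwAnd(res$flag, 16L) > 0L, "-", "+")

  # mates not already in the window
  mate_key <- paste0(res$qname, "/", ifelse(second, 1L, 2L))
  need <- !(mate_key %in% key) & !is.na(res$mpos) & !is.na(res$mrnm)
  if (any(need)) {
    mgr <- GenomicRanges::reduce(GenomicRanges::GRanges(
      as.character(res$mrnm[need]),
      IRanges::IRanges(res$mpos[need], res$mpos[need] + l)
    ))
    mres <- tryCatch(
      Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(
        which = mgr, what = what, flag = flags)),
      error = function(e) NULL
    )
    if (!is.null(mres)) {
      for (m in mres) {
        if (!length(m$qname)) next
        msecond <- bitwAnd(m$flag, 128L) > 0L
        mk <- paste0(m$qname, "/", ifelse(msecond, 2L, 1L))
        sel <- mk %in% mate_key & !(mk %in% key)
        if (any(sel)) {
          key <- c(key, mk[sel])
          seqs <- c(seqs, as.character(m$seq)[sel])
          strands <- c(strands, ifelse(bitwAnd(m$flag[sel], 16L) > 0L, "-", "+"))
        }
      }
    }
  }
  dup <- duplicated(key)
  out <- setNames(seqs[!dup], key[!dup])
  attr(out, "strand") <- setNames(strands[!dup], key[!dup])
  out
}

format_info <- function(record) {
  switch(record$type,
    deletion = sprintf("SVTYPE=DEL;END=%d;SVLEN=-%d",
                       record$end, record$end - record$start),
    insertion = sprintf("SVTYPE=INS;SVLEN=%d;SEQ=%s",
                        nchar(record$alt_seq), record$alt_seq),
    swap = sprintf("SVTYPE=SWAP;END=%d", record$end)
  )
}

vcf_alleles <- function(record, reference) {
  if (!is.null(reference)) {
    pad_pos <- record$start - 1L
    pad <- if (pad_pos >= 0) ref_fetch(reference, record$contig, pad_pos, record$start)
           else "N"
    ref_mid <- if (record$end > record$start)
      ref_fetch(reference, record$contig, record$start, record$end) else ""
    return(list(pos = internal_to_vcf(pad_pos), ref = paste0(pad, ref_mid),
                alt = paste0(pad, record$alt_seq)))
  }
  if (record$type == "swap")
    svgt_error("svgt_bad_vcf", "swap records need a reference to serialize")
  if (record$type == "deletion")
    return(list(pos = internal_to_vcf(record$start - 1L), ref = "N", alt = "<DEL>"))
  list(pos = internal_to_vcf(record$start - 1L), ref = "N", alt = "<INS>")
}

sample_field <- function(g) {
  if (inherits(g, "sv_genotype")) {
    counts <- lapply(g$breakpoints, `[[`, "counts")
    dp <- sum(vapply(counts, `[[`, 0L, "R"))
    ad <- Reduce(`+`, lapply(counts, function(cn) cn$R_h))
    sprintf("%s:%s:%d:%s:%d", gt_to_vcf(g$gt), g$filter, dp,
            paste(ad, collapse = ","), round(g$gq))
  } else {
    sprintf("%s:%s:%d:%s:%d", g$gt, g$filter, g$dp,
            paste(g$ad, collapse = ","), round(g$gq))
  }
}

#' Write a genotyped multi-sample VCF
#'
#' Emits VCF 4.2 with FORMAT fields GT (genotype), FT (per-sample filter),
#' DP (total breakpoint read count), AD (per-allele supporting reads) and GQ.
#' With a reference accessor the alleles are written sequence-resolved;
#' otherwise deletions/insertions are written symbolically.
#'
#' @param records list of [sv_record()]s.
#' @param genotypes list over samples; each element a list (parallel to
#'   `records`) of `sv_genotype` objects (or lists with gt/filter/dp/ad/gq).
#' @param samples sample names (column order preserved).
#' @param path output file.
#' @param reference optional reference accessor for sequence-resolved output.
#' @return `path`, invisibly.
#' @export
write_genotyped_vcf <- function(records, genotypes, samples, path,
                                reference = NULL) {
  stopifnot(length(genotypes) == length(samples))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svgt",
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based, last replaced base)\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
    "##INFO=<ID=SEQ,Number=1,Type=String,Description=\"Inserted sequence\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=FT,Number=1,Type=String,Description=\"Per-sample filter from the breakpoint decision tree\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total breakpoint read count\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Reads supporting each allele\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Phred genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  lines <- vapply(seq_along(records), function(i) {
    rec <- records[[i]]
    al <- vcf_alleles(rec, reference)
    cells <- vapply(genotypes, function(gl) sample_field(gl[[i]]), "")
    site_filters <- vapply(genotypes, function(gl) {
      g <- gl[[i]]; if (inherits(g, "sv_genotype")) g$filter else g$filter
    }, "")
    site <- if (all(site_filters == "PASS")) "PASS" else
      paste(unique(site_filters[site_filters != "PASS"]), collapse = ";")
    paste(c(rec$contig, al$pos, rec$id, al$ref, al$alt, ".", site,
            format_info(rec), "GT:FT:DP:AD:GQ", cells), collapse = "\t")
  }, "")
  ok <- tryCatch({ writeLines(c(hdr, lines), path); TRUE },
                 error = function(e) FALSE)
  if (!ok) svgt_error("svgt_write_failed", sprintf("cannot write %s", path))
  invisible(path)
}

#' Genotype every SV in a VCF against a BAM sample
#'
#' The end-to-end driver: parse SVs, and for each record extract reads,
#' realign to the allele graph and genotype.
#'
#' @param vcf input VCF of candidate SVs.
#' @param bam indexed BAM of the sample.
#' @param reference reference accessor ([Rsamtools::FaFile] path or named
#'   character vector).
#' @param out optional output VCF path.
#' @param sample sample name for the output.
#' @param depth genome-average depth (required; drives the Poisson mean).
#' @param read_length read length; estimated from the BAM when `NULL`.
#' @param gparams,aparams,tparams parameter objects; `read_length`/`depth`
#'   override the corresponding fields when given.
#' @param verbose log progress?
#' @return data.frame with one row per genotyped record (id, type, gt, filter,
#'   branch, gq, dp, n_reads); attribute `"genotypes"` holds the
#'   `sv_genotype` objects, attribute `"skipped"` the parse log.
#' @export
genotype_vcf <- function(vcf, bam, reference, out = NULL, sample = "SAMPLE",
                         depth = 30, read_length = NULL,
                         gparams = NULL, aparams = alignment_params(),
                         tparams = NULL, verbose = FALSE) {
  if (is.character(reference) && length(reference) == 1L && file.exists(reference))
    reference <- Rsamtools::FaFile(reference)
  if (is.null(read_length)) read_length <- estimate_read_length(bam)
  if (is.null(gparams)) gparams <- graph_params(read_length = read_length)
  if (is.null(tparams))
    tparams <- genotyping_params(depth = depth, read_length = read_length)
  records <- parse_sv_vcf(vcf, gparams)
  log_msg(verbose, "parsed %d records (%d skipped)", length(records),
          nrow(attr(records, "skipped")))
  gts <- vector("list", length(records))
  for (i in seq_along(records)) {
    reads <- extract_reads(bam, records[[i]], read_length)
    gts[[i]] <- genotype_sv(records[[i]], reads, reference,
                            gparams, aparams, tparams)
    log_msg(verbose, "%s: %s (%s)", records[[i]]$id, gts[[i]]$gt, gts[[i]]$filter)
  }
  res <- data.frame(
    id = vapply(records, `[[`, "", "id"),
    type = vapply(records, `[[`, "", "type"),
    gt = vapply(gts, function(g) gt_to_vcf(g$gt), ""),
    filter = vapply(gts, `[[`, "", "filter"),
    branch = vapply(gts, `[[`, "", "branch"),
    gq = vapply(gts, `[[`, 0.0, "gq"),
    dp = vapply(gts, function(g)
      sum(vapply(g$breakpoints, function(b) b$counts$R, 0L)), 0L),
    n_reads = vapply(gts, function(g) attr(g, "n_reads"), 0L),
    stringsAsFactors = FALSE
  )
  if (!is.null(out))
    write_genotyped_vcf(records, list(gts), sample, out, reference)
  attr(res, "genotypes") <- gts
  attr(res, "records") <- records
  attr(res, "skipped") <- attr(records, "skipped")
  res
}
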