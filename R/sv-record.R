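#' Structural variant record
#'
#' Normalized representation of one candidate SV. Coordinates are internal
#' 0-based half-open: `start`/`end` delimit the reference span replaced by the
#' alternative allele (for an insertion `start == end`, the insertion point).
#' Conversion from/to 1-based VCF coordinates happens only in the I/O layer.
#'
#' @param contig contig name.
#' @param start 0-based start of the replaced reference span.
#' @param end 0-based half-open end; `end >= start`.
#' @param type one of `"deletion"`, `"insertion"`, `"swap"`.
#' @param alt_seq alternative allele sequence ("" for a pure deletion;
#'   required for insertions and swaps).
#' @param id record identifier.
#' @param genotype optional known/true genotype string (simulator, truth sets).
#' @return object of class `sv_record`.
#' @export
sv_record <- function(contig, start, end, type,
                      alt_seq = "", id = NA_character_, genotype = NA_character_) {
  start <- as.integer(start); end <- as.integer(end)
  if (!type %in% c("deletion", "insertion", "swap"))
    svgt_error("svgt_unsupported_svtype",
               sprintf("unsupported SV type '%s'", type))
  if (end < start)
    svgt_error("svgt_bad_record", "end must be >= start")
  if (type == "deletion" && end == start)
    svgt_error("svgt_bad_record", "deletion span is empty")
  if (type %in% c("insertion", "swap") && !nzchar(alt_seq))
    svgt_error("svgt_missing_alt",
               sprintf("%s record requires an alternative sequence", type))
  if (type == "insertion" && end != start)
    svgt_error("svgt_bad_record", "insertion must have start == end")
  if (nzchar(alt_seq) && !is_dna(alt_seq))
    svgt_error("svgt_bad_record", "alt_seq contains non-IUPAC characters")
  structure(list(
    contig = as.character(contig), start = start, end = end,
    type = type, alt_seq = toupper(alt_seq), id = as.character(id),
    genotype = as.character(genotype)
  ), class = "sv_record")
}

#' @export
print.sv_record <- function(x, ...) {
  cat(sprintf("<sv_record %s %s:%d-%d %s len=%d>\n",
              x$id, x$contig, x$start, x$end, x$type, sv_length(x)))
  invisible(x)
}

#' Length of a structural variant
#'
#' Deletion: deleted bases; insertion: inserted bases; swap: the larger of the
#' replaced and replacement lengths.
#'
#' @param record an `sv_record`.
#' @return integer length.
#' @export
sv_length <- function(record) {
  switch(record$type,
    deletion  = record$end - record$start,
    insertion = nchar(record$alt_seq),
    swap      = max(record$end - record$start, nchar(record$alt_seq))
  )
}
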