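# Read realignment to an allele graph and per-breakpoint support counting.

graph_layout <- function(graph) {
  ids <- topo_order(graph)
  if (is.null(ids)) svgt_error("svgt_bad_graph", "cyclic graph")
  seqs <- vapply(graph$nodes[ids], `[[`, "", "seq")
  lens <- nchar(seqs)
  first <- cumsum(c(0L, lens[-length(lens)]))
  names(first) <- ids
  preds <- lapply(ids, function(id) {
    ins <- vapply(Filter(function(e) e$to == id, graph$edges), `[[`, "", "from")
    match(ins, ids) - 1L
  })
  list(ids = ids, seqs = unname(seqs), first = first,
       last = first + lens - 1L, preds = preds)
}

#' Align reads to an allele graph
#'
#' Junction-aware affine local alignment (plain dynamic programming whose
#' scores equal the striped formulation). Both strands of each read are
#' aligned and the better strand kept (both on a tie). All co-optimal
#' alignments, up to `params$max_alignments`, are returned per read so that
#' mapping uniqueness can be decided.
#'
#' @param reads character vector of read sequences (named to keep read ids).
#' @param graph an `allele_graph`.
#' @param params [alignment_params()].
#' @return a list (one element per read) of lists of `graph_alignment`
#'   objects. Each alignment has `score`, `strand`, `path` (node ids),
#'   `node_overlap` (aligned read bases per path node), `read_start`,
#'   `read_end`, `graph_start`, `graph_end` (0-based columns of the
#'   concatenated graph), and `mismatches`.
#' @export
align_reads <- function(reads, graph, params = alignment_params()) {
  if (any(!nzchar(reads))) svgt_error("svgt_empty_read", "empty read sequence")
  lay <- graph_layout(graph)
  raw <- .graph_align_batch(unname(toupper(reads)), lay$seqs, lay$preds,
                            params$match, params$mismatch,
                            params$gap_open, params$gap_extend,
                            params$max_alignments)
  ids <- if (is.null(names(reads))) as.character(seq_along(reads)) else names(reads)
  out <- vector("list", length(reads))
  for (i in seq_along(raw)) {
    out[[i]] <- lapply(raw[[i]], function(a) {
      path <- lay$ids[a$node_path + 1L]
      structure(list(
        read_id = ids[i], score = a$score, strand = a$strand,
        path = path,
        node_overlap = setNames(a$node_overlap, path),
        read_start = a$read_start, read_end = a$read_end,
        graph_start = a$graph_start, graph_end = a$graph_end,
        mismatches = a$mismatches,
        read_length = nchar(reads[[i]])
      ), class = "graph_alignment")
    })
  }
  names(out) <- ids
  out
}

#' @rdname align_reads
#' @param read a single read sequence.
#' @export
align_read_to_graph <- function(read, graph, params = alignment_params()) {
  align_reads(stats::setNames(read, "read"), graph, params)[[1L]]
}

#' Is a read uniquely mapped?
#'
#' TRUE iff exactly one graph location (strand, start column, node path)
#' attains the best alignment score. An empty alignment list is not unique.
#'
#' @param alignments list of `graph_alignment` for one read.
#' @return logical flag.
#' @export
is_uniquely_mapped <- function(alignments) {
  if (!length(alignments)) return(FALSE)
  sc <- vapply(alignments, `[[`, 0L, "score")
  top <- alignments[sc == max(sc)]
  loc <- vapply(top, function(a)
    paste(a$strand, a$graph_start, paste(a$path, collapse = ">")), "")
  length(unique(loc)) == 1L
}

#' All k-mers of a graph (node k-mers plus edge-spanning k-mers)
#'
#' Edge-spanning k-mers are taken from the junction window formed by the last
#' k-1 bases of the source node and the first k-1 bases of the target node;
#' every window k-mer crosses the junction, so none duplicates a node-interior
#' k-mer. K-mers spanning three or more nodes are not enumerated (nodes are
#' flank- or read-length sized in practice, far longer than k).
#'
#' @param graph an `allele_graph`.
#' @param k k-mer length.
#' @return character vector (with repeats; a multiset).
#' @export
graph_kmers <- function(graph, k) {
  kmers_of <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }
  out <- unlist(lapply(graph$nodes, function(n) kmers_of(n$seq)), use.names = FALSE)
  for (e in graph$edges) {
    u <- graph$nodes[[e$from]]$seq
    v <- graph$nodes[[e$to]]$seq
    win <- paste0(substr(u, max(1L, nchar(u) - k + 2L), nchar(u)),
                  substr(v, 1L, min(nchar(v), k - 1L)))
    out <- c(out, kmers_of(win))
  }
  out
}

#' Does a read contain a k-mer unique in the graph?
#'
#' Both strands of the read are considered; graph k-mers are taken as written.
#' Reads shorter than k have no k-mers and return FALSE.
#'
#' @param read read sequence.
#' @param graph an `allele_graph`.
#' @param k k-mer length.
#' @param graph_kmer_table optional precomputed `table(graph_kmers(graph, k))`.
#' @return logical flag.
#' @export
has_unique_kmer <- function(read, graph, k, graph_kmer_table = NULL) {
  read <- toupper(read)
  if (nchar(read) < k) return(FALSE)
  if (is.null(graph_kmer_table)) graph_kmer_table <- table(graph_kmers(graph, k))
  n <- nchar(read)
  rk <- c(substring(read, 1:(n - k + 1L), k:n))
  rc <- revcomp1(read)
  rk <- unique(c(rk, substring(rc, 1:(n - k + 1L), k:n)))
  counts <- graph_kmer_table[rk]
  any(!is.na(counts) & counts == 1L)
}

overlap_threshold <- function(node_len, read_length, params) {
  min(ceiling(params$min_overlap_fraction * read_length), node_len)
}

#' Does an alignment support a node?
#'
#' A read supports a node when its alignment overlaps the node by at least
#' `min(ceil(min_overlap_fraction * read_length), node_length)` bases.
#'
#' @param aln a `graph_alignment`.
#' @param node node id.
#' @param graph the `allele_graph` aligned against.
#' @param params [alignment_params()].
#' @return logical flag.
#' @export
supports_node <- function(aln, node, graph, params = alignment_params()) {
  ov <- aln$node_overlap[node]
  if (is.na(ov)) return(FALSE)
  thr <- overlap_threshold(nchar(graph$nodes[[node]]$seq), aln$read_length, params)
  ov >= thr
}

#' Does an alignment support an edge?
#'
#' TRUE iff the edge lies on the alignment path and both endpoint nodes are
#' supported under the node-overlap criterion.
#'
#' @param aln a `graph_alignment`.
#' @param edge list with `from`/`to` node ids.
#' @param graph the `allele_graph`.
#' @param params [alignment_params()].
#' @return logical flag.
#' @export
supports_edge <- function(aln, edge, graph, params = alignment_params()) {
  p <- aln$path
  if (length(p) < 2L) return(FALSE)
  on_path <- any(p[-length(p)] == edge$from & p[-1L] == edge$to)
  on_path &&
    supports_node(aln, edge$from, graph, params) &&
    supports_node(aln, edge$to, graph, params)
}

#' Per-breakpoint read support counts
#'
#' For one breakpoint (a node side with >= 2 connected edges), tallies over a
#' set of filtered (uniquely mapped, unique-kmer) read alignments:
#' `R_h` per connecting edge/haplotype (reads whose path contains the edge and
#' supports both its nodes), and `R_neither` — reads at the breakpoint
#' supporting no connecting edge, either because they cross a connecting edge
#' without meeting the overlap threshold or because their alignment stops at
#' the junction with at least the minimum overlap of the read left unaligned.
#' Forward/reverse strand tallies are kept per category.
#'
#' @param breakpoint a `breakpoint` from [enumerate_breakpoints()].
#' @param alignments list of one best `graph_alignment` per read.
#' @param graph the `allele_graph`.
#' @param params [alignment_params()].
#' @return object of class `breakpoint_counts` with fields `haplotypes`,
#'   `R_h` (named), `fwd`, `rev` (named, per haplotype), `R_neither`,
#'   `neither_fwd`, `neither_rev`, `R`.
#' @export
count_breakpoint_support <- function(breakpoint, alignments, graph,
                                     params = alignment_params()) {
  lay <- graph_layout(graph)
  node <- breakpoint$node
  haps <- breakpoint$haplotypes
  R_h <- setNames(integer(length(haps)), haps)
  fwd <- R_h; rev <- R_h
  R_neither <- 0L; neither_fwd <- 0L; neither_rev <- 0L
  junction_col <- if (breakpoint$side == "outgoing") lay$last[[node]] else lay$first[[node]]
  for (aln in alignments) {
    supp <- NA_character_
    crosses <- FALSE
    for (j in seq_along(breakpoint$edges)) {
      e <- breakpoint$edges[[j]]
      p <- aln$path
      on_path <- length(p) >= 2L && any(p[-length(p)] == e$from & p[-1L] == e$to)
      if (on_path) {
        crosses <- TRUE
        if (supports_edge(aln, e, graph, params)) { supp <- haps[j]; break }
      }
    }
    clipped <- FALSE
    if (!crosses) {
      # alignment stops exactly at the junction with unaligned read remaining
      min_ov <- ceiling(params$min_overlap_fraction * aln$read_length)
      if (breakpoint$side == "outgoing") {
        clipped <- aln$graph_end == junction_col &&
          (aln$read_length - aln$read_end) >= min_ov
      } else {
        clipped <- aln$graph_start == junction_col && (aln$read_start - 1L) >= min_ov
      }
    }
    if (!is.na(supp)) {
      R_h[supp] <- R_h[supp] + 1L
      if (aln$strand == "+") fwd[supp] <- fwd[supp] + 1L else rev[supp] <- rev[supp] + 1L
    } else if (crosses || clipped) {
      R_neither <- R_neither + 1L
      if (aln$strand == "+") neither_fwd <- neither_fwd + 1L
      else neither_rev <- neither_rev + 1L
    }
  }
  structure(list(
    breakpoint = breakpoint$name, haplotypes = haps,
    R_h = R_h, fwd = fwd, rev = rev,
    R_neither = R_neither, neither_fwd = neither_fwd, neither_rev = neither_rev,
    R = sum(R_h) + R_neither
  ), class = "breakpoint_counts")
}

#' Construct breakpoint counts directly (tests, simulations)
#'
#' @param R_h named integer vector of per-haplotype supporting reads.
#' @param R_neither reads supporting no connecting haplotype.
#' @param fwd,rev optional named strand tallies (default: an even split).
#' @param neither_fwd,neither_rev strand tallies of the neither category.
#' @param breakpoint breakpoint name.
#' @return `breakpoint_counts`.
#' @export
breakpoint_counts <- function(R_h, R_neither = 0L, fwd = NULL, rev = NULL,
                              neither_fwd = NULL, neither_rev = NULL,
                              breakpoint = "bp") {
  stopifnot(!is.null(names(R_h)), all(R_h >= 0), R_neither >= 0)
  R_h <- as.integer(R_h) |> setNames(names(R_h))
  if (is.null(fwd)) fwd <- R_h %/% 2L
  if (is.null(rev)) rev <- R_h - fwd
  if (is.null(neither_fwd)) neither_fwd <- as.integer(R_neither) %/% 2L
  if (is.null(neither_rev)) neither_rev <- as.integer(R_neither) - neither_fwd
  stopifnot(all(fwd + rev == R_h), neither_fwd + neither_rev == R_neither)
  structure(list(
    breakpoint = breakpoint, haplotypes = names(R_h),
    R_h = R_h, fwd = setNames(as.integer(fwd), names(R_h)),
    rev = setNames(as.integer(rev), names(R_h)),
    R_neither = as.integer(R_neither),
    neither_fwd = as.integer(neither_fwd), neither_rev = as.integer(neither_rev),
    R = sum(R_h) + as.integer(R_neither)
  ), class = "breakpoint_counts")
}

#' Filter read alignments for genotyping
#'
#' Applies, in order, the unique-mapping filter then the unique-kmer filter,
#' and returns the single best alignment per surviving read.
#'
#' @param alignments output of [align_reads()].
#' @param reads the read sequences aligned (same order/names).
#' @param graph the `allele_graph`.
#' @param params [alignment_params()].
#' @return named list of one `graph_alignment` per retained read.
#' @export
filter_alignments <- function(alignments, reads, graph,
                              params = alignment_params()) {
  kt <- table(graph_kmers(graph, params$kmer_size))
  keep <- list()
  for (i in seq_along(alignments)) {
    alns <- alignments[[i]]
    if (!is_uniquely_mapped(alns)) next
    if (!has_unique_kmer(reads[[i]], graph, params$kmer_size, kt)) next
    sc <- vapply(alns, `[[`, 0L, "score")
    keep[[names(alignments)[i]]] <- alns[[which.max(sc)]]
  }
  keep
}

# best alignment per uniquely-mapped read (no k-mer check)
best_unique_alignments <- function(alignments) {
  keep <- list()
  for (i in seq_along(alignments)) {
    alns <- alignments[[i]]
    if (!is_uniquely_mapped(alns)) next
    sc <- vapply(alns, `[[`, 0L, "score")
    keep[[names(alignments)[i]]] <- alns[[which.max(sc)]]
  }
  keep
}

#' Diagnostic table of alignments
#'
#' @param filtered output of [filter_alignments()].
#' @return data.frame with one row per read.
#' @export
alignment_table <- function(filtered) {
  do.call(rbind, lapply(filtered, function(a) data.frame(
    read_id = a$read_id, score = a$score, strand = a$strand,
    path = paste(a$path, collapse = ">"),
    mismatches = a$mismatches, stringsAsFactors = FALSE
  )))
}
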