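#' Fetch reference sequence (0-based half-open)
#'
#' Uniform accessor over the two supported reference backends: a named
#' character vector of contig sequences (in-memory, as produced by the
#' simulator) or an indexed FASTA via [Rsamtools::FaFile].
#'
#' @param reference named character vector or `FaFile`.
#' @param contig contig name.
#' @param start,end 0-based half-open span.
#' @return upper-case sequence string.
#' @export
ref_fetch <- function(reference, contig, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0 || end < start)
    svgt_error("svgt_ref_fetch", sprintf("bad reference span %d-%d", start, end))
  if (methods::is(reference, "FaFile")) {
    gr <- GenomicRanges::GRanges(contig, IRanges::IRanges(start + 1L, end))
    seq <- tryCatch(
      as.character(Rsamtools::scanFa(reference, gr)[[1L]]),
      error = function(e) svgt_error("svgt_ref_fetch", conditionMessage(e))
    )
    return(toupper(seq))
  }
  if (is.character(reference)) {
    if (!contig %in% names(reference))
      svgt_error("svgt_ref_fetch", sprintf("contig '%s' not in reference", contig))
    if (end > nchar(reference[[contig]]))
      svgt_error("svgt_ref_fetch", "span exceeds contig length")
    return(toupper(substr(reference[[contig]], start + 1L, end)))
  }
  svgt_error("svgt_ref_fetch", "unsupported reference accessor")
}

new_node <- function(id, seq, origin, ref_span = NULL) {
  if (nchar(seq) < 1) svgt_error("svgt_bad_graph", "node sequence must be >= 1 base")
  if (!is_dna(seq)) svgt_error("svgt_bad_graph", "node sequence has non-IUPAC characters")
  list(id = id, seq = toupper(seq), origin = origin, ref_span = ref_span)
}

new_graph <- function(nodes, edges, alleles, sv_type, contig, record = NULL) {
  names(nodes) <- vapply(nodes, `[[`, "", "id")
  g <- structure(list(
    nodes = nodes, edges = edges, alleles = alleles,
    sv_type = sv_type, contig = contig,
    source = nodes[[1L]]$id, sink = nodes[[length(nodes)]]$id,
    record = record
  ), class = "allele_graph")
  validate_graph(g)
  g
}

#' Build the local allele graph for one SV record
#'
#' The graph has a left flank node, a right flank node and an allele-specific
#' middle: for a deletion the REF path traverses the deleted-sequence node and
#' the ALT path is a direct flank-to-flank edge; an insertion is symmetric
#' (ALT traverses the inserted-sequence node); a swap has two parallel middle
#' nodes. Every edge is labeled with the allele path(s) that use it.
#'
#' @param record an [sv_record()].
#' @param reference reference accessor (see [ref_fetch()]).
#' @param params [graph_params()].
#' @return object of class `allele_graph`.
#' @export
#' @examples
#' ref <- c(chr1 = paste(rep("ACGTT", 400), collapse = ""))
#' rec <- sv_record("chr1", 1000, 1300, "deletion", id = "del1")
#' g <- build_graph(rec, ref, graph_params(read_length = 150))
#' length(g$nodes) # 4: two flanks, deleted node, and the graph bookkeeping
build_graph <- function(record, reference, params = graph_params()) {
  if (!inherits(record, "sv_record"))
    svgt_error("svgt_bad_record", "record must be an sv_record")
  fl <- params$flank_length
  contig <- record$contig
  lf_start <- max(0L, record$start - fl)
  lf <- new_node("LF", ref_fetch(reference, contig, lf_start, record$start),
                 "reference-fetched", c(contig, lf_start, record$start))
  rf <- new_node("RF", ref_fetch(reference, contig, record$end, record$end + fl),
                 "reference-fetched", c(contig, record$end, record$end + fl))

  edge <- function(from, to, labels) list(from = from, to = to, labels = labels)

  if (record$type == "deletion") {
    mid <- new_node("DEL", ref_fetch(reference, contig, record$start, record$end),
                    "reference-fetched", c(contig, record$start, record$end))
    nodes <- list(lf, mid, rf)
    edges <- list(edge("LF", "DEL", "REF"), edge("DEL", "RF", "REF"),
                  edge("LF", "RF", "ALT"))
    alleles <- list(REF = c("LF", "DEL", "RF"), ALT = c("LF", "RF"))
  } else if (record$type == "insertion") {
    mid <- new_node("INS", record$alt_seq, "explicit")
    nodes <- list(lf, mid, rf)
    edges <- list(edge("LF", "INS", "ALT"), edge("INS", "RF", "ALT"),
                  edge("LF", "RF", "REF"))
    alleles <- list(REF = c("LF", "RF"), ALT = c("LF", "INS", "RF"))
  } else { # swap
    refn <- new_node("REFSEQ", ref_fetch(reference, contig, record$start, record$end),
                     "reference-fetched", c(contig, record$start, record$end))
    altn <- new_node("ALTSEQ", record$alt_seq, "explicit")
    nodes <- list(lf, refn, altn, rf)
    edges <- list(edge("LF", "REFSEQ", "REF"), edge("REFSEQ", "RF", "REF"),
                  edge("LF", "ALTSEQ", "ALT"), edge("ALTSEQ", "RF", "ALT"))
    alleles <- list(REF = c("LF", "REFSEQ", "RF"), ALT = c("LF", "ALTSEQ", "RF"))
  }
  new_graph(nodes, edges, alleles, record$type, contig, record)
}

#' Validate allele-graph invariants
#'
#' Checks acyclicity (topological sort), that every allele path runs
#' source to sink along existing edges, and that every edge carries at least
#' one allele label.
#'
#' @param graph an `allele_graph`.
#' @return the graph, invisibly; errors on violation.
#' @export
validate_graph <- function(graph) {
  ids <- names(graph$nodes)
  ek <- vapply(graph$edges, function(e) paste(e$from, e$to), "")
  if (anyDuplicated(ek)) svgt_error("svgt_bad_graph", "duplicate edges")
  for (e in graph$edges) {
    if (!e$from %in% ids || !e$to %in% ids)
      svgt_error("svgt_bad_graph", "edge endpoint not a node")
    if (length(e$labels) < 1)
      svgt_error("svgt_bad_graph", "edge without allele label")
  }
  if (is.null(topo_order(graph)))
    svgt_error("svgt_bad_graph", "graph has a cycle")
  for (al in names(graph$alleles)) {
    p <- graph$alleles[[al]]
    if (p[1L] != graph$source || p[length(p)] != graph$sink)
      svgt_error("svgt_bad_graph", sprintf("allele %s does not run source->sink", al))
    if (length(p) > 1) {
      steps <- paste(p[-length(p)], p[-1L])
      if (!all(steps %in% ek))
        svgt_error("svgt_bad_graph", sprintf("allele %s uses a missing edge", al))
    }
  }
  invisible(graph)
}

#' Topological order of graph nodes
#'
#' Kahn's algorithm; returns `NULL` when the graph is cyclic.
#'
#' @param graph an `allele_graph`.
#' @return character vector of node ids or `NULL`.
#' @export
topo_order <- function(graph) {
  ids <- names(graph$nodes)
  indeg <- setNames(integer(length(ids)), ids)
  for (e in graph$edges) indeg[e$to] <- indeg[e$to] + 1L
  queue <- ids[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    # stable: keep the original node order among ready nodes
    queue <- ids[ids %in% queue]
    n <- queue[1L]; queue <- queue[-1L]
    out <- c(out, n)
    for (e in graph$edges) {
      if (e$from == n) {
        indeg[e$to] <- indeg[e$to] - 1L
        if (indeg[e$to] == 0L) queue <- c(queue, e$to)
      }
    }
  }
  if (length(out) == length(ids)) out else NULL
}

#' Replace over-long nodes by their breakpoint-proximal ends
#'
#' Reads informative for a breakpoint overlap it by less than one read length,
#' so interior sequence of very long nodes carries no genotyping signal. Any
#' node longer than `2 * read_length` is replaced by two nodes holding its
#' first and last `read_length` bases; the halves are joined by an edge
#' carrying the original node's allele labels so every allele path still runs
#' source to sink (the spelled interior sequence is shortened by design).
#' Idempotent.
#'
#' @param graph an `allele_graph`.
#' @param read_length positive integer.
#' @return a (possibly) modified `allele_graph`.
#' @export
split_long_nodes <- function(graph, read_length) {
  stopifnot(read_length > 0)
  rl <- as.integer(read_length)
  long <- names(graph$nodes)[vapply(graph$nodes, function(n) nchar(n$seq), 0L) > 2L * rl]
  if (!length(long)) return(graph)
  nodes <- list(); alleles <- graph$alleles
  for (n in graph$nodes) {
    if (!n$id %in% long) { nodes <- c(nodes, list(n)); next }
    len <- nchar(n$seq)
    span_l <- span_r <- NULL
    if (!is.null(n$ref_span)) {
      s <- as.integer(n$ref_span[2L])
      span_l <- c(n$ref_span[1L], s, s + rl)
      span_r <- c(n$ref_span[1L], s + len - rl, s + len)
    }
    left  <- new_node(paste0(n$id, ".L"), substr(n$seq, 1L, rl), n$origin, span_l)
    right <- new_node(paste0(n$id, ".R"), substr(n$seq, len - rl + 1L, len),
                      n$origin, span_r)
    nodes <- c(nodes, list(left, right))
  }
  relab <- function(ids) {
    out <- character(0)
    for (id in ids) {
      out <- c(out, if (id %in% long) paste0(id, c(".L", ".R")) else id)
    }
    out
  }
  alleles <- lapply(alleles, relab)
  edges <- list()
  for (e in graph$edges) {
    from <- if (e$from %in% long) paste0(e$from, ".R") else e$from
    to   <- if (e$to %in% long) paste0(e$to, ".L") else e$to
    edges <- c(edges, list(list(from = from, to = to, labels = e$labels)))
  }
  for (id in long) {
    # labels of the bridge edge = union of allele labels over the node's edges
    labs <- unique(unlist(lapply(
      graph$edges, function(e) if (e$from == id || e$to == id) e$labels else NULL
    )))
    edges <- c(edges, list(list(from = paste0(id, ".L"),
                                to = paste0(id, ".R"), labels = labs)))
  }
  # keep topological node order (left half before right half, original order)
  new_graph(nodes, edges, alleles, graph$sv_type, graph$contig, graph$record)
}

#' Enumerate breakpoints of an allele graph
#'
#' A breakpoint is a node side (outgoing or incoming) with two or more
#' connected edges. Order is deterministic: by node reference coordinate
#' (explicit nodes sort after reference-fetched ones at the same rank, then by
#' node order), outgoing side before incoming.
#'
#' @param graph an `allele_graph`.
#' @return list of `breakpoint` objects with fields `node`, `side`, `edges`
#'   (each edge: from, to, labels) and `name`.
#' @export
enumerate_breakpoints <- function(graph) {
  bps <- list()
  for (idx in seq_along(graph$nodes)) {
    n <- graph$nodes[[idx]]
    for (side in c("outgoing", "incoming")) {
      es <- Filter(function(e)
        if (side == "outgoing") e$from == n$id else e$to == n$id, graph$edges)
      if (length(es) >= 2L) {
        bps <- c(bps, list(structure(list(
          node = n$id, side = side, edges = es,
          name = paste0(n$id, ":", side),
          haplotypes = vapply(es, function(e) e$labels[[1L]], "")
        ), class = "breakpoint")))
      }
    }
  }
  ord <- order(vapply(bps, function(b) match(b$node, names(graph$nodes)), 0),
               vapply(bps, function(b) match(b$side, c("outgoing", "incoming")), 0))
  bps[ord]
}

#' Sequence spelled by one allele path
#'
#' @param graph an `allele_graph`.
#' @param allele allele label, e.g. `"REF"` or `"ALT"`.
#' @return the concatenated path sequence.
#' @export
allele_path_seq <- function(graph, allele) {
  p <- graph$alleles[[allele]]
  if (is.null(p)) svgt_error("svgt_bad_graph", sprintf("no allele '%s'", allele))
  paste(vapply(graph$nodes[p], `[[`, "", "seq"), collapse = "")
}

#' Serialize a graph to JSON (debugging aid)
#'
#' @param graph an `allele_graph`.
#' @param path optional output file.
#' @return JSON string, invisibly if written to file.
#' @export
graph_to_json <- function(graph, path = NULL) {
  doc <- list(
    sv_type = graph$sv_type, contig = graph$contig,
    nodes = lapply(unname(graph$nodes), function(n)
      list(id = n$id, sequence = n$seq, origin = n$origin)),
    edges = lapply(graph$edges, function(e)
      list(from = e$from, to = e$to, alleles = as.list(e$labels))),
    alleles = graph$alleles
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' @export
print.allele_graph <- function(x, ...) {
  cat(sprintf("<allele_graph %s %s: %d nodes, %d edges, alleles %s>\n",
              x$sv_type, x$contig, length(x$nodes), length(x$edges),
              paste(names(x$alleles), collapse = ",")))
  invisible(x)
}
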