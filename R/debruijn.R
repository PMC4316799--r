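#' Assembly parameters
#'
#' Bundles the tunable parameters of the two-stage assembler.
#'
#' @param k k-mer length (default 25; at most 31). Edges of the de Bruijn
#'   graph are k-mers; nodes are their flanking (k-1)-mers, held implicitly.
#' @param alpha minimum edge frequency for seeding a path during graph
#'   reduction (default 50).
#' @param beta minimum edge frequency for extending a path (default 5).
#' @param epsilon minimum per-base full-length-read coverage for a candidate
#'   region to be retained as a final transcript (default 20).
#' @param capacity maximum number of distinct edges held in the graph before
#'   a capacity-triggered reduction (default \code{2^24}).
#' @param min_transcript_length minimum length (nt) of a retained transcript
#'   region; defaults to \code{2 * k}, which guarantees non-trivial k-mer
#'   support.
#' @param max_mismatches mismatches tolerated when aligning reads back to
#'   candidate transcripts in stage 2 (default 2).
#' @return an object of class \code{assembly_params}.
#' @export
assembly_params <- function(k = 25, alpha = 50, beta = 5, epsilon = 20,
                            capacity = 2^24, min_transcript_length = 2 * k,
                            max_mismatches = 2) {
  stopifnot(k >= 2, k <= 31, alpha >= beta, beta >= 1, epsilon >= 1,
            capacity > 0, min_transcript_length >= 1, max_mismatches >= 0)
  structure(list(k = as.integer(k), alpha = as.integer(alpha),
                 beta = as.integer(beta), epsilon = as.integer(epsilon),
                 capacity = as.numeric(capacity),
                 min_transcript_length = as.integer(min_transcript_length),
                 max_mismatches = as.integer(max_mismatches)),
            class = "assembly_params")
}

#' Split a sequence into its constituent k-mers
#'
#' Returns the consecutive length-k substrings in order, excluding any k-mer
#' containing a non-ACGT symbol. Sequences shorter than k yield an empty
#' vector.
#'
#' @param sequence a nucleotide string.
#' @param k k-mer length (>= 2).
#' @return character vector of k-mers.
#' @export
#' @examples
#' kmerize("ACGTA", 4)
#' kmerize("ACNGT", 2)
kmerize <- function(sequence, k) {
  stopifnot(is_string(sequence), k >= 2)
  .kmerize(toupper(sequence), as.integer(k))
}

#' Create an empty de Bruijn graph
#'
#' The graph is a hash table from k-mer edge to occurrence count, bounded at
#' \code{params$capacity} edges. The object has reference semantics (like an
#' environment): [add_read()], [extract_path()] and [reduce_graph()] modify
#' it in place.
#'
#' @param params an [assembly_params()] object.
#' @param strand_specific logical; when \code{FALSE} (strand-ambiguous data,
#'   the default) each k-mer is canonicalized to the lexicographic minimum of
#'   itself and its reverse complement before any lookup, and candidates are
#'   reported in canonical orientation.
#' @return an object of class \code{debruijn_graph}.
#' @export
de_bruijn_graph <- function(params = assembly_params(),
                            strand_specific = FALSE) {
  stopifnot(inherits(params, "assembly_params"))
  structure(list(ptr = .dbg_new(params$k, params$alpha, params$beta,
                                params$capacity, !strand_specific),
                 params = params, strand_specific = strand_specific),
            class = "debruijn_graph")
}

#' @export
print.debruijn_graph <- function(x, ...) {
  cat(sprintf("<debruijn_graph> k=%d alpha=%d beta=%d, %d edges\n",
              x$params$k, x$params$alpha, x$params$beta, graph_size(x)))
  invisible(x)
}

#' Add a read's k-mers to a de Bruijn graph
#'
#' Each k-mer of the read (canonicalized under the strand policy) is looked
#' up in \code{index} first: k-mers already part of an assembled candidate
#' transcript are skipped, the rest increment their edge count (insertion at
#' 1 when new). If an insertion would exceed the graph capacity, a
#' capacity-triggered [reduce_graph()] runs first and sub-alpha edges are
#' purged.
#'
#' @param graph a [de_bruijn_graph()].
#' @param read a nucleotide string (or a single-row read-set record).
#' @param index optionally, the [fm_index()] of candidate transcripts.
#' @return the number of edges added or incremented, invisibly modifying
#'   \code{graph}.
#' @export
add_read <- function(graph, read, index = NULL) {
  stopifnot(inherits(graph, "debruijn_graph"))
  if (is.data.frame(read)) read <- read$sequence
  stopifnot(is_string(read))
  .dbg_add_read(graph$ptr, toupper(read),
                if (is.null(index)) NULL else index$ptr)
}

#' Extract one candidate transcript by greedy path traversal
#'
#' Starting from \code{seed} (which must be present with frequency at least
#' alpha), the path is extended rightward as long as some edge overlapping
#' the terminal (k-1)-mer has frequency at least beta — the most frequent
#' such edge is taken, ties resolved toward the lexicographically smallest
#' base — and then leftward symmetrically. Every traversed edge, seed
#' included, is removed from the graph.
#'
#' @param graph a [de_bruijn_graph()].
#' @param seed a k-mer string present in the graph with count >= alpha.
#' @return the assembled candidate sequence (length >= k).
#' @export
extract_path <- function(graph, seed) {
  stopifnot(inherits(graph, "debruijn_graph"), is_string(seed))
  .dbg_extract_path(graph$ptr, toupper(seed))
}

#' Reduce a de Bruijn graph into candidate transcripts
#'
#' Repeatedly seeds [extract_path()] at the remaining edge of maximal count
#' while that count is at least alpha (ties resolved toward the
#' lexicographically smallest k-mer). Afterwards no edge with count >= alpha
#' remains. Candidates are appended to \code{index} when one is supplied.
#' A capacity-triggered purge (\code{purge = TRUE}) additionally discards
#' the untraversed sub-alpha edges to reclaim memory; the end-of-input
#' reduction leaves them in place.
#'
#' @param graph a [de_bruijn_graph()].
#' @param index optionally, the [fm_index()] receiving the candidates.
#' @param purge logical; discard sub-alpha edges afterwards?
#' @return character vector of candidate transcript sequences.
#' @export
reduce_graph <- function(graph, index = NULL, purge = FALSE) {
  stopifnot(inherits(graph, "debruijn_graph"))
  .dbg_reduce(graph$ptr, if (is.null(index)) NULL else index$ptr, purge)
}

#' Inspect the edges of a de Bruijn graph
#'
#' @param graph a [de_bruijn_graph()].
#' @return named integer vector of edge counts, names sorted k-mers.
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "debruijn_graph"))
  .dbg_edges(graph$ptr)
}

#' @rdname graph_edges
#' @export
graph_size <- function(graph) {
  stopifnot(inherits(graph, "debruijn_graph"))
  as.integer(.dbg_size(graph$ptr))
}

# test scaffolding: install edges with explicit counts (strand policy applied)
set_graph_edges <- function(graph, counts) {
  stopifnot(inherits(graph, "debruijn_graph"), !is.null(names(counts)))
  .dbg_set_edges(graph$ptr, names(counts), as.integer(counts))
  invisible(graph)
}
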