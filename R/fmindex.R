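#' Build a Burrows-Wheeler (FM) index over nucleotide sequences
#'
#' The index stores the Burrows-Wheeler transform of the concatenation of
#' all sequences, each terminated by a sentinel, together with checkpointed
#' rank counts and sampled suffix-array positions. Pattern counting and
#' locating run by backward search in time proportional to the pattern
#' length; occurrences never span a sentinel. Like [de_bruijn_graph()], the
#' object has reference semantics.
#'
#' @param sequences named character vector of sequences over
#'   \code{{A,C,G,T}} (names are the sequence ids). May be empty.
#' @param occ_stride stride (symbols) between rank checkpoints.
#' @param sa_stride stride (suffixes) between suffix-array samples.
#' @return an object of class \code{fm_index}.
#' @export
#' @examples
#' idx <- fm_index(c(t1 = "ACGTACGT"))
#' fm_count(idx, "ACG")
fm_index <- function(sequences = character(), occ_stride = 128L,
                     sa_stride = 32L) {
  validate_index_seqs(sequences, character())
  structure(list(ptr = .fm_new(names2(sequences), unname(sequences),
                               as.integer(occ_stride),
                               as.integer(sa_stride)),
                 occ_stride = as.integer(occ_stride),
                 sa_stride = as.integer(sa_stride)),
            class = "fm_index")
}

names2 <- function(x) {
  nm <- names(x)
  if (is.null(nm)) nm <- if (length(x)) paste0("seq_", seq_along(x)) else
    character()
  nm
}

validate_index_seqs <- function(sequences, existing) {
  if (length(sequences) == 0L) return(invisible())
  sequences <- toupper(sequences)
  if (any(!nzchar(sequences)))
    stop_dn("indexed sequences must be non-empty",
            class = "denovotx_validation_error")
  if (any(grepl("[^ACGT]", sequences)))
    stop_dn("indexed sequences must be over {A,C,G,T}",
            class = "denovotx_validation_error")
  nm <- names2(sequences)
  dup <- c(existing, nm)[duplicated(c(existing, nm))]
  if (length(dup))
    stop_dn("duplicate sequence id '%s'", dup[1],
            class = "denovotx_validation_error")
  invisible()
}

#' @export
print.fm_index <- function(x, ...) {
  cat(sprintf("<fm_index> %d sequences, N=%d nt\n",
              length(fm_sequences(x)), fm_length(x)))
  invisible(x)
}

#' Add a sequence to an FM index
#'
#' Incremental maintenance is implemented as a batched rebuild: the result
#' is behaviorally identical to building the index over the union of
#' sequences.
#'
#' @param index an [fm_index()].
#' @param id unused sequence id.
#' @param sequence nucleotide string over \code{{A,C,G,T}}.
#' @return the index, invisibly (modified in place).
#' @export
fm_add_sequence <- function(index, id, sequence) {
  stopifnot(inherits(index, "fm_index"), is_string(id), is_string(sequence))
  validate_index_seqs(setNames(sequence, id), .fm_ids(index$ptr))
  .fm_add(index$ptr, id, toupper(sequence))
  invisible(index)
}

#' Count pattern occurrences in an FM index
#'
#' Backward search; each pattern symbol costs one rank step. Patterns
#' containing non-ACGT symbols count 0 by convention.
#'
#' @param index an [fm_index()].
#' @param patterns character vector of patterns.
#' @return numeric vector of occurrence counts.
#' @export
fm_count <- function(index, patterns) {
  stopifnot(inherits(index, "fm_index"), is.character(patterns))
  .fm_count(index$ptr, toupper(patterns))
}

#' Locate pattern occurrences in an FM index
#'
#' @param index an [fm_index()].
#' @param pattern a single pattern.
#' @return data frame with columns \code{seq_id} and 0-based \code{offset},
#'   sorted by position.
#' @export
fm_locate <- function(index, pattern) {
  stopifnot(inherits(index, "fm_index"), is_string(pattern))
  hits <- .fm_locate(index$ptr, toupper(pattern))
  ids <- .fm_ids(index$ptr)
  data.frame(seq_id = ids[hits$doc], offset = as.integer(hits$offset),
             stringsAsFactors = FALSE)
}

#' Align reads full-length against an FM index
#'
#' Exact (0-mismatch) alignments are found by pure backward search.
#' Mismatch-tolerant alignment uses pigeonhole seeding: the read is split
#' into \code{max_mismatches + 1} equal segments, each segment is matched
#' exactly, and candidate loci are verified by direct comparison. All
#' returned alignments are full-length and ungapped.
#'
#' @param index an [fm_index()].
#' @param reads character vector of read sequences.
#' @param both_strands logical; also align the reverse complement (set for
#'   strand-ambiguous data).
#' @param max_mismatches maximum Hamming mismatches tolerated.
#' @return data frame with columns \code{query} (read index), \code{seq_id},
#'   0-based \code{offset}, \code{strand} and \code{mismatches}.
#' @export
fm_align <- function(index, reads, both_strands = TRUE, max_mismatches = 0) {
  stopifnot(inherits(index, "fm_index"), is.character(reads))
  aln <- .fm_align(index$ptr, toupper(reads), both_strands,
                   as.integer(max_mismatches))
  # a read identical to its reverse complement reports each locus twice;
  # keep one record per (query, locus)
  key <- paste(aln$query, aln$doc, aln$offset)
  aln <- aln[!duplicated(key), , drop = FALSE]
  ids <- .fm_ids(index$ptr)
  out <- data.frame(query = aln$query, seq_id = ids[aln$doc],
                    offset = as.integer(aln$offset), strand = aln$strand,
                    mismatches = aln$mismatches, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Sequences held by an FM index
#'
#' @param index an [fm_index()].
#' @return named character vector of the indexed sequences.
#' @export
fm_sequences <- function(index) {
  stopifnot(inherits(index, "fm_index"))
  setNames(.fm_seqs(index$ptr), .fm_ids(index$ptr))
}

#' @rdname fm_sequences
#' @export
fm_length <- function(index) {
  stopifnot(inherits(index, "fm_index"))
  as.integer(.fm_total_length(index$ptr))
}

#' @rdname fm_sequences
#' @export
fm_bwt <- function(index) {
  stopifnot(inherits(index, "fm_index"))
  .fm_bwt(index$ptr)
}

# cumulative backward-search step counter; used to assert the O(m) contract
fm_search_steps <- function(index, reset = FALSE) {
  .fm_steps(index$ptr, reset)
}

#' Persist and restore an FM index
#'
#' The on-disk representation is a versioned container of the indexed
#' sequences and sampling strides; the rank and suffix-array structures are
#' rebuilt on load, which is behaviorally identical to the saved index.
#'
#' @param index an [fm_index()].
#' @param path file path.
#' @return \code{fm_save} returns \code{path} invisibly; \code{fm_load}
#'   returns the restored [fm_index()].
#' @export
fm_save <- function(index, path) {
  stopifnot(inherits(index, "fm_index"))
  saveRDS(list(format = "denovotx-fm", version = 1L,
               ids = .fm_ids(index$ptr), seqs = .fm_seqs(index$ptr),
               occ_stride = index$occ_stride, sa_stride = index$sa_stride),
          path)
  invisible(path)
}

#' @rdname fm_save
#' @export
fm_load <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "denovotx-fm"))
    stop_dn("'%s' is not a serialized fm_index", path,
            class = "denovotx_format_error")
  fm_index(setNames(obj$seqs, obj$ids), obj$occ_stride, obj$sa_stride)
}
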