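#' Paired-end consistency constraint
#'
#' @param min_insert,max_insert fragment-length bounds (nt).
#' @param orientation expected relative orientation of the mates; only
#'   inward (forward-reverse) libraries are supported.
#' @return an object of class \code{pair_constraint}.
#' @export
pair_constraint <- function(min_insert = 1, max_insert = 500,
                            orientation = "inward") {
  stopifnot(min_insert > 0, min_insert <= max_insert,
            orientation == "inward")
  structure(list(min_insert = as.integer(min_insert),
                 max_insert = as.integer(max_insert),
                 orientation = orientation),
            class = "pair_constraint")
}

#' Do two mate alignments form a consistent scaffold?
#'
#' Both mates must align full-length to the same transcript, on opposite
#' strands in inward orientation, with an implied fragment length within the
#' insert bounds.
#'
#' @param a1,a2 single alignments (one-row data frames or lists with fields
#'   \code{seq_id}, \code{offset}, \code{strand}) of mate 1 and mate 2.
#' @param len1,len2 the mate read lengths.
#' @param constraint a [pair_constraint()].
#' @return logical.
#' @export
paired_consistent <- function(a1, a2, len1, len2,
                              constraint = pair_constraint()) {
  if (a1$seq_id != a2$seq_id || a1$strand == a2$strand) return(FALSE)
  if (a1$strand == "+") {
    left_off <- a1$offset; right_end <- a2$offset + len2
  } else {
    left_off <- a2$offset; right_end <- a1$offset + len1
  }
  frag <- right_end - left_off
  frag >= constraint$min_insert && frag <= constraint$max_insert &&
    left_off <= (right_end - max(len1, len2))
}

as_read_set_list <- function(reads) {
  if (inherits(reads, "read_set")) reads <- list(reads)
  stopifnot(length(reads) >= 1,
            all(vapply(reads, inherits, logical(1), "read_set")))
  reads
}

# stage-1 input sequences for one sample: in strand-specific mode the
# second mate is reverse-complemented so all k-mers read in sense
stage1_sequences <- function(rs) {
  seqs <- rs$reads$sequence
  if (rs$strand_specific && rs$paired) {
    m2 <- rs$reads$mate_role == "mate2"
    seqs[m2] <- revcomp(seqs[m2])
  }
  seqs
}

#' Stage 1: assemble candidate transcripts
#'
#' Streams all reads through the de Bruijn graph in file order, with
#' capacity-triggered reductions as needed and one final reduction after the
#' last read. Every k-mer of every candidate occurred in at least one read.
#'
#' @param reads a [read_set()] or list of read sets (one per sample).
#' @param params an [assembly_params()].
#' @return list with \code{candidates} (data frame of \code{candidate_id},
#'   \code{sequence}) and \code{index}, the [fm_index()] over exactly those
#'   candidates.
#' @export
stage1 <- function(reads, params = assembly_params()) {
  reads <- as_read_set_list(reads)
  strand_specific <- reads[[1]]$strand_specific
  g <- de_bruijn_graph(params, strand_specific = strand_specific)
  idx <- fm_index()
  total <- 0L
  for (rs in reads) {
    seqs <- stage1_sequences(rs)
    total <- total + length(seqs)
    if (length(seqs)) .dbg_add_reads(g$ptr, seqs, idx$ptr)
  }
  if (total == 0L) warning("no reads supplied; empty candidate set")
  reduce_graph(g, index = idx, purge = FALSE)
  seqs <- fm_sequences(idx)
  list(candidates = data.frame(candidate_id = names2(seqs),
                               sequence = unname(seqs),
                               stringsAsFactors = FALSE),
       index = idx, graph = g)
}

# per-sample read-to-candidate alignment with mate filtering and unique
# random assignment of multimapping reads; returns one row per aligned read
align_sample <- function(index, rs, params, constraint) {
  n <- nrow(rs$reads)
  empty <- data.frame(read = integer(), seq_id = character(),
                      offset = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  seqs <- rs$reads$sequence
  aln <- fm_align(index, seqs, both_strands = !rs$strand_specific,
                  max_mismatches = params$max_mismatches)
  if (rs$strand_specific) {
    # sense alignment only: mate1 forward, mate2 reverse
    m2 <- rs$reads$mate_role[aln$query] == "mate2"
    aln <- aln[(aln$strand == "+" & !m2) | (aln$strand == "-" & m2), ,
               drop = FALSE]
  }
  if (nrow(aln) == 0L) return(empty)
  rl <- nchar(seqs)

  if (!rs$paired) {
    best <- stats::ave(aln$mismatches, aln$query, FUN = min)
    aln <- aln[aln$mismatches == best, , drop = FALSE]
    aln <- aln[sample.int(nrow(aln)), , drop = FALSE]  # random tie-break
    aln <- aln[!duplicated(aln$query), , drop = FALSE]
    return(data.frame(read = aln$query, seq_id = aln$seq_id,
                      offset = aln$offset, length = rl[aln$query],
                      stringsAsFactors = FALSE))
  }

  # paired: enumerate mate1 x mate2 alignment combinations per pair and
  # keep consistent ones with minimal total mismatches
  pair_of <- (seq_len(n) + 1L) %/% 2L
  a1 <- aln[rs$reads$mate_role[aln$query] == "mate1", , drop = FALSE]
  a2 <- aln[rs$reads$mate_role[aln$query] == "mate2", , drop = FALSE]
  a1$pair <- pair_of[a1$query]; a2$pair <- pair_of[a2$query]
  cmb <- merge(a1, a2, by = "pair", suffixes = c("1", "2"))
  if (nrow(cmb) == 0L) return(empty)
  cmb <- cmb[cmb$seq_id1 == cmb$seq_id2 & cmb$strand1 != cmb$strand2, ,
             drop = FALSE]
  if (nrow(cmb) == 0L) return(empty)
  l1 <- rl[cmb$query1]; l2 <- rl[cmb$query2]
  left <- ifelse(cmb$strand1 == "+", cmb$offset1, cmb$offset2)
  rend <- ifelse(cmb$strand1 == "+", cmb$offset2 + l2, cmb$offset1 + l1)
  frag <- rend - left
  ok <- frag >= constraint$min_insert & frag <= constraint$max_insert &
    left <= rend - pmax(l1, l2)
  cmb <- cmb[ok, , drop = FALSE]
  if (nrow(cmb) == 0L) return(empty)
  mmtot <- cmb$mismatches1 + cmb$mismatches2
  best <- stats::ave(mmtot, cmb$pair, FUN = min)
  cmb <- cmb[mmtot == best, , drop = FALSE]
  cmb <- cmb[sample.int(nrow(cmb)), , drop = FALSE]
  cmb <- cmb[!duplicated(cmb$pair), , drop = FALSE]
  data.frame(read = c(cmb$query1, cmb$query2),
             seq_id = c(cmb$seq_id1, cmb$seq_id2),
             offset = c(cmb$offset1, cmb$offset2),
             length = c(rl[cmb$query1], rl[cmb$query2]),
             stringsAsFactors = FALSE)
}

#' Maximal epsilon-covered regions of a coverage profile
#'
#' Returns the maximal intervals over which per-base depth is at least
#' \code{epsilon}, discarding intervals shorter than \code{min_length}.
#' Intervals are disjoint, sorted, 0-based half-open.
#'
#' @param depth integer vector of per-base alignment depth.
#' @param epsilon minimum depth.
#' @param min_length minimum interval length (nt).
#' @return data frame with columns \code{start}, \code{end}.
#' @export
#' @examples
#' retain_regions(c(rep(25, 30), rep(0, 10), rep(25, 60)), 20, 50)
retain_regions <- function(depth, epsilon, min_length) {
  r <- S4Vectors::Rle(as.integer(depth))
  ir <- IRanges::ranges(IRanges::slice(r, lower = epsilon))
  ir <- ir[IRanges::width(ir) >= min_length]
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Stage 2: filter candidates into final transcripts
#'
#' Aligns every read (or read pair) full-length to the candidate index.
#' Pairs failing the scaffold-consistency constraint contribute nothing;
#' reads aligning equally well to several candidates are assigned to one
#' uniformly at random (reproducible under [set.seed()]). Per-base coverage
#' profiles are accumulated across all samples, sufficiently long regions
#' with depth at least \code{epsilon} become final transcripts, and
#' per-sample counts are recomputed over the retained intervals: a read
#' counts toward a transcript when its alignment lies within the interval.
#'
#' @param reads a [read_set()] or list of read sets (one per sample).
#' @param candidates data frame from [stage1()].
#' @param index the [fm_index()] over the candidates.
#' @param params an [assembly_params()].
#' @param constraint a [pair_constraint()].
#' @return list with \code{transcripts} (data frame), \code{counts}
#'   (a [count_matrix()]), and \code{profiles} (per-candidate depth).
#' @export
stage2 <- function(reads, candidates, index, params = assembly_params(),
                   constraint = pair_constraint()) {
  reads <- as_read_set_list(reads)
  nsamp <- length(reads)
  sample_ids <- names(reads)
  if (is.null(sample_ids))
    sample_ids <- paste0("sample_", seq_len(nsamp))
  cand_len <- setNames(nchar(candidates$sequence), candidates$candidate_id)

  aln <- do.call(rbind, lapply(seq_len(nsamp), function(s) {
    a <- align_sample(index, reads[[s]], params, constraint)
    if (nrow(a)) a$sample <- s else a$sample <- integer()
    a
  }))

  profiles <- list()
  transcripts <- NULL
  counts <- NULL
  tcount <- 0L
  for (cid in candidates$candidate_id) {
    L <- cand_len[[cid]]
    ca <- aln[aln$seq_id == cid, , drop = FALSE]
    depth <- if (nrow(ca) == 0L) integer(L) else
      as.integer(IRanges::coverage(
        IRanges::IRanges(start = ca$offset + 1L, width = ca$length),
        width = L))
    profiles[[cid]] <- depth
    regs <- retain_regions(depth, params$epsilon,
                           params$min_transcript_length)
    if (nrow(regs) == 0L) next
    for (j in seq_len(nrow(regs))) {
      tcount <- tcount + 1L
      s0 <- regs$start[j]; e0 <- regs$end[j]
      inside <- ca$offset >= s0 & (ca$offset + ca$length) <= e0
      cvec <- tabulate(ca$sample[inside], nbins = nsamp)
      seq_j <- substr(candidates$sequence[candidates$candidate_id == cid],
                      s0 + 1L, e0)
      transcripts <- rbind(transcripts, data.frame(
        transcript_id = sprintf("%s.%d", cid, j), sequence = seq_j,
        source_candidate = cid, start = s0, end = e0,
        length = e0 - s0,
        mean_coverage = mean(depth[(s0 + 1):e0]),
        stringsAsFactors = FALSE))
      counts <- rbind(counts, cvec)
    }
  }
  if (is.null(transcripts)) {
    transcripts <- data.frame(transcript_id = character(),
                              sequence = character(),
                              source_candidate = character(),
                              start = integer(), end = integer(),
                              length = integer(),
                              mean_coverage = numeric(),
                              stringsAsFactors = FALSE)
    counts <- matrix(0L, 0, nsamp)
  }
  rownames(transcripts) <- NULL
  dimnames(counts) <- list(transcripts$transcript_id, sample_ids)
  list(transcripts = transcripts,
       counts = count_matrix(counts, transcripts$length),
       profiles = profiles)
}

#' Assemble a transcriptome de novo
#'
#' Runs the full two-stage workflow: candidate assembly from the de Bruijn
#' graph, then full-length read-back alignment and epsilon-coverage
#' filtering. Supply one read set per sample (or a single set); per-sample
#' transcript counts feed [upper_quartile_factors()] and
#' [diff_expression()] downstream.
#'
#' @param reads a [read_set()] or (optionally named) list of read sets.
#' @param params an [assembly_params()].
#' @param constraint a [pair_constraint()] for paired-end data.
#' @param seed optional integer seed fixing the random assignment of
#'   multimapping reads.
#' @return an object of class \code{assembly}: list with \code{transcripts},
#'   \code{counts}, \code{candidates}, \code{index} (over the candidates)
#'   and \code{params}.
#' @export
assemble <- function(reads, params = assembly_params(),
                     constraint = pair_constraint(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s1 <- stage1(reads, params)
  s2 <- stage2(reads, s1$candidates, s1$index, params, constraint)
  structure(list(transcripts = s2$transcripts, counts = s2$counts,
                 candidates = s1$candidates, index = s1$index,
                 profiles = s2$profiles, params = params),
            class = "assembly")
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf(
    "<assembly> %d final transcripts from %d candidates (k=%d, alpha=%d, beta=%d, epsilon=%d)\n",
    nrow(x$transcripts), nrow(x$candidates), x$params$k, x$params$alpha,
    x$params$beta, x$params$epsilon))
  if (nrow(x$transcripts))
    cat(sprintf("  total length %d nt, median %d nt\n",
                sum(x$transcripts$length),
                as.integer(stats::median(x$transcripts$length))))
  invisible(x)
}
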