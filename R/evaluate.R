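#' Reference genes: the evaluable subset of an annotation
#'
#' A reference gene is an annotated gene whose every k-mer occurs in at
#' least one sequencing read (under the strand policy of the assembler);
#' only these genes can possibly be reconstructed de novo. Genes shorter
#' than k are excluded.
#'
#' @param genes data frame with columns \code{gene_id}, \code{strand},
#'   \code{start}, \code{end} (0-based half-open genome coordinates) and
#'   \code{sequence}.
#' @param reads a [read_set()] or character vector of read sequences.
#' @param k k-mer length (default 25).
#' @param strand_specific logical; use as-read k-mers instead of canonical.
#' @return the subset of \code{genes} that are reference genes.
#' @export
reference_genes <- function(genes, reads, k = 25, strand_specific = FALSE) {
  stopifnot(k >= 2, is.data.frame(genes), "sequence" %in% names(genes))
  seqs <- if (inherits(reads, "read_set")) reads$reads$sequence else reads
  keep <- .kmers_all_in_reads(toupper(seqs), toupper(genes$sequence),
                              as.integer(k), !strand_specific)
  genes[keep, , drop = FALSE]
}

#' Align assembled transcripts to a genome
#'
#' Two evaluation aligners are provided. \code{"exact"} reports full-length
#' exact substring matches against either genome strand — sufficient and
#' unambiguous for the delta = 1.0 metrics. \code{"permissive"} additionally
#' rescues transcripts without an exact match through seed-anchored local
#' alignment (unit-cost dynamic programming on a window around the best
#' seed diagonal), accepting alignments with at least \code{min_identity}
#' identity over at least \code{min_length} aligned columns.
#'
#' @param transcripts data frame with \code{transcript_id} and
#'   \code{sequence}, or a named character vector.
#' @param genome genome sequence (single character string).
#' @param method \code{"exact"} or \code{"permissive"}.
#' @param min_identity,min_length acceptance thresholds for the permissive
#'   aligner.
#' @return data frame with one row per alignment: \code{transcript_id},
#'   \code{t_len}, \code{aligned_length} (alignment columns),
#'   \code{perfect_matches}, \code{g_start}, \code{g_end} (0-based
#'   half-open), \code{strand}. Transcripts that do not align are absent.
#' @export
genome_alignments <- function(transcripts, genome,
                              method = c("exact", "permissive"),
                              min_identity = 0.95, min_length = 50) {
  method <- match.arg(method)
  tr <- as_transcript_df(transcripts)
  genome <- toupper(genome[[1]])
  gidx <- fm_index(c(genome = genome))
  rows <- list()
  for (i in seq_len(nrow(tr))) {
    tid <- tr$transcript_id[i]
    s <- toupper(tr$sequence[i])
    len <- nchar(s)
    hit <- FALSE
    for (strand in c("+", "-")) {
      q <- if (strand == "+") s else revcomp(s)
      loc <- fm_locate(gidx, q)
      if (nrow(loc)) {
        hit <- TRUE
        rows[[length(rows) + 1]] <- data.frame(
          transcript_id = tid, t_len = len, aligned_length = len,
          perfect_matches = len, g_start = loc$offset,
          g_end = loc$offset + len, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
    if (!hit && method == "permissive") {
      pa <- permissive_align(s, genome, gidx, min_identity, min_length)
      if (!is.null(pa)) {
        pa$transcript_id <- tid
        pa$t_len <- len
        rows[[length(rows) + 1]] <- pa
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(), t_len = integer(),
               aligned_length = integer(), perfect_matches = integer(),
               g_start = integer(), g_end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[, c("transcript_id", "t_len", "aligned_length", "perfect_matches",
          "g_start", "g_end", "strand")]
}

# seed-anchored local alignment of one transcript against a genome window
permissive_align <- function(s, genome, gidx, min_identity, min_length,
                             seed_k = 25L, seed_stride = 20L) {
  len <- nchar(s)
  best <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") s else revcomp(s)
    if (len < seed_k) next
    starts <- unique(c(seq(1L, len - seed_k + 1L, by = seed_stride),
                       len - seed_k + 1L))
    diags <- integer()
    for (b in starts) {
      loc <- fm_locate(gidx, substr(q, b, b + seed_k - 1L))
      if (nrow(loc) && nrow(loc) <= 50)
        diags <- c(diags, loc$offset - (b - 1L))
    }
    if (!length(diags)) next
    diag <- as.integer(names(sort(table(diags), decreasing = TRUE))[1])
    w0 <- max(0L, diag - 100L)
    w1 <- min(nchar(genome), diag + len + 100L)
    window <- substr(genome, w0 + 1L, w1)
    pa <- Biostrings::pairwiseAlignment(
      q, window, type = "local",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = TRUE),
      gapOpening = 1, gapExtension = 1)
    cols <- nchar(as.character(Biostrings::alignedPattern(pa)))
    pm <- Biostrings::nmatch(pa)
    if (cols >= min_length && pm / cols >= min_identity) {
      cand <- data.frame(
        aligned_length = cols, perfect_matches = pm,
        g_start = w0 + Biostrings::start(Biostrings::subject(pa)) - 1L,
        g_end = w0 + Biostrings::end(Biostrings::subject(pa)),
        strand = strand, stringsAsFactors = FALSE)
      if (is.null(best) || cand$perfect_matches > best$perfect_matches)
        best <- cand
    }
  }
  best
}

as_transcript_df <- function(transcripts) {
  if (inherits(transcripts, "assembly")) return(transcripts$transcripts)
  if (is.character(transcripts))
    return(data.frame(transcript_id = names2(transcripts),
                      sequence = unname(transcripts),
                      stringsAsFactors = FALSE))
  stopifnot(is.data.frame(transcripts),
            all(c("transcript_id", "sequence") %in% names(transcripts)))
  transcripts
}

#' Assembly specificity
#'
#' Fraction of assembled transcripts whose alignment covers at least
#' \code{delta} of their length (delta = 1.0 by default: the transcript
#' aligns full-length). One minus the false-positive rate.
#'
#' @param transcripts transcripts (data frame, named character vector, or
#'   an \code{assembly}).
#' @param genome genome sequence.
#' @param delta alignment-fraction threshold in \code{(0, 1]}.
#' @param alignments optional precomputed [genome_alignments()].
#' @return fraction in \code{[0, 1]}; \code{NaN} with a warning when there
#'   are no transcripts.
#' @export
specificity <- function(transcripts, genome, delta = 1,
                        alignments = NULL) {
  stopifnot(delta > 0, delta <= 1)
  tr <- as_transcript_df(transcripts)
  if (nrow(tr) == 0L) {
    warning("specificity is undefined for an empty transcript set")
    return(NaN)
  }
  if (is.null(alignments))
    alignments <- genome_alignments(tr, genome,
                                    method = if (delta >= 1) "exact" else
                                      "permissive")
  frac <- vapply(tr$transcript_id, function(tid) {
    a <- alignments[alignments$transcript_id == tid, , drop = FALSE]
    if (nrow(a) == 0L) 0 else max(a$aligned_length / a$t_len)
  }, numeric(1))
  mean(frac >= delta)
}

gene_coverage <- function(genes, alignments) {
  # per-gene covered base count (by any alignment) and best-single-transcript
  # covered base count
  al <- IRanges::IRanges(start = alignments$g_start + 1L,
                         end = alignments$g_end)
  vapply(seq_len(nrow(genes)), function(i) {
    gi <- IRanges::IRanges(genes$start[i] + 1L, genes$end[i])
    if (length(al) == 0L) return(c(0, 0))
    cov_all <- sum(IRanges::width(IRanges::reduce(
      IRanges::restrict(al, IRanges::start(gi), IRanges::end(gi)))))
    hits <- IRanges::findOverlaps(al, gi)
    if (length(hits) == 0L) return(c(cov_all, 0))
    idx <- S4Vectors::queryHits(hits)
    per_tr <- tapply(
      IRanges::width(IRanges::pintersect(al[idx], rep(gi, length(idx)))),
      alignments$transcript_id[idx], sum)
    c(cov_all, max(per_tr))
  }, numeric(2))
}

#' Assembly sensitivity
#'
#' Fraction of reference-gene sequence covered by aligned transcripts:
#' \eqn{\sum_g |g^T| / \sum_g |g|}. With \code{genome_wide = TRUE} the
#' genome-wide variant \eqn{|G^T|/|G|} is computed instead (appropriate for
#' DNA-seq assemblies).
#'
#' @param transcripts transcripts.
#' @param reference reference gene data frame (see [reference_genes()]).
#' @param genome genome sequence.
#' @param genome_wide logical; cover the whole genome instead of genes.
#' @param alignments optional precomputed [genome_alignments()].
#' @return fraction in \code{[0, 1]}.
#' @export
sensitivity <- function(transcripts, reference, genome,
                        genome_wide = FALSE, alignments = NULL) {
  if (is.null(alignments))
    alignments <- genome_alignments(transcripts, genome, method = "exact")
  if (genome_wide) {
    glen <- nchar(genome[[1]])
    cov <- sum(IRanges::width(IRanges::reduce(IRanges::restrict(
      IRanges::IRanges(alignments$g_start + 1L, alignments$g_end),
      1L, glen))))
    return(cov / glen)
  }
  if (is.null(reference) || nrow(reference) == 0L)
    stop_dn("sensitivity requires a non-empty reference gene set",
            class = "denovotx_validation_error")
  cv <- gene_coverage(reference, alignments)
  sum(cv[1, ]) / sum(reference$end - reference$start)
}

#' Assembly contiguity
#'
#' Fraction of reference genes at least \code{delta} (default 0.8) covered
#' by their single best-covering assembled transcript.
#'
#' @inheritParams sensitivity
#' @param delta coverage threshold in \code{(0, 1]}.
#' @return fraction in \code{[0, 1]}.
#' @export
contiguity <- function(transcripts, reference, genome, delta = 0.8,
                       alignments = NULL) {
  stopifnot(delta > 0, delta <= 1)
  if (is.null(reference) || nrow(reference) == 0L)
    stop_dn("contiguity requires a non-empty reference gene set",
            class = "denovotx_validation_error")
  if (is.null(alignments))
    alignments <- genome_alignments(transcripts, genome, method = "exact")
  cv <- gene_coverage(reference, alignments)
  mean(cv[2, ] / (reference$end - reference$start) >= delta)
}

#' Reads mapping back to transcripts (RMBT)
#'
#' Fraction of sequencing reads that align full-length to some assembled
#' transcript (the delta = 1.0 criterion; alignment is full-length or
#' nothing).
#'
#' @param reads a [read_set()] or character vector of read sequences.
#' @param transcripts transcripts.
#' @param max_mismatches mismatches tolerated in the full-length alignment.
#' @param index optional prebuilt [fm_index()] over the transcripts.
#' @return fraction in \code{[0, 1]}.
#' @export
rmbt <- function(reads, transcripts, max_mismatches = 0, index = NULL) {
  seqs <- if (inherits(reads, "read_set")) reads$reads$sequence else reads
  if (length(seqs) == 0L)
    stop_dn("RMBT requires a non-empty read set",
            class = "denovotx_validation_error")
  tr <- as_transcript_df(transcripts)
  if (nrow(tr) == 0L) return(0)
  if (is.null(index))
    index <- fm_index(setNames(tr$sequence, tr$transcript_id))
  aln <- fm_align(index, seqs, both_strands = TRUE,
                  max_mismatches = max_mismatches)
  length(unique(aln$query)) / length(seqs)
}

#' Assembly base-level accuracy
#'
#' For the transcripts that align to the genome, the fraction of alignment
#' columns that are perfect matches (as opposed to mismatches or gaps):
#' \eqn{\sum_t PM(a_G^t) / \sum_t |a_G^t|}. Each transcript contributes its
#' best alignment. The permissive aligner is used so that near-perfect
#' transcripts contribute their mismatch positions.
#'
#' @param transcripts transcripts.
#' @param genome genome sequence.
#' @param alignments optional precomputed [genome_alignments()].
#' @return fraction in \code{[0, 1]}; \code{NaN} with a warning when no
#'   transcript aligns.
#' @export
accuracy <- function(transcripts, genome, alignments = NULL) {
  if (is.null(alignments))
    alignments <- genome_alignments(transcripts, genome,
                                    method = "permissive")
  if (nrow(alignments) == 0L) {
    warning("accuracy is undefined: no transcript aligns to the genome")
    return(NaN)
  }
  best <- do.call(rbind, lapply(split(alignments,
                                      alignments$transcript_id),
                                function(a) {
    a[order(-a$aligned_length, -a$perfect_matches)[1], , drop = FALSE]
  }))
  sum(best$perfect_matches) / sum(best$aligned_length)
}

#' Sensitivity and contiguity by expression decile
#'
#' Reference genes are sorted by expression and split into 10 equal-size
#' groups (any remainder goes to the highest deciles; expression ties break
#' by gene id); sensitivity and contiguity are computed per group under the
#' permissive aligner, mirroring the dependence of assembly quality on
#' expression level.
#'
#' @param transcripts transcripts.
#' @param reference reference gene data frame.
#' @param expression named numeric vector of per-gene expression (names are
#'   gene ids; every reference gene must be present).
#' @param genome genome sequence.
#' @param delta contiguity threshold (default 0.8).
#' @return data frame with columns \code{decile}, \code{n_genes},
#'   \code{sensitivity}, \code{contiguity}.
#' @export
decile_performance <- function(transcripts, reference, expression, genome,
                               delta = 0.8) {
  n <- nrow(reference)
  if (n < 10)
    stop_dn("decile analysis requires at least 10 reference genes, found %d",
            n, class = "denovotx_validation_error")
  if (!all(reference$gene_id %in% names(expression)))
    stop_dn("expression must be defined for every reference gene",
            class = "denovotx_validation_error")
  ex <- expression[reference$gene_id]
  ord <- order(ex, reference$gene_id)
  base <- n %/% 10L; r <- n %% 10L
  sizes <- c(rep(base, 10L - r), rep(base + 1L, r))
  grp <- rep(seq_len(10L), times = sizes)
  alignments <- genome_alignments(transcripts, genome,
                                  method = "permissive")
  out <- lapply(seq_len(10L), function(d) {
    sub <- reference[ord[grp == d], , drop = FALSE]
    data.frame(decile = d, n_genes = nrow(sub),
               sensitivity = sensitivity(transcripts, sub, genome,
                                         alignments = alignments),
               contiguity = contiguity(transcripts, sub, genome, delta,
                                       alignments = alignments))
  })
  do.call(rbind, out)
}

#' Evaluate an assembly against an annotated genome
#'
#' Computes all five evaluation metrics in one pass: specificity and
#' accuracy from transcript-to-genome alignments, sensitivity and
#' contiguity over the reference genes (the annotated genes whose every
#' k-mer occurs in the reads), and RMBT from read-to-transcript alignment.
#'
#' @param transcripts transcripts (or an \code{assembly}).
#' @param genome genome sequence.
#' @param genes annotated gene data frame.
#' @param reads the sequencing reads used for the assembly.
#' @param k k-mer length used for the reference-gene definition.
#' @param max_mismatches mismatches tolerated in the RMBT alignment.
#' @return object of class \code{evaluation_report}.
#' @export
evaluate_assembly <- function(transcripts, genome, genes, reads, k = 25,
                              max_mismatches = 0) {
  tr <- as_transcript_df(transcripts)
  ref <- reference_genes(genes, reads, k = k)
  aln_exact <- genome_alignments(tr, genome, method = "exact")
  aln_perm <- genome_alignments(tr, genome, method = "permissive")
  structure(list(
    specificity = specificity(tr, genome, delta = 1,
                              alignments = aln_exact),
    sensitivity = if (nrow(ref)) sensitivity(tr, ref, genome,
                                             alignments = aln_exact) else
      NaN,
    contiguity = if (nrow(ref)) contiguity(tr, ref, genome,
                                           alignments = aln_exact) else NaN,
    rmbt = rmbt(reads, tr, max_mismatches = max_mismatches),
    accuracy = accuracy(tr, genome, alignments = aln_perm),
    n_transcripts = nrow(tr), n_reference_genes = nrow(ref),
    reference = ref), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  transcripts:      %d\n", x$n_transcripts))
  cat(sprintf("  reference genes:  %d\n", x$n_reference_genes))
  for (m in c("specificity", "sensitivity", "contiguity", "rmbt",
              "accuracy"))
    cat(sprintf("  %-12s %.4f\n", paste0(m, ":"), x[[m]]))
  invisible(x)
}
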