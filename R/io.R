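#' Construct a read set
#'
#' A read set is the in-memory container for sequencing reads: a data frame
#' of records plus flags describing the library (paired or single-end,
#' strand-specific or strand-ambiguous).
#'
#' @param reads data frame with columns \code{read_id}, \code{sequence},
#'   \code{quality} (NA when absent) and \code{mate_role} (one of
#'   \code{"unpaired"}, \code{"mate1"}, \code{"mate2"}).
#' @param paired logical; are the reads paired-end? Paired sets interleave
#'   mate1/mate2 records.
#' @param strand_specific logical; was the library strand-specific?
#' @param source character vector of originating file paths, if any.
#' @return an object of class \code{read_set}.
#' @export
read_set <- function(reads, paired = FALSE, strand_specific = FALSE,
                     source = character()) {
  stopifnot(is.data.frame(reads),
            all(c("read_id", "sequence", "quality", "mate_role") %in%
                  names(reads)))
  reads$sequence <- toupper(reads$sequence)
  bad <- grepl("[^ACGTN]", reads$sequence)
  if (any(bad))
    stop_dn("read %s contains symbols outside {A,C,G,T,N}",
            reads$read_id[which(bad)[1]], class = "denovotx_parse_error")
  qlen_bad <- !is.na(reads$quality) &
    nchar(reads$quality) != nchar(reads$sequence)
  if (any(qlen_bad))
    stop_dn("read %s: quality length differs from sequence length",
            reads$read_id[which(qlen_bad)[1]], class = "denovotx_parse_error")
  if (paired) {
    n1 <- sum(reads$mate_role == "mate1")
    n2 <- sum(reads$mate_role == "mate2")
    if (n1 != n2)
      stop_dn("paired read set has %d mate1 but %d mate2 records", n1, n2,
              class = "denovotx_pairing_error")
  }
  structure(list(reads = reads, paired = paired,
                 strand_specific = strand_specific, source = source),
            class = "read_set")
}

#' @export
length.read_set <- function(x) nrow(x$reads)

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("<read_set> %d reads (%s, %s)\n", nrow(x$reads),
              if (x$paired) "paired-end" else "single-end",
              if (x$strand_specific) "strand-specific" else
                "strand-ambiguous"))
  invisible(x)
}

is_gzipped <- function(path) {
  magic <- readBin(path, "raw", n = 2L)
  length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

read_all_lines <- function(path) {
  con <- if (is_gzipped(path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

# content-based format detection: '@' opens FASTQ unless it is a SAM header
# tag; '>' opens FASTA; otherwise tab-delimited layouts are probed (SAM has
# >= 11 fields with an integer FLAG and a CIGAR-shaped field 6, QSEQ has
# exactly 11 fields with the sequence in field 9)
detect_format <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return("empty")
  first <- lines[1]
  if (grepl("^@(HD|SQ|RG|PG|CO)\t", first)) return("sam")
  c1 <- substr(first, 1, 1)
  if (c1 == "@") return("fastq")
  if (c1 == ">") return("fasta")
  f <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (length(f) >= 11 && grepl("^[0-9]+$", f[2]) &&
      grepl("^(\\*|[0-9MIDNSHP=X]+)$", f[6]) &&
      grepl("^[ACGTNacgtn.=*]+$", f[10]))
    return("sam")
  if (length(f) == 11 && grepl("^[ACGTNacgtn.]+$", f[9]))
    return("qseq")
  "unknown"
}

parse_fastq <- function(lines) {
  keep <- nzchar(lines)
  # FASTQ is strictly 4 lines per record; trailing blank lines tolerated
  lines <- lines[seq_len(max(which(keep), 0L))]
  n <- length(lines)
  if (n %% 4 != 0)
    stop_dn("truncated FASTQ record starting at line %d", (n %/% 4) * 4 + 1,
            class = "denovotx_parse_error")
  if (n == 0L) return(empty_reads())
  i <- seq(1, n, by = 4)
  bad_at <- !startsWith(lines[i], "@")
  if (any(bad_at))
    stop_dn("FASTQ parse error at line %d: record does not start with '@'",
            i[which(bad_at)[1]], class = "denovotx_parse_error")
  bad_plus <- !startsWith(lines[i + 2], "+")
  if (any(bad_plus))
    stop_dn("FASTQ parse error at line %d: expected '+' separator",
            i[which(bad_plus)[1]] + 2, class = "denovotx_parse_error")
  seqs <- lines[i + 1]
  quals <- lines[i + 3]
  mismatch <- nchar(seqs) != nchar(quals)
  if (any(mismatch))
    stop_dn("FASTQ parse error at line %d: quality length (%d) differs from sequence length (%d)",
            i[which(mismatch)[1]] + 3, nchar(quals[which(mismatch)[1]]),
            nchar(seqs[which(mismatch)[1]]),
            class = "denovotx_parse_error")
  ids <- sub("\\s.*$", "", substring(lines[i], 2))
  data.frame(read_id = ids, sequence = seqs, quality = quals,
             mate_role = "unpaired", stringsAsFactors = FALSE)
}

parse_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(dss))
  data.frame(read_id = ids, sequence = as.character(dss, use.names = FALSE),
             quality = NA_character_, mate_role = "unpaired",
             stringsAsFactors = FALSE)
}

parse_qseq <- function(lines) {
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_reads())
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf != 11))
    stop_dn("QSEQ parse error at line %d: expected 11 tab-separated fields, found %d",
            which(nf != 11)[1], nf[which(nf != 11)[1]],
            class = "denovotx_parse_error")
  m <- do.call(rbind, f)
  ids <- apply(m[, 1:8, drop = FALSE], 1, paste, collapse = ":")
  seqs <- chartr(".", "N", m[, 9])
  data.frame(read_id = ids, sequence = seqs, quality = m[, 10],
             mate_role = "unpaired", stringsAsFactors = FALSE)
}

parse_sam <- function(lines) {
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (length(lines) == 0L) return(empty_reads())
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11))
    stop_dn("SAM parse error at line %d: fewer than 11 fields",
            which(nf < 11)[1], class = "denovotx_parse_error")
  ids <- vapply(f, `[`, character(1), 1)
  seqs <- vapply(f, `[`, character(1), 10)
  quals <- vapply(f, `[`, character(1), 11)
  keep <- seqs != "*"   # unaligned placeholder records carry no sequence
  data.frame(read_id = ids[keep], sequence = seqs[keep],
             quality = ifelse(quals[keep] == "*", NA_character_,
                              quals[keep]),
             mate_role = "unpaired", stringsAsFactors = FALSE)
}

empty_reads <- function() {
  data.frame(read_id = character(), sequence = character(),
             quality = character(), mate_role = character(),
             stringsAsFactors = FALSE)
}

#' Read sequencing reads from FASTQ, QSEQ, FASTA or SAM files
#'
#' Parses one file of sequencing reads into a [read_set()]. The format is
#' auto-detected from the file content unless \code{format} is given, and
#' gzip compression is detected from the magic bytes for FASTQ, QSEQ and
#' FASTA. SAM records contribute only their read identifier, sequence and
#' quality; all alignment fields are ignored. Lowercase bases are uppercased;
#' \code{N} bases are preserved (they are excluded later, at k-mer
#' extraction). Qualities are assumed Phred+33.
#'
#' @param path path to the input file.
#' @param format optional format hint: one of \code{"fastq"}, \code{"qseq"},
#'   \code{"fasta"}, \code{"sam"}.
#' @param strand_specific logical flag recorded on the returned set.
#' @return a [read_set()].
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ACGTACGT", ">r2", "TTTTGGGG"), fa)
#' rs <- read_sequences(fa)
#' length(rs)
read_sequences <- function(path, format = NULL, strand_specific = FALSE) {
  if (!file.exists(path))
    stop_dn("cannot read '%s': no such file", path,
            class = "denovotx_io_error")
  lines <- read_all_lines(path)
  fmt <- if (is.null(format)) detect_format(lines) else
    match.arg(tolower(format), c("fastq", "qseq", "fasta", "sam"))
  reads <- switch(fmt,
    fastq = parse_fastq(lines),
    fasta = parse_fasta(path),
    qseq  = parse_qseq(lines),
    sam   = parse_sam(lines),
    empty = empty_reads(),
    stop_dn("unrecognized sequence format in '%s'", path,
            class = "denovotx_format_error"))
  read_set(reads, paired = FALSE, strand_specific = strand_specific,
           source = path)
}

strip_mate_suffix <- function(ids) {
  sub("[/_.][12]$", "", sub("\\s.*$", "", ids))
}

#' Pair two read sets into one paired-end set
#'
#' Mate files are matched record-by-record; identifiers must agree after
#' stripping conventional mate suffixes (\code{/1}, \code{/2}, \code{_1},
#' \code{_2}). The result interleaves mate1/mate2 records, preserving the
#' input order.
#'
#' @param set1,set2 [read_set()] objects holding mate 1 and mate 2 reads.
#' @return a paired [read_set()].
#' @export
pair_reads <- function(set1, set2) {
  stopifnot(inherits(set1, "read_set"), inherits(set2, "read_set"))
  n1 <- nrow(set1$reads); n2 <- nrow(set2$reads)
  if (n1 != n2)
    stop_dn("cannot pair read sets of unequal size (%d vs %d)", n1, n2,
            class = "denovotx_pairing_error")
  id1 <- strip_mate_suffix(set1$reads$read_id)
  id2 <- strip_mate_suffix(set2$reads$read_id)
  bad <- id1 != id2
  if (any(bad))
    stop_dn("unpairable read identifiers at record %d: '%s' vs '%s'",
            which(bad)[1], set1$reads$read_id[which(bad)[1]],
            set2$reads$read_id[which(bad)[1]],
            class = "denovotx_pairing_error")
  r1 <- set1$reads; r2 <- set2$reads
  r1$mate_role <- rep("mate1", n1)
  r2$mate_role <- rep("mate2", n2)
  idx <- rep(seq_len(max(n1, 0L)), each = 2) +
    rep(c(0L, n1), times = n1)
  merged <- rbind(r1, r2)[idx, , drop = FALSE]
  rownames(merged) <- NULL
  read_set(merged, paired = TRUE,
           strand_specific = set1$strand_specific,
           source = c(set1$source, set2$source))
}

#' Write assembled transcripts as FASTA
#'
#' One record per transcript, 70-column wrapped; the description line carries
#' the transcript length and, when available, the mean read coverage.
#'
#' @param transcripts data frame with columns \code{transcript_id},
#'   \code{sequence}, and optionally \code{mean_coverage}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_transcripts <- function(transcripts, path) {
  stopifnot(is.data.frame(transcripts),
            all(c("transcript_id", "sequence") %in% names(transcripts)))
  if (anyDuplicated(transcripts$transcript_id))
    stop_dn("duplicate transcript id '%s'",
            transcripts$transcript_id[duplicated(transcripts$transcript_id)][1],
            class = "denovotx_validation_error")
  if (nrow(transcripts) > 0 && any(!nzchar(transcripts$sequence)))
    stop_dn("empty transcript sequence", class = "denovotx_validation_error")
  dss <- Biostrings::DNAStringSet(transcripts$sequence)
  desc <- sprintf("%s length=%d", transcripts$transcript_id,
                  nchar(transcripts$sequence))
  if ("mean_coverage" %in% names(transcripts))
    desc <- sprintf("%s meanCov=%.1f", desc, transcripts$mean_coverage)
  names(dss) <- desc
  Biostrings::writeXStringSet(dss, path, width = 70L)
  invisible(path)
}
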