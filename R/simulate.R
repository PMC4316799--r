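#' Configuration for synthetic RNA-seq data
#'
#' The generator emulates a bacterial RNA-seq experiment at desk scale: a
#' random genome, non-overlapping transcripts on random strands with
#' per-transcript expression (target read coverage) drawn log-uniformly,
#' and uniformly positioned reads with independent per-base substitution
#' errors. Defaults follow the short-read regime the assembler targets
#' (100-nt reads, coverage spanning 50-200x).
#'
#' @param genome_length genome length (nt, >= 1000).
#' @param n_transcripts number of transcripts to place.
#' @param length_range transcript length range (nt).
#' @param coverage_range per-transcript coverage range; coverage is drawn
#'   log-uniformly over it.
#' @param read_length read length (nt).
#' @param error_rate per-base substitution probability (< 0.1; no indels).
#' @param paired logical; generate inward-oriented mate pairs.
#' @param insert_mean,insert_sd fragment-length distribution for pairs (nt).
#' @param strand_specific logical; reads always sequence the sense strand.
#' @param seed integer seed; every stage is reproducible given it.
#' @return an object of class \code{simulation_config}.
#' @export
simulation_config <- function(genome_length = 200000, n_transcripts = 50,
                              length_range = c(500, 2000),
                              coverage_range = c(50, 200),
                              read_length = 100, error_rate = 0,
                              paired = FALSE, insert_mean = 300,
                              insert_sd = 30, strand_specific = FALSE,
                              seed = 1) {
  stopifnot(genome_length >= 1000, n_transcripts >= 0,
            length_range[1] >= 1, length_range[1] <= length_range[2],
            coverage_range[1] > 0, coverage_range[1] <= coverage_range[2],
            read_length >= 1, error_rate >= 0, error_rate < 0.1,
            insert_mean > 0, insert_sd >= 0)
  structure(list(genome_length = as.integer(genome_length),
                 n_transcripts = as.integer(n_transcripts),
                 length_range = as.integer(length_range),
                 coverage_range = as.numeric(coverage_range),
                 read_length = as.integer(read_length),
                 error_rate = error_rate, paired = paired,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 strand_specific = strand_specific,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a genome
#'
#' An i.i.d. uniform ACGT sequence of the configured length, seeded from
#' \code{config$seed}.
#'
#' @param config a [simulation_config()].
#' @return named character vector of length 1 (the genome sequence).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  c(genome = random_dna(config$genome_length))
}

#' Simulate transcripts on a genome
#'
#' Places non-overlapping intervals on random strands, with lengths uniform
#' in \code{length_range} and per-transcript target coverage log-uniform in
#' \code{coverage_range}.
#'
#' @param genome genome sequence (from [simulate_genome()]).
#' @param config a [simulation_config()].
#' @return data frame with columns \code{gene_id}, \code{strand},
#'   \code{start}, \code{end} (0-based half-open), \code{sequence},
#'   \code{coverage}.
#' @export
simulate_transcripts <- function(genome, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  genome <- genome[[1]]
  G <- nchar(genome)
  n <- config$n_transcripts
  if (n == 0L)
    return(data.frame(gene_id = character(), strand = character(),
                      start = integer(), end = integer(),
                      sequence = character(), coverage = numeric(),
                      stringsAsFactors = FALSE))
  lens <- sample(seq(config$length_range[1], config$length_range[2]), n,
                 replace = TRUE)
  placed_s <- integer(); placed_e <- integer()
  starts <- integer(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(1000L)) {
      s0 <- sample.int(G - lens[i] + 1L, 1L) - 1L
      e0 <- s0 + lens[i]
      if (!any(s0 < placed_e & e0 > placed_s)) { ok <- TRUE; break }
    }
    if (!ok)
      stop_dn("could not place %d non-overlapping transcripts in a %d-nt genome; increase genome_length",
              n, G, class = "denovotx_validation_error")
    starts[i] <- s0
    placed_s <- c(placed_s, s0); placed_e <- c(placed_e, e0)
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- substring(genome, starts + 1L, starts + lens)
  seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
  cr <- config$coverage_range
  coverage <- if (cr[1] == cr[2]) rep(cr[1], n) else
    exp(runif(n, log(cr[1]), log(cr[2])))
  data.frame(gene_id = sprintf("gene_%03d", seq_len(n)), strand = strand,
             start = starts, end = starts + lens, sequence = seqs,
             coverage = coverage, stringsAsFactors = FALSE)
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  hit <- which(runif(total) < rate)
  if (!length(hit)) return(seqs)
  ends <- cumsum(lens)
  read_of <- findInterval(hit - 1L, ends) + 1L
  pos <- hit - c(0L, ends)[read_of]
  bases <- c("A", "C", "G", "T")
  for (j in seq_along(hit)) {
    r <- read_of[j]; p <- pos[j]
    old <- substr(seqs[r], p, p)
    substr(seqs[r], p, p) <- sample(setdiff(bases, old), 1L)
  }
  seqs
}

#' Simulate sequencing reads from transcripts
#'
#' Reads (or inward-oriented mate pairs with truncated-normal fragment
#' lengths) are positioned uniformly along each transcript to reach its
#' target coverage (\code{coverage = reads x read_length / transcript
#' length}); substitution errors are injected at \code{error_rate}. For
#' strand-ambiguous data each read sequences either strand with equal
#' probability. Read identifiers record the provenance
#' (\code{gene:position:strand}).
#'
#' @param transcripts data frame from [simulate_transcripts()].
#' @param config a [simulation_config()].
#' @return a [read_set()] (paired and interleaved when
#'   \code{config$paired}).
#' @export
simulate_reads <- function(transcripts, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  m <- config$read_length
  if (nrow(transcripts) && any(nchar(transcripts$sequence) < m))
    stop_dn("read_length exceeds the shortest transcript",
            class = "denovotx_validation_error")
  ids <- character(); seqs <- character(); roles <- character()
  for (i in seq_len(nrow(transcripts))) {
    tseq <- transcripts$sequence[i]
    L <- nchar(tseq)
    if (config$paired) {
      npair <- max(1L, as.integer(round(
        transcripts$coverage[i] * L / (2 * m))))
      frag <- pmin(pmax(as.integer(round(
        rnorm(npair, config$insert_mean, config$insert_sd))), m), L)
      fstart <- vapply(frag, function(f) sample.int(L - f + 1L, 1L),
                       integer(1))
      sense1 <- substr_vec(tseq, fstart, fstart + m - 1L)
      sense2 <- revcomp(substr_vec(tseq, fstart + frag - m,
                                   fstart + frag - 1L))
      flip <- if (config$strand_specific) rep(FALSE, npair) else
        runif(npair) < 0.5
      r1 <- ifelse(flip, sense2, sense1)
      r2 <- ifelse(flip, sense1, sense2)
      base <- sprintf("%s:%d:%s", transcripts$gene_id[i], fstart - 1L,
                      ifelse(flip, "-", "+"))
      ids <- c(ids, as.vector(rbind(paste0(base, "/1"),
                                    paste0(base, "/2"))))
      seqs <- c(seqs, as.vector(rbind(r1, r2)))
      roles <- c(roles, rep(c("mate1", "mate2"), npair))
    } else {
      nread <- max(1L, as.integer(round(transcripts$coverage[i] * L / m)))
      rstart <- sample.int(L - m + 1L, nread, replace = TRUE)
      rs <- substr_vec(tseq, rstart, rstart + m - 1L)
      flip <- if (config$strand_specific) rep(FALSE, nread) else
        runif(nread) < 0.5
      rs[flip] <- revcomp(rs[flip])
      ids <- c(ids, sprintf("%s:%d:%s", transcripts$gene_id[i],
                            rstart - 1L, ifelse(flip, "-", "+")))
      seqs <- c(seqs, rs)
      roles <- c(roles, rep("unpaired", nread))
    }
  }
  seqs <- inject_errors(seqs, config$error_rate)
  read_set(data.frame(read_id = ids, sequence = seqs,
                      quality = strrep("I", nchar(seqs)),
                      mate_role = roles, stringsAsFactors = FALSE),
           paired = config$paired,
           strand_specific = config$strand_specific,
           source = "simulated")
}

substr_vec <- function(s, start, stop) {
  substring(s, start, stop)
}

#' Simulate a complete synthetic dataset
#'
#' Genome, transcripts and reads in one call; optionally written to
#' \code{out_dir} as \code{genome.fasta}, \code{genes.gff},
#' \code{truth.tsv} and gzipped FASTQ read files.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional output directory.
#' @return list with \code{genome}, \code{transcripts} (the ground truth,
#'   including true coverages) and \code{reads} (a [read_set()]).
#' @export
#' @examples
#' sim <- simulate_dataset(simulation_config(genome_length = 20000,
#'   n_transcripts = 3, length_range = c(300, 500), seed = 7))
#' nrow(sim$transcripts)
simulate_dataset <- function(config = simulation_config(), out_dir = NULL) {
  genome <- simulate_genome(config)
  transcripts <- simulate_transcripts(genome, config)
  reads <- simulate_reads(transcripts, config)
  out <- list(genome = genome, transcripts = transcripts, reads = reads)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    gs <- Biostrings::DNAStringSet(setNames(genome[[1]], "genome"))
    Biostrings::writeXStringSet(gs, file.path(out_dir, "genome.fasta"),
                                width = 70L)
    write_gff3(transcripts, file.path(out_dir, "genes.gff"))
    utils::write.table(
      transcripts[, c("gene_id", "strand", "start", "end", "coverage")],
      file.path(out_dir, "truth.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_fastq(reads, out_dir)
  }
  out
}

write_gff3 <- function(transcripts, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(transcripts))
    writeLines(sprintf(
      "genome\tdenovotx\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
      transcripts$start + 1L, transcripts$end, transcripts$strand,
      transcripts$gene_id), con)
  invisible(path)
}

write_fastq <- function(reads, out_dir) {
  fq <- function(df, path) {
    con <- gzfile(path, "wt")
    on.exit(close(con))
    if (nrow(df))
      writeLines(as.vector(rbind(paste0("@", df$read_id), df$sequence,
                                 "+", df$quality)), con)
  }
  if (reads$paired) {
    fq(reads$reads[reads$reads$mate_role == "mate1", ],
       file.path(out_dir, "reads_1.fastq.gz"))
    fq(reads$reads[reads$reads$mate_role == "mate2", ],
       file.path(out_dir, "reads_2.fastq.gz"))
  } else {
    fq(reads$reads, file.path(out_dir, "reads.fastq.gz"))
  }
  invisible(out_dir)
}

#' Read gene annotations from GFF3 or BED
#'
#' Thin wrapper over \pkg{rtracklayer} returning the gene data frame used
#' by the evaluation functions (0-based half-open coordinates, sequences
#' extracted from the genome, minus-strand genes reverse-complemented).
#'
#' @param path GFF3 or BED file.
#' @param genome genome sequence.
#' @return gene data frame.
#' @export
read_genes <- function(path, genome) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_dn("reading annotations requires the rtracklayer package",
            class = "denovotx_io_error")
  df <- as.data.frame(rtracklayer::import(path))
  if ("type" %in% names(df)) df <- df[df$type == "gene", , drop = FALSE]
  ids <- if ("ID" %in% names(df)) df$ID else if ("name" %in% names(df))
    df$name else sprintf("gene_%03d", seq_len(nrow(df)))
  start0 <- df$start - 1L
  end0 <- df$end
  seqs <- substring(genome[[1]], start0 + 1L, end0)
  minus <- as.character(df$strand) == "-"
  seqs[minus] <- revcomp(seqs[minus])
  data.frame(gene_id = as.character(ids), strand = as.character(df$strand),
             start = start0, end = end0, sequence = seqs,
             coverage = NA_real_, stringsAsFactors = FALSE)
}
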