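test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- simulation_config(genome_length = 20000, n_transcripts = 4,
                           length_range = c(300, 600),
                           coverage_range = c(40, 80), seed = 5)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$reads$reads, b$reads$reads)

  cfg2 <- simulation_config(genome_length = 20000, n_transcripts = 4,
                            length_range = c(300, 600),
                            coverage_range = c(40, 80), seed = 6)
  expect_false(identical(simulate_dataset(cfg2)$genome, a$genome))
})

test_that("the simulated genome has near-uniform base composition", {
  cfg <- simulation_config(genome_length = 100000, seed = 9)
  g <- simulate_genome(cfg)
  tab <- table(strsplit(g[[1]], "")[[1]])
  expect_setequal(names(tab), c("A", "C", "G", "T"))
  expect_true(all(abs(tab / 100000 - 0.25) < 0.02))
})

test_that("transcripts are placed without overlap, with recorded coverage", {
  cfg <- simulation_config(genome_length = 200000, n_transcripts = 50,
                           length_range = c(500, 2000),
                           coverage_range = c(50, 50), seed = 13)
  g <- simulate_genome(cfg)
  tr <- simulate_transcripts(g, cfg)
  expect_equal(nrow(tr), 50L)
  o <- tr[order(tr$start), ]
  expect_true(all(o$start[-1] >= o$end[-nrow(o)]))    # pairwise disjoint
  expect_true(all(tr$coverage == 50))
  # sequences match coordinates and strand
  fwd <- substring(g[[1]], tr$start + 1, tr$end)
  expect_equal(tr$sequence,
               ifelse(tr$strand == "+", fwd, revcomp(fwd)))

  cfg0 <- simulation_config(genome_length = 20000, n_transcripts = 0,
                            seed = 13)
  expect_equal(nrow(simulate_transcripts(g, cfg0)), 0L)
  # impossible placements fail with guidance
  tight <- simulation_config(genome_length = 1000, n_transcripts = 10,
                             length_range = c(400, 500), seed = 13)
  expect_error(simulate_transcripts(simulate_genome(tight), tight),
               "genome_length", class = "denovotx_validation_error")
})

test_that("error-free reads are exact transcript substrings at target coverage", {
  cfg <- simulation_config(genome_length = 50000, n_transcripts = 6,
                           length_range = c(600, 1200),
                           coverage_range = c(50, 50), read_length = 100,
                           error_rate = 0, seed = 21)
  sim <- simulate_dataset(cfg)
  reads <- sim$reads$reads
  prov <- strsplit(reads$read_id, ":")
  src <- match(vapply(prov, `[`, character(1), 1), sim$transcripts$gene_id)
  pos <- as.integer(vapply(prov, `[`, character(1), 2))
  strand <- vapply(prov, `[`, character(1), 3)
  truth <- substring(sim$transcripts$sequence[src], pos + 1, pos + 100)
  truth[strand == "-"] <- revcomp(truth[strand == "-"])
  expect_equal(reads$sequence, truth)

  # realized interior depth is close to the nominal coverage
  t1 <- sim$transcripts[1, ]
  r1 <- reads[src == 1, ]
  depth <- as.integer(IRanges::coverage(
    IRanges::IRanges(pos[src == 1] + 1L, width = 100L),
    width = nchar(t1$sequence)))
  interior <- depth[150:(nchar(t1$sequence) - 150)]
  expect_lt(abs(mean(interior) / 50 - 1), 0.25)
})

test_that("substitution errors appear at the configured rate", {
  cfg <- simulation_config(genome_length = 50000, n_transcripts = 6,
                           length_range = c(600, 1200),
                           coverage_range = c(60, 60), read_length = 100,
                           error_rate = 0.01, seed = 23)
  sim <- simulate_dataset(cfg)
  reads <- sim$reads$reads
  prov <- strsplit(reads$read_id, ":")
  src <- match(vapply(prov, `[`, character(1), 1), sim$transcripts$gene_id)
  pos <- as.integer(vapply(prov, `[`, character(1), 2))
  strand <- vapply(prov, `[`, character(1), 3)
  truth <- substring(sim$transcripts$sequence[src], pos + 1, pos + 100)
  truth[strand == "-"] <- revcomp(truth[strand == "-"])
  nbases <- sum(nchar(truth))
  mism <- sum(vapply(seq_along(truth), function(i)
    sum(utf8ToInt(reads$sequence[i]) != utf8ToInt(truth[i])), numeric(1)))
  expect_gt(nbases, 1e5)
  expect_lt(abs(mism / nbases - 0.01), 0.002)
})

test_that("simulated mate pairs are scaffold-consistent by construction", {
  cfg <- simulation_config(genome_length = 40000, n_transcripts = 4,
                           length_range = c(800, 1200),
                           coverage_range = c(40, 40), paired = TRUE,
                           insert_mean = 300, insert_sd = 30, seed = 29)
  sim <- simulate_dataset(cfg)
  reads <- sim$reads$reads
  expect_true(sim$reads$paired)
  m1 <- reads[reads$mate_role == "mate1", ]
  m2 <- reads[reads$mate_role == "mate2", ]
  expect_equal(nrow(m1), nrow(m2))
  idx <- fm_index(setNames(sim$transcripts$sequence,
                           sim$transcripts$gene_id))
  con <- pair_constraint(max(1, 300 - 4 * 30), 300 + 4 * 30)
  bad <- 0L
  for (i in seq_len(nrow(m1))) {
    a1 <- fm_align(idx, m1$sequence[i], max_mismatches = 0)[1, ]
    a2 <- fm_align(idx, m2$sequence[i], max_mismatches = 0)[1, ]
    if (!paired_consistent(a1, a2, 100, 100, con)) bad <- bad + 1L
  }
  expect_equal(bad, 0L)
})

test_that("simulated datasets write standard files", {
  cfg <- simulation_config(genome_length = 20000, n_transcripts = 3,
                           length_range = c(300, 500),
                           coverage_range = c(30, 30), seed = 31)
  out <- tempfile("simdir")
  sim <- simulate_dataset(cfg, out_dir = out)
  expect_true(all(file.exists(file.path(
    out, c("genome.fasta", "genes.gff", "truth.tsv", "reads.fastq.gz")))))
  back <- read_sequences(file.path(out, "reads.fastq.gz"))
  expect_equal(back$reads$sequence, sim$reads$reads$sequence)
  g <- read_sequences(file.path(out, "genome.fasta"))
  expect_equal(g$reads$sequence, unname(sim$genome))
  skip_if_not_installed("rtracklayer")
  genes <- read_genes(file.path(out, "genes.gff"), sim$genome)
  expect_equal(genes$start, sim$transcripts$start)
  expect_equal(genes$sequence, sim$transcripts$sequence)
})
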