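make_genes <- function(genome, starts, ends, strand = NULL) {
  n <- length(starts)
  if (is.null(strand)) strand <- rep("+", n)
  seqs <- substring(genome, starts + 1L, ends)
  seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
  data.frame(gene_id = sprintf("g%02d", seq_len(n)), strand = strand,
             start = starts, end = ends, sequence = seqs,
             stringsAsFactors = FALSE)
}

test_that("reference genes require every k-mer to occur in some read", {
  set.seed(139)
  genome <- random_seq(500)
  genes <- make_genes(genome, c(100L, 300L), c(130L, 360L))
  g1 <- genes$sequence[1]   # 30 nt -> six 25-mers
  reads <- substring(g1, 1:6, 25:30)
  ref <- reference_genes(genes, reads, k = 25)
  expect_equal(ref$gene_id, "g01")
  # drop one 25-mer: the gene is no longer a reference gene
  ref2 <- reference_genes(genes, reads[-3], k = 25)
  expect_equal(nrow(ref2), 0L)
  # reverse-complemented reads still count under the canonical policy
  ref3 <- reference_genes(genes, revcomp(reads), k = 25)
  expect_equal(ref3$gene_id, "g01")
  # genes shorter than k are excluded
  short <- make_genes(genome, 10L, 20L)
  expect_equal(nrow(reference_genes(short, reads, k = 25)), 0L)
})

test_that("specificity counts transcripts aligning full-length to the genome", {
  set.seed(149)
  genome <- random_seq(2000)
  tr <- c(t1 = substr(genome, 101, 300),
          t2 = revcomp(substr(genome, 501, 700)),
          t3 = random_seq(200))
  expect_equal(specificity(tr, genome), 2 / 3)
  expect_equal(specificity(tr[1:2], genome), 1.0)
  expect_equal(specificity(c(x = random_seq(100), y = random_seq(80)),
                           genome), 0.0)
  expect_warning(v <- specificity(character(), genome), "empty")
  expect_true(is.nan(v))
})

test_that("sensitivity is the covered fraction of reference-gene bases", {
  set.seed(151)
  genome <- random_seq(3000)
  genes <- make_genes(genome, c(200L, 1000L), c(300L, 1300L))  # 100, 300 nt
  # transcripts covering 50 of gene 1 and all of gene 2
  tr <- c(t1 = substr(genome, 201, 250), t2 = substr(genome, 1001, 1300))
  expect_equal(sensitivity(tr, genes, genome), 350 / 400)
  tr_full <- setNames(genes$sequence, genes$gene_id)
  expect_equal(sensitivity(tr_full, genes, genome), 1.0)
  expect_equal(sensitivity(c(x = random_seq(100)), genes, genome), 0.0)
  expect_error(sensitivity(tr, genes[0, ], genome),
               class = "denovotx_validation_error")
  # genome-wide variant
  expect_equal(sensitivity(tr, NULL, genome, genome_wide = TRUE),
               350 / 3000)
})

test_that("contiguity requires a single best transcript covering 80%", {
  set.seed(157)
  genome <- random_seq(3000)
  genes <- make_genes(genome, c(200L, 1000L), c(300L, 1100L))  # 100 nt each
  tr <- c(t1 = substr(genome, 201, 285),    # 85% of gene 1
          t2 = substr(genome, 1001, 1079))  # 79% of gene 2
  expect_equal(contiguity(tr, genes, genome), 0.5)
  expect_equal(contiguity(tr, genes[1, ], genome), 1.0)
  expect_equal(contiguity(tr, genes[2, ], genome), 0.0)
  # two half-covering transcripts do not add up for contiguity
  halves <- c(a = substr(genome, 201, 250), b = substr(genome, 251, 300))
  expect_equal(contiguity(halves, genes[1, ], genome), 0.0)
  expect_equal(sensitivity(halves, genes[1, ], genome), 1.0)
})

test_that("rmbt is the fraction of reads aligning full-length", {
  set.seed(163)
  tr <- c(t1 = random_seq(500), t2 = random_seq(400))
  good <- c(substring(tr[1], 1:10 * 30, 1:10 * 30 + 99),
            substring(tr[2], 1:10 * 25, 1:10 * 25 + 99))
  expect_equal(rmbt(good, tr), 1.0)
  bad <- vapply(1:20, function(i) random_seq(100), character(1))
  expect_equal(rmbt(c(good, bad), tr), 0.5)
  expect_equal(rmbt(good, data.frame(transcript_id = character(),
                                     sequence = character())), 0)
  expect_error(rmbt(character(), tr), class = "denovotx_validation_error")
})

test_that("accuracy is the perfect-match fraction of aligned columns", {
  set.seed(167)
  genome <- random_seq(3000)
  exact <- c(t1 = substr(genome, 101, 400), t2 = substr(genome, 1001, 1200))
  expect_equal(accuracy(exact, genome), 1.0)

  mut <- substr(genome, 2001, 2100)
  substr(mut, 50, 50) <- chartr("ACGT", "CAGT",
                                substr(mut, 50, 50))  # one substitution
  expect_equal(accuracy(c(m = mut), genome), 99 / 100)

  mix <- c(exact, m = mut)
  expect_equal(accuracy(mix, genome), (300 + 200 + 99) / (300 + 200 + 100))

  expect_warning(v <- accuracy(c(x = random_seq(200)), genome), "no transcript")
  expect_true(is.nan(v))
})

test_that("metrics agree with a brute-force per-base oracle on random fixtures", {
  set.seed(173)
  for (case in 1:10) {
    genome <- random_seq(4000)
    starts <- sort(sample(seq(0, 3400, by = 400), 4))
    genes <- make_genes(genome, starts, starts + sample(100:300, 4, TRUE))
    tx <- lapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      w <- sample(0:2, 1)
      if (w == 0) return(NULL)                          # gene unassembled
      len <- g$end - g$start
      keep <- sample(seq(30, len), 1)
      substr(genome, g$start + 1, g$start + keep)       # prefix transcript
    })
    tx <- c(Filter(Negate(is.null), tx), list(random_seq(150)))
    tx <- setNames(unlist(tx), sprintf("t%02d", seq_along(tx)))
    want <- oracle_metrics(tx, genes, genome)
    aln <- genome_alignments(tx, genome, method = "exact")
    expect_equal(specificity(tx, genome, alignments = aln),
                 want$specificity)
    expect_equal(sensitivity(tx, genes, genome, alignments = aln),
                 want$sensitivity)
    expect_equal(contiguity(tx, genes, genome, alignments = aln),
                 want$contiguity)
  }
})

test_that("sensitivity and contiguity never decrease when transcripts are added", {
  set.seed(179)
  genome <- random_seq(3000)
  genes <- make_genes(genome, c(100L, 1200L, 2400L),
                      c(500L, 1500L, 2700L))
  pool <- lapply(1:6, function(i) {
    g <- genes[sample(3, 1), ]
    a <- sort(sample(g$start:(g$end - 60), 1))
    setNames(substr(genome, a + 1, a + 60), sprintf("p%d", i))
  })
  sens <- cont <- numeric(6)
  for (i in 1:6) {
    tx <- unlist(pool[1:i])
    sens[i] <- sensitivity(tx, genes, genome)
    cont[i] <- contiguity(tx, genes, genome)
  }
  expect_true(all(diff(sens) >= 0))
  expect_true(all(diff(cont) >= -1e-12))
})

test_that("decile grouping follows the remainder-to-top rule", {
  set.seed(181)
  genome <- random_seq(30000)
  starts <- seq(0L, 24000L, by = 1000L)[1:25]
  genes <- make_genes(genome, starts, starts + 400L)
  ex <- setNames(seq_len(25), genes$gene_id)
  tx <- setNames(genes$sequence, paste0("t_", genes$gene_id))
  dec <- decile_performance(tx, genes, ex, genome)
  expect_equal(dec$n_genes, c(2, 2, 2, 2, 2, 3, 3, 3, 3, 3))
  # every gene fully assembled: all deciles identical
  expect_equal(dec$sensitivity, rep(1, 10))
  expect_equal(dec$contiguity, rep(1, 10))
  expect_error(decile_performance(tx, genes[1:5, ], ex, genome),
               class = "denovotx_validation_error")
})

test_that("the permissive aligner rescues near-exact transcripts", {
  set.seed(191)
  genome <- random_seq(5000)
  t_exact <- substr(genome, 1001, 1800)
  t_mut <- substr(genome, 3001, 3800)
  for (p in sample(800, 6)) {
    old <- substr(t_mut, p, p)
    substr(t_mut, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  }
  tx <- c(e = t_exact, m = t_mut)
  aln <- genome_alignments(tx, genome, method = "permissive")
  expect_setequal(aln$transcript_id, c("e", "m"))
  am <- aln[aln$transcript_id == "m", ]
  expect_gte(am$perfect_matches / am$aligned_length, 0.99)
  expect_lt(am$perfect_matches, am$aligned_length)
  # exact mode reports only the exact transcript
  expect_equal(genome_alignments(tx, genome, "exact")$transcript_id, "e")
})
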