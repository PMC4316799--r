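test_that("epsilon-covered regions are extracted as maximal intervals", {
  expect_equal(retain_regions(rep(25L, 500), 20, 50),
               data.frame(start = 0L, end = 500L))
  expect_equal(retain_regions(c(rep(25L, 30), rep(0L, 10), rep(25L, 60)),
                              20, 50),
               data.frame(start = 40L, end = 100L))
  expect_equal(nrow(retain_regions(integer(300), 20, 50)), 0L)
  expect_equal(nrow(retain_regions(rep(5L, 300), 20, 50)), 0L)
})

test_that("lowering epsilon weakly enlarges the retained intervals", {
  set.seed(71)
  for (i in 1:20) {
    depth <- as.integer(pmax(0, round(rnorm(300, 25, 15))))
    hi <- retain_regions(depth, 25, 10)
    lo <- retain_regions(depth, 10, 10)
    in_hi <- unlist(mapply(seq, hi$start, hi$end - 1, SIMPLIFY = FALSE))
    in_lo <- unlist(mapply(seq, lo$start, lo$end - 1, SIMPLIFY = FALSE))
    expect_true(all(in_hi %in% in_lo))
  }
})

test_that("scaffold consistency enforces transcript, orientation and insert", {
  con <- pair_constraint(min_insert = 100, max_insert = 500)
  a1 <- list(seq_id = "t1", offset = 100L, strand = "+")
  a2 <- list(seq_id = "t1", offset = 300L, strand = "-")
  expect_true(paired_consistent(a1, a2, 100, 100, con))   # fragment 300
  expect_false(paired_consistent(a1, list(seq_id = "t2", offset = 300L,
                                          strand = "-"), 100, 100, con))
  a_far <- list(seq_id = "t1", offset = 600L, strand = "-")
  expect_false(paired_consistent(a1, a_far, 100, 100, con))  # fragment 600
  expect_false(paired_consistent(a1, list(seq_id = "t1", offset = 300L,
                                          strand = "+"), 100, 100, con))
})

test_that("stage 1 recovers uniformly covered transcripts exactly", {
  set.seed(73)
  tr <- random_seq(1000)
  reads <- make_read_set(tile_reads(tr, m = 100, step = 20, times = 50),
                         strand_specific = TRUE)
  s1 <- stage1(reads)
  expect_equal(nrow(s1$candidates), 1L)
  expect_equal(s1$candidates$sequence, tr)

  # below the seeding threshold nothing is assembled
  low <- make_read_set(tile_reads(tr, m = 100, step = 20, times = 10),
                       strand_specific = TRUE)
  expect_equal(nrow(stage1(low)$candidates), 0L)
})

test_that("stage 1 separates transcripts sharing no (k-1)-mer", {
  set.seed(79)
  t1 <- random_seq(600)
  t2 <- random_seq(600)
  reads <- make_read_set(c(tile_reads(t1, 100, 25, 60),
                           tile_reads(t2, 100, 25, 60)),
                         strand_specific = TRUE)
  s1 <- stage1(reads)
  expect_equal(nrow(s1$candidates), 2L)
  expect_setequal(s1$candidates$sequence, c(t1, t2))
})

test_that("stage 2 keeps, splits, or drops candidates by coverage", {
  set.seed(83)
  cand_seq <- random_seq(400)
  candidates <- data.frame(candidate_id = "cand_00001",
                           sequence = cand_seq, stringsAsFactors = FALSE)
  idx <- fm_index(c(cand_00001 = cand_seq))
  params <- assembly_params()

  # uniform deep coverage: the candidate passes through unchanged
  deep <- make_read_set(tile_reads(cand_seq, 100, 10, 25),
                        strand_specific = TRUE)
  s2 <- stage2(deep, candidates, idx, params)
  expect_equal(nrow(s2$transcripts), 1L)
  expect_equal(s2$transcripts$sequence, cand_seq)
  expect_equal(s2$transcripts$start, 0L)
  expect_equal(s2$transcripts$end, 400L)

  # an uncovered middle stretch splits the candidate into two transcripts
  left <- substr(cand_seq, 1, 180)
  right <- substr(cand_seq, 221, 400)
  split_reads <- make_read_set(c(tile_reads(left, 60, 10, 25),
                                 tile_reads(right, 60, 10, 25)),
                               strand_specific = TRUE)
  s2b <- stage2(split_reads, candidates, idx, params)
  expect_equal(nrow(s2b$transcripts), 2L)
  expect_equal(s2b$transcripts$sequence, c(left, right))

  # uniform depth 5 (non-overlapping tiles, 5 copies) is below epsilon
  shallow <- make_read_set(tile_reads(cand_seq, 100, 100, 5),
                           strand_specific = TRUE)
  expect_equal(nrow(stage2(shallow, candidates, idx, params)$transcripts),
               0L)
})

test_that("per-sample counts never exceed the number of aligned reads", {
  set.seed(89)
  tr <- random_seq(800)
  s_a <- make_read_set(tile_reads(tr, 100, 10, 30), strand_specific = TRUE)
  s_b <- make_read_set(tile_reads(tr, 100, 15, 40), strand_specific = TRUE)
  asm <- assemble(list(A = s_a, B = s_b), seed = 3)
  expect_equal(colnames(asm$counts$counts), c("A", "B"))
  expect_lte(sum(asm$counts$counts[, "A"]), length(s_a))
  expect_lte(sum(asm$counts$counts[, "B"]), length(s_b))
  # deep uniform tiling: nearly every read lies inside the retained region
  expect_gte(sum(asm$counts$counts), 0.8 * (length(s_a) + length(s_b)))
})

test_that("multimapping reads are assigned reproducibly under a seed", {
  set.seed(97)
  dup <- random_seq(300)
  # two candidates with identical sequence content under different ids
  reads <- make_read_set(tile_reads(dup, 100, 10, 60),
                         strand_specific = TRUE)
  s1 <- stage1(reads)
  a1 <- assemble(reads, seed = 5)
  a2 <- assemble(reads, seed = 5)
  expect_identical(a1$counts$counts, a2$counts$counts)
})

test_that("paired-end data assemble with scaffold filtering", {
  cfg <- simulation_config(genome_length = 30000, n_transcripts = 5,
                           length_range = c(600, 900),
                           coverage_range = c(120, 120), paired = TRUE,
                           insert_mean = 300, insert_sd = 30, seed = 17)
  sim <- simulate_dataset(cfg)
  expect_true(sim$reads$paired)
  asm <- assemble(sim$reads, seed = 2,
                  constraint = pair_constraint(1, 500))
  expect_gte(nrow(asm$transcripts), 4L)
  expect_equal(specificity(asm$transcripts, sim$genome), 1.0)
})

test_that("assembling an empty read set warns and returns nothing", {
  empty <- make_read_set(character())
  expect_warning(asm <- assemble(empty), "no reads")
  expect_equal(nrow(asm$transcripts), 0L)
  expect_equal(nrow(asm$candidates), 0L)
})
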