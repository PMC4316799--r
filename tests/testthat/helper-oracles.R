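# independent oracles, kept deliberately naive and string-based

# greedy graph reduction re-implemented over character k-mers: seed at the
# most frequent remaining edge (ties: lexicographically smallest k-mer)
# while its count >= alpha; extend right then left taking the most frequent
# neighbor with count >= beta (ties: smallest base); remove traversed edges
oracle_extract_path <- function(env, seed, k, beta) {
  path <- seed
  rm(list = seed, envir = env)
  repeat {
    suff <- substr(path, nchar(path) - k + 2L, nchar(path))
    cand <- paste0(suff, c("A", "C", "G", "T"))
    cnt <- vapply(cand, function(x)
      if (exists(x, envir = env, inherits = FALSE))
        get(x, envir = env) else -1L, integer(1))
    if (max(cnt) < beta) break
    pick <- cand[which.max(cnt)]   # which.max keeps the first (smallest base)
    rm(list = pick, envir = env)
    path <- paste0(path, substr(pick, k, k))
  }
  repeat {
    pref <- substr(path, 1L, k - 1L)
    cand <- paste0(c("A", "C", "G", "T"), pref)
    cnt <- vapply(cand, function(x)
      if (exists(x, envir = env, inherits = FALSE))
        get(x, envir = env) else -1L, integer(1))
    if (max(cnt) < beta) break
    pick <- cand[which.max(cnt)]
    rm(list = pick, envir = env)
    path <- paste0(substr(pick, 1L, 1L), path)
  }
  path
}

oracle_reduce <- function(edges, k, alpha, beta) {
  env <- new.env()
  for (nm in names(edges)) assign(nm, as.integer(edges[[nm]]), envir = env)
  out <- character()
  repeat {
    nms <- ls(env)
    if (length(nms) == 0L) break
    cnt <- vapply(nms, get, integer(1), envir = env)
    ord <- order(-cnt, nms)
    if (cnt[ord[1]] < alpha) break
    out <- c(out, oracle_extract_path(env, nms[ord[1]], k, beta))
  }
  list(candidates = out,
       remaining = {
         nms <- ls(env)
         setNames(vapply(nms, get, integer(1), envir = env), nms)
       })
}

# occurrence count by Biostrings pattern matching (overlaps included)
naive_count <- function(text, pattern) {
  Biostrings::countPattern(pattern, Biostrings::DNAString(text))
}

naive_positions <- function(text, pattern) {
  Biostrings::start(Biostrings::matchPattern(
    pattern, Biostrings::DNAString(text))) - 1L
}

# invert a single-document BWT (text terminated by one '$') via LF mapping
bwt_invert <- function(bwt) {
  chars <- strsplit(bwt, "")[[1]]
  n <- length(chars)
  idx <- order(chars)          # stable: F rows in order of L occurrences
  lf <- integer(n)
  lf[idx] <- seq_len(n)
  out <- character(n - 1L)
  i <- 1L                      # row of the suffix "$"
  for (j in seq_len(n - 1L)) {
    out[n - j] <- chars[i]
    i <- lf[i]
  }
  paste(c(out, "$"), collapse = "")
}

# all full-length Hamming alignments of a read against a set of sequences
sliding_hamming <- function(seqs, read, max_mm) {
  hits <- NULL
  m <- nchar(read)
  for (si in seq_along(seqs)) {
    s <- seqs[[si]]
    L <- nchar(s)
    if (L < m) next
    for (off in 0:(L - m)) {
      mm <- sum(strsplit(substr(s, off + 1L, off + m), "")[[1]] !=
                  strsplit(read, "")[[1]])
      if (mm <= max_mm)
        hits <- rbind(hits, data.frame(seq = si, offset = off,
                                       mismatches = mm))
    }
  }
  hits
}

# brute-force conditional NB test: explicit loop over all splits of the
# observed total, mirroring the definition rather than the implementation
oracle_nb_test <- function(counts_a, counts_b, factors_a, factors_b,
                           dispersion) {
  ka <- sum(counts_a); kb <- sum(counts_b)
  K <- ka + kb
  if (K == 0) return(1)
  q0 <- mean(c(counts_a / factors_a, counts_b / factors_b))
  v0 <- q0 + dispersion * q0^2
  pmf <- function(x, sf) {
    mu <- q0 * sum(sf); v <- sum(sf^2) * v0
    if (mu <= 0) return(as.numeric(x == 0))
    if (v <= mu * (1 + 1e-8)) dpois(x, mu) else
      dnbinom(x, size = mu^2 / (v - mu), mu = mu)
  }
  obs <- pmf(ka, factors_a) * pmf(kb, factors_b)
  num <- 0; den <- 0
  for (a in 0:K) {
    term <- pmf(a, factors_a) * pmf(K - a, factors_b)
    den <- den + term
    if (term <= obs * (1 + 1e-7)) num <- num + term
  }
  if (den <= 0) 1 else min(num / den, 1)
}

# per-base metric oracles over exact substring alignment (both strands)
oracle_exact_hits <- function(transcript, genome) {
  hits <- naive_positions(genome, transcript)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(transcript)))
  hits <- c(hits, naive_positions(genome, rc))
  hits
}

oracle_metrics <- function(transcripts, genes, genome) {
  glen <- nchar(genome)
  covered <- logical(glen)
  best_cov <- matrix(0L, nrow = length(transcripts), ncol = nrow(genes))
  aligned <- logical(length(transcripts))
  for (ti in seq_along(transcripts)) {
    t <- transcripts[[ti]]
    for (h in oracle_exact_hits(t, genome)) {
      aligned[ti] <- TRUE
      span <- (h + 1L):(h + nchar(t))
      covered[span] <- TRUE
      for (gi in seq_len(nrow(genes))) {
        gspan <- (genes$start[gi] + 1L):genes$end[gi]
        best_cov[ti, gi] <- best_cov[ti, gi] +
          length(intersect(span, gspan))
      }
    }
  }
  gene_cov <- vapply(seq_len(nrow(genes)), function(gi)
    sum(covered[(genes$start[gi] + 1L):genes$end[gi]]), integer(1))
  gene_len <- genes$end - genes$start
  list(specificity = mean(aligned),
       sensitivity = sum(gene_cov) / sum(gene_len),
       contiguity = mean(apply(best_cov, 2, max) / gene_len >= 0.8))
}
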