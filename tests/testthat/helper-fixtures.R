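# fixture builders shared across the suite

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_read_set <- function(seqs, ...) {
  n <- length(seqs)
  read_set(data.frame(read_id = sprintf("r%04d", seq_len(n)),
                      sequence = as.character(seqs),
                      quality = rep(NA_character_, n),
                      mate_role = rep("unpaired", n),
                      stringsAsFactors = FALSE),
           ...)
}

# tile a sequence with reads of length m starting every `step` positions
# (always including the final window), each repeated `times` times
tile_reads <- function(seq, m = 100L, step = 50L, times = 1L) {
  L <- nchar(seq)
  starts <- unique(c(seq(1L, L - m + 1L, by = step), L - m + 1L))
  rep(substring(seq, starts, starts + m - 1L), each = times)
}

write_tmp_lines <- function(lines, ext = ".txt", gz = FALSE) {
  path <- tempfile(fileext = if (gz) paste0(ext, ".gz") else ext)
  con <- if (gz) gzfile(path, "wt") else file(path, "wt")
  writeLines(lines, con)
  close(con)
  path
}
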