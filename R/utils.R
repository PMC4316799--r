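#' Reverse complement of nucleotide strings
#'
#' @param x character vector of sequences over \code{{A,C,G,T,N}}.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)),
               use.names = FALSE)
}

# lexicographic minimum of a sequence and its reverse complement
canonical_seq <- function(x) {
  r <- revcomp(x)
  ifelse(x <= r, x, r)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stop_dn <- function(..., class) {
  stop(errorCondition(sprintf(...), class = c(class, "denovotx_error")))
}
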