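DNA_BASES4 <- c("A", "C", "G", "T")

# Integer codes shared with the C++ kernels: A/C/G/T -> 0..3, anything else 4.
# For references code 4 means gap/N (never matches); for observations it means
# a neutral symbol ('-' or N) emitted with probability 1 by every state.
encode_symbols <- function(x) {
  out <- match(x, DNA_BASES4, nomatch = 5L) - 1L
  out
}

# Observation characters in {A,C,G,T,-,N} -> codes; other symbols are the
# caller's responsibility (thread_query normalizes them to N).
encode_obs <- function(obs) {
  if (length(obs) == 1L && nchar(obs[1L]) > 1L)
    obs <- strsplit(obs, "", fixed = TRUE)[[1L]]
  encode_symbols(obs)
}

# One rate per (reference, rate-class) pair. DB mode shares a single grid
# across references; BW mode carries fitted per-reference rates.
rates_matrix <- function(config, N) {
  if (!is.null(config$rate_matrix)) {
    rm <- config$rate_matrix
    if (!is.matrix(rm)) rm <- matrix(rm, ncol = 1L)
    stopifnot(nrow(rm) == N)
    return(rm)
  }
  matrix(config$rates, nrow = N, ncol = length(config$rates), byrow = TRUE)
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector of sequences (gaps allowed).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
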