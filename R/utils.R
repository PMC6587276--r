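#' @useDynLib pingpongr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the \{A,C,G,T,N\} alphabet.
#'
#' @param x Character vector of uppercase DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# most frequent integer value; ties broken towards the smallest
mode_int <- function(x) {
  if (length(x) == 0L) return(NA_integer_)
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

# normalize a sequence vector: uppercase, RNA -> DNA alphabet
normalize_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

assert_dna <- function(x, what = "sequence") {
  bad <- grep("[^ACGTN]", x)
  if (length(bad) > 0L) {
    stop(sprintf("%s %d contains characters outside {A,C,G,T,N,U}",
                 what, bad[1L]), call. = FALSE)
  }
  invisible(TRUE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

msg <- function(...) message(sprintf(...))
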