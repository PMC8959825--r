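# Shared small helpers: sequence handling and input checks.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a nucleotide string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that keeps plain
#' character vectors in and out. `N` is preserved.
#'
#' @param x character vector of sequences over `{A,C,G,T,N}`.
#' @return character vector of the same length.
#' @export
#' @examples
#' reverse_complement("GTGGACCC")
reverse_complement <- function(x) {
  stopifnot(is.character(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# split a sequence string into a character vector of single bases
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# assert a single non-missing string
check_string <- function(x, name = deparse(substitute(x))) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    abort(glue("`{name}` must be a single string"))
  }
  invisible(x)
}

check_number <- function(x, name = deparse(substitute(x)), min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(glue("`{name}` must be a single number in [{min}, {max}]"))
  }
  invisible(x)
}

# random DNA string(s) of given lengths, uses the current RNG stream
random_dna <- function(lengths) {
  vapply(lengths, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))
}

# zero-padded gene identifiers g0001, ...
make_gene_ids <- function(n) {
  sprintf("g%0*d", max(4L, nchar(as.character(n))), seq_len(n))
}
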