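# Internal helpers shared across modules.

READ_SIZES <- 18:30

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a character vector of DNA sequences
#' @param x character vector over ACGTN
#' @return character vector
#' @keywords internal
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Draw read lengths from a probability vector over 18..30 nt.
draw_lengths <- function(n, size_dist) {
  stopifnot(length(size_dist) == length(READ_SIZES))
  sample(READ_SIZES, n, replace = TRUE, prob = size_dist)
}

# Copies-weighted counts; alignments are GRanges with a `copies` mcol.
aln_copies <- function(aln) {
  cp <- S4Vectors::mcols(aln)$copies
  if (is.null(cp)) rep(1, length(aln)) else cp
}

aln_lengths <- function(aln) GenomicRanges::width(aln)

# 5' end genomic coordinate: start on +, end on -.
five_prime_pos <- function(aln) {
  ifelse(as.character(GenomicRanges::strand(aln)) == "-",
         GenomicRanges::end(aln), GenomicRanges::start(aln))
}

stop_if_not_acgt <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop(sprintf("%d %s(s) contain non-ACGT characters", sum(bad), what))
  }
  invisible(x)
}
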