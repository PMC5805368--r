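# Fixtures and independent brute-force oracles used across the suite.

make_genome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# degenerate size distribution: all mass on one read length
size_point <- function(L) {
  p <- stats::setNames(rep(0, 13), 18:30)
  p[as.character(L)] <- 1
  p
}

# Brute-force exact mapping: naive O(nm) sliding-window scan, both strands.
naive_map <- function(reads_df, genome) {
  out <- list()
  for (r in seq_len(nrow(reads_df))) {
    s <- reads_df$sequence[r]
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    L <- nchar(s)
    for (chrom in names(genome)) {
      g <- as.character(genome[[chrom]])
      n <- nchar(g)
      if (n < L) next
      for (i in seq_len(n - L + 1)) {
        win <- substr(g, i, i + L - 1)
        if (win == s) {
          out[[length(out) + 1]] <- data.frame(
            read_id = reads_df$read_id[r], chrom = chrom, start = i,
            end = i + L - 1, strand = "+", stringsAsFactors = FALSE)
        }
        if (win == rc) {
          out[[length(out) + 1]] <- data.frame(
            read_id = reads_df$read_id[r], chrom = chrom, start = i,
            end = i + L - 1, strand = "-", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(read_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start, df$strand, df$read_id), , drop = FALSE]
}

# Brute-force 5'-overlap pair counts: enumerate every plus x minus
# alignment pair and tally its 5'-end distance, copies-weighted.
brute_overlap <- function(aln, L1 = "all", L2 = "all", o_max = 30) {
  str <- as.character(GenomicRanges::strand(aln))
  w <- GenomicRanges::width(aln)
  cp <- S4Vectors::mcols(aln)$copies
  if (is.null(cp)) cp <- rep(1, length(aln))
  plus <- which(str == "+" & (identical(L1, "all") | w == L1))
  minus <- which(str == "-" & (identical(L2, "all") | w == L2))
  Z <- numeric(o_max)
  for (i in plus) {
    for (j in minus) {
      if (as.character(GenomicRanges::seqnames(aln))[i] !=
          as.character(GenomicRanges::seqnames(aln))[j]) next
      o <- GenomicRanges::end(aln)[j] - GenomicRanges::start(aln)[i] + 1
      if (o >= 1 && o <= o_max) Z[o] <- Z[o] + cp[i] * cp[j]
    }
  }
  Z
}

# Random alignment set for property tests.
random_alignments <- function(n, chrom_len = 600, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- sample(18:30, n, replace = TRUE)
  start <- sample(chrom_len - 30, n, replace = TRUE)
  GenomicRanges::GRanges("chrA", IRanges::IRanges(start, width = L),
                         strand = sample(c("+", "-"), n, replace = TRUE),
                         read_id = sprintf("r%04d", seq_len(n)),
                         copies = sample(1:3, n, replace = TRUE),
                         n_hits = rep(1L, n))
}

# GRanges alignment builder for hand-constructed cases.
aln_gr <- function(start, end, strand, chrom = "chr1", copies = 1,
                   n_hits = 1, sequence = NULL, read_id = NULL) {
  n <- length(start)
  gr <- GenomicRanges::GRanges(rep(chrom, length.out = n),
                               IRanges::IRanges(start, end),
                               strand = strand)
  S4Vectors::mcols(gr)$read_id <- read_id %||% sprintf("r%03d", seq_len(n))
  S4Vectors::mcols(gr)$copies <- rep_len(copies, n)
  S4Vectors::mcols(gr)$n_hits <- rep_len(as.integer(n_hits), n)
  if (!is.null(sequence)) S4Vectors::mcols(gr)$sequence <- sequence
  gr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
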