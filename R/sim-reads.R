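# Mechanistically labelled read simulators. Each returns reads as a GRanges
# (the true origin of each read) with mcols: read_id, sequence, copies,
# mechanism. Sequences always equal the genome subsequence at the recorded
# coordinates, reverse-complemented on the minus strand.

#' Extract strand-aware sequence from a genome
#' @param genome DNAStringSet
#' @param gr GRanges of regions
#' @return character vector of sequences (5'->3' on the range's strand)
#' @export
extract_seq <- function(genome, gr) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  out <- vapply(seq_along(gr), function(i) {
    s <- Biostrings::subseq(genome[[chrom[i]]],
                            start = GenomicRanges::start(gr)[i],
                            end = GenomicRanges::end(gr)[i])
    as.character(s)
  }, character(1))
  minus <- as.character(GenomicRanges::strand(gr)) == "-"
  out[minus] <- revcomp_chr(out[minus])
  out
}

reads_granges <- function(chrom, start, end, strand, genome, mechanism, prefix) {
  gr <- GenomicRanges::GRanges(rep(chrom, length.out = length(start)),
                               IRanges::IRanges(start, end), strand = strand)
  if (length(gr)) {
    S4Vectors::mcols(gr)$read_id <- sprintf("%s%06d", prefix, seq_along(gr))
    S4Vectors::mcols(gr)$sequence <- extract_seq(genome, gr)
    S4Vectors::mcols(gr)$copies <- rep(1L, length(gr))
    S4Vectors::mcols(gr)$mechanism <-
      if (length(mechanism) == length(gr)) mechanism else rep(mechanism, length.out = length(gr))
  } else {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(read_id = character(0),
                                                 sequence = character(0),
                                                 copies = integer(0),
                                                 mechanism = character(0))
  }
  gr
}

#' Simulate Dicer-duplex small RNA reads
#'
#' Each duplex of length L placed with its plus-strand 5' end at position p
#' yields a plus read covering `[p, p+L-1]` and a minus read covering
#' `[p-2, p+L-3]` (1-based closed), i.e. the two 5' ends overlap by exactly
#' `L - 2` nt — the 2-nt 3' overhang register characteristic of RNase III
#' (Dicer) cleavage. Both duplex arms share one length L drawn from
#' `size_dist`.
#'
#' @param genome DNAStringSet.
#' @param region single-range GRanges the duplexes are placed in; must be at
#'   least `max(READ_SIZES) + 2` bp wide.
#' @param n_duplexes number of duplexes (2 reads each).
#' @param size_dist probability vector over lengths 18..30.
#' @param seed optional integer seed.
#' @return GRanges of reads (see file header for mcols).
#' @export
simulate_dicer_reads <- function(genome, region, n_duplexes,
                                 size_dist = default_size_dist(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(region) == 1)
  rs <- GenomicRanges::start(region); re <- GenomicRanges::end(region)
  if (re - rs + 1 < max(READ_SIZES) + 2) {
    stop("region shorter than max read length + 2")
  }
  chrom <- as.character(GenomicRanges::seqnames(region))
  if (n_duplexes == 0) {
    return(reads_granges(chrom, integer(0), integer(0), character(0), genome,
                         character(0), "dcr"))
  }
  L <- draw_lengths(n_duplexes, size_dist)
  # plus read [p, p+L-1], minus read [p-2, p+L-3]: need p-2 >= rs, p+L-1 <= re
  lo <- rs + 2L
  hi <- re - L + 1L
  bad <- hi < lo
  tries <- 0L
  while (any(bad)) {
    tries <- tries + 1L
    if (tries > 1000L) stop("could not place duplexes inside region after 1000 tries")
    L[bad] <- draw_lengths(sum(bad), size_dist)
    hi <- re - L + 1L
    bad <- hi < lo
  }
  p <- lo + floor(stats::runif(n_duplexes) * (hi - lo + 1))
  p <- as.integer(pmin(p, hi))
  starts <- c(p, p - 2L)
  ends <- c(p + L - 1L, p + L - 3L)
  strands <- rep(c("+", "-"), each = n_duplexes)
  reads_granges(chrom, starts, ends, strands, genome,
                rep("dicer", 2L * n_duplexes), "dcr")
}

#' Simulate ping-pong amplification read pairs
#'
#' Each pair consists of a guide read and a responder read on opposite
#' strands whose 5' ends overlap by exactly 10 nt (the Piwi slicer register).
#' Because responder position 10 is the complement of guide position 1, one
#' genomic base per pair carries both biases: it is edited to T on the guide
#' sense with probability `1 - (1-guide_5p_bias)*(1-responder_10A_bias)`, and
#' otherwise drawn uniformly from {A, C, G}. Editing happens on the genome
#' before read extraction, so reads and genome stay consistent.
#'
#' @inheritParams simulate_dicer_reads
#' @param n_pairs number of guide/responder pairs.
#' @param guide_5p_bias probability of U (T) at guide position 1.
#' @param responder_10A_bias probability of A at responder position 10.
#' @return list with `reads` (GRanges; mcols mechanism = "pingpong", role
#'   guide/responder) and `genome` (the edited DNAStringSet).
#' @export
simulate_pingpong_reads <- function(genome, region, n_pairs,
                                    size_dist = default_size_dist(),
                                    guide_5p_bias = 0.25,
                                    responder_10A_bias = 0,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(region) == 1)
  rs <- GenomicRanges::start(region); re <- GenomicRanges::end(region)
  if (re - rs + 1 < max(READ_SIZES) + 10) {
    stop("region shorter than max read length + 10")
  }
  chrom <- as.character(GenomicRanges::seqnames(region))
  if (n_pairs == 0) {
    return(list(reads = reads_granges(chrom, integer(0), integer(0),
                                      character(0), genome, character(0), "pp"),
                genome = genome))
  }
  Lg <- draw_lengths(n_pairs, size_dist)
  Lr <- draw_lengths(n_pairs, size_dist)
  guide_plus <- stats::runif(n_pairs) < 0.5

  # plus guide: 5' at g, spans [g, g+Lg-1]; responder minus, 5' at g+9,
  # spans [g+10-Lr, g+9]. Minus guide mirrors this geometry. Guide 5'
  # positions are drawn without replacement from the region interior (a
  # margin of max read length - 1 keeps every pair inside for any length
  # and orientation) so each planted 1U/10A base is edited exactly once
  # and never overwritten by another pair.
  margin <- max(READ_SIZES) - 1L
  avail <- seq.int(rs + margin, re - margin)
  if (length(avail) < n_pairs) {
    stop(sprintf("region too small for %d ping-pong pairs (%d usable guide positions)",
                 n_pairs, length(avail)))
  }
  g <- sample(avail, n_pairs)

  # plant the shared 1U/10A base at the guide 5' position (guide sense)
  p_t <- 1 - (1 - guide_5p_bias) * (1 - responder_10A_bias)
  is_t <- stats::runif(n_pairs) < p_t
  base_guide_sense <- character(n_pairs)
  base_guide_sense[is_t] <- "T"
  base_guide_sense[!is_t] <- sample(c("A", "C", "G"), sum(!is_t), replace = TRUE)
  plus_base <- ifelse(guide_plus, base_guide_sense,
                      chartr("ACGT", "TGCA", base_guide_sense))
  genome[[chrom]] <- Biostrings::replaceLetterAt(
    genome[[chrom]], g, paste(plus_base, collapse = ""))

  gstart <- ifelse(guide_plus, g, g - Lg + 1L)
  gend <- ifelse(guide_plus, g + Lg - 1L, g)
  rstart <- ifelse(guide_plus, g + 10L - Lr, g - 9L)
  rend <- ifelse(guide_plus, g + 9L, g - 10L + Lr)
  starts <- as.integer(c(gstart, rstart))
  ends <- as.integer(c(gend, rend))
  strands <- c(ifelse(guide_plus, "+", "-"), ifelse(guide_plus, "-", "+"))
  reads <- reads_granges(chrom, starts, ends, strands, genome,
                         rep("pingpong", 2L * n_pairs), "pp")
  S4Vectors::mcols(reads)$role <- rep(c("guide", "responder"), each = n_pairs)
  list(reads = reads, genome = genome)
}

#' Simulate single-stranded degradation fragments
#'
#' Fragments sampled uniform-start along a stranded transcript, lengths from
#' `size_dist`, truncated at the transcript 3' end; all reads lie on the
#' transcript's strand, so opposite-strand overlap structure is absent.
#'
#' @inheritParams simulate_dicer_reads
#' @param transcript single-range stranded GRanges (+ or -).
#' @param n number of fragments.
#' @return GRanges of reads (mechanism = "degradation").
#' @export
simulate_degradation_reads <- function(genome, transcript, n,
                                       size_dist = default_size_dist(),
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(transcript) == 1)
  strand <- as.character(GenomicRanges::strand(transcript))
  if (!strand %in% c("+", "-")) stop("transcript locus must be stranded (+ or -)")
  ts <- GenomicRanges::start(transcript); te <- GenomicRanges::end(transcript)
  chrom <- as.character(GenomicRanges::seqnames(transcript))
  if (n == 0) {
    return(reads_granges(chrom, integer(0), integer(0), character(0), genome,
                         character(0), "deg"))
  }
  # uniform 5' start, length from size_dist, truncated at the transcript 3'
  # end; fragments shorter than the sequencing size selection (18 nt) are
  # resampled, mirroring library size selection
  min_len <- min(READ_SIZES)
  s_acc <- integer(0); e_acc <- integer(0)
  tries <- 0L
  while (length(s_acc) < n) {
    tries <- tries + 1L
    if (tries > 1000L) stop("could not draw size-selected fragments after 1000 rounds")
    k <- n - length(s_acc)
    L <- draw_lengths(k, size_dist)
    if (strand == "+") {
      s <- ts + floor(stats::runif(k) * (te - ts + 1))
      e <- pmin(s + L - 1L, te)
    } else {
      e <- ts + floor(stats::runif(k) * (te - ts + 1))
      s <- pmax(e - L + 1L, ts)
    }
    ok <- (e - s + 1L) >= min_len
    s_acc <- c(s_acc, as.integer(s[ok])); e_acc <- c(e_acc, as.integer(e[ok]))
  }
  reads_granges(chrom, s_acc, e_acc, rep(strand, n), genome,
                rep("degradation", n), "deg")
}

#' Simulate a complete labelled small-RNA dataset
#'
#' Orchestrates [simulate_genome()] and the three read mechanisms under one
#' global seed, in a fixed draw order (genome, dicer, ping-pong,
#' degradation, methylation calls). Dicer duplexes are placed in the planted
#' master locus, ping-pong pairs in the first TE copy, and degradation
#' fragments across the mRNA loci in proportion to the mixture fractions.
#'
#' @param config a [sim_config()] object.
#' @return list: `genome` (possibly edited by ping-pong planting),
#'   `annotation`, `te_catalog`, `truth` (per-read mechanism labels live in
#'   the reads' mcols), `reads` (GRanges), `methyl_calls` (data.frame).
#' @export
simulate_srna_dataset <- function(config) {
  g <- simulate_genome(config)
  ann <- g$annotation
  genome <- g$genome
  mx <- config$mixture
  n_dicer <- round(config$n_reads * mx[["dicer"]])
  n_pp <- round(config$n_reads * mx[["pingpong"]])
  n_deg <- config$n_reads - n_dicer - n_pp

  master <- ann[ann$feature_class == "master"]
  dcr <- simulate_dicer_reads(genome, master, floor(n_dicer / 2),
                              size_dist = config$size_dist)

  pp <- NULL
  if (n_pp > 0) {
    te1 <- ann[ann$feature_class == "TE"][1]
    res <- simulate_pingpong_reads(genome, te1, floor(n_pp / 2),
                                   size_dist = config$size_dist,
                                   guide_5p_bias = config$guide_5p_bias,
                                   responder_10A_bias = config$responder_10A_bias)
    pp <- res$reads
    genome <- res$genome
    # re-extract dicer read sequences in case editing touched them (it
    # cannot: regions are disjoint, but keep the contract airtight)
    S4Vectors::mcols(dcr)$sequence <- extract_seq(genome, dcr)
  }

  deg <- NULL
  if (n_deg > 0) {
    mrna <- ann[ann$feature_class == "mRNA"]
    per <- diff(round(seq(0, n_deg, length.out = length(mrna) + 1)))
    parts <- lapply(seq_along(mrna), function(i) {
      simulate_degradation_reads(genome, mrna[i], per[i],
                                 size_dist = config$size_dist)
    })
    deg <- do.call(c, parts)
  }

  parts <- Filter(Negate(is.null), list(dcr, pp, deg))
  parts <- lapply(parts, function(x) { # harmonize optional mcols
    if (is.null(S4Vectors::mcols(x)$role)) {
      S4Vectors::mcols(x)$role <- rep(NA_character_, length(x))
    }
    S4Vectors::mcols(x) <- S4Vectors::mcols(x)[, c("read_id", "sequence",
                                                   "copies", "mechanism", "role")]
    x
  })
  reads <- do.call(c, parts)
  S4Vectors::mcols(reads)$read_id <- sprintf("read%06d", seq_along(reads))

  calls <- simulate_methyl_calls(genome, ann, config$methyl_rates,
                                 config$coverage_mean)
  list(genome = genome, annotation = ann, te_catalog = g$te_catalog,
       truth = g$truth, reads = reads, methyl_calls = calls)
}
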