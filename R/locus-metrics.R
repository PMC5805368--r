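# Per-locus descriptive metrics: strand bias, read-size distribution,
# 5' nucleotide composition and length-normalized coverage metagenes.

#' Strand bias of a locus
#'
#' |plus - minus| / (plus + minus) on copies-weighted read counts: 1 for a
#' single-stranded source, ~0 for dsRNA-derived reads. `NA` for zero-read
#' loci. With `mode = "coverage"` the per-base strand-specific coverage sums
#' replace the read counts.
#'
#' @param alignments GRanges.
#' @param locus optional single-range GRanges restriction.
#' @param mode "reads" (default) or "coverage".
#' @return value in [0, 1] or NA.
#' @export
strand_bias <- function(alignments, locus = NULL, mode = c("reads", "coverage")) {
  mode <- match.arg(mode)
  a <- alignments
  if (!is.null(locus)) {
    a <- a[IRanges::overlapsAny(a, locus, ignore.strand = TRUE)]
  }
  w <- aln_copies(a)
  if (mode == "coverage") w <- w * aln_lengths(a)
  plus <- sum(w[as.character(GenomicRanges::strand(a)) == "+"])
  minus <- sum(w[as.character(GenomicRanges::strand(a)) == "-"])
  tot <- plus + minus
  if (tot == 0) return(NA_real_)
  abs(plus - minus) / tot
}

#' Copies-weighted read-size distribution
#'
#' @param alignments GRanges (or simulated reads).
#' @param sizes histogram support (default 18:30).
#' @return list: `hist` (named, normalized; all-zero when empty), `mode`
#'   (modal length; NA when empty).
#' @export
size_distribution <- function(alignments, sizes = READ_SIZES) {
  len <- aln_lengths(alignments)
  w <- aln_copies(alignments)
  h <- vapply(sizes, function(L) sum(w[len == L]), numeric(1))
  names(h) <- sizes
  if (sum(h) == 0) return(list(hist = h, mode = NA_integer_))
  list(hist = h / sum(h), mode = sizes[which.max(h)])
}

#' 5' nucleotide composition and information content
#'
#' Copies-weighted base frequencies at read positions 1..`n_pos` (position 1
#' is the 5' end on the read's own sense) and the per-position information
#' content IC = 2 + sum(f * log2 f) bits (0 for uniform, 2 for a fixed
#' base). No small-sample correction is applied.
#'
#' @param alignments GRanges with `sequence` mcol, or character sequences.
#' @param n_pos number of 5'-proximal positions profiled (default 1).
#' @return list: `freq` (4 x n_pos matrix, rows A/C/G/T), `ic` (bits per
#'   position).
#' @export
five_prime_composition <- function(alignments, n_pos = 1L) {
  if (inherits(alignments, "GRanges")) {
    seqs <- S4Vectors::mcols(alignments)$sequence
    if (is.null(seqs)) stop("alignments lack a sequence mcol")
    w <- aln_copies(alignments)
  } else {
    seqs <- as.character(alignments)
    w <- rep(1, length(seqs))
  }
  bases <- c("A", "C", "G", "T")
  freq <- matrix(0, nrow = 4, ncol = n_pos, dimnames = list(bases, seq_len(n_pos)))
  for (p in seq_len(n_pos)) {
    b <- substr(seqs, p, p)
    ok <- b %in% bases
    tot <- sum(w[ok])
    if (tot == 0) next
    for (base in bases) freq[base, p] <- sum(w[ok & b == base]) / tot
  }
  ic <- apply(freq, 2, function(f) {
    f <- f[f > 0]
    if (length(f) == 0) return(NA_real_)
    2 + sum(f * log2(f))
  })
  list(freq = freq, ic = ic)
}

#' Length-normalized binned coverage profiles and class metagene
#'
#' Per-base copies-weighted coverage of each locus rescaled to `n_bins` bins
#' (mean within bin; loci shorter than `n_bins` are linearly interpolated),
#' oriented 5' to 3' along the locus strand (unstranded treated as plus, so
#' minus-strand loci are reversed). The class metagene is the per-bin mean
#' across loci, and the 3'-enrichment score is mean(last decile) /
#' mean(first decile), capped at `enrich_cap` when the first decile is
#' empty.
#'
#' @param loci GRanges with `id` mcol.
#' @param alignments GRanges.
#' @param n_bins bins per locus (default 100).
#' @param enrich_cap sentinel for an infinite 3'-enrichment ratio.
#' @return list: `profiles` (loci x bins matrix), `metagene` (length
#'   `n_bins`), `enrichment3p` (per locus; NA when the locus has no reads).
#' @export
binned_coverage <- function(loci, alignments, n_bins = 100L,
                            enrich_cap = 1000) {
  ids <- S4Vectors::mcols(loci)$id %||% sprintf("locus%d", seq_along(loci))
  profiles <- matrix(0, nrow = length(loci), ncol = n_bins,
                     dimnames = list(ids, NULL))
  enrich <- rep(NA_real_, length(loci))
  for (i in seq_along(loci)) {
    s <- GenomicRanges::start(loci)[i]; e <- GenomicRanges::end(loci)[i]
    width <- e - s + 1L
    cov <- numeric(width)
    a <- alignments[IRanges::overlapsAny(alignments, loci[i],
                                         ignore.strand = TRUE)]
    if (length(a)) {
      w <- aln_copies(a)
      st <- pmax(GenomicRanges::start(a), s) - s + 1L
      en <- pmin(GenomicRanges::end(a), e) - s + 1L
      same_chr <- as.character(GenomicRanges::seqnames(a)) ==
        as.character(GenomicRanges::seqnames(loci[i]))
      for (k in which(same_chr)) cov[st[k]:en[k]] <- cov[st[k]:en[k]] + w[k]
    }
    if (as.character(GenomicRanges::strand(loci))[i] == "-") cov <- rev(cov)
    profiles[i, ] <- rescale_to_bins(cov, n_bins)
    dec <- max(1L, n_bins %/% 10L)
    first <- mean(profiles[i, seq_len(dec)])
    last <- mean(profiles[i, (n_bins - dec + 1L):n_bins])
    if (sum(cov) > 0) {
      enrich[i] <- if (first == 0) enrich_cap else last / first
    }
  }
  list(profiles = profiles,
       metagene = colMeans(profiles),
       enrichment3p = stats::setNames(enrich, ids))
}

# Mean-within-bin rescaling; shorter-than-n_bins vectors interpolated.
rescale_to_bins <- function(x, n_bins) {
  n <- length(x)
  if (n == n_bins) return(x)
  if (n < n_bins) {
    return(stats::approx(seq_len(n), x, n = n_bins)$y)
  }
  edges <- floor(seq(0, n, length.out = n_bins + 1L))
  vapply(seq_len(n_bins), function(b) {
    mean(x[(edges[b] + 1L):edges[b + 1L]])
  }, numeric(1))
}

#' Per-locus metric table and per-class RDI-style summary
#'
#' @param loci GRanges with mcols `id` and `feature_class`.
#' @param alignments GRanges.
#' @return list: `per_locus` data.frame (id, class, reads_plus, reads_minus,
#'   strand_bias, modal_size), `per_class` data.frame (class, n_loci,
#'   mean_bias, sd_bias, total_reads).
#' @export
locus_metrics <- function(loci, alignments) {
  ids <- S4Vectors::mcols(loci)$id %||% sprintf("locus%d", seq_along(loci))
  cls <- S4Vectors::mcols(loci)$feature_class %||% rep(NA_character_, length(loci))
  rows <- lapply(seq_along(loci), function(i) {
    a <- alignments[IRanges::overlapsAny(alignments, loci[i],
                                         ignore.strand = TRUE)]
    w <- aln_copies(a)
    plus <- sum(w[as.character(GenomicRanges::strand(a)) == "+"])
    minus <- sum(w[as.character(GenomicRanges::strand(a)) == "-"])
    data.frame(id = ids[i], feature_class = cls[i],
               reads_plus = plus, reads_minus = minus,
               strand_bias = if (plus + minus > 0) abs(plus - minus) / (plus + minus) else NA_real_,
               modal_size = size_distribution(a)$mode,
               stringsAsFactors = FALSE)
  })
  per_locus <- do.call(rbind, rows)
  per_class <- do.call(rbind, lapply(split(per_locus, per_locus$feature_class),
                                     function(d) {
    data.frame(feature_class = d$feature_class[1], n_loci = nrow(d),
               mean_bias = mean(d$strand_bias, na.rm = TRUE),
               sd_bias = stats::sd(d$strand_bias, na.rm = TRUE),
               total_reads = sum(d$reads_plus + d$reads_minus),
               stringsAsFactors = FALSE)
  }))
  rownames(per_class) <- NULL
  list(per_locus = per_locus, per_class = per_class)
}
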