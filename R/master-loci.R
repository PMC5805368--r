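# Discovery of siRNA-producing TE-control master loci: dual-strand
# expressed loci carrying exact TE-family homology, plus the fraction of
# TE-mapped reads they account for.

#' Maximal exact matches between a locus and a TE catalog
#'
#' Reports every maximal exact match of at least `min_match` bp between the
#' locus sequence and any TE family sequence, in either orientation, as
#' locus-coordinate intervals tagged with the family and orientation.
#' Matches are seeded on shared `min_match`-mers and extended maximally;
#' duplicate and strictly nested intervals from the same family/orientation
#' are dropped.
#'
#' @param locus_seq character or DNAString, the locus sequence.
#' @param te_catalog named DNAStringSet (or named character) of family
#'   sequences.
#' @param min_match minimum exact match length, bp (default 25).
#' @return data.frame(start, end, family, orientation, te_start, te_end)
#'   with locus coordinates 1-based inclusive.
#' @export
te_homology_segments <- function(locus_seq, te_catalog, min_match = 25L) {
  locus <- toupper(as.character(locus_seq))
  stop_if_not_acgt(locus, "locus")
  fams <- as.character(te_catalog)
  names(fams) <- names(te_catalog)
  k <- as.integer(min_match)
  lb <- strsplit(locus, "")[[1]]
  n <- length(lb)
  if (n < k || length(fams) == 0) return(empty_segments())

  # hash every k-mer of the locus
  if (n - k + 1L <= 0) return(empty_segments())
  kmers <- substring(locus, 1:(n - k + 1L), k:n)
  index <- split(seq_along(kmers), kmers)

  out <- list()
  for (fam in names(fams)) {
    for (ori in c("+", "-")) {
      te <- if (ori == "+") fams[[fam]] else revcomp_chr(fams[[fam]])
      tb <- strsplit(te, "")[[1]]
      m <- length(tb)
      if (m < k) next
      seen <- character(0)
      for (j in 1:(m - k + 1L)) {
        km <- substr(te, j, j + k - 1L)
        pos <- index[[km]]
        if (is.null(pos)) next
        for (i in pos) {
          # extend the seed (locus i..i+k-1 == te j..j+k-1) maximally
          li <- i; tj <- j
          while (li > 1L && tj > 1L && lb[li - 1L] == tb[tj - 1L]) {
            li <- li - 1L; tj <- tj - 1L
          }
          re <- i + k - 1L; te_e <- j + k - 1L
          while (re < n && te_e < m && lb[re + 1L] == tb[te_e + 1L]) {
            re <- re + 1L; te_e <- te_e + 1L
          }
          key <- paste(li, re, tj, sep = ":")
          if (key %in% seen) next
          seen <- c(seen, key)
          out[[length(out) + 1L]] <- data.frame(
            start = li, end = re, family = fam, orientation = ori,
            te_start = if (ori == "+") tj else m - te_e + 1L,
            te_end = if (ori == "+") te_e else m - tj + 1L,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) return(empty_segments())
  seg <- unique(do.call(rbind, out))
  # drop intervals strictly nested in a longer match of same family/orientation
  keep <- rep(TRUE, nrow(seg))
  for (i in seq_len(nrow(seg))) {
    same <- seg$family == seg$family[i] & seg$orientation == seg$orientation[i]
    nested <- same & seg$start <= seg$start[i] & seg$end >= seg$end[i] &
      (seg$end - seg$start > seg$end[i] - seg$start[i])
    if (any(nested)) keep[i] <- FALSE
  }
  seg <- seg[keep, , drop = FALSE]
  rownames(seg) <- NULL
  seg[order(seg$start, seg$end, seg$family), , drop = FALSE]
}

empty_segments <- function() {
  data.frame(start = integer(0), end = integer(0), family = character(0),
             orientation = character(0), te_start = integer(0),
             te_end = integer(0), stringsAsFactors = FALSE)
}

#' Call siRNA-producing master loci
#'
#' Among candidate expressed loci, keeps those that are dual-strand
#' (strand bias at most `bias_cutoff`) and carry at least one exact
#' TE-homologous segment of `min_match` bp or more. Attaches the four
#' per-strand density tracks (all-mapping and unique-mapping per-base
#' coverage).
#'
#' @param expressed_loci GRanges (e.g. from [discover_expressed_loci()]).
#' @param alignments GRanges with `copies` and `n_hits` mcols.
#' @param te_catalog named DNAStringSet of TE family sequences.
#' @param genome DNAStringSet.
#' @param bias_cutoff dual-strand strand-bias cutoff (default 0.3).
#' @param min_match minimum TE homology match, bp.
#' @return list: `loci` (GRanges with mcols strand_bias, n_te_segments,
#'   te_families), `segments` (per-locus homology data.frames), `tracks`
#'   (per-locus list of 4 coverage vectors: plus_all, minus_all,
#'   plus_unique, minus_unique).
#' @export
call_master_loci <- function(expressed_loci, alignments, te_catalog, genome,
                             bias_cutoff = 0.3, min_match = 25L) {
  ids <- S4Vectors::mcols(expressed_loci)$id %||%
    sprintf("XL-%d", seq_along(expressed_loci))
  keep <- logical(length(expressed_loci))
  bias <- numeric(length(expressed_loci))
  segs <- vector("list", length(expressed_loci))
  tracks <- vector("list", length(expressed_loci))
  for (i in seq_along(expressed_loci)) {
    locus <- expressed_loci[i]
    bias[i] <- strand_bias(alignments, locus)
    seq <- extract_seq(genome, GenomicRanges::GRanges(
      GenomicRanges::seqnames(locus),
      IRanges::IRanges(GenomicRanges::start(locus), GenomicRanges::end(locus)),
      strand = "+"))
    segs[[i]] <- te_homology_segments(seq, te_catalog, min_match)
    tracks[[i]] <- density_tracks(locus, alignments)
    keep[i] <- !is.na(bias[i]) && bias[i] <= bias_cutoff && nrow(segs[[i]]) >= 1
  }
  out <- expressed_loci[keep]
  S4Vectors::mcols(out)$strand_bias <- bias[keep]
  S4Vectors::mcols(out)$n_te_segments <-
    vapply(segs[keep], nrow, integer(1))
  S4Vectors::mcols(out)$te_families <-
    vapply(segs[keep], function(s) paste(sort(unique(s$family)), collapse = ","),
           character(1))
  list(loci = out,
       segments = stats::setNames(segs[keep], ids[keep]),
       tracks = stats::setNames(tracks[keep], ids[keep]))
}

# The four Fig-style per-base coverage tracks over one locus.
density_tracks <- function(locus, alignments) {
  nh <- S4Vectors::mcols(alignments)$n_hits
  if (is.null(nh)) nh <- rep(1L, length(alignments))
  cov1 <- function(a, str) {
    a <- a[as.character(GenomicRanges::strand(a)) == str]
    s <- GenomicRanges::start(locus); e <- GenomicRanges::end(locus)
    cov <- numeric(e - s + 1L)
    a <- a[IRanges::overlapsAny(a, locus, ignore.strand = TRUE)]
    if (length(a)) {
      w <- aln_copies(a)
      st <- pmax(GenomicRanges::start(a), s) - s + 1L
      en <- pmin(GenomicRanges::end(a), e) - s + 1L
      for (k in seq_along(a)) cov[st[k]:en[k]] <- cov[st[k]:en[k]] + w[k]
    }
    cov
  }
  list(plus_all = cov1(alignments, "+"),
       minus_all = cov1(alignments, "-"),
       plus_unique = cov1(alignments[nh == 1], "+"),
       minus_unique = cov1(alignments[nh == 1], "-"))
}

#' Fraction of TE-mapped reads accounted for by master loci
#'
#' Copies-weighted fraction of reads whose full sequence occurs exactly
#' (either orientation) within any master-locus sequence. Invariant to read
#' order and to collapsing.
#'
#' @param te_reads collapsed-read data.frame (read_id, sequence, copies) or
#'   anything [collapse_reads()] accepts; must be non-empty.
#' @param master_seqs character vector / DNAStringSet of master-locus
#'   sequences.
#' @return fraction in [0, 1].
#' @export
te_read_accountability <- function(te_reads, master_seqs) {
  if (!is.data.frame(te_reads)) te_reads <- collapse_reads(te_reads)
  if (nrow(te_reads) == 0) stop("empty read set")
  masters <- toupper(as.character(master_seqs))
  hit <- vapply(te_reads$sequence, function(s) {
    rc <- revcomp_chr(s)
    any(vapply(masters, function(m) {
      grepl(s, m, fixed = TRUE) || grepl(rc, m, fixed = TRUE)
    }, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  sum(te_reads$copies[hit]) / sum(te_reads$copies)
}
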