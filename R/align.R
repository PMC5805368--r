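# Exact mapping of collapsed small-RNA reads, the multimap cap, genome
# segmentation, per-class read cleaning and expressed-locus discovery.

# Precedence used when annotations overlap: abundant structural ncRNA
# classes dominate contamination, so they win over genic/TE classes.
FEATURE_PRECEDENCE <- c("rRNA", "tRNA", "snRNA", "miRNA", "mRNA", "TE",
                        "master", "unknown")

#' Collapse reads to unique sequences
#'
#' @param reads character vector of read sequences, or a GRanges with a
#'   `sequence` mcol (e.g. from the simulators), or a DNAStringSet.
#' @return data.frame with read_id, sequence, copies (identical sequences
#'   summed).
#' @export
collapse_reads <- function(reads) {
  if (inherits(reads, "GRanges")) {
    seqs <- S4Vectors::mcols(reads)$sequence
    copies <- aln_copies(reads)
  } else if (inherits(reads, "DNAStringSet")) {
    seqs <- as.character(reads)
    copies <- rep(1L, length(seqs))
  } else {
    seqs <- as.character(reads)
    copies <- rep(1L, length(seqs))
  }
  agg <- tapply(copies, seqs, sum)
  data.frame(read_id = sprintf("read%06d", seq_along(agg)),
             sequence = names(agg),
             copies = as.integer(agg),
             stringsAsFactors = FALSE)
}

#' Map reads to a genome, capturing every exact occurrence
#'
#' Every exact occurrence of each read is reported: forward matches on the
#' plus strand and reverse-complement matches on the minus strand, across
#' all contigs. `n_hits` is the total genome-wide number of mapping events
#' of the read. Reads containing non-ACGT characters are skipped with a
#' warning; reads with zero occurrences are returned in `unmapped`.
#'
#' @param reads collapsed reads: a data.frame with columns `read_id`,
#'   `sequence`, `copies`, or anything [collapse_reads()] accepts.
#' @param genome DNAStringSet.
#' @return list: `alignments` (GRanges with mcols read_id, sequence, copies,
#'   n_hits), `unmapped` (data.frame of unmapped collapsed reads).
#' @export
map_reads_exact <- function(reads, genome) {
  if (!is.data.frame(reads)) reads <- collapse_reads(reads)
  stopifnot(all(c("read_id", "sequence", "copies") %in% names(reads)))
  bad <- grepl("[^ACGT]", reads$sequence)
  if (any(bad)) {
    warning(sprintf("skipping %d read(s) with non-ACGT characters", sum(bad)))
    reads <- reads[!bad, , drop = FALSE]
  }
  hits <- list()
  if (nrow(reads) > 0) {
    L <- nchar(reads$sequence)
    # one variable-width dictionary per orientation (trusted band = the
    # shortest read length; matchPDict verifies the remainder exactly)
    tb <- min(L)
    fwd <- Biostrings::PDict(Biostrings::DNAStringSet(reads$sequence),
                             tb.start = 1, tb.width = tb)
    rev <- Biostrings::PDict(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads$sequence)), tb.start = 1, tb.width = tb)
    for (chrom in names(genome)) {
      subj <- genome[[chrom]]
      for (str in c("+", "-")) {
        m <- Biostrings::matchPDict(if (str == "+") fwd else rev, subj)
        cnt <- S4Vectors::elementNROWS(m)
        if (sum(cnt) == 0) next
        idx <- rep(seq_along(cnt), cnt)
        st <- unlist(Biostrings::startIndex(m), use.names = FALSE)
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = chrom, start = st, end = st + L[idx] - 1L, strand = str,
          read_id = reads$read_id[idx], sequence = reads$sequence[idx],
          copies = reads$copies[idx], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    aln <- GenomicRanges::GRanges()
    S4Vectors::mcols(aln) <- S4Vectors::DataFrame(read_id = character(0),
                                                  sequence = character(0),
                                                  copies = integer(0),
                                                  n_hits = integer(0))
    return(list(alignments = aln, unmapped = reads))
  }
  df <- do.call(rbind, hits)
  nh <- table(df$read_id)
  df$n_hits <- as.integer(nh[df$read_id])
  aln <- GenomicRanges::GRanges(df$chrom,
                                IRanges::IRanges(df$start, df$end),
                                strand = df$strand,
                                read_id = df$read_id,
                                sequence = df$sequence,
                                copies = df$copies,
                                n_hits = df$n_hits)
  aln <- GenomicRanges::sort(aln, ignore.strand = TRUE)
  unmapped <- reads[!reads$read_id %in% df$read_id, , drop = FALSE]
  list(alignments = aln, unmapped = unmapped)
}

#' Remove reads with at least `max_hits` mapping events
#'
#' Keeps all mapping events of reads that map *fewer than* `max_hits` times;
#' every alignment of a read with `n_hits >= max_hits` is removed (a read
#' with exactly `max_hits` events is discarded).
#'
#' @param alignments GRanges from [map_reads_exact()].
#' @param max_hits mapping-event cap (default 100).
#' @return list: `kept`, `removed` (GRanges), `discarded_fraction`
#'   (copies-weighted fraction of mapped reads removed).
#' @export
cap_multimappers <- function(alignments, max_hits = 100L) {
  nh <- S4Vectors::mcols(alignments)$n_hits
  if (is.null(nh)) stop("alignments lack an n_hits mcol")
  keep <- nh < max_hits
  per_read <- function(a) {
    if (length(a) == 0) return(0)
    first <- !duplicated(S4Vectors::mcols(a)$read_id)
    sum(aln_copies(a)[first])
  }
  tot <- per_read(alignments)
  disc <- per_read(alignments[!keep])
  list(kept = alignments[keep],
       removed = alignments[!keep],
       discarded_fraction = if (tot > 0) disc / tot else 0)
}

#' Label alignments by the feature class they overlap
#'
#' An alignment overlapping an annotated locus by at least 1 bp (either
#' strand) takes that locus's class; overlaps with several classes are
#' resolved by the fixed precedence rRNA > tRNA > snRNA > miRNA > mRNA >
#' TE > master > unknown, and ties within a class go to the leftmost locus.
#' Alignments outside all annotation are labelled "intergenic".
#'
#' @param alignments GRanges.
#' @param annotation GRanges with mcols `feature_class` and `id`.
#' @return `alignments` with mcols `feature_class` and `locus_id` added.
#' @export
assign_to_features <- function(alignments, annotation) {
  cls <- S4Vectors::mcols(annotation)$feature_class
  prec <- match(cls, FEATURE_PRECEDENCE)
  prec[is.na(prec)] <- length(FEATURE_PRECEDENCE) + 1L
  ov <- GenomicRanges::findOverlaps(alignments, annotation, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  # order candidate loci by precedence, then start, then id; first wins
  o <- order(qh, prec[sh], GenomicRanges::start(annotation)[sh],
             S4Vectors::mcols(annotation)$id[sh])
  qh <- qh[o]; sh <- sh[o]
  firsts <- !duplicated(qh)
  label <- rep("intergenic", length(alignments))
  locus <- rep(NA_character_, length(alignments))
  label[qh[firsts]] <- cls[sh[firsts]]
  locus[qh[firsts]] <- S4Vectors::mcols(annotation)$id[sh[firsts]]
  S4Vectors::mcols(alignments)$feature_class <- label
  S4Vectors::mcols(alignments)$locus_id <- locus
  alignments
}

#' Clean a read set down to one target feature class
#'
#' Re-maps the reads and keeps only those none of whose mapping events fall
#' in an annotated non-target class: reads mapping exclusively to
#' `target_class` loci and/or intergenic space survive. Unmapped reads are
#' removed.
#'
#' @param reads collapsed reads (see [map_reads_exact()]).
#' @param genome DNAStringSet.
#' @param annotation GRanges annotation.
#' @param target_class one of the feature-class vocabulary.
#' @return collapsed-read data.frame subset.
#' @export
clean_by_feature <- function(reads, genome, annotation, target_class) {
  if (!is.data.frame(reads)) reads <- collapse_reads(reads)
  if (!target_class %in% FEATURE_PRECEDENCE) {
    stop(sprintf("unknown target_class '%s'", target_class))
  }
  res <- map_reads_exact(reads, genome)
  aln <- assign_to_features(res$alignments, annotation)
  fc <- S4Vectors::mcols(aln)$feature_class
  offender <- !(fc %in% c(target_class, "intergenic"))
  bad_reads <- unique(S4Vectors::mcols(aln)$read_id[offender])
  mapped <- unique(S4Vectors::mcols(aln)$read_id)
  keep <- reads$read_id %in% setdiff(mapped, bad_reads)
  reads[keep, , drop = FALSE]
}

#' Discover expressed small-RNA loci outside the annotation
#'
#' Merges the footprints of alignments that do not touch any annotated
#' feature (gap up to `merge_gap` bp bridged) and keeps merged islands whose
#' copies-weighted read count exceeds `min_reads` (strictly) and whose span
#' exceeds `min_len` bp (strictly).
#'
#' @param alignments GRanges with `copies` mcol.
#' @param annotation GRanges of prior annotation.
#' @param min_reads strict lower bound on copies-weighted read count.
#' @param min_len strict lower bound on locus span, bp.
#' @param merge_gap largest gap (bp) bridged when merging footprints.
#' @return GRanges of loci, mcols: feature_class = "unknown", id ("XL-n"),
#'   read_count.
#' @export
discover_expressed_loci <- function(alignments, annotation,
                                    min_reads = 1000L, min_len = 200L,
                                    merge_gap = 50L) {
  outside <- alignments[!IRanges::overlapsAny(alignments, annotation,
                                              ignore.strand = TRUE)]
  if (length(outside) == 0) return(empty_locus_granges())
  cand <- GenomicRanges::reduce(outside, min.gapwidth = merge_gap + 1L,
                                ignore.strand = TRUE)
  cand <- GenomicRanges::setdiff(cand, annotation, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(outside, cand, ignore.strand = TRUE)
  cnt <- numeric(length(cand))
  tab <- tapply(aln_copies(outside)[S4Vectors::queryHits(ov)],
                S4Vectors::subjectHits(ov), sum)
  cnt[as.integer(names(tab))] <- tab
  keep <- cnt > min_reads & GenomicRanges::width(cand) > min_len
  out <- cand[keep]
  if (length(out) == 0) return(empty_locus_granges())
  S4Vectors::mcols(out)$feature_class <- rep("unknown", length(out))
  S4Vectors::mcols(out)$id <- sprintf("XL-%d", seq_along(out))
  S4Vectors::mcols(out)$read_count <- cnt[keep]
  out
}

empty_locus_granges <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(feature_class = character(0),
                                               id = character(0),
                                               read_count = numeric(0))
  gr
}
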