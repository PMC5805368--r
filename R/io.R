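# On-disk formats: FASTA (genome, collapsed reads), BED6 (annotation, loci,
# alignments), SAM (alignments with NH tag), TSV (methylation calls,
# 0-based positions on disk). Internals are 1-based closed (GRanges);
# conversion happens here and only here.

#' Write / read a genome FASTA
#' @param genome DNAStringSet
#' @param path file path
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write collapsed reads as FASTA with `id_xCOUNT` headers
#'
#' @param reads collapsed-read data.frame (read_id, sequence, copies) or
#'   anything [collapse_reads()] accepts.
#' @param path file path.
#' @export
write_reads_fasta <- function(reads, path) {
  if (!is.data.frame(reads)) reads <- collapse_reads(reads)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- sprintf("%s_x%d", reads$read_id, reads$copies)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read collapsed reads from FASTA (or plain FASTQ)
#'
#' Copy counts are parsed from a trailing `_xCOUNT` in the header (1 when
#' absent); FASTQ qualities are ignored.
#'
#' @param path file path.
#' @param format "fasta" or "fastq".
#' @return collapsed-read data.frame (read_id, sequence, copies).
#' @export
read_reads_fasta <- function(path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::readDNAStringSet(path, format = format)
  hdr <- sub("\\s.*$", "", names(x))
  has_cnt <- grepl("_x\\d+$", hdr)
  copies <- rep(1L, length(x))
  copies[has_cnt] <- as.integer(sub("^.*_x(\\d+)$", "\\1", hdr[has_cnt]))
  ids <- sub("_x\\d+$", "", hdr)
  df <- data.frame(read_id = ids, sequence = as.character(x),
                   copies = copies, stringsAsFactors = FALSE)
  # re-collapse in case the file repeats sequences
  agg <- tapply(df$copies, df$sequence, sum)
  data.frame(read_id = sprintf("read%06d", seq_along(agg)),
             sequence = names(agg), copies = as.integer(agg),
             stringsAsFactors = FALSE)
}

#' Write an annotation (or locus set) as BED6
#'
#' Name field is `id|feature_class`; score is the read_count mcol when
#' present, else 0.
#' @param annotation GRanges with mcols id, feature_class.
#' @param path file path.
#' @export
write_annotation_bed <- function(annotation, path) {
  gr <- annotation
  mc <- S4Vectors::mcols(gr)
  S4Vectors::mcols(gr) <- NULL
  GenomicRanges::strand(gr)[GenomicRanges::strand(gr) == "*"] <- "*"
  S4Vectors::mcols(gr)$name <- paste0(mc$id %||% seq_along(gr), "|",
                                      mc$feature_class %||% "unknown")
  S4Vectors::mcols(gr)$score <- as.numeric(mc$read_count %||% rep(0, length(gr)))
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' @rdname write_annotation_bed
#' @export
read_annotation_bed <- function(path) {
  gr <- rtracklayer::import.bed(path)
  nm <- S4Vectors::mcols(gr)$name
  parts <- strsplit(nm %||% rep("", length(gr)), "|", fixed = TRUE)
  S4Vectors::mcols(gr)$id <- vapply(parts, function(p) p[1] %||% NA_character_,
                                    character(1))
  S4Vectors::mcols(gr)$feature_class <-
    vapply(parts, function(p) if (length(p) > 1) p[2] else "unknown",
           character(1))
  gr
}

#' Write alignments as BED6 (score column = copies)
#' @param alignments GRanges with read_id/copies mcols.
#' @param path file path.
#' @export
write_alignments_bed <- function(alignments, path) {
  gr <- alignments
  mc <- S4Vectors::mcols(gr)
  S4Vectors::mcols(gr) <- NULL
  S4Vectors::mcols(gr)$name <- mc$read_id
  S4Vectors::mcols(gr)$score <- as.numeric(mc$copies)
  rtracklayer::export.bed(gr, path)
  invisible(path)
}

#' Read alignments from BED6 written by [write_alignments_bed()]
#'
#' Sequences and n_hits are reconstructed from the genome when given.
#' @param path file path.
#' @param genome optional DNAStringSet for sequence reconstruction.
#' @export
read_alignments_bed <- function(path, genome = NULL) {
  gr <- rtracklayer::import.bed(path)
  S4Vectors::mcols(gr)$read_id <- S4Vectors::mcols(gr)$name
  S4Vectors::mcols(gr)$copies <- as.integer(S4Vectors::mcols(gr)$score)
  S4Vectors::mcols(gr)$name <- NULL
  S4Vectors::mcols(gr)$score <- NULL
  nh <- table(S4Vectors::mcols(gr)$read_id)
  S4Vectors::mcols(gr)$n_hits <- as.integer(nh[S4Vectors::mcols(gr)$read_id])
  if (!is.null(genome)) S4Vectors::mcols(gr)$sequence <- extract_seq(genome, gr)
  gr
}

#' Write alignments as SAM with an NH tag
#'
#' Minimal single-end SAM: FLAG 0/16, MAPQ 255, full-match CIGAR, constant
#' 'I' qualities, NH = n_hits.
#' @param alignments GRanges.
#' @param genome DNAStringSet (for the header @SQ lines).
#' @param path file path.
#' @export
write_alignments_sam <- function(alignments, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  for (chrom in names(genome)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", chrom, length(genome[[chrom]])), con)
  }
  if (length(alignments)) {
    minus <- as.character(GenomicRanges::strand(alignments)) == "-"
    seqs <- S4Vectors::mcols(alignments)$sequence
    # SAM stores the plus-strand sequence
    seqs[minus] <- revcomp_chr(seqs[minus])
    lines <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNH:i:%d",
                     S4Vectors::mcols(alignments)$read_id,
                     ifelse(minus, 16L, 0L),
                     as.character(GenomicRanges::seqnames(alignments)),
                     GenomicRanges::start(alignments),
                     aln_lengths(alignments), seqs,
                     strrep("I", aln_lengths(alignments)),
                     S4Vectors::mcols(alignments)$n_hits)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a SAM file written by [write_alignments_sam()]
#' @param path file path.
#' @param copies optional named vector (read_id -> copies), default 1.
#' @export
read_alignments_sam <- function(path, copies = NULL) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0) {
    return(map_reads_exact(data.frame(read_id = character(0),
                                      sequence = character(0),
                                      copies = integer(0)),
                           Biostrings::DNAStringSet())$alignments)
  }
  f <- strsplit(lines, "\t")
  read_id <- vapply(f, `[[`, character(1), 1)
  flag <- as.integer(vapply(f, `[[`, character(1), 2))
  chrom <- vapply(f, `[[`, character(1), 3)
  start <- as.integer(vapply(f, `[[`, character(1), 4))
  seq <- vapply(f, `[[`, character(1), 10)
  nh <- vapply(f, function(x) {
    tag <- grep("^NH:i:", x, value = TRUE)
    if (length(tag)) as.integer(sub("^NH:i:", "", tag[1])) else NA_integer_
  }, integer(1))
  minus <- bitwAnd(flag, 16L) > 0
  rdseq <- seq
  rdseq[minus] <- revcomp_chr(seq[minus])
  cp <- if (is.null(copies)) rep(1L, length(read_id)) else
    as.integer(copies[read_id])
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start, start + nchar(seq) - 1L),
                               strand = ifelse(minus, "-", "+"),
                               read_id = read_id, sequence = rdseq,
                               copies = cp, n_hits = nh)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Write / read per-cytosine methylation calls as TSV
#'
#' On disk the position column is 0-based (chrom, pos, strand, context,
#' n_meth, n_unmeth); in memory positions are 1-based.
#' @param calls data.frame with 1-based `pos`.
#' @param path file path.
#' @export
write_methyl_tsv <- function(calls, path) {
  out <- data.frame(chrom = calls$chrom, pos = calls$pos - 1L,
                    strand = calls$strand, context = calls$context,
                    n_meth = calls$n_meth, n_unmeth = calls$n_unmeth)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_methyl_tsv
#' @export
read_methyl_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  df$pos <- df$pos + 1L
  df
}

#' Write a signature matrix as TSV (rows = overlaps, columns = sizes)
#' @param m matrix from [signature_matrix()].
#' @param path file path.
#' @export
write_signature_tsv <- function(m, path) {
  df <- data.frame(overlap = seq_len(nrow(m)), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
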