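# Assembly decontamination: per-contig matched fraction against a foreign
# sequence hit table, the >10% discard rule, and summary statistics (N50).

#' Per-contig hit set
#'
#' @param contig_id contig name.
#' @param contig_length contig length, bp.
#' @param starts,ends hit intervals, 1-based inclusive, within the contig.
#' @return object of class `contig_hits`.
#' @export
contig_hits <- function(contig_id, contig_length, starts = integer(0),
                        ends = integer(0)) {
  stopifnot(length(starts) == length(ends))
  if (length(starts) && (any(starts < 1) || any(ends > contig_length) ||
                         any(starts > ends))) {
    stop(sprintf("hit interval out of bounds for contig %s (length %d)",
                 contig_id, contig_length))
  }
  structure(list(contig_id = as.character(contig_id),
                 contig_length = as.integer(contig_length),
                 hits = IRanges::IRanges(start = as.integer(starts),
                                         end = as.integer(ends))),
            class = "contig_hits")
}

#' Matched fraction of a contig
#'
#' Length of the union of the hit intervals divided by the contig length.
#' Overlapping hits are merged (union, never summed), so the fraction is
#' bounded by 1. Set `union_hits = FALSE` to sum raw hit lengths instead.
#'
#' @param hitset a [contig_hits()] object.
#' @param union_hits merge overlapping hits before measuring (default TRUE).
#' @return fraction in [0, 1] (can exceed 1 only when `union_hits = FALSE`).
#' @export
matched_fraction <- function(hitset, union_hits = TRUE) {
  stopifnot(inherits(hitset, "contig_hits"))
  if (length(hitset$hits) == 0) return(0)
  covered <- if (union_hits) {
    sum(IRanges::width(IRanges::reduce(hitset$hits)))
  } else {
    sum(IRanges::width(hitset$hits))
  }
  covered / hitset$contig_length
}

#' Discard contigs with more than `threshold` foreign-matched fraction
#'
#' A contig is discarded iff its matched fraction strictly exceeds the
#' threshold (a contig matched over exactly 10% of its length is kept at
#' the default). Monotone in `threshold`: the kept set only grows as the
#' threshold rises.
#'
#' @param hitsets list of [contig_hits()] objects.
#' @param threshold matched-fraction cutoff (default 0.10).
#' @param union_hits see [matched_fraction()].
#' @return list: `kept`, `discarded` (character ids), `fractions`
#'   (data.frame contig_id, contig_length, matched_fraction, discarded).
#' @export
filter_contaminated <- function(hitsets, threshold = 0.10, union_hits = TRUE) {
  if (length(hitsets) == 0) {
    return(list(kept = character(0), discarded = character(0),
                fractions = data.frame(contig_id = character(0),
                                       contig_length = integer(0),
                                       matched_fraction = numeric(0),
                                       discarded = logical(0))))
  }
  fr <- vapply(hitsets, matched_fraction, numeric(1), union_hits = union_hits)
  ids <- vapply(hitsets, `[[`, character(1), "contig_id")
  lens <- vapply(hitsets, `[[`, integer(1), "contig_length")
  disc <- fr > threshold
  list(kept = ids[!disc], discarded = ids[disc],
       fractions = data.frame(contig_id = ids, contig_length = lens,
                              matched_fraction = fr, discarded = disc,
                              stringsAsFactors = FALSE))
}

#' Assembly summary statistics
#'
#' N50 is the largest contig length L such that contigs of length >= L sum
#' to at least half the total assembly size (descending cumulative sum).
#'
#' @param lengths positive integer contig lengths.
#' @return list(n_contigs, total_bp, n50).
#' @export
assembly_stats <- function(lengths) {
  if (length(lengths) == 0) stop("no contig lengths supplied")
  if (any(lengths <= 0)) stop("contig lengths must be positive")
  lens <- sort(as.numeric(lengths), decreasing = TRUE)
  csum <- cumsum(lens)
  n50 <- lens[which(csum >= sum(lens) / 2)[1]]
  list(n_contigs = length(lens), total_bp = sum(lens), n50 = n50)
}

#' Read a BLAST outfmt-6-like hit table into per-contig hit sets
#'
#' Expects at least columns qseqid, qstart, qend (1-based inclusive; start
#' and end swapped when reversed). Contigs without hits still get an (empty)
#' hit set from `contig_lengths`.
#'
#' @param path TSV path (no header: qseqid qstart qend in the first three
#'   columns, extra columns ignored) or a data.frame with those names.
#' @param contig_lengths named vector of contig lengths.
#' @return list of [contig_hits()] objects, one per contig in
#'   `contig_lengths`.
#' @export
read_blast_hits <- function(path, contig_lengths) {
  if (is.data.frame(path)) {
    df <- path
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    names(df)[1:3] <- c("qseqid", "qstart", "qend")
  }
  lo <- pmin(df$qstart, df$qend)
  hi <- pmax(df$qstart, df$qend)
  lapply(stats::setNames(names(contig_lengths), names(contig_lengths)),
         function(id) {
    sel <- df$qseqid == id
    contig_hits(id, contig_lengths[[id]], lo[sel], hi[sel])
  })
}
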