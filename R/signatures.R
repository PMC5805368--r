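# 5'-overlap pair-count signatures and z-scores: the statistic that
# distinguishes ping-pong slicing (10-nt 5' overlap) from Dicer duplex
# processing (overlap = read length - 2, i.e. a 2-nt 3' overhang).

#' Build per-stratum 5'-end count profiles
#'
#' For every (chrom, strand, read length) stratum, a copies-weighted count
#' of read 5' ends per genomic position. The 5' end of a minus-strand read
#' is its rightmost base.
#'
#' @param alignments GRanges with `copies` mcol (and `sequence` optional).
#' @param size_range inclusive read-length window kept (default 18..30).
#' @return object of class `five_prime_profile`: data.frame(chrom, strand,
#'   length, pos, count).
#' @export
build_profiles <- function(alignments, size_range = c(18L, 30L)) {
  len <- aln_lengths(alignments)
  keep <- len >= size_range[1] & len <= size_range[2]
  a <- alignments[keep]
  if (length(a) == 0) {
    out <- data.frame(chrom = character(0), strand = character(0),
                      length = integer(0), pos = integer(0), count = numeric(0))
    class(out) <- c("five_prime_profile", "data.frame")
    return(out)
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(a)),
                   strand = as.character(GenomicRanges::strand(a)),
                   length = aln_lengths(a),
                   pos = five_prime_pos(a),
                   count = aln_copies(a),
                   stringsAsFactors = FALSE)
  agg <- stats::aggregate(count ~ chrom + strand + length + pos, df, sum)
  agg <- agg[order(agg$chrom, agg$strand, agg$length, agg$pos), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("five_prime_profile", "data.frame")
  agg
}

#' Count plus/minus read pairs per 5'-overlap length
#'
#' For overlap o in 1..`o_max`, sums over chromosomes and positions the
#' product of plus-strand 5'-end counts at p (length L1) and minus-strand
#' 5'-end counts at p + o - 1 (length L2); pairs are counted on
#' copies-weighted 5'-end counts and do not require the reads to span the
#' overlap physically. `L1 = L2 = "all"` pools counts over all sizes, so
#' every (L1, L2) size combination is counted once.
#'
#' @param profile a [build_profiles()] result.
#' @param L1,L2 plus-/minus-strand read lengths, or "all".
#' @param o_max largest overlap considered (default 30).
#' @return object of class `overlap_signature`: list(size_pair, o, Z, z,
#'   defined).
#' @export
overlap_pair_counts <- function(profile, L1 = "all", L2 = "all", o_max = 30L) {
  plus <- profile[profile$strand == "+" &
                    (identical(L1, "all") | profile$length == L1), , drop = FALSE]
  minus <- profile[profile$strand == "-" &
                     (identical(L2, "all") | profile$length == L2), , drop = FALSE]
  # pool strata of the same position (sizes and, for "all", lengths)
  Z <- numeric(o_max)
  if (nrow(plus) > 0 && nrow(minus) > 0) {
    pk <- stats::aggregate(count ~ chrom + pos, plus, sum)
    mk <- stats::aggregate(count ~ chrom + pos, minus, sum)
    mcount <- stats::setNames(mk$count, paste(mk$chrom, mk$pos))
    for (o in seq_len(o_max)) {
      key <- paste(pk$chrom, pk$pos + o - 1L)
      hit <- mcount[key]
      hit[is.na(hit)] <- 0
      Z[o] <- sum(pk$count * hit)
    }
  }
  structure(list(size_pair = c(as.character(L1), as.character(L2)),
                 o = seq_len(o_max), Z = Z, z = rep(NA_real_, o_max),
                 defined = NA),
            class = "overlap_signature")
}

#' Standardize an overlap signature to z-scores
#'
#' z(o) = (Z(o) - mean) / SD over the overlap window, with the population
#' SD (fixed descriptive window). A window with zero variance (e.g. no
#' overlapping pairs at all) is flagged `defined = FALSE` and rendered
#' blank.
#'
#' @param signature an [overlap_pair_counts()] result.
#' @return the signature with `z` and `defined` filled.
#' @export
zscore <- function(signature) {
  stopifnot(inherits(signature, "overlap_signature"))
  Z <- signature$Z
  mu <- mean(Z)
  sigma <- sqrt(mean((Z - mu)^2))
  if (sigma == 0) {
    signature$z <- rep(NA_real_, length(Z))
    signature$defined <- FALSE
  } else {
    signature$z <- (Z - mu) / sigma
    signature$defined <- TRUE
  }
  signature
}

#' Convert a size-matched overlap signature to an overhang signature
#'
#' For size-matched pairs of length L, the 3' overhang is h = L - o. The
#' value at overhang h equals the source value at overlap o = L - h; the
#' transposition preserves total mass.
#'
#' @param signature size-matched (`L1 == L2`, numeric) overlap signature.
#' @param positive_only clamp z-scores below 0 to 0 in the report.
#' @return object of class `overhang_signature`: list(L, h, Z, z, defined).
#' @export
overhang_signature <- function(signature, positive_only = FALSE) {
  stopifnot(inherits(signature, "overlap_signature"))
  sp <- suppressWarnings(as.numeric(signature$size_pair))
  if (any(is.na(sp)) || sp[1] != sp[2]) {
    stop("overhang conversion requires a size-matched (L, L) signature")
  }
  L <- sp[1]
  h <- L - signature$o
  z <- signature$z
  if (positive_only && isTRUE(signature$defined)) z <- pmax(z, 0)
  structure(list(L = L, h = h, Z = signature$Z, z = z,
                 defined = signature$defined),
            class = "overhang_signature")
}

#' Overlap z-score matrix across read sizes
#'
#' One column per size-matched pair (18/18 .. 30/30) plus an "all" column
#' pooling every size combination; rows are overlaps 1..`o_max`. Undefined
#' (zero-variance) columns are NA ("blank").
#'
#' @param alignments GRanges.
#' @param sizes read sizes (default 18:30).
#' @param o_max overlap window.
#' @return numeric matrix `o_max` x (length(sizes) + 1), with an attribute
#'   `argmax` (per-column argmax overlap, ties to the smallest; NA when
#'   undefined).
#' @export
signature_matrix <- function(alignments, sizes = READ_SIZES, o_max = 30L) {
  profile <- build_profiles(alignments,
                            size_range = range(c(sizes, READ_SIZES)))
  cols <- c(as.character(sizes), "all")
  m <- matrix(NA_real_, nrow = o_max, ncol = length(cols),
              dimnames = list(overlap = seq_len(o_max), size = cols))
  for (L in sizes) {
    sig <- zscore(overlap_pair_counts(profile, L, L, o_max))
    if (isTRUE(sig$defined)) m[, as.character(L)] <- sig$z
  }
  sig_all <- zscore(overlap_pair_counts(profile, "all", "all", o_max))
  if (isTRUE(sig_all$defined)) m[, "all"] <- sig_all$z
  attr(m, "argmax") <- apply(m, 2, function(col) {
    if (all(is.na(col))) NA_integer_ else which.max(col)  # ties -> smallest o
  })
  m
}

#' Per-locus signature matrices and read accumulation
#'
#' Restricts [signature_matrix()] to the alignments overlapping each locus
#' and reports per-locus log2 copies-weighted read accumulation per size.
#'
#' @param alignments GRanges.
#' @param loci GRanges with an `id` mcol.
#' @param sizes read sizes.
#' @param o_max overlap window.
#' @return named list per locus: `matrix` (all-NA "blank" when the locus has
#'   no reads), `log2_reads_per_size` (log2 of copies-weighted count + 0 for
#'   empty sizes as -Inf).
#' @export
per_locus_signatures <- function(alignments, loci, sizes = READ_SIZES,
                                 o_max = 30L) {
  ids <- S4Vectors::mcols(loci)$id %||% sprintf("locus%d", seq_along(loci))
  out <- lapply(seq_along(loci), function(i) {
    a <- alignments[IRanges::overlapsAny(alignments, loci[i],
                                         ignore.strand = TRUE)]
    m <- signature_matrix(a, sizes = sizes, o_max = o_max)
    cnt <- vapply(sizes, function(L) sum(aln_copies(a)[aln_lengths(a) == L]),
                  numeric(1))
    list(matrix = m,
         log2_reads_per_size = stats::setNames(log2(cnt), sizes))
  })
  stats::setNames(out, ids)
}

#' Averaged size-matched overhang signature of unique alignments
#'
#' For each size pair 18/18 .. 28/28 computes the overlap z-score signature
#' of uniquely mapping reads (n_hits == 1), converts it to overhang space
#' (h = L - o) and averages the curves across sizes at each overhang.
#'
#' @param alignments GRanges with `n_hits` mcol.
#' @param loci optional GRanges restriction.
#' @param sizes size pairs averaged (default 18:28).
#' @param h_range overhang window reported (default 0:12).
#' @param o_max overlap window used per size.
#' @return data.frame(h, mean_z, n_sizes) with attribute `argmax` (overhang
#'   with maximal mean z; ties to the smallest h).
#' @export
averaged_overhang <- function(alignments, loci = NULL, sizes = 18:28,
                              h_range = 0:12, o_max = 30L) {
  nh <- S4Vectors::mcols(alignments)$n_hits
  if (is.null(nh)) stop("alignments lack an n_hits mcol")
  a <- alignments[nh == 1]
  if (!is.null(loci)) {
    a <- a[IRanges::overlapsAny(a, loci, ignore.strand = TRUE)]
  }
  if (length(a) == 0) stop("empty input: no uniquely mapping alignments")
  profile <- build_profiles(a)
  curves <- matrix(NA_real_, nrow = length(h_range), ncol = length(sizes),
                   dimnames = list(h = h_range, size = sizes))
  for (j in seq_along(sizes)) {
    L <- sizes[j]
    sig <- zscore(overlap_pair_counts(profile, L, L, o_max))
    if (!isTRUE(sig$defined)) next
    o_needed <- L - h_range
    ok <- o_needed >= 1 & o_needed <= o_max
    curves[ok, j] <- sig$z[o_needed[ok]]
  }
  mean_z <- rowMeans(curves, na.rm = TRUE)
  n_sizes <- rowSums(!is.na(curves))
  mean_z[n_sizes == 0] <- NA_real_
  out <- data.frame(h = h_range, mean_z = mean_z, n_sizes = n_sizes)
  if (all(is.na(out$mean_z))) {
    attr(out, "argmax") <- NA_integer_
  } else {
    attr(out, "argmax") <- out$h[which.max(out$mean_z)]
  }
  out
}
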