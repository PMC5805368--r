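# Per-context cytosine methylation accounting with the >4-read coverage
# filter, feature-class breakdown and context validation.

METHYL_CONTEXTS <- c("CG", "CHG", "CHH")

#' Filter methylation calls by read coverage
#'
#' Retains calls whose coverage exceeds `min_reads` strictly (default:
#' coverage > 4, i.e. at least 5 reads); `strict_greater = FALSE` relaxes
#' the bound to >=. Idempotent and monotone in `min_reads`.
#'
#' @param calls data.frame with columns n_meth and n_unmeth (coverage is
#'   their sum; a `coverage` column is recomputed if absent).
#' @param min_reads coverage bound (default 4).
#' @param strict_greater strict (>) vs inclusive (>=) comparison.
#' @return filtered data.frame.
#' @export
filter_coverage <- function(calls, min_reads = 4L, strict_greater = TRUE) {
  cov <- calls$n_meth + calls$n_unmeth
  keep <- if (strict_greater) cov > min_reads else cov >= min_reads
  calls[keep, , drop = FALSE]
}

#' Per-context methylation rates, globally and per feature class
#'
#' rate = 100 * sum(n_meth) / sum(coverage) per (context x class), pooled
#' over sites (coverage-weighted), plus a "genome" class over all calls and
#' an "all" context over all contexts. Classes come from overlapping call
#' positions with a BED-style annotation; a class with zero covered
#' cytosines in a context yields NA. Denominators report both covered-C
#' counts and total call rows.
#'
#' @param calls data.frame (chrom, pos 1-based, strand, context, n_meth,
#'   n_unmeth), normally already through [filter_coverage()].
#' @param annotation optional GRanges with mcols feature_class.
#' @return data.frame(feature_class, context, rate_percent, n_sites,
#'   n_meth, coverage).
#' @export
context_rates <- function(calls, annotation = NULL) {
  calls$coverage <- calls$n_meth + calls$n_unmeth
  calls$feature_class <- "genome"
  tabs <- list(calls)
  if (!is.null(annotation) && length(annotation) > 0) {
    pos <- GenomicRanges::GRanges(calls$chrom,
                                  IRanges::IRanges(calls$pos, calls$pos))
    ov <- GenomicRanges::findOverlaps(pos, annotation, ignore.strand = TRUE)
    cls <- S4Vectors::mcols(annotation)$feature_class
    hit <- calls[S4Vectors::queryHits(ov), , drop = FALSE]
    hit$feature_class <- cls[S4Vectors::subjectHits(ov)]
    tabs[[2]] <- hit
  }
  all_calls <- do.call(rbind, tabs)
  one <- function(d, cls, ctx) {
    data.frame(feature_class = cls, context = ctx,
               rate_percent = if (nrow(d) == 0 || sum(d$coverage) == 0) NA_real_
                              else 100 * sum(d$n_meth) / sum(d$coverage),
               n_sites = nrow(d), n_meth = sum(d$n_meth),
               coverage = sum(d$coverage), stringsAsFactors = FALSE)
  }
  out <- list()
  for (cls in unique(all_calls$feature_class)) {
    dc <- all_calls[all_calls$feature_class == cls, , drop = FALSE]
    for (ctx in METHYL_CONTEXTS) {
      out[[length(out) + 1L]] <- one(dc[dc$context == ctx, , drop = FALSE], cls, ctx)
    }
    out[[length(out) + 1L]] <- one(dc, cls, "all")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate cytosine positions with their trinucleotide context
#'
#' CG if the next base (on the cytosine's strand) is G; CHG if the pattern
#' is C-H-G; otherwise CHH (H = A, C or T). Minus-strand positions are
#' evaluated on the reverse complement. Positions that are not a C on the
#' stated strand raise an error listing the offending records.
#'
#' @param genome DNAStringSet.
#' @param positions data.frame(chrom, pos 1-based, strand).
#' @return character vector of contexts.
#' @export
context_annotate <- function(genome, positions) {
  out <- character(nrow(positions))
  bad <- integer(0)
  for (chrom in unique(positions$chrom)) {
    idx <- which(positions$chrom == chrom)
    b <- strsplit(as.character(genome[[chrom]]), "")[[1]]
    n <- length(b)
    p <- positions$pos[idx]
    minus <- positions$strand[idx] == "-"
    base <- b[p]
    is_c <- ifelse(minus, base == "G", base == "C")
    bad <- c(bad, idx[!is_c])
    out[idx[!minus & is_c]] <-
      context_from_bases(b, p[!minus & is_c], n, minus_strand = FALSE)
    out[idx[minus & is_c]] <-
      context_from_bases(b, p[minus & is_c], n, minus_strand = TRUE)
  }
  if (length(bad)) {
    stop(sprintf("position(s) not a C on the stated strand: %s",
                 paste(utils::head(paste0(positions$chrom[bad], ":",
                                          positions$pos[bad],
                                          positions$strand[bad]), 10),
                       collapse = ", ")))
  }
  out
}
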