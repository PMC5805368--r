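#' Simulate a toy genome with TE families, a master locus and annotations
#'
#' Builds a single-contig genome hosting: dispersed copies of each TE family
#' consensus (random strand), a dual-strand "master" locus assembled from
#' exact fragments (>= 25 bp) of every TE family in mixed orientations, mRNA
#' loci and structural ncRNA loci (rRNA/tRNA/snRNA). Features never overlap
#' and are separated by at least `min_gap` bp of random background.
#'
#' @param config a [sim_config()] object.
#' @param min_gap minimum background gap between planted features, bp.
#' @return list with elements:
#'   * `genome`: [Biostrings::DNAStringSet] (one contig, `chr1`)
#'   * `annotation`: [GenomicRanges::GRanges] with mcols `feature_class`
#'     (TE/mRNA/rRNA/tRNA/snRNA/master), `id`, `family` (TEs only)
#'   * `te_catalog`: [Biostrings::DNAStringSet] of family consensi
#'   * `truth`: list with the planted master-locus range and the exact
#'     fragment composition of the master locus
#' @export
simulate_genome <- function(config, min_gap = 100L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  nf <- config$n_te_families
  te_catalog <- Biostrings::DNAStringSet(
    stats::setNames(vapply(seq_len(max(nf, 0)), function(i) random_dna(config$te_length),
                           character(1)),
                    if (nf > 0) paste0("fam", seq_len(nf)) else character(0)))

  master <- build_master_sequence(te_catalog, config$master_locus_length)

  feats <- list()
  add <- function(class, id, seq, strand, family = NA_character_) {
    feats[[length(feats) + 1L]] <<- list(class = class, id = id, seq = seq,
                                         strand = strand, family = family)
  }
  if (nf > 0) {
    for (i in seq_len(nf)) {
      cons <- as.character(te_catalog[[i]])
      for (j in seq_len(config$te_copies)) {
        strand <- sample(c("+", "-"), 1)
        seq <- if (strand == "-") revcomp_chr(cons) else cons
        add("TE", sprintf("TE_fam%d_c%d", i, j), seq, strand, names(te_catalog)[i])
      }
    }
  }
  add("master", "ML-1", master$seq, "*")
  for (i in seq_len(config$n_mrna)) {
    add("mRNA", sprintf("mRNA_%d", i), random_dna(config$mrna_length),
        sample(c("+", "-"), 1))
  }
  for (cls in c("rRNA", "tRNA", "snRNA")) {
    n <- switch(cls, rRNA = config$n_rrna, tRNA = config$n_trna, snRNA = config$n_snrna)
    for (i in seq_len(n)) {
      add(cls, sprintf("%s_%d", cls, i), random_dna(config$ncrna_length), "+")
    }
  }

  feats <- feats[sample(length(feats))]
  feat_len <- vapply(feats, function(f) nchar(f$seq), integer(1))
  n <- length(feats)
  demand <- sum(feat_len) + (n + 1L) * min_gap
  if (demand > config$genome_length) {
    stop(sprintf("feature demand (%d bp incl. gaps) exceeds genome_length (%d bp)",
                 demand, config$genome_length))
  }
  extra <- config$genome_length - demand
  # spread the surplus background over the n+1 gaps
  gap_extra <- if (extra > 0) as.integer(stats::rmultinom(1, extra, rep(1, n + 1L))) else integer(n + 1L)
  gaps <- min_gap + gap_extra

  pieces <- character(2L * n + 1L)
  starts <- integer(n)
  pos <- 0L
  for (i in seq_len(n)) {
    pieces[2L * i - 1L] <- random_dna(gaps[i])
    pos <- pos + gaps[i]
    starts[i] <- pos + 1L
    pieces[2L * i] <- feats[[i]]$seq
    pos <- pos + feat_len[i]
  }
  pieces[2L * n + 1L] <- random_dna(gaps[n + 1L])

  genome <- Biostrings::DNAStringSet(stats::setNames(paste(pieces, collapse = ""), "chr1"))
  annotation <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(start = starts, width = feat_len),
    strand = vapply(feats, `[[`, character(1), "strand"),
    feature_class = vapply(feats, `[[`, character(1), "class"),
    id = vapply(feats, `[[`, character(1), "id"),
    family = vapply(feats, `[[`, character(1), "family"))

  master_idx <- which(annotation$feature_class == "master")
  truth <- list(master_locus = annotation[master_idx],
                master_fragments = master$fragments)
  list(genome = genome, annotation = annotation, te_catalog = te_catalog,
       truth = truth)
}

# Concatenate TE fragments (>= 25 bp each, mixed orientation) into a master
# sequence of exactly `len` bp; every family contributes at least one intact
# fragment. With no TE families the master locus is plain random sequence.
build_master_sequence <- function(te_catalog, len) {
  nf <- length(te_catalog)
  if (nf == 0) {
    return(list(seq = random_dna(len),
                fragments = data.frame(family = character(0), start = integer(0),
                                       end = integer(0), orientation = character(0))))
  }
  frags <- list()
  seq_parts <- character(0)
  total <- 0L
  i <- 0L
  while (total < len) {
    i <- i + 1L
    fam <- if (i <= nf) i else sample(nf, 1)  # first pass guarantees coverage
    cons <- as.character(te_catalog[[fam]])
    flen <- sample(60:200, 1)
    flen <- min(flen, nchar(cons))
    fstart <- sample(nchar(cons) - flen + 1L, 1)
    frag <- substr(cons, fstart, fstart + flen - 1L)
    ori <- sample(c("+", "-"), 1)
    if (ori == "-") frag <- revcomp_chr(frag)
    # never truncate one of the guaranteed per-family fragments below 25 bp
    if (i <= nf && total + flen > len) {
      flen <- max(25L, len - total)
      frag <- substr(frag, 1L, flen)
    }
    frags[[i]] <- data.frame(family = names(te_catalog)[fam],
                             start = total + 1L, end = total + nchar(frag),
                             orientation = ori)
    seq_parts[i] <- frag
    total <- total + nchar(frag)
  }
  seq <- substr(paste(seq_parts, collapse = ""), 1L, len)
  fragments <- do.call(rbind, frags)
  fragments <- fragments[fragments$start <= len, , drop = FALSE]
  fragments$end <- pmin(fragments$end, len)
  list(seq = seq, fragments = fragments)
}
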