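# Exact mapping vs a naive scan oracle, the multimap cap, feature
# assignment precedence, class cleaning, expressed-locus discovery.

test_that("exact mapper agrees with the naive sliding-window oracle", {
  set.seed(101)
  genome <- make_genome(chrA = rand_dna(4000), chrB = rand_dna(2500))
  # planted repeat: same 24-mer at three sites, one reverse-complemented
  planted <- rand_dna(24)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(planted)))
  gA <- as.character(genome[["chrA"]])
  substr(gA, 101, 124) <- planted
  substr(gA, 1001, 1024) <- planted
  gB <- as.character(genome[["chrB"]])
  substr(gB, 501, 524) <- rc
  genome <- make_genome(chrA = gA, chrB = gB)

  reads <- data.frame(
    read_id = c("planted", "uniq", "absent"),
    sequence = c(planted,
                 substr(gA, 2001, 2024),
                 paste(rep("A", 24), collapse = "")),
    copies = c(2L, 1L, 1L), stringsAsFactors = FALSE)
  res <- map_reads_exact(reads, genome)
  aln <- res$alignments

  got <- data.frame(read_id = S4Vectors::mcols(aln)$read_id,
                    chrom = as.character(GenomicRanges::seqnames(aln)),
                    start = GenomicRanges::start(aln),
                    end = GenomicRanges::end(aln),
                    strand = as.character(GenomicRanges::strand(aln)),
                    stringsAsFactors = FALSE)
  got <- got[order(got$chrom, got$start, got$strand, got$read_id), ]
  oracle <- naive_map(reads, genome)
  rownames(got) <- rownames(oracle) <- NULL
  expect_equal(got, oracle)

  pl <- aln[S4Vectors::mcols(aln)$read_id == "planted"]
  expect_length(pl, 3)
  expect_equal(unique(S4Vectors::mcols(pl)$n_hits), 3L)
  expect_equal(sum(as.character(GenomicRanges::strand(pl)) == "-"), 1)
  expect_equal(res$unmapped$read_id, "absent")
})

test_that("exact mapper matches the oracle on random read sets", {
  for (seed in c(7, 17, 27)) {
    set.seed(seed)
    genome <- make_genome(chr1 = rand_dna(3000))
    g <- as.character(genome[["chr1"]])
    starts <- sample(2900, 25)
    reads <- data.frame(read_id = sprintf("r%02d", 1:25),
                        sequence = substring(g, starts, starts + sample(18:30, 25, TRUE) - 1),
                        copies = 1L, stringsAsFactors = FALSE)
    flip <- seq(1, 25, by = 3)
    reads$sequence[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads$sequence[flip])))
    reads <- reads[!duplicated(reads$sequence), ]
    res <- map_reads_exact(reads, genome)
    aln <- res$alignments
    got <- data.frame(read_id = S4Vectors::mcols(aln)$read_id,
                      chrom = as.character(GenomicRanges::seqnames(aln)),
                      start = GenomicRanges::start(aln),
                      end = GenomicRanges::end(aln),
                      strand = as.character(GenomicRanges::strand(aln)),
                      stringsAsFactors = FALSE)
    got <- got[order(got$chrom, got$start, got$strand, got$read_id), ]
    oracle <- naive_map(reads, genome)
    rownames(got) <- rownames(oracle) <- NULL
    expect_equal(got, oracle)
  }
})

test_that("non-ACGT reads are skipped with a warning", {
  genome <- make_genome(chr1 = rand_dna(500))
  reads <- data.frame(read_id = c("ok", "bad"),
                      sequence = c(substr(as.character(genome[[1]]), 1, 20),
                                   "ACGTNACGTNACGTNACGTN"),
                      copies = 1L)
  expect_warning(res <- map_reads_exact(reads, genome), "non-ACGT")
  expect_true(all(S4Vectors::mcols(res$alignments)$read_id == "ok"))
})

test_that("multimap cap removes reads at the boundary and is idempotent", {
  aln <- aln_gr(start = c(1, 50, 100, 150), end = c(24, 73, 123, 173),
                strand = "+", copies = c(10, 5, 1, 4),
                n_hits = c(100L, 99L, 1L, 101L),
                read_id = c("at100", "at99", "uniq", "over"))
  res <- cap_multimappers(aln, max_hits = 100)
  expect_false("at100" %in% S4Vectors::mcols(res$kept)$read_id)
  expect_true("at99" %in% S4Vectors::mcols(res$kept)$read_id)
  expect_false("over" %in% S4Vectors::mcols(res$kept)$read_id)
  # kept U removed = input
  expect_equal(length(res$kept) + length(res$removed), length(aln))
  # copies-weighted discarded fraction: (10 + 4) / 20
  expect_equal(res$discarded_fraction, 14 / 20)
  # idempotent
  again <- cap_multimappers(res$kept, max_hits = 100)
  expect_identical(again$kept, res$kept)
  expect_equal(again$discarded_fraction, 0)
  # all unique -> nothing discarded
  uni <- aln_gr(start = c(1, 50), end = c(24, 73), strand = "+", n_hits = 1)
  expect_equal(cap_multimappers(uni)$discarded_fraction, 0)
})

test_that("feature assignment honours the precedence table", {
  ann <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(100, 150, 500), c(200, 260, 600)),
                                strand = "+",
                                feature_class = c("TE", "rRNA", "mRNA"),
                                id = c("te1", "rrna1", "m1"))
  aln <- aln_gr(start = c(160, 120, 550, 900), end = c(183, 143, 573, 923),
                strand = c("+", "-", "+", "+"))
  out <- assign_to_features(aln, ann)
  expect_equal(S4Vectors::mcols(out)$feature_class,
               c("rRNA",       # overlaps both TE and rRNA -> rRNA wins
                 "TE",         # TE only (strand ignored)
                 "mRNA",
                 "intergenic"))
})

test_that("cleaning retains only target-class and intergenic mappers", {
  set.seed(55)
  te <- rand_dna(300); rrna <- rand_dna(150)
  shared <- rand_dna(24)          # occurs in both TE and rRNA
  te_only <- substr(te, 50, 73)
  genome <- make_genome(chr1 = paste0(rand_dna(200), te, rand_dna(100),
                                      rrna, shared, rand_dna(100),
                                      shared, rand_dna(50)))
  # shared 24-mer sits right after the rRNA (inside an extended rRNA locus)
  ann <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(201, 601), c(500, 774)),
                                strand = "+",
                                feature_class = c("TE", "rRNA"),
                                id = c("te1", "rrna1"))
  reads <- data.frame(read_id = c("teonly", "shared", "unmapped"),
                      sequence = c(te_only, shared, paste(rep("C", 24), collapse = "")),
                      copies = 1L)
  kept <- clean_by_feature(reads, genome, ann, "TE")
  expect_equal(kept$read_id, "teonly")
  # invariant: no kept read maps to a non-target class
  res <- map_reads_exact(kept, genome)
  lab <- assign_to_features(res$alignments, ann)
  expect_true(all(S4Vectors::mcols(lab)$feature_class %in% c("TE", "intergenic")))
  expect_error(clean_by_feature(reads, genome, ann, "nonsense"), "target_class")
})

test_that("expressed-locus discovery applies strict read and length thresholds", {
  ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9000, 9500),
                                strand = "+", feature_class = "mRNA", id = "m1")
  island <- function(start, width, n_reads, copies = 1) {
    pos <- as.integer(seq(start, start + width - 24, length.out = n_reads))
    aln_gr(start = pos, end = pos + 23L, strand = "+", copies = copies)
  }
  # 500 bp island, 1500 reads -> accepted
  a1 <- island(1000, 500, 1500)
  loci <- discover_expressed_loci(a1, ann, min_reads = 1000, min_len = 200)
  expect_length(loci, 1)
  expect_equal(S4Vectors::mcols(loci)$feature_class, "unknown")
  # 150 bp span -> length-filtered even with 1500 reads
  a2 <- island(3000, 150, 1500)
  expect_length(discover_expressed_loci(a2, ann, 1000, 200), 0)
  # exactly 1000 reads -> rejected (strict > 1000)
  a3 <- island(5000, 500, 1000)
  expect_length(discover_expressed_loci(a3, ann, 1000, 200), 0)
  a4 <- island(5000, 500, 1001)
  expect_length(discover_expressed_loci(a4, ann, 1000, 200), 1)
  # loci disjoint from prior annotation
  a5 <- c(island(1000, 500, 1500), island(9100, 300, 1500))
  out <- discover_expressed_loci(a5, ann, 1000, 200)
  expect_false(any(IRanges::overlapsAny(out, ann)))
})

test_that("merge_gap bridges close footprints into one locus", {
  ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10), strand = "+",
                                feature_class = "mRNA", id = "m1")
  left <- aln_gr(start = rep(1000, 600), end = rep(1023, 600), strand = "+")
  right <- aln_gr(start = rep(1063, 600), end = rep(1283, 600), strand = "+")
  both <- c(left, right)
  merged <- discover_expressed_loci(both, ann, min_reads = 1000,
                                    min_len = 200, merge_gap = 50)
  expect_length(merged, 1)
  split <- discover_expressed_loci(both, ann, min_reads = 1000,
                                   min_len = 200, merge_gap = 10)
  expect_length(split, 0)  # each side alone fails a threshold
})
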