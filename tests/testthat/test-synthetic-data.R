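# The synthetic generator: geometry, determinism, planted-parameter truth.

test_that("config validation rejects malformed mixtures, rates and sizes", {
  expect_error(sim_config(mixture = c(dicer = 0.5, pingpong = 0.5)),
               "mixture")
  expect_error(sim_config(mixture = c(dicer = 0.7, pingpong = 0.2,
                                      degradation = 0.2)), "sum to 1")
  expect_error(sim_config(guide_5p_bias = 1.2), "rates")
  expect_error(sim_config(size_dist = rep(1 / 12, 12)), "size_dist")
  expect_s3_class(sim_config(), "sim_config")
})

test_that("simulated genome hosts non-overlapping features and TE-fragment master locus", {
  cfg <- sim_config(seed = 42, n_te_families = 2, genome_length = 60000)
  g <- simulate_genome(cfg)
  ann <- g$annotation
  # no two features overlap
  expect_equal(length(GenomicRanges::reduce(ann, ignore.strand = TRUE)),
               length(ann))
  # master locus shares an exact >= 25 bp fragment with every family
  master_seq <- extract_seq(g$genome, ann[ann$feature_class == "master"])
  for (fam in names(g$te_catalog)) {
    segs <- te_homology_segments(master_seq, g$te_catalog[fam], min_match = 25)
    expect_gte(nrow(segs), 1)
  }
  # and the recorded fragments really are exact substrings
  frag <- g$truth$master_fragments[1, ]
  piece <- substr(master_seq, frag$start, frag$end)
  cons <- as.character(g$te_catalog[[frag$family]])
  if (frag$orientation == "-") {
    cons <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cons)))
  }
  expect_true(grepl(piece, cons, fixed = TRUE) ||
                grepl(piece, as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(cons))), fixed = TRUE))
})

test_that("zero TE families yields a fragment-free random master locus", {
  cfg <- sim_config(seed = 5, n_te_families = 0, te_copies = 0,
                    genome_length = 30000)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$truth$master_fragments), 0)
  expect_equal(sum(g$annotation$feature_class == "master"), 1)
})

test_that("feature demand beyond the genome length raises a capacity error", {
  expect_error(simulate_genome(sim_config(seed = 1, genome_length = 5000)),
               "exceeds genome_length")
})

test_that("identical config gives byte-identical FASTA outputs and reads", {
  cfg <- sim_config(seed = 99, n_reads = 400, genome_length = 60000)
  s1 <- simulate_srna_dataset(cfg)
  s2 <- simulate_srna_dataset(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_genome_fasta(s1$genome, f1); write_genome_fasta(s2$genome, f2)
  expect_identical(readLines(f1), readLines(f2))
  r1 <- tempfile(); r2 <- tempfile()
  write_reads_fasta(s1$reads, r1); write_reads_fasta(s2$reads, r2)
  expect_identical(readLines(r1), readLines(r2))
  expect_identical(s1$methyl_calls, s2$methyl_calls)
})

test_that("dicer duplexes land in the 2-nt overhang register for every length", {
  g <- simulate_genome(sim_config(seed = 8, genome_length = 60000))
  region <- g$annotation[g$annotation$feature_class == "master"]
  for (L in c(18L, 24L, 30L)) {
    reads <- simulate_dicer_reads(g$genome, region, 5,
                                  size_dist = size_point(L), seed = L)
    plus <- reads[as.character(GenomicRanges::strand(reads)) == "+"]
    minus <- reads[as.character(GenomicRanges::strand(reads)) == "-"]
    expect_equal(GenomicRanges::width(plus), rep(L, 5))
    expect_equal(GenomicRanges::start(minus), GenomicRanges::start(plus) - 2)
    # 5' overlap = minus 5' (its end) - plus 5' + 1 = L - 2
    expect_equal(GenomicRanges::end(minus) - GenomicRanges::start(plus) + 1,
                 rep(L - 2, 5))
  }
  expect_length(simulate_dicer_reads(g$genome, region, 0), 0)
  small <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 20))
  expect_error(simulate_dicer_reads(g$genome, small, 1), "region shorter")
})

test_that("ping-pong pairs overlap by exactly 10 nt at their 5' ends", {
  g <- simulate_genome(sim_config(seed = 12, genome_length = 60000))
  region <- g$annotation[g$annotation$feature_class == "master"]
  res <- simulate_pingpong_reads(g$genome, region, 50, seed = 4)
  reads <- res$reads
  guides <- reads[S4Vectors::mcols(reads)$role == "guide"]
  resp <- reads[S4Vectors::mcols(reads)$role == "responder"]
  g5 <- ifelse(as.character(GenomicRanges::strand(guides)) == "-",
               GenomicRanges::end(guides), GenomicRanges::start(guides))
  r5 <- ifelse(as.character(GenomicRanges::strand(resp)) == "-",
               GenomicRanges::end(resp), GenomicRanges::start(resp))
  expect_true(all(as.character(GenomicRanges::strand(guides)) !=
                    as.character(GenomicRanges::strand(resp))))
  expect_equal(abs(r5 - g5), rep(9, 50))
  # reads stay consistent with the edited genome
  expect_identical(extract_seq(res$genome, reads),
                   S4Vectors::mcols(reads)$sequence)
})

test_that("guide 5' U frequency tracks the planted bias", {
  g <- simulate_genome(sim_config(seed = 2, genome_length = 60000,
                                  master_locus_length = 4000))
  region <- g$annotation[g$annotation$feature_class == "master"]
  res <- simulate_pingpong_reads(g$genome, region, 500, guide_5p_bias = 1,
                                 responder_10A_bias = 0, seed = 31)
  guides <- res$reads[S4Vectors::mcols(res$reads)$role == "guide"]
  expect_true(all(substr(S4Vectors::mcols(guides)$sequence, 1, 1) == "T"))
  # and the 10A complement shows on the responders
  resp <- res$reads[S4Vectors::mcols(res$reads)$role == "responder"]
  expect_true(all(substr(S4Vectors::mcols(resp)$sequence, 10, 10) == "A"))

  res2 <- simulate_pingpong_reads(g$genome, region, 1000, guide_5p_bias = 0.25,
                                  responder_10A_bias = 0, seed = 32)
  guides2 <- res2$reads[S4Vectors::mcols(res2$reads)$role == "guide"]
  f <- mean(substr(S4Vectors::mcols(guides2)$sequence, 1, 1) == "T")
  # 99% binomial interval around 0.25 at n = 1000
  expect_lt(abs(f - 0.25), 2.576 * sqrt(0.25 * 0.75 / 1000))
})

test_that("degradation fragments are single-stranded and bounded by the transcript", {
  g <- simulate_genome(sim_config(seed = 6, genome_length = 60000))
  for (str in c("+", "-")) {
    tx <- g$annotation[g$annotation$feature_class == "mRNA" &
                         as.character(GenomicRanges::strand(g$annotation)) == str][1]
    reads <- simulate_degradation_reads(g$genome, tx, 100, seed = 9)
    expect_true(all(as.character(GenomicRanges::strand(reads)) == str))
    expect_true(all(GenomicRanges::start(reads) >= GenomicRanges::start(tx)))
    expect_true(all(GenomicRanges::end(reads) <= GenomicRanges::end(tx)))
    expect_equal(strand_bias(reads), 1)
  }
  un <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 2000), strand = "*")
  expect_error(simulate_degradation_reads(g$genome, un, 1), "stranded")
  tx <- g$annotation[g$annotation$feature_class == "mRNA"][1]
  one <- simulate_degradation_reads(g$genome, tx, 1, seed = 1)
  expect_length(one, 1)
  expect_identical(simulate_degradation_reads(g$genome, tx, 20, seed = 3),
                   simulate_degradation_reads(g$genome, tx, 20, seed = 3))
})

test_that("methylation calls carry correct contexts and planted rates", {
  g <- simulate_genome(sim_config(seed = 21, genome_length = 30000,
                                  n_mrna = 2, te_copies = 2))
  zero <- simulate_methyl_calls(g$genome, methyl_rates = c(CG = 0, CHG = 0, CHH = 0),
                                coverage_mean = 5, seed = 1)
  expect_true(all(zero$n_meth == 0))
  full <- simulate_methyl_calls(g$genome, methyl_rates = c(CG = 1, CHG = 0, CHH = 0),
                                coverage_mean = 10, seed = 2)
  cg <- full[full$context == "CG" & full$coverage > 0, ]
  expect_true(all(cg$n_meth == cg$coverage))
  # contexts agree with independent re-annotation from the genome
  sub <- full[sample(nrow(full), 200), ]
  expect_identical(context_annotate(g$genome, sub), sub$context)

  calls <- simulate_methyl_calls(g$genome,
                                 methyl_rates = c(CG = 0.3, CHG = 0, CHH = 0),
                                 coverage_mean = 6, seed = 3)
  cg <- calls[calls$context == "CG", ]
  expect_gt(nrow(cg), 1000)
  rate <- sum(cg$n_meth) / sum(cg$coverage)
  se <- sqrt(0.3 * 0.7 / sum(cg$coverage))
  expect_lt(abs(rate - 0.3), 3 * se)
})
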