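#' Simulation configuration
#'
#' Bundles and validates every tunable of the synthetic small-RNA dataset
#' generator. Defaults emulate the dust-mite-like study conditions the
#' statistics in this package were designed for: a Dicer-dominated small RNA
#' population (roughly three quarters of reads) with a unimodal read-size
#' distribution peaked at 24 nt, no ping-pong fraction, no 5' U bias
#' (uniform first-base composition), sparse cytosine methylation (0.5% in
#' every context) and ~6X bisulfite coverage.
#'
#' @param seed integer RNG seed; one global seed drives every draw.
#' @param genome_length genome size in bp.
#' @param n_te_families number of transposable-element families.
#' @param te_copies dispersed copies planted per family.
#' @param te_length length of each family consensus, bp.
#' @param master_locus_length length of the planted dual-strand master locus,
#'   built as a concatenation of TE fragments in mixed orientations.
#' @param n_mrna,mrna_length number and length of mRNA loci.
#' @param n_rrna,n_trna,n_snrna counts of structural ncRNA loci.
#' @param ncrna_length length of each structural ncRNA locus, bp.
#' @param mixture named fractions (`dicer`, `pingpong`, `degradation`) of the
#'   read population attributed to each biogenesis mechanism; must be
#'   non-negative and sum to 1.
#' @param n_reads total simulated reads.
#' @param size_dist probability vector over read lengths 18..30 nt.
#' @param guide_5p_bias probability that a ping-pong guide read begins with U
#'   (T in genome space).
#' @param responder_10A_bias probability that a ping-pong responder carries A
#'   at its position 10. Because a 10-nt 5' overlap makes responder position
#'   10 the complement of guide position 1, the generator plants a single
#'   base per pair: T on the guide sense with probability
#'   `1 - (1 - guide_5p_bias) * (1 - responder_10A_bias)`.
#' @param methyl_rates named per-context (`CG`, `CHG`, `CHH`) methylation
#'   probabilities.
#' @param coverage_mean mean bisulfite read depth per cytosine (Poisson).
#'
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 100000L,
                       n_te_families = 3L,
                       te_copies = 4L,
                       te_length = 400L,
                       master_locus_length = 2000L,
                       n_mrna = 5L,
                       mrna_length = 1000L,
                       n_rrna = 2L,
                       n_trna = 2L,
                       n_snrna = 1L,
                       ncrna_length = 150L,
                       mixture = c(dicer = 0.75, pingpong = 0, degradation = 0.25),
                       n_reads = 6000L,
                       size_dist = default_size_dist(),
                       guide_5p_bias = 0.25,
                       responder_10A_bias = 0,
                       methyl_rates = c(CG = 0.005, CHG = 0.005, CHH = 0.005),
                       coverage_mean = 6) {
  cfg <- list(seed = as.integer(seed),
              genome_length = as.integer(genome_length),
              n_te_families = as.integer(n_te_families),
              te_copies = as.integer(te_copies),
              te_length = as.integer(te_length),
              master_locus_length = as.integer(master_locus_length),
              n_mrna = as.integer(n_mrna),
              mrna_length = as.integer(mrna_length),
              n_rrna = as.integer(n_rrna),
              n_trna = as.integer(n_trna),
              n_snrna = as.integer(n_snrna),
              ncrna_length = as.integer(ncrna_length),
              mixture = mixture,
              n_reads = as.integer(n_reads),
              size_dist = size_dist,
              guide_5p_bias = guide_5p_bias,
              responder_10A_bias = responder_10A_bias,
              methyl_rates = methyl_rates,
              coverage_mean = coverage_mean)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

#' Default read-size distribution: unimodal, peaked at 24 nt
#'
#' Discretized Gaussian over 18..30 nt centred on 24 (sd 1.5), normalized.
#' @return named probability vector over lengths 18..30.
#' @export
default_size_dist <- function() {
  w <- stats::dnorm(READ_SIZES, mean = 24, sd = 1.5)
  stats::setNames(w / sum(w), READ_SIZES)
}

validate_sim_config <- function(cfg) {
  mx <- cfg$mixture
  if (!all(c("dicer", "pingpong", "degradation") %in% names(mx))) {
    stop("mixture must name fractions dicer, pingpong, degradation")
  }
  if (any(mx < 0) || abs(sum(mx) - 1) > 1e-9) {
    stop("mixture fractions must be non-negative and sum to 1 (within 1e-9)")
  }
  if (length(cfg$size_dist) != length(READ_SIZES) ||
      any(cfg$size_dist < 0) || abs(sum(cfg$size_dist) - 1) > 1e-9) {
    stop("size_dist must be a probability vector over read lengths 18..30")
  }
  rates <- c(cfg$guide_5p_bias, cfg$responder_10A_bias, cfg$methyl_rates)
  if (any(rates < 0 | rates > 1)) stop("all rates/biases must lie in [0, 1]")
  if (!all(c("CG", "CHG", "CHH") %in% names(cfg$methyl_rates))) {
    stop("methyl_rates must name contexts CG, CHG, CHH")
  }
  if (cfg$coverage_mean < 0) stop("coverage_mean must be non-negative")
  if (cfg$genome_length <= 0) stop("genome_length must be positive")
  invisible(cfg)
}
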