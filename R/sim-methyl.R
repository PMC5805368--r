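#' Simulate per-cytosine bisulfite methylation calls
#'
#' Every cytosine on both genome strands receives its trinucleotide context
#' (CG / CHG / CHH, H = A, C or T), a Poisson(`coverage_mean`) read depth and
#' a methylated-read count drawn Binomial(depth, context rate). The planted
#' per-context rate is the recorded truth.
#'
#' @param genome DNAStringSet.
#' @param annotation optional GRanges (carried through untouched; contexts
#'   depend only on the sequence).
#' @param methyl_rates named per-context probabilities (CG, CHG, CHH).
#' @param coverage_mean mean read depth per cytosine.
#' @param seed optional integer seed.
#' @return data.frame with columns chrom, pos (1-based), strand, context,
#'   n_meth, n_unmeth, coverage, true_rate.
#' @export
simulate_methyl_calls <- function(genome, annotation = NULL,
                                  methyl_rates = c(CG = 0.005, CHG = 0.005, CHH = 0.005),
                                  coverage_mean = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(methyl_rates < 0 | methyl_rates > 1)) stop("methyl_rates must lie in [0, 1]")
  sites <- cytosine_sites(genome)
  if (nrow(sites) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0), strand = character(0),
                      context = character(0), n_meth = integer(0),
                      n_unmeth = integer(0), coverage = integer(0),
                      true_rate = numeric(0)))
  }
  rate <- unname(methyl_rates[sites$context])
  depth <- stats::rpois(nrow(sites), coverage_mean)
  n_meth <- stats::rbinom(nrow(sites), depth, rate)
  data.frame(chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
             context = sites$context, n_meth = n_meth,
             n_unmeth = depth - n_meth, coverage = depth, true_rate = rate,
             stringsAsFactors = FALSE)
}

# All cytosines on both strands with their CG/CHG/CHH context.
# Plus strand: C at pos; minus strand: G at pos on the plus sequence.
cytosine_sites <- function(genome) {
  out <- lapply(names(genome), function(chrom) {
    s <- as.character(genome[[chrom]])
    n <- nchar(s)
    b <- strsplit(s, "")[[1]]
    plus <- which(b == "C")
    minus <- which(b == "G")
    ctx_p <- context_from_bases(b, plus, n, minus_strand = FALSE)
    ctx_m <- context_from_bases(b, minus, n, minus_strand = TRUE)
    data.frame(chrom = chrom,
               pos = c(plus, minus),
               strand = rep(c("+", "-"), c(length(plus), length(minus))),
               context = c(ctx_p, ctx_m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
}

# Trinucleotide context of a cytosine given the plus-strand base vector.
# On the minus strand the 3-mer runs leftwards through complemented bases:
# next base after the C (minus sense) sits at pos-1 on the plus strand.
context_from_bases <- function(b, pos, n, minus_strand) {
  if (length(pos) == 0) return(character(0))
  if (!minus_strand) {
    p1 <- ifelse(pos + 1 <= n, b[pmin(pos + 1, n)], "N")
    p2 <- ifelse(pos + 2 <= n, b[pmin(pos + 2, n)], "N")
    ifelse(p1 == "G", "CG", ifelse(p2 == "G", "CHG", "CHH"))
  } else {
    p1 <- ifelse(pos - 1 >= 1, b[pmax(pos - 1, 1)], "N")
    p2 <- ifelse(pos - 2 >= 1, b[pmax(pos - 2, 1)], "N")
    # minus-sense G corresponds to plus-strand C
    ifelse(p1 == "C", "CG", ifelse(p2 == "C", "CHG", "CHH"))
  }
}
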