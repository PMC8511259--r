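# shared fixture builders (everything generated in code; no binary data)

# tiny genotype matrix from a plain integer matrix, positions 1 kb apart
toy_genotypes <- function(geno, ploidy = 2L, chrom = "chr1", pop = NULL,
                          ref = "A", alt = "G") {
  geno <- as.matrix(geno)
  sites <- data.frame(chrom = chrom, pos = seq_len(ncol(geno)) * 1000L,
                      ref = ref, alt = alt)
  genotype_matrix(geno, sites, ploidy = ploidy, pop = pop)
}

# unadmixed two-population cohort
two_pop_cohort <- function(n_per = 30, n_sites = 2000, drift = 0.05,
                           seed = 1, chrom_lengths = c(chr1 = 5e7,
                                                       chr2 = 5e7)) {
  m <- ancestral_model(K = 2, n_sites = n_sites, drift = drift,
                       chrom_lengths = chrom_lengths, seed = seed)
  simulate_admixed_cohort(m, list(A = list(n = n_per, q = c(1, 0)),
                                  B = list(n = n_per, q = c(0, 1))))
}

# dense single-population cohort suitable for the ROH caller (2.5 kb
# marker spacing, WGS-like)
roh_test_cohort <- function(n = 30, seed = 1, n_sites = 16000,
                            tracts = list(long = list(n = 2, min_bp = 2e6,
                                                      max_bp = 6e6)),
                            het_error = 0.002) {
  m <- ancestral_model(K = 1, n_sites = n_sites, drift = 0,
                       chrom_lengths = c(chr1 = 2e7, chr2 = 2e7),
                       seed = seed)
  co <- simulate_admixed_cohort(m, list(P = list(n = n, q = 1)))
  plant_roh(co, tracts, het_error = het_error)
}

# exact conditional HWE p-value by direct enumeration (log-gamma formula,
# independent of the recurrence in the package)
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab      # allele A count
  if (na == 0 || na == 2 * n) return(1)
  hs <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  logp <- vapply(hs, function(h) {
    a <- (na - h) / 2                 # hom-A count
    bb <- (2 * n - na - h) / 2        # hom-B count
    lgamma(n + 1) - lgamma(a + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) + lgamma(na + 1) + lgamma(2 * n - na + 1) -
      lgamma(2 * n + 1)
  }, 1)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  p_obs <- p[match(n_ab, hs)]
  min(1, sum(p[p <= p_obs + 1e-12]))
}

# overlap of called segments with planted tracts: per-tract covered
# fraction and overall base-pair precision
roh_overlap <- function(segments, truth) {
  covered <- mapply(function(s, ch, st, en) {
    cand <- segments[segments$sample == s & segments$chrom == ch, ,
                     drop = FALSE]
    if (!nrow(cand)) return(0)
    sum(pmax(0, pmin(cand$end_bp, en) - pmax(cand$start_bp, st) + 1)) /
      (en - st + 1)
  }, truth$sample, truth$chrom, truth$start_bp, truth$end_bp)
  in_truth <- mapply(function(s, ch, st, en) {
    tr <- truth[truth$sample == s & truth$chrom == ch, , drop = FALSE]
    if (!nrow(tr)) return(0)
    sum(pmax(0, pmin(tr$end_bp, en) - pmax(tr$start_bp, st) + 1))
  }, segments$sample, segments$chrom, segments$start_bp, segments$end_bp)
  list(tract_coverage = unname(covered),
       precision = sum(in_truth) /
         sum(segments$end_bp - segments$start_bp + 1))
}

# Balding-Nichols population frequency draw around ancestral p
bn_draw <- function(p, F) {
  if (F == 0) return(p)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

# allele-count site-frequency table from per-population frequencies
counts_from_freqs <- function(freq_list, n_dip, block_chrom = NULL) {
  pops <- names(freq_list)
  m <- length(freq_list[[1]])
  ac <- sapply(pops, function(pp)
    stats::rbinom(m, 2 * n_dip, freq_list[[pp]]))
  an <- matrix(2 * n_dip, m, length(pops),
               dimnames = list(NULL, pops))
  sites <- if (is.null(block_chrom))
    data.frame(chrom = "chr1", pos = seq_len(m) * 1000L, ref = "A",
               alt = "G")
  else data.frame(chrom = block_chrom, pos = seq_len(m) * 1000L,
                  ref = "A", alt = "G")
  freq_table_from_counts(ac, an, sites)
}
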