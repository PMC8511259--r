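#' Per-sample quality control
#'
#' Computes per-sample missingness (total and per chromosome), call counts,
#' non-reference and heterozygous counts, the het/(het+hom-alt) ratio and
#' the transition/transversion ratio; excludes samples breaching the
#' missingness thresholds and flags (without excluding) samples whose
#' count/het/TiTv metrics fall more than `sd_multiplier` standard deviations
#' from the cohort mean.
#'
#' @param g diploid genotype_matrix
#' @param total_missingness_max exclude samples with total missingness above
#'   this rate (default 0.05)
#' @param per_chrom_missingness_max exclude samples with any single
#'   chromosome's missingness above this rate (default 0.20; chosen well
#'   above plausible batch noise but below catastrophic failures)
#' @param sd_multiplier outlier flag threshold in SD units (default 3)
#' @param exclude_outliers if TRUE, flagged outliers are also excluded
#'   (off by default; flags are advisory)
#' @return list with `report` (one row per input sample: metrics, flags,
#'   excluded) and `retained` (sample ids passing all exclusion rules)
#' @export
sample_qc <- function(g, total_missingness_max = 0.05,
                      per_chrom_missingness_max = 0.20,
                      sd_multiplier = 3, exclude_outliers = FALSE) {
  stopifnot(inherits(g, "genotype_matrix"), g$ploidy == 2L)
  if (nrow(g$geno) < 2L) stop("sample_qc needs >= 2 samples")
  miss <- is.na(g$geno)
  total_miss <- rowMeans(miss)
  chroms <- unique(g$sites$chrom)
  per_chrom <- sapply(chroms, function(ch)
    rowMeans(miss[, g$sites$chrom == ch, drop = FALSE]))
  if (is.null(dim(per_chrom))) per_chrom <- t(per_chrom)
  worst_chrom_miss <- apply(per_chrom, 1L, max)
  worst_chrom <- chroms[apply(per_chrom, 1L, which.max)]
  n_called <- rowSums(!miss)
  n_nonref <- rowSums(g$geno > 0L, na.rm = TRUE)
  n_het <- rowSums(g$geno == 1L, na.rm = TRUE)
  n_homalt <- rowSums(g$geno == 2L, na.rm = TRUE)
  het_ratio <- ifelse(n_het + n_homalt > 0, n_het / (n_het + n_homalt), NA)
  ## transitions: {A,G} or {C,T} ref/alt pairs
  pair <- paste0(pmin(g$sites$ref, g$sites$alt), pmax(g$sites$ref, g$sites$alt))
  is_ti <- pair %in% c("AG", "CT")
  nonref <- !miss & g$geno > 0L
  n_ti <- rowSums(nonref[, is_ti, drop = FALSE])
  n_tv <- rowSums(nonref[, !is_ti, drop = FALSE])
  titv <- ifelse(n_tv > 0, n_ti / n_tv, NA)

  flag_metric <- function(x) {
    mu <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(rep(FALSE, length(x)))
    abs(x - mu) > sd_multiplier * s & !is.na(x)
  }
  out_count <- flag_metric(n_nonref)
  out_het <- flag_metric(n_het)
  out_titv <- flag_metric(titv)

  excl_total <- total_miss > total_missingness_max
  excl_chrom <- worst_chrom_miss > per_chrom_missingness_max
  flags <- mapply(function(a, b, c, d, e) {
    paste(c(if (a) "total_missingness", if (b) "chrom_missingness",
            if (c) "outlier_nonref", if (d) "outlier_het",
            if (e) "outlier_titv"), collapse = ";")
  }, excl_total, excl_chrom, out_count, out_het, out_titv)
  excluded <- excl_total | excl_chrom
  if (exclude_outliers) excluded <- excluded | out_count | out_het | out_titv
  report <- data.frame(
    sample = rownames(g$geno),
    total_missingness = total_miss,
    worst_chrom = worst_chrom,
    worst_chrom_missingness = worst_chrom_miss,
    n_called = n_called, n_nonref = n_nonref, n_het = n_het,
    het_ratio = het_ratio, titv = titv,
    flags = flags, excluded = excluded,
    stringsAsFactors = FALSE, row.names = NULL)
  retained <- report$sample[!report$excluded]
  if (!length(retained)) {
    tally <- c(total_missingness = sum(excl_total),
               chrom_missingness = sum(excl_chrom))
    stop("all samples excluded by sample QC (",
         paste(sprintf("%s=%d", names(tally), tally), collapse = ", "), ")")
  }
  list(report = report, retained = retained)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test (Wigginton-style): conditional on the observed
#' allele counts, the two-sided p-value sums the probabilities of every
#' heterozygote configuration whose probability does not exceed that of the
#' observed configuration.  Valid at the rare-variant end where asymptotic
#' chi-square tests break down.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (non-negative, total
#'   >= 1)
#' @return two-sided exact p-value; monomorphic sites return 1 by convention
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n < 1) stop("empty genotype table")
  n_rare <- 2L * min(n_hom_ref, n_hom_alt) + n_het
  if (n_rare == 0L || n_rare == 2L * n) return(1)  # monomorphic
  ## feasible het counts share the parity of the rare allele count
  h_obs <- n_het
  hs <- seq.int(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  ## unnormalized probabilities via the Levene-Haldane recurrence
  lp <- numeric(length(hs))
  for (i in seq_along(hs)[-1]) {
    h <- hs[i]
    ## P(h) / P(h-2) = 4 * n_AA(h-2) * n_aa(h-2) / (h * (h - 1))
    hom_r <- (n_rare - (h - 2L)) / 2
    hom_c <- n - (h - 2L) - hom_r
    lp[i] <- lp[i - 1] + log(4 * hom_r * hom_c) - log(h * (h - 1))
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  p_obs <- p[match(h_obs, hs)]
  if (is.na(p_obs)) stop("observed het count infeasible for allele counts")
  min(1, sum(p[p <= p_obs + 1e-12]))
}

#' Variant filter specification
#'
#' @param max_missingness sites with missingness above this are excluded
#'   (default 0.01, i.e. missingness > 1\% excluded)
#' @param min_minor_allele_count minimum MAC (default 3: MAC <= 2 excluded)
#' @param hwe_p_threshold sites with exact HWE p below this are excluded
#'   (default 1e-5)
#' @param exclusion_bed optional data.frame from [read_bed()] (0-based
#'   half-open) of regions to exclude, e.g. low-complexity regions
#' @return object of class `variant_filter_spec`
#' @export
variant_filter_spec <- function(max_missingness = 0.01,
                                min_minor_allele_count = 3L,
                                hwe_p_threshold = 1e-5,
                                exclusion_bed = NULL) {
  stopifnot(max_missingness >= 0, max_missingness <= 1,
            min_minor_allele_count >= 0,
            hwe_p_threshold >= 0, hwe_p_threshold <= 1)
  structure(list(max_missingness = max_missingness,
                 min_minor_allele_count = as.integer(min_minor_allele_count),
                 hwe_p_threshold = hwe_p_threshold,
                 exclusion_bed = exclusion_bed),
            class = "variant_filter_spec")
}

#' Variant-level filtering
#'
#' A site survives iff its missingness is <= `max_missingness`, its minor
#' allele count is >= `min_minor_allele_count`, its exact HWE p-value is
#' >= `hwe_p_threshold`, and it does not fall inside an exclusion region.
#' Exclusion counts attribute each removed site to the first failing rule in
#' the order missingness -> MAC -> HWE -> region.  Missing genotypes are
#' excluded from MAC and HWE counts, not imputed.
#'
#' @param g diploid genotype_matrix
#' @param spec a [variant_filter_spec()]
#' @return list with `genotypes` (surviving sites), `counts` (named
#'   exclusion tally by first failing rule) and `keep` (logical per input
#'   site)
#' @export
variant_filter <- function(g, spec = variant_filter_spec()) {
  stopifnot(inherits(g, "genotype_matrix"),
            inherits(spec, "variant_filter_spec"))
  miss_rate <- colMeans(is.na(g$geno))
  cnt <- allele_counts(g)
  mac <- pmin(cnt$ac, cnt$an - cnt$ac)
  fail_miss <- miss_rate > spec$max_missingness
  fail_mac <- mac < spec$min_minor_allele_count
  hwe_p <- rep(1, ncol(g$geno))
  if (g$ploidy == 2L) {
    need <- which(!fail_miss & !fail_mac)
    for (j in need) {
      gj <- g$geno[, j]
      hwe_p[j] <- hwe_exact_test(sum(gj == 0L, na.rm = TRUE),
                                 sum(gj == 1L, na.rm = TRUE),
                                 sum(gj == 2L, na.rm = TRUE))
    }
  }
  fail_hwe <- hwe_p < spec$hwe_p_threshold
  fail_region <- rep(FALSE, ncol(g$geno))
  if (!is.null(spec$exclusion_bed)) {
    bed <- spec$exclusion_bed
    for (i in seq_len(nrow(bed))) {
      fail_region <- fail_region |
        (g$sites$chrom == bed$chrom[i] &
           g$sites$pos - 1L >= bed$start[i] & g$sites$pos - 1L < bed$end[i])
    }
  }
  first_fail <- rep(NA_character_, ncol(g$geno))
  first_fail[fail_region] <- "region"
  first_fail[fail_hwe] <- "hwe"
  first_fail[fail_mac] <- "mac"
  first_fail[fail_miss] <- "missingness"
  keep <- is.na(first_fail)
  counts <- c(missingness = sum(first_fail == "missingness", na.rm = TRUE),
              mac = sum(first_fail == "mac", na.rm = TRUE),
              hwe = sum(first_fail == "hwe", na.rm = TRUE),
              region = sum(first_fail == "region", na.rm = TRUE))
  list(genotypes = subset_genotypes(g, sites = keep), counts = counts,
       keep = keep)
}

#' Merge cohorts on their common site set
#'
#' Retains only sites present in every cohort with identical
#' (chrom, pos, ref, alt); samples are concatenated.  Sites matching on
#' position but with mismatched alleles (e.g. allele swaps) are dropped and
#' counted — strand/allele flips are never attempted.
#'
#' @param cohorts list of >= 2 genotype_matrix objects with equal ploidy
#' @return list with `genotypes` (merged matrix on the common site set) and
#'   `n_allele_mismatch` (positions shared by all cohorts but dropped for
#'   allele disagreement)
#' @export
intersect_sites <- function(cohorts) {
  stopifnot(is.list(cohorts), length(cohorts) >= 2)
  ploidy <- unique(vapply(cohorts, function(g) g$ploidy, 1L))
  if (length(ploidy) != 1L) stop("cohorts differ in ploidy")
  ids <- unlist(lapply(cohorts, function(g) rownames(g$geno)))
  if (anyDuplicated(ids))
    stop("duplicate sample ids across cohorts: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  full_keys <- lapply(cohorts, site_keys)
  pos_keys <- lapply(cohorts, function(g)
    paste(g$sites$chrom, g$sites$pos, sep = ":"))
  common_full <- Reduce(intersect, full_keys)
  common_pos <- Reduce(intersect, pos_keys)
  ## positions shared everywhere whose full key is not: allele mismatch
  pos_of_full <- sub("^([^:]+:[^:]+):.*$", "\\1", common_full)
  n_mismatch <- length(setdiff(common_pos, pos_of_full))
  if (n_mismatch > 0)
    warning(n_mismatch, " shared position(s) dropped for allele mismatch")
  if (!length(common_full)) {
    warning("cohorts share no sites; result is empty")
  }
  parts <- lapply(cohorts, function(g) {
    idx <- match(common_full, site_keys(g))
    g$geno[, idx, drop = FALSE]
  })
  geno <- do.call(rbind, parts)
  ref_sites <- cohorts[[1]]$sites[match(common_full, full_keys[[1]]), ,
                                  drop = FALSE]
  ord <- order(ref_sites$chrom, ref_sites$pos)
  pop <- unlist(lapply(cohorts, function(g)
    if (is.null(g$pop)) rep(NA_character_, nrow(g$geno)) else g$pop))
  list(genotypes = genotype_matrix(geno[, ord, drop = FALSE],
                                   ref_sites[ord, , drop = FALSE],
                                   ploidy = ploidy,
                                   pop = if (!all(is.na(pop))) pop),
       n_allele_mismatch = n_mismatch)
}
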