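#' HMM parameters for the ROH caller
#'
#' @param het_error emission probability of a heterozygous call inside an
#'   autozygous tract (absorbs genotyping error; default 0.001)
#' @param az_mean_bp expected autozygous tract length in bp (default 1 Mb);
#'   sets the AZ exit rate 1/az_mean_bp per bp
#' @param hw_mean_bp expected non-autozygous stretch in bp (default 10 Mb);
#'   sets the entry rate 1/hw_mean_bp per bp
#' @param quality_min Phred-scale filter: only segments with quality
#'   strictly greater than this are kept (default 50)
#' @return list of class `roh_params`
#' @export
roh_params <- function(het_error = 0.001, az_mean_bp = 1e6,
                       hw_mean_bp = 1e7, quality_min = 50) {
  stopifnot(het_error >= 0, het_error < 1, az_mean_bp > 0, hw_mean_bp > 0)
  structure(list(het_error = het_error, az_mean_bp = az_mean_bp,
                 hw_mean_bp = hw_mean_bp, quality_min = quality_min),
            class = "roh_params")
}

## forward-backward posterior of the AZ state for one sample / chromosome.
## emissions: P(het|AZ) = e, hom split by allele frequency; P(.|HW) from
## Hardy-Weinberg at the cohort frequency.  Transitions are the two-state
## continuous process with rates 1/az_mean (AZ->HW) and 1/hw_mean (HW->AZ),
## integrated over the inter-site distance.
roh_posterior <- function(obs, pos, p, params) {
  n <- length(obs)
  e <- params$het_error
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  em_az <- ifelse(obs == 1L, e,
                  (1 - e) * ifelse(obs == 0L, 1 - p, p))
  em_hw <- ifelse(obs == 1L, 2 * p * (1 - p),
                  ifelse(obs == 0L, (1 - p)^2, p^2))
  a <- 1 / params$az_mean_bp   # AZ -> HW rate
  b <- 1 / params$hw_mean_bp   # HW -> AZ rate
  s <- a + b
  pi_az <- b / s; pi_hw <- a / s
  d <- diff(pos)
  E <- exp(-s * d)
  t_aa <- pi_az + pi_hw * E   # AZ -> AZ
  t_ah <- pi_hw * (1 - E)
  t_ha <- pi_az * (1 - E)
  t_hh <- pi_hw + pi_az * E
  fa <- numeric(n); fh <- numeric(n); scale <- numeric(n)
  fa[1] <- pi_az * em_az[1]; fh[1] <- pi_hw * em_hw[1]
  scale[1] <- fa[1] + fh[1]
  fa[1] <- fa[1] / scale[1]; fh[1] <- fh[1] / scale[1]
  for (i in 2:n) {
    fa[i] <- (fa[i - 1] * t_aa[i - 1] + fh[i - 1] * t_ha[i - 1]) * em_az[i]
    fh[i] <- (fa[i - 1] * t_ah[i - 1] + fh[i - 1] * t_hh[i - 1]) * em_hw[i]
    scale[i] <- fa[i] + fh[i]
    fa[i] <- fa[i] / scale[i]; fh[i] <- fh[i] / scale[i]
  }
  ba <- numeric(n); bh <- numeric(n)
  ba[n] <- 1; bh[n] <- 1
  for (i in (n - 1):1) {
    ba[i] <- (t_aa[i] * em_az[i + 1] * ba[i + 1] +
                t_ah[i] * em_hw[i + 1] * bh[i + 1])
    bh[i] <- (t_ha[i] * em_az[i + 1] * ba[i + 1] +
                t_hh[i] * em_hw[i + 1] * bh[i + 1])
    norm <- ba[i] + bh[i]
    ba[i] <- ba[i] / norm; bh[i] <- bh[i] / norm
  }
  post_az <- fa * ba / (fa * ba + fh * bh)
  post_az
}

#' Call runs of homozygosity with a two-state HMM
#'
#' Per sample and chromosome, a two-state HMM (AZ autozygous / HW
#' non-autozygous) is decoded by posterior probability; maximal runs of
#' sites with P(AZ) > 0.5 become segments.  Segment quality is the mean of
#' the per-site Phred scores -10 log10(1 - P(AZ)) over the run (per-site
#' scores capped at 100), the convention of HMM-based ROH callers; segments
#' with quality <= `quality_min` are filtered out (strictly-greater
#' retention).
#'
#' @param g diploid genotype_matrix with sorted positions per chromosome
#' @param params [roh_params()]
#' @return data.frame of segments: sample, chrom, start_bp, end_bp,
#'   n_sites, quality, class (NA until [fit_roh_classes()])
#' @export
call_roh <- function(g, params = roh_params()) {
  stopifnot(inherits(g, "genotype_matrix"), g$ploidy == 2L)
  p_all <- allele_freq(g)
  segs <- list()
  chroms <- sort(unique(g$sites$chrom))
  for (ch in chroms) {
    idx <- which(g$sites$chrom == ch)
    pos <- g$sites$pos[idx]
    if (is.unsorted(pos, strictly = FALSE))
      stop("positions unsorted on ", ch)
    for (s in sort(rownames(g$geno))) {
      obs_all <- g$geno[s, idx]
      ok <- !is.na(obs_all) & is.finite(p_all[idx]) &
        p_all[idx] > 0 & p_all[idx] < 1
      if (sum(ok) < 2L) next
      post <- roh_posterior(obs_all[ok], pos[ok], p_all[idx][ok], params)
      r <- rle(post > 0.5)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      az_runs <- which(r$values)
      ppos <- pos[ok]
      site_phred <- -10 * log10(pmax(1 - post, 1e-10))
      for (k in az_runs) {
        i0 <- starts[k]; i1 <- ends[k]
        qual <- mean(site_phred[i0:i1])
        segs[[length(segs) + 1L]] <- data.frame(
          sample = s, chrom = ch,
          start_bp = ppos[i0], end_bp = ppos[i1],
          n_sites = i1 - i0 + 1L, quality = qual,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(sample = character(), chrom = character(),
               start_bp = integer(), end_bp = integer(),
               n_sites = integer(), quality = numeric())
  out <- out[out$quality > params$quality_min, , drop = FALSE]
  out <- out[order(out$sample, out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out$class <- rep(NA_character_, nrow(out))
  out
}

#' Population-specific ROH size classes by Gaussian mixture
#'
#' Fits a 3-component Gaussian mixture (EM, multiple restarts, unequal
#' variances) on log10(segment length in bp) per population; components are
#' ordered by mean and the class boundaries b1 < b2 are the log-lengths
#' between adjacent component means where the weighted posterior
#' responsibility flips.  Populations with fewer than `min_segments`
#' segments fall back to the pooled model with a warning; persistent EM
#' degeneracy falls back to quantile boundaries with a diagnostic flag.
#'
#' @param segments data.frame from [call_roh()]
#' @param pop_map named character vector sample -> population (NULL = one
#'   pooled population)
#' @param min_segments minimum per-population segment count (default 30)
#' @param n_restarts EM restarts (default 10)
#' @param seed integer seed for restart jitter
#' @return list: `models` (per population: means, sds, weights on log10 bp,
#'   boundaries_bp, fallback flag), `segments` (input with `class` filled
#'   short/medium/long)
#' @export
fit_roh_classes <- function(segments, pop_map = NULL, min_segments = 30L,
                            n_restarts = 10L, seed = 1L) {
  if (!nrow(segments)) stop("no segments to classify")
  len <- segments$end_bp - segments$start_bp + 1
  loglen <- log10(len)
  pops <- if (is.null(pop_map)) rep("pooled", nrow(segments)) else {
    p <- unname(pop_map[segments$sample])
    if (anyNA(p)) stop("pop_map missing for some samples")
    p
  }
  fit_one <- function(x) {
    fit <- gmm3_em(x, n_restarts = n_restarts, seed = seed)
    if (is.null(fit)) {
      qs <- stats::quantile(x, c(1, 2) / 3)
      return(list(means = NA_real_, sds = NA_real_, weights = NA_real_,
                  boundaries_log10 = unname(qs),
                  boundaries_bp = unname(10^qs), fallback = TRUE))
    }
    b1 <- gaussian_crossing(fit$weights[1], fit$means[1], fit$sds[1],
                            fit$weights[2], fit$means[2], fit$sds[2])
    b2 <- gaussian_crossing(fit$weights[2], fit$means[2], fit$sds[2],
                            fit$weights[3], fit$means[3], fit$sds[3])
    list(means = fit$means, sds = fit$sds, weights = fit$weights,
         loglik = fit$loglik, boundaries_log10 = c(b1, b2),
         boundaries_bp = 10^c(b1, b2), fallback = FALSE)
  }
  pooled <- NULL
  models <- list()
  for (pp in unique(pops)) {
    x <- loglen[pops == pp]
    if (length(x) < min_segments) {
      warning("population ", pp, " has ", length(x),
              " segments (< ", min_segments, "); using pooled model")
      if (is.null(pooled)) pooled <- fit_one(loglen)
      models[[pp]] <- c(pooled, list(pooled_fallback = TRUE))
    } else {
      models[[pp]] <- c(fit_one(x), list(pooled_fallback = FALSE))
    }
  }
  cls <- character(nrow(segments))
  for (pp in unique(pops)) {
    b <- models[[pp]]$boundaries_log10
    sel <- pops == pp
    cls[sel] <- c("short", "medium", "long")[
      findInterval(loglen[sel], sort(b)) + 1L]
  }
  segments$class <- cls
  list(models = models, segments = segments)
}

#' Method-of-moments inbreeding coefficient
#'
#' Per sample, F = (O - E)/(M - E) where O is the observed homozygous-call
#' count over usable (non-missing, cohort-polymorphic) sites, M the usable
#' site count, and E the expected homozygous count under Hardy-Weinberg at
#' plain cohort allele frequencies with the 2N/(2N-1) small-sample
#' correction.  Frequencies are not recomputed leaving the focal sample
#' out.
#'
#' @param g diploid genotype_matrix
#' @param min_sites samples with fewer usable sites get F = NA (default
#'   100)
#' @return data.frame: sample, n_usable, obs_hom, exp_hom, F
#' @export
inbreeding_f <- function(g, min_sites = 100L) {
  stopifnot(inherits(g, "genotype_matrix"), g$ploidy == 2L)
  p <- allele_freq(g)
  ncall <- colSums(!is.na(g$geno))
  usable_site <- is.finite(p) & p > 0 & p < 1 & ncall >= 2L
  exp_het_site <- 2 * p * (1 - p) * (2 * ncall) / (2 * ncall - 1)
  res <- lapply(rownames(g$geno), function(s) {
    gi <- g$geno[s, ]
    use <- usable_site & !is.na(gi)
    M <- sum(use)
    O <- sum(gi[use] != 1L)
    E <- M - sum(exp_het_site[use])
    data.frame(sample = s, n_usable = M, obs_hom = O, exp_hom = E,
               F = if (M >= min_sites && (M - E) > 0) (O - E) / (M - E)
                   else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-sample ROH summaries and complete gene overlap
#'
#' Cumulative length and count per size class per sample, plus the count of
#' genes completely contained in an ROH segment ("complete overlap": the
#' whole gene interval lies inside a single segment).  Gene intervals come
#' from a BED file (0-based half-open) and are reconciled to the segments'
#' 1-based inclusive coordinates; containment is evaluated with a sorted
#' sweep per sample and chromosome.
#'
#' @param segments classified segments from [fit_roh_classes()]
#' @param gene_bed data.frame from [read_bed()] (optional)
#' @return list: `class_summary` (sample, class, n, cum_bp),
#'   `gene_counts` (sample, n_genes_contained; present when gene_bed given)
#' @export
roh_summaries <- function(segments, gene_bed = NULL) {
  len <- segments$end_bp - segments$start_bp + 1
  cs <- stats::aggregate(cbind(n = rep(1, nrow(segments)), cum_bp = len),
                         by = list(sample = segments$sample,
                                   class = segments$class), FUN = sum)
  out <- list(class_summary = cs[order(cs$sample, cs$class), ])
  rownames(out$class_summary) <- NULL
  if (!is.null(gene_bed)) {
    g1 <- data.frame(chrom = gene_bed$chrom,
                     start_bp = gene_bed$start + 1,  # to 1-based inclusive
                     end_bp = gene_bed$end)
    counts <- vapply(unique(segments$sample), function(s) {
      tot <- 0L
      for (ch in unique(g1$chrom)) {
        segs <- segments[segments$sample == s & segments$chrom == ch, ,
                         drop = FALSE]
        genes <- g1[g1$chrom == ch, , drop = FALSE]
        if (!nrow(segs) || !nrow(genes)) next
        segs <- segs[order(segs$start_bp), , drop = FALSE]
        ## sweep: candidate segment = last with start <= gene start
        j <- findInterval(genes$start_bp, segs$start_bp)
        ok <- j >= 1L
        tot <- tot + sum(ok & segs$end_bp[pmax(j, 1L)] >= genes$end_bp)
      }
      tot
    }, 1L)
    out$gene_counts <- data.frame(sample = names(counts),
                                  n_genes_contained = unname(counts),
                                  stringsAsFactors = FALSE)
  }
  out
}
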