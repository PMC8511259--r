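#' Variant-discovery saturation curve
#'
#' For each of `n_permutations` random sample orderings, adds samples one at
#' a time and counts the distinct sites carrying at least one non-reference
#' allele so far.  Reports the per-permutation curves, their mean, a
#' least-squares fit of count versus log(sample index) over the curve tail,
#' and the implied growth per additional 100 samples as a percentage of the
#' final count.
#'
#' @param g genotype_matrix (>= 2 samples)
#' @param n_permutations number of sample orderings (default 10)
#' @param seed integer seed
#' @param tail_start first sample index of the log-fit tail (default half
#'   the cohort)
#' @return list: `mean_curve`, `curves` (samples x permutations),
#'   `log_fit` (intercept, slope), `growth_per_100_pct`
#' @export
saturation_curve <- function(g, n_permutations = 10L, seed = 1L,
                             tail_start = NULL) {
  stopifnot(inherits(g, "genotype_matrix"), nrow(g$geno) >= 2L)
  n <- nrow(g$geno)
  nonref <- !is.na(g$geno) & g$geno > 0L
  curves <- with_substream(seed, "saturation", {
    vapply(seq_len(n_permutations), function(b) {
      ord <- sample.int(n)
      seen <- rep(FALSE, ncol(g$geno))
      out <- integer(n)
      for (i in seq_len(n)) {
        seen <- seen | nonref[ord[i], ]
        out[i] <- sum(seen)
      }
      out
    }, integer(n))
  })
  mean_curve <- rowMeans(curves)
  if (is.null(tail_start)) tail_start <- max(2L, floor(n / 2))
  ix <- seq.int(tail_start, n)
  fit <- stats::lm.fit(cbind(1, log(ix)), mean_curve[ix])
  slope <- fit$coefficients[2]
  growth <- slope * (log(n + 100) - log(n)) / mean_curve[n] * 100
  list(mean_curve = mean_curve, curves = curves,
       log_fit = c(intercept = unname(fit$coefficients[1]),
                   slope = unname(slope)),
       growth_per_100_pct = unname(growth))
}

#' Restrict truth genotypes to an array manifest (pseudo-array)
#'
#' @param truth genotype_matrix of held-out truth genotypes
#' @param manifest data.frame with chrom and pos columns (array site list);
#'   manifest rows matching no truth site are counted and dropped
#' @return list: `typed` (genotype_matrix on manifest sites),
#'   `typed_idx`, `withheld_idx` (indices into `truth` sites),
#'   `n_unmatched`
#' @export
make_pseudo_array <- function(truth, manifest) {
  stopifnot(inherits(truth, "genotype_matrix"))
  tk <- paste(truth$sites$chrom, truth$sites$pos, sep = ":")
  mk <- paste(manifest$chrom, manifest$pos, sep = ":")
  typed_idx <- which(tk %in% mk)
  n_unmatched <- sum(!(mk %in% tk))
  if (!length(typed_idx))
    stop("manifest shares no sites with the truth set")
  withheld_idx <- setdiff(seq_along(tk), typed_idx)
  list(typed = subset_genotypes(truth, sites = typed_idx),
       typed_idx = typed_idx, withheld_idx = withheld_idx,
       n_unmatched = n_unmatched)
}

#' Stand-in imputation engines
#'
#' Minimal imputers used only to exercise the evaluator; their quality
#' scores are NOT comparable to external imputation-engine r2 metrics.
#' `freq`: the dosage at every withheld site is twice the panel
#' non-reference allele frequency (constant across samples; quality 0 by
#' convention).  `nearest_haplotype`: each target sample copies the
#' genotypes of the panel sample minimizing the mismatch rate at typed
#' sites (tie: lowest panel index); quality is 1 - mismatch rate.
#'
#' @param pseudo typed-only genotype_matrix (the pseudo-array)
#' @param panel reference genotype_matrix covering typed and withheld sites
#' @param withheld_sites site table (chrom, pos, ...) or index vector into
#'   `panel` sites designating imputation targets
#' @param method "freq" or "nearest_haplotype"
#' @return list: `dosage` (target samples x withheld sites), `quality`
#'   (per withheld site), `sample_quality` (nearest_haplotype only),
#'   `withheld_idx` (indices into panel sites)
#' @export
impute_naive <- function(pseudo, panel, withheld_sites,
                         method = c("freq", "nearest_haplotype")) {
  method <- match.arg(method)
  stopifnot(inherits(pseudo, "genotype_matrix"),
            inherits(panel, "genotype_matrix"))
  if (!nrow(panel$geno)) stop("empty reference panel")
  pk <- site_keys(panel)
  if (is.numeric(withheld_sites)) {
    w_idx <- as.integer(withheld_sites)
  } else {
    wk <- paste(withheld_sites$chrom, withheld_sites$pos, sep = ":")
    w_idx <- which(paste(panel$sites$chrom, panel$sites$pos,
                         sep = ":") %in% wk)
  }
  t_idx <- match(site_keys(pseudo), pk)
  if (anyNA(t_idx)) stop("panel is missing ", sum(is.na(t_idx)),
                         " typed site(s)")
  n_t <- nrow(pseudo$geno)
  if (method == "freq") {
    af <- allele_freq(subset_genotypes(panel, sites = w_idx))
    dosage <- matrix(rep(panel$ploidy * af, each = n_t), nrow = n_t)
    rownames(dosage) <- rownames(pseudo$geno)
    return(list(dosage = dosage, quality = rep(0, length(w_idx)),
                withheld_idx = w_idx, method = method))
  }
  panel_typed <- panel$geno[, t_idx, drop = FALSE]
  dosage <- matrix(NA_real_, n_t, length(w_idx))
  rownames(dosage) <- rownames(pseudo$geno)
  sq <- numeric(n_t)
  for (i in seq_len(n_t)) {
    gi <- pseudo$geno[i, ]
    mm <- colMeans(gi != t(panel_typed), na.rm = TRUE)
    best <- which.min(mm)  # ties: lowest panel index
    dosage[i, ] <- panel$geno[best, w_idx]
    sq[i] <- 1 - mm[best]
  }
  list(dosage = dosage, quality = rep(mean(sq), length(w_idx)),
       sample_quality = stats::setNames(sq, rownames(pseudo$geno)),
       withheld_idx = w_idx, method = method)
}

#' Allele-frequency bin specification
#'
#' @param edges strictly increasing non-reference allele-frequency
#'   thresholds ending at 1 (default c(0.001, 0.01, 0.1, 0.5, 1)), giving
#'   bins (0, e1], (e1, e2], ...
#' @return object of class `af_bin_spec`
#' @export
af_bin_spec <- function(edges = c(0.001, 0.01, 0.1, 0.5, 1)) {
  stopifnot(all(diff(edges) > 0), edges[length(edges)] == 1)
  labels <- paste0("(", c(0, utils::head(edges, -1)), ",", edges, "]")
  structure(list(edges = edges, labels = labels), class = "af_bin_spec")
}

bin_of <- function(af, spec) {
  b <- findInterval(af, c(0, spec$edges), left.open = TRUE,
                    rightmost.closed = FALSE)
  b[af <= 0 | af > 1 | is.na(af)] <- NA_integer_
  b
}

#' Aggregate imputation R-squared by allele-frequency bin
#'
#' Pools all (true genotype, imputed dosage) pairs of the variants in each
#' allele-frequency bin and reports the squared Pearson correlation — the
#' "aggregate R2" semantics of the standard concordance utilities, as
#' opposed to averaging per-variant R2.  Per-variant R2 is also emitted for
#' diagnostics, along with the per-bin count of variants whose quality
#' score exceeds `quality_gt` (when quality scores are supplied).
#'
#' @param truth genotype_matrix of held-out true genotypes
#' @param dosage samples x sites dosage matrix aligned to `sites_idx`
#' @param sites_idx indices into `truth` sites matching dosage columns
#' @param af per-site allele frequency used for binning (panel AF by
#'   default upstream; truth AF for simulation studies)
#' @param bins [af_bin_spec()]
#' @param quality optional per-site quality scores
#' @param quality_min optional filter: keep sites with quality strictly
#'   greater than this before computing R2
#' @param quality_gt threshold for the reported high-quality variant count
#'   (default 0.5)
#' @return data.frame per bin: bin, n_variants, n_pairs, r2, reason (why
#'   undefined, if so), n_quality_gt
#' @export
aggregate_r2 <- function(truth, dosage, sites_idx, af,
                         bins = af_bin_spec(), quality = NULL,
                         quality_min = NULL, quality_gt = 0.5) {
  stopifnot(length(sites_idx) == ncol(dosage), length(af) == ncol(dosage))
  rows <- if (is.null(rownames(dosage))) seq_len(nrow(dosage))
          else rownames(dosage)
  tg <- truth$geno[rows, sites_idx, drop = FALSE]
  b <- bin_of(af, bins)
  keep <- !is.na(b)
  if (!is.null(quality) && !is.null(quality_min))
    keep <- keep & quality > quality_min
  rows <- lapply(seq_along(bins$edges), function(k) {
    sel <- which(keep & b == k)
    nq <- if (!is.null(quality))
      sum(quality[which(!is.na(b) & b == k)] > quality_gt) else NA_integer_
    if (!length(sel))
      return(data.frame(bin = bins$labels[k], n_variants = 0L,
                        n_pairs = 0L, r2 = NA_real_, reason = "no variants",
                        n_quality_gt = nq))
    tt <- as.vector(tg[, sel, drop = FALSE])
    dd <- as.vector(dosage[, sel, drop = FALSE])
    ok <- !is.na(tt) & !is.na(dd)
    tt <- tt[ok]; dd <- dd[ok]
    if (length(tt) < 2L)
      return(data.frame(bin = bins$labels[k], n_variants = length(sel),
                        n_pairs = length(tt), r2 = NA_real_,
                        reason = "fewer than 2 pairs", n_quality_gt = nq))
    if (stats::var(tt) == 0 || stats::var(dd) == 0)
      return(data.frame(bin = bins$labels[k], n_variants = length(sel),
                        n_pairs = length(tt), r2 = NA_real_,
                        reason = "zero variance", n_quality_gt = nq))
    data.frame(bin = bins$labels[k], n_variants = length(sel),
               n_pairs = length(tt), r2 = stats::cor(tt, dd)^2,
               reason = "", n_quality_gt = nq)
  })
  out <- do.call(rbind, rows)
  attr(out, "per_variant_r2") <- vapply(seq_along(af), function(j) {
    tt <- tg[, j]; dd <- dosage[, j]
    ok <- !is.na(tt) & !is.na(dd)
    if (sum(ok) < 2L || stats::var(tt[ok]) == 0 ||
        stats::var(dd[ok]) == 0) NA_real_
    else stats::cor(tt[ok], dd[ok])^2
  }, 1)
  out
}
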