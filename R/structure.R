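#' Read / validate an admixture Q matrix
#'
#' A Q matrix holds, per sample, its estimated ancestry fractions over K
#' components (rows sum to 1).  Q matrices are consumed, not estimated,
#' by this package.
#'
#' @param x numeric matrix (samples x K, rownames = sample ids) or a TSV
#'   path with columns sample, q_1..q_K
#' @param tol row-sum tolerance (default 1e-6)
#' @return validated numeric matrix of class `q_matrix`
#' @export
q_matrix <- function(x, tol = 1e-6) {
  if (is.character(x)) {
    df <- read_tsv(x)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    x <- m
  }
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("Q matrix needs K >= 2 components")
  if (any(x < 0 | x > 1)) stop("ancestry fractions must lie in [0, 1]")
  bad <- abs(rowSums(x) - 1) > tol
  if (any(bad))
    stop(sum(bad), " Q-matrix row(s) do not sum to 1 within ", tol)
  if (is.null(colnames(x))) colnames(x) <- paste0("K", seq_len(ncol(x)))
  class(x) <- c("q_matrix", class(x))
  x
}

#' Greedy LD pruning
#'
#' Sliding-window LD pruning in the style of PLINK's pairwise pruning: within
#' each window of `window_snps` sites (advancing by `step_snps`), every pair
#' of retained sites with squared genotype correlation above `r2_max` drops
#' the member with the lower minor allele frequency (tie: the later
#' position).  Deterministic left-to-right order.  Monomorphic sites have
#' undefined correlation and are never dropped on account of it.
#'
#' @param g diploid genotype_matrix
#' @param r2_max r-squared threshold (default 0.2)
#' @param window_snps window width in SNPs (default 50)
#' @param step_snps window step in SNPs (default 5)
#' @return integer vector of retained site indices
#' @export
ld_prune <- function(g, r2_max = 0.2, window_snps = 50L, step_snps = 5L) {
  stopifnot(inherits(g, "genotype_matrix"), window_snps >= 2L,
            step_snps >= 1L)
  m <- ncol(g$geno)
  if (m == 0L) return(integer())
  af <- allele_freq(g)
  maf <- pmin(af, 1 - af)
  keep <- rep(TRUE, m)
  ## per-chromosome windows: r2 across chromosomes is not meaningful
  for (ch in unique(g$sites$chrom)) {
    idx <- which(g$sites$chrom == ch)
    start <- 1L
    repeat {
      win <- idx[seq.int(start, min(start + window_snps - 1L, length(idx)))]
      act <- win[keep[win]]
      if (length(act) >= 2L) {
        cc <- suppressWarnings(
          stats::cor(g$geno[, act, drop = FALSE],
                     use = "pairwise.complete.obs"))
        for (a in seq_len(length(act) - 1L)) {
          if (!keep[act[a]]) next
          for (b in seq.int(a + 1L, length(act))) {
            if (!keep[act[b]]) next
            r2 <- cc[a, b]^2
            if (is.na(r2) || r2 <= r2_max) next
            drop <- if (maf[act[a]] < maf[act[b]]) act[a]
                    else if (maf[act[b]] < maf[act[a]]) act[b]
                    else max(act[a], act[b])  # tie: later position
            keep[drop] <- FALSE
            if (drop == act[a]) break
          }
        }
      }
      if (start + window_snps - 1L >= length(idx)) break
      start <- start + step_snps
    }
  }
  which(keep)
}

#' Principal component analysis of a genotype matrix
#'
#' Missing calls are mean-imputed per site; each site is centered by twice
#' its sample allele frequency and scaled by sqrt(2 p (1 - p)); the sample
#' covariance of the standardized matrix is eigendecomposed.  Monomorphic
#' sites carry no information and are dropped.  Sign convention: within each
#' component the largest-magnitude loading is positive.
#'
#' @param g diploid genotype_matrix (post-QC, LD-pruned input recommended)
#' @param n_components number of PCs to return
#' @return list with `scores` (samples x k), `eigenvalues` (all, length =
#'   rank bound, non-increasing), `loadings` (sites x k), `sites_used`
#'   (indices of polymorphic sites), `total_variance`
#' @export
pca_genotypes <- function(g, n_components = 10L) {
  stopifnot(inherits(g, "genotype_matrix"), g$ploidy == 2L)
  G <- g$geno
  mu <- colMeans(G, na.rm = TRUE)
  if (anyNA(G)) {
    for (j in which(colSums(is.na(G)) > 0L)) G[is.na(G[, j]), j] <- mu[j]
  }
  p <- mu / 2
  poly <- which(p > 0 & p < 1)
  X <- sweep(G[, poly, drop = FALSE], 2L, 2 * p[poly])
  X <- sweep(X, 2L, sqrt(2 * p[poly] * (1 - p[poly])), "/")
  sv <- svd(X)
  m <- length(poly)
  eigenvalues <- sv$d^2 / m
  rank <- sum(sv$d > max(sv$d) * 1e-10)
  k <- min(n_components, rank)
  if (k < n_components)
    warning("requested ", n_components, " components but rank is ", rank,
            "; truncated")
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(g$geno)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, eigenvalues = eigenvalues, loadings = loadings,
       sites_used = poly, total_variance = sum(X^2) / m)
}

#' Allele sharing between two cohorts
#'
#' The fraction of sites segregating in cohort A (non-reference allele
#' observed at least once) that also segregate in cohort B, matching sites
#' by (chrom, pos, ref, alt).  Directional by construction: sharing(A, B)
#' need not equal sharing(B, A).  This operationalizes a cross-cohort
#' allele-overlap summary; it is a documented stand-in, not a canonical
#' statistic.
#'
#' @param cohort_a,cohort_b genotype_matrix objects on a harmonized site
#'   universe (see [intersect_sites()])
#' @return shared fraction in [0, 1]
#' @export
allele_sharing <- function(cohort_a, cohort_b) {
  seg_a <- allele_counts(cohort_a)$ac > 0L
  if (!any(seg_a)) stop("cohort A has no segregating sites")
  keys_b <- site_keys(cohort_b)
  seg_b_keys <- keys_b[allele_counts(cohort_b)$ac > 0L]
  keys_a_seg <- site_keys(cohort_a)[seg_a]
  mean(keys_a_seg %in% seg_b_keys)
}

#' Dominant-ancestry assignment from a Q matrix
#'
#' A sample is labeled with its largest ancestry component when that
#' fraction meets the threshold (default >= 0.5), and `ADMIXED` otherwise.
#' An exact tie at the maximum (possible only at threshold = 0.5) is
#' ADMIXED by rule.
#'
#' @param q a [q_matrix()] (or coercible)
#' @param threshold dominance threshold (default 0.5)
#' @param comparator `">="` (default; matches the figure convention) or
#'   `">"`
#' @return data.frame (sample, label, max_q) with the threshold recorded in
#'   attributes
#' @export
assign_dominant_ancestry <- function(q, threshold = 0.5,
                                     comparator = c(">=", ">")) {
  comparator <- match.arg(comparator)
  q <- q_matrix(unclass(q))
  mx <- apply(q, 1L, max)
  arg <- apply(q, 1L, which.max)
  n_at_max <- rowSums(q >= mx - 1e-12)
  meets <- if (comparator == ">=") mx >= threshold else mx > threshold
  label <- ifelse(meets & n_at_max == 1L, colnames(q)[arg], "ADMIXED")
  out <- data.frame(sample = rownames(q), label = label, max_q = mx,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "threshold") <- threshold
  attr(out, "comparator") <- comparator
  out
}
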