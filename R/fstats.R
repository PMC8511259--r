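#' Site frequency table over populations
#'
#' Per population and site: the non-reference allele count and the sampled
#' (non-missing) allele count.  The site table is shared, so sites stay
#' aligned across populations.
#'
#' @param g genotype_matrix with population labels (or `pops` supplied)
#' @param pops optional per-sample population labels overriding `g$pop`
#' @return object of class `site_freq_table`: `ac`, `an` (sites x pops
#'   integer matrices), `sites`, `ploidy`
#' @export
site_freq_table <- function(g, pops = g$pop) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (is.null(pops)) stop("population labels required")
  pops <- as.character(pops)
  labs <- unique(pops)
  ac <- sapply(labs, function(p)
    colSums(g$geno[pops == p, , drop = FALSE], na.rm = TRUE))
  an <- sapply(labs, function(p)
    colSums(!is.na(g$geno[pops == p, , drop = FALSE])) * g$ploidy)
  structure(list(ac = ac, an = an, sites = g$sites, ploidy = g$ploidy),
            class = "site_freq_table")
}

#' Assemble a site frequency table from raw count matrices
#' @param ac,an sites x populations matrices of non-reference and sampled
#'   allele counts (same dimnames)
#' @param sites site table (chrom, pos, ...); defaults to one dummy
#'   chromosome with unit spacing
#' @param ploidy 1 or 2
#' @return `site_freq_table`
#' @export
freq_table_from_counts <- function(ac, an, sites = NULL, ploidy = 2L) {
  ac <- as.matrix(ac); an <- as.matrix(an)
  stopifnot(all(dim(ac) == dim(an)), all(ac >= 0), all(ac <= an))
  if (is.null(sites))
    sites <- data.frame(chrom = "chr1", pos = seq_len(nrow(ac)),
                        ref = "A", alt = "G")
  structure(list(ac = ac, an = an, sites = sites, ploidy = ploidy),
            class = "site_freq_table")
}

## contiguous genomic block ids for the jackknife
genomic_blocks <- function(sites, block_size_bp) {
  paste(sites$chrom, (sites$pos - 1) %/% block_size_bp, sep = "_")
}

#' Weighted block jackknife for a ratio (or mean) statistic
#'
#' The statistic is sum(num)/sum(den) over sites; delete-one-block
#' estimates are formed from per-block sums and combined with the weighted
#' jackknife of Busing et al. (block weight = usable-site count), the
#' behavior of the standard f-statistic toolchain.
#'
#' @param num,den per-site numerator and denominator terms (use den = 1 for
#'   a plain mean)
#' @param block per-site block id
#' @return list: `statistic`, `se`, `z`, `n_blocks`, `n_sites`,
#'   `per_block` (block, num, den, n_sites), `delete_one` (per-block
#'   leave-one-out estimates)
#' @export
block_jackknife <- function(num, den, block) {
  stopifnot(length(num) == length(den), length(num) == length(block))
  keep <- is.finite(num) & is.finite(den)
  num <- num[keep]; den <- den[keep]; block <- block[keep]
  bs <- rowsum(cbind(num, den, 1), block)
  g <- nrow(bs)
  if (g < 2L) stop("block jackknife needs >= 2 blocks with usable sites")
  tot_num <- sum(bs[, 1]); tot_den <- sum(bs[, 2])
  if (tot_den == 0) stop("zero denominator over all sites")
  theta <- tot_num / tot_den
  theta_del <- (tot_num - bs[, 1]) / (tot_den - bs[, 2])
  m <- bs[, 3]
  n <- sum(m)
  h <- n / m
  theta_J <- g * theta - sum((1 - m / n) * theta_del)
  tau <- h * theta - (h - 1) * theta_del
  var_J <- sum((tau - theta_J)^2 / (h - 1)) / g
  se <- sqrt(var_J)
  list(statistic = theta, se = se,
       z = if (se > 0) theta / se else NA_real_,
       n_blocks = g, n_sites = n,
       per_block = data.frame(block = rownames(bs), num = bs[, 1],
                              den = bs[, 2], n_sites = m, row.names = NULL),
       delete_one = theta_del)
}

block_stat_result <- function(jk, populations, statistic_name) {
  structure(list(statistic = jk$statistic, se = jk$se, z = jk$z,
                 n_blocks = jk$n_blocks, n_sites = jk$n_sites,
                 populations = populations, name = statistic_name,
                 per_block = jk$per_block),
            class = "block_stat")
}

#' @export
print.block_stat <- function(x, ...) {
  cat(sprintf("%s(%s) = %.6g  SE %.3g  Z %.2f  (%d blocks, %d sites)\n",
              x$name, paste(x$populations, collapse = ", "),
              x$statistic, x$se, x$z, x$n_blocks, x$n_sites))
  invisible(x)
}

freq_of <- function(ft, pop) {
  if (!pop %in% colnames(ft$ac)) stop("unknown population: ", pop)
  ft$ac[, pop] / ft$an[, pop]
}

#' f3 admixture statistic
#'
#' f3(A, B; C) estimates the mean product of allele-frequency differences
#' (c - a)(c - b) with the finite-sample heterozygosity correction
#' c(1 - c)/(n_C - 1) subtracted for the target C.  A significantly
#' negative value (Z < -3) indicates that C is admixed between populations
#' related to A and B.  Standard errors come from a weighted block
#' jackknife over contiguous genomic blocks.
#'
#' @param freqs `site_freq_table`
#' @param A,B source population names; `C` target population name
#' @param block_size_bp jackknife block size (default 5 Mb)
#' @return `block_stat` with roles A, B, C
#' @export
f3_statistic <- function(freqs, A, B, C, block_size_bp = 5e6) {
  a <- freq_of(freqs, A); b <- freq_of(freqs, B); c <- freq_of(freqs, C)
  nA <- freqs$an[, A]; nB <- freqs$an[, B]; nC <- freqs$an[, C]
  tot_ac <- freqs$ac[, A] + freqs$ac[, B] + freqs$ac[, C]
  tot_an <- nA + nB + nC
  usable <- nA >= 2L & nB >= 2L & nC >= 2L & tot_ac > 0L & tot_ac < tot_an
  for (nm in c(A, B, C)) {
    if (!any(usable & freqs$an[, nm] >= 2L))
      stop("population ", nm, " has zero usable sites")
  }
  term <- (c - a) * (c - b) - c * (1 - c) / (nC - 1)
  blocks <- genomic_blocks(freqs$sites, block_size_bp)
  jk <- block_jackknife(term[usable], rep(1, sum(usable)), blocks[usable])
  block_stat_result(jk, c(A = A, B = B, C = C), "f3")
}

#' Patterson's D statistic (ABBA-BABA)
#'
#' D(W, X; Y, Outgroup) on derived-allele frequencies, with the outgroup's
#' major allele defining the ancestral state.  Sites where the outgroup is
#' polymorphic beyond `outgroup_tol` are dropped.  Positive D indicates
#' excess derived-allele sharing between Y and W relative to X.
#'
#' @param freqs `site_freq_table`
#' @param W,X,Y,Z_out population names (Z_out = outgroup)
#' @param block_size_bp jackknife block size (default 5 Mb)
#' @param outgroup_tol maximum outgroup minor-allele frequency (default
#'   0.01)
#' @return `block_stat` with roles W, X, Y, Z_out
#' @export
d_statistic <- function(freqs, W, X, Y, Z_out, block_size_bp = 5e6,
                        outgroup_tol = 0.01) {
  w <- freq_of(freqs, W); x <- freq_of(freqs, X)
  y <- freq_of(freqs, Y); z <- freq_of(freqs, Z_out)
  usable <- freqs$an[, W] >= 2L & freqs$an[, X] >= 2L &
    freqs$an[, Y] >= 2L & freqs$an[, Z_out] >= 1L &
    pmin(z, 1 - z, na.rm = FALSE) <= outgroup_tol & !is.na(z)
  ## polarize: outgroup major allele is ancestral
  flip <- !is.na(z) & z > 0.5
  w[flip] <- 1 - w[flip]; x[flip] <- 1 - x[flip]
  y[flip] <- 1 - y[flip]; z[flip] <- 1 - z[flip]
  num <- (w - x) * (y - z)
  den <- (w + x - 2 * w * x) * (y + z - 2 * y * z)
  informative <- usable & !is.na(num) & !is.na(den) & den > 0
  if (sum(den[informative]) == 0)
    stop("zero D-statistic denominator (", sum(informative),
         " usable sites, none informative)")
  blocks <- genomic_blocks(freqs$sites, block_size_bp)
  jk <- block_jackknife(num[informative], den[informative],
                        blocks[informative])
  block_stat_result(jk, c(W = W, X = X, Y = Y, Z_out = Z_out), "D")
}

#' Pairwise FST (Hudson or Weir-Cockerham)
#'
#' Ratio-of-averages FST over sites: the mean is sum(numerator) /
#' sum(denominator), robust to rare variants.  Hudson's estimator uses the
#' unbiased within-population heterozygosity correction; the
#' Weir-Cockerham form is the allele-level ANOVA estimator (the two agree
#' within sampling noise at equal sample sizes).  Works for haploid tables
#' (allele counts are then sample counts).
#'
#' @param freqs `site_freq_table`
#' @param pop1,pop2 population names
#' @param estimator "hudson" (default) or "weir_cockerham"
#' @return list: `fst` (ratio of averages), `per_site` (num, den, clipped
#'   ratio), `n_sites`
#' @export
fst_pairwise <- function(freqs, pop1, pop2,
                         estimator = c("hudson", "weir_cockerham")) {
  estimator <- match.arg(estimator)
  p1 <- freq_of(freqs, pop1); p2 <- freq_of(freqs, pop2)
  n1 <- freqs$an[, pop1]; n2 <- freqs$an[, pop2]
  usable <- n1 >= 2L & n2 >= 2L & is.finite(p1) & is.finite(p2)
  p1 <- p1[usable]; p2 <- p2[usable]; n1 <- n1[usable]; n2 <- n2[usable]
  if (estimator == "hudson") {
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
  } else {
    nbar <- (n1 + n2) / 2
    nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    msb <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2)  # r - 1 = 1
    msw <- (n1 * p1 * (1 - p1) + n2 * p2 * (1 - p2)) / (n1 + n2 - 2)
    num <- msb - msw
    den <- msb + (nc - 1) * msw
  }
  poly <- den > 0
  fst <- sum(num[poly]) / sum(den[poly])
  per_site <- data.frame(num = num, den = den,
                         fst = pmin(1, pmax(-1, ifelse(den > 0,
                                                       num / den, NA))))
  list(fst = fst, per_site = per_site, n_sites = sum(poly),
       estimator = estimator)
}

#' Build an admixture network from f3 results
#'
#' Keeps only results with f3 < 0 and Z below the significance threshold
#' (signed rule, default Z < -3); edges connect the donor pair (A, B) for
#' each target C.
#'
#' @param f3_results list of `block_stat` objects from [f3_statistic()]
#' @param z_max signed Z threshold (default -3)
#' @return list per target: `edges` data.frame (A, B, f3, z) and `degree`
#'   (named donor edge counts); targets with no qualifying pair get an
#'   empty network
#' @export
build_admixture_network <- function(f3_results, z_max = -3) {
  rows <- lapply(f3_results, function(r) {
    stopifnot(inherits(r, "block_stat"))
    if (is.na(r$z) || r$statistic >= 0 || r$z >= z_max) return(NULL)
    data.frame(target = r$populations[["C"]], A = r$populations[["A"]],
               B = r$populations[["B"]], f3 = r$statistic, z = r$z,
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  if (is.null(edges))
    edges <- data.frame(target = character(), A = character(),
                        B = character(), f3 = numeric(), z = numeric())
  nets <- lapply(split(edges, edges$target), function(e) {
    list(edges = e[order(e$z), , drop = FALSE],
         degree = sort(table(c(e$A, e$B)), decreasing = TRUE))
  })
  structure(list(edges = edges, networks = nets, z_max = z_max),
            class = "admixture_network")
}

#' @export
print.admixture_network <- function(x, ...) {
  cat(sprintf("<admixture_network> %d significant edge(s) over %d target(s) (Z < %g)\n",
              nrow(x$edges), length(x$networks), x$z_max))
  invisible(x)
}
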