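## Trees are handled as ape "phylo" objects; internal node labels carry
## bootstrap supports in [0, 1].  For topology surgery we convert to a
## nested-list form and back through newick, which keeps node numbering
## consistent with ape's parser.

#' Read a support tree from newick
#'
#' @param path newick file with branch lengths and internal-node support
#'   labels in [0, 1]
#' @return ape `phylo` with `node.label`
#' @export
read_support_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr$edge.length) || any(tr$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  tr
}

node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(rep(NA_real_, tree$Nnode))
  suppressWarnings(as.numeric(tree$node.label))
}

as_nested <- function(tree) {
  ntip <- ape::Ntip(tree)
  sup <- node_supports(tree)
  build <- function(node, len) {
    if (node <= ntip)
      return(list(label = tree$tip.label[node], len = len, children = NULL))
    kids <- which(tree$edge[, 1] == node)
    list(label = NA_character_, len = len,
         support = sup[node - ntip],
         children = lapply(kids, function(e)
           build(tree$edge[e, 2], tree$edge.length[e])))
  }
  root <- ntip + 1L
  build(root, 0)
}

to_newick <- function(node) {
  fmt_len <- function(l) format(l, scientific = FALSE, trim = TRUE,
                                digits = 15)
  rec <- function(nd) {
    if (is.null(nd$children))
      return(paste0(nd$label, ":", fmt_len(nd$len)))
    inner <- paste(vapply(nd$children, rec, ""), collapse = ",")
    sup <- if (!is.null(nd$support) && !is.na(nd$support))
      format(nd$support, trim = TRUE) else ""
    paste0("(", inner, ")", sup, ":", fmt_len(nd$len))
  }
  paste0(rec(node), ";")
}

#' Collapse weakly supported branches into polytomies
#'
#' Internal edges whose child node's bootstrap support is below
#' `min_support` are contracted: the child's subtrees reattach to its
#' parent with the removed edge's length added to each child branch.  The
#' leaf set is unchanged; the root is exempt (its "support" is
#' meaningless).  Missing supports are treated as 1 (never collapsed).
#'
#' @param tree ape `phylo` with supports in `node.label`
#' @param min_support collapse threshold (default 0.9)
#' @return collapsed `phylo`
#' @export
collapse_low_support <- function(tree, min_support = 0.9) {
  nested <- as_nested(tree)
  collapse <- function(nd) {
    if (is.null(nd$children)) return(nd)
    nd$children <- lapply(nd$children, collapse)
    out <- list()
    for (ch in nd$children) {
      sup <- if (is.null(ch$support) || is.na(ch$support)) 1 else ch$support
      if (!is.null(ch$children) && sup < min_support) {
        for (gc in ch$children) {
          gc$len <- gc$len + ch$len
          out[[length(out) + 1L]] <- gc
        }
      } else out[[length(out) + 1L]] <- ch
    }
    nd$children <- out
    nd
  }
  ape::read.tree(text = to_newick(collapse(nested)))
}

## per-node max leaf-pair patristic distance and descendant tips,
## postorder over the edge matrix
clade_stats <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  down <- numeric(nn)      # max distance node -> descendant leaf
  maxpair <- numeric(nn)   # max leaf-pair distance within clade
  tips <- vector("list", nn)
  for (i in seq_len(ntip)) tips[[i]] <- i
  kids_h <- vector("list", nn)  # child heights (edge + child's down)
  done <- rep(FALSE, nn)
  finalize <- function(nd) {
    hs <- sort(kids_h[[nd]], decreasing = TRUE)
    down[nd] <<- hs[1]
    if (length(hs) >= 2L) maxpair[nd] <<- max(maxpair[nd], hs[1] + hs[2])
    done[nd] <<- TRUE
  }
  ## postorder: every edge in a child's subtree precedes the child's own
  ## up-edge, so the child can be finalized when its up-edge is reached
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    if (ch > ntip && !done[ch]) finalize(ch)
    kids_h[[par]] <- c(kids_h[[par]], tr$edge.length[e] + down[ch])
    tips[[par]] <- c(tips[[par]], tips[[ch]])
    maxpair[par] <- max(maxpair[par], maxpair[ch])
  }
  root <- ntip + 1L
  if (!done[root]) finalize(root)
  list(maxpair = maxpair, tips = tips)
}

#' Pick clusters at a patristic-distance cutoff
#'
#' Depth-first from the root, a clade is emitted as a cluster iff the
#' maximum pairwise patristic distance among its leaves is at most
#' `distance_cutoff` and it holds at least two leaves; only maximal such
#' clades are emitted (no nested clusters).  Leaves in no cluster are
#' returned as singletons.
#'
#' @param tree (collapsed) `phylo`
#' @param distance_cutoff maximum intra-cluster patristic distance in
#'   substitutions/site (> 0)
#' @return list: `clusters` (each: members, node, max_dist), `singletons`
#'   (leaf labels), `cutoff`
#' @export
pick_clusters <- function(tree, distance_cutoff) {
  if (distance_cutoff <= 0) stop("distance_cutoff must be > 0")
  ntip <- ape::Ntip(tree)
  st <- clade_stats(tree)
  clusters <- list()
  walk <- function(node) {
    if (node <= ntip) return(invisible())
    if (st$maxpair[node] <= distance_cutoff &&
        length(st$tips[[node]]) >= 2L) {
      clusters[[length(clusters) + 1L]] <<- list(
        members = sort(tree$tip.label[st$tips[[node]]]),
        node = node, max_dist = st$maxpair[node])
      return(invisible())
    }
    for (ch in tree$edge[tree$edge[, 1] == node, 2]) walk(ch)
  }
  walk(ntip + 1L)
  in_cluster <- unlist(lapply(clusters, `[[`, "members"))
  list(clusters = clusters,
       singletons = sort(setdiff(tree$tip.label, in_cluster)),
       cutoff = distance_cutoff)
}

#' Default cutoff grid for the cluster scan
#'
#' Genetic-distance cutoffs spanning 1e-5 to 4e-3 substitutions/site.
#' @return numeric vector
#' @export
default_cutoff_grid <- function() {
  sort(unique(c(seq(1e-5, 9e-5, 1e-5), seq(1e-4, 9e-4, 1e-4),
                seq(1e-3, 4e-3, 5e-4))))
}

#' Scan distance cutoffs for the one maximizing large clusters
#'
#' Runs [pick_clusters()] at every cutoff in the grid and picks the cutoff
#' with the most clusters whose size exceeds `large_min`.  Ties break first
#' toward the fewest singletons (a cutoff sitting exactly on a cluster's
#' diameter strands boundary members as singletons while still counting the
#' cluster as large), then toward the smaller cutoff (finer resolution).
#'
#' @param tree (collapsed) `phylo`
#' @param grid cutoff grid (default [default_cutoff_grid()])
#' @param large_min a cluster is "large" when its size is strictly greater
#'   than this (default 10)
#' @return list: `chosen` cutoff, `tally` (cutoff, n_clusters, n_large,
#'   n_singletons), `clusters` at the chosen cutoff
#' @export
scan_cutoffs <- function(tree, grid = default_cutoff_grid(),
                         large_min = 10L) {
  if (!length(grid)) stop("empty cutoff grid")
  grid <- sort(grid)
  rows <- lapply(grid, function(cu) {
    pc <- pick_clusters(tree, cu)
    sizes <- lengths(lapply(pc$clusters, `[[`, "members"))
    data.frame(cutoff = cu, n_clusters = length(pc$clusters),
               n_large = sum(sizes > large_min),
               n_singletons = length(pc$singletons))
  })
  tally <- do.call(rbind, rows)
  best <- tally[tally$n_large == max(tally$n_large), ]
  best <- best[best$n_singletons == min(best$n_singletons), ]
  chosen <- min(best$cutoff)
  list(chosen = chosen, tally = tally,
       clusters = pick_clusters(tree, chosen))
}

#' Cluster-defining SNVs and sub-haplogroup definitions
#'
#' For every cluster, computes the per-site haploid Hudson FST between the
#' cluster and all remaining samples (after dropping singleton variants and
#' sites with missingness above `max_missingness`), and defines the
#' sub-haplogroup by the sites with FST = 1 (within 1e-12) and
#' within-cluster derived allele frequency = 1.  Clusters with an empty
#' defining set produce no sub-haplogroup; clusters with identical defining
#' sets are merged (and the merge recorded).
#'
#' @param haplotypes haploid genotype_matrix
#' @param clusters `clusters` element from [pick_clusters()] (or a list of
#'   character member vectors)
#' @param max_missingness site filter (default 0.01)
#' @param drop_singletons drop variants whose derived allele occurs once
#'   overall (default TRUE)
#' @return list of sub-haplogroups, each: `id`, `members`, `defining_sites`
#'   (site indices into `haplotypes`), `s_bar` (mean per-member derived
#'   count at cluster-private segregating sites, i.e. since the cluster
#'   MRCA), `member_counts`, `merged_from`
#' @export
informative_snps <- function(haplotypes, clusters, max_missingness = 0.01,
                             drop_singletons = TRUE) {
  stopifnot(inherits(haplotypes, "genotype_matrix"),
            haplotypes$ploidy == 1L)
  members_of <- lapply(clusters, function(cl)
    if (is.list(cl)) cl$members else cl)
  g <- haplotypes$geno
  miss <- colMeans(is.na(g))
  dac <- colSums(g, na.rm = TRUE)
  site_ok <- miss <= max_missingness &
    (!drop_singletons | dac != 1L)
  defs <- vector("list", length(members_of))
  sbars <- numeric(length(members_of))
  counts <- vector("list", length(members_of))
  keep <- logical(length(members_of))
  for (i in seq_along(members_of)) {
    mem <- members_of[[i]]
    if (length(mem) < 2L) {
      warning("cluster ", i, " has fewer than 2 members; skipped")
      next
    }
    inside <- rownames(g) %in% mem
    p1 <- colMeans(g[inside, , drop = FALSE], na.rm = TRUE)
    p2 <- colMeans(g[!inside, , drop = FALSE], na.rm = TRUE)
    n1 <- colSums(!is.na(g[inside, , drop = FALSE]))
    n2 <- colSums(!is.na(g[!inside, , drop = FALSE]))
    num <- (p1 - p2)^2 - p1 * (1 - p1) / pmax(n1 - 1, 1) -
      p2 * (1 - p2) / pmax(n2 - 1, 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    fst <- ifelse(den > 0, num / den, NA_real_)
    defining <- which(site_ok & !is.na(fst) & abs(fst - 1) <= 1e-12 &
                        p1 == 1)
    ## dating counts keep singletons: terminal-branch variants are real
    ## post-MRCA mutations and dropping them would bias the clock down
    private_seg <- which(miss <= max_missingness & p2 == 0 &
                           p1 > 0 & p1 < 1)
    percount <- rowSums(g[inside, private_seg, drop = FALSE],
                        na.rm = TRUE)
    defs[[i]] <- defining
    sbars[i] <- mean(percount)
    counts[[i]] <- percount
    attr(counts[[i]], "site_freqs") <- p1[private_seg]
    keep[i] <- length(defining) > 0L
  }
  ## merge clusters with identical defining sets
  idx <- which(keep)
  sig <- vapply(defs[idx], function(d) paste(d, collapse = ","), "")
  groups <- split(idx, sig)
  out <- lapply(seq_along(groups), function(j) {
    ii <- groups[[j]]
    mc <- unlist(lapply(counts[ii], as.vector))
    list(id = paste0("SH", j),
         members = sort(unlist(members_of[ii])),
         defining_sites = defs[[ii[1]]],
         s_bar = mean(mc),
         member_counts = mc,
         private_site_freqs = unlist(lapply(counts[ii],
                                            attr, "site_freqs")),
         merged_from = ii)
  })
  ## stable ordering by first member
  out[order(vapply(out, function(s) s$members[1], ""))]
}

#' Date sub-haplogroup lineages
#'
#' Poznik-style lineage dating: the age of a sub-haplogroup's MRCA is
#' t = S_bar / (mu * L) with S_bar the mean per-member count of derived
#' SNVs accumulated since the MRCA, mu the mutation rate per site per year
#' and L the callable region length.  If the rate is per generation,
#' t = S_bar * g / (mu_gen * L) with g years per generation.  95\%
#' confidence intervals by bootstrap.  The default resampling unit is the
#' private SNV site: S_bar equals the sum of within-cluster frequencies of
#' the cluster-private segregating sites, and conditional on the clade
#' these mutation events are independent, whereas per-member counts share
#' tree branches and a member-level bootstrap understates the variance
#' (`boot_unit = "member"` is provided for comparison).
#'
#' @param subhaps list from [informative_snps()]
#' @param mu mutation rate (default 0.76e-9 per site per year)
#' @param L callable region length in bp (default 1e7)
#' @param g years per generation (default 30; used only with
#'   `rate_per = "generation"`)
#' @param rate_per "year" (default) or "generation"
#' @param n_boot bootstrap replicates (default 1000)
#' @param boot_unit "site" (default) or "member"
#' @param seed integer seed
#' @return data.frame: id, n_members, n_defining, s_bar, age_years,
#'   ci_lo, ci_hi
#' @export
date_lineages <- function(subhaps, mu = 0.76e-9, L = 1e7, g = 30,
                          rate_per = c("year", "generation"),
                          n_boot = 1000L, boot_unit = c("site", "member"),
                          seed = 1L) {
  rate_per <- match.arg(rate_per)
  boot_unit <- match.arg(boot_unit)
  to_years <- function(sbar) {
    if (rate_per == "year") sbar / (mu * L) else sbar * g / (mu * L)
  }
  rows <- with_substream(seed, "date_lineages", {
    lapply(subhaps, function(sh) {
      sbar <- sh$s_bar
      if (is.na(sbar) || sbar == 0) {
        return(data.frame(id = sh$id, n_members = length(sh$members),
                          n_defining = length(sh$defining_sites),
                          s_bar = sbar, age_years = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_,
                          flag = "zero_snv_count"))
      }
      boots <- if (boot_unit == "site" &&
                     !is.null(sh$private_site_freqs)) {
        ## Poisson bootstrap: both which sites mutated and how many sites
        ## there are is Poisson, so each site enters with Poisson(1)
        ## multiplicity; the replicate variance is then sum(f^2), the
        ## compound-Poisson truth conditional on the clade
        f <- sh$private_site_freqs
        vapply(seq_len(n_boot), function(b)
          to_years(sum(f * stats::rpois(length(f), 1))), 1)
      } else {
        cnt <- sh$member_counts
        vapply(seq_len(n_boot), function(b)
          to_years(mean(sample(cnt, replace = TRUE))), 1)
      }
      ci <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
      data.frame(id = sh$id, n_members = length(sh$members),
                 n_defining = length(sh$defining_sites),
                 s_bar = sbar, age_years = to_years(sbar),
                 ci_lo = ci[1], ci_hi = ci[2], flag = "")
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney / Wilcoxon rank-sum comparison of lineage ages
#'
#' Exact two-sided test by full enumeration of group assignments when the
#' combined sample size is at most `exact_max` (ties handled by midranks,
#' so identical groups give p = 1); normal approximation with tie
#' correction and continuity correction otherwise.
#'
#' @param ages_a,ages_b numeric age vectors (each >= 3 values)
#' @param exact_max enumeration limit on combined n (default 20)
#' @return list: `U` (for group A), `p_value`, `method`
#' @export
compare_group_ages <- function(ages_a, ages_b, exact_max = 20L) {
  if (length(ages_a) < 3L || length(ages_b) < 3L)
    stop("each group needs >= 3 ages")
  n1 <- length(ages_a); n2 <- length(ages_b); n <- n1 + n2
  pooled <- c(ages_a, ages_b)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  EU <- n1 * n2 / 2
  if (n <= exact_max) {
    combos <- utils::combn(n, n1)
    Us <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - EU) >= abs(U_obs - EU) - 1e-12)
    return(list(U = U_obs, p_value = p, method = "exact"))
  }
  ties <- table(pooled)
  tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
  varU <- n1 * n2 / 12 * ((n + 1) - tie_corr)
  z <- (abs(U_obs - EU) - 0.5) / sqrt(varU)
  list(U = U_obs, p_value = min(1, 2 * stats::pnorm(-z)),
       method = "normal_approx")
}
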