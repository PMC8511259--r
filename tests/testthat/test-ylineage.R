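# maximal-clade oracle using the cophenetic distance matrix (independent
# of the incremental maxpair computation in pick_clusters)
pick_oracle <- function(tree, cutoff) {
  dm <- ape::cophenetic.phylo(tree)
  ntip <- ape::Ntip(tree)
  clusters <- list()
  walk <- function(node) {
    if (node <= ntip) return(invisible())
    tips <- tree$tip.label[arabpop:::clade_tips(tree, node)]
    if (length(tips) >= 2 &&
        max(dm[tips, tips]) <= cutoff) {
      clusters[[length(clusters) + 1L]] <<- sort(tips)
      return(invisible())
    }
    for (ch in tree$edge[tree$edge[, 1] == node, 2]) walk(ch)
  }
  walk(ntip + 1L)
  clusters
}

test_that("collapse_low_support contracts exactly the weak edges", {
  # ((a:1,b:1)0.95:1,(c:1,d:1)0.5:1)
  tr <- ape::read.tree(text = "((a:1,b:1)0.95:1,(c:1,d:1)0.5:1);")
  out <- collapse_low_support(tr, 0.9)
  expect_equal(ape::Ntip(out), 4)
  expect_equal(out$Nnode, 2)  # one internal node lost
  # c and d now hang off the root with the collapsed length added
  dm <- ape::cophenetic.phylo(out)
  expect_equal(dm["c", "d"], 4)      # 2 + 2 after length transfer
  expect_equal(dm["a", "b"], 2)      # untouched cherry
  expect_equal(dm["a", "c"], 1 + 1 + 2)

  # all supports 1: unchanged distances
  tr2 <- ape::read.tree(text = "((a:1,b:2)1.0:3,(c:1,d:1)1.0:1);")
  out2 <- collapse_low_support(tr2, 0.9)
  expect_equal(ape::cophenetic.phylo(out2)[c("a", "b", "c", "d"),
                                           c("a", "b", "c", "d")],
               ape::cophenetic.phylo(tr2)[c("a", "b", "c", "d"),
                                          c("a", "b", "c", "d")])

  # all supports 0: star tree
  tr3 <- ape::read.tree(
    text = "(((a:1,b:1)0:1,c:1)0:1,(d:1,e:1)0:1);")
  out3 <- collapse_low_support(tr3, 0.9)
  expect_equal(out3$Nnode, 1)
})

test_that("pick_clusters emits maximal clades under the distance cutoff", {
  yl <- simulate_y_locus(3, sizes = c(6, 8, 10), seed = 4)
  tree <- yl$tree
  diam <- max(ape::cophenetic.phylo(tree))
  # cutoff >= diameter: one cluster with all leaves
  pc <- pick_clusters(tree, diam + 1e-9)
  expect_length(pc$clusters, 1)
  expect_setequal(pc$clusters[[1]]$members, tree$tip.label)
  # cutoff below the smallest cherry: all singletons
  dm <- ape::cophenetic.phylo(tree)
  diag(dm) <- Inf
  pc0 <- pick_clusters(tree, min(dm) / 2)
  expect_length(pc0$clusters, 0)
  expect_setequal(pc0$singletons, tree$tip.label)
  expect_error(pick_clusters(tree, 0), "> 0")
})

test_that("pick_clusters equals the cophenetic-matrix oracle across
           cutoffs", {
  yl <- simulate_y_locus(4, sizes = c(5, 7, 9, 11), seed = 19)
  tree <- collapse_low_support(yl$tree)
  dm <- ape::cophenetic.phylo(tree)
  for (cutoff in quantile(dm[upper.tri(dm)], c(0.05, 0.3, 0.6, 0.95))) {
    got <- lapply(pick_clusters(tree, cutoff)$clusters, `[[`, "members")
    want <- pick_oracle(tree, cutoff)
    expect_equal(got[order(vapply(got, `[`, "", 1))],
                 want[order(vapply(want, `[`, "", 1))])
  }
})

test_that("clusters at any cutoff are leaf-disjoint clades", {
  yl <- simulate_y_locus(4, sizes = 8, seed = 23)
  tree <- collapse_low_support(yl$tree)
  for (cutoff in c(1e-5, 1e-4, 5e-4, 2e-3)) {
    cl <- pick_clusters(tree, cutoff)$clusters
    mem <- unlist(lapply(cl, `[[`, "members"))
    expect_equal(anyDuplicated(mem), 0)
    for (c1 in cl) expect_lte(c1$max_dist, cutoff)
  }
})

test_that("scan_cutoffs maximizes large clusters with ties to the smaller
           cutoff", {
  yl <- simulate_y_locus(4, sizes = 12, depth_years = 12000, seed = 6)
  tree <- collapse_low_support(yl$tree)
  sc <- scan_cutoffs(tree, large_min = 10)
  tl <- sc$tally
  expect_equal(tl$n_large[tl$cutoff == sc$chosen], 4)
  # chosen is the smallest cutoff attaining the max large-cluster count
  # with the fewest singletons
  best <- tl[tl$n_large == max(tl$n_large), ]
  expect_equal(sc$chosen,
               min(best$cutoff[best$n_singletons ==
                                 min(best$n_singletons)]))
  # the recovered partition equals the truth
  got <- lapply(sc$clusters$clusters, `[[`, "members")
  want <- split(names(yl$true_clusters), unname(yl$true_clusters))
  expect_equal(length(got), length(want))
  for (w in want)
    expect_true(any(vapply(got, function(g) setequal(g, sort(w)), TRUE)))
  # single-cutoff grid: that cutoff is chosen
  expect_equal(scan_cutoffs(tree, grid = 3e-4)$chosen, 3e-4)
  expect_error(scan_cutoffs(tree, grid = numeric()), "empty")
})

test_that("informative_snps recovers exactly the planted private SNVs and
           the defining sets are sound", {
  for (sd in 1:3) {
    yl <- simulate_y_locus(4, sizes = 12, seed = 30 + sd)
    sc <- scan_cutoffs(collapse_low_support(yl$tree), large_min = 10)
    sh <- informative_snps(yl$haplotypes, sc$clusters$clusters)
    expect_length(sh, 4)
    got <- sort(unname(unlist(lapply(sh, `[[`, "defining_sites"))))
    expect_equal(got, sort(unname(unlist(yl$private_snvs))))
    g <- yl$haplotypes$geno
    for (s in sh) {
      inside <- rownames(g) %in% s$members
      def <- s$defining_sites
      # every member all-derived; every non-member carries an ancestral
      # allele at the set
      expect_true(all(g[inside, def] == 1L))
      if (length(def) == 1L) {
        expect_true(all(g[!inside, def] == 0L))
      } else {
        expect_true(all(rowSums(g[!inside, def] == 0L) >= 1))
      }
    }
  }
})

test_that("informative_snps excludes segregating-in-cluster sites and
           skips undersized clusters", {
  yl <- simulate_y_locus(2, sizes = c(10, 10), seed = 3)
  g <- yl$haplotypes$geno
  cl1 <- sort(names(yl$true_clusters[yl$true_clusters == "C1"]))
  sh <- informative_snps(yl$haplotypes, list(cl1))
  def <- sh[[1]]$defining_sites
  p_in <- colMeans(g[cl1, , drop = FALSE])
  seg_inside <- which(p_in > 0 & p_in < 1)
  expect_length(intersect(def, seg_inside), 0)
  expect_warning(informative_snps(yl$haplotypes,
                                  list(cl1, cl1[1])), "fewer than 2")
})

test_that("lineage dating arithmetic and scaling", {
  sh <- list(list(id = "SH1", members = paste0("m", 1:4),
                  defining_sites = 1:3, s_bar = 100,
                  member_counts = rep(100, 4),
                  private_site_freqs = rep(1 / 4, 400)))
  a1 <- date_lineages(sh, mu = 1e-9, L = 1e7, n_boot = 200, seed = 1)
  expect_equal(a1$age_years, 10000)
  a2 <- date_lineages(sh, mu = 2e-9, L = 1e7, n_boot = 200, seed = 1)
  expect_equal(a2$age_years, 5000)   # doubling mu halves t
  # per-generation parameterization: t = S * g / (mu_gen * L)
  a3 <- date_lineages(sh, mu = 3e-8, L = 1e7, g = 30,
                      rate_per = "generation", n_boot = 10, seed = 1)
  expect_equal(a3$age_years, 100 * 30 / (3e-8 * 1e7))
  # zero-count haplogroup flagged
  sh0 <- list(list(id = "SH0", members = c("a", "b"),
                   defining_sites = 1L, s_bar = 0,
                   member_counts = c(0, 0),
                   private_site_freqs = numeric()))
  a0 <- date_lineages(sh0, n_boot = 10)
  expect_true(is.na(a0$age_years))
  expect_equal(a0$flag, "zero_snv_count")
})

test_that("rank-sum comparison: exact enumeration, ties, and agreement
           with the normal approximation", {
  # completely separated groups of 5: U = 0, exact p = 2/252
  r <- compare_group_ages(1:5, 6:10)
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 2 / 252)
  expect_equal(r$method, "exact")
  # identical groups: p = 1 despite full ties
  expect_equal(compare_group_ages(rep(7, 5), rep(7, 6))$p_value, 1)
  # agreement with stats::wilcox.test in the exact no-tie regime
  set.seed(77)
  for (i in 1:3) {
    a <- rnorm(6); b <- rnorm(7, 0.8)
    expect_equal(compare_group_ages(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
  # exact vs normal approximation within 0.01 at n = 20
  for (i in 1:5) {
    a <- rnorm(10); b <- rnorm(10, 0.5)
    expect_lt(abs(compare_group_ages(a, b)$p_value -
                    compare_group_ages(a, b, exact_max = 0)$p_value),
              0.01)
  }
  expect_error(compare_group_ages(1:2, 1:5), ">= 3")
})
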