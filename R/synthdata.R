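#' Ancestral population model for cohort simulation
#'
#' Defines K ancestral populations whose per-site allele frequencies are
#' drifted away from a shared ancestral frequency under the Balding-Nichols
#' model: population k's frequency at a site with ancestral frequency p is
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with F the per-population drift parameter
#' (equal in expectation to the FST between the population and the ancestor;
#' F = 0 is the no-drift limit where the frequency equals p exactly).
#'
#' @param K number of ancestral populations (>= 1)
#' @param n_sites number of biallelic variant sites
#' @param drift per-population drift F in [0, 1); recycled to length K
#' @param ancestral_freqs optional vector of ancestral frequencies strictly
#'   inside (0, 1); by default drawn Uniform(0.05, 0.95) so sites stay
#'   informative
#' @param chrom_lengths named numeric vector of chromosome lengths in bp
#'   (default two 50-Mb chromosomes)
#' @param seed integer seed; all randomness in the model derives from it
#' @return object of class `ancestral_model`
#' @export
ancestral_model <- function(K, n_sites, drift, ancestral_freqs = NULL,
                            chrom_lengths = c(chr1 = 5e7, chr2 = 5e7),
                            seed = 1L) {
  stopifnot(K >= 1, n_sites >= 1)
  drift <- rep_len(drift, K)
  if (any(drift < 0 | drift >= 1))
    stop("drift parameters must lie in [0, 1)")
  if (is.null(ancestral_freqs)) {
    ancestral_freqs <- with_substream(seed, "ancestral_freqs",
                                      stats::runif(n_sites, 0.05, 0.95))
  }
  if (length(ancestral_freqs) != n_sites)
    stop("ancestral_freqs must have length n_sites")
  if (any(ancestral_freqs <= 0 | ancestral_freqs >= 1))
    stop("ancestral_freqs must be strictly inside (0, 1)")
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  structure(list(K = as.integer(K), n_sites = as.integer(n_sites),
                 drift = drift, ancestral_freqs = ancestral_freqs,
                 chrom_lengths = chrom_lengths, seed = seed),
            class = "ancestral_model")
}

## Balding-Nichols draw of per-population site frequencies (sites x K)
bn_population_freqs <- function(model) {
  p <- model$ancestral_freqs
  out <- matrix(NA_real_, model$n_sites, model$K)
  for (k in seq_len(model$K)) {
    F <- model$drift[k]
    out[, k] <- if (F == 0) p else
      stats::rbeta(model$n_sites, p * (1 - F) / F, (1 - p) * (1 - F) / F)
  }
  out
}

## Sorted unique positions across the model's chromosomes, allocated
## proportionally to chromosome length.
sim_positions <- function(model) {
  lens <- model$chrom_lengths
  n <- model$n_sites
  alloc <- floor(n * lens / sum(lens))
  rem <- n - sum(alloc)
  if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
  chrom <- rep(names(lens), alloc)
  pos <- unlist(lapply(seq_along(lens), function(i) {
    sort(sample.int(lens[i], alloc[i]))
  }), use.names = FALSE)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n,
              length(alpha), byrow = TRUE)
  x / rowSums(x)
}

#' Simulate an admixed cohort under a Balding-Nichols ancestral model
#'
#' Each group draws per-individual ancestry proportions q from a Dirichlet
#' distribution (or uses a fixed q vector), and individual genotypes at site
#' j are Binomial(2, sum_k q_k p_kj) where p_kj are the drifted population
#' frequencies.  The generating Q matrix and population frequencies are kept
#' as ground truth.
#'
#' @param model `ancestral_model`
#' @param groups named list; each element a list with `n` (group size >= 1)
#'   and either `alpha` (Dirichlet parameters, all > 0, length K) or `q`
#'   (fixed ancestry vector summing to 1)
#' @param missing_rate optional per-call Bernoulli missingness (default 0)
#' @param seed integer seed (defaults to the model's)
#' @return object of class `sim_cohort`: fields `genotypes`
#'   (genotype_matrix with group labels), `true_Q` (samples x K),
#'   `true_roh` (empty registry, see [plant_roh()]), `pop_freqs`,
#'   `model`
#' @export
simulate_admixed_cohort <- function(model, groups, missing_rate = 0,
                                    seed = model$seed) {
  stopifnot(inherits(model, "ancestral_model"), length(groups) >= 1)
  if (is.null(names(groups)))
    names(groups) <- paste0("G", seq_along(groups))
  for (gn in names(groups)) {
    g <- groups[[gn]]
    if (is.null(g$n) || g$n < 1) stop("group ", gn, " has empty size")
    if (!is.null(g$alpha)) {
      if (length(g$alpha) != model$K || any(g$alpha <= 0))
        stop("group ", gn, ": Dirichlet parameters must be > 0, length K")
    } else if (!is.null(g$q)) {
      if (length(g$q) != model$K || abs(sum(g$q) - 1) > 1e-9 || any(g$q < 0))
        stop("group ", gn, ": fixed q must be a length-K probability vector")
    } else stop("group ", gn, ": needs alpha or q")
  }
  pf <- with_substream(seed, "pop_freqs", bn_population_freqs(model))
  sites <- with_substream(seed, "positions", sim_positions(model))
  ns <- vapply(groups, function(g) as.integer(g$n), 1L)
  n_tot <- sum(ns)
  Q <- matrix(NA_real_, n_tot, model$K)
  row0 <- 0L
  with_substream(seed, "q_draws", {
    for (i in seq_along(groups)) {
      g <- groups[[i]]
      idx <- row0 + seq_len(ns[i])
      Q[idx, ] <- if (!is.null(g$q))
        matrix(g$q, ns[i], model$K, byrow = TRUE)
      else rdirichlet(ns[i], g$alpha)
      row0 <- row0 + ns[i]
    }
  })
  Q <- Q / rowSums(Q)
  geno <- with_substream(seed, "genotypes", {
    gm <- matrix(NA_integer_, n_tot, model$n_sites)
    for (i in seq_len(n_tot)) {
      pi_i <- as.vector(pf %*% Q[i, ])
      gm[i, ] <- stats::rbinom(model$n_sites, 2L, pi_i)
    }
    gm
  })
  if (missing_rate > 0) {
    with_substream(seed, "missingness", {
      miss <- matrix(stats::runif(length(geno)) < missing_rate,
                     nrow = nrow(geno))
      geno[miss] <- NA_integer_
    })
  }
  pop <- rep(names(groups), ns)
  ids <- sprintf("%s_%03d", pop, unlist(lapply(ns, seq_len)))
  rownames(geno) <- ids
  colnames(Q) <- paste0("K", seq_len(model$K))
  rownames(Q) <- ids
  structure(list(
    genotypes = genotype_matrix(geno, sites, ploidy = 2L, pop = pop),
    true_Q = Q,
    true_roh = data.frame(sample = character(), chrom = character(),
                          start_bp = integer(), end_bp = integer(),
                          class = character(), stringsAsFactors = FALSE),
    pop_freqs = pf,
    model = model,
    groups = groups,
    seed = seed), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d samples x %d sites, K=%d, %d planted tracts\n",
              nrow(x$genotypes$geno), ncol(x$genotypes$geno),
              x$model$K, nrow(x$true_roh)))
  invisible(x)
}

#' Plant autozygous tracts into a simulated cohort
#'
#' Overwrites genotypes inside randomly placed tracts with fully homozygous
#' calls (allele drawn once per site from the individual's expected
#' frequency), then flips each tract call to heterozygous with probability
#' `het_error` to emulate residual genotyping error.  Tracts are placed by
#' rejection sampling so they never overlap within a sample.
#'
#' @param cohort `sim_cohort`
#' @param tract_spec named list of size classes, each a list with `n`
#'   (tracts per sample per class), `min_bp`, `max_bp` (log-uniform length
#'   range); e.g. `list(long = list(n = 2, min_bp = 2e6, max_bp = 8e6))`
#' @param het_error residual heterozygosity rate in [0, 0.05]
#' @param samples sample ids to plant into (default: all)
#' @param max_retries placement retries per tract before failing
#' @param seed integer seed
#' @return the cohort with modified genotypes and a filled `true_roh`
#'   registry (sample, chrom, start_bp, end_bp, class)
#' @export
plant_roh <- function(cohort, tract_spec, het_error = 0, samples = NULL,
                      max_retries = 100L, seed = cohort$seed) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (het_error < 0 || het_error > 0.05)
    stop("het_error must lie in [0, 0.05]")
  lens <- cohort$model$chrom_lengths
  for (cl in names(tract_spec)) {
    sp <- tract_spec[[cl]]
    if (sp$max_bp >= max(lens))
      stop("class ", cl, ": tract lengths must be below chromosome length")
  }
  g <- cohort$genotypes
  if (is.null(samples)) samples <- rownames(g$geno)
  Q <- cohort$true_Q
  pf <- cohort$pop_freqs
  reg <- list()
  with_substream(seed, "plant_roh", {
    for (s in samples) {
      si <- match(s, rownames(g$geno))
      if (is.na(si)) stop("unknown sample ", s)
      prev <- cohort$true_roh[cohort$true_roh$sample == s, , drop = FALSE]
      placed <- data.frame(chrom = prev$chrom, start = prev$start_bp,
                           end = prev$end_bp)
      for (cl in names(tract_spec)) {
        sp <- tract_spec[[cl]]
        for (t in seq_len(sp$n)) {
          L <- round(exp(stats::runif(1, log(sp$min_bp), log(sp$max_bp))))
          ok <- FALSE
          for (try in seq_len(max_retries)) {
            ch <- sample(names(lens), 1L, prob = lens)
            st <- sample.int(lens[[ch]] - L, 1L)
            en <- st + L - 1L
            clash <- placed$chrom == ch & placed$start <= en & placed$end >= st
            if (!any(clash)) { ok <- TRUE; break }
          }
          if (!ok) stop("could not place non-overlapping tract for sample ",
                        s, " after ", max_retries, " retries")
          placed <- rbind(placed,
                          data.frame(chrom = ch, start = st, end = en))
          idx <- which(g$sites$chrom == ch & g$sites$pos >= st &
                         g$sites$pos <= en)
          if (length(idx)) {
            pi_i <- as.vector(pf[idx, , drop = FALSE] %*% Q[si, ])
            hom <- 2L * stats::rbinom(length(idx), 1L, pi_i)
            if (het_error > 0) {
              flip <- stats::runif(length(idx)) < het_error
              hom[flip] <- 1L
            }
            g$geno[si, idx] <- hom
          }
          reg[[length(reg) + 1L]] <-
            data.frame(sample = s, chrom = ch, start_bp = as.integer(st),
                       end_bp = as.integer(en), class = cl,
                       stringsAsFactors = FALSE)
        }
      }
    }
  })
  cohort$genotypes <- g
  if (length(reg))
    cohort$true_roh <- rbind(cohort$true_roh, do.call(rbind, reg))
  rownames(cohort$true_roh) <- NULL
  cohort
}

#' Simulate a haploid locus evolving on a clustered phylogeny
#'
#' Builds one ultrametric pure-birth subtree per cluster (depth =
#' `depth_years`), joins the subtrees at a deeper root, and drops mutations
#' on every branch as Poisson(mu x region_len_bp x branch_years).  Each
#' cluster's stem branch is guaranteed at least one mutation, so every
#' cluster owns private fixed SNVs (haploid cluster-vs-rest FST = 1 by
#' construction).  Branch lengths of the returned tree are rescaled to
#' realized substitutions per site (mutation count / region length) so that
#' patristic distances and haplotype differences agree, as they would on a
#' maximum-likelihood tree; all support values are 1.0.
#'
#' @param n_clusters number of clusters
#' @param sizes per-cluster sample counts (all >= 2); recycled
#' @param mu mutation rate per site per year (default 0.76e-9)
#' @param region_len_bp callable region length in bp (default 10 Mb)
#' @param depth_years per-cluster TMRCA in years (recycled)
#' @param root_depth_years depth of the shared root; default 4 x max depth
#' @param seed integer seed
#' @return object of class `sim_y_locus`: `tree` (phylo with node.label
#'   supports), `haplotypes` (haploid genotype_matrix), `true_clusters`
#'   (named vector sample -> cluster), `private_snvs` (list cluster -> site
#'   indices), plus the simulation parameters
#' @export
simulate_y_locus <- function(n_clusters, sizes, mu = 0.76e-9,
                             region_len_bp = 1e7, depth_years = 12000,
                             root_depth_years = NULL, seed = 1L) {
  sizes <- rep_len(as.integer(sizes), n_clusters)
  depth_years <- rep_len(depth_years, n_clusters)
  if (any(sizes < 2L)) stop("cluster sizes must be >= 2")
  if (any(depth_years <= 0)) stop("depth_years must be > 0")
  if (is.null(root_depth_years)) root_depth_years <- 4 * max(depth_years)
  if (root_depth_years <= max(depth_years))
    stop("root_depth_years must exceed every cluster depth")
  with_substream(seed, "y_locus", {
    subtrees <- vector("list", n_clusters)
    for (c in seq_len(n_clusters)) {
      tr <- ape::rphylo(sizes[c], birth = 1, death = 0)
      tr$edge.length <- tr$edge.length * depth_years[c] / max(ape::node.depth.edgelength(tr))
      tr$tip.label <- sprintf("C%d_%02d", c, seq_len(sizes[c]))
      subtrees[[c]] <- tr
    }
    stems <- root_depth_years - depth_years
    parts <- vapply(seq_len(n_clusters), function(c) {
      nwk <- ape::write.tree(subtrees[[c]])
      paste0(sub(";$", "", nwk), ":", format(stems[c], scientific = FALSE))
    }, "")
    tree <- ape::read.tree(text = paste0("(", paste(parts, collapse = ","), ");"))
    ## mutations: Poisson per branch on branch length in years
    n_edge <- nrow(tree$edge)
    exp_mut <- mu * region_len_bp * tree$edge.length
    mut <- stats::rpois(n_edge, exp_mut)
    ## identify stem edges (children of the root) per cluster
    root <- ape::Ntip(tree) + 1L
    stem_edges <- which(tree$edge[, 1] == root)
    ## order stem edges by cluster: match first tip below each stem
    tipsets <- lapply(stem_edges, function(e)
      tree$tip.label[clade_tips(tree, tree$edge[e, 2])])
    cl_of_stem <- vapply(tipsets, function(ts)
      as.integer(sub("^C(\\d+)_.*$", "\\1", ts[1])), 1L)
    forced <- 0L
    for (i in seq_along(stem_edges)) {
      e <- stem_edges[i]
      if (mut[e] == 0L) { mut[e] <- 1L; forced <- forced + 1L }
    }
    if (forced > 0L)
      warning(forced, " cluster stem(s) drew zero mutations; ",
              "one private SNV planted on each (recorded)")
    total <- sum(mut)
    pos <- sort(sample.int(region_len_bp, total))
    ## assign sites to edges
    edge_of_site <- rep(seq_len(n_edge), mut)[order(stats::runif(total))]
    ## haplotypes: leaf carries derived allele at sites on its root path
    tips <- seq_len(ape::Ntip(tree))
    geno <- matrix(0L, length(tips), total)
    rownames(geno) <- tree$tip.label
    for (e in seq_len(n_edge)) {
      sites_e <- which(edge_of_site == e)
      if (!length(sites_e)) next
      below <- clade_tips(tree, tree$edge[e, 2])
      geno[below, sites_e] <- 1L
    }
    ## rescale branch lengths to realized substitutions/site
    tree$edge.length <- mut / region_len_bp
    tree$node.label <- rep("1.0", tree$Nnode)
    sites <- data.frame(chrom = "chrY", pos = as.integer(pos),
                        ref = "A", alt = "G", stringsAsFactors = FALSE)
    true_clusters <- stats::setNames(
      sub("^(C\\d+)_.*$", "\\1", tree$tip.label), tree$tip.label)
    private_snvs <- lapply(seq_along(stem_edges), function(i)
      which(edge_of_site == stem_edges[i]))
    names(private_snvs) <- paste0("C", cl_of_stem)
    private_snvs <- private_snvs[order(cl_of_stem)]
    structure(list(
      tree = tree,
      haplotypes = genotype_matrix(geno, sites, ploidy = 1L,
                                   pop = unname(true_clusters)),
      true_clusters = true_clusters,
      private_snvs = private_snvs,
      mu_per_site_year = mu,
      region_len_bp = region_len_bp,
      depth_years = stats::setNames(depth_years,
                                    paste0("C", seq_len(n_clusters))),
      forced_stem_snvs = forced,
      seed = seed), class = "sim_y_locus")
  })
}

## tip indices descending from a node (the node itself if a tip)
clade_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  out <- integer()
  stack <- node
  while (length(stack)) {
    nd <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    tips <- kids[kids <= ntip]
    out <- c(out, tips)
    stack <- c(stack, kids[kids > ntip])
  }
  sort(out)
}

#' @export
print.sim_y_locus <- function(x, ...) {
  cat(sprintf(
    "<sim_y_locus> %d haplotypes, %d clusters, %d sites over %.0f bp\n",
    nrow(x$haplotypes$geno), length(x$private_snvs),
    ncol(x$haplotypes$geno), x$region_len_bp))
  invisible(x)
}

#' Split a cohort into reference-panel and imputation-target artifacts
#'
#' Draws disjoint reference and target sample sets, selects the "typed"
#' pseudo-array site subset, and writes three standard files: a reference
#' VCF, a target truth VCF and an array manifest TSV (chrom, pos).
#'
#' @param cohort `sim_cohort`
#' @param n_ref,n_target disjoint sample counts (sum <= cohort size)
#' @param array_fraction fraction of sites on the pseudo-array, in (0, 1)
#' @param dir output directory (created if needed)
#' @param seed integer seed
#' @return list with `reference`, `target` (genotype_matrix), `manifest`
#'   (data.frame chrom/pos), `typed_sites` (indices) and the three `paths`
#' @export
make_panel_pair <- function(cohort, n_ref, n_target, array_fraction,
                            dir = tempdir(), seed = cohort$seed) {
  stopifnot(inherits(cohort, "sim_cohort"))
  g <- cohort$genotypes
  if (n_ref + n_target > nrow(g$geno))
    stop("n_ref + n_target exceeds cohort size")
  if (array_fraction <= 0 || array_fraction >= 1)
    stop("array_fraction must be in (0, 1)")
  n_typed <- round(array_fraction * ncol(g$geno))
  with_substream(seed, "panel_pair", {
    perm <- sample(rownames(g$geno))
    ref_ids <- perm[seq_len(n_ref)]
    tgt_ids <- perm[n_ref + seq_len(n_target)]
    typed <- sort(sample.int(ncol(g$geno), n_typed))
    per_chrom <- table(g$sites$chrom[typed])
    if (length(per_chrom) < length(unique(g$sites$chrom)) ||
        any(per_chrom < 2L))
      stop("array_fraction leaves fewer than 2 typed sites on a chromosome")
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    reference <- subset_genotypes(g, ref_ids)
    target <- subset_genotypes(g, tgt_ids)
    manifest <- data.frame(chrom = g$sites$chrom[typed],
                           pos = g$sites$pos[typed])
    paths <- c(reference = file.path(dir, "reference.vcf"),
               target = file.path(dir, "target_truth.vcf"),
               manifest = file.path(dir, "array_manifest.tsv"))
    write_vcf(reference, paths[["reference"]])
    write_vcf(target, paths[["target"]])
    write_tsv(manifest, paths[["manifest"]])
    list(reference = reference, target = target, manifest = manifest,
         typed_sites = typed, paths = paths)
  })
}

#' Write the ground-truth registries of a simulated cohort or Y locus
#'
#' @param x `sim_cohort` or `sim_y_locus`
#' @param dir output directory
#' @return named vector of written paths
#' @export
write_truth_registries <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if (inherits(x, "sim_cohort")) {
    p <- file.path(dir, "true_roh.tsv")
    write_tsv(x$true_roh, p)
    paths["true_roh"] <- p
    q <- data.frame(sample = rownames(x$true_Q), x$true_Q)
    p2 <- file.path(dir, "true_Q.tsv")
    write_tsv(q, p2)
    paths["true_Q"] <- p2
  } else if (inherits(x, "sim_y_locus")) {
    ps <- do.call(rbind, lapply(names(x$private_snvs), function(cl)
      data.frame(cluster = cl, site_index = x$private_snvs[[cl]])))
    p <- file.path(dir, "private_snvs.tsv")
    write_tsv(ps, p)
    paths["private_snvs"] <- p
    cl <- data.frame(sample = names(x$true_clusters),
                     cluster = unname(x$true_clusters))
    p2 <- file.path(dir, "true_clusters.tsv")
    write_tsv(cl, p2)
    paths["true_clusters"] <- p2
    p3 <- file.path(dir, "tree.nwk")
    ape::write.tree(x$tree, p3)
    paths["tree"] <- p3
  } else stop("unsupported object")
  paths
}
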