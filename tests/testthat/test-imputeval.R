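test_that("saturation curve: monotone, conserved, flat for identical
           samples, and equal to hand enumeration", {
  # identical samples: flat after the first
  g <- toy_genotypes(matrix(rep(c(0L, 1L, 0L, 2L, 0L), 6), 6, 5,
                            byrow = TRUE))
  sat <- saturation_curve(g, n_permutations = 3, seed = 1)
  expect_true(all(sat$mean_curve == sat$mean_curve[1]))

  # 5-sample toy with hand-listed variant sets
  geno <- rbind(s1 = c(1L, 0L, 0L, 0L, 0L, 0L),
                s2 = c(1L, 2L, 0L, 0L, 0L, 0L),
                s3 = c(0L, 0L, 1L, 0L, 0L, 0L),
                s4 = c(0L, 0L, 0L, 0L, 0L, 0L),
                s5 = c(1L, 0L, 1L, 2L, 1L, 0L))
  g2 <- toy_genotypes(geno)
  # identity permutation oracle: cumulative set unions
  sets <- apply(geno > 0, 1, which, simplify = FALSE)
  oracle <- vapply(1:5, function(k)
    length(Reduce(union, sets[1:k])), 1L)
  # force the identity permutation by checking every permutation's final
  # value and monotonicity, plus the exact curve via n_permutations = 1
  # on a seed whose first permutation we recompute here
  sat2 <- saturation_curve(g2, n_permutations = 6, seed = 42)
  expect_true(all(apply(sat2$curves, 2, function(cv) all(diff(cv) >= 0))))
  expect_true(all(sat2$curves[5, ] == 5))  # conservation, any order
  ord <- arabpop:::with_substream(42, "saturation", sample.int(5))
  oracle_perm <- vapply(1:5, function(k)
    length(Reduce(union, sets[ord[1:k]])), 1L)
  expect_equal(unname(sat2$curves[, 1]), oracle_perm)
  expect_equal(oracle[5], 5L)
})

test_that("make_pseudo_array partitions sites and counts unmatched
           manifest rows", {
  co <- two_pop_cohort(n_per = 6, n_sites = 100, seed = 13)
  g <- co$genotypes
  manifest <- data.frame(chrom = g$sites$chrom[1:40],
                         pos = g$sites$pos[1:40])
  pa <- make_pseudo_array(g, manifest)
  expect_equal(pa$typed_idx, 1:40)
  expect_setequal(c(pa$typed_idx, pa$withheld_idx), 1:100)
  expect_equal(pa$n_unmatched, 0)
  # full manifest reproduces the input
  pa_full <- make_pseudo_array(g, g$sites[, c("chrom", "pos")])
  expect_identical(pa_full$typed$geno, g$geno)
  expect_length(pa_full$withheld_idx, 0)
  # unknown row dropped with count
  manifest2 <- rbind(manifest, data.frame(chrom = "chrX", pos = 1L))
  expect_equal(make_pseudo_array(g, manifest2)$n_unmatched, 1)
  expect_error(make_pseudo_array(
    g, data.frame(chrom = "chrX", pos = 1L)), "no sites")
})

test_that("impute_naive: frequency dosages, oracle-in-panel recovery and
           determinism", {
  co <- two_pop_cohort(n_per = 25, n_sites = 300, seed = 17)
  dir <- withr::local_tempdir()
  pp <- make_panel_pair(co, n_ref = 30, n_target = 12,
                        array_fraction = 0.4, dir = dir)
  pa <- make_pseudo_array(pp$target, pp$manifest)

  impf <- impute_naive(pa$typed, pp$reference, pa$withheld_idx, "freq")
  af <- allele_freq(subset_genotypes(pp$reference,
                                     sites = pa$withheld_idx))
  expect_equal(unname(impf$dosage[1, ]), 2 * af)
  expect_equal(unname(impf$dosage[12, ]), 2 * af)  # constant per site
  expect_equal(impf$quality, rep(0, length(pa$withheld_idx)))

  # panel containing the target's own genotypes: exact recovery
  imph <- impute_naive(pa$typed, pp$target, pa$withheld_idx,
                       "nearest_haplotype")
  truth <- pp$target$geno[rownames(imph$dosage), pa$withheld_idx]
  expect_equal(unname(imph$dosage), unname(truth))
  expect_equal(unname(imph$sample_quality), rep(1, 12))

  # determinism
  imp2 <- impute_naive(pa$typed, pp$reference, pa$withheld_idx,
                       "nearest_haplotype")
  imp3 <- impute_naive(pa$typed, pp$reference, pa$withheld_idx,
                       "nearest_haplotype")
  expect_identical(imp2, imp3)
  empty <- subset_genotypes(pp$reference, samples = integer())
  expect_error(impute_naive(pa$typed, empty, pa$withheld_idx), "empty")
})

test_that("aggregate R2: perfect dosages give 1, the pooled value matches
           the direct Pearson oracle, shuffling kills it", {
  co <- two_pop_cohort(n_per = 30, n_sites = 200, seed = 23)
  dir <- withr::local_tempdir()
  pp <- make_panel_pair(co, n_ref = 40, n_target = 15,
                        array_fraction = 0.3, dir = dir)
  pa <- make_pseudo_array(pp$target, pp$manifest)
  af <- allele_freq(subset_genotypes(pp$reference,
                                     sites = pa$withheld_idx))

  # dosage == truth
  truth_dos <- pp$target$geno[, pa$withheld_idx]
  t1 <- aggregate_r2(pp$target, truth_dos, pa$withheld_idx, af)
  expect_true(all(abs(t1$r2[!is.na(t1$r2)] - 1) < 1e-12))
  expect_true(any(!is.na(t1$r2)))

  # 20-variant fixture: pooled R2 equals the direct formula (freq method)
  w20 <- pa$withheld_idx[1:20]
  impf <- impute_naive(pa$typed, pp$reference, w20, "freq")
  af20 <- af[match(w20, pa$withheld_idx)]
  one_bin <- af_bin_spec(c(1))  # a single (0,1] bin
  tab <- aggregate_r2(pp$target, impf$dosage, w20, af20, bins = one_bin)
  tt <- as.vector(pp$target$geno[, w20])
  dd <- as.vector(impf$dosage)
  keep <- af20[col(matrix(0, 15, 20))] > 0
  expect_equal(tab$r2[1], cor(tt[keep], dd[keep])^2, tolerance = 1e-12)

  # shuffled dosages: ~0
  set.seed(1)
  shuf <- truth_dos[sample(nrow(truth_dos)), sample(ncol(truth_dos))]
  t2 <- aggregate_r2(pp$target, shuf, pa$withheld_idx, af,
                     bins = af_bin_spec(c(1)))
  expect_lt(t2$r2[1], 0.05)

  # invariance to sample and site ordering
  sp <- sample(nrow(truth_dos)); cp <- sample(ncol(truth_dos))
  t3 <- aggregate_r2(pp$target, truth_dos[sp, cp],
                     pa$withheld_idx[cp], af[cp])
  expect_equal(t3$r2, t1$r2)
})

test_that("undefined bins are flagged with a reason and quality filters
           apply", {
  g <- toy_genotypes(rbind(c(0L, 0L, 1L), c(0L, 1L, 2L)))
  dos <- rbind(c(0, 0.1, 0.9), c(0, 0.9, 1.8))
  tab <- aggregate_r2(g, dos, 1:3, af = c(0, 0.25, 0.6),
                      bins = af_bin_spec(c(0.5, 1)))
  # site 1 has af 0 -> no bin; bin (0,0.5] holds site 2; (0.5,1] site 3
  expect_equal(tab$n_variants, c(1L, 1L))
  # zero-variance truth in a bin
  g2 <- toy_genotypes(rbind(c(0L), c(0L)))
  tab2 <- aggregate_r2(g2, rbind(0.1, 0.2), 1L, af = 0.3,
                       bins = af_bin_spec(c(1)))
  expect_true(is.na(tab2$r2[1]))
  expect_match(tab2$reason[1], "zero variance")
  # quality pre-filter drops low-quality sites
  tab3 <- aggregate_r2(g, dos, 1:3, af = c(0, 0.25, 0.6),
                       bins = af_bin_spec(c(1)),
                       quality = c(0, 0.9, 0.1), quality_min = 0.5)
  expect_equal(tab3$n_variants, 1L)
  expect_equal(tab3$n_quality_gt, 1L)
})

test_that("panels from the target's own population beat diverged panels
           (freq method) and the in-panel oracle dominates freq", {
  better <- 0; n_seeds <- 5
  for (sd in 1:n_seeds) {
    m <- ancestral_model(2, 800, drift = c(0.02, 0.3), seed = 500 + sd)
    co <- simulate_admixed_cohort(
      m, list(own = list(n = 50, q = c(1, 0)),
              div = list(n = 40, q = c(0, 1))))
    g <- co$genotypes
    own_ids <- rownames(g$geno)[co$genotypes$pop == "own"]
    div_ids <- rownames(g$geno)[co$genotypes$pop == "div"]
    target <- subset_genotypes(g, own_ids[1:10])
    own_panel <- subset_genotypes(g, own_ids[11:50])
    div_panel <- subset_genotypes(g, div_ids)
    typed <- seq(1, 800, by = 3)
    withheld <- setdiff(seq_len(800), typed)
    pseudo <- subset_genotypes(target, sites = typed)
    af_t <- allele_freq(subset_genotypes(target, sites = withheld))
    r2_of <- function(panel, method) {
      imp <- impute_naive(pseudo, panel, withheld, method)
      tab <- aggregate_r2(target, imp$dosage, withheld, af_t,
                          bins = af_bin_spec(c(1)))
      tab$r2[1]
    }
    own_r2 <- r2_of(own_panel, "freq")
    div_r2 <- r2_of(div_panel, "freq")
    if (own_r2 >= div_r2) better <- better + 1
    # nearest-haplotype dominance in the regime the no-LD world supports:
    # the panel containing the target's haplotypes is exact
    oracle_r2 <- r2_of(target, "nearest_haplotype")
    expect_equal(oracle_r2, 1)
    expect_gte(oracle_r2, own_r2)
  }
  expect_gte(better, n_seeds - 1)
})
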