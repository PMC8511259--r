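# explicit delete-one-block oracle: recompute the ratio from the site
# table with each block removed, then apply the weighted jackknife formula
jackknife_oracle <- function(num, den, block) {
  blocks <- unique(block)
  g <- length(blocks)
  theta <- sum(num) / sum(den)
  theta_del <- vapply(blocks, function(b)
    sum(num[block != b]) / sum(den[block != b]), 1)
  m <- vapply(blocks, function(b) sum(block == b), 1)
  n <- sum(m); h <- n / m
  theta_J <- g * theta - sum((1 - m / n) * theta_del)
  sqrt(sum((h * theta - (h - 1) * theta_del - theta_J)^2 / (h - 1)) / g)
}

test_that("block jackknife SE equals explicit delete-one recomputation", {
  set.seed(11)
  for (rep in 1:5) {
    n_blocks <- sample(3:10, 1)
    sizes <- sample(5:40, n_blocks, replace = TRUE)
    block <- rep(paste0("b", seq_len(n_blocks)), sizes)
    num <- rnorm(length(block))
    den <- runif(length(block), 0.5, 2)
    jk <- block_jackknife(num, den, block)
    expect_equal(jk$se, jackknife_oracle(num, den, block),
                 tolerance = 1e-12)
    expect_equal(jk$statistic, sum(num) / sum(den), tolerance = 1e-12)
  }
  # equal block sizes reduce to the classic delete-one jackknife
  block <- rep(paste0("b", 1:8), each = 10)
  num <- rnorm(80)
  jk <- block_jackknife(num, rep(1, 80), block)
  theta_del <- vapply(unique(block), function(b)
    mean(num[block != b]), 1)
  classic <- sqrt((8 - 1) / 8 * sum((theta_del - mean(theta_del))^2))
  expect_equal(jk$se, classic, tolerance = 1e-12)
  expect_error(block_jackknife(1:3, rep(1, 3), rep("b", 3)),
               ">= 2 blocks")
})

test_that("f3 matches the analytic limit and a brute-force 3-block
           oracle", {
  # a = 0, b = 1, c = 0.5 at large n_C: term -> -0.25
  m <- 300
  n <- 10000L
  ac <- cbind(A = rep(0L, m), B = rep(n, m), C = rep(n / 2, m))
  an <- matrix(n, m, 3, dimnames = list(NULL, c("A", "B", "C")))
  ft <- freq_table_from_counts(ac, an)
  r <- f3_statistic(ft, "A", "B", "C", block_size_bp = 50)
  expect_equal(r$statistic, -0.25, tolerance = 1e-3)

  # 3-block toy: value and SE equal brute-force recomputation
  set.seed(21)
  m <- 90
  ac <- cbind(A = rbinom(m, 40, 0.4), B = rbinom(m, 40, 0.6),
              C = rbinom(m, 40, 0.5))
  an <- matrix(40L, m, 3, dimnames = list(NULL, colnames(ac)))
  sites <- data.frame(chrom = rep(c("c1", "c2", "c3"), each = 30),
                      pos = rep(seq_len(30) * 1000L, 3),
                      ref = "A", alt = "G")
  ft <- freq_table_from_counts(ac, an, sites)
  r <- f3_statistic(ft, "A", "B", "C", block_size_bp = 1e9)
  expect_equal(r$n_blocks, 3)
  a <- ac[, 1] / 40; b <- ac[, 2] / 40; cc <- ac[, 3] / 40
  term <- (cc - a) * (cc - b) - cc * (1 - cc) / 39
  usable <- (ac[, 1] + ac[, 2] + ac[, 3]) > 0 &
    (ac[, 1] + ac[, 2] + ac[, 3]) < 120
  blk <- rep(c("c1", "c2", "c3"), each = 30)[usable]
  expect_equal(r$statistic, mean(term[usable]), tolerance = 1e-12)
  expect_equal(r$se, jackknife_oracle(term[usable],
                                      rep(1, sum(usable)), blk),
               tolerance = 1e-12)
  expect_error(f3_statistic(ft, "A", "B", "nope"), "unknown population")
})

test_that("f3 is negative with Z < -3 for admixed targets and
           non-negative for independently drifted targets", {
  sig_admixed <- 0; nonneg_indep <- 0
  n_seeds <- 12
  for (sd in seq_len(n_seeds)) {
    set.seed(400 + sd)
    m <- 12000
    p0 <- runif(m, 0.05, 0.95)
    pa <- bn_draw(p0, 0.2); pb <- bn_draw(p0, 0.2)
    pc_adm <- bn_draw((pa + pb) / 2, 0.001)   # 50/50 admixture
    pc_ind <- bn_draw(p0, 0.2)                # independent drift
    ft <- counts_from_freqs(list(A = pa, B = pb, Cadm = pc_adm,
                                 Cind = pc_ind), n_dip = 50)
    r1 <- f3_statistic(ft, "A", "B", "Cadm", block_size_bp = 5e5)
    r2 <- f3_statistic(ft, "A", "B", "Cind", block_size_bp = 5e5)
    if (r1$statistic < 0 && r1$z < -3) sig_admixed <- sig_admixed + 1
    if (r2$statistic >= 0) nonneg_indep <- nonneg_indep + 1
  }
  expect_gte(sig_admixed / n_seeds, 0.95)
  expect_gte(nonneg_indep / n_seeds, 0.95)
})

test_that("D statistic: maximal ABBA gives 1, W == X gives exactly 0", {
  m <- 40
  ac <- cbind(W = rep(20L, m), X = rep(0L, m), Y = rep(20L, m),
              Z = rep(0L, m))
  an <- matrix(20L, m, 4, dimnames = list(NULL, colnames(ac)))
  sites <- data.frame(chrom = rep(c("c1", "c2"), each = 20),
                      pos = rep(seq_len(20) * 1000L, 2), ref = "A",
                      alt = "G")
  ft <- freq_table_from_counts(ac, an, sites)
  r <- d_statistic(ft, "W", "X", "Y", "Z", block_size_bp = 1e9)
  expect_equal(r$statistic, 1)

  set.seed(31)
  acw <- rbinom(m, 20, 0.5)
  ac2 <- cbind(W = acw, X = acw, Y = rbinom(m, 20, 0.5),
               Z = rep(0L, m))
  ft2 <- freq_table_from_counts(ac2, an, sites)
  r2 <- d_statistic(ft2, "W", "X", "Y", "Z", block_size_bp = 1e9)
  expect_identical(r2$statistic, 0)
})

test_that("D polarizes by the outgroup major allele and drops polymorphic
           outgroup sites", {
  # site 1: outgroup fixed ALT -> flip; site 2: outgroup at 50% -> drop
  ac <- cbind(W = c(0L, 5L, 10L, 0L), X = c(10L, 5L, 0L, 0L),
              Y = c(0L, 5L, 10L, 0L), Z = c(10L, 5L, 0L, 0L))
  an <- matrix(10L, 4, 4, dimnames = list(NULL, colnames(ac)))
  sites <- data.frame(chrom = c("c1", "c1", "c2", "c2"),
                      pos = c(1e3, 2e3, 1e3, 2e3), ref = "A", alt = "G")
  ft <- freq_table_from_counts(ac, an, sites)
  r <- d_statistic(ft, "W", "X", "Y", "Z", block_size_bp = 1e9)
  # flipped site 1 is BABA-free ABBA: derived w=1,x=0,y=1,z=0 -> D = 1;
  # site 3 identical unflipped; site 2 dropped (polymorphic outgroup);
  # site 4 uninformative
  expect_equal(r$statistic, 1)
  expect_equal(r$n_sites, 2)
})

test_that("D sign convention tracks the introgression direction", {
  set.seed(55)
  m <- 20000
  p0 <- runif(m, 0.05, 0.95)
  pz <- bn_draw(p0, 0.8)              # outgroup, mostly near fixation
  py <- bn_draw(p0, 0.3)
  pw0 <- bn_draw(p0, 0.1); px0 <- bn_draw(p0, 0.1)
  mix <- runif(m) < 0.3               # 30% introgressed sites
  pw_in <- ifelse(mix, 0.5 * pw0 + 0.5 * py, pw0)
  px_in <- ifelse(mix, 0.5 * px0 + 0.5 * py, px0)
  ft_w <- counts_from_freqs(list(W = pw_in, X = px0, Y = py, Z = pz), 50)
  ft_x <- counts_from_freqs(list(W = pw0, X = px_in, Y = py, Z = pz), 50)
  dw <- d_statistic(ft_w, "W", "X", "Y", "Z", block_size_bp = 1e6)
  dx <- d_statistic(ft_x, "W", "X", "Y", "Z", block_size_bp = 1e6)
  expect_gt(dw$statistic, 0); expect_gt(dw$z, 3)
  expect_lt(dx$statistic, 0); expect_lt(dx$z, -3)
})

test_that("FST estimators: fixed difference gives 1, identical profiles
           give ~0, Hudson and Weir-Cockerham agree", {
  m <- 50
  ac <- cbind(P1 = rep(100L, m), P2 = rep(0L, m))
  an <- matrix(100L, m, 2, dimnames = list(NULL, c("P1", "P2")))
  ft <- freq_table_from_counts(ac, an)
  expect_equal(fst_pairwise(ft, "P1", "P2")$fst, 1)

  set.seed(61)
  co <- two_pop_cohort(n_per = 40, n_sites = 4000, drift = 0.08,
                       seed = 61)
  ft2 <- site_freq_table(co$genotypes)
  h <- fst_pairwise(ft2, "A", "B", estimator = "hudson")
  w <- fst_pairwise(ft2, "A", "B", estimator = "weir_cockerham")
  expect_equal(h$fst, w$fst, tolerance = 0.02)
  expect_error(fst_pairwise(ft2, "A", "B", estimator = "nei"))

  # two independent samples of the same population: ~0 (unbiased)
  p <- runif(4000, 0.1, 0.9)
  ft3 <- freq_table_from_counts(
    cbind(P1 = rbinom(4000, 80, p), P2 = rbinom(4000, 80, p)),
    matrix(80L, 4000, 2, dimnames = list(NULL, c("P1", "P2"))))
  expect_lt(abs(fst_pairwise(ft3, "P1", "P2")$fst), 0.005)
})

test_that("haploid frequency tables work through FST", {
  yl <- simulate_y_locus(2, sizes = c(10, 10), seed = 14)
  ft <- site_freq_table(yl$haplotypes)
  f <- fst_pairwise(ft, "C1", "C2")
  # private fixed SNVs have per-site FST exactly 1
  priv <- unlist(yl$private_snvs)
  expect_true(all(abs(f$per_site$fst[priv] - 1) < 1e-12))
})

test_that("admixture network keeps only f3 < 0 with Z < -3", {
  mk <- function(A, B, C, stat, z) {
    structure(list(statistic = stat, se = abs(stat / z), z = z,
                   n_blocks = 10, n_sites = 1000,
                   populations = c(A = A, B = B, C = C), name = "f3"),
              class = "block_stat")
  }
  rs <- list(mk("P", "Q", "T1", -0.01, -5), mk("P", "R", "T1", -0.01, -2),
             mk("Q", "R", "T2", 0.01, -5), mk("P", "Q", "T2", -0.02, -8))
  net <- build_admixture_network(rs)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$edges$target, c("T1", "T2"))
  expect_equal(as.integer(net$networks[["T1"]]$degree[c("P", "Q")]),
               c(1L, 1L))
  empty <- build_admixture_network(list(mk("A", "B", "C", 0.1, 2)))
  expect_equal(nrow(empty$edges), 0)
  expect_length(empty$networks, 0)
})
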