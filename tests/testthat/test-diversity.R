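test_that("per-site diversity equals the allele-pair enumeration", {
  # 0/0 vs 1/1: 4 of 6 pairs differ
  expect_equal(site_pi(c(0L, 1L), c(0L, 1L)), 2 / 3)
  # 0/0, 0/1, 1/1: 9 of 15 pairs differ
  expect_equal(site_pi(c(0L, 0L, 1L), c(0L, 1L, 1L)), 0.6)
  expect_equal(site_pi(c(0L, 0L), c(0L, 0L)), 0)
  expect_true(is.na(site_pi(c(NA_integer_, NA), c(NA_integer_, NA))))
  # property: 50 random columns against O(n^2) enumeration
  withr::with_seed(51, {
    for (i in 1:50) {
      n <- sample(3:20, 1)
      a1 <- sample(c(0L, 1L, NA), n, replace = TRUE)
      a2 <- ifelse(is.na(a1), NA, sample(c(0L, 1L), n, replace = TRUE))
      expect_equal(site_pi(a1, a2), oracle_site_pi(a1, a2))
    }
  })
})

test_that("windowed diversity divides by window length and sums site pi", {
  # one site with site_pi 0.5 in a 100 kb window
  g <- make_g(matrix(c("0/0", "0/1", "1/1", "0/1"), 1),
              chrom = "chr1", pos = 5000L)
  wp <- windowed_pi(g, chrom_lengths = c(chr1 = 100000))
  expect_equal(wp$pi[1], site_pi(c(0L, 0L, 1L, 0L),
                                 c(0L, 1L, 1L, 1L)) / 1e5)
  # empty window
  expect_equal(wp$n_snps[2], 0L)
  expect_equal(wp$pi[2], 0)
  # 50 synthetic sites: window values equal a direct summation oracle
  sim <- simulate_genotypes(sim_config(
    n_sites = 50, chrom_lengths = c(chr01 = 2e5), missing_rate = 0.1,
    seed = 52))
  g2 <- sim$genotypes
  wp2 <- windowed_pi(g2, chrom_lengths = c(chr01 = 2e5))
  for (i in seq_len(nrow(wp2))) {
    sel <- g2$variants$pos >= wp2$start[i] & g2$variants$pos <= wp2$end[i]
    manual <- sum(vapply(which(sel), function(s)
      oracle_site_pi(g2$a1[s, ], g2$a2[s, ]), 0), na.rm = TRUE)
    expect_equal(wp2$pi[i], manual / (wp2$end[i] - wp2$start[i] + 1))
  }
})

test_that("individual F hits its closed-form extremes", {
  # sample 1 heterozygous at every site where expected hom is 1/2:
  # with one 0/0 companion, c = 1 of n = 4 alleles gives site_pi = 0.5
  gt <- matrix(rep(c("0/1", "0/0"), 10), ncol = 2, byrow = TRUE)
  f <- individual_f(make_g(gt))
  expect_equal(f$f_is[1], -1)
  # fully homozygous sample -> F = 1
  gt2 <- matrix(rep(c("0/0", "0/1", "1/1", "0/1"), 8), ncol = 4,
                byrow = TRUE)
  f2 <- individual_f(make_g(gt2))
  expect_equal(f2$f_is[1], 1)
  expect_equal(f2$observed_hom[1], 8L)
})

test_that("individual F recovers the simulated inbreeding coefficient", {
  sim <- simulate_genotypes(sim_config(
    n_clusters = 1, samples_per_cluster = 30, n_sites = 10000,
    chrom_lengths = c(chr01 = 6e6), fst_divergence = 0.1, f_is = 0.55,
    indel_fraction = 0, missing_rate = 0, seed = 8))
  f <- individual_f(sim$genotypes)
  expect_equal(mean(f$f_is), 0.55, tolerance = 0.03 / 0.55)
  # and a non-inbred panel recovers zero
  sim0 <- simulate_genotypes(sim_config(
    n_clusters = 1, samples_per_cluster = 30, n_sites = 10000,
    chrom_lengths = c(chr01 = 6e6), fst_divergence = 0.1, f_is = 0,
    indel_fraction = 0, missing_rate = 0, seed = 9))
  f0 <- individual_f(sim0$genotypes)
  expect_lt(abs(mean(f0$f_is)), 0.03)
})

test_that("variant spacing rounds half-up to the nearest bp", {
  expect_equal(variant_spacing(469291, 306400000), 653L)
  expect_equal(variant_spacing(70509, 306400000), 4346L)
  expect_equal(variant_spacing(1, 100), 100L)
})

test_that("combined-density ratios reproduce the cross-species comparisons", {
  kersting <- species_density("kersting", bp_per_snp = 653,
                              bp_per_indel = 4346)
  lablab <- species_density("lablab", bp_per_snp = 34, bp_per_indel = 277)
  cowpea <- species_density("cowpea", bp_per_snp = 77, bp_per_indel = 648)
  expect_equal(diversity_ratio(kersting, kersting)$ratio, 1)
  expect_equal(diversity_ratio(kersting, kersting)$percent_reduction, 0)
  rl <- diversity_ratio(lablab, kersting)
  rc <- diversity_ratio(cowpea, kersting)
  expect_equal(rl$ratio, 18.7, tolerance = 0.01)
  expect_equal(rc$ratio, 8.2, tolerance = 0.01)
  expect_gt(rl$percent_reduction, 85)
  expect_lt(rl$percent_reduction, 95)
  expect_gt(rc$percent_reduction, 85)
})

test_that("cluster summaries subset correctly and order by simulated diversity", {
  sim <- simulate_genotypes(sim_config(
    n_clusters = 1, samples_per_cluster = 10, n_sites = 300,
    chrom_lengths = c(chr01 = 5e5), missing_rate = 0, seed = 61))
  g <- sim$genotypes
  asg <- sim$assignments
  # single cluster equals the global windowed means (within-cluster
  # polymorphism filter changes n_snps only, pi sums are identical)
  cs <- cluster_summary(g, asg, chrom_lengths = c(chr01 = 5e5))
  wp <- windowed_pi(g, chrom_lengths = c(chr01 = 5e5))
  expect_equal(cs$mean_pi, mean(wp$pi))
  # a cluster of clones has zero diversity
  gt <- matrix(rep("0/1", 12), ncol = 4)
  gt[, 3:4] <- "0/0"
  g2 <- make_g(gt)
  asg2 <- data.frame(sample = g2$samples, cluster = c(1, 1, 2, 2))
  cs2 <- cluster_summary(g2, asg2, window = 1000, step = 1000,
                         chrom_lengths = c(chr1 = 1000))
  expect_equal(cs2$mean_pi[2], 0)
  expect_gt(cs2$mean_pi[1], 0)
  # ordering matches simulated heterozygosity ordering
  cfgA <- sim_config(n_clusters = 2, samples_per_cluster = c(12, 12),
                     n_sites = 2000, chrom_lengths = c(chr01 = 1e6),
                     f_is = 0, missing_rate = 0, seed = 62)
  simA <- simulate_genotypes(cfgA)
  # make cluster 2 nearly monomorphic by construction: overwrite its
  # genotypes with the major allele
  gA <- simA$genotypes
  ids2 <- which(simA$assignments$cluster == 2)
  gA$a1[, ids2] <- 0L
  gA$a2[, ids2] <- 0L
  csA <- cluster_summary(gA, simA$assignments,
                         chrom_lengths = c(chr01 = 1e6))
  expect_gt(csA$mean_pi[1], csA$mean_pi[2])
})
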