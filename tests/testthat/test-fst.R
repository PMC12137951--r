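test_that("fixed-difference groups give theta = 1 with b = c = 0", {
  a1 <- c(rep(0L, 5), rep(1L, 5))
  grp <- rep(c("g1", "g2"), each = 5)
  r <- wc_fst_site(a1, a1, grp)
  expect_equal(r$theta, 1)
  expect_equal(r$a, 0.5)
  expect_equal(r$b, 0)
  expect_equal(r$c, 0)
})

test_that("a site monomorphic in both groups is excluded with zero components", {
  a1 <- rep(0L, 10)
  grp <- rep(c("g1", "g2"), each = 5)
  r <- wc_fst_site(a1, a1, grp)
  expect_equal(r$a, 0)
  expect_equal(r$b, 0)
  expect_equal(r$c, 0)
  expect_true(is.na(r$theta))
})

test_that("variance components equal a literal transcription of the 1984 formulas", {
  withr::with_seed(71, {
    for (i in 1:100) {
      n1 <- sample(3:12, 1)
      n2 <- sample(3:12, 1)
      a1 <- c(sample(0:1, n1, replace = TRUE),
              sample(0:1, n2, replace = TRUE))
      a2 <- c(sample(0:1, n1, replace = TRUE),
              sample(0:1, n2, replace = TRUE))
      miss <- runif(n1 + n2) < 0.1
      a1[miss] <- NA
      a2[miss] <- NA
      grp <- rep(c("g1", "g2"), c(n1, n2))
      if (sum(!miss[grp == "g1"]) < 1 || sum(!miss[grp == "g2"]) < 1)
        next
      mine <- wc_fst_site(a1, a2, grp)
      oracle <- oracle_wc_site(a1, a2, grp)
      expect_equal(mine$a, ifelse(is.na(oracle$a), 0, oracle$a))
      expect_equal(mine$b, ifelse(is.na(oracle$b), 0, oracle$b))
      expect_equal(mine$c, ifelse(is.na(oracle$c), 0, oracle$c))
      if (!is.na(oracle$theta))
        expect_equal(mine$theta, oracle$theta)
    }
  })
})

test_that("weighted window F_ST equals the component-sum ratio recomputed per site", {
  sim <- simulate_genotypes(sim_config(
    n_clusters = 2, samples_per_cluster = c(8, 8), n_sites = 600,
    chrom_lengths = c(chr01 = 6e5), fst_divergence = 0.12,
    missing_rate = 0.05, indel_fraction = 0, seed = 72))
  g <- sim$genotypes
  ct <- contrast("ab",
                 sim$assignments$sample[sim$assignments$cluster == 1],
                 sim$assignments$sample[sim$assignments$cluster == 2])
  win <- windowed_fst(g, ct, chrom_lengths = c(chr01 = 6e5))
  grp <- ifelse(g$samples %in% ct$light, "g1", "g2")
  for (i in seq_len(nrow(win))) {
    sel <- which(g$variants$pos >= win$start[i] &
                   g$variants$pos <= win$end[i])
    comps <- lapply(sel, function(s)
      oracle_wc_site(g$a1[s, ], g$a2[s, ], grp))
    num <- sum(vapply(comps, function(z) ifelse(is.na(z$a), 0, z$a), 0))
    den <- sum(vapply(comps, function(z)
      ifelse(is.na(z$a), 0, z$a + z$b + z$c), 0))
    if (den > 0) expect_equal(win$fst[i], num / den)
  }
})

test_that("windowed F_ST recovers the simulated divergence parameter", {
  cfg <- sim_config(n_clusters = 2, samples_per_cluster = c(50, 50),
                    n_sites = 50000,
                    chrom_lengths = c(chr01 = 15e6, chr02 = 15e6),
                    fst_divergence = 0.13, f_is = 0.55,
                    indel_fraction = 0, missing_rate = 0.02, seed = 7)
  sim <- simulate_genotypes(cfg)
  ct <- contrast("c12",
                 sim$assignments$sample[sim$assignments$cluster == 1],
                 sim$assignments$sample[sim$assignments$cluster == 2])
  wf <- windowed_fst(sim$genotypes, ct,
                     chrom_lengths = cfg$chrom_lengths)
  expect_equal(mean(wf$fst, na.rm = TRUE), 0.13,
               tolerance = 0.02 / 0.13)
})

test_that("a window of fixed differences scores 1 and empty windows are excluded", {
  gt <- matrix(rep(c("1/1", "1/1", "0/0", "0/0"), 5), ncol = 4,
               byrow = TRUE)
  g <- make_g(gt, pos = seq(1000L, 5000L, by = 1000L))
  ct <- contrast("x", c("s1", "s2"), c("s3", "s4"))
  win <- windowed_fst(g, ct, chrom_lengths = c(chr1 = 2e5))
  expect_equal(win$fst[1], 1)
  expect_true(is.na(win$fst[nrow(win)]))
  expect_error(windowed_fst(g, contrast("y", c("s1", "s2"),
                                        c("nope", "s4"))),
               "absent")
})

test_that("top-quantile sets use the ceiling rule with strict thresholds", {
  th <- quantile_thresholds(1:100, c(0.99, 0.95))
  expect_equal(th$top1$members, 100L)
  expect_equal(th$top1$threshold, 99)
  expect_equal(sort(th$top5$members), 96:100)
  expect_equal(th$top5$threshold, 95)
  # membership is exactly "value > threshold"
  expect_setequal(which(1:100 > th$top5$threshold), th$top5$members)
  # constant vector: empty set, threshold equals the value
  suppressWarnings(thc <- quantile_thresholds(rep(2, 10)))
  expect_length(thc$top1$members, 0)
  expect_equal(thc$top1$threshold, 2)
  # NA windows are excluded but indices refer to the full vector
  v <- c(NA, 1:50, NA)
  th2 <- suppressWarnings(quantile_thresholds(v, 0.99))
  expect_equal(th2[[1]]$members, 51L)
})

test_that("outlier regions extend seeds through contiguous top-5% flanks", {
  win <- data.frame(chrom = "chr1",
                    start = c(1, 50001, 100001),
                    end = c(100000, 150000, 200000),
                    fst = c(0.5, 0.9, 0.55))
  # middle window in top1, all three in top5 -> one region 1-200k
  rg <- build_outlier_regions(win, top1 = 2L, top5 = 1:3, "c")
  expect_equal(nrow(rg), 1L)
  expect_equal(rg$start, 1)
  expect_equal(rg$end, 200000)
  expect_equal(rg$seed_windows[[1]], 2L)
  expect_setequal(rg$flank_windows[[1]], c(1L, 3L))
  # isolated seed with non-top5 neighbours stays a single window
  rg2 <- build_outlier_regions(win, top1 = 2L, top5 = 2L, "c")
  expect_equal(c(rg2$start, rg2$end), c(50001, 150000))
  # two seeds whose flanks touch merge into one region
  win3 <- data.frame(chrom = "chr1",
                     start = seq(1, by = 50000, length.out = 5),
                     end = seq(100000, by = 50000, length.out = 5),
                     fst = c(0.9, 0.5, 0.5, 0.5, 0.9))
  rg3 <- build_outlier_regions(win3, top1 = c(1L, 5L), top5 = 1:5, "c")
  expect_equal(nrow(rg3), 1L)
  expect_equal(c(rg3$start, rg3$end), c(1, 300000))
  # region construction invariant to which seed comes first
  rg3b <- build_outlier_regions(win3, top1 = c(5L, 1L), top5 = 1:5, "c")
  expect_equal(rg3b$start, rg3$start)
  expect_equal(rg3b$end, rg3$end)
  expect_equal(nrow(build_outlier_regions(win, integer(0), 1:3, "c")), 0L)
})

test_that("cross-checking assigns tiers by the window evidence in the overlap", {
  win <- data.frame(chrom = "chr1",
                    start = seq(1, by = 50000, length.out = 6),
                    end = seq(100000, by = 50000, length.out = 6),
                    fst = 0.5)
  reg <- function(s, e, nm) data.frame(chrom = "chr1", start = s,
                                       end = e, contrast = nm)
  # same single-window region in both top1 sets -> tier 1
  cand <- cross_compare(reg(50001, 150000, "A"), reg(50001, 150000, "B"),
                        win, 2L, 2L, 2L, 2L)
  expect_equal(cand$tier, 1L)
  # A's top1 window overlapping only B's top5 flank -> tier 2
  cand2 <- cross_compare(reg(50001, 150000, "A"), reg(100001, 250000, "B"),
                         win, 2L, 2L, 4L, 3:4)
  expect_equal(cand2$tier[1], 2L)
  # overlap only between two top5 flanks -> tier 3
  cand3 <- cross_compare(reg(1, 150000, "A"), reg(100001, 250000, "B"),
                         win, 1L, 1:3, 4L, 3:4)
  expect_equal(cand3$tier[1], 3L)
  # non-overlapping regions come back untier-ed
  cand4 <- cross_compare(reg(1, 100000, "A"), reg(200001, 300000, "B"),
                         win, 1L, 1L, 5L, 5L)
  expect_true(all(is.na(cand4$tier)))
  expect_equal(nrow(cand4), 2L)
})

test_that("gene intersection is inclusive-coordinate exact and matches brute force", {
  regions <- data.frame(chrom = "chr1", start = 150, end = 300)
  genes <- data.frame(chrom = "chr1", start = c(100, 100), end = c(200, 149),
                      strand = "+", gene_id = c("hit", "miss"),
                      description = NA)
  hits <- intersect_genes(regions, genes)
  expect_equal(hits$gene_id, "hit")
  # boundary: gene ending exactly at region start - 1 does not hit
  genes2 <- data.frame(chrom = "chr1", start = 100, end = 200,
                       strand = "+", gene_id = "g", description = NA)
  expect_equal(nrow(intersect_genes(
    data.frame(chrom = "chr1", start = 201, end = 300), genes2)), 0L)
  expect_equal(nrow(intersect_genes(
    data.frame(chrom = "chr1", start = 200, end = 300), genes2)), 1L)
  # random fixture vs O(n*m) enumeration
  withr::with_seed(81, {
    rg <- data.frame(chrom = sample(c("c1", "c2"), 30, replace = TRUE),
                     start = sample(1e4, 30))
    rg$end <- rg$start + sample(500, 30)
    gn <- data.frame(chrom = sample(c("c1", "c2"), 50, replace = TRUE),
                     start = sample(1e4, 50), strand = "+",
                     gene_id = paste0("g", 1:50), description = NA)
    gn$end <- gn$start + sample(300, 50)
  })
  hits <- intersect_genes(rg, gn)
  brute <- 0L
  for (i in seq_len(nrow(rg))) for (j in seq_len(nrow(gn)))
    if (rg$chrom[i] == gn$chrom[j] && rg$start[i] <= gn$end[j] &&
        rg$end[i] >= gn$start[j]) brute <- brute + 1L
  expect_equal(nrow(hits), brute)
})

test_that("locus overlap checks use inclusive bounds", {
  regions <- data.frame(chrom = c("chr1", "chr7"),
                        start = c(1, 1000), end = c(5000, 2000))
  expect_false(check_locus_overlap(
    regions, "chr7:18,230,603-18,249,975")$overlaps)
  expect_true(check_locus_overlap(regions, "chr7:1500-1600")$overlaps)
  expect_false(check_locus_overlap(regions, "chr7:2001-2100")$overlaps)
})

test_that("raising the planted displacement never lowers the window's F_ST rank", {
  # rank among background windows (those not overlapping the planted
  # interval, whose own F_ST also rises with delta)
  ranks <- vapply(c(0.2, 0.4, 0.6, 0.8, 1), function(delta) {
    cfg <- scan_test_config(seed = 99, delta = delta, n_sites = 2500L)
    sim <- simulate_genotypes(cfg)
    wf <- windowed_fst(sim$genotypes, sim$contrasts$A,
                       chrom_lengths = cfg$chrom_lengths)
    i <- which(wf$chrom == "chr01" & wf$start == 1000001)
    planted <- (wf$chrom == "chr01" & wf$start <= 1100000 &
                  wf$end >= 1000001) |
      (wf$chrom == "chr02" & wf$start <= 600000 & wf$end >= 500001) |
      (wf$chrom == "chr02" & wf$start <= 1900000 & wf$end >= 1800001)
    sum(wf$fst[!planted] > wf$fst[i], na.rm = TRUE)
  }, 0)
  expect_true(all(diff(ranks) <= 0))
})
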