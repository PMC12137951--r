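test_that("p-distance follows allele-multiset matching", {
  g <- make_g(matrix(c("0/0", "0/1"), 1), samples = c("x", "y"))
  expect_equal(p_distance(g)$d["x", "y"], 0.5)
  gt <- matrix(rep(c("0/0", "1/1"), 6), ncol = 2, byrow = TRUE)
  g2 <- make_g(gt, samples = c("x", "y"))
  expect_equal(p_distance(g2)$d["x", "y"], 1)
  g3 <- make_g(cbind(gt[, 1], gt[, 1]), samples = c("x", "y"))
  expect_equal(p_distance(g3)$d["x", "y"], 0)
  # zero iff identical over joint sites; symmetry; joint-site counting
  gt4 <- rbind(c("0/1", "0/1"), c("./.", "1/1"), c("0/0", "./."))
  g4 <- make_g(gt4, samples = c("x", "y"))
  pd <- p_distance(g4)
  expect_equal(pd$d["x", "y"], 0)
  expect_equal(pd$n_sites["x", "y"], 1L)
  expect_identical(pd$d, t(pd$d))
})

test_that("neighbour joining is exact on additive matrices", {
  # hand-built additive 4-taxon tree ((A:1,B:2):1,(C:3,D:4))
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- neighbor_joining(d)
  expect_equal(unname(as.matrix(ape::cophenetic.phylo(tr))[
    rownames(d), colnames(d)]), unname(d), tolerance = 1e-12)
  ref <- ape::unroot(ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);"))
  expect_equal(as.numeric(ape::dist.topo(tr, ref)), 0)
})

test_that("random additive trees (5-12 taxa) are recovered exactly", {
  withr::with_seed(91, {
    for (n in c(5, 7, 9, 12)) {
      tr <- ape::rtree(n)
      tr$edge.length <- runif(nrow(tr$edge), 0.1, 2)
      d <- ape::cophenetic.phylo(tr)
      nj1 <- neighbor_joining(d)
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), nj1)), 0)
      expect_lt(max(abs(ape::cophenetic.phylo(nj1)[rownames(d),
                                                   colnames(d)] - d)),
                1e-9)
      # and it agrees topologically with ape's independent NJ
      expect_equal(as.numeric(ape::dist.topo(ape::nj(d), nj1)), 0)
    }
  })
})

test_that("three taxa give the closed-form star and ties resolve deterministically", {
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighbor_joining(d3)
  expect_equal(ape::write.tree(tr), "(a:0.5,b:1.5,c:2.5);")
  # equidistant taxa: any resolution, but identical across runs
  d4 <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d4) <- 0
  expect_identical(ape::write.tree(neighbor_joining(d4)),
                   ape::write.tree(neighbor_joining(d4)))
  expect_error(neighbor_joining(d3[1:2, 1:2]), "at least 3")
})

test_that("negative branch lengths are clamped with the deficit moved to the sibling", {
  # matrix engineered to give a negative NJ length
  d <- matrix(c(0, 5, 9, 9, 5, 0, 8, 8, 9, 8, 0, 2, 9, 8, 2, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  raw <- neighbor_joining(d, clamp_negative = FALSE)
  clamped <- neighbor_joining(d)
  expect_true(all(clamped$edge.length >= 0))
  # total tree length preserved when a sibling absorbs the deficit
  expect_equal(sum(clamped$edge.length), sum(raw$edge.length))
})

test_that("bootstrap supports behave at the extremes and are reproducible", {
  cfg <- sim_config(n_clusters = 2, samples_per_cluster = c(8, 8),
                    n_sites = 800, chrom_lengths = c(chr01 = 1e6),
                    fst_divergence = 0.9, f_is = 0.5,
                    indel_fraction = 0, missing_rate = 0.01, seed = 5)
  sim <- simulate_genotypes(cfg)
  tr <- bootstrap_support(sim$genotypes, n_reps = 200, seed = 42)
  bi <- popgenscan:::bipartitions(tr)
  split <- paste(sort(sim$assignments$sample[
    sim$assignments$cluster == 2]), collapse = "|")
  expect_equal(tr$node.label[match(split, bi)], "100")
  # determinism
  tr2 <- bootstrap_support(sim$genotypes, n_reps = 50, seed = 7)
  tr3 <- bootstrap_support(sim$genotypes, n_reps = 50, seed = 7)
  expect_identical(tr2$node.label, tr3$node.label)
  # single replicate: supports are 0 or 100
  tr1 <- bootstrap_support(sim$genotypes, n_reps = 1, seed = 3)
  sup <- suppressWarnings(as.integer(tr1$node.label))
  expect_true(all(sup[!is.na(sup)] %in% c(0L, 100L)))
})

test_that("bootstrap supports are invariant to leaf-label permutation", {
  cfg <- sim_config(n_clusters = 2, samples_per_cluster = c(5, 5),
                    n_sites = 400, chrom_lengths = c(chr01 = 5e5),
                    fst_divergence = 0.8, f_is = 0.3,
                    indel_fraction = 0, missing_rate = 0, seed = 14)
  sim <- simulate_genotypes(cfg)
  g <- sim$genotypes
  perm <- rev(seq_along(g$samples))
  gp <- subset_genotypes(g, samples = perm)
  t1 <- bootstrap_support(g, n_reps = 50, seed = 9)
  t2 <- bootstrap_support(gp, n_reps = 50, seed = 9)
  s1 <- setNames(t1$node.label, popgenscan:::bipartitions(t1))
  s2 <- setNames(t2$node.label, popgenscan:::bipartitions(t2))
  shared <- intersect(names(s1)[!is.na(names(s1))],
                      names(s2)[!is.na(names(s2))])
  expect_gt(length(shared), 0)
  expect_identical(s1[shared], s2[shared])
})

test_that("outgroup rooting splits the outgroup edge and preserves bipartitions", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0.5);")
  rooted <- root_with_outgroup(tr, "D")
  expect_true(ape::is.rooted(rooted))
  root_children <- rooted$edge[rooted$edge[, 1] ==
                                 ape::Ntip(rooted) + 1L, 2]
  expect_true(match("D", rooted$tip.label) %in% root_children)
  # the outgroup edge length 4 is split 2 + 2
  d_edge <- rooted$edge.length[rooted$edge[, 2] ==
                                 match("D", rooted$tip.label)]
  expect_equal(d_edge, 2)
  # bipartitions unchanged by rooting
  expect_setequal(
    stats::na.omit(popgenscan:::bipartitions(rooted)),
    stats::na.omit(popgenscan:::bipartitions(tr)))
  # idempotent topology under re-rooting on the same leaf
  rooted2 <- root_with_outgroup(rooted, "D")
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(rooted),
                                         ape::unroot(rooted2))), 0)
  expect_error(root_with_outgroup(tr, "Z"), "not in tree")
})
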