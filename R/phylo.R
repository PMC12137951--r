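#' Pairwise genotype p-distance matrix
#'
#' For each sample pair, over sites called in both, the per-site
#' distance is `1 - (shared alleles)/2` under allele-multiset matching
#' of the two diploid calls (identical homozygotes share 2 alleles,
#' homozygote vs heterozygote share 1, opposite homozygotes share 0,
#' identical heterozygotes share 2); the pair distance is the mean
#' per-site distance. For biallelic dosages this is
#' `mean(|g_i - g_j|) / 2`.
#'
#' @param g A [genotypes()] object of biallelic SNPs.
#' @param samples Samples to include (default all).
#' @return List with `d` (symmetric matrix, zero diagonal) and
#'   `n_sites` (matrix of jointly-called site counts). Pairs with no
#'   joint site get `NA` distance.
#' @export
p_distance <- function(g, samples = g$samples) {
  sub <- subset_genotypes(g, samples = samples)
  dos <- dosage(sub)
  m <- length(samples)
  d <- matrix(0, m, m, dimnames = list(samples, samples))
  njoint <- matrix(0L, m, m, dimnames = list(samples, samples))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      shared <- !is.na(dos[, i]) & !is.na(dos[, j])
      njoint[i, j] <- njoint[j, i] <- sum(shared)
      d[i, j] <- d[j, i] <- if (any(shared))
        mean(abs(dos[shared, i] - dos[shared, j])) / 2 else NA_real_
    }
  }
  list(d = d, n_sites = njoint)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler Q-criterion
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`; ties are
#' broken deterministically toward the pair with the lowest (sorted)
#' subtree leaf labels, making the result independent of input order. Branch
#' lengths come from the standard split formula; on an additive matrix
#' the generating topology and branch lengths are recovered exactly.
#' Negative branch lengths are clamped to zero with the deficit
#' transferred to the sibling edge (path lengths preserved) unless
#' `clamp_negative = FALSE`.
#'
#' @param d Symmetric distance matrix with labelled rows/columns, or
#'   the `d` element of [p_distance()] output.
#' @param clamp_negative Clamp negative branch lengths.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d, clamp_negative = TRUE) {
  if (is.list(d) && !is.matrix(d)) d <- d$d
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbour joining needs at least 3 taxa")
  if (any(!is.finite(d)))
    stop("distance matrix has undefined entries (a pair with no ",
         "jointly-called site?)")
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  frag <- labs                      # newick fragment per active node
  rep_lab <- labs                   # smallest leaf label in each subtree
  fmt <- function(x) sprintf("%.12g", x)
  while (n > 3L) {
    r <- rowSums(d)
    Q <- (n - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] != best[, 2], , drop = FALSE]
    # tie-break on the lowest (sorted) pair of subtree leaf labels, so
    # the result does not depend on input row order
    lo <- pmin(rep_lab[best[, 1]], rep_lab[best[, 2]])
    hi <- pmax(rep_lab[best[, 1]], rep_lab[best[, 2]])
    pick <- order(lo, hi)[1]
    i <- min(best[pick, ]); j <- max(best[pick, ])
    vi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- d[i, j] - vi
    if (clamp_negative) {
      if (vi < 0) { vj <- vj + vi; vi <- 0 }
      if (vj < 0) { vi <- vi + vj; vj <- 0 }
      vi <- max(vi, 0); vj <- max(vj, 0)
    }
    newfrag <- paste0("(", frag[i], ":", fmt(vi), ",",
                      frag[j], ":", fmt(vj), ")")
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    rep_lab <- c(rep_lab[keep], min(rep_lab[i], rep_lab[j]))
    d <- d2
    n <- n - 1L
  }
  v1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  v2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  v3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (clamp_negative) { v1 <- max(v1, 0); v2 <- max(v2, 0); v3 <- max(v3, 0) }
  nwk <- paste0("(", frag[1], ":", fmt(v1), ",", frag[2], ":", fmt(v2),
                ",", frag[3], ":", fmt(v3), ");")
  ape::read.tree(text = nwk)
}

# canonical bipartition strings of a tree's internal edges: each
# bipartition is represented by the sorted leaf set on the side NOT
# containing the alphabetically first label; trivial splits dropped.
bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  pp <- ape::prop.part(tree)
  out <- vapply(pp, function(idx) {
    side <- sort(tree$tip.label[idx])
    if (anchor %in% side) side <- setdiff(tips, side)
    if (length(side) < 2L || length(side) > length(tips) - 2L)
      return(NA_character_)
    paste(side, collapse = "|")
  }, character(1))
  out
}

#' SNP-column bootstrap supports for a neighbour-joining tree
#'
#' Resamples SNP columns with replacement to the original count,
#' rebuilds the p-distance matrix and NJ tree per replicate, and scores
#' each internal edge of the full-data tree by the percentage of
#' replicates containing the same leaf bipartition. A replicate whose
#' resampled columns leave some pair with no jointly-called site is
#' redrawn (up to 100 retries, logged via a warning beyond that).
#'
#' @param g A [genotypes()] object of biallelic SNPs.
#' @param samples Samples to include (default all).
#' @param n_reps Number of bootstrap replicates.
#' @param seed RNG seed (results are deterministic given the seed).
#' @return The full-data NJ tree (`phylo`) with integer percentage
#'   supports in `node.label` (empty for the trivial root split).
#' @export
bootstrap_support <- function(g, samples = g$samples, n_reps = 1000L,
                              seed = 1L) {
  sub <- subset_genotypes(g, samples = samples)
  if (length(samples) < 4L)
    stop("bootstrap supports need at least 4 taxa")
  main <- neighbor_joining(p_distance(sub)$d)
  main_bi <- bipartitions(main)
  counts <- stats::setNames(rep(0L, length(main_bi)), main_bi)
  withr::with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      tree <- NULL
      for (try in 1:100) {
        idx <- sample.int(n_sites(sub), n_sites(sub), replace = TRUE)
        dd <- p_distance(subset_genotypes(sub, sites = idx))$d
        if (all(is.finite(dd))) {
          tree <- neighbor_joining(dd)
          break
        }
      }
      if (is.null(tree)) {
        warning("bootstrap replicate ", rep,
                " kept producing undefined distances; skipped")
        next
      }
      bi <- bipartitions(tree)
      hit <- main_bi[!is.na(main_bi) & main_bi %in% bi]
      counts[hit] <- counts[hit] + 1L
    }
  })
  lab <- ifelse(is.na(main_bi), "",
                as.character(as.integer(round(
                  100 * counts[main_bi] / n_reps))))
  main$node.label <- lab
  main
}

#' Root a tree on the edge leading to an outgroup
#'
#' The root is placed on the edge subtending the outgroup leaf,
#' splitting its length equally. Node labels (bootstrap supports) are
#' re-assigned by matching leaf bipartitions, which are unchanged by
#' rooting.
#'
#' @param tree An `ape::phylo` tree.
#' @param outgroup Tip label of the outgroup.
#' @return A rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup) {
  k <- match(outgroup, tree$tip.label)
  if (is.na(k)) stop("outgroup '", outgroup, "' not in tree")
  has_support <- !is.null(tree$node.label)
  support_map <- NULL
  if (has_support) {
    bi <- bipartitions(tree)
    support_map <- stats::setNames(tree$node.label, bi)
    support_map <- support_map[!is.na(names(support_map))]
  }
  edge_len <- tree$edge.length[tree$edge[, 2] == k]
  rooted <- phytools::reroot(tree, k, position = edge_len / 2)
  if (has_support) {
    bi2 <- bipartitions(rooted)
    rooted$node.label <- ifelse(is.na(bi2), "",
                                unname(support_map[bi2]))
    rooted$node.label[is.na(rooted$node.label)] <- ""
  }
  rooted
}
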