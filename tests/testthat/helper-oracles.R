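# Independent oracles and tiny fixture builders shared by the suite.
# Each oracle is a deliberately naive re-derivation (scalar loops,
# exhaustive enumeration) kept separate from the vectorised package
# code it checks.

# build a genotypes object from genotype strings like "0/1" / "./."
make_g <- function(gt, chrom = NULL, pos = NULL, ref = NULL, alt = NULL,
                   qual = NA_real_, dp = NULL,
                   samples = paste0("s", seq_len(ncol(gt)))) {
  gt <- as.matrix(gt)
  n <- nrow(gt)
  parse <- function(part) {
    v <- suppressWarnings(as.integer(part))
    v
  }
  a1 <- matrix(parse(sub("/.*", "", gt)), n)
  a2 <- matrix(parse(sub(".*/", "", gt)), n)
  a1[is.na(a2)] <- NA_integer_
  a2[is.na(a1)] <- NA_integer_
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("T", n)
  genotypes(chrom = chrom, pos = pos, ref = ref, alt = alt, qual = qual,
            a1 = a1, a2 = a2, dp = dp, samples = samples)
}

# literal transcription of the Weir & Cockerham (1984) two-group
# variance components, scalar arithmetic on one site
oracle_wc_site <- function(a1, a2, group) {
  lv <- unique(group[!is.na(group)])
  stopifnot(length(lv) == 2)
  r <- 2
  n_i <- p_i <- h_i <- numeric(r)
  for (i in 1:2) {
    sel <- which(group == lv[i] & !is.na(a1))
    n_i[i] <- length(sel)
    if (n_i[i] == 0) return(list(a = NA, b = NA, c = NA, theta = NA))
    p_i[i] <- sum(a1[sel] + a2[sel]) / (2 * n_i[i])
    h_i[i] <- sum(a1[sel] != a2[sel]) / n_i[i]
  }
  nbar <- (n_i[1] + n_i[2]) / r
  if (nbar <= 1) return(list(a = NA, b = NA, c = NA, theta = NA))
  nc <- (r * nbar - (n_i[1]^2 + n_i[2]^2) / (r * nbar)) / (r - 1)
  pbar <- (n_i[1] * p_i[1] + n_i[2] * p_i[2]) / (r * nbar)
  s2 <- (n_i[1] * (p_i[1] - pbar)^2 + n_i[2] * (p_i[2] - pbar)^2) /
    ((r - 1) * nbar)
  hbar <- (n_i[1] * h_i[1] + n_i[2] * h_i[2]) / (r * nbar)
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  theta <- if (a + b + cc > 0) a / (a + b + cc) else NA
  list(a = a, b = b, c = cc, theta = theta)
}

# site-by-site application of each filter rule, independent of the
# vectorised filter_sites()
oracle_filter_keep <- function(g, params) {
  n <- n_sites(g)
  keep <- logical(n)
  for (i in seq_len(n)) {
    a1 <- g$a1[i, ]
    a2 <- g$a2[i, ]
    if (!is.na(params$min_qual) &&
        !is.na(g$variants$qual[i]) &&
        g$variants$qual[i] <= params$min_qual) next
    if (!is.null(g$dp) && !is.na(params$min_depth)) {
      low <- !is.na(g$dp[i, ]) & g$dp[i, ] <= params$min_depth
      a1[low] <- NA
      a2[low] <- NA
    }
    if (params$drop_indels && g$variants$is_indel[i]) next
    alts <- strsplit(g$variants$alt[i], ",")[[1]]
    if (params$biallelic_only &&
        (length(alts) != 1 || alts[1] == ".")) next
    if (sum(is.na(a1)) > params$max_missing_samples) next
    alleles <- c(a1, a2)
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) == 0) next
    f <- mean(alleles)
    if (min(f, 1 - f) < params$min_maf) next
    keep[i] <- TRUE
  }
  keep
}

# O(n^2) allele-pair enumeration of per-site diversity
oracle_site_pi <- function(a1, a2) {
  alleles <- c(a1, a2)
  alleles <- alleles[!is.na(alleles)]
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diff <- 0
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    if (alleles[i] != alleles[j]) diff <- diff + 1
  }
  diff / tot
}

# exhaustive SSR enumeration: for every (start, unit length) pair,
# extend the periodic run character by character and report maximal
# primitive repeats meeting the thresholds
oracle_find_ssrs <- function(s, thresholds = ssr_thresholds()) {
  s <- toupper(s)
  x <- strsplit(s, "")[[1]]
  L <- length(x)
  rows <- list()
  for (k in 1:6) {
    for (a in seq_len(max(L - k * thresholds[k] + 1, 0))) {
      # a must start a maximal run: the previous position must break
      # the period
      if (a > 1 && !is.na(x[a - 1 + k]) && x[a - 1] != "N" &&
          x[a - 1] == x[a - 1 + k]) next
      e <- a + k - 1
      if (any(x[a:e] == "N")) next
      while (e + 1 <= L && x[e + 1] != "N" && x[e + 1] == x[e + 1 - k])
        e <- e + 1
      n <- (e - a + 1) %/% k
      if (n < thresholds[k]) next
      motif <- paste(x[a:(a + k - 1)], collapse = "")
      primitive <- TRUE
      for (p in seq_len(k - 1)) {
        if (k %% p != 0) next
        if (strrep(substr(motif, 1, p), k / p) == motif)
          primitive <- FALSE
      }
      if (!primitive) next
      rows[[length(rows) + 1]] <- data.frame(
        start = a, end = a + n * k - 1, motif = motif,
        motif_length = k, n_repeats = n, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0), motif_length = integer(0),
                      n_repeats = integer(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$motif_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# simulation config used by several scan tests: three clusters, two
# contrasts sharing cluster 1, one shared and two private planted
# windows at delta = 0.8
scan_test_config <- function(seed, delta = 0.8, n_sites = 4000L) {
  contrasts <- list(A = list(A = 1L, B = 2L), B = list(A = 1L, B = 3L))
  pw <- list(
    list(chrom = "chr01", start = 1000001, end = 1100000,
         contrast = "A", delta = delta),
    list(chrom = "chr01", start = 1000001, end = 1100000,
         contrast = "B", delta = delta),
    list(chrom = "chr02", start = 500001, end = 600000,
         contrast = "A", delta = delta),
    list(chrom = "chr02", start = 1800001, end = 1900000,
         contrast = "B", delta = delta))
  sim_config(n_clusters = 3, samples_per_cluster = c(9, 9, 9),
             n_sites = n_sites,
             chrom_lengths = c(chr01 = 2.55e6, chr02 = 2.55e6),
             fst_divergence = 0.1, f_is = 0.55, indel_fraction = 0.1,
             missing_rate = 0.02, planted_windows = pw,
             contrasts = contrasts, seed = seed)
}

# one full scan of the three-cluster fixture; returns the candidate
# table plus the planted intervals. The scan runs on the QC-filtered
# SNP set (LD pruning serves the phylogeny/clustering analyses, not
# the windowed statistics).
run_scan_once <- function(seed, delta = 0.8, n_sites = 4000L) {
  cfg <- scan_test_config(seed, delta, n_sites)
  sim <- simulate_genotypes(cfg)
  fl <- filter_sites(sim$genotypes)
  gf <- fl$genotypes
  scA <- fst_scan(gf, sim$contrasts$A, chrom_lengths = cfg$chrom_lengths)
  scB <- fst_scan(gf, sim$contrasts$B, chrom_lengths = cfg$chrom_lengths)
  cand <- cross_compare(scA$regions, scB$regions, scA$windows,
                        scA$thresholds$top1$members,
                        scA$thresholds$top5$members,
                        scB$thresholds$top1$members,
                        scB$thresholds$top5$members)
  list(candidates = cand, scan_a = scA, scan_b = scB, config = cfg)
}

# does interval (chrom, start, end) overlap row set of a region table?
region_covering <- function(regions, chrom, start, end) {
  which(regions$chrom == chrom & regions$start <= end &
          regions$end >= start)
}
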