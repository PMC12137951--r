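#' Site-filter parameters
#'
#' Defaults follow the strictest of the two calling settings used for
#' the analysis this package reproduces: site quality Q > 20, per-call
#' depth DP > 10, indels removed, biallelic SNPs only, at most 3 samples
#' missing a call, and minor-allele frequency of at least 0.05 (the rule
#' is strict: MAF < 0.05 is removed, MAF exactly 0.05 is retained).
#'
#' @param max_missing_samples Sites with strictly more missing calls are
#'   removed.
#' @param min_maf Sites with MAF strictly below this are removed.
#' @param min_qual Sites with QUAL <= this are removed (`NA` disables).
#' @param min_depth Calls with DP <= this are set missing (`NA` disables);
#'   they then count toward the missingness rule.
#' @param drop_indels Remove indel records.
#' @param biallelic_only Keep only sites with exactly one ALT allele.
#' @return A list of class `"filter_params"`.
#' @export
filter_params <- function(max_missing_samples = 3L,
                          min_maf = 0.05,
                          min_qual = 20,
                          min_depth = 10,
                          drop_indels = TRUE,
                          biallelic_only = TRUE) {
  stopifnot(max_missing_samples >= 0,
            min_maf >= 0, min_maf <= 0.5)
  structure(list(max_missing_samples = as.integer(max_missing_samples),
                 min_maf = min_maf,
                 min_qual = min_qual,
                 min_depth = min_depth,
                 drop_indels = isTRUE(drop_indels),
                 biallelic_only = isTRUE(biallelic_only)),
            class = "filter_params")
}

#' LD-pruning parameters (SNP-count window / step / r-squared)
#'
#' The 50 / 5 / 0.5 defaults correspond to PLINK's
#' `--indep-pairwise 50 5 0.5`.
#'
#' @param window_size Window size in SNPs.
#' @param step Window step in SNPs.
#' @param r2_threshold Squared dosage-correlation cutoff.
#' @return A list of class `"ld_params"`.
#' @export
ld_params <- function(window_size = 50L, step = 5L, r2_threshold = 0.5) {
  stopifnot(step >= 1L, step <= window_size,
            r2_threshold >= 0, r2_threshold <= 1)
  structure(list(window_size = as.integer(window_size),
                 step = as.integer(step),
                 r2_threshold = r2_threshold),
            class = "ld_params")
}

#' Minor-allele frequency of a biallelic genotype column
#'
#' `min(f, 1 - f)` with `f` the alternate-allele frequency over
#' non-missing alleles. All calls missing gives `NA` (undefined).
#'
#' @param a1,a2 Integer allele vectors (0/1, `NA` = missing call).
#' @return MAF in \[0, 0.5\], or `NA_real_` when no allele is called.
#' @export
compute_maf <- function(a1, a2) {
  alleles <- c(a1, a2)
  alleles <- alleles[!is.na(alleles)]
  if (length(alleles) == 0L) return(NA_real_)
  f <- mean(alleles)
  min(f, 1 - f)
}

# vectorised MAF over all sites of a genotypes object
site_maf <- function(g) {
  called <- !is.na(g$a1)
  n <- 2L * rowSums(called)
  cnt <- rowSums(g$a1, na.rm = TRUE) + rowSums(g$a2, na.rm = TRUE)
  f <- ifelse(n > 0L, cnt / n, NA_real_)
  pmin(f, 1 - f)
}

#' Apply the site filters in their fixed order
#'
#' Rules run in the order QUAL -> depth mask -> indels -> biallelic ->
#' missingness -> MAF, with each removed site attributed to the first
#' rule that triggers. The depth rule does not remove sites: a call with
#' DP <= `min_depth` is set missing and subsequently counts toward the
#' missingness rule. MAF is computed on non-missing alleles after
#' masking. The operation is idempotent.
#'
#' @param g A [genotypes()] object.
#' @param params A [filter_params()] object.
#' @return List with `genotypes` (retained sites), `removed` (named
#'   counts per rule), `n_masked_calls`, and `kept` (logical index into
#'   the input sites).
#' @export
filter_sites <- function(g, params = filter_params()) {
  n0 <- n_sites(g)
  removed <- c(qual = 0L, indel = 0L, multiallelic = 0L,
               missingness = 0L, maf = 0L)
  alive <- rep(TRUE, n0)

  if (!is.null(params$min_qual) && !is.na(params$min_qual)) {
    fail <- !(g$variants$qual > params$min_qual)
    fail[is.na(fail)] <- FALSE
    removed["qual"] <- sum(alive & fail)
    alive <- alive & !fail
  }

  n_masked <- 0L
  if (!is.null(params$min_depth) && !is.na(params$min_depth) &&
      !is.null(g$dp)) {
    mask <- !is.na(g$dp) & g$dp <= params$min_depth & !is.na(g$a1)
    n_masked <- sum(mask)
    g$a1[mask] <- NA_integer_
    g$a2[mask] <- NA_integer_
  }

  if (params$drop_indels) {
    fail <- g$variants$is_indel
    removed["indel"] <- sum(alive & fail)
    alive <- alive & !fail
  }

  if (params$biallelic_only) {
    fail <- n_alt_alleles(g$variants$alt) != 1L
    removed["multiallelic"] <- sum(alive & fail)
    alive <- alive & !fail
  }

  n_miss <- rowSums(is.na(g$a1))
  fail <- n_miss > params$max_missing_samples
  removed["missingness"] <- sum(alive & fail)
  alive <- alive & !fail

  maf <- site_maf(g)
  fail <- is.na(maf) | maf < params$min_maf
  removed["maf"] <- sum(alive & fail)
  alive <- alive & !fail

  list(genotypes = subset_genotypes(g, sites = alive),
       removed = removed,
       n_masked_calls = n_masked,
       kept = alive)
}

#' Squared dosage correlation between two genotype columns
#'
#' Pearson correlation of the 0/1/2 allele-dosage encodings over samples
#' called in both columns, squared. Undefined (fewer than two shared
#' calls, or zero variance in either column) gives `NA`, which LD
#' pruning treats as "not in LD".
#'
#' @param dos_a,dos_b Integer dosage vectors (`NA` = missing).
#' @return Squared correlation in \[0,1\], or `NA_real_`.
#' @export
genotype_r2 <- function(dos_a, dos_b) {
  shared <- !is.na(dos_a) & !is.na(dos_b)
  if (sum(shared) < 2L) return(NA_real_)
  a <- dos_a[shared]
  b <- dos_b[shared]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Windowed LD pruning of SNP columns
#'
#' Slides windows of `window_size` SNPs advanced by `step` along each
#' chromosome (a single window when a chromosome has fewer SNPs). Within
#' every window, for each pair with r-squared above the threshold the
#' later (higher-index) SNP is marked for removal; marks accumulate
#' across windows, so the result is independent of traversal order and
#' no retained within-window pair exceeds the threshold.
#'
#' @param g A [genotypes()] object of biallelic SNPs ordered by
#'   (chrom, pos).
#' @param params An [ld_params()] object.
#' @return Logical vector over sites: `TRUE` = retained.
#' @export
ld_prune <- function(g, params = ld_params()) {
  dos <- dosage(g)
  chrom <- g$variants$chrom
  keep <- rep(TRUE, n_sites(g))
  ws <- params$window_size
  st <- params$step
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    m <- length(idx)
    if (m < 2L) next
    if (m <= ws) {
      starts <- 1L
    } else {
      starts <- seq.int(1L, m - ws + 1L, by = st)
      if (starts[length(starts)] < m - ws + 1L)
        starts <- c(starts, m - ws + 1L)
    }
    drop <- logical(m)
    for (s in starts) {
      cols <- idx[s:min(s + ws - 1L, m)]
      cc <- suppressWarnings(
        stats::cor(dos[cols, , drop = FALSE] |> t(),
                   use = "pairwise.complete.obs"))^2
      cc[is.na(cc)] <- 0
      nw <- length(cols)
      for (p in seq_len(nw - 1L)) {
        hit <- which(cc[p, (p + 1L):nw] > params$r2_threshold)
        if (length(hit)) drop[s - 1L + p + hit] <- TRUE
      }
    }
    keep[idx[drop]] <- FALSE
  }
  keep
}
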