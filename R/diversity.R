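#' Per-site nucleotide diversity
#'
#' Unbiased per-site heterozygosity: with `n` non-missing alleles of
#' which `c` are the alternate, `pi = 2 c (n - c) / (n (n - 1))` — the
#' proportion of differing allele pairs. Fewer than two called alleles
#' gives `NA` (site skipped).
#'
#' @param a1,a2 Integer allele vectors (0/1, `NA` = missing).
#' @return Site diversity in \[0,1\], or `NA_real_`.
#' @export
site_pi <- function(a1, a2) {
  alleles <- c(a1, a2)
  alleles <- alleles[!is.na(alleles)]
  n <- length(alleles)
  if (n < 2L) return(NA_real_)
  cnt <- sum(alleles)
  2 * cnt * (n - cnt) / (n * (n - 1))
}

# vectorised site_pi over all sites
site_pi_all <- function(g) {
  called <- !is.na(g$a1)
  n <- 2L * rowSums(called)
  cnt <- rowSums(g$a1, na.rm = TRUE) + rowSums(g$a2, na.rm = TRUE)
  ifelse(n >= 2L, 2 * cnt * (n - cnt) / (n * (n - 1)), NA_real_)
}

# the shared 100 kb / 50 kb window grid: windows tile each chromosome
# from position 1; trailing windows are truncated to the chromosome end
# and flagged
make_windows <- function(chrom_lengths, window = 100000L, step = 50000L) {
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq.int(1L, max(len - step + 1L, 1L), by = step)
    starts <- starts[starts <= len]
    end <- pmin(starts + window - 1L, len)
    data.frame(chrom = ch, start = starts, end = end,
               truncated = end - starts + 1L < window,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# chromosome lengths inferred from the data when not supplied
infer_chrom_lengths <- function(g, chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) return(chrom_lengths)
  tapply(g$variants$pos, g$variants$chrom, max)[
    unique(g$variants$chrom)]
}

#' Windowed nucleotide diversity
#'
#' Sliding 100 kb windows in 50 kb steps (defaults). Window `pi` is the
#' sum of per-site diversities divided by the window length in bp
#' (invariant positions included), matching the per-bp scale of
#' vcftools' `--window-pi`.
#'
#' @param g A [genotypes()] object.
#' @param window,step Window size and step in bp.
#' @param chrom_lengths Named vector of chromosome lengths; inferred
#'   from the largest variant position per chromosome when `NULL`.
#' @return Data frame: `chrom`, `start`, `end`, `truncated`, `n_snps`,
#'   `pi`.
#' @export
windowed_pi <- function(g, window = 100000L, step = 50000L,
                        chrom_lengths = NULL) {
  chrom_lengths <- infer_chrom_lengths(g, chrom_lengths)
  win <- make_windows(chrom_lengths, window, step)
  sp <- site_pi_all(g)
  v <- g$variants
  win$n_snps <- 0L
  win$pi <- 0
  for (i in seq_len(nrow(win))) {
    sel <- v$chrom == win$chrom[i] & v$pos >= win$start[i] &
      v$pos <= win$end[i]
    win$n_snps[i] <- sum(sel)
    win$pi[i] <- sum(sp[sel], na.rm = TRUE) /
      (win$end[i] - win$start[i] + 1)
  }
  win
}

#' Per-individual inbreeding coefficient F
#'
#' For each sample, over sites where the sample is called and at least
#' two alleles are called panel-wide: observed homozygosity `O`,
#' expected homozygosity `E = sum(1 - 2 c (n - c) / (n (n - 1)))`, and
#' `F = (O - E) / (L - E)` with `L` the number of contributing sites.
#' `F` is 1 for a fully homozygous sample and -1 when every site is
#' heterozygous with expected homozygosity one half.
#'
#' @param g A [genotypes()] object (biallelic SNPs).
#' @param samples Samples to report (default all).
#' @return Data frame: `sample`, `observed_hom`, `expected_hom`,
#'   `n_sites`, `f_is` (`NA` when the denominator is zero).
#' @export
individual_f <- function(g, samples = g$samples) {
  j <- match(samples, g$samples)
  if (anyNA(j)) stop("unknown sample(s): ",
                     paste(samples[is.na(j)], collapse = ", "))
  exp_hom <- 1 - site_pi_all(g)   # NA where < 2 alleles called
  out <- lapply(j, function(col) {
    called <- !is.na(g$a1[, col]) & !is.na(exp_hom)
    L <- sum(called)
    O <- sum(g$a1[called, col] == g$a2[called, col])
    E <- sum(exp_hom[called])
    data.frame(sample = g$samples[col],
               observed_hom = O,
               expected_hom = E,
               n_sites = L,
               f_is = if (L - E != 0) (O - E) / (L - E) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Average spacing between variants
#'
#' `round(genome_length / n_variants)` with half-up rounding: 469,291
#' SNPs over the 306.4 Mb of pseudochromosome sequence gives one SNP
#' every 653 bp.
#'
#' @param n_variants Variant count (>= 1).
#' @param genome_length Genome length in bp.
#' @return Integer bp per variant.
#' @export
variant_spacing <- function(n_variants, genome_length) {
  stopifnot(n_variants >= 1, genome_length > 0)
  as.integer(floor(genome_length / n_variants + 0.5))
}

#' Combined SNP + indel density of a dataset
#'
#' Either from raw counts and a genome length, or from already-printed
#' spacings (bp per SNP / bp per indel). The combined density is
#' `n_snps/genome_length + n_indels/genome_length`, i.e.
#' `1/bp_per_snp + 1/bp_per_indel`.
#'
#' @param label Dataset label.
#' @param n_snps,n_indels Variant counts.
#' @param genome_length Genome length in bp.
#' @param bp_per_snp,bp_per_indel Alternatively, the spacings.
#' @return A list of class `"species_density"` with `label`,
#'   `bp_per_snp`, `bp_per_indel`, `combined_density`.
#' @export
species_density <- function(label, n_snps = NULL, n_indels = NULL,
                            genome_length = NULL,
                            bp_per_snp = NULL, bp_per_indel = NULL) {
  if (is.null(bp_per_snp)) {
    stopifnot(!is.null(n_snps), !is.null(n_indels),
              !is.null(genome_length))
    bp_per_snp <- variant_spacing(n_snps, genome_length)
    bp_per_indel <- variant_spacing(n_indels, genome_length)
    combined <- n_snps / genome_length + n_indels / genome_length
  } else {
    combined <- 1 / bp_per_snp + 1 / bp_per_indel
  }
  structure(list(label = label,
                 bp_per_snp = bp_per_snp,
                 bp_per_indel = bp_per_indel,
                 combined_density = combined),
            class = "species_density")
}

#' Diversity ratio between two datasets
#'
#' Ratio of combined variant densities `a / b` and the percentage
#' reduction of `b` relative to `a`. With lablab as `a` and Kersting's
#' groundnut as `b` the ratio is about 18.7 ("ca. 1/18 the diversity")
#' and the reduction about 94.7%.
#'
#' @param a,b [species_density()] objects (`a` = the richer dataset).
#' @return List with `ratio` and `percent_reduction`.
#' @export
diversity_ratio <- function(a, b) {
  stopifnot(a$combined_density > 0, b$combined_density > 0)
  list(ratio = a$combined_density / b$combined_density,
       percent_reduction = 100 * (1 - b$combined_density /
                                    a$combined_density))
}

#' Per-cluster diversity summary
#'
#' Subsets the panel by cluster and recomputes windowed diversity per
#' cluster. By default only sites polymorphic within the cluster count
#' as that cluster's SNPs (`within_only = TRUE`); the alternative
#' (all panel sites) is exposed because the convention of the upstream
#' report is ambiguous.
#'
#' @param g A [genotypes()] object.
#' @param assignments Data frame with `sample` and `cluster` columns.
#' @param window,step Window size / step in bp.
#' @param chrom_lengths Optional named chromosome lengths.
#' @param within_only Restrict each cluster's sites to those polymorphic
#'   within it.
#' @return Data frame: `cluster`, `n_samples`, `mean_pi`,
#'   `mean_snps_per_window`, `n_windows`.
#' @export
cluster_summary <- function(g, assignments, window = 100000L,
                            step = 50000L, chrom_lengths = NULL,
                            within_only = TRUE) {
  chrom_lengths <- infer_chrom_lengths(g, chrom_lengths)
  clusters <- sort(unique(assignments$cluster[!is.na(assignments$cluster)]))
  out <- lapply(clusters, function(k) {
    ids <- assignments$sample[!is.na(assignments$cluster) &
                                assignments$cluster == k]
    sub <- subset_genotypes(g, samples = ids)
    if (within_only) {
      maf <- site_maf(sub)
      sub <- subset_genotypes(sub, sites = !is.na(maf) & maf > 0)
    }
    wp <- windowed_pi(sub, window, step, chrom_lengths)
    data.frame(cluster = k,
               n_samples = length(ids),
               mean_pi = mean(wp$pi),
               mean_snps_per_window = mean(wp$n_snps),
               n_windows = nrow(wp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
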