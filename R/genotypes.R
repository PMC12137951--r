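#' Genotype matrix for a diploid resequencing panel
#'
#' The central in-memory container of the package: a variant table paired
#' with two allele-index matrices (one per chromosome copy) over samples.
#' Allele indices follow the VCF convention (0 = REF, 1 = first ALT, ...);
#' a missing call has `NA` in both matrices. All coordinates are 1-based
#' inclusive, as in VCF/GFF; only BED output converts (see [write_bed()]).
#'
#' @param chrom Character vector of chromosome ids, one per site.
#' @param pos Integer vector of 1-based positions.
#' @param ref,alt Character vectors of REF and ALT alleles. Multi-allelic
#'   ALTs are comma-separated; monomorphic sites may use `"."`.
#' @param qual Numeric vector of phred-scaled site qualities (`NA` allowed).
#' @param a1,a2 Integer matrices, sites x samples, of allele indices.
#' @param dp Optional integer matrix of per-sample read depths.
#' @param samples Character vector of sample names (defaults to the
#'   column names of `a1`).
#'
#' @return An object of class `"genotypes"`: a list with elements
#'   `variants` (data frame with `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `is_indel`), `a1`, `a2`, `dp` and `samples`.
#' @examples
#' g <- genotypes(chrom = "chr1", pos = 100L, ref = "A", alt = "G",
#'                qual = 50, a1 = matrix(0L, 1, 2), a2 = matrix(1L, 1, 2),
#'                samples = c("s1", "s2"))
#' dosage(g)
#' @export
genotypes <- function(chrom, pos, ref, alt, qual = NA_real_, a1, a2,
                      dp = NULL, samples = colnames(a1)) {
  a1 <- as.matrix(a1)
  a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  n <- nrow(a1)
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(a1)))
  variants <- data.frame(
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    qual = rep_len(as.numeric(qual), n),
    stringsAsFactors = FALSE
  )
  variants$is_indel <- is_indel_alleles(variants$ref, variants$alt)
  if (!is.null(dp)) {
    dp <- as.matrix(dp)
    storage.mode(dp) <- "integer"
  }
  obj <- structure(
    list(variants = variants, a1 = a1, a2 = a2, dp = dp,
         samples = as.character(samples)),
    class = "genotypes"
  )
  validate_genotypes(obj)
  obj
}

validate_genotypes <- function(g) {
  v <- g$variants
  if (nrow(v) != nrow(g$a1) || nrow(v) != nrow(g$a2))
    stop("variant table and allele matrices disagree on site count")
  if (ncol(g$a1) != length(g$samples) || ncol(g$a2) != length(g$samples))
    stop("allele matrices disagree with sample list")
  if (nrow(v) > 0L && any(v$pos < 1L, na.rm = TRUE))
    stop("positions must be >= 1")
  # a call must be missing in both copies or present in both
  half <- xor(is.na(g$a1), is.na(g$a2))
  if (any(half)) stop("half-missing genotype call (one allele NA)")
  n_alleles <- 1L + n_alt_alleles(v$alt)
  bad <- (g$a1 >= n_alleles) | (g$a2 >= n_alleles) | (g$a1 < 0L) | (g$a2 < 0L)
  if (any(bad, na.rm = TRUE))
    stop("genotype allele index outside the site's allele list")
  invisible(g)
}

is_indel_alleles <- function(ref, alt) {
  mapply(function(r, a) {
    if (is.na(a) || a == ".") return(FALSE)
    alts <- strsplit(a, ",", fixed = TRUE)[[1]]
    any(nchar(alts) != nchar(r))
  }, ref, alt, USE.NAMES = FALSE)
}

n_alt_alleles <- function(alt) {
  vapply(alt, function(a) {
    if (is.na(a) || a == ".") 0L
    else length(strsplit(a, ",", fixed = TRUE)[[1]])
  }, integer(1), USE.NAMES = FALSE)
}

#' @export
print.genotypes <- function(x, ...) {
  v <- x$variants
  cat(sprintf("genotypes: %d sites x %d samples\n", nrow(v), length(x$samples)))
  if (nrow(v)) {
    cat(sprintf("  chromosomes: %s\n",
                paste(unique(v$chrom), collapse = ", ")))
    cat(sprintf("  indels: %d; missing calls: %.2f%%\n",
                sum(v$is_indel),
                100 * mean(is.na(x$a1))))
  }
  invisible(x)
}

#' Number of sites / samples in a genotypes object
#' @param g A [genotypes()] object.
#' @return Integer count.
#' @export
n_sites <- function(g) nrow(g$variants)

#' @rdname n_sites
#' @export
n_samples <- function(g) length(g$samples)

#' Alternate-allele dosage matrix
#'
#' For biallelic sites the usual 0/1/2 encoding; `NA` where the call is
#' missing. Multi-allelic sites simply sum allele indices, so restrict to
#' biallelic sites (see [filter_sites()]) before using dosages in LD or
#' distance computations.
#'
#' @param g A [genotypes()] object.
#' @return Integer matrix, sites x samples.
#' @export
dosage <- function(g) g$a1 + g$a2

#' Subset a genotypes object
#'
#' @param g A [genotypes()] object.
#' @param sites Integer or logical index over sites.
#' @param samples Character names, or integer/logical index over samples.
#' @return A `genotypes` object.
#' @export
subset_genotypes <- function(g, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(g))
  j <- seq_along(g$samples)
  if (!is.null(samples)) {
    if (is.character(samples)) {
      j <- match(samples, g$samples)
      if (anyNA(j))
        stop("unknown sample(s): ",
             paste(samples[is.na(j)], collapse = ", "))
    } else j <- seq_along(g$samples)[samples]
  }
  genotypes(
    chrom = g$variants$chrom[sites],
    pos = g$variants$pos[sites],
    ref = g$variants$ref[sites],
    alt = g$variants$alt[sites],
    qual = g$variants$qual[sites],
    a1 = g$a1[sites, j, drop = FALSE],
    a2 = g$a2[sites, j, drop = FALSE],
    dp = if (!is.null(g$dp)) g$dp[sites, j, drop = FALSE],
    samples = g$samples[j]
  )
}

# missing-call indicator (sites x samples)
missing_calls <- function(g) is.na(g$a1)

# heterozygote indicator (NA where missing)
het_calls <- function(g) g$a1 != g$a2
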