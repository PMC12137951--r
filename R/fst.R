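#' Define a two-group contrast
#'
#' A named pair of disjoint sample groups (e.g. light vs dark seed
#' coats) between which windowed F_ST is computed.
#'
#' @param name Contrast name.
#' @param light,dark Character vectors of sample ids (>= 2 each).
#' @return A list of class `"contrast"`.
#' @export
contrast <- function(name, light, dark) {
  if (length(intersect(light, dark)))
    stop("contrast groups overlap")
  if (length(light) < 2L || length(dark) < 2L)
    stop("each contrast group needs at least two samples")
  structure(list(name = name, light = as.character(light),
                 dark = as.character(dark)),
            class = "contrast")
}

# Weir & Cockerham (1984) per-site variance components for r groups,
# vectorised over sites. Returns a data frame with a, b, c and theta
# (NA where a group has no called genotype or the denominator is 0).
wc_components <- function(g, groups) {
  r <- length(groups)
  stopifnot(r >= 2L)
  idx <- lapply(groups, function(ids) {
    j <- match(ids, g$samples)
    if (anyNA(j)) stop("contrast samples absent from panel: ",
                       paste(ids[is.na(j)], collapse = ", "))
    j
  })
  nsite <- n_sites(g)
  N <- P <- H <- matrix(NA_real_, nsite, r)
  for (i in seq_len(r)) {
    a1 <- g$a1[, idx[[i]], drop = FALSE]
    a2 <- g$a2[, idx[[i]], drop = FALSE]
    called <- !is.na(a1)
    ni <- rowSums(called)
    N[, i] <- ni
    P[, i] <- ifelse(ni > 0,
                     (rowSums(a1, na.rm = TRUE) +
                        rowSums(a2, na.rm = TRUE)) / (2 * ni), NA)
    H[, i] <- ifelse(ni > 0,
                     rowSums(a1 != a2, na.rm = TRUE) / ni, NA)
  }
  nbar <- rowSums(N) / r
  nc <- (r * nbar - rowSums(N^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(N * P) / (r * nbar)
  s2 <- rowSums(N * (P - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(N * H) / (r * nbar)
  ok <- rowSums(N > 0) == r & nbar > 1 & nc > 0
  a <- b <- cc <- rep(NA_real_, nsite)
  a[ok] <- (nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                 hbar / 4) / (nbar - 1)))[ok]
  b[ok] <- (nbar / (nbar - 1) *
              (pbar * (1 - pbar) - (r - 1) / r * s2 -
                 (2 * nbar - 1) / (4 * nbar) * hbar))[ok]
  cc[ok] <- (hbar / 2)[ok]
  denom <- a + b + cc
  theta <- ifelse(ok & is.finite(denom) & denom > 0, a / denom, NA_real_)
  data.frame(a = a, b = b, c = cc, theta = theta)
}

#' Weir-Cockerham variance components for a single site
#'
#' The 1984 estimator for two groups of diploid genotypes: among-group
#' (`a`), between-individual-within-group (`b`) and within-individual
#' (`c`) components from group sizes, allele frequencies and observed
#' heterozygote proportions; the per-site estimate is
#' `theta = a / (a + b + c)` when the denominator is positive. A site
#' monomorphic across both groups has zero components and `theta = NA`
#' (excluded from ratios).
#'
#' @param a1,a2 Integer allele vectors over all samples.
#' @param group Vector assigning each sample to one of two groups
#'   (`NA` = excluded).
#' @return List with `a`, `b`, `c`, `theta`.
#' @export
wc_fst_site <- function(a1, a2, group) {
  samples <- paste0("s", seq_along(a1))
  g <- genotypes(chrom = "x", pos = 1L, ref = "A", alt = "T",
                 a1 = matrix(as.integer(a1), 1L),
                 a2 = matrix(as.integer(a2), 1L),
                 samples = samples)
  lv <- unique(group[!is.na(group)])
  stopifnot(length(lv) == 2L)
  comp <- wc_components(g, list(samples[which(group == lv[1])],
                                samples[which(group == lv[2])]))
  zero <- function(x) if (is.na(x)) 0 else x
  list(a = zero(comp$a[1]), b = zero(comp$b[1]), c = zero(comp$c[1]),
       theta = comp$theta[1])
}

#' Windowed Weir-Cockerham F_ST for a contrast
#'
#' Per-site components are aggregated per 100 kb / 50 kb window
#' (defaults). The default `"weighted"` estimator is the ratio of sums
#' `sum(a) / sum(a + b + c)` over the window's usable sites (the
#' standard headline output of vcftools' windowed F_ST); the
#' alternative `"mean"` averages per-site theta. Negative per-site
#' components are retained, preserving the estimator's expectation;
#' windows with no usable site get `NA` and are excluded from
#' quantiles.
#'
#' @param g A [genotypes()] object (biallelic SNPs).
#' @param ct A [contrast()] object.
#' @param window,step Window size / step in bp.
#' @param chrom_lengths Optional named chromosome lengths.
#' @param estimator `"weighted"` or `"mean"`.
#' @return Data frame: `chrom`, `start`, `end`, `truncated`, `n_snps`,
#'   `fst`.
#' @export
windowed_fst <- function(g, ct, window = 100000L, step = 50000L,
                         chrom_lengths = NULL,
                         estimator = c("weighted", "mean")) {
  estimator <- match.arg(estimator)
  chrom_lengths <- infer_chrom_lengths(g, chrom_lengths)
  comp <- wc_components(g, list(ct$light, ct$dark))
  win <- make_windows(chrom_lengths, window, step)
  v <- g$variants
  win$n_snps <- 0L
  win$fst <- NA_real_
  usable <- !is.na(comp$a)
  denom_site <- comp$a + comp$b + comp$c
  for (i in seq_len(nrow(win))) {
    sel <- v$chrom == win$chrom[i] & v$pos >= win$start[i] &
      v$pos <= win$end[i] & usable
    win$n_snps[i] <- sum(sel)
    if (!any(sel)) next
    if (estimator == "weighted") {
      den <- sum(denom_site[sel])
      if (den > 0) win$fst[i] <- sum(comp$a[sel]) / den
    } else {
      th <- comp$theta[sel]
      th <- th[!is.na(th)]
      if (length(th)) win$fst[i] <- mean(th)
    }
  }
  win
}

#' Top-quantile window sets and their thresholds
#'
#' The top-q set holds the `ceiling((1 - q) * N)` largest values, with
#' ties broken toward inclusion; the reported threshold is the largest
#' value not in the set, so membership is exactly "F_ST > threshold"
#' (the convention behind statements like "the top 1% of F_ST windows
#' had F_ST > 0.7790"). All-identical values give an empty set with the
#' threshold equal to that value.
#'
#' @param fst Numeric vector of window F_ST values (`NA` = undefined
#'   windows, excluded).
#' @param levels Quantile levels, e.g. `c(0.99, 0.95)`.
#' @return Named list per level: `threshold` and `members` (indices
#'   into `fst`).
#' @export
quantile_thresholds <- function(fst, levels = c(0.99, 0.95)) {
  def <- which(!is.na(fst))
  if (length(def) < 20L)
    warning("fewer than 20 defined windows; quantile thresholds are ",
            "unstable")
  vals <- fst[def]
  out <- lapply(levels, function(q) {
    if (length(unique(vals)) == 1L)
      return(list(threshold = vals[1], members = integer(0)))
    # tolerance guards the ceiling against floating-point excess in
    # (1 - q) * N (e.g. 0.01 * 100 = 1.0000000000000002)
    k <- max(1L, ceiling((1 - q) * length(vals) - 1e-9))
    v <- sort(vals, decreasing = TRUE)[k]
    below <- vals[vals < v]
    threshold <- if (length(below)) max(below) else v
    list(threshold = threshold,
         members = def[vals > threshold])
  })
  names(out) <- paste0("top", formatC(100 * (1 - levels),
                                      format = "g"))
  out
}

#' Build outlier regions from top-1% seeds and top-5% flanks
#'
#' Every top-1% window seeds a region; the region extends left and
#' right through consecutive overlapping/adjacent windows that are in
#' the top-5% set, and regions with overlapping intervals are merged.
#' The region interval is the union of its member windows.
#'
#' @param windows Window data frame (as from [windowed_fst()]), sorted
#'   by (chrom, start).
#' @param top1,top5 Integer indices (into `windows`) of the top-1% and
#'   top-5% sets; `top1` must be a subset of `top5`.
#' @param contrast_name Label attached to each region.
#' @return Data frame of regions: `chrom`, `start`, `end`, `max_fst`,
#'   `contrast`, plus list-columns `seed_windows` and `flank_windows`
#'   of window indices.
#' @export
build_outlier_regions <- function(windows, top1, top5,
                                  contrast_name = NA_character_) {
  if (!all(top1 %in% top5)) stop("top1 set must be a subset of top5")
  if (length(top1) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), max_fst = numeric(0),
                      contrast = character(0)))
  ord <- order(windows$chrom, windows$start)
  if (!identical(ord, seq_len(nrow(windows))))
    stop("windows must be sorted by (chrom, start)")
  in5 <- seq_len(nrow(windows)) %in% top5
  adjacent <- function(i, j) {    # j follows i on the same chromosome
    windows$chrom[i] == windows$chrom[j] &&
      windows$start[j] <= windows$end[i] + 1 &&
      windows$end[j] >= windows$start[i] - 1
  }
  regions <- lapply(sort(top1), function(seed) {
    lo <- seed
    while (lo > 1L && in5[lo - 1L] && adjacent(lo - 1L, lo)) lo <- lo - 1L
    hi <- seed
    while (hi < nrow(windows) && in5[hi + 1L] && adjacent(hi, hi + 1L))
      hi <- hi + 1L
    members <- lo:hi
    list(chrom = windows$chrom[seed],
         start = min(windows$start[members]),
         end = max(windows$end[members]),
         members = members)
  })
  # merge overlapping regions
  merged <- list()
  for (rg in regions) {
    placed <- FALSE
    for (i in seq_along(merged)) {
      m <- merged[[i]]
      if (m$chrom == rg$chrom && rg$start <= m$end + 1 &&
          rg$end >= m$start - 1) {
        merged[[i]] <- list(chrom = m$chrom,
                            start = min(m$start, rg$start),
                            end = max(m$end, rg$end),
                            members = sort(unique(c(m$members,
                                                    rg$members))))
        placed <- TRUE
        break
      }
    }
    if (!placed) merged[[length(merged) + 1L]] <- rg
  }
  out <- do.call(rbind, lapply(merged, function(m) {
    seeds <- intersect(m$members, top1)
    data.frame(chrom = m$chrom, start = m$start, end = m$end,
               max_fst = max(windows$fst[seeds], na.rm = TRUE),
               contrast = contrast_name, stringsAsFactors = FALSE)
  }))
  out$seed_windows <- I(lapply(merged, function(m)
    intersect(m$members, top1)))
  out$flank_windows <- I(lapply(merged, function(m)
    setdiff(intersect(m$members, top5), top1)))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-check outlier regions between two contrasts
#'
#' Region pairs overlapping by at least 1 bp produce a merged candidate
#' classified by the strongest window evidence inside the overlap:
#' tier 1 when the overlap holds a top-1% window of both contrasts,
#' tier 2 when top-1% of exactly one and top-5% of the other, tier 3
#' when only top-5% windows of both. Regions of either contrast that
#' overlap nothing are reported with `tier = NA` (untier-ed).
#'
#' @param regions_a,regions_b Region data frames from
#'   [build_outlier_regions()] for the two contrasts.
#' @param windows The shared window grid both scans used.
#' @param top1_a,top5_a,top1_b,top5_b Window-index sets of the two
#'   contrasts.
#' @return Data frame: `chrom`, `start`, `end`, `tier`, `contrasts`.
#' @export
cross_compare <- function(regions_a, regions_b, windows,
                          top1_a, top5_a, top1_b, top5_b) {
  overlaps <- function(c1, s1, e1, c2, s2, e2)
    c1 == c2 & s1 <= e2 & e1 >= s2
  win_in <- function(set, chrom, s, e)
    any(overlaps(windows$chrom[set], windows$start[set],
                 windows$end[set], chrom, s, e))
  cand <- list()
  hit_a <- rep(FALSE, nrow(regions_a))
  hit_b <- rep(FALSE, nrow(regions_b))
  for (i in seq_len(nrow(regions_a))) {
    for (j in seq_len(nrow(regions_b))) {
      if (!overlaps(regions_a$chrom[i], regions_a$start[i],
                    regions_a$end[i], regions_b$chrom[j],
                    regions_b$start[j], regions_b$end[j])) next
      hit_a[i] <- TRUE
      hit_b[j] <- TRUE
      ov_s <- max(regions_a$start[i], regions_b$start[j])
      ov_e <- min(regions_a$end[i], regions_b$end[j])
      ch <- regions_a$chrom[i]
      t1a <- win_in(top1_a, ch, ov_s, ov_e)
      t5a <- win_in(top5_a, ch, ov_s, ov_e)
      t1b <- win_in(top1_b, ch, ov_s, ov_e)
      t5b <- win_in(top5_b, ch, ov_s, ov_e)
      tier <- if (t1a && t1b) 1L
      else if ((t1a && t5b) || (t5a && t1b)) 2L
      else if (t5a && t5b) 3L
      else NA_integer_
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = ch,
        start = min(regions_a$start[i], regions_b$start[j]),
        end = max(regions_a$end[i], regions_b$end[j]),
        tier = tier,
        contrasts = paste(regions_a$contrast[i], regions_b$contrast[j],
                          sep = "+"),
        stringsAsFactors = FALSE)
    }
  }
  # merge overlapping candidates, keeping the best (lowest) tier
  merged <- list()
  for (cd in cand) {
    placed <- FALSE
    for (k in seq_along(merged)) {
      m <- merged[[k]]
      if (m$chrom == cd$chrom && cd$start <= m$end && cd$end >= m$start) {
        m$start <- min(m$start, cd$start)
        m$end <- max(m$end, cd$end)
        m$tier <- min(m$tier, cd$tier, na.rm = TRUE)
        merged[[k]] <- m
        placed <- TRUE
        break
      }
    }
    if (!placed) merged[[length(merged) + 1L]] <- cd
  }
  solo <- function(regions, hit) {
    if (!nrow(regions)) return(NULL)
    keep <- which(!hit)
    if (!length(keep)) return(NULL)
    data.frame(chrom = regions$chrom[keep], start = regions$start[keep],
               end = regions$end[keep], tier = NA_integer_,
               contrasts = regions$contrast[keep],
               stringsAsFactors = FALSE)
  }
  out <- rbind(do.call(rbind, merged), solo(regions_a, hit_a),
               solo(regions_b, hit_b))
  if (is.null(out))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), tier = integer(0),
                      contrasts = character(0)))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intersect outlier regions with gene features
#'
#' A gene hits a region iff the 1-based inclusive spans overlap by at
#' least 1 bp.
#'
#' @param regions Data frame with `chrom`, `start`, `end`.
#' @param genes Gene data frame from [read_gff()].
#' @return Long data frame: one row per (region, gene) hit with
#'   `region`, `chrom`, `start`, `end`, `gene_id`, `gene_start`,
#'   `gene_end`, `description`.
#' @export
intersect_genes <- function(regions, genes) {
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    hit <- genes$chrom == regions$chrom[i] &
      genes$start <= regions$end[i] & genes$end >= regions$start[i]
    if (!any(hit)) next
    rows[[length(rows) + 1L]] <- data.frame(
      region = i,
      chrom = regions$chrom[i],
      start = regions$start[i],
      end = regions$end[i],
      gene_id = genes$gene_id[hit],
      gene_start = genes$start[hit],
      gene_end = genes$end[hit],
      description = genes$description[hit],
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(region = integer(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      gene_id = character(0), gene_start = numeric(0),
                      gene_end = numeric(0), description = character(0)))
  do.call(rbind, rows)
}

#' Does any outlier region overlap a given locus?
#'
#' Used for checks like whether any candidate region touches the
#' common-bean P-gene orthologue interval.
#'
#' @param regions Data frame with `chrom`, `start`, `end`.
#' @param locus A locus string `"chrom:start-end"` or a one-row data
#'   frame with `chrom`, `start`, `end`.
#' @return List with `overlaps` (logical) and `regions` (row indices of
#'   overlapping regions).
#' @export
check_locus_overlap <- function(regions, locus) {
  if (is.character(locus)) locus <- parse_locus(locus)
  hit <- which(regions$chrom == locus$chrom &
                 regions$start <= locus$end &
                 regions$end >= locus$start)
  list(overlaps = length(hit) > 0, regions = hit)
}

#' Full outlier scan for one contrast
#'
#' Convenience wrapper: windowed F_ST, top-1%/top-5% thresholding and
#' region construction.
#'
#' @inheritParams windowed_fst
#' @return List: `windows`, `thresholds` (from [quantile_thresholds()]),
#'   `regions`.
#' @export
fst_scan <- function(g, ct, window = 100000L, step = 50000L,
                     chrom_lengths = NULL,
                     estimator = c("weighted", "mean")) {
  win <- windowed_fst(g, ct, window, step, chrom_lengths,
                      estimator = match.arg(estimator))
  th <- quantile_thresholds(win$fst, c(0.99, 0.95))
  regions <- build_outlier_regions(win, th$top1$members,
                                   th$top5$members, ct$name)
  list(windows = win, thresholds = th, regions = regions)
}
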