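#' Configuration for the Balding-Nichols panel simulator
#'
#' The generator emulates a small, highly inbred, geographically
#' structured diploid resequencing panel: a handful of clusters whose
#' per-cluster allele frequencies are Balding-Nichols draws around a
#' shared ancestral frequency, strong within-individual inbreeding,
#' SNPs plus a minority of short indels, sporadic missing calls, and
#' optional "planted" windows in which two contrast groups of clusters
#' are pushed toward fixation for opposite alleles so that a windowed
#' F_ST scan has known positives.
#'
#' Defaults mirror the study conditions the package is validated
#' against: three clusters of 8/8/10 samples, pairwise cluster
#' divergence in the 0.07-0.13 band (per-cluster F = 0.1), inbreeding
#' coefficient 0.55, 13% of variants emitted as indels, ancestral
#' frequencies uniform on [0.05, 0.95], and variant spacing of roughly
#' one per 600 bp.
#'
#' @param n_clusters Number of population clusters.
#' @param samples_per_cluster Integer vector (recycled) of cluster sizes.
#' @param n_sites Total variant count (SNPs + indels).
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param fst_divergence Per-cluster Balding-Nichols differentiation
#'   parameter F in (0,1); scalar or one value per cluster. The expected
#'   pairwise Weir-Cockerham F_ST between clusters k and l is close to
#'   (F_k + F_l)/2.
#' @param f_is Within-individual inbreeding coefficient in \[0,1).
#' @param indel_fraction Proportion of variants emitted as 1-5 bp indels.
#' @param missing_rate Per-call missingness probability.
#' @param maf_floor Ancestral allele frequencies are drawn uniform on
#'   \[maf_floor, 1 - maf_floor\].
#' @param planted_windows List of lists with elements `chrom`, `start`,
#'   `end`, `contrast` (name), `delta` (frequency displacement in (0,1\]).
#' @param contrasts Named list; each element is `list(A = clusters,
#'   B = clusters)` giving the two cluster groups of a seed-colour-style
#'   contrast.
#' @param include_outgroup Add one outgroup sample drawn at high
#'   divergence (`outgroup_fst`) for rooting trees.
#' @param outgroup_fst Balding-Nichols F for the outgroup sample.
#' @param dp_mean Mean per-call Poisson read depth.
#' @param seed RNG seed; every product of the generator is a
#'   deterministic function of the config.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_clusters = 3L,
                       samples_per_cluster = c(8L, 8L, 10L),
                       n_sites = 20000L,
                       chrom_lengths = c(chr01 = 6e6, chr02 = 6e6),
                       fst_divergence = 0.10,
                       f_is = 0.55,
                       indel_fraction = 0.13,
                       missing_rate = 0.02,
                       maf_floor = 0.05,
                       planted_windows = list(),
                       contrasts = list(),
                       include_outgroup = FALSE,
                       outgroup_fst = 0.8,
                       dp_mean = 25,
                       seed = 1L) {
  cfg <- list(
    n_clusters = as.integer(n_clusters),
    samples_per_cluster = rep_len(as.integer(samples_per_cluster),
                                  n_clusters),
    n_sites = as.integer(n_sites),
    chrom_lengths = chrom_lengths,
    fst_divergence = rep_len(fst_divergence, n_clusters),
    f_is = f_is,
    indel_fraction = indel_fraction,
    missing_rate = missing_rate,
    maf_floor = maf_floor,
    planted_windows = planted_windows,
    contrasts = contrasts,
    include_outgroup = isTRUE(include_outgroup),
    outgroup_fst = outgroup_fst,
    dp_mean = dp_mean,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_clusters >= 1L,
    all(cfg$samples_per_cluster >= 1L),
    cfg$n_sites >= 1L,
    all(cfg$chrom_lengths >= 1),
    all(cfg$fst_divergence > 0 & cfg$fst_divergence < 1),
    cfg$f_is >= 0 && cfg$f_is < 1,
    cfg$indel_fraction >= 0 && cfg$indel_fraction <= 1,
    cfg$missing_rate >= 0 && cfg$missing_rate <= 1,
    cfg$maf_floor >= 0 && cfg$maf_floor < 0.5
  )
  if (is.null(names(cfg$chrom_lengths)))
    stop("chrom_lengths must be a named vector")
  if (cfg$n_sites > sum(cfg$chrom_lengths))
    stop("more variant sites requested than simulated bp")
  for (pw in cfg$planted_windows) {
    if (!pw$chrom %in% names(cfg$chrom_lengths))
      stop("planted window on unknown chromosome: ", pw$chrom)
    if (pw$end > cfg$chrom_lengths[[pw$chrom]] || pw$start < 1)
      stop("planted window outside chromosome: ", pw$chrom)
    if (!pw$contrast %in% names(cfg$contrasts))
      stop("planted window references undefined contrast: ", pw$contrast)
    if (pw$delta < 0 || pw$delta > 1)
      stop("planted delta must lie in [0, 1]")
  }
  invisible(cfg)
}

#' Draw per-cluster allele frequencies under the Balding-Nichols model
#'
#' Each cluster frequency is an independent draw from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, which has mean `p` and variance
#' `F p (1-p)`. Degenerate ancestral frequencies (0 or 1) are returned
#' unchanged for every cluster.
#'
#' @param p Vector of ancestral allele frequencies.
#' @param F Differentiation parameter in (0,1); scalar or one per cluster.
#' @param n_clusters Number of clusters to draw.
#' @return Matrix `length(p)` x `n_clusters` of cluster frequencies.
#' @export
draw_cluster_frequencies <- function(p, F, n_clusters) {
  stopifnot(all(p >= 0 & p <= 1), all(F > 0 & F < 1))
  F <- rep_len(F, n_clusters)
  out <- matrix(NA_real_, length(p), n_clusters)
  fixed <- p <= 0 | p >= 1
  for (k in seq_len(n_clusters)) {
    shape1 <- p * (1 - F[k]) / F[k]
    shape2 <- (1 - p) * (1 - F[k]) / F[k]
    out[, k] <- ifelse(fixed, p,
                       stats::rbeta(length(p), shape1, shape2))
  }
  out
}

#' Draw diploid genotypes with inbreeding
#'
#' Genotype probabilities follow the inbreeding generalisation of
#' Hardy-Weinberg: with allele frequency `p`, `q = 1 - p` and inbreeding
#' coefficient `f`, P(alt hom) = p^2 + f p q, P(het) = 2 p q (1 - f),
#' P(ref hom) = q^2 + f p q. Implemented by drawing an
#' identity-by-descent indicator per individual.
#'
#' @param p Vector of allele frequencies (one per draw).
#' @param f_is Inbreeding coefficient in \[0,1).
#' @return List with integer vectors `a1`, `a2` of allele indices.
#' @export
draw_genotype <- function(p, f_is) {
  stopifnot(all(p >= 0 & p <= 1), f_is >= 0, f_is < 1)
  n <- length(p)
  ibd <- stats::runif(n) < f_is
  a1 <- stats::rbinom(n, 1L, p)
  a2 <- ifelse(ibd, a1, stats::rbinom(n, 1L, p))
  list(a1 = as.integer(a1), a2 = as.integer(a2))
}

#' Plant a high-divergence window into a cluster-frequency matrix
#'
#' Within the interval, frequencies of the contrast-A clusters are
#' displaced toward 1 (`p + delta (1 - p)`) and those of the contrast-B
#' clusters toward 0 (`p (1 - delta)`), so the expected window F_ST
#' rises above the genome background; `delta = 1` fixes opposite
#' alleles (window F_ST = 1) and `delta = 0` is the identity.
#'
#' @param freqs Sites x clusters frequency matrix.
#' @param chrom,pos Per-site chromosome and position vectors aligned
#'   with `freqs`.
#' @param interval List or one-row data frame with `chrom`, `start`, `end`.
#' @param clusters_a,clusters_b Integer cluster indices of the two sides.
#' @param delta Displacement in \[0,1\].
#' @return The modified frequency matrix.
#' @export
plant_divergent_window <- function(freqs, chrom, pos, interval,
                                   clusters_a, clusters_b, delta) {
  stopifnot(delta >= 0, delta <= 1)
  sel <- chrom == interval$chrom & pos >= interval$start &
    pos <= interval$end
  freqs[sel, clusters_a] <- freqs[sel, clusters_a] +
    delta * (1 - freqs[sel, clusters_a])
  freqs[sel, clusters_b] <- freqs[sel, clusters_b] * (1 - delta)
  freqs
}

#' Simulate a genotype panel with known truth
#'
#' The in-memory core of the generator (no files written): draws variant
#' positions, ancestral and per-cluster frequencies, plants divergent
#' windows, samples inbred diploid genotypes per cluster, injects
#' missing calls and assigns SNP/indel alleles, qualities and depths.
#'
#' @param config A [sim_config()] object.
#' @return List with elements `genotypes` (a [genotypes()] object),
#'   `assignments` (data frame `sample`, `cluster`, `colour`),
#'   `contrasts` (named list of [contrast()] objects) and `truth`
#'   (cluster assignment, ancestral `p`, cluster frequency matrix
#'   `p_k`, planted windows, config).
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  withr::with_seed(config$seed, simulate_genotypes_impl(config))
}

simulate_genotypes_impl <- function(cfg) {
  chroms <- names(cfg$chrom_lengths)
  # apportion sites to chromosomes by length, then draw sorted positions
  n_per <- round(cfg$n_sites * cfg$chrom_lengths / sum(cfg$chrom_lengths))
  n_per[length(n_per)] <- cfg$n_sites - sum(n_per[-length(n_per)])
  chrom <- rep(chroms, n_per)
  pos <- unlist(lapply(seq_along(chroms), function(i)
    sort(sample.int(cfg$chrom_lengths[[i]], n_per[i]))), use.names = FALSE)
  n <- cfg$n_sites

  p_anc <- stats::runif(n, cfg$maf_floor, 1 - cfg$maf_floor)
  p_k <- draw_cluster_frequencies(p_anc, cfg$fst_divergence,
                                  cfg$n_clusters)
  for (pw in cfg$planted_windows) {
    ct <- cfg$contrasts[[pw$contrast]]
    p_k <- plant_divergent_window(p_k, chrom, pos,
                                  list(chrom = pw$chrom, start = pw$start,
                                       end = pw$end),
                                  ct$A, ct$B, pw$delta)
  }

  sizes <- cfg$samples_per_cluster
  samples <- unlist(lapply(seq_len(cfg$n_clusters), function(k)
    sprintf("c%d_s%02d", k, seq_len(sizes[k]))), use.names = FALSE)
  cluster_of <- rep(seq_len(cfg$n_clusters), sizes)
  if (cfg$include_outgroup) {
    samples <- c(samples, "outgroup")
    cluster_of <- c(cluster_of, NA_integer_)
  }
  ns <- length(samples)

  a1 <- matrix(NA_integer_, n, ns)
  a2 <- matrix(NA_integer_, n, ns)
  for (j in seq_len(ns)) {
    if (is.na(cluster_of[j])) {
      p_out <- draw_cluster_frequencies(p_anc, cfg$outgroup_fst, 1L)[, 1]
      gt <- draw_genotype(p_out, cfg$f_is)
    } else {
      gt <- draw_genotype(p_k[, cluster_of[j]], cfg$f_is)
    }
    a1[, j] <- gt$a1
    a2[, j] <- gt$a2
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(n * ns) < cfg$missing_rate, n, ns)
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  is_indel <- stats::runif(n) < cfg$indel_fraction
  if (any(is_indel)) {
    ins <- is_indel & stats::runif(n) < 0.5
    del <- is_indel & !ins
    ext <- function(k) paste(sample(bases, k, replace = TRUE),
                             collapse = "")
    extn <- sample(1:5, n, replace = TRUE)
    alt[ins] <- vapply(which(ins), function(i)
      paste0(ref[i], ext(extn[i])), "")
    ref[del] <- vapply(which(del), function(i)
      paste0(ref[i], ext(extn[i])), "")
    alt[del] <- substr(ref[del], 1L, 1L)
  }
  qual <- round(stats::runif(n, 15, 500), 1)
  dp <- matrix(stats::rpois(n * ns, cfg$dp_mean), n, ns)

  g <- genotypes(chrom = chrom, pos = pos, ref = ref, alt = alt,
                 qual = qual, a1 = a1, a2 = a2, dp = dp,
                 samples = samples)

  colour_names <- c("dark", "cream", "brown", "white", "red", "black")
  colour <- ifelse(is.na(cluster_of), NA_character_,
                   colour_names[(cluster_of - 1L) %% 6L + 1L])
  assignments <- data.frame(sample = samples,
                            cluster = cluster_of,
                            colour = colour,
                            stringsAsFactors = FALSE)
  contrasts <- lapply(names(cfg$contrasts), function(nm) {
    ct <- cfg$contrasts[[nm]]
    contrast(nm,
             light = samples[!is.na(cluster_of) & cluster_of %in% ct$A],
             dark = samples[!is.na(cluster_of) & cluster_of %in% ct$B])
  })
  names(contrasts) <- names(cfg$contrasts)

  truth <- list(cluster_assignment = stats::setNames(cluster_of, samples),
                p_ancestral = p_anc,
                p_cluster = p_k,
                planted_windows = cfg$planted_windows,
                config = cfg)
  list(genotypes = g, assignments = assignments, contrasts = contrasts,
       truth = truth)
}

#' Generate a complete synthetic dataset on disk
#'
#' Runs [simulate_genotypes()] and writes a VCF, a reference FASTA with
#' planted SSRs, a GFF3 of genes tiling the planted windows (plus
#' background genes), a sample-assignment TSV and a JSON truth sidecar.
#' Identical configs produce byte-identical files.
#'
#' @param config A [sim_config()] object.
#' @param dir Output directory (created if needed).
#' @param write_fasta Write the reference FASTA (can be skipped when only
#'   the VCF-based statistics are exercised).
#' @param planted_ssrs Data frame with `chrom`, `start`, `motif`,
#'   `n_repeats`, or `NULL` for a small default census. The FASTA
#'   background is scrubbed of chance SSRs so the planted census is the
#'   exact truth.
#' @return Invisibly, a list with the simulation products plus `paths`
#'   (named vector of written files), `fasta`, `genes`, `ssr_truth`.
#' @export
generate_dataset <- function(config, dir, write_fasta = TRUE,
                             planted_ssrs = NULL) {
  sim <- simulate_genotypes(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "panel.vcf"),
             assignments = file.path(dir, "samples.tsv"),
             gff = file.path(dir, "genes.gff3"),
             truth = file.path(dir, "truth.json"))
  write_vcf(sim$genotypes, paths[["vcf"]],
            chrom_lengths = config$chrom_lengths)
  utils::write.table(sim$assignments, paths[["assignments"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)

  genes <- withr::with_seed(config$seed + 101L, simulate_genes(config))
  write_gff(genes, paths[["gff"]])

  fasta <- NULL
  ssr_truth <- NULL
  if (write_fasta) {
    paths[["fasta"]] <- file.path(dir, "reference.fa")
    ref <- withr::with_seed(config$seed + 202L,
                            simulate_reference(config, planted_ssrs))
    fasta <- ref$seqs
    ssr_truth <- ref$ssrs
    write_fasta(fasta, paths[["fasta"]])
  }

  truth_json <- list(
    seed = config$seed,
    cluster_assignment = as.list(sim$truth$cluster_assignment),
    planted_windows = config$planted_windows,
    planted_ssrs = ssr_truth,
    contrasts = config$contrasts
  )
  jsonlite::write_json(truth_json, paths[["truth"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(c(sim, list(paths = paths, fasta = fasta, genes = genes,
                        ssr_truth = ssr_truth)))
}

# genes tiling each planted window (4 per window) plus background genes
# every ~500 kb; descriptions mark the planted ones as pigment-pathway
# style candidates so gene-intersection truth is known.
simulate_genes <- function(cfg) {
  rows <- list()
  gid <- 0L
  for (pw in cfg$planted_windows) {
    width <- pw$end - pw$start + 1
    starts <- round(seq(pw$start, pw$end - 5000, length.out = 4))
    for (s in starts) {
      gid <- gid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = pw$chrom, start = s, end = s + 4999,
        strand = sample(c("+", "-"), 1L),
        gene_id = sprintf("gene%04d", gid),
        description = "synthetic pigment-pathway candidate",
        stringsAsFactors = FALSE)
    }
  }
  for (ch in names(cfg$chrom_lengths)) {
    len <- cfg$chrom_lengths[[ch]]
    first <- min(250000, max(len %/% 2 - 2500, 1))
    if (first + 5000 > len) next
    for (s in seq(first, len - 5000, by = 500000)) {
      gid <- gid + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = s, end = s + 4999,
        strand = sample(c("+", "-"), 1L),
        gene_id = sprintf("gene%04d", gid),
        description = "synthetic background gene",
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# random reference scrubbed of chance SSRs, then planted with a known
# census of perfect repeats
simulate_reference <- function(cfg, planted_ssrs = NULL) {
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(cfg$chrom_lengths, function(len)
    paste(sample(bases, len, replace = TRUE), collapse = ""), "")
  names(seqs) <- names(cfg$chrom_lengths)
  # break any chance SSR by mutating a base near its middle
  for (pass in 1:8) {
    hits <- do.call(rbind, lapply(names(seqs), function(ch)
      find_ssrs(seqs[[ch]], chrom = ch)))
    if (is.null(hits) || nrow(hits) == 0L) break
    for (i in seq_len(nrow(hits))) {
      ch <- hits$chrom[i]
      mid <- hits$start[i] + (hits$end[i] - hits$start[i]) %/% 2L
      old <- substr(seqs[[ch]], mid, mid)
      substr(seqs[[ch]], mid, mid) <- sample(setdiff(bases, old), 1L)
    }
  }
  if (is.null(planted_ssrs)) {
    planted_ssrs <- data.frame(
      chrom = rep(names(seqs)[1], 4),
      start = c(11000, 52000, 93000, 134000),
      motif = c("A", "AG", "AAT", "ACGT"),
      n_repeats = c(14L, 9L, 7L, 5L),
      stringsAsFactors = FALSE)
    planted_ssrs <- planted_ssrs[
      planted_ssrs$start + nchar(planted_ssrs$motif) *
        planted_ssrs$n_repeats < cfg$chrom_lengths[[1]], , drop = FALSE]
  }
  for (i in seq_len(nrow(planted_ssrs))) {
    ch <- planted_ssrs$chrom[i]
    rep_str <- strrep(planted_ssrs$motif[i], planted_ssrs$n_repeats[i])
    s <- planted_ssrs$start[i]
    e <- s + nchar(rep_str) - 1L
    # guard flanks so the planted run is maximal: the base before the
    # run must differ from the base one period later (the motif's last
    # character) and the base after it from one period earlier (the
    # motif's first character)
    k <- nchar(planted_ssrs$motif[i])
    first <- substr(planted_ssrs$motif[i], 1L, 1L)
    last <- substr(planted_ssrs$motif[i], k, k)
    substr(seqs[[ch]], s - 1L, e + 1L) <-
      paste0(setdiff(bases, last)[1], rep_str, setdiff(bases, first)[1])
  }
  list(seqs = seqs, ssrs = planted_ssrs)
}
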