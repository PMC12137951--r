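#' End-to-end pipeline configuration
#'
#' Either simulated inputs (a [sim_config()]) or paths to a VCF,
#' reference FASTA, GFF3 and assignment TSV; plus filtering, window,
#' contrast and bootstrap settings.
#'
#' @param sim A [sim_config()], or `NULL` when real inputs are given.
#' @param vcf,fasta,gff,assignments Input paths (ignored when `sim` is
#'   given; the simulator writes its own).
#' @param filter A [filter_params()] object.
#' @param ld An [ld_params()] object, or `NULL` to skip LD pruning.
#' @param window,step Window size / step in bp.
#' @param contrasts Named list of [contrast()] objects, or `NULL` to
#'   take the simulator's contrasts.
#' @param outgroup Sample id used to root the tree (`NULL` = unrooted).
#' @param n_boot Bootstrap replicate count (0 skips supports).
#' @param locus Optional locus string checked against the candidate
#'   regions (e.g. a known seed-colour gene interval).
#' @param seed Seed for the bootstrap (and the simulator when `sim`
#'   carries no seed).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(sim = NULL, vcf = NULL, fasta = NULL, gff = NULL,
                       assignments = NULL, filter = filter_params(),
                       ld = ld_params(), window = 100000L,
                       step = 50000L, contrasts = NULL, outgroup = NULL,
                       n_boot = 0L, locus = NULL, seed = 1L) {
  if (is.null(sim) && is.null(vcf))
    stop("either a simulation config or a VCF path is required")
  structure(list(sim = sim, vcf = vcf, fasta = fasta, gff = gff,
                 assignments = assignments, filter = filter, ld = ld,
                 window = as.integer(window), step = as.integer(step),
                 contrasts = contrasts, outgroup = outgroup,
                 n_boot = as.integer(n_boot), locus = locus,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline and write a manifest
#'
#' Stages run in dependency order: simulate (or load) -> filter (with
#' the variant-count funnel logged after every rule) -> windowed
#' diversity and per-sample inbreeding -> NJ tree with bootstrap ->
#' per-contrast F_ST outlier scan with cross-check and gene
#' intersection -> SSR mining of the reference. Every output file is
#' listed in `manifest.json` with its md5 hash; identical configs and
#' seeds reproduce every output byte for byte. A missing contrast list
#' skips the scan stage (logged), a missing FASTA skips SSR mining.
#'
#' @param config A [run_config()] object.
#' @param out_dir Output directory.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the main in-memory results
#'   (`genotypes`, `filter`, `funnel`, `window_pi`, `sample_f`, `tree`,
#'   `scans`, `candidates`, `ssrs`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  log_lines <- character(0)
  log_add <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    say(line)
  }
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)

  # --- inputs -------------------------------------------------------
  chrom_lengths <- NULL
  fasta <- NULL
  genes <- NULL
  if (!is.null(config$sim)) {
    log_add("stage simulate: seed %d, %d sites", config$sim$seed,
            config$sim$n_sites)
    simdir <- file.path(out_dir, "simulated")
    sim <- generate_dataset(config$sim, simdir,
                            write_fasta = TRUE)
    for (p in sim$paths) emit(p)
    g <- sim$genotypes
    assignments <- sim$assignments
    contrasts <- if (is.null(config$contrasts)) sim$contrasts
    else config$contrasts
    chrom_lengths <- config$sim$chrom_lengths
    fasta <- sim$fasta
    genes <- sim$genes
  } else {
    log_add("stage load: %s", config$vcf)
    g <- read_vcf(config$vcf)
    assignments <- if (!is.null(config$assignments))
      read_assignments(config$assignments)
    contrasts <- config$contrasts
    if (!is.null(config$fasta)) fasta <- read_fasta(config$fasta)
    if (!is.null(config$gff)) genes <- read_gff(config$gff)
  }
  log_add("input: %d variants (%d SNPs, %d indels), %d samples",
          n_sites(g), sum(!g$variants$is_indel),
          sum(g$variants$is_indel), n_samples(g))

  # --- filter funnel ------------------------------------------------
  fl <- filter_sites(g, config$filter)
  for (rule in names(fl$removed))
    log_add("filter %-12s removed %d sites", rule, fl$removed[rule])
  log_add("filter retained %d SNPs (%d low-depth calls masked)",
          n_sites(fl$genotypes), fl$n_masked_calls)
  # windowed statistics and the outlier scan use the full QC-passed
  # SNP set; the LD-pruned subset feeds the phylogeny (pruning exists
  # to de-correlate sites for tree/cluster inference, and would
  # otherwise thin exactly the high-LD divergent windows the scan is
  # meant to find)
  gf <- fl$genotypes
  gt_tree <- gf
  n_ld <- 0L
  if (!is.null(config$ld)) {
    keep <- ld_prune(gf, config$ld)
    n_ld <- sum(!keep)
    log_add("LD pruning (%d/%d/%.2f) removed %d SNPs, retained %d for the tree",
            config$ld$window_size, config$ld$step,
            config$ld$r2_threshold, n_ld, sum(keep))
    gt_tree <- subset_genotypes(gf, sites = keep)
  }
  filter_report <- data.frame(
    rule = c(names(fl$removed), "retained", "ld_prune",
             "retained_for_tree"),
    n = c(unname(fl$removed), n_sites(gf), n_ld, n_sites(gt_tree)))
  p <- file.path(out_dir, "filter_report.tsv")
  utils::write.table(filter_report, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  emit(p)
  p <- file.path(out_dir, "filtered.vcf")
  write_vcf(gf, p, chrom_lengths = chrom_lengths)
  emit(p)

  # --- diversity stats ----------------------------------------------
  log_add("stage stats: %d kb windows, %d kb step",
          config$window %/% 1000L, config$step %/% 1000L)
  wp <- windowed_pi(gf, config$window, config$step, chrom_lengths)
  p <- file.path(out_dir, "windowed_pi.tsv")
  utils::write.table(
    wp[, c("chrom", "start", "end", "n_snps", "pi")], p,
    sep = "\t", quote = FALSE, row.names = FALSE)
  emit(p)
  sf <- individual_f(gf)
  p <- file.path(out_dir, "sample_f.tsv")
  utils::write.table(sf, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  emit(p)
  csum <- NULL
  if (!is.null(assignments)) {
    csum <- cluster_summary(gf, assignments, config$window,
                            config$step, chrom_lengths)
    p <- file.path(out_dir, "cluster_summary.tsv")
    utils::write.table(csum, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit(p)
  }

  # --- phylogeny (LD-pruned SNP set) --------------------------------
  tree <- NULL
  if (n_samples(gt_tree) >= 4L) {
    log_add("stage tree: %d taxa, %d SNPs, %d bootstrap replicates",
            n_samples(gt_tree), n_sites(gt_tree), config$n_boot)
    pd <- p_distance(gt_tree)
    p <- file.path(out_dir, "distances.phylip")
    write_phylip_dist(pd$d, p)
    emit(p)
    tree <- if (config$n_boot > 0L)
      bootstrap_support(gt_tree, n_reps = config$n_boot,
                        seed = config$seed)
    else neighbor_joining(pd$d)
    if (!is.null(config$outgroup) &&
        config$outgroup %in% tree$tip.label)
      tree <- root_with_outgroup(tree, config$outgroup)
    p <- file.path(out_dir, "tree.nwk")
    write_newick(tree, p)
    emit(p)
  }

  # --- outlier scan -------------------------------------------------
  scans <- NULL
  candidates <- NULL
  gene_hits <- NULL
  locus_overlap <- NULL
  if (is.null(contrasts) || length(contrasts) == 0L) {
    log_add("stage scan: skipped (no contrasts configured)")
  } else {
    log_add("stage scan: %d contrast(s)", length(contrasts))
    scans <- lapply(contrasts, function(ct)
      fst_scan(gf, ct, config$window, config$step, chrom_lengths))
    for (nm in names(scans)) {
      sc <- scans[[nm]]
      p <- file.path(out_dir, paste0("fst_windows_", nm, ".tsv"))
      utils::write.table(
        sc$windows[, c("chrom", "start", "end", "n_snps", "fst")], p,
        sep = "\t", quote = FALSE, row.names = FALSE)
      emit(p)
      if (nrow(sc$regions)) {
        p <- file.path(out_dir, paste0("regions_", nm, ".bed"))
        rg <- sc$regions[, c("chrom", "start", "end")]
        rg$label <- sprintf("%s_max_fst=%.4f", nm, sc$regions$max_fst)
        write_bed(rg, p)
        emit(p)
      }
      log_add("contrast %s: top1%% threshold %.4f (%d windows), %d regions",
              nm, sc$thresholds$top1$threshold,
              length(sc$thresholds$top1$members), nrow(sc$regions))
    }
    if (length(scans) >= 2L) {
      a <- scans[[1]]; b <- scans[[2]]
      candidates <- cross_compare(
        a$regions, b$regions, a$windows,
        a$thresholds$top1$members, a$thresholds$top5$members,
        b$thresholds$top1$members, b$thresholds$top5$members)
      p <- file.path(out_dir, "candidates.bed")
      cd <- candidates[, c("chrom", "start", "end")]
      cd$label <- ifelse(is.na(candidates$tier), "untiered",
                         paste0("tier", candidates$tier))
      write_bed(cd, p)
      emit(p)
      log_add("cross-check: %d tier-1, %d tier-2, %d tier-3, %d untiered",
              sum(candidates$tier == 1L, na.rm = TRUE),
              sum(candidates$tier == 2L, na.rm = TRUE),
              sum(candidates$tier == 3L, na.rm = TRUE),
              sum(is.na(candidates$tier)))
      if (!is.null(genes) && nrow(candidates)) {
        gene_hits <- intersect_genes(candidates, genes)
        p <- file.path(out_dir, "candidate_genes.tsv")
        utils::write.table(gene_hits, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        emit(p)
      }
      if (!is.null(config$locus)) {
        locus_overlap <- check_locus_overlap(candidates, config$locus)
        log_add("locus %s overlap: %s", config$locus,
                locus_overlap$overlaps)
      }
    }
  }

  # --- SSR mining ---------------------------------------------------
  ssrs <- NULL
  if (!is.null(fasta)) {
    log_add("stage ssr: %d sequence(s)", length(fasta))
    ssrs <- do.call(rbind, lapply(names(fasta), function(ch)
      find_ssrs(fasta[[ch]], chrom = ch)))
    p <- file.path(out_dir, "ssrs.tsv")
    utils::write.table(ssrs, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    emit(p)
  }

  # --- manifest -----------------------------------------------------
  p <- file.path(out_dir, "pipeline.log")
  writeLines(log_lines, p)
  emit(p)
  manifest <- data.frame(
    file = vapply(outputs, function(o)
      sub(paste0(out_dir, "/"), "", o, fixed = TRUE), "",
      USE.NAMES = FALSE),
    md5 = unname(tools::md5sum(outputs)),
    bytes = unname(file.size(outputs)),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       pretty = TRUE, digits = NA)

  invisible(list(genotypes = gf, genotypes_tree = gt_tree,
                 filter = fl, funnel = filter_report,
                 window_pi = wp, sample_f = sf,
                 cluster_summary = csum, tree = tree, scans = scans,
                 candidates = candidates, gene_hits = gene_hits,
                 locus_overlap = locus_overlap, ssrs = ssrs,
                 manifest = manifest))
}
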