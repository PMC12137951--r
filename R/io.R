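#' Read a multi-sample VCF into a genotypes object
#'
#' Wraps `vcfR::read.vcfR()` and converts the GT (and, when present, DP)
#' FORMAT fields into the package's [genotypes()] container. Records are
#' kept in file order, multi-allelic records are read intact (downstream
#' filtering decides their fate), phased and unphased genotypes are
#' treated identically, and missing calls (`./.` or `.`) are preserved
#' as `NA`.
#'
#' @param path Path to a VCF v4.x file (plain text or gzipped).
#' @return A [genotypes()] object.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such VCF file: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcf@fix
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt_raw)
  # strip phasing; parse the two allele indices
  n <- nrow(fix)
  a1 <- matrix(NA_integer_, n, length(samples))
  a2 <- matrix(NA_integer_, n, length(samples))
  parts <- strsplit(gsub("|", "/", gt_raw, fixed = TRUE), "/", fixed = TRUE)
  len <- lengths(parts)
  g1 <- vapply(parts, `[`, character(1), 1L)
  g2 <- vapply(parts, function(p) if (length(p) == 2L) p[2] else
    NA_character_, character(1))
  if (any(len > 2L)) {
    bad <- which(matrix(len, n, length(samples)) > 2L, arr.ind = TRUE)[1, ]
    stop(sprintf("non-diploid genotype at record %d, sample '%s'",
                 bad[1], samples[bad[2]]))
  }
  if (any(len == 1L & !(g1 == "." | is.na(g1))))
    stop("haploid (single-allele) genotype found; only diploid GT supported")
  a1[] <- suppressWarnings(as.integer(ifelse(g1 == "." | is.na(g1), NA, g1)))
  a2[] <- suppressWarnings(as.integer(ifelse(g2 == "." | is.na(g2), NA, g2)))
  # a call half-called like "0/." is demoted to fully missing
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA_integer_
  a2[half] <- NA_integer_
  dp <- NULL
  fmt <- vcf@gt[, 1L]
  if (any(grepl("DP", fmt, fixed = TRUE))) {
    dp <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE))
    storage.mode(dp) <- "integer"
  }
  genotypes(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = ifelse(is.na(fix[, "ALT"]), ".", fix[, "ALT"]),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    a1 = a1, a2 = a2, dp = dp, samples = samples
  )
}

#' Write a genotypes object as an uncompressed VCF v4.2 file
#'
#' Output is byte-stable given identical input: fields are formatted
#' deterministically, QUAL with up to 10 significant digits, genotypes
#' unphased (`a/b`), missing calls as `./.`. A `GT:DP` FORMAT column is
#' emitted when depths are present.
#'
#' @param g A [genotypes()] object.
#' @param path Output path.
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   `##contig` header lines.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(g, path, chrom_lengths = NULL) {
  v <- g$variants
  hdr <- c("##fileformat=VCFv4.2",
           "##source=popgenscan")
  if (!is.null(chrom_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths), as.integer(chrom_lengths)))
  hdr <- c(hdr,
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  has_dp <- !is.null(g$dp)
  if (has_dp)
    hdr <- c(hdr, paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,",
                         "Description=\"Read depth\">"))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", g$samples),
                      collapse = "\t"))
  gt <- matrix(paste0(ifelse(is.na(g$a1), ".", g$a1), "/",
                      ifelse(is.na(g$a2), ".", g$a2)),
               nrow = nrow(g$a1))
  if (has_dp)
    gt <- matrix(paste0(gt, ":", ifelse(is.na(g$dp), ".", g$dp)),
                 nrow = nrow(gt))
  qual <- ifelse(is.na(v$qual), ".", sprintf("%.10g", v$qual))
  body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, qual, ".", ".",
                if (has_dp) "GT:DP" else "GT",
                sep = "\t")
  if (nrow(gt) > 0L)
    body <- paste(body, apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a FASTA file as named character sequences
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per sequence.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  # drop description after first whitespace, as samtools does
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write named sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read gene-level features from a GFF3 file
#'
#' Only features of type `gene` are returned. The gene id is taken from
#' the `ID` attribute, falling back to `Name`; a free-text description is
#' taken from `Note`, `description` or `product` when present.
#'
#' @param path Path to a GFF3 file.
#' @return Data frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `strand`, `gene_id`, `description`.
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[!is.na(gr$type) & gr$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  pick <- function(keys) {
    for (k in keys)
      if (k %in% colnames(mc)) {
        val <- mc[[k]]
        if (is(val, "List") || is.list(val))
          val <- vapply(val, function(z)
            if (length(z)) paste(z, collapse = ";") else NA_character_,
            character(1))
        return(as.character(val))
      }
    rep(NA_character_, length(gr))
  }
  gene_id <- pick("ID")
  nm <- pick("Name")
  gene_id <- ifelse(is.na(gene_id) | gene_id == "", nm, gene_id)
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = gene_id,
    description = pick(c("Note", "description", "product")),
    stringsAsFactors = FALSE
  )
}

# minimal deterministic GFF3 writer used by the simulator
write_gff <- function(genes, path) {
  attrs <- sprintf("ID=%s", genes$gene_id)
  has_desc <- !is.na(genes$description) & genes$description != ""
  attrs[has_desc] <- paste0(attrs[has_desc], ";Note=",
                            genes$description[has_desc])
  lines <- paste(genes$chrom, "popgenscan", "gene", genes$start, genes$end,
                 ".", genes$strand, ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Write genomic intervals as BED
#'
#' Internal coordinates are 1-based inclusive; BED is the only 0-based
#' half-open boundary of the package, so `chr1:1-100` becomes
#' `chr1<TAB>0<TAB>100`.
#'
#' @param regions Data frame with `chrom`, `start`, `end` and optionally
#'   a `label` column (written as the 4th BED column).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(regions, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (any(regions$start > regions$end))
    stop("interval with start > end")
  lines <- paste(regions$chrom,
                 as.integer(regions$start) - 1L,
                 as.integer(regions$end),
                 sep = "\t")
  if ("label" %in% names(regions))
    lines <- paste(lines, regions$label, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a phylogenetic tree in Newick format
#'
#' Thin wrappers over `ape::write.tree()` / `ape::read.tree()`; branch
#' lengths and integer bootstrap supports stored as internal node labels
#' are preserved.
#'
#' @param tree An `ape::phylo` object.
#' @param path File path.
#' @return `write_newick()`: invisibly, `path`; `read_newick()`: a
#'   `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

# PHYLIP square distance-matrix writer (interoperability output)
write_phylip_dist <- function(d, path) {
  labs <- rownames(d)
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i)
               paste(formatC(labs[i], width = -10),
                     paste(sprintf("%.6f", d[i, ]), collapse = "  ")),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample assignment table
#'
#' A two-or-more-column TSV with a header; the first column is the sample
#' id, the second the population/cluster label. Extra columns (e.g. seed
#' colour) are kept.
#'
#' @param path Path to the TSV.
#' @return Data frame with at least `sample` and `cluster` columns.
#' @export
read_assignments <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(df)[1:2] <- c("sample", "cluster")
  df
}

#' Parse a locus string like "chr7:18230603-18249975"
#' @param locus Character scalar, `chrom:start-end` (1-based inclusive;
#'   commas allowed in numbers).
#' @return One-row data frame with `chrom`, `start`, `end`.
#' @export
parse_locus <- function(locus) {
  m <- regmatches(locus,
                  regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", locus))[[1]]
  if (length(m) != 4L) stop("cannot parse locus string: ", locus)
  start <- as.numeric(gsub(",", "", m[3], fixed = TRUE))
  end <- as.numeric(gsub(",", "", m[4], fixed = TRUE))
  if (start > end) stop("locus start exceeds end: ", locus)
  data.frame(chrom = m[2], start = start, end = end,
             stringsAsFactors = FALSE)
}
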