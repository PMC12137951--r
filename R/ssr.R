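#' Minimum repeat counts per SSR motif length
#'
#' Defaults are the classic MISA-style thresholds: mono-, di-, tri-,
#' tetra-, penta- and hexanucleotide repeats of at least 10, 8, 6, 4,
#' 4 and 4 units.
#'
#' @param thresholds Named or unnamed integer vector of length 6, the
#'   minimum repeat count for motif lengths 1..6.
#' @return Integer vector of length 6.
#' @export
ssr_thresholds <- function(thresholds = c(10L, 8L, 6L, 4L, 4L, 4L)) {
  stopifnot(length(thresholds) == 6L, all(thresholds >= 2L))
  as.integer(thresholds)
}

# is the motif primitive, i.e. not itself a repetition of a shorter unit
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (p in seq_len(k - 1L)) {
    if (k %% p != 0L) next
    if (strrep(substr(motif, 1L, p), k %/% p) == motif) return(FALSE)
  }
  TRUE
}

#' Find perfect microsatellites in a sequence
#'
#' Maximal perfect tandem repeats of primitive 1-6 bp motifs meeting
#' the per-unit-length thresholds. A run reportable at several unit
#' sizes (an `A` run seen as `AA` dimers, say) is reported once, at its
#' primitive period; `N` bases never take part in a repeat; matching is
#' case-insensitive so soft-masked sequence is eligible. Each reported
#' interval equals its motif repeated `n_repeats` times.
#'
#' @param sequence Character scalar over A/C/G/T/N (case-insensitive).
#' @param thresholds From [ssr_thresholds()].
#' @param chrom Chromosome/sequence label for the report.
#' @return Data frame: `chrom`, `start`, `end` (1-based inclusive),
#'   `motif`, `motif_length`, `n_repeats`, `canonical_motif`, sorted by
#'   `start` then `motif_length`.
#' @export
find_ssrs <- function(sequence, thresholds = ssr_thresholds(),
                      chrom = "seq") {
  s <- toupper(sequence)
  L <- nchar(s)
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), motif = character(0),
                      motif_length = integer(0), n_repeats = integer(0),
                      canonical_motif = character(0))
  if (L == 0L) return(empty)
  x <- strsplit(s, "", fixed = TRUE)[[1]]
  rows <- list()
  for (k in 1:6) {
    if (L < k * (thresholds[k])) next
    m <- x[seq_len(L - k)] == x[(k + 1L):L] &
      x[seq_len(L - k)] != "N"
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= k * (thresholds[k] - 1L))
    for (ri in runs) {
      a <- starts[ri]                   # first matching position
      reg_len <- r$lengths[ri] + k      # chars covered by the run
      n <- reg_len %/% k
      if (n < thresholds[k]) next
      motif <- substr(s, a, a + k - 1L)
      if (!is_primitive_motif(motif)) next
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = a, end = a + n * k - 1L,
        motif = motif, motif_length = k, n_repeats = n,
        canonical_motif = canonicalise_motif(motif),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$motif_length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Canonical class label of an SSR motif
#'
#' The lexicographically smallest string among all cyclic rotations of
#' the motif and of its reverse complement, so that e.g. `GA`, `AG`,
#' `TC` and `CT` all report as `AG`.
#'
#' @param motif Motif string over A/C/G/T.
#' @return Canonical label.
#' @export
canonicalise_motif <- function(motif) {
  motif <- toupper(motif)
  k <- nchar(motif)
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(motif, "")[[1]]),
                                     collapse = ""))
  rots <- function(m) vapply(seq_len(k), function(i)
    paste0(substr(m, i, k), substr(m, 1L, i - 1L)), "")
  min(c(rots(motif), rots(rc)))
}

#' Motif-class fractions of an SSR census
#'
#' @param records Data frame from [find_ssrs()].
#' @return List with `by_length` (fraction per motif length 1..6) and
#'   `by_motif` (fraction per canonical motif); empty input gives empty
#'   summaries.
#' @export
summarise_ssrs <- function(records) {
  if (!nrow(records))
    return(list(by_length = data.frame(motif_length = integer(0),
                                       n = integer(0),
                                       fraction = numeric(0)),
                by_motif = data.frame(canonical_motif = character(0),
                                      n = integer(0),
                                      fraction = numeric(0))))
  tl <- as.data.frame(table(records$motif_length),
                      stringsAsFactors = FALSE)
  names(tl) <- c("motif_length", "n")
  tl$motif_length <- as.integer(tl$motif_length)
  tl$fraction <- tl$n / sum(tl$n)
  tm <- as.data.frame(table(records$canonical_motif),
                      stringsAsFactors = FALSE)
  names(tm) <- c("canonical_motif", "n")
  tm$fraction <- tm$n / sum(tm$n)
  list(by_length = tl, by_motif = tm)
}
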