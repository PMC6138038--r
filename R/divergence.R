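## Pairwise divergence: substitution counts, uncorrected p-distance
## (global, per-locus, sliding-window) and banded whole-genome alignment.

#' Count substitutions between two equal-length sequences
#'
#' Positions where the two sequences carry different bases are counted;
#' positions with `N` (or a gap) in either sequence are ignored.
#'
#' @param s1,s2 equal-length nucleotide strings (pre-aligned, or
#'   near-identical equal-length genomes).
#' @return integer substitution count.
#' @export
countSubstitutions <- function(s1, s2) {
  if (nchar(s1) != nchar(s2))
    stop("sequences differ in length; align them first (see alignGenomes)")
  v1 <- strsplit(toupper(s1), "")[[1]]
  v2 <- strsplit(toupper(s2), "")[[1]]
  ok <- v1 %in% c("A", "C", "G", "T") & v2 %in% c("A", "C", "G", "T")
  sum(ok & v1 != v2)
}

#' Uncorrected p-distance between two aligned rows
#'
#' Mismatches divided by compared sites under pairwise deletion: any
#' column with `-` or `N` in either row is excluded.
#'
#' @param s1,s2 equal-length gapped rows.
#' @return p-distance in `[0, 1]`.
#' @examples
#' pDistance("ACGT", "ACGA")  # 0.25
#' @export
pDistance <- function(s1, s2) {
  if (nchar(s1) != nchar(s2)) stop("aligned rows must have equal length")
  v1 <- strsplit(toupper(s1), "")[[1]]
  v2 <- strsplit(toupper(s2), "")[[1]]
  ok <- v1 %in% c("A", "C", "G", "T") & v2 %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable sites (all gapped or ambiguous)")
  sum(v1[ok] != v2[ok]) / sum(ok)
}

#' Sliding-window p-distance along an alignment
#'
#' The window slides over alignment columns in steps of `step`; each
#' window reports its p-distance under pairwise deletion and the number of
#' compared sites. Windows with no comparable site are flagged `NA`. Only
#' windows fully inside the alignment are emitted.
#'
#' @param s1,s2 equal-length gapped rows.
#' @param window,step window width and step in alignment columns.
#' @return a [DivergenceProfile-class].
#' @export
slidingPDistance <- function(s1, s2, window = 300L, step = 25L) {
  if (nchar(s1) != nchar(s2)) stop("aligned rows must have equal length")
  Lc <- nchar(s1)
  if (window <= 0L || step <= 0L) stop("window and step must be positive")
  if (window > Lc) stop("window exceeds alignment length")
  v1 <- strsplit(toupper(s1), "")[[1]]
  v2 <- strsplit(toupper(s2), "")[[1]]
  ok <- v1 %in% c("A", "C", "G", "T") & v2 %in% c("A", "C", "G", "T")
  diff <- ok & v1 != v2
  cok <- c(0L, cumsum(ok)); cdiff <- c(0L, cumsum(diff))
  starts <- seq.int(0L, Lc - window, by = step)
  nok <- cok[starts + window + 1L] - cok[starts + 1L]
  nd <- cdiff[starts + window + 1L] - cdiff[starts + 1L]
  p <- ifelse(nok == 0L, NA_real_, nd / nok)
  new("DivergenceProfile", window = as.integer(window),
      step = as.integer(step),
      records = data.frame(column_start = as.integer(starts),
                           p_distance = p,
                           compared_sites = as.integer(nok)),
      globalP = sum(nd) / sum(nok))
}

#' Banded global alignment of two similar nucleotide sequences
#'
#' Affine-gap global alignment restricted to a diagonal band, intended for
#' near-identical whole mitogenomes where a full dynamic program is
#' unnecessary. Defaults: match +1, mismatch -1, gap open -8, gap extend
#' -1, band half-width 400 columns (automatically widened by the length
#' difference). Positions with `N` score 0 against anything.
#'
#' @param s1,s2 nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @param band band half-width around the main diagonal.
#' @return list with `aligned1`, `aligned2`, `score`.
#' @export
alignGenomes <- function(s1, s2, match = 1, mismatch = -1,
                         gap_open = -8, gap_extend = -1, band = 400L) {
  .banded_align_cpp(toupper(s1), toupper(s2), match, mismatch,
                    gap_open, gap_extend, as.integer(band))
}

#' Whole-genome p-distance of two annotated genomes
#'
#' Both circular genomes are rotated to start at the `anchor` gene
#' (removing arbitrary origin offsets), aligned with [alignGenomes()], and
#' the p-distance of the alignment is returned.
#'
#' @param genomeA,genomeB [AnnotatedGenome-class] objects.
#' @param anchor gene used to fix the rotation (default `cox1`); ignored
#'   when either genome lacks it or is linear.
#' @param ... passed to [alignGenomes()].
#' @return p-distance.
#' @export
genomePDistance <- function(genomeA, genomeB, anchor = "cox1", ...) {
  rot <- function(g) {
    hit <- .find_features(g, anchor)
    if (length(hit) && topology(g) == "circular")
      rotateGenome(g, hit[[1]]@segments[1, 1]) else g
  }
  a <- rot(genomeA); b <- rot(genomeB)
  al <- alignGenomes(genomeSeq(a), genomeSeq(b), ...)
  pDistance(al$aligned1, al$aligned2)
}

#' Per-locus p-distance between two annotated genomes
#'
#' Extracts the named locus from both genomes, globally aligns the two
#' sequences and returns the p-distance of the alignment.
#'
#' @param genomeA,genomeB [AnnotatedGenome-class] objects annotating
#'   `locus`.
#' @param locus normalized gene name (e.g. `"cox1"`).
#' @param ... passed to [alignGenomes()].
#' @return p-distance.
#' @export
locusPDistance <- function(genomeA, genomeB, locus, ...) {
  fa <- .find_features(genomeA, locus)
  fb <- .find_features(genomeB, locus)
  if (!length(fa))
    stop(sprintf("locus '%s' not annotated in genome %s", locus,
                 genomeId(genomeA)))
  if (!length(fb))
    stop(sprintf("locus '%s' not annotated in genome %s", locus,
                 genomeId(genomeB)))
  sa <- extractFeatureSeq(genomeA, fa[[1]])
  sb <- extractFeatureSeq(genomeB, fb[[1]])
  al <- alignGenomes(sa, sb, ...)
  pDistance(al$aligned1, al$aligned2)
}

#' Write a divergence profile as TSV
#'
#' @param profile a [DivergenceProfile-class].
#' @param file output path.
#' @param header optional `#` header lines.
#' @export
writeDivergenceTsv <- function(profile, file, header = character()) {
  r <- profile@records
  out <- data.frame(column_start = r$column_start + 1L,
                    p_distance = r$p_distance,
                    compared_sites = r$compared_sites)
  con <- file(file, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  writeLines(paste(names(out), collapse = "\t"), con)
  write.table(out, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}
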