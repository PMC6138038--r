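## Genome-wide and sliding-window base composition: AT skew and GC content.

.base_counts <- function(seq) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  c(A = sum(v == "A"), C = sum(v == "C"),
    G = sum(v == "G"), T = sum(v == "T"))
}

#' Genome-wide AT skew and GC content
#'
#' AT skew is `(A - T) / (A + T)` and GC content `(G + C)` over all
#' counted bases; `N` is excluded from every count. When the sequence has
#' no A or T the skew is undefined and returned as `NA`.
#'
#' @param seq nucleotide string, or an [AnnotatedGenome-class].
#' @return named numeric vector `c(at_skew=, gc_content=)`; `at_skew` is
#'   `NA` when undefined.
#' @examples
#' globalComposition("AATT")  # skew 0, GC 0
#' @export
globalComposition <- function(seq) {
  if (is(seq, "AnnotatedGenome")) seq <- genomeSeq(seq)
  n <- .base_counts(toupper(seq))
  if (sum(n) == 0) stop("no countable (non-N) bases in sequence")
  at <- n["A"] + n["T"]
  skew <- if (at == 0) NA_real_ else unname((n["A"] - n["T"]) / at)
  c(at_skew = skew, gc_content = unname((n["G"] + n["C"]) / sum(n)))
}

#' Sliding-window composition profile
#'
#' Computes AT skew and GC content in windows of `window` bp advanced by
#' `step` bp, anchored at position `offset` (default 0) of the deposited
#' sequence. On a circular genome windows wrap around the origin and every
#' start position `offset, offset+step, ...` below the genome length is
#' used (`ceiling(L/step)` windows); on a linear genome only windows fully
#' inside the sequence are emitted.
#'
#' @param genome an [AnnotatedGenome-class] or a nucleotide string
#'   (treated as circular unless `topology = "linear"`).
#' @param window,step window width and step in bp.
#' @param offset 0-based anchor of the first window.
#' @param topology used only when `genome` is a bare string.
#' @return a [CompositionProfile-class].
#' @export
windowedComposition <- function(genome, window = 300L, step = 25L,
                                offset = 0L, topology = "circular") {
  if (window <= 0L || step <= 0L) stop("window and step must be positive")
  if (is.character(genome)) genome <- annotatedGenome("seq", genome, topology)
  seq <- genomeSeq(genome)
  L <- nchar(seq)
  circ <- topology(genome) == "circular"
  if (!circ && window > L)
    stop("window exceeds sequence length on a linear genome")
  glob <- globalComposition(seq)

  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (circ && window > 1L) v <- c(v, v[seq_len(min(window - 1L, L))])
  # wrap more than once if window > L
  while (circ && length(v) < L + window - 1L)
    v <- c(v, v[seq_len(min(L, L + window - 1L - length(v)))])
  cums <- function(base) c(0L, cumsum(v == base))
  cA <- cums("A"); cT <- cums("T"); cG <- cums("G"); cC <- cums("C")

  starts <- if (circ) seq.int(offset %% L, L - 1L, by = step)
            else seq.int(offset, L - window, by = step)
  wc <- function(cs, s) cs[s + window + 1L] - cs[s + 1L]
  nA <- wc(cA, starts); nT <- wc(cT, starts)
  nG <- wc(cG, starts); nC <- wc(cC, starts)
  at <- nA + nT
  tot <- at + nG + nC
  skew <- ifelse(at == 0, NA_real_, (nA - nT) / at)
  gc <- ifelse(tot == 0, NA_real_, (nG + nC) / tot)
  new("CompositionProfile",
      window = as.integer(window), step = as.integer(step),
      records = data.frame(window_start = as.integer(starts),
                           at_skew = skew, gc_content = gc),
      globalAtSkew = glob[["at_skew"]], globalGc = glob[["gc_content"]])
}

#' Write a composition profile as TSV
#'
#' Window starts are exported 1-based; a `#`-prefixed provenance header can
#' be prepended by the CLI.
#'
#' @param profile a [CompositionProfile-class].
#' @param file output path.
#' @param header optional character vector of `#` header lines.
#' @export
writeCompositionTsv <- function(profile, file, header = character()) {
  r <- profile@records
  out <- data.frame(window_start = r$window_start + 1L,
                    at_skew = r$at_skew, gc_content = r$gc_content)
  con <- file(file, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  writeLines(paste(names(out), collapse = "\t"), con)
  write.table(out, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}
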