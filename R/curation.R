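## Alignment curation: dual-space (nucleotide vs amino-acid) consistency
## screening, PSSM profile construction, frameshift-aware recovery
## alignment of raw CDS nucleotides against a profile, and gap-column
## stripping.
##
## Database mitogenome CDSs sometimes contain single-nucleotide
## frameshifts (sequencing or annotation errors). Translating such a CDS
## garbles everything downstream of the error, so a protein row derived
## from the intended (conserved) protein disagrees with the re-translation
## of the deposited nucleotides over many columns. The screen below counts
## exactly those disagreements.

#' Translate a CDS and drop the terminal stop
#'
#' Convenience for profile building: translates with [translateMito()] and
#' removes a trailing `*` if present.
#'
#' @inheritParams translateMito
#' @return amino-acid string without terminal stop.
#' @export
cdsToProtein <- function(nt, code = "5") {
  aa <- suppressWarnings(translateMito(nt, code))
  sub("\\*$", "", as.character(aa))
}

#' Screen taxa for nucleotide/amino-acid alignment inconsistency
#'
#' For each taxon the gapped amino-acid row is back-mapped onto the raw
#' CDS nucleotides (each non-gap residue consumes one codon), the codons
#' are re-translated, and disagreements with the given row are counted. A
#' taxon is deemed `suspicious` when the nucleotide length cannot be
#' reconciled with the ungapped amino-acid length (difference outside
#' 0-3 nt, allowing for a complete or incomplete terminal stop) or when
#' the disagreement count reaches `threshold`.
#'
#' @param nt_rows named character vector of raw (ungapped) CDS nucleotide
#'   sequences, one per taxon.
#' @param aa_alignment named character vector of equal-length gapped
#'   amino-acid rows over the same taxa.
#' @param threshold minimum number of disagreeing columns for suspicion
#'   (default 5, so isolated ambiguous residues do not discard a taxon).
#' @param code NCBI genetic code id.
#' @return data.frame (one row per taxon) with columns `taxon`,
#'   `nt_length`, `aa_length`, `evidence` (disagreeing columns),
#'   `length_ok` and `verdict` (`"clean"`/`"suspicious"`); the threshold is
#'   attached as attribute `threshold`.
#' @export
dualSpaceConsistency <- function(nt_rows, aa_alignment, threshold = 5L,
                                 code = "5") {
  if (!setequal(names(nt_rows), names(aa_alignment)))
    stop("taxon sets of nt_rows and aa_alignment differ")
  if (length(unique(nchar(aa_alignment))) != 1L)
    stop("aa_alignment rows must have equal length")
  gc <- Biostrings::getGeneticCode(code)
  rows <- lapply(names(aa_alignment), function(tx) {
    aarow <- strsplit(toupper(aa_alignment[[tx]]), "")[[1]]
    nt <- toupper(nt_rows[[tx]])
    aa_len <- sum(aarow != "-")
    d <- nchar(nt) - 3L * aa_len
    length_ok <- d %in% 0:3
    # re-translate codon-by-codon along the row
    ev <- 0L
    pos <- 0L
    for (a in aarow) {
      if (a == "-") next
      if (pos + 3L <= nchar(nt)) {
        imp <- gc[substr(nt, pos + 1L, pos + 3L)]
        if (is.na(imp)) imp <- "X"
      } else imp <- "X"
      pos <- pos + 3L
      if (imp != "X" && a != "X" && imp != a) ev <- ev + 1L
    }
    data.frame(taxon = tx, nt_length = nchar(nt), aa_length = aa_len,
               evidence = ev, length_ok = length_ok,
               verdict = if (!length_ok || ev >= threshold) "suspicious"
                         else "clean",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  out
}

#' Remove suspicious taxa from a gene alignment
#'
#' Runs [dualSpaceConsistency()] and drops flagged taxa from both spaces.
#'
#' @inheritParams dualSpaceConsistency
#' @return list with `aa_alignment`, `nt_rows` (clean taxa only) and the
#'   full `report`.
#' @export
curateGeneAlignment <- function(nt_rows, aa_alignment, threshold = 5L,
                                code = "5") {
  rep <- dualSpaceConsistency(nt_rows, aa_alignment, threshold, code)
  keep <- rep$taxon[rep$verdict == "clean"]
  list(aa_alignment = aa_alignment[keep], nt_rows = nt_rows[keep],
       report = rep)
}

#' Build a position-specific scoring profile from a curated alignment
#'
#' Columns with a gap fraction of at least 50% are treated as insert
#' regions and dropped from the profile. Remaining columns get log-odds
#' scores `log2(((count + pseudocount * bg) / (n + pseudocount)) / bg)`
#' where `n` is the number of residues observed in the column, and a
#' consensus residue (count argmax, alphabetical tie-break).
#'
#' @param aa_alignment named character vector of equal-length gapped
#'   amino-acid rows.
#' @param background length-20 residue background frequencies in the
#'   order `ACDEFGHIKLMNPQRSTVWY` (default uniform `1/20`).
#' @param pseudocount pseudocount mass (default 1).
#' @param gap_open,gap_extend gap penalties stored with the profile and
#'   used by [frameshiftAwareAlign()].
#' @param source free-form label (e.g. `"cox1/M"`).
#' @return a [ProteinProfile-class]; the logical keep-mask over input
#'   columns is attached as attribute `column_mask`.
#' @export
buildProfile <- function(aa_alignment, background = rep(1 / 20, 20),
                         pseudocount = 1, gap_open = -11, gap_extend = -1,
                         source = "") {
  if (!length(aa_alignment)) stop("empty alignment")
  if (length(unique(nchar(aa_alignment))) != 1L)
    stop("alignment rows must have equal length")
  if (length(background) != 20L || abs(sum(background) - 1) > 1e-8)
    stop("background must be 20 frequencies summing to 1")
  mat <- do.call(rbind, strsplit(toupper(aa_alignment), ""))
  gapfrac <- colMeans(mat == "-")
  keep <- gapfrac < 0.5
  if (!any(keep)) stop("no columns left after dropping gap-majority columns")
  mat <- mat[, keep, drop = FALSE]
  C <- ncol(mat)
  counts <- vapply(seq_len(C), function(j) {
    tabulate(match(mat[, j], AA_LETTERS), nbins = 20L)
  }, integer(20))
  n <- colSums(counts)
  bg <- matrix(background, nrow = 20, ncol = C)
  scores <- log2(((counts + pseudocount * bg) /
                    rep(n + pseudocount, each = 20)) / bg)
  rownames(scores) <- AA_LETTERS
  cons <- paste(AA_LETTERS[apply(counts, 2, which.max)], collapse = "")
  prof <- new("ProteinProfile", scores = scores, consensus = cons,
              gapOpen = gap_open, gapExtend = gap_extend, source = source)
  attr(prof, "column_mask") <- keep
  prof
}

# codon -> AA_LETTERS row index map for the C++ kernel: -1 marks stop
.codon_aa_index <- function(code = "5") {
  gc <- Biostrings::getGeneticCode(code)
  bases <- c("A", "C", "G", "T")
  idx <- integer(64)
  k <- 1L
  for (a in bases) for (b in bases) for (c in bases) {
    aa <- gc[[paste0(a, b, c)]]
    idx[k] <- if (aa == "*") -1L else match(aa, AA_LETTERS) - 1L
    k <- k + 1L
  }
  idx
}

#' Frameshift-aware alignment of raw DNA against a protein profile
#'
#' Global dynamic program over (DNA position, profile column) recovering a
#' protein alignment row directly from raw nucleotides. Moves: a match
#' consumes 3 nt against one column (scored by the column log-odds of the
#' translated codon, invertebrate mitochondrial code by default); a
#' column deletion and a 3-nt DNA insertion take affine gap penalties; and
#' frameshift moves consume 4 nt (`+1` event, first three translated) or
#' 2 nt (`-1` event, residue `X`) against one column at `fs_penalty` each.
#' Stop codons inside the alignment score `stop_score`; codons containing
#' `N` score 0. Co-optimal paths are resolved match > delete > insert >
#' frameshift. With `fs_penalty = -Inf` the program reduces to plain
#' codon-level profile alignment.
#'
#' @param dna nucleotide string over `{A,C,G,T,N}`, length >= 3.
#' @param profile a [ProteinProfile-class].
#' @param fs_penalty penalty per frameshift event (default -12).
#' @param gap_open,gap_extend gap penalties; default to the profile's.
#' @param code NCBI genetic code id.
#' @param stop_score score of an internal stop codon (default -8).
#' @return a [RecoveredAlignment-class].
#' @export
frameshiftAwareAlign <- function(dna, profile, fs_penalty = -12,
                                 gap_open = profile@gapOpen,
                                 gap_extend = profile@gapExtend,
                                 code = "5", stop_score = -8) {
  dna <- toupper(dna)
  if (grepl("[^ACGTN]", dna))
    stop("dna contains characters outside {A,C,G,T,N}")
  if (nchar(dna) < 3L) stop("dna must be at least one codon long")
  v <- strsplit(dna, "")[[1]]
  idx <- match(v, c("A", "C", "G", "T")) - 1L
  idx[is.na(idx)] <- -1L  # N
  res <- .fs_align_cpp(as.integer(idx), profile@scores,
                       .codon_aa_index(code), paste(AA_LETTERS, collapse = ""),
                       fs_penalty, gap_open, gap_extend, stop_score)
  new("RecoveredAlignment", aaRow = res$aa_row, score = res$score,
      frameshifts = data.frame(dna_position = res$fs_dna_position,
                               kind = res$fs_kind),
      insertAfterColumn = res$insert_after_column)
}

#' Remove alignment columns containing gaps
#'
#' Every column with at least one `-` is removed, mirroring how gap
#' columns are excluded from phylogenetic reconstruction; the remaining
#' column count is the effective alignment length.
#'
#' @param aa_alignment named character vector of equal-length rows
#'   (nucleotide or amino acid).
#' @return list with `alignment` (stripped rows), `effective_length` and
#'   `mask` (logical keep-mask over input columns).
#' @export
stripGapColumns <- function(aa_alignment) {
  if (!length(aa_alignment)) stop("empty alignment")
  if (length(unique(nchar(aa_alignment))) != 1L)
    stop("alignment rows must have equal length")
  mat <- do.call(rbind, strsplit(aa_alignment, ""))
  keep <- colSums(mat == "-") == 0L
  if (!any(keep))
    warning("no gap-free columns remain; effective length 0")
  out <- if (any(keep))
    apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  else rep("", nrow(mat))
  names(out) <- names(aa_alignment)
  list(alignment = out, effective_length = sum(keep), mask = keep)
}
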