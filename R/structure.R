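## Structural comparison of annotated mitogenomes: canonical gene order,
## duplication / gain-loss detection, and tRNA classification by anticodon
## and nearest-reference identity.

# collapse duplicated-copy labels onto their base gene name
.base_gene_name <- function(n) {
  n <- sub("_(dup|copy)[0-9]*$", "", n)
  sub("^(m-ORF)[0-9]+$", "\\1", n)
}

#' Canonical signed gene order of a genome
#'
#' Feature names are listed in genome order, signed by strand, then put
#' in canonical form: the order is rotated so it starts at the anchor
#' gene, and if the anchor lies on the minus strand the whole order is
#' reverse-complemented (reversed with flipped signs) first. The result
#' is invariant under rotation of a circular genome and under full
#' reverse-complementation.
#'
#' @param genome an [AnnotatedGenome-class].
#' @param anchor anchor gene name (default `"cox1"`).
#' @return character vector of signed tokens, e.g. `"+cox1"`, `"-nad1"`.
#' @export
geneOrder <- function(genome, anchor = "cox1") {
  feats <- genome@features
  if (!length(feats)) stop("genome has no features")
  nm <- vapply(feats, function(f) f@name, "")
  st <- vapply(feats, function(f) f@strand, 0L)
  i <- which(nm == anchor)[1]
  if (is.na(i)) stop(sprintf("anchor gene '%s' not annotated", anchor))
  if (st[i] == -1L) {
    nm <- rev(nm); st <- -rev(st)
    i <- which(nm == anchor)[1]
  }
  if (i > 1L) {
    idx <- c(i:length(nm), 1:(i - 1L))
    nm <- nm[idx]; st <- st[idx]
  }
  paste0(ifelse(st == 1L, "+", "-"), nm)
}

#' Detect gained/lost features between two annotated genomes
#'
#' Feature names (with duplicated-copy suffixes collapsed onto their base
#' name) are compared as multisets: `gained` lists names with a higher
#' copy number in the query than in the reference, `lost` the converse.
#' `rearranged` reports whether the canonical gene orders still differ
#' after removing gained/lost names.
#'
#' @param query,reference [AnnotatedGenome-class] objects with normalized
#'   feature names.
#' @param anchor anchor gene for the gene-order comparison.
#' @return list with `gained` and `lost` (data.frames `name`,
#'   `copies_query`, `copies_reference`) and logical `rearranged` (`NA`
#'   when the anchor is missing from either genome).
#' @export
detectExtraFeatures <- function(query, reference, anchor = "cox1") {
  names_of <- function(g)
    .base_gene_name(vapply(g@features, function(f) f@name, ""))
  nq <- names_of(query); nr <- names_of(reference)
  all_names <- union(nq, nr)
  cq <- vapply(all_names, function(n) sum(nq == n), 0L)
  cr <- vapply(all_names, function(n) sum(nr == n), 0L)
  gained <- data.frame(name = all_names[cq > cr],
                       copies_query = cq[cq > cr],
                       copies_reference = cr[cq > cr],
                       row.names = NULL, stringsAsFactors = FALSE)
  lost <- data.frame(name = all_names[cq < cr],
                     copies_query = cq[cq < cr],
                     copies_reference = cr[cq < cr],
                     row.names = NULL, stringsAsFactors = FALSE)
  shared <- all_names[cq > 0 & cr > 0]
  rearranged <- tryCatch({
    strip <- function(ord) {
      base <- .base_gene_name(sub("^[+-]", "", ord))
      keep <- base %in% shared & !duplicated(base)
      ord[keep]
    }
    !identical(strip(geneOrder(query, anchor)),
               strip(geneOrder(reference, anchor)))
  }, error = function(e) NA)
  list(gained = gained, lost = lost, rearranged = rearranged)
}

# percent identity of a global alignment of two short sequences
.pct_identity <- function(s1, s2) {
  al <- alignGenomes(s1, s2, band = max(nchar(s1), nchar(s2)))
  v1 <- strsplit(al$aligned1, "")[[1]]
  v2 <- strsplit(al$aligned2, "")[[1]]
  100 * sum(v1 == v2 & v1 != "-") / length(v1)
}

#' Classify a tRNA by anticodon and nearest reference
#'
#' The amino-acid assignment follows the anticodon through the genetic
#' code (the anticodon read on the gene strand is reverse-complemented to
#' the codon it decodes; `TAT` decodes `ATA`, methionine under the
#' invertebrate mitochondrial code). The nearest reference is the
#' reference tRNA with the highest global-alignment percent identity;
#' the full ranking is returned and ties at the top are flagged. When the
#' anticodon is not annotated, a heuristic fallback reads the 3-mer at
#' the position aligned with the nearest reference's anticodon.
#'
#' @param trn_seq tRNA gene sequence (gene strand).
#' @param anticodon annotated 3-mer (DNA, gene strand) or `NA` to use
#'   the fallback.
#' @param reference_trns named character vector of reference tRNA
#'   sequences.
#' @param reference_anticodons optional named 3-mer vector for the
#'   references (needed by the fallback).
#' @param code NCBI genetic code id.
#' @return list with `amino_acid`, `anticodon`, `anticodon_source`
#'   (`"annotation"` or `"alignment-heuristic"`), `nearest`, `ranking`
#'   (data.frame `reference`, `identity`), `tie`.
#' @export
classifyTrn <- function(trn_seq, anticodon = NA_character_, reference_trns,
                        reference_anticodons = NULL, code = "5") {
  if (!length(reference_trns)) stop("reference set is empty")
  ids <- vapply(reference_trns, .pct_identity, 0, s1 = toupper(trn_seq))
  ranking <- data.frame(reference = names(reference_trns),
                        identity = unname(ids),
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$identity, ranking$reference), ]
  rownames(ranking) <- NULL
  tie <- nrow(ranking) > 1L &&
    isTRUE(all.equal(ranking$identity[1], ranking$identity[2]))
  src <- "annotation"
  if (is.na(anticodon)) {
    src <- "alignment-heuristic"
    cand <- ranking$reference[!is.na(reference_anticodons[ranking$reference])]
    if (!length(cand))
      stop("anticodon not annotated and no reference anticodon available")
    ref <- cand[1]
    refseq <- toupper(reference_trns[[ref]])
    refanti <- toupper(reference_anticodons[[ref]])
    # anticodon position in the reference: central-most occurrence
    occ <- gregexpr(refanti, refseq, fixed = TRUE)[[1]]
    if (occ[1] == -1) stop("reference anticodon not found in its sequence")
    pos <- occ[which.min(abs(occ - (nchar(refseq) / 2)))]
    al <- alignGenomes(toupper(trn_seq), refseq,
                       band = max(nchar(trn_seq), nchar(refseq)))
    v1 <- strsplit(al$aligned1, "")[[1]]
    v2 <- strsplit(al$aligned2, "")[[1]]
    ref_i <- cumsum(v2 != "-")
    cols <- which(ref_i %in% pos:(pos + 2L) & v2 != "-")
    anticodon <- paste(v1[cols], collapse = "")
    if (nchar(anticodon) != 3L || grepl("[^ACGT]", anticodon))
      stop("could not locate a clean anticodon 3-mer by alignment")
  }
  anticodon <- toupper(anticodon)
  codon <- revComp(anticodon)
  aa <- Biostrings::getGeneticCode(code)[[codon]]
  list(amino_acid = aa, anticodon = anticodon, anticodon_source = src,
       nearest = ranking$reference[1], ranking = ranking, tie = tie)
}
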