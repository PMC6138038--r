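#' Single annotated mitogenome feature
#'
#' A typed, stranded feature on an annotated genome. Coordinates are stored
#' internally as 0-based half-open `[start, end)` segments in transcription
#' order; a feature crossing the origin of a circular genome is represented
#' by two segments. GenBank input/output converts to and from the 1-based
#' inclusive convention.
#'
#' @slot kind one of `"CDS"`, `"rRNA"`, `"tRNA"`, `"other"`.
#' @slot name normalized gene label (e.g. `"cox1"`, `"m-ORF"`, `"trnM"`).
#' @slot strand integer, `+1L` or `-1L`.
#' @slot segments integer matrix with columns `start`, `end` (0-based
#'   half-open), one row per segment, in transcription order.
#' @slot anticodon 3-letter DNA anticodon for tRNA features, or `NA`.
#' @export
setClass("MitoFeature",
  representation(kind = "character", name = "character", strand = "integer",
                 segments = "matrix", anticodon = "character"),
  prototype(anticodon = NA_character_))

setValidity("MitoFeature", function(object) {
  msg <- character()
  if (!object@kind %in% c("CDS", "rRNA", "tRNA", "other"))
    msg <- c(msg, "kind must be CDS, rRNA, tRNA or other")
  if (!object@strand %in% c(1L, -1L))
    msg <- c(msg, "strand must be +1 or -1")
  seg <- object@segments
  if (!is.matrix(seg) || ncol(seg) != 2L || nrow(seg) < 1L)
    msg <- c(msg, "segments must be a matrix with >= 1 row and 2 columns")
  else {
    if (any(seg[, 2] <= seg[, 1]))
      msg <- c(msg, "each segment must satisfy end > start")
    if (any(seg < 0))
      msg <- c(msg, "segment coordinates must be non-negative")
  }
  if (!is.na(object@anticodon) &&
      (nchar(object@anticodon) != 3L ||
       grepl("[^ACGT]", object@anticodon)))
    msg <- c(msg, "anticodon must be a 3-mer over ACGT")
  if (length(msg)) msg else TRUE
})

#' Annotated mitochondrial genome
#'
#' A nucleotide sequence over `{A,C,G,T,N}` with circular or linear topology
#' and an ordered list of [MitoFeature-class] annotations. Features are kept
#' sorted by the start of their first segment.
#'
#' @slot id accession-like identifier.
#' @slot seq upper-case nucleotide string.
#' @slot topology `"circular"` or `"linear"`.
#' @slot features list of [MitoFeature-class] objects sorted by start.
#' @export
setClass("AnnotatedGenome",
  representation(id = "character", seq = "character", topology = "character",
                 features = "list"))

setValidity("AnnotatedGenome", function(object) {
  msg <- character()
  L <- nchar(object@seq)
  if (length(object@seq) != 1L || L < 1L)
    msg <- c(msg, "seq must be a single non-empty string")
  else if (grepl("[^ACGTN]", object@seq))
    msg <- c(msg, "seq may only contain A, C, G, T, N")
  if (!object@topology %in% c("circular", "linear"))
    msg <- c(msg, "topology must be circular or linear")
  if (length(object@features)) {
    if (!all(vapply(object@features, is, logical(1), "MitoFeature")))
      msg <- c(msg, "features must all be MitoFeature objects")
    else {
      starts <- vapply(object@features, function(f) f@segments[1, 1], 0)
      if (is.unsorted(starts))
        msg <- c(msg, "features must be sorted by start")
      ends <- unlist(lapply(object@features, function(f) f@segments[, 2]))
      if (L >= 1L && any(ends > L))
        msg <- c(msg, "feature segments exceed sequence length")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Sliding-window base-composition profile
#'
#' Per-window AT skew (`(A-T)/(A+T)`) and GC content tracks together with
#' the genome-wide values, as produced by [windowedComposition()].
#'
#' @slot window window width in bp.
#' @slot step step between window starts in bp.
#' @slot records data.frame with columns `window_start` (0-based),
#'   `at_skew` (`NA` where `A+T == 0`) and `gc_content`.
#' @slot globalAtSkew,globalGc genome-wide values.
#' @export
setClass("CompositionProfile",
  representation(window = "integer", step = "integer",
                 records = "data.frame",
                 globalAtSkew = "numeric", globalGc = "numeric"))

setValidity("CompositionProfile", function(object) {
  r <- object@records
  msg <- character()
  if (!all(c("window_start", "at_skew", "gc_content") %in% names(r)))
    msg <- c(msg, "records must have window_start, at_skew, gc_content")
  else {
    gc <- r$gc_content[!is.na(r$gc_content)]
    if (any(gc < 0 | gc > 1)) msg <- c(msg, "gc_content outside [0, 1]")
    sk <- r$at_skew[!is.na(r$at_skew)]
    if (any(sk < -1 | sk > 1)) msg <- c(msg, "at_skew outside [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Sliding-window divergence profile
#'
#' Per-window uncorrected p-distance track over an aligned sequence pair,
#' as produced by [slidingPDistance()].
#'
#' @slot window,step window width and step in alignment columns.
#' @slot records data.frame with columns `column_start` (0-based),
#'   `p_distance` (`NA` when no site is comparable) and `compared_sites`.
#' @slot globalP alignment-wide p-distance.
#' @export
setClass("DivergenceProfile",
  representation(window = "integer", step = "integer",
                 records = "data.frame", globalP = "numeric"))

setValidity("DivergenceProfile", function(object) {
  r <- object@records
  msg <- character()
  if (!all(c("column_start", "p_distance", "compared_sites") %in% names(r)))
    msg <- c(msg, "records must have column_start, p_distance, compared_sites")
  else {
    p <- r$p_distance[!is.na(r$p_distance)]
    if (any(p < 0 | p > 1)) msg <- c(msg, "p_distance outside [0, 1]")
    if (any(r$compared_sites > object@window))
      msg <- c(msg, "compared_sites exceeds window")
  }
  if (length(msg)) msg else TRUE
})

#' Position-specific protein scoring profile
#'
#' Per-column log-odds scores over the 20 amino acids built from a curated
#' alignment by [buildProfile()], plus the gap penalties used when aligning
#' against the profile.
#'
#' @slot scores 20 x C numeric matrix, rows named by amino acid.
#' @slot consensus length-C consensus string (argmax residue per column,
#'   alphabetical tie-break).
#' @slot gapOpen,gapExtend penalties for profile-column/insert gaps.
#' @slot source label of the gene/lineage the profile was built from.
#' @export
setClass("ProteinProfile",
  representation(scores = "matrix", consensus = "character",
                 gapOpen = "numeric", gapExtend = "numeric",
                 source = "character"))

setValidity("ProteinProfile", function(object) {
  msg <- character()
  if (nrow(object@scores) != 20L)
    msg <- c(msg, "scores must have 20 rows (amino acids)")
  if (ncol(object@scores) < 1L)
    msg <- c(msg, "profile must have >= 1 column")
  if (any(!is.finite(object@scores)))
    msg <- c(msg, "all scores must be finite")
  if (nchar(object@consensus) != ncol(object@scores))
    msg <- c(msg, "consensus length must equal column count")
  if (length(msg)) msg else TRUE
})

#' Result of frameshift-aware alignment against a profile
#'
#' @slot aaRow gapped amino-acid string with one character per profile
#'   column (`-` for deleted columns, `X` for residues not resolvable).
#' @slot score summed log-odds of the optimal path.
#' @slot frameshifts data.frame with columns `dna_position` (1-based) and
#'   `kind` (`+1` extra nucleotide consumed, `-1` missing nucleotide).
#' @slot insertAfterColumn profile columns after which a DNA codon was
#'   inserted (consumed against no column).
#' @export
setClass("RecoveredAlignment",
  representation(aaRow = "character", score = "numeric",
                 frameshifts = "data.frame", insertAfterColumn = "integer"))

#' Concatenated partitioned supermatrix
#'
#' @slot taxa ordered taxon names.
#' @slot seqs named character vector, one concatenated gapped sequence per
#'   taxon.
#' @slot partitions data.frame with columns `name`, `datatype` (`nt` or
#'   `aa`), `start`, `end` (1-based inclusive), tiling the full length.
#' @export
setClass("Supermatrix",
  representation(taxa = "character", seqs = "character",
                 partitions = "data.frame"))

setValidity("Supermatrix", function(object) {
  msg <- character()
  p <- object@partitions
  if (!all(c("name", "datatype", "start", "end") %in% names(p)))
    msg <- c(msg, "partitions must have name, datatype, start, end")
  else {
    total <- if (nrow(p)) max(p$end) else 0L
    if (nrow(p)) {
      if (p$start[1] != 1L) msg <- c(msg, "first partition must start at 1")
      if (nrow(p) > 1L && any(p$start[-1] != p$end[-nrow(p)] + 1L))
        msg <- c(msg, "partitions must tile without gaps or overlap")
      if (anyDuplicated(p$name)) msg <- c(msg, "duplicate partition names")
      if (!all(p$datatype %in% c("nt", "aa")))
        msg <- c(msg, "datatype must be nt or aa")
    }
    if (length(object@seqs) &&
        any(nchar(object@seqs) != total))
      msg <- c(msg, "all rows must have length equal to total length")
    if (!identical(sort(names(object@seqs)), sort(object@taxa)))
      msg <- c(msg, "seqs must be named by taxa")
  }
  if (length(msg)) msg else TRUE
})

#' Rooted tree with node heights
#'
#' Thin wrapper around an [ape::read.tree()] `phylo` object that exposes
#' node heights (maximum root-to-leaf path length minus node depth) and
#' remembers whether heights have been normalized to a named MRCA.
#'
#' @slot phylo a rooted `phylo` object with branch lengths.
#' @slot normalized `TRUE` after [normalizeToMrca()].
#' @export
setClass("HeightTree",
  representation(phylo = "ANY", normalized = "logical"),
  prototype(normalized = FALSE))

setValidity("HeightTree", function(object) {
  msg <- character()
  if (!inherits(object@phylo, "phylo"))
    msg <- c(msg, "phylo slot must be an ape phylo object")
  else {
    if (is.null(object@phylo$edge.length))
      msg <- c(msg, "tree must have branch lengths")
    if (anyDuplicated(object@phylo$tip.label))
      msg <- c(msg, "duplicate leaf labels")
  }
  if (length(msg)) msg else TRUE
})
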