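#' @rdname AnnotatedGenome-class
#' @param x an object.
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))

#' @rdname AnnotatedGenome-class
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))

#' @rdname AnnotatedGenome-class
#' @export
setGeneric("topology", function(x) standardGeneric("topology"))

#' @rdname AnnotatedGenome-class
#' @export
setGeneric("features", function(x) standardGeneric("features"))

#' @rdname CompositionProfile-class
#' @param x an object with per-window records.
#' @export
setGeneric("profileRecords", function(x) standardGeneric("profileRecords"))

#' @rdname ProteinProfile-class
#' @param x a profile-like object.
#' @export
setGeneric("consensus", function(x) standardGeneric("consensus"))

#' @rdname HeightTree-class
#' @param x a tree-like object.
#' @export
setGeneric("nodeHeights", function(x) standardGeneric("nodeHeights"))

#' @describeIn AnnotatedGenome-class accession identifier.
setMethod("genomeId", "AnnotatedGenome", function(x) x@id)

#' @describeIn AnnotatedGenome-class nucleotide sequence string.
setMethod("genomeSeq", "AnnotatedGenome", function(x) x@seq)

#' @describeIn AnnotatedGenome-class `"circular"` or `"linear"`.
setMethod("topology", "AnnotatedGenome", function(x) x@topology)

#' @describeIn AnnotatedGenome-class list of [MitoFeature-class] objects.
setMethod("features", "AnnotatedGenome", function(x) x@features)

#' @describeIn CompositionProfile-class per-window records.
setMethod("profileRecords", "CompositionProfile", function(x) x@records)

#' @describeIn DivergenceProfile-class per-window records.
setMethod("profileRecords", "DivergenceProfile", function(x) x@records)

#' @describeIn ProteinProfile-class consensus string.
setMethod("consensus", "ProteinProfile", function(x) x@consensus)

setMethod("show", "MitoFeature", function(object) {
  seg <- paste(apply(object@segments, 1, function(s)
    sprintf("[%d,%d)", s[1], s[2])), collapse = "+")
  cat(sprintf("MitoFeature %s (%s) strand %+d %s%s\n",
              object@name, object@kind, object@strand, seg,
              if (is.na(object@anticodon)) ""
              else paste0(" anticodon=", object@anticodon)))
})

setMethod("show", "AnnotatedGenome", function(object) {
  kinds <- table(vapply(object@features, function(f) f@kind, ""))
  cat(sprintf("AnnotatedGenome %s: %d bp, %s, %d features (%s)\n",
              object@id, nchar(object@seq), object@topology,
              length(object@features),
              paste(sprintf("%s: %d", names(kinds), kinds), collapse = ", ")))
})

setMethod("show", "CompositionProfile", function(object) {
  cat(sprintf(paste0("CompositionProfile: %d windows of %d bp, step %d; ",
                     "global AT skew %.4f, GC %.4f\n"),
              nrow(object@records), object@window, object@step,
              object@globalAtSkew, object@globalGc))
})

setMethod("show", "DivergenceProfile", function(object) {
  cat(sprintf("DivergenceProfile: %d windows of %d, step %d; global p %.4f\n",
              nrow(object@records), object@window, object@step,
              object@globalP))
})

setMethod("show", "ProteinProfile", function(object) {
  cat(sprintf("ProteinProfile [%s]: %d columns, consensus %s%s\n",
              object@source, ncol(object@scores),
              substr(object@consensus, 1, 40),
              if (nchar(object@consensus) > 40) "..." else ""))
})

setMethod("show", "RecoveredAlignment", function(object) {
  cat(sprintf("RecoveredAlignment: score %.2f, %d frameshift event(s)\n",
              object@score, nrow(object@frameshifts)))
})

setMethod("show", "Supermatrix", function(object) {
  total <- if (nrow(object@partitions)) max(object@partitions$end) else 0L
  cat(sprintf("Supermatrix: %d taxa x %d columns, %d partition(s)\n",
              length(object@taxa), total, nrow(object@partitions)))
})

setMethod("show", "HeightTree", function(object) {
  cat(sprintf("HeightTree: %d leaves, root height %.4g%s\n",
              length(object@phylo$tip.label), max(nodeHeights(object)),
              if (object@normalized) " (MRCA-normalized)" else ""))
})
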