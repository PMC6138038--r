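## Tree input, MRCA height normalization, Robinson-Foulds bipartition
## comparison and matched-clade height tables for M-vs-F congruence.

#' Parse a rooted tree with branch lengths
#'
#' Reads Newick or NEXUS (trees block) via \pkg{ape}. Square-bracket
#' comment annotations (as written by Bayesian samplers) are stripped
#' before parsing. Duplicate leaf labels and syntactically invalid input
#' raise errors.
#'
#' @param text tree string or path to a file.
#' @param format `"newick"` or `"nexus"`.
#' @return a [HeightTree-class].
#' @examples
#' parseTree("((A:1,B:1):1,C:2);")
#' @export
parseTree <- function(text, format = c("newick", "nexus")) {
  format <- match.arg(format)
  is_path <- length(text) == 1L && !grepl("[(;\n]", text) && file.exists(text)
  if (format == "nexus") {
    tr <- if (is_path) ape::read.nexus(text)
          else ape::read.nexus(textConnection(text))
    if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  } else {
    s <- if (is_path) paste(readLines(text), collapse = "") else text
    s <- gsub("\\[[^]]*\\]", "", s)  # strip comment annotations
    np <- lengths(regmatches(s, gregexpr("\\(", s)))
    nc <- lengths(regmatches(s, gregexpr("\\)", s)))
    if (np != nc) stop("unbalanced parentheses in Newick string")
    tr <- tryCatch(ape::read.tree(text = s), error = function(e) NULL,
                   warning = function(w) NULL)
    if (is.null(tr)) stop("could not parse Newick string")
  }
  new("HeightTree", phylo = tr, normalized = FALSE)
}

#' @describeIn HeightTree-class node heights (max root-to-leaf path length
#'   minus node depth), indexed like the `phylo` object: tips
#'   `1..Ntip`, then internal nodes; tip entries are named.
setMethod("nodeHeights", "HeightTree", function(x) {
  d <- ape::node.depth.edgelength(x@phylo)
  h <- max(d) - d
  names(h)[seq_along(x@phylo$tip.label)] <- x@phylo$tip.label
  h
})

#' Normalize node heights to the MRCA of a named clade
#'
#' All branch lengths (and hence node heights) are divided by the height
#' of the most recent common ancestor of `taxa`, so that node sits at
#' height exactly 1. Topology is unchanged; the operation is idempotent
#' and invariant under pre-scaling of the whole tree.
#'
#' @param tree a [HeightTree-class].
#' @param taxa two or more leaf labels whose MRCA anchors the scale.
#' @return normalized [HeightTree-class].
#' @export
normalizeToMrca <- function(tree, taxa) {
  ph <- tree@phylo
  if (length(taxa) < 2L) stop("need at least two taxa to define an MRCA")
  missing <- setdiff(taxa, ph$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  node <- ape::getMRCA(ph, taxa)
  h <- nodeHeights(tree)[node]
  if (h <= 0) stop("MRCA height is zero; cannot normalize")
  ph$edge.length <- ph$edge.length / h
  new("HeightTree", phylo = ph, normalized = TRUE)
}

# canonical non-trivial bipartitions of a tree viewed as unrooted
.bipartitions <- function(ph) {
  tips <- sort(ph$tip.label)
  n <- length(tips)
  ref <- tips[1]
  pp <- ape::prop.part(ph)
  labs <- attr(pp, "labels")
  out <- character()
  for (s in pp) {
    side <- sort(labs[s])
    if (ref %in% side) side <- setdiff(tips, side)
    if (length(side) >= 2L && length(side) <= n - 2L)
      out <- c(out, paste(side, collapse = "|"))
  }
  unique(out)
}

#' Robinson-Foulds distance and bipartition comparison
#'
#' Rooted input trees are compared as unrooted: the distance is the size
#' of the symmetric difference of their non-trivial bipartitions; 0 means
#' identical unrooted topologies. Shared and tree-specific bipartitions
#' are also returned.
#'
#' @param t1,t2 [HeightTree-class] objects over identical leaf sets
#'   (after applying `taxon_map`).
#' @param taxon_map optional named character vector renaming leaves
#'   before comparison (e.g. accession to species key).
#' @return list with `rf` (integer), `shared`, `unique1`, `unique2`
#'   (character vectors of `|`-joined clades).
#' @export
rfDistance <- function(t1, t2, taxon_map = NULL) {
  p1 <- t1@phylo; p2 <- t2@phylo
  remap <- function(ph) {
    if (!is.null(taxon_map)) {
      hit <- taxon_map[ph$tip.label]
      ph$tip.label[!is.na(hit)] <- hit[!is.na(hit)]
    }
    ph
  }
  p1 <- remap(p1); p2 <- remap(p2)
  if (!setequal(p1$tip.label, p2$tip.label))
    stop("leaf sets differ: ",
         paste(c(setdiff(p1$tip.label, p2$tip.label),
                 setdiff(p2$tip.label, p1$tip.label)), collapse = ", "))
  b1 <- .bipartitions(p1); b2 <- .bipartitions(p2)
  list(rf = length(setdiff(b1, b2)) + length(setdiff(b2, b1)),
       shared = intersect(b1, b2),
       unique1 = setdiff(b1, b2), unique2 = setdiff(b2, b1))
}

#' Matched clade heights between two normalized trees
#'
#' Clades (descendant leaf sets of internal nodes) are matched between
#' the two trees by identical leaf sets; for each match the table reports
#' both heights and their ratio. Clades present in only one tree (e.g.
#' conspecific haplogroup cherries without a counterpart) are listed as
#' unmatched. Both trees must have been normalized with
#' [normalizeToMrca()] so that heights are on a common scale.
#'
#' @param tM,tF normalized [HeightTree-class] objects.
#' @param taxon_map optional leaf renaming applied before matching.
#' @return list with `table` (data.frame `clade`, `height_M`, `height_F`,
#'   `ratio`), `unmatched_M`, `unmatched_F`.
#' @export
matchedCladeHeights <- function(tM, tF, taxon_map = NULL) {
  if (!tM@normalized || !tF@normalized)
    stop("both trees must be normalized to a common MRCA first")
  clades <- function(ht) {
    ph <- ht@phylo
    if (!is.null(taxon_map)) {
      hit <- taxon_map[ph$tip.label]
      ph$tip.label[!is.na(hit)] <- hit[!is.na(hit)]
    }
    h <- nodeHeights(new("HeightTree", phylo = ph, normalized = TRUE))
    ntip <- length(ph$tip.label)
    nodes <- (ntip + 1L):(ntip + ph$Nnode)
    key <- vapply(nodes, function(nd) {
      paste(sort(ape::extract.clade(ph, nd)$tip.label), collapse = "|")
    }, "")
    setNames(h[nodes], key)
  }
  cM <- clades(tM); cF <- clades(tF)
  common <- intersect(names(cM), names(cF))
  tab <- data.frame(clade = common,
                    height_M = unname(cM[common]),
                    height_F = unname(cF[common]),
                    ratio = unname(cM[common] / cF[common]),
                    stringsAsFactors = FALSE)
  list(table = tab,
       unmatched_M = setdiff(names(cM), names(cF)),
       unmatched_F = setdiff(names(cF), names(cM)))
}
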