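## Seeded simulator of annotated F/M mitogenome pairs: a template genome
## evolved along a guide tree with lineage-specific rates, plus explicit
## frameshift and tandem-duplication injections for curation and
## structure-comparison fixtures.

# deterministic stream seed from a label and the master seed (31-bit)
.seed_from <- function(label, seed) {
  v <- utf8ToInt(label)
  h <- as.double(seed) %% 2147483647
  for (ch in v) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Default mitogenome template
#'
#' Gene complement and layout emulating a unionid M-type mitogenome:
#' 13 protein-coding genes, 2 rRNAs, 22 tRNAs and one supernumerary
#' `m-ORF` followed by the adjacent `trnD` (the block whose duplication
#' [injectDuplication()] emulates), on both strands, with short
#' intergenic spacers; about 16 kb in total.
#'
#' @return data.frame with columns `name`, `kind`, `strand`, `length`,
#'   `spacer_after`.
#' @export
defaultTemplate <- function() {
  g <- function(name, kind, strand, length, spacer = 10L)
    data.frame(name = name, kind = kind, strand = strand,
               length = as.integer(length), spacer_after = as.integer(spacer),
               stringsAsFactors = FALSE)
  t1 <- function(aa, strand = 1L) g(paste0("trn", aa), "tRNA", strand, 68L, 6L)
  rbind(
    g("cox1", "CDS", 1L, 1536L), t1("V"),
    g("cox2", "CDS", 1L, 750L),
    g("atp8", "CDS", 1L, 168L), g("atp6", "CDS", 1L, 699L), t1("F"),
    g("nad5", "CDS", 1L, 1713L), t1("H"),
    g("nad4", "CDS", 1L, 1380L), g("nad4L", "CDS", 1L, 291L), t1("T"),
    g("nad6", "CDS", -1L, 480L), t1("P", -1L),
    g("cob", "CDS", 1L, 1140L), t1("S1"),
    g("rrnL", "rRNA", 1L, 1250L, 4L), t1("L1"), t1("L2"),
    g("nad1", "CDS", 1L, 912L), t1("I"), t1("Q", -1L), t1("M"),
    g("nad2", "CDS", 1L, 963L), t1("W"), t1("C", -1L), t1("Y", -1L),
    g("cox3", "CDS", 1L, 783L), t1("G"),
    g("nad3", "CDS", 1L, 351L), t1("A"), t1("R"), t1("N"), t1("S2"),
    g("rrnS", "rRNA", 1L, 850L, 4L), t1("E"), t1("K"),
    g("m-ORF", "CDS", 1L, 552L, 2L), t1("D"))
}

# canonical anticodon (DNA, gene strand) for an amino-acid one-letter code
.canonical_anticodon <- function(aa1, code = "5") {
  gc <- Biostrings::getGeneticCode(code)
  # prefer the familiar anticodons for M and D; otherwise first codon
  if (aa1 == "M") return("CAT")
  if (aa1 == "D") return("GTC")
  codon <- names(gc)[gc == aa1][1]
  if (is.na(codon)) stop("no codon for amino acid ", aa1)
  revComp(codon)
}

#' Simulation parameter set
#'
#' @param tree guide tree: Newick string, path, `phylo` or
#'   [HeightTree-class]; branch lengths in substitutions/site.
#' @param rate_m rate multiplier of the M lineage (`>= 1`); the F lineage
#'   has rate 1.
#' @param kappa transition:transversion ratio of the substitution process.
#' @param base_freqs target base composition `c(A=,C=,G=,T=)`; the default
#'   reproduces the strong negative AT skew of unionid M mitogenomes.
#' @param lineage_stem length (substitutions/site, at rate 1) of the stem
#'   branch separating the F and M ancestors from the shared root genome;
#'   models the deep F/M divergence that predates the species radiation.
#' @param template gene layout, see [defaultTemplate()].
#' @param seed master seed; all per-branch streams are derived from it.
#' @return validated parameter list of class `"mitoSimParams"`.
#' @export
simulationParams <- function(tree, rate_m = 3, kappa = 3,
                             base_freqs = c(A = 0.2295, C = 0.1642,
                                            G = 0.1642, T = 0.4421),
                             lineage_stem = 0.25,
                             template = defaultTemplate(), seed = 1L) {
  ph <- if (is(tree, "HeightTree")) tree@phylo
        else if (inherits(tree, "phylo")) tree
        else parseTree(tree)@phylo
  if (is.null(ph$edge.length) || any(!is.finite(ph$edge.length)) ||
      any(ph$edge.length < 0))
    stop("guide tree must have finite non-negative branch lengths")
  if (!is.finite(rate_m) || rate_m < 1) stop("rate_m must be >= 1")
  if (!is.finite(kappa) || kappa <= 0) stop("kappa must be > 0")
  if (length(base_freqs) != 4L || abs(sum(base_freqs) - 1) > 1e-8 ||
      any(base_freqs < 0))
    stop("base_freqs must be 4 non-negative frequencies summing to 1")
  names(base_freqs) <- c("A", "C", "G", "T")
  structure(list(tree = ph, rate_m = rate_m, kappa = kappa,
                 base_freqs = base_freqs, lineage_stem = lineage_stem,
                 template = template, seed = as.integer(seed)),
            class = "mitoSimParams")
}

#' Evolve a sequence along one branch
#'
#' Per-site independent substitution: each site substitutes with
#' probability `1 - exp(-b * rate)`; the replacement base is drawn with
#' weight `base_freqs[y] * kappa` for transitions and `base_freqs[y]` for
#' transversions (an HKY-flavoured kernel). `N` sites are left unchanged.
#'
#' @param seq nucleotide string.
#' @param b branch length in substitutions/site.
#' @param rate lineage rate multiplier.
#' @param kappa transition:transversion ratio.
#' @param base_freqs target base frequencies `c(A=,C=,G=,T=)`.
#' @param seed integer seed for this branch.
#' @return evolved nucleotide string.
#' @export
evolveSequence <- function(seq, b, rate = 1, kappa = 3,
                           base_freqs = c(A = 0.25, C = 0.25,
                                          G = 0.25, T = 0.25),
                           seed = 1L) {
  p <- 1 - exp(-b * rate)
  if (p == 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  v0 <- v  # replacements are drawn against the pre-branch state
  set.seed(seed)
  hit <- runif(length(v)) < p
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  for (x in c("A", "C", "G", "T")) {
    i <- which(hit & v0 == x)
    if (!length(i)) next
    others <- setdiff(c("A", "C", "G", "T"), x)
    w <- base_freqs[others] * ifelse(others == transition[[x]], kappa, 1)
    v[i] <- sample(others, length(i), replace = TRUE, prob = w / sum(w))
  }
  paste(v, collapse = "")
}

# draw the template root genome: stop-free CDSs with start/stop codons,
# tRNAs carrying their canonical anticodon at the centre
.draw_root_genome <- function(params) {
  set.seed(.seed_from("root", params$seed))
  fr <- params$base_freqs
  bases <- names(fr)
  # the composition target applies to the deposited (plus) strand, so
  # minus-strand transcripts are drawn from the complemented frequencies
  fr_rc <- setNames(fr[c("T", "G", "C", "A")], bases)
  draw <- function(n, f = fr)
    paste(sample(bases, n, replace = TRUE, prob = f), collapse = "")
  draw_cds <- function(n, f) {
    stopifnot(n %% 3 == 0)
    ncod <- n / 3 - 2L
    # iid codons, conditioned on not being a stop (TAA/TAG under table 5)
    cods <- substring(draw(3L * ncod, f), 3L * seq_len(ncod) - 2L,
                      3L * seq_len(ncod))
    repeat {
      bad <- which(cods %in% c("TAA", "TAG"))
      if (!length(bad)) break
      redraw <- draw(3L * length(bad), f)
      cods[bad] <- substring(redraw, 3L * seq_along(bad) - 2L,
                             3L * seq_along(bad))
    }
    paste0("ATG", paste(cods, collapse = ""), "TAA")
  }
  draw_trn <- function(n, anti, f) {
    s <- draw(n, f)
    mid <- floor((n - 3) / 2)
    paste0(substr(s, 1, mid), anti, substr(s, mid + 4, n))
  }
  tpl <- params$template
  seq_parts <- character()
  feats <- list()
  pos <- 0L
  for (i in seq_len(nrow(tpl))) {
    nm <- tpl$name[i]; kind <- tpl$kind[i]
    len <- tpl$length[i]; strand <- tpl$strand[i]
    anti <- NA_character_
    f <- if (strand == 1L) fr else fr_rc
    if (kind == "CDS") transcript <- draw_cds(len, f)
    else if (kind == "tRNA") {
      aa1 <- substr(normalizeGeneName(nm), 4, 4)
      anti <- .canonical_anticodon(aa1)
      transcript <- draw_trn(len, anti, f)
    } else transcript <- draw(len, f)
    slice <- if (strand == 1L) transcript else revComp(transcript)
    seq_parts <- c(seq_parts, slice)
    feats[[length(feats) + 1L]] <-
      mitoFeature(kind, nm, strand, c(pos, pos + len), anticodon = anti)
    pos <- pos + len
    sp <- tpl$spacer_after[i]
    if (sp > 0L) { seq_parts <- c(seq_parts, draw(sp)); pos <- pos + sp }
  }
  annotatedGenome("root", paste(seq_parts, collapse = ""), "circular", feats)
}

#' Simulate annotated F/M mitogenome pairs along a guide tree
#'
#' A root genome is drawn from the target base composition following the
#' template layout. The F and M ancestors diverge from it along a stem of
#' `lineage_stem` substitutions/site (the M stem scaled by `rate_m`), and
#' each lineage then evolves down the guide tree, every branch of length
#' `b` substituting each site with probability `1 - exp(-b * rate)`.
#' Annotation coordinates are stable (substitutions only); indels and
#' duplications are introduced explicitly via [injectFrameshift()] and
#' [injectDuplication()]. Identical parameters and seed give
#' byte-identical output; per-branch random streams are derived by
#' hashing the branch identity with the master seed, so results do not
#' depend on traversal order.
#'
#' @param params a parameter set from [simulationParams()].
#' @return list with elements `F` and `M`, each a named list of
#'   [AnnotatedGenome-class] per leaf (genome ids `<leaf>_F` /
#'   `<leaf>_M`), plus the `root` genome.
#' @export
simulateMitogenomes <- function(params) {
  stopifnot(inherits(params, "mitoSimParams"))
  ph <- params$tree
  root_g <- .draw_root_genome(params)
  ntip <- length(ph$tip.label)
  root_node <- ntip + 1L
  # stable branch identity: sorted leaves below the child node
  clade_id <- function(node) {
    if (node <= ntip) return(ph$tip.label[node])
    paste(sort(ape::extract.clade(ph, node)$tip.label), collapse = ",")
  }
  out <- list(F = list(), M = list(), root = root_g)
  for (lineage in c("F", "M")) {
    rate <- if (lineage == "F") 1 else params$rate_m
    anc <- evolveSequence(root_g@seq, params$lineage_stem, rate,
                          params$kappa, params$base_freqs,
                          .seed_from(paste0("stem|", lineage), params$seed))
    seqs <- setNames(vector("list", ntip + ph$Nnode), NULL)
    seqs[[root_node]] <- anc
    # edges in preorder so parents are filled before children
    ord <- ape::reorder.phylo(ph, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]; chl <- ord$edge[e, 2]
      b <- ord$edge.length[e]
      s <- .seed_from(paste0(lineage, "|", clade_id(chl)), params$seed)
      seqs[[chl]] <- evolveSequence(seqs[[par]], b, rate, params$kappa,
                                    params$base_freqs, s)
    }
    for (t in seq_len(ntip)) {
      leaf <- ph$tip.label[t]
      out[[lineage]][[leaf]] <- annotatedGenome(
        paste0(leaf, "_", lineage), seqs[[t]], "circular", root_g@features)
    }
  }
  out
}

#' Inject a single-nucleotide frameshift into a gene
#'
#' Inserts or deletes one nucleotide at `offset` (0-based, transcript
#' coordinates) inside the named gene. The genome length changes by one
#' and all downstream feature coordinates shift accordingly; the mutated
#' gene's own length changes by one, so its translation is garbled
#' downstream of the event — the error signature the dual-space screen
#' detects.
#'
#' @param genome an [AnnotatedGenome-class]; the target gene must be a
#'   single-segment feature.
#' @param gene gene name.
#' @param offset 0-based offset within the gene (`0 <= offset < length`).
#' @param kind `"insert"` or `"delete"`.
#' @param seed seed for the inserted base.
#' @return mutated [AnnotatedGenome-class].
#' @export
injectFrameshift <- function(genome, gene, offset, kind = c("insert", "delete"),
                             seed = 1L) {
  kind <- match.arg(kind)
  hit <- .find_features(genome, gene)
  if (!length(hit)) stop(sprintf("gene '%s' not annotated", gene))
  f <- hit[[1]]
  if (nrow(f@segments) != 1L)
    stop("frameshift injection supports single-segment features only")
  glen <- f@segments[1, 2] - f@segments[1, 1]
  if (offset < 0 || offset >= glen) stop("offset outside the gene")
  pos <- if (f@strand == 1L) f@segments[1, 1] + offset
         else f@segments[1, 2] - 1L - offset  # transcript -> genome coords
  seq <- genome@seq
  if (kind == "insert") {
    set.seed(.seed_from(paste("fs", gene, offset), seed))
    base <- sample(c("A", "C", "G", "T"), 1)
    seq <- paste0(substr(seq, 1, pos), base,
                  substr(seq, pos + 1L, nchar(seq)))
    d <- 1L
  } else {
    seq <- paste0(substr(seq, 1, pos),
                  substr(seq, pos + 2L, nchar(seq)))
    d <- -1L
  }
  feats <- lapply(genome@features, function(g) {
    segs <- g@segments
    segs[, 1] <- segs[, 1] + ifelse(segs[, 1] > pos, d, 0L)
    segs[, 2] <- segs[, 2] + ifelse(segs[, 2] > pos, d, 0L)
    mitoFeature(g@kind, g@name, g@strand, segs, anticodon = g@anticodon,
                normalize = FALSE)
  })
  annotatedGenome(genome@id, seq, genome@topology, feats)
}

#' Duplicate a contiguous feature block
#'
#' Copies the genomic block spanned by the named features (which must be
#' adjacent in the feature list, with no other feature in between) and
#' inserts the copy immediately after the block. New copies are annotated
#' with a `_dup` suffix; all downstream coordinates shift by the block
#' length. This emulates a tandem duplication such as the one covering
#' the supernumerary `m-ORF` and its adjacent tRNA in *S. woodiana*.
#'
#' @param genome an [AnnotatedGenome-class].
#' @param feature_names names of the contiguous features to duplicate.
#' @return mutated [AnnotatedGenome-class] with two extra features.
#' @export
injectDuplication <- function(genome, feature_names) {
  nm <- vapply(genome@features, function(f) f@name, "")
  idx <- match(feature_names, nm)
  if (anyNA(idx))
    stop("features not annotated: ",
         paste(feature_names[is.na(idx)], collapse = ", "))
  idx <- sort(idx)
  if (!all(diff(idx) == 1L))
    stop("features must be contiguous (adjacent in the feature list)")
  segs <- do.call(rbind, lapply(genome@features[idx], function(f) f@segments))
  if (any(vapply(genome@features[idx], function(f) nrow(f@segments), 0L) > 1L))
    stop("duplication of origin-spanning features is not supported")
  bstart <- min(segs[, 1]); bend <- max(segs[, 2])
  blen <- bend - bstart
  seq <- paste0(substr(genome@seq, 1, bend),
                substr(genome@seq, bstart + 1L, bend),
                substr(genome@seq, bend + 1L, nchar(genome@seq)))
  shift_feat <- function(g, d) {
    segs <- g@segments + d
    mitoFeature(g@kind, g@name, g@strand, segs, anticodon = g@anticodon,
                normalize = FALSE)
  }
  feats <- lapply(genome@features, function(g) {
    if (g@segments[1, 1] >= bend) shift_feat(g, blen) else g
  })
  copies <- lapply(genome@features[idx], function(g) {
    cp <- shift_feat(g, bend - bstart)
    mitoFeature(cp@kind, paste0(g@name, "_dup"), cp@strand, cp@segments,
                anticodon = cp@anticodon, normalize = FALSE)
  })
  annotatedGenome(genome@id, seq, genome@topology, c(feats, copies))
}
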