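## GenBank flat-file and FASTA input/output for annotated mitogenomes,
## feature sequence extraction and mitochondrial translation.

#' Normalize heterogeneous mitochondrial gene labels
#'
#' Database mitogenome records label the same genes inconsistently
#' (`COI`/`COX1`/`cox1`, `ND2`/`nad2`, `16S`/`rrnL`, `MT-ORF`/`morf` ...).
#' This maps common variants onto one canonical set: `cox1..cox3`, `cob`,
#' `nad1..nad6`, `nad4L`, `atp6`, `atp8`, `rrnL`, `rrnS`, `m-ORF`, and
#' `trnX` one-letter tRNA labels. Unrecognized labels are returned
#' unchanged (case preserved).
#'
#' @param name character vector of gene labels.
#' @return character vector of canonical labels.
#' @examples
#' normalizeGeneName(c("COI", "ND4L", "16S", "MT-ORF", "tRNA-Met"))
#' @export
normalizeGeneName <- function(name) {
  vapply(name, function(x) {
    x0 <- x
    x <- toupper(gsub("[ _]", "-", x))
    # tRNAs: one- or three-letter forms
    m <- regmatches(x, regexec("^TRN([A-Z])([A-Z]{2})?[0-9]?$", x))[[1]]
    if (length(m)) {
      if (nchar(m[3])) {
        aa3 <- paste0(m[2], tolower(m[3]))
        one <- .AA3TO1[aa3]
        if (!is.na(one)) return(paste0("trn", one))
      }
      return(paste0("trn", m[2]))
    }
    m <- regmatches(x, regexec("^TRNA-([A-Z][A-Z]{2})$", x))[[1]]
    if (length(m)) {
      one <- .AA3TO1[paste0(substr(m[2], 1, 1), tolower(substr(m[2], 2, 3)))]
      if (!is.na(one)) return(paste0("trn", one))
    }
    x <- sub("^MT-", "", x)
    key <- gsub("-", "", x)
    hit <- .GENE_ALIASES[key]
    if (!is.na(hit)) unname(hit) else x0
  }, character(1), USE.NAMES = FALSE)
}

.AA3TO1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

.GENE_ALIASES <- local({
  tab <- c(
    COX1 = "cox1", COI = "cox1", CO1 = "cox1", COXI = "cox1",
    COX2 = "cox2", COII = "cox2", CO2 = "cox2", COXII = "cox2",
    COX3 = "cox3", COIII = "cox3", CO3 = "cox3", COXIII = "cox3",
    COB = "cob", CYTB = "cob", CYB = "cob",
    ND1 = "nad1", NAD1 = "nad1", NADH1 = "nad1",
    ND2 = "nad2", NAD2 = "nad2", NADH2 = "nad2",
    ND3 = "nad3", NAD3 = "nad3", NADH3 = "nad3",
    ND4 = "nad4", NAD4 = "nad4", NADH4 = "nad4",
    ND4L = "nad4L", NAD4L = "nad4L", NADH4L = "nad4L",
    ND5 = "nad5", NAD5 = "nad5", NADH5 = "nad5",
    ND6 = "nad6", NAD6 = "nad6", NADH6 = "nad6",
    ATP6 = "atp6", ATPASE6 = "atp6", ATP8 = "atp8", ATPASE8 = "atp8",
    "16S" = "rrnL", RRNL = "rrnL", LRRNA = "rrnL", "16SRRNA" = "rrnL",
    "12S" = "rrnS", RRNS = "rrnS", SRRNA = "rrnS", "12SRRNA" = "rrnS",
    MTORF = "m-ORF", MORF = "m-ORF", ORF = "m-ORF", FORF = "f-ORF")
  tab
})

#' Construct a genome feature
#'
#' @param kind `"CDS"`, `"rRNA"`, `"tRNA"` or `"other"`.
#' @param name gene label; normalized with [normalizeGeneName()] unless
#'   `normalize = FALSE`.
#' @param strand `+1` or `-1`.
#' @param segments integer matrix (rows `start`, `end`, 0-based half-open)
#'   or a length-2 vector for a single segment.
#' @param anticodon optional 3-mer (DNA sense) for tRNA features.
#' @param normalize normalize the name on construction?
#' @return a [MitoFeature-class].
#' @export
mitoFeature <- function(kind, name, strand, segments,
                        anticodon = NA_character_, normalize = TRUE) {
  if (is.null(dim(segments)))
    segments <- matrix(as.integer(segments), ncol = 2, byrow = TRUE)
  storage.mode(segments) <- "integer"
  colnames(segments) <- c("start", "end")
  if (normalize) name <- normalizeGeneName(name)
  new("MitoFeature", kind = kind, name = name,
      strand = as.integer(strand), segments = segments,
      anticodon = toupper(anticodon))
}

#' Construct an annotated genome
#'
#' @param id accession-like identifier.
#' @param seq nucleotide string over `{A,C,G,T,N}`; upper-cased.
#' @param topology `"circular"` or `"linear"`.
#' @param features list of [MitoFeature-class]; sorted by start on
#'   construction.
#' @return an [AnnotatedGenome-class].
#' @export
annotatedGenome <- function(id, seq, topology = "circular",
                            features = list()) {
  seq <- toupper(seq)
  if (length(features)) {
    starts <- vapply(features, function(f) f@segments[1, 1], 0)
    features <- features[order(starts)]
  }
  new("AnnotatedGenome", id = id, seq = seq, topology = topology,
      features = features)
}

## ---- GenBank parsing ----------------------------------------------------

.parse_location <- function(loc, lineno) {
  strand <- 1L
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc))
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  segs <- t(vapply(parts, function(p) {
    p <- trimws(p)
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      ab <- as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^[0-9]+$", p)) {
      ab <- c(as.integer(p), as.integer(p))
    } else {
      stop(sprintf("malformed location '%s' at line %d", p, lineno),
           call. = FALSE)
    }
    c(ab[1] - 1L, ab[2])  # 1-based inclusive -> 0-based half-open
  }, integer(2)))
  dimnames(segs) <- list(NULL, c("start", "end"))
  # minus-strand joins are written in genome order; transcription order is
  # the reverse
  if (strand == -1L && nrow(segs) > 1L) segs <- segs[nrow(segs):1, , drop = FALSE]
  list(strand = strand, segments = segs)
}

.qual_value <- function(quals, key) {
  i <- grep(paste0("^/", key, "="), quals)
  if (!length(i)) return(NA_character_)
  v <- sub(paste0("^/", key, "="), "", quals[i[1]])
  gsub('^"|"$', "", v)
}

#' Read a GenBank flat file
#'
#' Parses `LOCUS` (length and topology), the `FEATURES` table (CDS, tRNA,
#' rRNA and other features, including `join`/`complement` locations) and
#' the `ORIGIN` sequence block. GenBank 1-based inclusive coordinates are
#' converted to the internal 0-based half-open convention, and gene labels
#' are passed through [normalizeGeneName()].
#'
#' @param file path to a GenBank flat file, or a character vector of its
#'   lines.
#' @return an [AnnotatedGenome-class].
#' @seealso [writeGenBank()], [featureTable()]
#' @export
readGenBank <- function(file) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    readLines(file) else unlist(strsplit(file, "\n", fixed = TRUE))
  iloc <- grep("^LOCUS", lines)
  if (!length(iloc)) stop("malformed record: no LOCUS line (line 1)")
  locus <- lines[iloc[1]]
  toks <- strsplit(trimws(locus), "[[:space:]]+")[[1]]
  id <- toks[2]
  topo <- if (any(tolower(toks) == "circular")) "circular" else "linear"
  ifeat <- grep("^FEATURES", lines)
  iorig <- grep("^ORIGIN", lines)
  if (!length(iorig)) stop("malformed record: no ORIGIN block")

  # sequence
  seq_lines <- lines[(iorig[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (grepl("[^ACGTN]", seq))
    stop("sequence contains IUPAC ambiguity codes other than N")
  L <- nchar(seq)

  feats <- list()
  if (length(ifeat)) {
    block <- lines[(ifeat[1] + 1L):(iorig[1] - 1L)]
    lnos <- (ifeat[1] + 1L):(iorig[1] - 1L)
    # group physical lines into feature entries
    is_key <- grepl("^ {1,10}[A-Za-z_'-]+ {2,}", block) &
      !grepl("^ {12,}", block)
    entry <- cumsum(is_key)
    for (e in unique(entry[entry > 0])) {
      el <- block[entry == e]
      eln <- lnos[entry == e][1]
      key <- sub("^ +([A-Za-z_'-]+).*", "\\1", el[1])
      if (key %in% c("source", "gene")) next
      rest <- trimws(sub("^ +[A-Za-z_'-]+ +", "", el[1]))
      body <- trimws(el[-1])
      # location may continue over lines until the first qualifier
      qual_start <- grep("^/", body)
      nq <- if (length(qual_start)) qual_start[1] - 1L else length(body)
      loc <- paste0(rest, paste(body[seq_len(nq)], collapse = ""))
      quals <- if (length(qual_start)) body[qual_start[1]:length(body)]
               else character()
      parsed <- .parse_location(loc, eln)
      kind <- switch(key, CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA", "other")
      nm <- .qual_value(quals, "gene")
      if (is.na(nm)) nm <- .qual_value(quals, "product")
      if (is.na(nm)) nm <- .qual_value(quals, "note")
      if (is.na(nm)) nm <- key
      anti <- .qual_value(quals, "anticodon")
      if (!is.na(anti)) {
        m <- regmatches(anti, regexec("seq:([acgtACGT]{3})", anti))[[1]]
        anti <- if (length(m)) toupper(m[2])
                else if (grepl("^[acgtACGT]{3}$", anti)) toupper(anti)
                else NA_character_
      }
      segs <- parsed$segments
      if (any(segs[, 2] > L)) {
        stop(sprintf("feature '%s' exceeds sequence length %d (line %d)",
                     nm, L, eln))
      }
      # a join stepping backwards marks an origin-spanning feature
      fwd <- if (parsed$strand == 1L) segs else segs[nrow(segs):1, , drop = FALSE]
      if (nrow(fwd) > 1L && any(diff(fwd[, 1]) < 0) && topo != "circular")
        stop(sprintf("origin-spanning feature '%s' on a linear genome (line %d)",
                     nm, eln))
      feats[[length(feats) + 1L]] <-
        mitoFeature(kind, nm, parsed$strand, segs, anticodon = anti)
    }
  }
  annotatedGenome(id, seq, topo, feats)
}

.format_location <- function(f) {
  segs <- f@segments
  if (f@strand == -1L && nrow(segs) > 1L)
    segs <- segs[nrow(segs):1, , drop = FALSE]  # back to genome order
  parts <- apply(segs, 1, function(s) sprintf("%d..%d", s[1] + 1L, s[2]))
  loc <- if (length(parts) > 1L)
    sprintf("join(%s)", paste(parts, collapse = ",")) else parts
  if (f@strand == -1L) sprintf("complement(%s)", loc) else loc
}

#' Write a GenBank flat file
#'
#' Emits a canonical record (LOCUS, FEATURES, ORIGIN) that [readGenBank()]
#' parses back to an identical genome; repeated write/read cycles are
#' byte-stable.
#'
#' @param genome an [AnnotatedGenome-class].
#' @param file optional path; if `NULL` the lines are returned invisibly.
#' @return character vector of lines, invisibly.
#' @export
writeGenBank <- function(genome, file = NULL) {
  L <- nchar(genome@seq)
  out <- sprintf("LOCUS       %s %d bp    DNA     %s MITO",
                 genome@id, L, genome@topology)
  out <- c(out, "FEATURES             Location/Qualifiers")
  for (f in genome@features) {
    key <- switch(f@kind, CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  "misc_feature")
    out <- c(out, sprintf("     %-16s%s", key, .format_location(f)))
    qkey <- if (f@kind == "other") "note" else "gene"
    out <- c(out, sprintf('                     /%s="%s"', qkey, f@name))
    if (!is.na(f@anticodon))
      out <- c(out, sprintf('                     /anticodon="%s"',
                            f@anticodon))
  }
  out <- c(out, "ORIGIN")
  starts <- seq(1L, L, by = 60L)
  out <- c(out, vapply(starts, function(s) {
    chunk <- substr(genome@seq, s, min(s + 59L, L))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    sprintf("%9d %s", s, tolower(paste(groups, collapse = " ")))
  }, character(1)))
  out <- c(out, "//")
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' Read/write genome sequences as FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()]; FASTA carries no annotations, so reading
#' yields genomes without features.
#'
#' @param file FASTA path.
#' @param topology topology to assign on read.
#' @return `readGenomeFasta`: list of [AnnotatedGenome-class].
#' @export
readGenomeFasta <- function(file, topology = "circular") {
  ss <- Biostrings::readDNAStringSet(file)
  lapply(seq_along(ss), function(i)
    annotatedGenome(sub(" .*", "", names(ss)[i]), as.character(ss[[i]]),
                    topology))
}

#' @rdname readGenomeFasta
#' @param genomes list of [AnnotatedGenome-class] (or a single genome).
#' @export
writeGenomeFasta <- function(genomes, file) {
  if (is(genomes, "AnnotatedGenome")) genomes <- list(genomes)
  ss <- Biostrings::DNAStringSet(vapply(genomes, genomeSeq, ""))
  names(ss) <- vapply(genomes, genomeId, "")
  Biostrings::writeXStringSet(ss, file)
  invisible(file)
}

#' Tabulate genome features
#'
#' @param genome an [AnnotatedGenome-class].
#' @return data.frame with `id`, `kind`, `name`, `strand`, `segments`
#'   (1-based inclusive, `start..end` joined by `+` in transcription order)
#'   and `anticodon`.
#' @export
featureTable <- function(genome) {
  rows <- lapply(genome@features, function(f) {
    segs <- paste(apply(f@segments, 1, function(s)
      sprintf("%d..%d", s[1] + 1L, s[2])), collapse = "+")
    data.frame(id = genome@id, kind = f@kind, name = f@name,
               strand = f@strand, segments = segs,
               anticodon = f@anticodon, stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(id = character(), kind = character(),
                      name = character(), strand = integer(),
                      segments = character(), anticodon = character()))
  do.call(rbind, rows)
}

## ---- sequence operations ------------------------------------------------

#' Reverse complement of a nucleotide string
#'
#' @param s nucleotide string over `{A,C,G,T,N}` (case preserved as upper).
#' @return reverse-complemented string.
#' @export
revComp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Extract the transcript sequence of a feature
#'
#' Segments are concatenated in transcription order; for minus-strand
#' features the reverse complement of the concatenation is returned.
#' Origin-spanning features of circular genomes are represented as split
#' segments and concatenate across the origin.
#'
#' @param genome an [AnnotatedGenome-class].
#' @param feature a [MitoFeature-class] belonging to `genome`, or a gene
#'   name to look up.
#' @return nucleotide string.
#' @export
extractFeatureSeq <- function(genome, feature) {
  if (is.character(feature)) {
    hit <- Filter(function(f) f@name == feature, genome@features)
    if (!length(hit))
      stop(sprintf("genome %s has no feature named '%s'",
                   genome@id, feature))
    feature <- hit[[1]]
  }
  L <- nchar(genome@seq)
  if (any(feature@segments[, 2] > L))
    stop("feature coordinates exceed genome length")
  pieces <- apply(feature@segments, 1, function(s)
    substr(genome@seq, s[1] + 1L, s[2]))
  s <- paste(pieces, collapse = "")
  if (feature@strand == -1L) revComp(s) else s
}

#' Translate a mitochondrial coding sequence
#'
#' Translation defaults to the invertebrate mitochondrial code (NCBI
#' transl_table 5: `AGA`/`AGG` = Ser, `ATA` = Met, `TGA` = Trp). A trailing
#' 1-2 nt remainder is dropped with a warning and flagged; internal stop
#' codons are kept as `*` and flagged; codons containing `N` translate to
#' `X`.
#'
#' @param nt nucleotide string, length >= 3, over `{A,C,G,T,N}`.
#' @param code NCBI genetic code id (default `"5"`).
#' @return amino-acid string with logical attributes `remainder` and
#'   `internal_stop`.
#' @examples
#' translateMito("ATAAGATGA")  # "MSW"
#' @export
translateMito <- function(nt, code = "5") {
  nt <- toupper(nt)
  if (grepl("[^ACGTN]", nt))
    stop("sequence contains characters outside {A,C,G,T,N}")
  n <- nchar(nt)
  if (n < 3L) stop("need at least one full codon")
  rem <- n %% 3L
  if (rem) warning(sprintf("dropping %d trailing nucleotide(s)", rem))
  gc <- Biostrings::getGeneticCode(code)
  starts <- seq(1L, n - rem, by = 3L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  out <- paste(aa, collapse = "")
  internal <- grepl("\\*", substr(out, 1L, nchar(out) - 1L))
  structure(out, remainder = rem > 0L, internal_stop = internal)
}

#' Rotate a circular genome to a new origin
#'
#' The sequence is rotated so that position `shift` (0-based) becomes
#' position 0, and all feature coordinates are shifted accordingly;
#' features that come to span the new origin are split into two segments.
#' Feature transcript sequences are invariant under rotation.
#'
#' @param genome a circular [AnnotatedGenome-class].
#' @param shift 0-based position of the new origin.
#' @return rotated [AnnotatedGenome-class].
#' @export
rotateGenome <- function(genome, shift) {
  if (genome@topology != "circular")
    stop("only circular genomes can be rotated")
  L <- nchar(genome@seq)
  shift <- ((shift %% L) + L) %% L
  if (shift == 0L) return(genome)
  seq2 <- paste0(substr(genome@seq, shift + 1L, L),
                 substr(genome@seq, 1L, shift))
  feats <- lapply(genome@features, function(f) {
    segs <- f@segments
    newsegs <- list()
    for (r in seq_len(nrow(segs))) {
      s <- (segs[r, 1] - shift) %% L
      e <- s + (segs[r, 2] - segs[r, 1])
      if (e <= L) newsegs[[length(newsegs) + 1L]] <- c(s, e)
      else {
        newsegs[[length(newsegs) + 1L]] <- c(s, L)
        newsegs[[length(newsegs) + 1L]] <- c(0L, e - L)
      }
    }
    mitoFeature(f@kind, f@name, f@strand,
                matrix(as.integer(unlist(newsegs)), ncol = 2, byrow = TRUE),
                anticodon = f@anticodon, normalize = FALSE)
  })
  annotatedGenome(genome@id, seq2, "circular", feats)
}

# look up features by name (exact, normalized)
.find_features <- function(genome, name) {
  Filter(function(f) f@name == name, genome@features)
}
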