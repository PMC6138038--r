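## Partitioned supermatrix construction and NEXUS / relaxed PHYLIP /
## RAxML-style export.

.guess_datatype <- function(rows) {
  chars <- unique(strsplit(paste(toupper(rows), collapse = ""), "")[[1]])
  chars <- setdiff(chars, c("-", "?", "N", "X", "*"))
  if (all(chars %in% c("A", "C", "G", "T", "U"))) "nt" else "aa"
}

# split a Supermatrix back into its per-partition alignments
.expand_partitions <- function(sm) {
  p <- sm@partitions
  out <- lapply(seq_len(nrow(p)), function(i)
    substr(sm@seqs, p$start[i], p$end[i]))
  names(out) <- p$name
  attr(out, "datatype") <- p$datatype
  out
}

#' Concatenate alignments into a partitioned supermatrix
#'
#' Each input alignment becomes one partition, in input order. Row names
#' are first mapped to species-level taxon keys via `taxon_map`, so that
#' e.g. the M and F records of one species can share a taxon set. Under
#' `taxon_policy = "strict"` every taxon must be present in every
#' partition; under `"pad"` missing rows are filled with gaps.
#'
#' @param alignments named list; each element a named character vector of
#'   equal-length rows, or a [Supermatrix-class] whose partitions are
#'   spliced in (making concatenation associative).
#' @param taxon_policy `"strict"` or `"pad"`.
#' @param datatype optional character vector (`"nt"`/`"aa"`) per
#'   alignment; guessed from the alphabet when omitted.
#' @param taxon_map optional named character vector mapping row names to
#'   taxon keys.
#' @return a [Supermatrix-class].
#' @export
concatenateAlignments <- function(alignments,
                                  taxon_policy = c("strict", "pad"),
                                  datatype = NULL, taxon_map = NULL) {
  taxon_policy <- match.arg(taxon_policy)
  # Supermatrix elements carry their own partition names; all others need one
  needs_name <- !vapply(alignments, is, logical(1), "Supermatrix")
  nm <- names(alignments)
  if (any(needs_name) &&
      (is.null(nm) || any(nm[needs_name] == "")))
    stop("alignments must be a named list (partition names)")
  # splice nested supermatrices
  flat <- list(); dts <- character()
  for (i in seq_along(alignments)) {
    el <- alignments[[i]]
    if (is(el, "Supermatrix")) {
      sub <- .expand_partitions(el)
      flat <- c(flat, sub)
      dts <- c(dts, attr(sub, "datatype"))
    } else {
      flat[[names(alignments)[i]]] <- el
      dts <- c(dts, if (!is.null(datatype)) datatype[i]
               else .guess_datatype(el))
    }
  }
  if (anyDuplicated(names(flat)))
    stop("duplicate partition names: ",
         paste(unique(names(flat)[duplicated(names(flat))]), collapse = ", "))
  flat <- lapply(flat, function(a) {
    if (length(unique(nchar(a))) != 1L)
      stop("all rows of a partition must have equal length")
    if (!is.null(taxon_map)) {
      hit <- taxon_map[names(a)]
      names(a)[!is.na(hit)] <- hit[!is.na(hit)]
    }
    if (anyDuplicated(names(a))) stop("duplicate taxa within one partition")
    a
  })
  taxa <- sort(unique(unlist(lapply(flat, names))))
  widths <- vapply(flat, function(a) nchar(a[[1]]), 0L)
  seqs <- setNames(rep("", length(taxa)), taxa)
  for (i in seq_along(flat)) {
    a <- flat[[i]]
    missing <- setdiff(taxa, names(a))
    if (length(missing)) {
      if (taxon_policy == "strict")
        stop(sprintf("taxon %s absent from partition '%s'",
                     paste(missing, collapse = ", "), names(flat)[i]))
      a[missing] <- strrep("-", widths[i])
    }
    seqs <- paste0(seqs, a[taxa])
  }
  names(seqs) <- taxa
  ends <- cumsum(widths)
  parts <- data.frame(name = names(flat), datatype = dts,
                      start = as.integer(c(1L, head(ends, -1) + 1L)),
                      end = as.integer(ends), stringsAsFactors = FALSE)
  new("Supermatrix", taxa = taxa, seqs = seqs, partitions = parts)
}

#' Export a supermatrix
#'
#' Formats: `"nexus"` (data block plus `charset` lines, 1-based inclusive;
#' mixed nt+aa matrices use a `datatype=mixed(...)` format line),
#' `"phylip"` (relaxed PHYLIP; refused for mixed datatypes, which the
#' format cannot express) and `"raxml"` (RAxML-style partition file only).
#'
#' @param sm a [Supermatrix-class].
#' @param format `"nexus"`, `"phylip"` or `"raxml"`.
#' @param file optional output path.
#' @return character vector of lines, invisibly when `file` is given.
#' @export
exportSupermatrix <- function(sm, format = c("nexus", "phylip", "raxml"),
                              file = NULL) {
  format <- match.arg(format)
  p <- sm@partitions
  total <- max(p$end)
  mixed <- length(unique(p$datatype)) > 1L
  out <- switch(format,
    nexus = {
      dt <- if (mixed) {
        sprintf("mixed(%s)", paste(sprintf("%s:%d-%d",
          ifelse(p$datatype == "aa", "protein", "dna"),
          p$start, p$end), collapse = ","))
      } else if (p$datatype[1] == "aa") "protein" else "dna"
      c("#NEXUS",
        "begin data;",
        sprintf("  dimensions ntax=%d nchar=%d;", length(sm@taxa), total),
        sprintf("  format datatype=%s gap=- missing=?;", dt),
        "  matrix",
        sprintf("    %s  %s", format(sm@taxa,
                                     width = max(nchar(sm@taxa))),
                sm@seqs[sm@taxa]),
        "  ;",
        "end;",
        "begin sets;",
        sprintf("  charset %s = %d-%d;", p$name, p$start, p$end),
        "end;")
    },
    phylip = {
      if (mixed)
        stop(paste("relaxed PHYLIP cannot express mixed nt+aa matrices;",
                   "use NEXUS instead"))
      c(sprintf("%d %d", length(sm@taxa), total),
        sprintf("%s  %s", format(sm@taxa, width = max(nchar(sm@taxa))),
                sm@seqs[sm@taxa]))
    },
    raxml = sprintf("%s, %s = %d-%d",
                    ifelse(p$datatype == "aa", "AA", "DNA"),
                    p$name, p$start, p$end))
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

#' Read back a NEXUS supermatrix written by [exportSupermatrix()]
#'
#' Parses the data block and charset lines into a [Supermatrix-class];
#' export followed by import reproduces the object exactly.
#'
#' @param file NEXUS path or character vector of lines.
#' @return a [Supermatrix-class].
#' @export
readNexusSupermatrix <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file)
           else file
  if (!grepl("^#NEXUS", lines[1])) stop("not a NEXUS file")
  fmt <- grep("^\\s*format", lines, value = TRUE)[1]
  dtspec <- sub(".*datatype=([^ ;]+).*", "\\1", fmt)
  im <- grep("^\\s*matrix\\s*$", lines)
  iend <- grep("^\\s*;\\s*$", lines)
  iend <- iend[iend > im][1]
  rows <- trimws(lines[(im + 1L):(iend - 1L)])
  rows <- rows[nzchar(rows)]
  toks <- strsplit(rows, "\\s+")
  seqs <- setNames(vapply(toks, `[`, "", 2), vapply(toks, `[`, "", 1))
  cs <- grep("charset", lines, value = TRUE)
  cname <- sub("^\\s*charset\\s+(\\S+)\\s*=.*", "\\1", cs)
  crange <- sub(".*=\\s*([0-9]+)-([0-9]+);.*", "\\1 \\2", cs)
  se <- do.call(rbind, lapply(strsplit(crange, " "), as.integer))
  dts <- if (grepl("^mixed", dtspec)) {
    inner <- sub("^mixed\\((.*)\\)$", "\\1", dtspec)
    specs <- strsplit(inner, ",")[[1]]
    sstart <- as.integer(sub(".*:([0-9]+)-[0-9]+", "\\1", specs))
    stype <- ifelse(grepl("^protein", specs), "aa", "nt")
    stype[match(se[, 1], sstart)]
  } else if (dtspec == "protein") rep("aa", length(cname))
    else rep("nt", length(cname))
  new("Supermatrix", taxa = sort(names(seqs)), seqs = seqs,
      partitions = data.frame(name = cname, datatype = dts,
                              start = se[, 1], end = se[, 2],
                              stringsAsFactors = FALSE))
}
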