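# Shared fixtures: a compact genome template for fast simulations, clean
# gene-alignment builders, and the brute-force oracle for the
# frameshift-aware dynamic program.

# ~1.2 kb template: enough gene variety for io/curation/structure tests
small_template <- function() {
  g <- function(name, kind, strand, length, spacer = 4L)
    data.frame(name = name, kind = kind, strand = strand,
               length = as.integer(length),
               spacer_after = as.integer(spacer), stringsAsFactors = FALSE)
  rbind(g("cox1", "CDS", 1L, 300L), g("trnM", "tRNA", 1L, 68L),
        g("cox2", "CDS", 1L, 210L), g("nad1", "CDS", -1L, 150L),
        g("trnP", "tRNA", -1L, 68L), g("rrnS", "rRNA", 1L, 200L),
        g("m-ORF", "CDS", 1L, 120L), g("trnD", "tRNA", 1L, 68L))
}

sim_small <- function(seed = 1L, tree = "((A:0.02,B:0.02):0.02,C:0.04);",
                      rate_m = 3, stem = 0.1, ...) {
  simulateMitogenomes(simulationParams(tree, rate_m = rate_m,
                                       lineage_stem = stem,
                                       template = small_template(),
                                       seed = seed, ...))
}

# nt CDS rows plus the matching clean protein rows; the final codon is
# dropped uniformly (not stop-stripped) so substitutions at a stop codon
# cannot change row lengths
clean_gene_rows <- function(genomes, gene) {
  nt <- vapply(genomes, function(g) extractFeatureSeq(g, gene), "")
  aa <- vapply(nt, function(x)
    as.character(suppressWarnings(
      translateMito(substr(x, 1, nchar(x) - 3L)))), "")
  names(aa) <- names(nt)
  list(nt = nt, aa = aa)
}

random_dna <- function(n, seed, freqs = c(0.25, 0.25, 0.25, 0.25)) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = freqs),
        collapse = "")
}

random_profile <- function(C, seed) {
  set.seed(seed)
  rows <- vapply(seq_len(max(2L, C)), function(i)
    paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], C,
                 replace = TRUE), collapse = ""), "")
  names(rows) <- paste0("t", seq_along(rows))
  buildProfile(rows)
}

# exact DNA back-translation of an amino-acid string under table 5,
# choosing the first codon for each residue
back_translate <- function(aa, code = "5") {
  gc <- Biostrings::getGeneticCode(code)
  vapply(strsplit(aa, "")[[1]], function(a) names(gc)[gc == a][1], "") |>
    paste(collapse = "")
}

# Brute-force maximum over all frameshift-aware move sequences; written as
# direct path enumeration, independent of the DP kernel.
fs_oracle_score <- function(dna, profile, fs_penalty = -12,
                            gap_open = profile@gapOpen,
                            gap_extend = profile@gapExtend,
                            stop_score = -8, code = "5") {
  gc <- Biostrings::getGeneticCode(code)
  scores <- profile@scores
  n <- nchar(dna)
  C <- ncol(scores)
  colsc <- function(p, j) {
    cod <- substr(dna, p, p + 2L)
    if (grepl("N", cod)) return(0)
    aa <- gc[[cod]]
    if (aa == "*") return(stop_score)
    unname(scores[aa, j])
  }
  best <- -Inf
  rec <- function(i, j, state, acc) {
    if (i == n && j == C) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    if (j < C) {
      if (i + 3L <= n) rec(i + 3L, j + 1L, "M", acc + colsc(i + 1L, j + 1L))
      if (i + 4L <= n)
        rec(i + 4L, j + 1L, "M", acc + fs_penalty + colsc(i + 1L, j + 1L))
      if (i + 2L <= n) rec(i + 2L, j + 1L, "M", acc + fs_penalty)
      rec(i, j + 1L, "D",
          acc + if (state == "D") gap_extend else gap_open)
    }
    if (i + 3L <= n)
      rec(i + 3L, j, "I", acc + if (state == "I") gap_extend else gap_open)
  }
  rec(0L, 0L, "M", 0)
  best
}

# small literal GenBank record exercising joins, complement, anticodon
# qualifier and multi-line ORIGIN
genbank_fixture_text <- function() {
  c("LOCUS       FIX01 120 bp    DNA     circular MITO",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    '                     /organism="synthetic"',
    "     CDS             1..30",
    '                     /gene="COI"',
    "     tRNA            complement(31..60)",
    '                     /gene="tRNA-Met"',
    "                     /anticodon=(pos:complement(44..46),aa:Met,seq:cat)",
    "     rRNA            join(101..120,1..20)",
    '                     /product="16S"',
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    paste0("       61 ", paste(rep("ggatccggat", 6), collapse = " ")),
    "//")
}
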