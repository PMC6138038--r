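# GenBank parsing/writing, coordinate conventions, feature extraction and
# mitochondrial translation.

test_that("GenBank coordinates, strands and qualifiers parse correctly", {
  g <- readGenBank(genbank_fixture_text())
  expect_s4_class(g, "AnnotatedGenome")
  expect_identical(genomeId(g), "FIX01")
  expect_identical(topology(g), "circular")
  expect_identical(nchar(genomeSeq(g)), 120L)
  expect_length(features(g), 3L)

  cds <- features(g)[[1]]
  expect_identical(cds@kind, "CDS")
  expect_identical(cds@name, "cox1")       # COI normalized
  expect_equal(unname(cds@segments[1, ]), c(0L, 30L))

  trn <- features(g)[[2]]
  expect_identical(trn@strand, -1L)
  expect_identical(trn@name, "trnM")
  expect_identical(trn@anticodon, "CAT")   # from (pos:...,seq:cat)

  rrn <- features(g)[[3]]
  expect_identical(rrn@name, "rrnL")       # 16S normalized
  expect_equal(nrow(rrn@segments), 2L)     # origin-spanning join
  expect_identical(sum(rrn@segments[, 2] - rrn@segments[, 1]), 40L)
})

test_that("origin-spanning features are rejected on linear genomes", {
  lines <- genbank_fixture_text()
  lines[1] <- "LOCUS       FIX01 120 bp    DNA     linear MITO"
  expect_error(readGenBank(lines), "linear")
})

test_that("features exceeding the sequence raise a coordinate error", {
  lines <- c("LOCUS       BAD 10 bp DNA linear",
             "FEATURES             Location/Qualifiers",
             "     CDS             1..30",
             '                     /gene="x"',
             "ORIGIN",
             "        1 acgtacgtac",
             "//")
  expect_error(readGenBank(lines), "exceeds sequence length")
})

test_that("write/read round trip preserves sequence and features exactly", {
  sim <- sim_small(seed = 11)
  g <- sim$M$A
  g2 <- readGenBank(writeGenBank(g))
  expect_identical(genomeSeq(g2), genomeSeq(g))
  expect_identical(topology(g2), topology(g))
  expect_identical(length(features(g2)), length(features(g)))
  for (i in seq_along(features(g))) {
    expect_identical(features(g2)[[i]]@segments, features(g)[[i]]@segments)
    expect_identical(features(g2)[[i]]@strand, features(g)[[i]]@strand)
    expect_identical(features(g2)[[i]]@name, features(g)[[i]]@name)
  }
  # and the writer is byte-stable under re-reading
  expect_identical(writeGenBank(readGenBank(writeGenBank(g))),
                   writeGenBank(g))
})

test_that("feature extraction honours strand, order and circular wrap", {
  lin <- annotatedGenome("x", "AACGTTAA", "linear")
  plus <- mitoFeature("CDS", "g", 1L, c(2, 6))
  minus <- mitoFeature("CDS", "g", -1L, c(2, 6))
  expect_identical(extractFeatureSeq(lin, plus), "CGTT")
  expect_identical(extractFeatureSeq(lin, minus), "AACG")
  expect_identical(extractFeatureSeq(lin, plus),
                   revComp(extractFeatureSeq(lin, minus)))

  circ <- annotatedGenome("y", "AAACCC", "circular")
  wrap <- mitoFeature("CDS", "g", 1L,
                      matrix(c(4L, 6L, 0L, 2L), ncol = 2, byrow = TRUE))
  expect_identical(extractFeatureSeq(circ, wrap), "CCAA")
})

test_that("extracted feature sequences are invariant under rotation", {
  g <- sim_small(seed = 3)$F$A
  ref <- vapply(features(g), function(f) extractFeatureSeq(g, f), "")
  for (shift in c(1L, 137L, 700L, nchar(genomeSeq(g)) - 5L)) {
    r <- rotateGenome(g, shift)
    nm <- vapply(features(r), function(f) f@name, "")
    got <- vapply(features(r), function(f) extractFeatureSeq(r, f), "")
    refnm <- vapply(features(g), function(f) f@name, "")
    expect_setequal(paste(nm, got), paste(refnm, ref))
  }
})

test_that("mitochondrial translation follows table 5 and flags anomalies", {
  expect_identical(as.character(translateMito("ATAAGATGA")), "MSW")
  expect_warning(translateMito("ATGAAAT"), "trailing")
  out <- suppressWarnings(translateMito("ATGAAAT"))
  expect_identical(as.character(out), "MK")
  expect_true(attr(out, "remainder"))
  out2 <- translateMito("ATGTAAATG")
  expect_identical(as.character(out2), "M*M")
  expect_true(attr(out2, "internal_stop"))
  expect_false(attr(out2, "remainder"))
  expect_error(translateMito("ATGRAT"), "outside")
  expect_error(translateMito("AT"), "codon")
})

test_that("gene name normalization maps common aliases", {
  expect_identical(
    normalizeGeneName(c("COI", "CO2", "ND4L", "16S", "12S rRNA",
                        "MT-ORF", "morf", "tRNA-Met", "trnSer2", "CYTB")),
    c("cox1", "cox2", "nad4L", "rrnL", "rrnS",
      "m-ORF", "m-ORF", "trnM", "trnS", "cob"))
})

test_that("FASTA export/import and feature tables work", {
  g <- sim_small(seed = 5)$F$B
  fa <- tempfile(fileext = ".fa")
  writeGenomeFasta(g, fa)
  back <- readGenomeFasta(fa)[[1]]
  expect_identical(genomeSeq(back), genomeSeq(g))
  expect_identical(genomeId(back), genomeId(g))

  tab <- featureTable(g)
  expect_identical(nrow(tab), length(features(g)))
  expect_true(all(c("kind", "name", "strand", "segments") %in% names(tab)))
  expect_match(tab$segments[1], "^[0-9]+\\.\\.[0-9]+$")
})
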