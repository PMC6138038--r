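# Dual-space consistency screening, profile building, frameshift-aware
# recovery alignment and gap-column stripping.

test_that("clean back-translations pass the dual-space screen", {
  sim <- sim_small(seed = 31)
  rows <- clean_gene_rows(sim$F, "cox2")
  rep <- dualSpaceConsistency(rows$nt, rows$aa)
  expect_true(all(rep$verdict == "clean"))
  expect_true(all(rep$evidence == 0L))
  expect_identical(attr(rep, "threshold"), 5L)
})

test_that("a single-nt frameshift makes exactly that taxon suspicious", {
  sim <- sim_small(seed = 32)
  rows <- clean_gene_rows(sim$F, "cox2")
  mut <- injectFrameshift(sim$F$B, "cox2", offset = 60, kind = "delete")
  rows$nt["B"] <- extractFeatureSeq(mut, "cox2")
  rep <- dualSpaceConsistency(rows$nt, rows$aa)
  expect_identical(rep$verdict[rep$taxon == "B"], "suspicious")
  expect_true(rep$evidence[rep$taxon == "B"] >= 5L)
  expect_true(all(rep$verdict[rep$taxon != "B"] == "clean"))
  cur <- curateGeneAlignment(rows$nt, rows$aa)
  expect_false("B" %in% names(cur$aa_alignment))
})

test_that("an in-frame 3-nt deletion stays clean", {
  sim <- sim_small(seed = 33)
  rows <- clean_gene_rows(sim$F, "cox2")
  # remove codon 11 from taxon C in both spaces (a gap in its aa row)
  nt <- rows$nt[["C"]]
  rows$nt["C"] <- paste0(substr(nt, 1, 30), substr(nt, 34, nchar(nt)))
  aa <- rows$aa[["C"]]
  rows$aa["C"] <- paste0(substr(aa, 1, 10), "-",
                         substr(aa, 12, nchar(aa)))
  rep <- dualSpaceConsistency(rows$nt, rows$aa)
  expect_true(all(rep$verdict == "clean"))
})

test_that("irreconcilable lengths are suspicious; taxon mismatch errors", {
  rows <- list(nt = c(a = "ATGAAATTT", b = "ATGAAATTT"),
               aa = c(a = "MKF", b = "MKF"))
  rows$nt["b"] <- "ATGAAATTTCCCGGG"          # 5 codons vs 3 residues
  rep <- dualSpaceConsistency(rows$nt, rows$aa)
  expect_identical(rep$verdict[rep$taxon == "b"], "suspicious")
  expect_false(rep$length_ok[rep$taxon == "b"])
  expect_error(dualSpaceConsistency(c(a = "ATG"), c(x = "M")), "taxon sets")
})

test_that("profile construction follows counts, gap rule and tie-breaks", {
  p1 <- buildProfile(c(a = "MKV"))
  expect_identical(ncol(p1@scores), 3L)
  expect_identical(consensus(p1), "MKV")

  rows5 <- c(a = "MAAAA", b = "MCCCC", c = "MDDDD", d = "MEEEE", e = "MFFFF")
  p5 <- buildProfile(rows5)
  expect_identical(substr(consensus(p5), 1, 1), "M")
  # tie among A,C,D,E,F in column 2 resolves alphabetically
  expect_identical(substr(consensus(p5), 2, 2), "A")

  # 10 columns, 6 rows, 2 columns gapped in 4/6 rows -> dropped
  base <- strrep("M", 10)
  gapped <- paste0("M", "-", strrep("M", 6), "-", "M")
  rows6 <- c(r1 = base, r2 = base, r3 = gapped, r4 = gapped,
             r5 = gapped, r6 = gapped)
  p6 <- buildProfile(rows6)
  expect_identical(ncol(p6@scores), 8L)
  expect_identical(sum(attr(p6, "column_mask")), 8L)

  expect_error(buildProfile(character()), "empty")
  # log-odds sanity: observed residue scores above background
  expect_true(p1@scores["M", 1] > 0)
  expect_true(all(is.finite(p5@scores)))
})

test_that("exact back-translations align to the consensus without events", {
  prof <- buildProfile(c(a = "MKVLIFGW", b = "MKVLIFGW", c = "MKVLMFGW"))
  dna <- back_translate("MKVLIFGW")
  ra <- frameshiftAwareAlign(dna, prof)
  expect_identical(ra@aaRow, "MKVLIFGW")
  expect_identical(nrow(ra@frameshifts), 0L)
  expect_length(ra@insertAfterColumn, 0L)
})

test_that("an inserted nucleotide yields exactly one +1 frameshift event", {
  prof <- buildProfile(c(a = "MKVLIFGW"))
  dna <- back_translate("MKVLIFGW")
  dna2 <- paste0(substr(dna, 1, 9), "G", substr(dna, 10, nchar(dna)))
  ra <- frameshiftAwareAlign(dna2, prof)
  expect_identical(nrow(ra@frameshifts), 1L)
  expect_identical(ra@frameshifts$kind, 1L)
  # the +1 event is consumed by the 4-nt move covering codon 4
  expect_true(abs(ra@frameshifts$dna_position - 10) <= 3)
  expect_identical(ra@aaRow, "MKVLIFGW")
})

test_that("infinite frameshift penalty reduces to codon-level alignment", {
  prof <- buildProfile(c(a = "MKVLIFGW", b = "MKVLIFGW"))
  dna <- back_translate("MKVIFGW")              # one residue missing
  ra <- frameshiftAwareAlign(dna, prof, fs_penalty = -Inf)
  expect_identical(nrow(ra@frameshifts), 0L)
  expect_identical(gsub("-", "", ra@aaRow), "MKVIFGW")
  expect_identical(nchar(ra@aaRow), 8L)         # one deleted column
})

test_that("DP score matches the brute-force oracle on random instances", {
  cases <- expand.grid(C = 2:5, rep = 1:3)
  for (k in seq_len(nrow(cases))) {
    C <- cases$C[k]
    prof <- random_profile(C, seed = 900 + k)
    n <- sample(c(3 * C - 3, 3 * C - 1, 3 * C, 3 * C + 1, 3 * C + 2), 1)
    n <- max(3, min(18, n))
    dna <- random_dna(n, seed = 1000 + k)
    got <- frameshiftAwareAlign(dna, prof)@score
    want <- fs_oracle_score(dna, prof)
    expect_equal(got, want, info = sprintf("case C=%d n=%d", C, n))
  }
})

test_that("DP score is monotone in penalties", {
  prof <- random_profile(4, seed = 77)
  dna <- random_dna(13, seed = 78)
  s0 <- frameshiftAwareAlign(dna, prof, fs_penalty = -5,
                             gap_open = -5, gap_extend = -1)@score
  s1 <- frameshiftAwareAlign(dna, prof, fs_penalty = -20,
                             gap_open = -5, gap_extend = -1)@score
  s2 <- frameshiftAwareAlign(dna, prof, fs_penalty = -5,
                             gap_open = -15, gap_extend = -3)@score
  expect_true(s1 <= s0)
  expect_true(s2 <= s0)
})

test_that("gap-column stripping removes exactly the gapped columns", {
  aln <- c(a = "MKVLIF", b = "MKVLIF")
  out <- stripGapColumns(aln)
  expect_identical(out$alignment, aln)
  expect_identical(out$effective_length, 6L)

  aln2 <- c(a = "MKVLIF", b = "MK-LIF")
  out2 <- stripGapColumns(aln2)
  expect_identical(out2$effective_length, 5L)
  expect_identical(unname(out2$alignment[["a"]]), "MKLIF")
  # idempotent
  expect_identical(stripGapColumns(out2$alignment)$alignment, out2$alignment)

  aln3 <- c(a = "MKV", b = "---")
  expect_warning(out3 <- stripGapColumns(aln3), "effective length 0")
  expect_identical(out3$effective_length, 0L)
})
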