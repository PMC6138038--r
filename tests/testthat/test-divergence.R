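# Substitution counting, p-distances and the banded whole-genome aligner.

test_that("substitution counting ignores N and requires equal lengths", {
  expect_identical(countSubstitutions("ACGT", "ACGT"), 0L)
  expect_identical(countSubstitutions("ACGT", "ACGA"), 1L)
  expect_identical(countSubstitutions("ACGN", "ACTA"), 1L)
  expect_error(countSubstitutions("ACG", "ACGT"), "align")
})

test_that("p-distance uses pairwise deletion", {
  expect_equal(pDistance("ACGT", "ACGA"), 0.25)
  expect_equal(pDistance("AC-T", "ACGT"), 0)          # 3 compared sites
  expect_equal(pDistance("ACNT", "ACGA"), 1 / 3)
  expect_error(pDistance("----", "ACGT"), "comparable")
  expect_error(pDistance("ACG", "ACGT"), "equal length")
})

test_that("p-distance is symmetric, zero on identity and bounded", {
  for (seed in 1:10) {
    a <- random_dna(200, seed)
    b <- random_dna(200, seed + 100)
    expect_equal(pDistance(a, b), pDistance(b, a))
    expect_equal(pDistance(a, a), 0)
    expect_true(pDistance(a, b) >= 0 && pDistance(a, b) <= 1)
    expect_identical(countSubstitutions(a, b),
                     as.integer(round(pDistance(a, b) * 200)))
  }
})

test_that("sliding p-distance localizes a mutated block", {
  base <- random_dna(3000, seed = 1)
  v <- strsplit(base, "")[[1]]
  w <- v
  set.seed(2)
  block <- 1201:1500
  mut <- sample(block, 90)                       # 30% of the block
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  w[mut] <- rot[w[mut]]
  prof <- slidingPDistance(base, paste(w, collapse = ""),
                           window = 300, step = 25)
  r <- profileRecords(prof)
  inside <- r[r$column_start + 1 >= 1201 & r$column_start + 300 <= 1500, ]
  outside <- r[r$column_start + 300 < 1201 | r$column_start + 1 > 1500, ]
  expect_equal(inside$p_distance, 0.30)          # exactly the window over the block
  expect_true(all(outside$p_distance == 0))
})

test_that("zero-divergence pairs give all-zero windows", {
  s <- random_dna(1000, seed = 4)
  r <- profileRecords(slidingPDistance(s, s, 300, 25))
  expect_true(all(r$p_distance == 0))
  expect_true(all(r$compared_sites == 300L))
})

test_that("non-overlapping tiling reproduces the global p exactly", {
  for (seed in 1:10) {
    n <- 1200
    a <- random_dna(n, seed)
    v <- strsplit(a, "")[[1]]
    set.seed(seed + 500)
    i <- sample(n, 60)
    v[i] <- c(A = "G", C = "T", G = "A", T = "C")[v[i]]
    v[sample(n, 20)] <- "-"                      # some gap columns too
    b <- paste(v, collapse = "")
    prof <- slidingPDistance(a, b, window = 100, step = 100)
    r <- profileRecords(prof)
    ok <- !is.na(r$p_distance)
    expect_equal(sum(r$p_distance[ok] * r$compared_sites[ok]) /
                   sum(r$compared_sites[ok]),
                 prof@globalP)
    expect_equal(prof@globalP, pDistance(a, b))
  }
})

test_that("banded aligner agrees with Biostrings on similar pairs", {
  # gap of length k costs 9 + (k-1) here and 8 + k in Biostrings: identical
  for (seed in 1:6) {
    a <- random_dna(250, seed)
    v <- strsplit(a, "")[[1]]
    set.seed(seed + 50)
    v[sample(250, 12)] <- sample(c("A", "C", "G", "T"), 12, replace = TRUE)
    del <- sort(sample(250, 3))
    b <- paste(v[-del], collapse = "")
    ours <- alignGenomes(a, b, match = 1, mismatch = -1,
                         gap_open = -9, gap_extend = -1, band = 50)
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = TRUE)
    ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 8, gapExtension = 1)
    expect_equal(ours$score, Biostrings::score(ref))
    expect_identical(gsub("-", "", ours$aligned1), a)
    expect_identical(gsub("-", "", ours$aligned2), b)
  }
})

test_that("locus p-distance extracts, aligns and compares annotated genes", {
  sim <- sim_small(seed = 21)
  g1 <- sim$M$A; g2 <- sim$M$B
  expect_equal(locusPDistance(g1, g1, "cox1"), 0)
  p <- locusPDistance(g1, g2, "cox1")
  expect_true(p > 0 && p < 0.5)
  expect_error(locusPDistance(g1, g2, "cox99"), "not annotated")
})

test_that("whole-genome p-distance is rotation-invariant via cox1 anchoring", {
  sim <- sim_small(seed = 8)
  g1 <- sim$F$A; g2 <- sim$F$B
  p0 <- genomePDistance(g1, g2)
  p1 <- genomePDistance(rotateGenome(g1, 400), g2)
  expect_equal(p0, p1)
  expect_equal(p0, pDistance(genomeSeq(sim$F$A), genomeSeq(sim$F$B)),
               tolerance = 1e-6)
})
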