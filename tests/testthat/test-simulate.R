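# Simulator: determinism, composition control, substitution statistics and
# the explicit mutation injectors.

test_that("identical parameters and seed give byte-identical genomes", {
  s1 <- sim_small(seed = 5)
  s2 <- sim_small(seed = 5)
  for (lin in c("F", "M"))
    for (leaf in names(s1[[lin]]))
      expect_identical(genomeSeq(s1[[lin]][[leaf]]),
                       genomeSeq(s2[[lin]][[leaf]]))
  s3 <- sim_small(seed = 6)
  expect_false(identical(genomeSeq(s1$F$A), genomeSeq(s3$F$A)))
})

test_that("zero branch lengths and stem reproduce the root at every leaf", {
  sim <- sim_small(seed = 9, tree = "((A:0,B:0):0,C:0);", stem = 0)
  for (lin in c("F", "M"))
    for (leaf in c("A", "B", "C"))
      expect_identical(genomeSeq(sim[[lin]][[leaf]]), genomeSeq(sim$root))
})

test_that("root composition tracks the target frequencies", {
  p <- simulationParams("(A:0,B:0);", seed = 12)
  sim <- simulateMitogenomes(p)
  L <- nchar(genomeSeq(sim$root))
  expect_true(L >= 15000)
  target_skew <- (0.2295 - 0.4421) / (0.2295 + 0.4421)
  comp <- globalComposition(sim$root)
  expect_lt(abs(comp[["at_skew"]] - target_skew), 0.02)
  expect_lt(abs(comp[["gc_content"]] - 0.3284), 0.02)
})

test_that("per-branch substitution counts follow the binomial expectation", {
  L <- 15000L
  b <- 0.05
  root <- random_dna(L, seed = 99)
  p <- 1 - exp(-b)
  expected <- L * p
  sdev <- sqrt(L * p * (1 - p))
  counts <- vapply(1:5, function(s)
    countSubstitutions(root, evolveSequence(root, b, 1, seed = s)), 0L)
  expect_true(all(abs(counts - expected) < 3 * sdev))
})

test_that("template annotations are complete and coordinates consistent", {
  sim <- simulateMitogenomes(simulationParams("(A:0,B:0);", seed = 2))
  g <- sim$root
  kinds <- table(vapply(features(g), function(f) f@kind, ""))
  expect_identical(unname(kinds[["CDS"]]), 14L)   # 13 + m-ORF
  expect_identical(unname(kinds[["rRNA"]]), 2L)
  expect_identical(unname(kinds[["tRNA"]]), 22L)
  # every CDS translates from ATG without internal stops
  for (f in Filter(function(f) f@kind == "CDS", features(g))) {
    aa <- translateMito(extractFeatureSeq(g, f))
    expect_false(attr(aa, "internal_stop"))
    expect_identical(substr(as.character(aa), 1, 1), "M")
  }
  # every tRNA carries its anticodon at the annotated centre
  for (f in Filter(function(f) f@kind == "tRNA", features(g))) {
    s <- extractFeatureSeq(g, f)
    mid <- floor((nchar(s) - 3) / 2)
    expect_identical(substr(s, mid + 1, mid + 3), f@anticodon)
  }
})

test_that("frameshift injection shifts coordinates by exactly one", {
  sim <- sim_small(seed = 14)
  g <- sim$F$A
  L <- nchar(genomeSeq(g))
  cds_len <- function(gn, gene) {
    f <- Filter(function(f) f@name == gene, features(gn))[[1]]
    sum(f@segments[, 2] - f@segments[, 1])
  }
  downstream_start <- function(gn, gene) {
    f <- Filter(function(f) f@name == gene, features(gn))[[1]]
    f@segments[1, 1]
  }
  del <- injectFrameshift(g, "cox2", 30, "delete")
  expect_identical(nchar(genomeSeq(del)), L - 1L)
  expect_identical(cds_len(del, "cox2"), cds_len(g, "cox2") - 1L)
  expect_identical(downstream_start(del, "rrnS"),
                   downstream_start(g, "rrnS") - 1L)
  ins <- injectFrameshift(g, "cox2", 30, "insert")
  expect_identical(nchar(genomeSeq(ins)), L + 1L)
  expect_identical(downstream_start(ins, "rrnS"),
                   downstream_start(g, "rrnS") + 1L)
  # upstream features untouched
  expect_identical(downstream_start(ins, "cox1"),
                   downstream_start(g, "cox1"))
  expect_error(injectFrameshift(g, "cox2", 10000, "delete"), "offset")
  expect_error(injectFrameshift(g, "nope", 1, "delete"), "not annotated")
})

test_that("duplication injection adds the block and is reversible", {
  sim <- sim_small(seed = 15)
  g <- sim$M$A
  dup <- injectDuplication(g, c("m-ORF", "trnD"))
  expect_identical(length(features(dup)), length(features(g)) + 2L)
  blen <- sum(vapply(c("m-ORF", "trnD"), function(n) {
    f <- Filter(function(f) f@name == n, features(g))[[1]]
    sum(f@segments[, 2] - f@segments[, 1])
  }, 0L)) + 4L  # spacer between the two template genes
  expect_identical(nchar(genomeSeq(dup)), nchar(genomeSeq(g)) + blen)
  # copies carry the same transcript sequence
  expect_identical(extractFeatureSeq(dup, "m-ORF_dup"),
                   extractFeatureSeq(g, "m-ORF"))
  # removing the copies restores the original annotation multiset
  nm0 <- sort(vapply(features(g), function(f) f@name, ""))
  nm1 <- vapply(features(dup), function(f) f@name, "")
  expect_identical(sort(nm1[!grepl("_dup$", nm1)]), nm0)
  expect_error(injectDuplication(g, c("cox1", "m-ORF")), "contiguous")
})

test_that("frameshift + curation round trip flags only the mutated taxon", {
  sim <- sim_small(seed = 16, tree = "((A:0.01,B:0.01):0.01,C:0.02);")
  rows <- clean_gene_rows(sim$F, "cox1")
  mut <- injectFrameshift(sim$F$C, "cox1", 45, "insert")
  rows$nt["C"] <- extractFeatureSeq(mut, "cox1")
  rep <- dualSpaceConsistency(rows$nt, rows$aa)
  expect_identical(rep$taxon[rep$verdict == "suspicious"], "C")
})
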