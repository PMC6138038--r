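# Tree parsing, MRCA normalization, Robinson-Foulds bipartitions and
# matched clade heights.

test_that("Newick parsing yields heights; malformed input errors", {
  t <- parseTree("((A:1,B:1):1,C:2);")
  expect_s4_class(t, "HeightTree")
  h <- nodeHeights(t)
  expect_identical(length(t@phylo$tip.label), 3L)
  expect_equal(max(h), 2)
  expect_equal(unname(h[["A"]]), 0)
  expect_error(parseTree("((A:1,B:1):1,C:2;"), "parenthes")
  expect_error(parseTree("((A,B),(A,C));"), "uplicate")
})

test_that("NEXUS translate-table trees resolve labels", {
  tf <- tempfile(fileext = ".nex")
  ape::write.nexus(ape::read.tree(text = "((A:1,B:1):1,C:2);"),
                   file = tf, translate = TRUE)
  t <- parseTree(tf, format = "nexus")
  expect_setequal(t@phylo$tip.label, c("A", "B", "C"))
})

test_that("comment annotations are stripped before parsing", {
  t <- parseTree("((A:1,B:1)[&height_95%_HPD={0.8,1.2}]:1,C:2);")
  expect_identical(length(t@phylo$tip.label), 3L)
})

test_that("MRCA normalization rescales heights as specified", {
  t <- parseTree("((A:2,B:2):2,C:4);")
  n <- normalizeToMrca(t, c("A", "B"))
  h <- nodeHeights(n)
  ntip <- 3L
  mrca <- ape::getMRCA(n@phylo, c("A", "B"))
  expect_equal(unname(h[mrca]), 1)
  expect_equal(max(h), 2)                  # root was at 4 = 2 x MRCA
  # all leaves -> root at 1
  nr <- normalizeToMrca(t, c("A", "B", "C"))
  expect_equal(max(nodeHeights(nr)), 1)
})

test_that("normalization is idempotent and scale-invariant", {
  for (seed in 1:10) {
    set.seed(seed)
    ph <- ape::rtree(8)
    t <- new("HeightTree", phylo = ph, normalized = FALSE)
    taxa <- sample(ph$tip.label, 3)
    n1 <- normalizeToMrca(t, taxa)
    n2 <- normalizeToMrca(n1, taxa)
    expect_equal(n2@phylo$edge.length, n1@phylo$edge.length)
    ph7 <- ph; ph7$edge.length <- ph7$edge.length * 7
    n7 <- normalizeToMrca(new("HeightTree", phylo = ph7,
                              normalized = FALSE), taxa)
    expect_equal(n7@phylo$edge.length, n1@phylo$edge.length)
  }
})

test_that("normalization errors on zero-height MRCA and unknown taxa", {
  t <- parseTree("((A:0,B:0):1,C:1);")
  expect_error(normalizeToMrca(t, c("A", "B")), "zero")
  expect_error(normalizeToMrca(t, c("A", "Z")), "not in tree")
  expect_error(normalizeToMrca(t, "A"), "two")
})

test_that("RF distance is 0 on identical topologies, 2 after one NNI", {
  cat5 <- parseTree("((((A:1,B:1):1,C:2):1,D:3):1,E:4);")
  nni <- parseTree("((((A:1,C:1):1,B:2):1,D:3):1,E:4);")
  expect_identical(rfDistance(cat5, cat5)$rf, 0L)
  r <- rfDistance(cat5, nni)
  expect_identical(r$rf, 2L)
  # canonical split labels name the side away from the reference tip A
  expect_identical(sort(c(r$unique1, r$unique2)),
                   sort(c("C|D|E", "B|D|E")))
})

test_that("a taxon moved across an edge shows up in unique bipartitions", {
  base <- parseTree("(((A:1,B:1):1,(C:1,D:1):1):1,(E:1,F:1):2);")
  moved <- parseTree("(((A:1,B:1):1,(C:1,E:1):1):1,(D:1,F:1):2);")
  r <- rfDistance(base, moved)
  expect_true(r$rf > 0)
  expect_true(any(grepl("C|D", r$unique1, fixed = TRUE)))
  expect_true(any(grepl("C|E", r$unique2, fixed = TRUE)))
})

test_that("RF agrees with phangorn on random tree pairs", {
  skip_if_not_installed("phangorn")
  for (seed in 1:10) {
    set.seed(seed)
    t1 <- ape::rtree(10); t2 <- ape::rtree(10)
    ours <- rfDistance(new("HeightTree", phylo = t1, normalized = FALSE),
                       new("HeightTree", phylo = t2, normalized = FALSE))$rf
    ref <- phangorn::RF.dist(t1, t2)
    expect_identical(ours, as.integer(ref))
  }
})

test_that("leaf-set mismatches are reported with the differing taxa", {
  t1 <- parseTree("((A:1,B:1):1,C:2);")
  t2 <- parseTree("((A:1,B:1):1,D:2);")
  expect_error(rfDistance(t1, t2), "C.*D|D.*C")
})

test_that("matched clade heights: identity, scale invariance, unmatched", {
  tM <- normalizeToMrca(parseTree("((A:1,B:1):1,(C:1.5,D:1.5):0.5);"),
                        c("A", "B", "C", "D"))
  same <- matchedCladeHeights(tM, tM)
  expect_true(all(same$table$ratio == 1))
  expect_length(same$unmatched_M, 0L)

  phF <- parseTree("((A:2,B:2):2,(C:3,D:3):1);")   # x2 before normalization
  tF <- normalizeToMrca(phF, c("A", "B", "C", "D"))
  sc <- matchedCladeHeights(tM, tF)
  expect_equal(sc$table$ratio, rep(1, nrow(sc$table)))

  # an extra conspecific cherry in the M tree has no F counterpart
  tM2 <- normalizeToMrca(
    parseTree("(((Sw1:0.2,Sw2:0.2):0.8,B:1):1,(C:1.5,D:1.5):0.5);"),
    c("Sw1", "B", "C", "D"))
  r <- matchedCladeHeights(tM2, tF, taxon_map = c(Sw1 = "A"))
  expect_true("Sw2|A" %in% r$unmatched_M || "A|Sw2" %in% r$unmatched_M)
  expect_true("C|D" %in% r$table$clade)
  expect_error(matchedCladeHeights(tM, parseTree("((A:1,B:1):1,C:2);")),
               "normalized")
})
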