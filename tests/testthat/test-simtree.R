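test_that("global alignment matches worked identity examples", {
  expect_equal(global_align("MKV", "MKV")$identity_pct, 100)
  al <- global_align("MKV", "MRV")
  expect_equal(al$identity_pct, 100 * 2 / 3, tolerance = 1e-9)
  al2 <- global_align("MKVLL", "MKV")
  expect_equal(nchar(al2$aligned_a), 5)
  expect_equal(sum(chars(al2$aligned_b) == "-"), 2)
  expect_equal(al2$identity_pct, 60)
  expect_error(global_align("", "MKV"), "empty")
})

test_that("alignment scores equal an independent implementation exactly", {
  set.seed(77)
  for (i in 1:100) {
    a <- random_protein(sample(3:40, 1))
    b <- random_protein(sample(3:40, 1))
    mine <- global_align(a, b)$score
    ref <- Biostrings::pairwiseAlignment(
      a, b, substitutionMatrix = "BLOSUM62", gapOpening = 10,
      gapExtension = 1, type = "global", scoreOnly = TRUE)
    expect_equal(mine, ref)
  }
})

test_that("aligned strings recover their inputs and identity is symmetric", {
  set.seed(31)
  for (i in 1:20) {
    a <- random_protein(sample(5:50, 1))
    b <- random_protein(sample(5:50, 1))
    al <- global_align(a, b)
    expect_equal(gsub("-", "", al$aligned_a), a)
    expect_equal(gsub("-", "", al$aligned_b), b)
    expect_equal(nchar(al$aligned_a), nchar(al$aligned_b))
    expect_equal(al$identity_pct, global_align(b, a)$identity_pct)
  }
})

test_that("class similarity summary orders within above between", {
  ds <- fixture_dataset()
  prots <- stats::setNames(vapply(ds$records, `[[`, "", "protein"),
                           ds$truth$id)
  s <- class_similarity_summary(prots, ds$truth$class)
  within <- s[s$class_a == s$class_b, ]
  between <- s[s$class_a != s$class_b, ]
  expect_gt(min(within$mean), max(between$mean))

  # two identical records -> within mean 100
  twin <- c(a = prots[[1]], b = prots[[1]])
  s2 <- class_similarity_summary(twin, c("Sn1", "Sn1"))
  expect_equal(s2$mean[s2$class_a == "Sn1" & s2$class_b == "Sn1"], 100)

  # a single class yields no between rows, singleton within is NA
  s3 <- class_similarity_summary(twin[1], "Sn1")
  expect_equal(nrow(s3), 1L)
  expect_true(is.na(s3$mean))
})

test_that("neighbor joining reproduces the three-taxon closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- stats::setNames(tr$edge.length,
                        tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 1)
  expect_equal(bl[["B"]], 1)
  expect_equal(bl[["C"]], 3)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  asym <- d; asym[1, 2] <- 5
  expect_error(nj_tree(asym), "symmetric")
})

test_that("neighbor joining is exact on additive matrices", {
  set.seed(2024)
  for (i in 1:10) {
    gt <- random_additive_tree(8)
    tr <- nj_tree(gt$d)
    dd <- ape::cophenetic.phylo(tr)
    dd <- dd[rownames(gt$d), colnames(gt$d)]
    expect_lt(max(abs(dd - gt$d)), 1e-9)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), gt$tree)), 0)
  }
})

test_that("zero-distance taxa are joined first", {
  d <- matrix(c(0, 0, 3, 3,
                0, 0, 3, 3,
                3, 3, 0, 1,
                3, 3, 1, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(d)
  # a and b form a cherry
  rooted <- ape::root(tr, outgroup = "c", resolve.root = TRUE)
  expect_true(ape::is.monophyletic(rooted, c("a", "b")))
})

test_that("monophyly is detected under unrooted-tree semantics", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  labs <- c(a1 = "Sn1", a2 = "Sn1", b1 = "Sn2", b2 = "Sn2")
  expect_true(all(is_class_monophyletic(tr, labs)))

  tr2 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,b2:1):1);")
  m <- is_class_monophyletic(tr2, labs)
  expect_false(m[["Sn1"]])
  expect_false(m[["Sn2"]])

  expect_error(is_class_monophyletic(tr, labs[1:3]), "without class")
})

test_that("the synthetic dataset yields class-monophyletic NJ trees", {
  ds <- fixture_dataset()
  prots <- stats::setNames(vapply(ds$records, `[[`, "", "protein"),
                           ds$truth$id)
  ident <- pairwise_identity(prots)
  tr <- nj_tree(identity_distance(ident))
  mono <- is_class_monophyletic(
    tr, stats::setNames(ds$truth$class, ds$truth$id))
  expect_true(all(mono))
})
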