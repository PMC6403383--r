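dm <- function(v, lab) {
  n <- length(lab)
  m <- matrix(0, n, n, dimnames = list(lab, lab))
  m[lower.tri(m)] <- v
  m + t(m)
}

test_that("upgma reproduces the textbook ultrametric case", {
  m <- dm(c(2, 4, 4), c("A", "B", "C"))
  tr <- upgma(m)
  expect_identical(to_newick(tr), "(C:2.000000,(A:1.000000,B:1.000000):1.000000);")

  m2 <- dm(0.8, c("x", "y"))
  expect_identical(to_newick(upgma(m2)), "(x:0.400000,y:0.400000);")
})

test_that("upgma recovers trees that generated ultrametric matrices", {
  set.seed(91)
  for (i in 1:10) {
    ref <- ape::rcoal(6) # coalescent trees are ultrametric
    d <- cophenetic(ref)
    tr <- upgma(d)
    expect_identical(rf_distance(tr, ref), 0L)
    # ultrametric output: equal root-to-leaf depths
    depths <- ape::node.depth.edgelength(tr)[1:6]
    expect_lt(diff(range(depths)), 1e-9)
    # and the clustering heights reproduce the generating distances
    expect_lt(max(abs(cophenetic(tr)[rownames(d), colnames(d)] - d)), 1e-9)
  }
})

test_that("neighbor joining inverts additive matrices exactly", {
  ref <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:1):0);")
  d <- cophenetic(ref)[LETTERS[1:4], LETTERS[1:4]]
  tr <- neighbor_joining(d)
  expect_identical(rf_distance(tr, ref), 0L)
  expect_lt(max(abs(cophenetic(tr)[LETTERS[1:4], LETTERS[1:4]] - d)), 1e-9)

  set.seed(101)
  for (i in 1:10) {
    ref <- ape::rtree(7)
    d <- cophenetic(ref)
    tr <- neighbor_joining(d)
    expect_identical(rf_distance(tr, ref), 0L)
    expect_lt(max(abs(cophenetic(tr)[rownames(d), colnames(d)] - d)), 1e-8)
    # cross-check against the ape implementation on the same input
    expect_identical(rf_distance(tr, ape::nj(d)), 0L)
  }
})

test_that("neighbor joining handles 3 taxa by the three-point formulas", {
  m <- dm(c(3, 4, 5), c("A", "B", "C"))
  tr <- neighbor_joining(m)
  # a = (dAB + dAC - dBC)/2 etc.
  d <- cophenetic(tr)
  expect_equal(d["A", "B"], 3)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 5)
  expect_error(neighbor_joining(dm(1, c("a", "b"))), "at least 3")
})

test_that("negative NJ branch lengths are clamped with a warning", {
  # triangle-inequality violation forces a negative three-point solution
  m <- dm(c(1, 1, 3), c("A", "B", "C"))
  expect_warning(tr <- neighbor_joining(m), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("tree builders are invariant to taxon permutation", {
  set.seed(111)
  for (i in 1:5) {
    ref <- ape::rcoal(6)
    d <- cophenetic(ref)
    perm <- sample(rownames(d))
    expect_identical(rf_distance(upgma(d), upgma(d[perm, perm])), 0L)
    expect_identical(rf_distance(neighbor_joining(d), neighbor_joining(d[perm, perm])), 0L)
  }
})

test_that("to_newick writes fixed precision and round-trips", {
  tr <- upgma(dm(1, c("A", "B")))
  expect_identical(to_newick(tr), "(A:0.500000,B:0.500000);")
  expect_identical(to_newick(tr, precision = 2), "(A:0.50,B:0.50);")

  set.seed(121)
  for (i in 1:5) {
    ref <- ape::rtree(8)
    back <- ape::read.tree(text = to_newick(ref))
    expect_identical(rf_distance(ref, back), 0L)
    expect_lt(max(abs(cophenetic(back)[ref$tip.label, ref$tip.label] -
                        cophenetic(ref))), 1e-5)
  }

  spaced <- upgma(dm(1, c("taxon one", "taxon two")))
  expect_identical(to_newick(spaced), "(taxon_one:0.500000,taxon_two:0.500000);")
})
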