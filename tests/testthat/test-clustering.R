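test_that("Pearson distance matches the direct formula and its bounds", {
  expect_equal(pearson_distance(c(1, 0, 1, 0), c(1, 0, 1, 0)), 0)
  expect_equal(pearson_distance(c(1, 0, 1, 0), c(0, 1, 0, 1)), 2)
  for (seed in 1:5) {
    v <- withr::with_seed(seed, list(a = rnorm(10), b = rnorm(10)))
    a <- v$a; b <- v$b
    r <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(pearson_distance(a, b), 1 - r)
    expect_equal(pearson_distance(a, b, scale = "half"), (1 - r) / 2)
  }
  expect_error(pearson_distance(1, 2), "length")
})

test_that("zero-variance profiles use the documented fallback, no exception", {
  expect_equal(pearson_distance(c(1, 1, 1), c(1, 1, 1)), 0)
  expect_equal(pearson_distance(c(0, 0, 0), c(1, 1, 1)), 1)
  expect_equal(pearson_distance(c(1, 1, 1), c(0, 1, 0)), 1)
})

test_that("UPGMA recovers forced topologies and validates input", {
  D <- matrix(c(0, 1, 4,
                1, 0, 4,
                4, 4, 0), 3, 3, dimnames = list(c("A", "B", "C"),
                                                c("A", "B", "C")))
  tr <- upgma(D)
  # A,B merge first at height 1/2, C joins at 4/2
  expect_equal(sort(tr$height), c(0.5, 2))
  phy <- as_phylo(tr)
  ab <- ape::getMRCA(phy, c("A", "B"))
  expect_false(ab == ape::getMRCA(phy, c("A", "C")))
  expect_error(upgma(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  D2 <- D; diag(D2) <- 1
  expect_error(upgma(D2), "zero diagonal")
})

test_that("UPGMA agrees with a naive O(n^3) reference on random profiles", {
  for (seed in 1:5) {
    prof <- withr::with_seed(seed,
      matrix(rbinom(6 * 12, 1, 0.4), 6, 12,
             dimnames = list(paste0("e", 1:6), NULL)))
    D <- pearson_distance_matrix(prof)
    tr <- upgma(D)
    got <- stats::cophenetic(tr$hclust)  # heights already on the d/2 scale
    want <- upgma_oracle_cophenetic(D)
    labs <- rownames(want)
    expect_equal(as.matrix(got)[labs, labs], want, tolerance = 1e-10)
  }
})

test_that("merge heights are ultrametric and zero-distance pairs merge first", {
  for (seed in 1:5) {
    prof <- withr::with_seed(seed,
      matrix(rbinom(7 * 10, 1, 0.5), 7, 10,
             dimnames = list(paste0("e", 1:7), NULL)))
    prof[2, ] <- prof[1, ]  # plant an identical pair
    D <- pearson_distance_matrix(prof)
    tr <- upgma(D)
    expect_true(all(diff(tr$height) >= -1e-12))
    expect_equal(tr$height[1], 0)
    coph <- as.matrix(stats::cophenetic(tr$hclust)) / 2
    expect_equal(coph["e1", "e2"], 0)
  }
})

test_that("leaf input order does not change the tree (up to tie-breaking)", {
  prof <- withr::with_seed(42,
    matrix(rbinom(6 * 14, 1, 0.4), 6, 14,
           dimnames = list(paste0("e", 1:6), NULL)))
  D <- pearson_distance_matrix(prof)
  perm <- c(4, 2, 6, 1, 3, 5)
  t1 <- upgma(D)
  t2 <- upgma(D[perm, perm])
  c1 <- as.matrix(stats::cophenetic(t1$hclust))
  c2 <- as.matrix(stats::cophenetic(t2$hclust))
  labs <- sort(rownames(c1))
  expect_equal(c1[labs, labs], c2[labs, labs])
})

test_that("internal nodes inherit a process label only when leaves agree", {
  D <- matrix(c(0, 0.1, 1, 1,
                0.1, 0, 1, 1,
                1, 1, 0, 0.2,
                1, 1, 0.2, 0), 4, 4,
              dimnames = list(c("a1", "a2", "n1", "n2"),
                              c("a1", "a2", "n1", "n2")))
  tr <- upgma(D)
  tr <- tree_labels(tr, c(a1 = "apoptosis", a2 = "apoptosis",
                          n1 = "necroptosis", n2 = "necroptosis"))
  expect_setequal(tr$node_labels[!is.na(tr$node_labels)],
                  c("apoptosis", "necroptosis"))
  expect_true(is.na(tr$node_labels[nrow(tr$merge)]))  # mixed root
  expect_error(tree_labels(tr, c(zz = "x")), "unknown leaves")
})

test_that("Newick export writes a readable ultrametric tree", {
  prof <- withr::with_seed(7, matrix(rbinom(5 * 9, 1, 0.5), 5, 9,
                                     dimnames = list(letters[1:5], NULL)))
  tr <- upgma(pearson_distance_matrix(prof))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, letters[1:5])
  depths <- ape::node.depth.edgelength(phy)[seq_len(5)]
  expect_true(max(depths) - min(depths) < 1e-8)
})
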