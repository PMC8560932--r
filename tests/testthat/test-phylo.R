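test_that("additive relationship matches the hand-computed 2-sample case", {
  calls <- matrix(c(0L, 1L), 1, dimnames = list(NULL, c("s1", "s2")))
  A <- additive_relationship(calls)
  expect_equal(unclass(A)[1:2, 1:2],
               matrix(c(2, -2, -2, 2), 2,
                      dimnames = list(c("s1", "s2"), c("s1", "s2"))))
  expect_equal(attr(A, "n_markers"), 1L)
})

test_that("identical samples get identical relationship rows", {
  set.seed(2)
  calls <- matrix(sample(0:1, 30, replace = TRUE), 10,
                  dimnames = list(NULL, c("a", "b", "c")))
  calls[, "b"] <- calls[, "a"]
  calls <- calls[rowMeans(calls) %% 1 != 0, , drop = FALSE]  # keep polymorphic
  A <- additive_relationship(calls)
  expect_equal(A["a", ], A["b", ])
})

test_that("additive relationship equals the elementwise oracle, site-order invariant", {
  set.seed(4)
  for (i in 1:20) {
    n <- sample(6:10, 1)
    repeat {
      calls <- matrix(sample(c(0L, 1L, NA), 20 * n, replace = TRUE,
                             prob = c(0.45, 0.45, 0.1)), 20)
      p <- rowMeans(calls, na.rm = TRUE)
      if (all(!is.na(p) & p > 0 & p < 1)) break
    }
    colnames(calls) <- sprintf("s%02d", seq_len(n))
    A <- additive_relationship(calls)
    expect_equal(unclass(A)[,], oracle_amatrix(calls), tolerance = 1e-10)
    A2 <- additive_relationship(calls[sample(20), , drop = FALSE])
    expect_equal(unclass(A2)[,], unclass(A)[,], tolerance = 1e-12)
  }
})

test_that("monomorphic markers are rejected by the A matrix", {
  calls <- rbind(c(0L, 1L, 0L), c(0L, 0L, 0L))
  colnames(calls) <- c("a", "b", "c")
  expect_error(additive_relationship(calls), "monomorphic")
})

test_that("Euclidean distance on A rows matches hand computation", {
  calls <- matrix(c(0L, 1L), 1, dimnames = list(NULL, c("s1", "s2")))
  D <- distance_from_A(additive_relationship(calls))
  expect_equal(D["s1", "s2"], sqrt(32), tolerance = 1e-12)
  expect_equal(diag(D), c(s1 = 0, s2 = 0))
})

test_that("permuting samples permutes distances consistently", {
  set.seed(6)
  calls <- matrix(sample(0:1, 12 * 6, replace = TRUE), 12,
                  dimnames = list(NULL, letters[1:6]))
  calls <- calls[apply(calls, 1, function(r) length(unique(r)) > 1), ]
  D <- distance_from_A(additive_relationship(calls))
  ord <- sample(letters[1:6])
  D2 <- distance_from_A(additive_relationship(calls[, ord]))
  expect_equal(D2[letters[1:6], letters[1:6]], D, tolerance = 1e-12)
})

test_that("hierarchical clustering merges the closest pair first", {
  D <- matrix(c(0, 1, 10, 1, 0, 10, 10, 10, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  h <- hierarchical_cluster(D, "complete")
  expect_equal(h$height[1], 1)
  expect_equal(sort(h$labels[-h$merge[1, ]]), c("a", "b"))
  expect_error(hierarchical_cluster(matrix(0, 1, 1)), "at least two")
})

test_that("ultrametric input yields the same merge heights for all linkages", {
  # heights from a perfectly nested (ultrametric) tree
  D <- matrix(4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D[1, 2] <- D[2, 1] <- 1; D[3, 4] <- D[4, 3] <- 2
  diag(D) <- 0
  hs <- lapply(c("complete", "average", "single"), function(l)
    hierarchical_cluster(D, l)$height)
  expect_equal(hs[[1]], hs[[2]])
  expect_equal(hs[[1]], hs[[3]])
})

test_that("merge heights match the naive agglomerative oracle", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(6:10, 1)
    pts <- matrix(stats::rnorm(2 * n), n)
    D <- as.matrix(stats::dist(pts))
    dimnames(D) <- list(sprintf("u%02d", 1:n), sprintf("u%02d", 1:n))
    for (link in c("complete", "average", "single")) {
      h <- hierarchical_cluster(D, link)
      expect_equal(sort(h$height), oracle_agglom_heights(D, link),
                   tolerance = 1e-10)
    }
  }
})

test_that("neighbor joining recovers a known 4-taxon additive tree", {
  true <- read_newick("((A:1,B:2):1.5,C:3,D:4);")
  D <- ape::cophenetic.phylo(true)
  tree <- neighbor_joining(D)
  expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(tree)), 0,
               ignore_attr = TRUE)
  expect_equal(ape::cophenetic.phylo(tree)[rownames(D), colnames(D)], D,
               tolerance = 1e-9)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("NJ path lengths reproduce random additive distances", {
  set.seed(10)
  for (i in 1:10) {
    gen <- random_additive_matrix(6)
    tree <- neighbor_joining(gen$D)
    got <- ape::cophenetic.phylo(tree)[rownames(gen$D), colnames(gen$D)]
    expect_equal(got, gen$D, tolerance = 1e-9)
  }
})

test_that("two identical taxa yield a zero-length terminal pair", {
  D <- matrix(c(0, 0, 5, 5,
                0, 0, 5, 5,
                5, 5, 0, 2,
                5, 5, 2, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tree <- neighbor_joining(D)
  cp <- ape::cophenetic.phylo(tree)
  expect_equal(cp["a", "b"], 0, tolerance = 1e-12)
})

test_that("clade cuts are nested, size-ordered and permutation invariant", {
  set.seed(12)
  pts <- rbind(matrix(rnorm(10, 0), 5), matrix(rnorm(8, 10), 4),
               matrix(rnorm(6, 20), 3))
  D <- as.matrix(stats::dist(pts))
  dimnames(D) <- list(sprintf("u%02d", 1:12), sprintf("u%02d", 1:12))
  h <- hierarchical_cluster(D)
  cp <- cut_clades(h, k_major = 3, k_sub = 5)
  expect_equal(sort(unique(cp$major_clade)), c("I", "II", "III"))
  # major clade I is the largest
  expect_equal(names(which.max(table(cp$major_clade))), "I")
  nest <- unique(cp[, c("major_clade", "subclade")])
  expect_false(anyDuplicated(nest$subclade) > 0)
  # permuting the input units leaves the labelling unchanged
  ord <- sample(12)
  h2 <- hierarchical_cluster(D[ord, ord])
  cp2 <- cut_clades(h2, 3, 5)
  expect_equal(cp2$major_clade[match(cp$unit, cp2$unit)], cp$major_clade)
  expect_equal(cp2$subclade[match(cp$unit, cp2$unit)], cp$subclade)
  # degenerate cuts
  expect_equal(cut_clades(h, 3, 3)$subclade,
               as.integer(factor(cut_clades(h, 3, 3)$major_clade,
                                 levels = c("I", "II", "III"))))
  expect_equal(sort(cut_clades(h, 3, 12)$subclade), 1:12)
  expect_error(cut_clades(h, 5, 3), "k_sub")
})

test_that("newick round-trips preserve topology and branch lengths", {
  t1 <- read_newick("(A:1,B:2);")
  expect_equal(sort(t1$tip.label), c("A", "B"))
  expect_equal(sort(read_newick(write_newick(t1))$edge.length), c(1, 2))
  t2 <- read_newick("((A,B),(C,D));")
  expect_equal(ape::dist.topo(ape::unroot(read_newick(write_newick(t2))),
                              ape::unroot(t2)), 0, ignore_attr = TRUE)
  set.seed(14)
  t3 <- ape::rtree(10)
  rt <- read_newick(write_newick(t3))
  expect_equal(ape::dist.topo(ape::unroot(rt), ape::unroot(t3)), 0,
               ignore_attr = TRUE)
  expect_equal(sort(rt$edge.length), sort(t3$edge.length), tolerance = 1e-9)
  expect_error(read_newick("((A,B);"), "parenthes")
  expect_error(read_newick("(A:1,A:2);"), "duplicate")
})
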