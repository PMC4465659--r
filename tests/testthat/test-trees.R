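test_that("three taxa give the closed-form branch lengths", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- fitch_margoliash(d)
  # a = (dAB + dAC - dBC)/2 = 1, b = 2, c = 4
  lens <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(lens[c("A", "B", "C")]), c(1, 2, 4))
  expect_equal(attr(tr, "objective"), 0, tolerance = 1e-12)
})

test_that("additive matrices are recovered exactly, topology and lengths", {
  for (seed in 1:4) {
    n <- c(4, 5, 6, 8)[seed]
    gen <- random_additive(n, seed = seed + 40)
    fit <- fitch_margoliash(gen$d)
    expect_equal(attr(fit, "objective"), 0, tolerance = 1e-10)
    expect_equal(attr(fit, "fitted")[rownames(gen$d), colnames(gen$d)],
                 gen$d, tolerance = 1e-8)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen$tree), ape::unroot(fit))), 0)
    expect_true(all(fit$edge.length >= 0))
  }
})

test_that("small perturbations of an additive matrix keep the topology", {
  gen <- random_additive(6, seed = 99)
  eps <- 0.01 * min(gen$d[gen$d > 0])
  set.seed(100)
  noise <- matrix(stats::runif(36, -eps, eps), 6)
  noise <- (noise + t(noise)) / 2
  diag(noise) <- 0
  fit <- fitch_margoliash(gen$d + noise)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(gen$tree), ape::unroot(fit))), 0)
})

test_that("an all-zero matrix degrades to a star tree with a warning", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(tr <- fitch_margoliash(d), "star tree")
  expect_identical(tr$Nnode, 1L)
  expect_true(all(tr$edge.length == 0))
})

test_that("identical trees give a consensus with all supports 100", {
  t1 <- ape::read.tree(text = "((A,B),(C,(D,E)));")
  cons <- majority_consensus(list(t1, t1, t1))
  expect_setequal(tree_bipartitions(cons), tree_bipartitions(t1))
  sup <- as.numeric(cons$node.label[nzchar(cons$node.label)])
  expect_true(all(sup == 100))
})

test_that("consensus supports equal direct bipartition counts", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,B),(C,D));")
  t3 <- ape::read.tree(text = "((A,C),(B,D));")
  cons <- majority_consensus(list(t1, t2, t3))
  splits <- attr(cons, "splits")
  expect_identical(splits$n[splits$split == "C|D"], 2L)
  expect_identical(tree_bipartitions(cons), "C|D")
  expect_equal(splits$support[splits$split == "C|D"], 100 * 2 / 3)
  sup <- as.numeric(cons$node.label[nzchar(cons$node.label)])
  expect_equal(sup, 66.7)
  # topology agrees with the independent implementation in ape
  ape_cons <- ape::consensus(list(t1, t2, t3), p = 0.5)
  expect_setequal(tree_bipartitions(cons), tree_bipartitions(ape_cons))
  expect_error(majority_consensus(list(t1, ape::read.tree(text = "((A,B),(C,E));"))),
               "share one leaf set")
})

test_that("consensus retains only mutually compatible strict-majority splits", {
  set.seed(17)
  trees <- replicate(9, ape::rtree(7, rooted = FALSE), simplify = FALSE)
  cons <- majority_consensus(trees)
  splits <- attr(cons, "splits")
  kept <- splits[splits$n > length(trees) / 2, ]
  expect_setequal(tree_bipartitions(cons), kept$split)
  expect_true(all(splits$support <= 100))
  # pairwise compatibility of the kept splits
  if (nrow(kept) > 1) {
    sides <- strsplit(kept$split, "|", fixed = TRUE)
    for (i in seq_len(nrow(kept) - 1)) {
      for (j in seq(i + 1, nrow(kept))) {
        a <- sides[[i]]; b <- sides[[j]]
        expect_true(!length(intersect(a, b)) || all(a %in% b) || all(b %in% a))
      }
    }
  }
})

test_that("newick round trips preserve lengths, labels and multifurcations", {
  txt <- "((A:1,B:1):0.5,C:2);"
  tr <- parse_newick(txt)
  expect_identical(write_newick(tr), "((A:1,B:1):0.5,C:2);")
  # supports as internal node labels survive a round trip
  t2 <- parse_newick("((A:1,B:1)87:0.5,C:2);")
  expect_identical(t2$node.label[2], "87")
  expect_identical(write_newick(t2), "((A:1,B:1)87:0.5,C:2);")
  # PHYLIP-style multifurcation parses
  t3 <- parse_newick("(A,B,C,D);")
  expect_identical(t3$Nnode, 1L)
  expect_error(parse_newick("((A,B);"), "malformed")
  # file round trip
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick_file(list(tr, t3), path)
  back <- read_newick_file(path)
  expect_length(back, 2L)
  expect_identical(write_newick(back[[1]]), write_newick(tr))
})
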