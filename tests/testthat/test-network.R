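test_that("a mutational chain is reconstructed as a path", {
  aln <- make_aln(c("AAAAAA", "AAAAAT", "AAAATT"),
                  ids = c("H1", "H2", "H3"))
  net <- build_network(aln)
  expect_identical(nrow(net$edges), 2L)
  key <- paste(net$edges$from, net$edges$to)
  expect_setequal(key, c("H1 H2", "H2 H3"))
  expect_identical(net$edges$length, c(1L, 1L))
})

test_that("the diagnostic fixture yields the path BGp - BGa - SG with BGa internal", {
  net <- build_network(diagnostic_fixture())
  expect_identical(nrow(net$edges), 2L)
  e <- net$edges[order(net$edges$length), ]
  expect_setequal(c(e$from[1], e$to[1]), c("BGp", "BGa"))
  expect_setequal(c(e$from[2], e$to[2]), c("BGa", "SG"))
  expect_identical(e$length, c(2L, 4L))
})

test_that("tied minimum spanning edges are all retained", {
  # 4 haplotypes all at pairwise distance 2: every edge is in some MST
  aln4 <- make_aln(c("AAAA", "AATT", "ATAT", "ATTA"),
                   ids = c("a", "b", "c", "d"))
  net <- build_network(aln4)
  expect_identical(nrow(net$edges), 6L) # complete graph retained
  expect_true(all(net$edges$length == 2L))
})

test_that("duplicate haplotypes collapse with summed frequencies", {
  aln <- make_aln(c("AAAA", "AAAA", "AATT"), freq = c(3L, 4L, 1L))
  net <- build_network(aln)
  expect_identical(nrow(net$nodes), 2L)
  expect_identical(net$nodes$freq[net$nodes$id == "h1"], 7L)
})

test_that("central haplotype selection obeys the method and tie rules", {
  # star: hub at frequency 40
  seqs <- c("AAAAAA", "AAAAAT", "AAAATA", "AAATAA", "AATAAA")
  aln <- make_aln(seqs, ids = c("hub", "t1", "t2", "t3", "t4"),
                  freq = c(40L, 1L, 1L, 1L, 1L))
  net <- build_network(aln)
  expect_identical(identify_central(net, "g", "frequency"), "hub")
  expect_identical(identify_central(net, "g", "degree"), "hub")

  # degree tie (both internal nodes of a 4-chain) broken by frequency
  aln2 <- make_aln(c("AAAA", "AAAT", "AATT", "ATTT"),
                   ids = c("a", "b", "c", "d"), freq = c(3L, 10L, 3L, 1L))
  net2 <- build_network(aln2)
  expect_identical(identify_central(net2, "g", "degree"), "b")
  expect_error(identify_central(net2, "nope"), "no haplotypes")
})

test_that("orientation from the central reads mutations centrifugally", {
  net <- build_network(diagnostic_fixture())
  om <- orient_mutations(net, "BGa")
  bgp <- om[om$group == "BGp", ]
  expect_identical(nrow(bgp), 2L)
  expect_true(all(bgp$from_base == "T" & bgp$to_base == "C"))
  expect_true(all(bgp$ws_class == "W>S"))
  expect_true(all(bgp$synonymous))
  # single-edge network: orientation equals central -> other
  aln <- make_aln(c("AAAA", "AAAT"), ids = c("c", "p"))
  net1 <- build_network(aln)
  om1 <- orient_mutations(net1, "c")
  expect_identical(om1$from_node, "c")
  expect_identical(om1$to_node, "p")
})

test_that("reversing the central on a path swaps W>S and S>W counts", {
  aln <- make_aln(c("TTTTTT", "CTTTTT", "CCTTTT", "CCCTTT"),
                  ids = c("a", "b", "c", "d"))
  net <- build_network(aln)
  fwd <- orient_mutations(net, "a")
  bwd <- orient_mutations(net, "d")
  expect_identical(sum(fwd$ws_class == "W>S"), sum(bwd$ws_class == "S>W"))
  expect_identical(sum(fwd$ws_class == "S>W"), sum(bwd$ws_class == "W>S"))
})

test_that("oriented mutation multiset is invariant to haplotype input order", {
  sim <- simulate_haplotypes(sim_config(seed = 5, gene_length = 300L,
    groups = tibble::tibble(name = "G", central_freq = 20L,
                            n_peripheral = 6L, lambda = 1.5, beta = 0.7),
    diagnostics = list()))
  aln <- sim$alignment
  set.seed(9)
  perm <- sample(length(aln$ids))
  aln2 <- hap_alignment(aln$ids[perm], aln$seqs[perm], aln$meta$group[perm],
                        aln$meta$freq[perm], aln$frame_offset,
                        aln$ref_offset, aln$code_table)
  key <- function(om) sort(paste(om$column, om$from_base, om$to_base))
  om1 <- orient_mutations(build_network(aln), "G_c")
  om2 <- orient_mutations(build_network(aln2), "G_c")
  expect_identical(key(om1), key(om2))
})

test_that("orientation recovers simulator ground truth exactly on star data", {
  sim <- simulate_haplotypes(sim_config(seed = 21))
  net <- build_network(sim$alignment)
  om <- orient_mutations(net, sim$truth$centrals[["BGa"]])
  truth_keys <- with(sim$truth$mutations, paste(column, from_base, to_base))
  est_keys <- with(om, paste(column, from_base, to_base))
  expect_identical(sort(est_keys), sort(truth_keys))
})
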