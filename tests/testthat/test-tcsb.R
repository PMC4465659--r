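test_that("spectra count only synonymous mutations, conserving the total", {
  net <- build_network(diagnostic_fixture())
  om <- orient_mutations(net, "BGa")
  sp <- tally_spectrum(om)
  bgp <- sp[sp$group == "BGp", ]
  expect_identical(bgp$n[bgp$ws_class == "W>S"], 2L) # the T>C pair
  expect_identical(sum(bgp$n), 2L)
  sg <- sp[sp$group == "SG", ]
  expect_identical(unique(sg$n_excluded_nonsyn), 2L)
  # conservation: synonymous mutations = sum over the four classes
  expect_identical(sum(sp$n),
                   sum(om$synonymous & !is.na(om$synonymous)))
  # percentages sum to 100 within groups that have counts
  expect_equal(sum(bgp$pct), 100)
})

test_that("an empty oriented set yields an all-zero spectrum", {
  net <- build_network(make_aln(c("AAA", "AAT")))
  om <- orient_mutations(net, "h1")
  sp <- tally_spectrum(om[0, ], groups = "g")
  expect_true(all(sp$n == 0L))
  expect_true(all(sp$pct == 0))
})

test_that("fisher_exact_2x2 matches enumeration and fisher.test conventions", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  # diagonal table: exactly two extreme tables out of C(20,10)
  expect_equal(fisher_exact_2x2(rbind(c(10, 0), c(0, 10))), 2 / choose(20, 10))
  # zero margin carries no information
  expect_equal(fisher_exact_2x2(rbind(c(0, 0), c(5, 7))), 1)
  # row swap invariance
  set.seed(77)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 6), 2)
    p1 <- fisher_exact_2x2(tab)
    expect_equal(p1, fisher_exact_2x2(tab[2:1, ]))
    expect_equal(p1, enum_fisher_p(tab))
    expect_equal(p1, stats::fisher.test(tab)$p.value)
  }
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("group comparison uses only the W>S / S>W table", {
  net <- build_network(diagnostic_fixture())
  sp <- tally_spectrum(orient_mutations(net, "BGa"))
  t <- compare_groups(sp, "BGp", "SG")
  expect_identical(dim(t$table), c(2L, 2L))
  expect_identical(unname(t$table["BGp", ]), c(2L, 0L))
  expect_identical(unname(t$table["SG", ]), c(1L, 1L))
  expect_true(t$p_value >= 0 && t$p_value <= 1)

  # identical spectra give p = 1; strongly opposed spectra reject hard
  expect_equal(fisher_exact_2x2(rbind(c(7, 3), c(7, 3))), 1)
  expect_lt(fisher_exact_2x2(rbind(c(50, 5), c(5, 50))), 1e-6)
  expect_equal(fisher_exact_2x2(rbind(c(50, 5), c(5, 50))),
               enum_fisher_p(rbind(c(50, 5), c(5, 50))))
})

test_that("tidy and glance summarise a TCSB test", {
  net <- build_network(diagnostic_fixture())
  sp <- tally_spectrum(orient_mutations(net, "BGa"))
  t <- compare_groups(sp, "BGp", "SG")
  td <- tidy(t)
  expect_identical(td$group, c("BGp", "SG"))
  expect_identical(td$p_value, rep(t$p_value, 2))
  gl <- glance(t)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$n_total, sum(t$table))
})

test_that("simulated W>S fraction tracks the configured bias", {
  sim <- simulate_haplotypes(sim_config(seed = 31, gene_length = 1140L,
    groups = tibble::tibble(name = "G", central_freq = 30L,
                            n_peripheral = 50L, lambda = 2, beta = 0.8),
    diagnostics = list(), p_ws_event = 1))
  net <- build_network(sim$alignment)
  om <- orient_mutations(net, "G_c")
  sp <- tally_spectrum(om)
  ws <- sp$n[sp$ws_class == "W>S"]
  sw <- sp$n[sp$ws_class == "S>W"]
  n <- ws + sw
  expect_gt(n, 50)
  # within 3 binomial SDs of beta
  expect_lt(abs(ws / n - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})
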