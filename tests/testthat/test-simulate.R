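test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 123)
  s1 <- simulate_haplotypes(cfg)
  s2 <- simulate_haplotypes(cfg)
  expect_identical(s1$alignment$seqs, s2$alignment$seqs)
  expect_identical(s1$truth$mutations, s2$truth$mutations)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_simulation(s1, d1); p2 <- write_simulation(s2, d2)
  expect_identical(readLines(p1[["fasta"]]), readLines(p2[["fasta"]]))
  s3 <- simulate_haplotypes(sim_config(seed = 124))
  expect_false(identical(s1$alignment$seqs, s3$alignment$seqs))
})

test_that("every emitted mutation is classified synonymous by the classifier", {
  sim <- simulate_haplotypes(sim_config(seed = 55))
  aln <- sim$alignment
  tm <- sim$truth$mutations
  for (r in seq_len(nrow(tm))) {
    cls <- classify_substitution(aln, tm$column[r], tm$from_base[r], tm$to_base[r])
    expect_true(cls$synonymous, label = paste("row", r))
    expect_identical(cls$ws_class, tm$ws_class[r])
  }
})

test_that("no simulated haplotype contains an internal stop codon", {
  sim <- simulate_haplotypes(sim_config(seed = 77))
  code <- genetic_code("2")
  for (s in sim$alignment$seqs) {
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(code[codons] == "*"))
  }
})

test_that("degenerate bias beta = 1 makes every W<->S mutation W>S", {
  sim <- simulate_haplotypes(sim_config(seed = 9,
    groups = tibble::tibble(name = "G", central_freq = 10L,
                            n_peripheral = 10L, lambda = 2, beta = 1),
    diagnostics = list(), p_ws_event = 1))
  tm <- sim$truth$mutations
  expect_gt(nrow(tm), 0)
  expect_true(all(tm$ws_class == "W>S"))
})

test_that("spaced diagnostics reproduce the two T>C substitutions 4 nt apart", {
  sim <- simulate_haplotypes(sim_config(seed = 17))
  dm <- sim$truth$mutations[sim$truth$mutations$diagnostic &
                              sim$truth$mutations$group == "BGp", ]
  expect_identical(nrow(dm), 2L)
  expect_true(all(dm$from_base == "T" & dm$to_base == "C"))
  expect_identical(diff(sort(dm$column)) - 1L, 4L)
  # and the pattern survives the full classification pipeline
  aln <- sim$alignment
  bga <- aln$seqs[aln$ids == "BGa_c"]
  bgp <- aln$seqs[aln$ids == "BGp_c"]
  diff_cols <- which(strsplit(bga, "")[[1]] != strsplit(bgp, "")[[1]]) - 1L
  expect_identical(sort(diff_cols), sort(dm$column))
})

test_that("empirical W>S fraction converges to beta", {
  sim <- simulate_haplotypes(sim_config(seed = 202,
    groups = tibble::tibble(name = "G", central_freq = 10L,
                            n_peripheral = 60L, lambda = 3, beta = 0.7),
    diagnostics = list(), p_ws_event = 1))
  tm <- sim$truth$mutations
  n <- sum(tm$ws_class %in% c("W>S", "S>W"))
  frac <- sum(tm$ws_class == "W>S") / n
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / n))
})

test_that("recovery report scores central, orientation and bias correctly", {
  sim <- simulate_haplotypes(sim_config(seed = 42))
  rep <- recovery_report(sim, central = sim$truth$centrals[["BGa"]])
  expect_true(all(rep$centrals$correct))
  expect_equal(rep$orientation$accuracy, 1.0)
  expect_true(all(abs(rep$groups$beta_hat - rep$groups$beta_true) < 0.35))
  expect_identical(nrow(rep$tests), 3L)
})

test_that("infeasible diagnostic placement errors out", {
  cfg <- sim_config(seed = 1, gene_length = 9L,
    groups = tibble::tibble(name = c("A", "B"), central_freq = c(2L, 2L),
                            n_peripheral = c(0L, 0L), lambda = c(1, 1),
                            beta = c(0.5, 0.5)),
    diagnostics = list(B = list(count = 2L, spacing = 7L,
                                from = "T", to = "C", synonymous = TRUE)))
  expect_error(simulate_haplotypes(cfg), "placement|admissible")
})
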