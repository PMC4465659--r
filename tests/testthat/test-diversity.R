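test_that("pi matches its definition on simple cases", {
  # two haplotypes (freq 1) differing at 3 of 100 columns
  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("A", 97), "TTT")
  aln <- make_aln(c(s1, s2))
  expect_equal(nucleotide_diversity(aln, 0:99), 0.03)
  # monomorphic window
  expect_equal(nucleotide_diversity(aln, 0:49), 0)
  expect_error(nucleotide_diversity(aln, integer(0)), "non-empty")
  aln1 <- make_aln("ACGT")
  expect_error(nucleotide_diversity(aln1, 0:3), "frequency >= 2")
})

test_that("pi equals the frequency-expanded brute-force average", {
  set.seed(12)
  for (rep in 1:5) {
    n <- 4
    L <- 40
    seqs <- replicate(n, paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = ""))
    freq <- sample(1:5, n, replace = TRUE)
    aln <- make_aln(seqs, freq = freq)
    cols <- sort(sample(0:(L - 1), 25))
    expect_equal(nucleotide_diversity(aln, cols), brute_pi(aln, cols))
  }
})

test_that("pi is invariant to haplotype order and frequencies are authoritative", {
  seqs <- c("AAAAAAAAAA", "AAAAATTTTT", "TTTTTTTTTT")
  aln <- make_aln(seqs, freq = c(2L, 3L, 1L))
  p1 <- nucleotide_diversity(aln, 0:9)
  perm <- c(3, 1, 2)
  aln2 <- make_aln(seqs[perm], ids = paste0("h", perm), freq = c(1L, 2L, 3L))
  expect_equal(nucleotide_diversity(aln2, 0:9), p1)
  # duplicating a record while keeping total frequency fixed changes nothing
  aln3 <- make_aln(c(seqs, seqs[1]), ids = c("a", "b", "c", "a2"),
                   freq = c(1L, 3L, 1L, 1L))
  aln4 <- make_aln(seqs, ids = c("a", "b", "c"), freq = c(2L, 3L, 1L))
  expect_equal(nucleotide_diversity(aln3, 0:9), nucleotide_diversity(aln4, 0:9))
})

test_that("window grid: 1140 bp with width 100 and step 10 gives 105 full windows", {
  sim <- simulate_haplotypes(sim_config(seed = 3))
  net <- build_network(sim$alignment)
  om <- orient_mutations(net, "BGa_c")
  prof <- sliding_profile(sim$alignment, om, width = 100L, step = 10L)
  expect_identical(sum(!prof$truncated), 105L)
  expect_identical(prof$start, seq(0L, 1040L, by = 10L))
  expect_true(all(prof$pi_total >= 0))
})

test_that("class diversity is local to the windows covering the site", {
  # one W>S segregating site at column 45 of a 100-bp gene
  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("A", 45), "G", strrep("A", 54))
  aln <- make_aln(c(s1, s2), ids = c("c", "p"), freq = c(5L, 1L))
  om <- orient_mutations(build_network(aln), "c")
  expect_identical(om$ws_class, "W>S")
  prof <- sliding_profile(aln, om, width = 20L, step = 5L)
  covering <- prof$start <= 45 & prof$end > 45
  expect_true(all(prof$pi_ws[covering] > 0))
  expect_true(all(prof$pi_ws[!covering] == 0))
})

test_that("class-partitioned diversity sums to the total over all classes", {
  sim <- simulate_haplotypes(sim_config(seed = 13, gene_length = 600L,
    groups = tibble::tibble(name = "G", central_freq = 10L,
                            n_peripheral = 10L, lambda = 2, beta = 0.5),
    diagnostics = list()))
  aln <- sim$alignment
  om <- orient_mutations(build_network(aln), "G_c")
  prof <- sliding_profile(aln, om, width = 100L, step = 100L)
  # per-class pi over the four classes == pi_total (all sites oriented here)
  contrib_classes <- sapply(c("W>S", "S>W", "W>W", "S>S"), function(cl) {
    cols <- unique(om$column[om$ws_class == cl])
    sapply(seq_len(nrow(prof)), function(i) {
      cc <- cols[cols >= prof$start[i] & cols < prof$end[i]]
      if (!length(cc)) 0 else
        nucleotide_diversity(aln, cc, length_norm = prof$end[i] - prof$start[i])
    })
  })
  expect_equal(rowSums(contrib_classes), prof$pi_total, tolerance = 1e-12)
  # and the profile's own two classes never exceed the total
  expect_true(all(prof$pi_ws + prof$pi_sw <= prof$pi_total + 1e-12))
})

test_that("step equal to width reproduces the block computation", {
  sim <- simulate_haplotypes(sim_config(seed = 8, gene_length = 300L,
    groups = tibble::tibble(name = "G", central_freq = 5L,
                            n_peripheral = 8L, lambda = 2, beta = 0.5),
    diagnostics = list()))
  aln <- sim$alignment
  om <- orient_mutations(build_network(aln), "G_c")
  prof <- sliding_profile(aln, om, width = 50L, step = 50L)
  blocks <- split(0:299, rep(1:6, each = 50))
  manual <- vapply(blocks, function(cols) {
    nucleotide_diversity(aln, cols, length_norm = 50)
  }, numeric(1))
  expect_equal(prof$pi_total, unname(manual))
})
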