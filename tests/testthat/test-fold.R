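test_that("transcription maps T to U and rejects other symbols", {
  expect_identical(transcribe("ACTG"), "ACUG")
  expect_identical(transcribe("TTTT"), "UUUU")
  expect_identical(transcribe("acg"), "ACG")
  expect_error(transcribe("ACGU"), "only A, C, G, T")
})

test_that("temperature grids and per-entry monotonicity behave as modelled", {
  grid <- temperature_grid(1.0, 4.0, 0.1)
  expect_length(grid, 31L)
  expect_equal(grid[[1]]$temperature, 1.0)
  expect_equal(grid[[31]]$temperature, 4.0)
  expect_length(temperature_grid(2, 2, 0.1), 1L)
  expect_error(temperature_grid(1, 4, 0), "positive")

  # dG is linear in T with slope -dS/1000: stacks (dS < 0) weaken as T
  # rises, loop penalties (also dS < 0) grow
  m1 <- energy_model(temperature = 1)
  m2 <- model_at_temperature(m1, 4)
  expect_true(all(m2$dG_stack > m1$dG_stack))
  expect_true(all(m2$dG_hairpin > m1$dG_hairpin))
  expect_error(model_at_temperature(m1, 250), "sensible range")
})

test_that("folding finds the expected structures on canonical examples", {
  expect_identical(fold_mfe("AAAAAA")$dotbracket, "......")
  expect_equal(fold_mfe("AAAAAA")$energy, 0)

  hp <- fold_mfe("GGGAAACCC")
  oracle <- brute_force_fold("GGGAAACCC")
  expect_identical(hp$dotbracket, "(((...)))")
  expect_equal(hp$energy, oracle$energy)

  # minimum hairpin rule: GCGC cannot close any loop
  bf <- brute_force_fold("GCGC")
  expect_identical(bf$dotbracket, "....")
  expect_equal(bf$energy, 0)

  expect_error(brute_force_fold(strrep("GC", 20)), "refuses")
})

test_that("dot-bracket and pair-set representations are bijective", {
  set.seed(4)
  for (i in 1:20) {
    st <- random_structure(sample(10:40, 1))
    pairing <- dotbracket_to_pairing(st$dotbracket)
    expect_identical(tcsb:::pairing_to_dotbracket(pairing), st$dotbracket)
    expect_identical(tcsb:::pairing_to_pairs(pairing), st$pairs)
    if (nrow(st$pairs)) {
      expect_true(all(st$pairs[, 2] - st$pairs[, 1] > 3))
    }
  }
  expect_error(dotbracket_to_pairing("(()"), "unbalanced")
  expect_error(dotbracket_to_pairing("))(("), "unbalanced")
})

test_that("folding is deterministic and never beaten by any enumerated structure", {
  set.seed(5)
  bases <- c("A", "C", "G", "U")
  for (i in 1:40) {
    s <- paste(sample(bases, sample(8:16, 1), TRUE), collapse = "")
    f1 <- fold_mfe(s)
    f2 <- fold_mfe(s)
    expect_identical(f1$dotbracket, f2$dotbracket)
    expect_identical(f1$energy, f2$energy)
    # MFE <= open chain and <= oracle minimum (equality with the oracle)
    expect_lte(f1$energy, 0)
    bf <- brute_force_fold(s)
    expect_equal(f1$energy, bf$energy, tolerance = 1e-9)
    # the reported structure's own energy equals the reported MFE
    expect_equal(structure_energy(s, f1$dotbracket), f1$energy, tolerance = 1e-9)
  }
})

test_that("a single synonymous T>C change can rearrange the fixture's mRNA fold", {
  aln <- diagnostic_fixture()
  model <- energy_model(temperature = 3.5)
  rna <- stats::setNames(transcribe(aln$seqs), aln$ids)
  f_bga <- fold_mfe(rna[["BGa"]], model)
  f_bgp <- fold_mfe(rna[["BGp"]], model)
  key <- function(st) paste(st$pairs[, 1], st$pairs[, 2])
  expect_false(setequal(key(f_bga), key(f_bgp)))
})
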