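test_that("reverse_complement: examples, involution, error contract", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("AAAC"), "GTTT")
  for (s in 1:100) {
    x <- rand_seq(40, seed = 1000 + s)
    expect_identical(reverse_complement(reverse_complement(x)), x)
  }
  expect_error(reverse_complement("ACGNT"), "position 4")
})

test_that("dna_sequence rejects ambiguity codes and reports positions", {
  expect_identical(dna_sequence("acgtACGT"), "ACGTACGT")
  expect_error(dna_sequence("ACRGT"), "'R' at position 3")
  expect_error(dna_sequence("ACGT-N"), "position 5.*position 6")
})

test_that("shipped parameter set is complete and strand-symmetric", {
  p <- nn_params()
  stacks <- names(p$dH)
  expect_length(stacks, 16L)
  expect_true(all(is.finite(c(p$dH, p$dS))))
  # a stack and its reverse complement describe the same duplex step,
  # so the table must be strand-symmetric before symmetry properties of
  # nn_sum / Tm can be relied on
  for (st in stacks) {
    rc <- reverse_complement(st)
    expect_identical(p$dH[[st]], p$dH[[rc]])
    expect_identical(p$dS[[st]], p$dS[[rc]])
  }
})

test_that("nn_sum: single stack, oracle 10-mer, strand symmetry", {
  p <- nn_params()
  hs <- nn_sum("AT")
  # two A.T terminals + the single AT stack; "AT" is its own reverse
  # complement, so the symmetry correction applies too
  expect_equal(hs[["dH"]], p$dH[["AT"]] + 2 * p$init_dH_AT + p$sym_dH)
  expect_equal(hs[["dS"]], p$dS[["AT"]] + 2 * p$init_dS_AT + p$sym_dS)

  ten <- "GATCCGGATA"
  expect_equal(nn_sum(ten), oracle_nn_sum(ten), tolerance = 1e-12)

  for (s in 1:20) {
    x <- rand_seq(20, seed = 2000 + s)
    expect_equal(nn_sum(x), nn_sum(reverse_complement(x)),
                 tolerance = 1e-12)
  }
  expect_error(nn_sum("A"), "too short")
})

test_that("melting_temperature matches the independent oracle to 1e-9", {
  for (s in 1:30) {
    len <- 20 + (s * 7) %% 41
    x <- rand_seq(len, seed = 3000 + s)
    expect_equal(melting_temperature(x), tm_oracle(x), tolerance = 1e-9)
    expect_equal(
      melting_temperature(x, cond = thermo_conditions(0.2, 5e-7)),
      tm_oracle(x, na = 0.2, ct = 5e-7), tolerance = 1e-9)
  }
})

test_that("Tm strand symmetry, salt/concentration monotonicity, determinism", {
  x <- rand_seq(25, seed = 11)
  expect_equal(melting_temperature(x),
               melting_temperature(reverse_complement(x)),
               tolerance = 1e-9)

  tm_na <- vapply(c(0.05, 0.2, 1.0), function(na)
    melting_temperature(x, cond = thermo_conditions(na_molar = na)),
    numeric(1))
  expect_true(all(diff(tm_na) > 0))

  tm_ct <- vapply(c(1e-7, 1e-6, 1e-5), function(ct)
    melting_temperature(x, cond = thermo_conditions(ct_molar = ct)),
    numeric(1))
  expect_true(all(diff(tm_ct) > 0))

  expect_identical(melting_temperature(x), melting_temperature(x))
})

test_that("Tm is non-decreasing under A->G substitutions", {
  for (s in 1:20) {
    x <- rand_seq(30, seed = 4000 + s)
    pos <- which(strsplit(x, "")[[1]] == "A")
    if (!length(pos)) next
    base_tm <- melting_temperature(x)
    for (p in pos[seq_len(min(5, length(pos)))]) {
      y <- x
      substr(y, p, p) <- "G"
      expect_gte(melting_temperature(y), base_tm)
    }
  }
})

test_that("strand symmetry holds across many lengths", {
  for (s in 1:200) {
    len <- 20 + (s * 13) %% 41
    x <- rand_seq(len, seed = 5000 + s)
    expect_lt(abs(melting_temperature(x) -
                  melting_temperature(reverse_complement(x))), 1e-9)
  }
})
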