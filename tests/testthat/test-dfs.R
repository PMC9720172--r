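test_that("shrunk_overlap slices correctly and guards the floor", {
  g <- rand_seq(100, seed = 50)
  plan <- initial_split(100, 25)
  expect_identical(shrunk_overlap(g, plan, 2, 0, 0), substr(g, 26, 50))

  seq12 <- "AAACCCGGGTTT"
  plan12 <- segmentation_plan(c(0L, 12L, 24L), 24L, min_overlap_len = 9L)
  expect_identical(
    shrunk_overlap(paste0(seq12, seq12), plan12, 1, 2, 1,
                   min_overlap_len = 9L),
    "ACCCGGGTT")
  expect_error(shrunk_overlap(g, plan, 1, 6, 6), "min_overlap_len")

  # Tm of a shrunk overlap from scratch equals the profile path
  tm_direct <- melting_temperature(shrunk_overlap(g, plan, 2, 1, 2))
  prof <- oligodesign:::tm_profile(g)
  expect_equal(prof$tm(26L, 48L), tm_direct, tolerance = 1e-12)
})

test_that("overlap_std: closed forms and oracle", {
  expect_equal(overlap_std(c(70, 70, 70)), 0)
  expect_equal(overlap_std(c(68, 72)), 2)
  x <- c(61.2, 63.5, 60.1, 64.8, 62.2)
  expect_equal(overlap_std(x), oracle_pop_sd(x), tolerance = 1e-12)
  expect_error(overlap_std(70), "at least two")
})

test_that("dfs_optimize: B=0 degenerate case", {
  g <- rand_seq(120, seed = 51)
  r <- refine(g, initial_split(120, 25))
  o <- dfs_optimize(g, r$plan, cfg = optimizer_config(budget = 0))
  expect_true(all(o$assignment == 0L))
  expect_equal(o$std_tm, overlap_std(segment_tms(g, r$plan)),
               tolerance = 1e-12)
})

test_that("dfs_optimize equals exhaustive enumeration on small instances", {
  for (s in 1:8) {
    n <- 90 + 5 * s
    g <- rand_seq(n, seed = 7000 + s)
    r <- refine(g, initial_split(n, 28))
    B <- 1 + s %% 3
    o <- dfs_optimize(g, r$plan, cfg = optimizer_config(budget = B))
    oracle <- dfs_oracle(g, r$plan, budget = B)
    # the oracle recomputes every candidate Tm through an independent
    # code path; agreement is to thermo-oracle precision
    expect_equal(o$std_tm, oracle$std, tolerance = 1e-9)
    expect_identical(unname(o$assignment), unname(oracle$ab))
  }
})

test_that("pruning never changes the result", {
  for (s in 1:10) {
    n <- 100 + 10 * s
    g <- rand_seq(n, seed = 8000 + s)
    r <- refine(g, initial_split(n, 25))
    on <- dfs_optimize(g, r$plan, cfg = optimizer_config(budget = 2))
    off <- dfs_optimize(g, r$plan,
                        cfg = optimizer_config(budget = 2, prune = FALSE))
    expect_identical(on$std_tm, off$std_tm)
    expect_identical(on$assignment, off$assignment)
    expect_lte(on$nodes_explored, off$nodes_explored)
  }
})

test_that("dfs result never exceeds the unshrunk std, and is deterministic", {
  for (s in 1:6) {
    n <- 150 + 40 * s
    g <- rand_seq(n, seed = 9000 + s)
    r <- refine(g, initial_split(n, 25))
    o <- dfs_optimize(g, r$plan)
    expect_lte(o$std_tm, overlap_std(segment_tms(g, r$plan)) + 1e-12)
    o2 <- dfs_optimize(g, r$plan)
    expect_identical(o, o2)
  }
})

test_that("dfs errors on fewer than two overlaps", {
  g <- rand_seq(30, seed = 52)
  plan <- segmentation_plan(c(0L, 30L), 30L)
  expect_error(dfs_optimize(g, plan), "two overlaps")
})

test_that("one-end mode restricts left shrinks to zero", {
  g <- rand_seq(200, seed = 53)
  r <- refine(g, initial_split(200, 25))
  o <- dfs_optimize(g, r$plan,
                    cfg = optimizer_config(budget = 3, one_end = TRUE))
  expect_true(all(o$assignment[, "a"] == 0L))
})
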