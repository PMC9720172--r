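test_that("initial_split: exact, remainder, minimal and banded cases", {
  expect_identical(initial_split(100, 25)$boundaries,
                   c(0L, 25L, 50L, 75L, 100L))
  p <- initial_split(103, 25)
  expect_identical(diff(p$boundaries), c(26L, 26L, 26L, 25L))
  expect_identical(initial_split(50, 25)$boundaries, c(0L, 25L, 50L))
  expect_error(initial_split(30, 25), "at least")

  # the overlap-length band reshapes the count when round() would leave it
  for (n in c(155, 388, 1000)) for (t in c(20L, 25L, 30L)) {
    lens <- diff(initial_split(n, t)$boundaries)
    expect_true(all(lens >= 20 & lens <= 30),
                info = sprintf("n=%d t=%d lens=%s", n, t,
                               paste(lens, collapse = ",")))
    expect_identical(sum(lens), as.integer(n))
  }
})

test_that("segment_tms delegates to the thermo engine", {
  x <- rand_seq(25, seed = 21)
  plan <- segmentation_plan(c(0L, 25L), 25L)
  expect_equal(segment_tms(x, plan), melting_temperature(x),
               tolerance = 1e-12)

  # periodic sequence, equal phase-aligned segments: identical Tm
  per <- paste(rep("ACGTT", 24), collapse = "")   # 120 bp, period 5
  plan <- segmentation_plan(seq(0L, 120L, by = 20L), 120L)
  tms <- segment_tms(per, plan)
  expect_equal(max(tms) - min(tms), 0)

  # spot-check one segment against the independent oracle
  g <- rand_seq(120, seed = 22)
  plan <- initial_split(120, 25)
  b <- plan$boundaries
  tms <- segment_tms(g, plan)
  expect_equal(tms[2], tm_oracle(substr(g, b[2] + 1, b[3])),
               tolerance = 1e-9)
})

test_that("refine: converged input returned unchanged, history length 1", {
  per <- paste(rep("ACGTT", 24), collapse = "")
  plan <- segmentation_plan(seq(0L, 120L, by = 20L), 120L)
  r <- refine(per, plan)
  expect_identical(r$plan$boundaries, plan$boundaries)
  expect_length(r$history, 1L)
})

test_that("refine improves, tiles, stays monotone and is idempotent", {
  for (s in 1:10) {
    g <- rand_seq(120 + 30 * s, seed = 6000 + s)
    plan <- initial_split(nchar(g), 25)
    r <- refine(g, plan)
    expect_lte(tail(r$history, 1), r$initial_sd)
    expect_true(all(diff(c(r$initial_sd, r$history)) <= 0))
    # exact tiling conserved
    expect_identical(r$plan$boundaries[1], 0L)
    expect_identical(tail(r$plan$boundaries, 1), as.integer(nchar(g)))
    expect_true(all(diff(r$plan$boundaries) >= r$plan$min_overlap_len))
    # idempotence at convergence
    r2 <- refine(g, r$plan)
    expect_identical(r2$plan$boundaries, r$plan$boundaries)
    expect_length(r2$history, 1L)
  }
})

test_that("refine halts within max_iter and warns when capped", {
  g <- rand_seq(300, seed = 77)
  plan <- initial_split(300, 25)
  expect_warning(refine(g, plan, cfg = convergence_config(1e-12, 1L)),
                 "max_iter")
})

test_that("refine reaches the +/-3 window optimum on a 3-segment case", {
  g <- rand_seq(90, seed = 33)
  plan <- initial_split(90, 30)
  expect_identical(plan$L, 3L)
  r <- refine(g, plan)
  refined_sd <- tail(r$history, 1)
  # exhaustive oracle over all placements of the two internal
  # boundaries within +/-3 bp of the equal split, restricted to the
  # refiner's own feasible set (the 20-30 bp overlap-length band)
  b <- plan$boundaries
  best <- Inf
  for (d1 in -3:3) for (d2 in -3:3) {
    b1 <- b[2] + d1; b2 <- b[3] + d2
    lens <- c(b1, b2 - b1, 90 - b2)
    if (any(lens < 20 | lens > 30)) next
    tms <- c(tm_oracle(substr(g, 1, b1)),
             tm_oracle(substr(g, b1 + 1, b2)),
             tm_oracle(substr(g, b2 + 1, 90)))
    best <- min(best, oracle_pop_sd(tms))
  }
  expect_lte(refined_sd, best + 1e-9)
})

test_that("plan serializes to a BED-like table", {
  g <- rand_seq(100, seed = 44)
  plan <- initial_split(100, 25)
  bed <- plan_to_bed(g, plan, id = "g1")
  expect_identical(names(bed), c("chrom", "start", "end", "tm"))
  expect_identical(bed$start, c(0L, 25L, 50L, 75L))
  expect_identical(bed$end, c(25L, 50L, 75L, 100L))
})
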