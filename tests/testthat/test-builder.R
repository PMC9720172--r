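test_that("build_gapless on [0,25,50,75,100]: geometry forced by tiling", {
  g <- rand_seq(100, seed = 60)
  plan <- segmentation_plan(c(0L, 25L, 50L, 75L, 100L), 100L)
  oset <- build_gapless(g, plan)
  ol <- oset$oligos
  expect_identical(nrow(ol), 3L)
  expect_identical(ol$start, c(0L, 25L, 50L))
  expect_identical(ol$end, c(50L, 75L, 100L))
  expect_identical(ol$strand, c("sense", "antisense", "sense"))
  expect_identical(nrow(oset$gaps), 0L)

  # duplex check: 3' 25-mer of oligo 1 vs 3' 25-mer of oligo 2
  expect_identical(substr(ol$sequence[1], 26, 50),
                   reverse_complement(substr(ol$sequence[2], 26, 50)))

  # reconstruction: non-overlap prefixes of sense projections
  proj <- ifelse(ol$strand == "sense", ol$sequence,
                 vapply(ol$sequence, reverse_complement, "",
                        USE.NAMES = FALSE))
  expect_identical(paste0(substr(proj[1], 1, 25), substr(proj[2], 1, 25),
                          substr(proj[3], 1, 50)), g)

  # primer identity
  expect_identical(oset$primers$forward, substr(g, 1, 25))
  expect_identical(oset$primers$reverse,
                   reverse_complement(substr(g, 76, 100)))
  expect_length(check_oligo_set(oset), 0L)
})

test_that("build_gapped: zero assignment reproduces gapless exactly", {
  g <- rand_seq(150, seed = 61)
  r <- refine(g, initial_split(150, 25))
  a0 <- matrix(0L, r$plan$L, 2, dimnames = list(NULL, c("a", "b")))
  expect_identical(build_gapped(g, r$plan, a0), build_gapless(g, r$plan))
})

test_that("build_gapped: a single (1,1) shrink leaves exactly 2 gap bases", {
  g <- rand_seq(100, seed = 62)
  plan <- segmentation_plan(c(0L, 25L, 50L, 75L, 100L), 100L)
  asn <- matrix(0L, 4, 2, dimnames = list(NULL, c("a", "b")))
  asn[2, ] <- c(1L, 1L)
  oset <- build_gapped(g, plan, asn)
  gaps <- oset$gaps
  expect_identical(sum(gaps$end - gaps$start), 2L)
  expect_identical(sort(c(gaps$start, gaps$end)), c(25L, 26L, 49L, 50L))
  # both flanking oligos shortened accordingly
  expect_identical(oset$oligos$end[1], 49L)    # right trim of overlap 2
  expect_identical(oset$oligos$start[2], 26L)  # left trim of overlap 2
  # effective overlap is the shrunk interval
  expect_identical(oset$overlaps$start[2], 26L)
  expect_identical(oset$overlaps$end[2], 49L)
  expect_length(check_oligo_set(oset), 0L)
})

test_that("build_gapped rejects invalid assignments", {
  g <- rand_seq(100, seed = 63)
  plan <- segmentation_plan(c(0L, 25L, 50L, 75L, 100L), 100L)
  bad <- matrix(0L, 4, 2)
  bad[1, 1] <- 1L
  expect_error(build_gapped(g, plan, bad), "forward primer")
  bad <- matrix(0L, 4, 2)
  bad[2, ] <- c(6L, 6L)
  expect_error(build_gapped(g, plan, bad), "floor")
  expect_error(build_gapped(g, plan, matrix(0L, 3, 2)), "L x 2")
})

test_that("apply_tail: no-op when parity already closes, tail otherwise", {
  # 125 bp at target 25 -> L = 5, odd: no tail
  g5 <- rand_seq(125, seed = 64)
  t5 <- apply_tail(g5, 25)
  expect_identical(t5$seq, g5)
  expect_identical(t5$tail, "")

  # 100 bp at target 25 -> L = 4, even: tail appended, odd closure
  g4 <- rand_seq(100, seed = 65)
  t4 <- apply_tail(g4, 25, seed = 9)
  expect_gt(nchar(t4$tail), 0L)
  expect_identical(t4$seq, paste0(g4, t4$tail))
  expect_identical(initial_split(nchar(t4$seq), 25)$L %% 2L, 1L)

  # deterministic for a fixed seed
  expect_identical(apply_tail(g4, 25, seed = 9), t4)
  expect_false(identical(apply_tail(g4, 25, seed = 10)$tail, t4$tail))
})

test_that("design: full-pipeline invariants in both modes", {
  g <- rand_seq(500, seed = 66)
  gl <- design(g, design_config(mode = "gapless", seed = 2))
  expect_length(check_oligo_set(gl), 0L)
  gp <- design(g, design_config(mode = "gapped", seed = 2))
  expect_length(check_oligo_set(gp), 0L)
  expect_lte(gp$std_overlap_tm, gl$std_overlap_tm + 1e-12)
  # oligo length envelope at default target 25
  expect_true(all(gl$oligos$length >= 40 & gl$oligos$length <= 60))
  # alternating strands start on sense
  expect_identical(gl$oligos$strand[1:2], c("sense", "antisense"))
})

test_that("design reports the failing stage", {
  expect_error(design("ACGTN"), "\\[input\\]")
  expect_error(design(rand_seq(20, seed = 1)), "\\[split\\]|\\[tail\\]")
})
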