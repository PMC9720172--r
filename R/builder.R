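# Construction of the oligonucleotide set from a segmentation plan.
#
# Geometry: with segments (overlap regions) 1..L over boundaries
# b_1 = 0 < ... < b_{L+1} = n, oligo j (1-based, j = 1..L-1) covers
# segments j and j+1, i.e. the template interval [b_j, b_{j+2}).  Odd
# oligos sit on the sense strand, even oligos on the antisense strand,
# giving the alternating, shingle-like arrangement required for assembly
# by overlap extension.  Segment 1 is the forward-primer region (covered
# only by oligo 1) and segment L the reverse-primer region.
#
# Gapped mode: shrinking overlap i by (a_i, b_i) moves the effective
# duplex to [b_i + a_i, b_{i+1} - b_i).  The oligo whose end sits on a
# shrunk flank is trimmed to the effective overlap, so each excised base
# becomes a gap on exactly one strand, always strictly inside the
# opposite-strand oligo that spans it (the polymerase fills it during
# cycling).  Terminal flanks (left of overlap 1, right of overlap L)
# carry no oligo end; their shrinks are pinned to zero so the primers
# stay anchored on the template termini.

zero_assignment <- function(L) {
  m <- matrix(0L, nrow = L, ncol = 2L, dimnames = list(NULL, c("a", "b")))
  m
}

#' Build the oligo set for gapless (LCR / gapless PCR) assembly
#'
#' Produces the L-1 alternating-strand oligos whose overlaps tile the
#' input exactly, plus the PCR primers (forward primer = first overlap;
#' reverse primer = reverse complement of the last overlap).
#'
#' @inheritParams segment_tms
#' @return An object of class \code{oligo_set}; see
#'   \code{\link{build_gapped}} for the fields.
#' @export
build_gapless <- function(seq, plan, params = nn_params(),
                          cond = thermo_conditions()) {
  build_gapped(seq, plan, zero_assignment(plan$L), params, cond)
}

#' Build the oligo set for gapped PCR assembly
#'
#' As \code{\link{build_gapless}}, but each overlap is first shrunk by
#' the per-overlap (left, right) base counts of \code{assignment}; the
#' excised bases become single-strand gaps spanned by the opposite
#' strand.  The all-zero assignment reproduces the gapless build.
#'
#' @inheritParams segment_tms
#' @param assignment integer matrix with L rows and columns \code{a}
#'   (left shrink) and \code{b} (right shrink), e.g. from
#'   \code{\link{dfs_optimize}}.
#' @return An object of class \code{oligo_set}: a list with
#'   \describe{
#'     \item{oligos}{data.frame: index, strand, start, end (0-based
#'       half-open template coordinates), length, sequence (5'->3'),
#'       oligo_tm, left_overlap, right_overlap}
#'     \item{overlaps}{data.frame of effective overlap intervals with Tm}
#'     \item{gaps}{data.frame of single-strand gap intervals (empty for
#'       gapless) with the strand missing the bases}
#'     \item{primers}{list(forward, reverse), 5'->3'}
#'     \item{mean_overlap_tm, std_overlap_tm}{population statistics of
#'       the effective overlap Tm values}
#'   }
#'   plus the plan, assignment, conditions and input sequence.
#' @export
build_gapped <- function(seq, plan, assignment, params = nn_params(),
                         cond = thermo_conditions()) {
  seq <- dna_sequence(seq)
  L <- plan$L
  if (L < 2L) stop("need at least two overlaps to build oligos",
                   call. = FALSE)
  assignment <- validate_assignment(assignment, plan)
  prof <- tm_profile(seq, params, cond)
  if (prof$n != plan$n)
    stop("plan does not match sequence length", call. = FALSE)
  bo <- plan$boundaries
  a <- assignment[, "a"]; b <- assignment[, "b"]

  # effective overlaps
  ov_start <- bo[seq_len(L)] + a
  ov_end <- bo[seq_len(L) + 1L] - b
  ov_tm <- prof$tm(ov_start, ov_end)

  # oligo j spans [b_j + a_j, b_{j+2} - b_{j+1}) after trimming
  j <- seq_len(L - 1L)
  o_start <- bo[j] + a[j]
  o_end <- bo[j + 2L] - b[j + 1L]
  strand <- ifelse(j %% 2L == 1L, "sense", "antisense")
  region <- substring(seq, o_start + 1L, o_end)
  oseq <- ifelse(strand == "sense", region,
                 vapply(region, reverse_complement, character(1L),
                        USE.NAMES = FALSE))
  oligos <- data.frame(
    index = j,
    strand = strand,
    start = o_start,
    end = o_end,
    length = o_end - o_start,
    sequence = oseq,
    oligo_tm = prof$tm(o_start, o_end),
    left_overlap = j,
    right_overlap = j + 1L,
    stringsAsFactors = FALSE)

  # gaps: excised flanks of internal overlaps, each on the strand of the
  # trimmed oligo
  gaps <- list()
  for (i in seq_len(L)[-c(1L, L)]) {
    if (a[i] > 0L)             # left flank: trims oligo i's left end
      gaps[[length(gaps) + 1L]] <- data.frame(
        start = bo[i], end = bo[i] + a[i],
        strand = oligos$strand[i], overlap = i)
    if (b[i] > 0L)             # right flank: trims oligo (i-1)'s right end
      gaps[[length(gaps) + 1L]] <- data.frame(
        start = bo[i + 1L] - b[i], end = bo[i + 1L],
        strand = oligos$strand[i - 1L], overlap = i)
  }
  gaps <- if (length(gaps)) do.call(rbind, gaps) else
    data.frame(start = integer(0), end = integer(0),
               strand = character(0), overlap = integer(0))

  fwd <- substring(seq, ov_start[1L] + 1L, ov_end[1L])
  rev <- reverse_complement(substring(seq, ov_start[L] + 1L, ov_end[L]))

  structure(list(
    oligos = oligos,
    overlaps = data.frame(index = seq_len(L), start = ov_start,
                          end = ov_end, length = ov_end - ov_start,
                          tm = ov_tm),
    gaps = gaps,
    primers = list(forward = fwd, reverse = rev),
    mean_overlap_tm = mean(ov_tm),
    std_overlap_tm = pop_sd(ov_tm),
    plan = plan,
    assignment = assignment,
    conditions = cond,
    sequence = seq),
    class = "oligo_set")
}

validate_assignment <- function(assignment, plan) {
  L <- plan$L
  if (is.null(assignment)) return(zero_assignment(L))
  assignment <- as.matrix(assignment)
  storage.mode(assignment) <- "integer"
  if (nrow(assignment) != L || ncol(assignment) != 2L)
    stop("assignment must be an L x 2 (a, b) matrix", call. = FALSE)
  colnames(assignment) <- c("a", "b")
  if (any(assignment < 0L))
    stop("shrink counts must be non-negative", call. = FALSE)
  if (assignment[1L, "a"] != 0L)
    stop("first overlap's left shrink must be 0 (forward primer anchor)",
         call. = FALSE)
  if (assignment[L, "b"] != 0L)
    stop("last overlap's right shrink must be 0 (reverse primer anchor)",
         call. = FALSE)
  eff <- diff(plan$boundaries) - assignment[, "a"] - assignment[, "b"]
  if (any(eff < plan$min_overlap_len))
    stop(sprintf("overlap %d shrunk below the length floor",
                 which(eff < plan$min_overlap_len)[1L]), call. = FALSE)
  assignment
}

#' Append a 3' tail to close the imbricated structure
#'
#' The alternating oligo arrangement closes properly only when the
#' number of overlap segments L is odd (the last oligo then presents its
#' terminal overlap on the antisense side).  When the split implied by
#' \code{target_len} yields an even L, a pseudo-random tail of
#' \code{target_len} bases at about 50\% GC is appended to the 3' end so
#' the tailed sequence splits into an odd number of segments.  Candidate
#' tails are screened so the terminal overlap's Tm stays within 3 degrees
#' Celsius of the mean segment Tm; the tail can be removed from the
#' assembled product by PCR with specific primers.
#'
#' @param seq input sequence (character scalar, A/C/G/T).
#' @param target_len target overlap length in bp.
#' @param seed integer seed for tail generation.
#' @param params,cond thermodynamic parameter set and conditions used for
#'   tail screening.
#' @param max_tries candidate tails screened before falling back to the
#'   closest one (default 64).
#' @return list(seq = possibly tailed sequence, tail = appended suffix or
#'   "" if none was needed).
#' @export
apply_tail <- function(seq, target_len = 25L, seed = 1L,
                       params = nn_params(), cond = thermo_conditions(),
                       max_tries = 64L) {
  seq <- dna_sequence(seq)
  n <- nchar(seq)
  L <- split_count(n, target_len)
  if (L %% 2L == 1L) return(list(seq = seq, tail = ""))
  # tail length: target_len, nudged by up to 5 bp if the band-aware
  # split count of the tailed sequence would still come out even
  tl <- NA_integer_
  for (d in c(0L, as.vector(rbind(seq_len(5L), -seq_len(5L))))) {
    cand_tl <- target_len + d
    if (cand_tl < 10L) next
    if (split_count(n + cand_tl, target_len) %% 2L == 1L) {
      tl <- cand_tl
      break
    }
  }
  if (is.na(tl)) tl <- target_len      # give up on parity, still tail
  best <- NULL
  best_dev <- Inf
  with_local_seed(seed, {
    for (k in seq_len(max_tries)) {
      tail <- paste(sample(c("A", "C", "G", "T"), tl,
                           replace = TRUE), collapse = "")
      tailed <- paste0(seq, tail)
      plan <- initial_split(nchar(tailed), target_len)
      tms <- segment_tms(tailed, plan, params, cond)
      dev <- abs(tms[length(tms)] - mean(tms))
      if (dev < best_dev) {
        best_dev <- dev
        best <- tail
      }
      if (dev <= 3) break
    }
  })
  list(seq = paste0(seq, best), tail = best)
}

#' Design configuration
#'
#' Bundles every tunable of the design pipeline.
#'
#' @param target_len target overlap length in bp, 20-30 (default 25);
#'   yields oligos of roughly twice that length.
#' @param mode \code{"gapless"} (LCR / gapless PCR; overlaps tile the
#'   sequence) or \code{"gapped"} (end-shrink optimization introduces
#'   single-strand gaps).
#' @param var_threshold refinement convergence threshold in degrees
#'   Celsius (default 0.001).
#' @param budget DFS shrink budget per overlap in bp (default 3; gapped
#'   mode only).
#' @param min_overlap_len minimum overlap length in bp (default 15).
#' @param na_molar,ct_molar thermodynamic conditions (mol/L).
#' @param seed integer seed for stochastic choices (tail generation).
#' @param max_iter refinement sweep cap (default 1000).
#' @return An object of class \code{design_config}.
#' @export
design_config <- function(target_len = 25L, mode = c("gapless", "gapped"),
                          var_threshold = 0.001, budget = 3L,
                          min_overlap_len = 15L, na_molar = 0.05,
                          ct_molar = 1e-6, seed = 1L, max_iter = 1000L) {
  mode <- match.arg(mode)
  target_len <- as.integer(target_len)
  if (target_len < 20L || target_len > 30L)
    stop("target_len must be in [20, 30] bp", call. = FALSE)
  cfg <- list(target_len = target_len, mode = mode,
              var_threshold = var_threshold, budget = as.integer(budget),
              min_overlap_len = as.integer(min_overlap_len),
              na_molar = na_molar, ct_molar = ct_molar,
              seed = as.integer(seed), max_iter = as.integer(max_iter))
  # delegate bound checks to the per-module constructors
  thermo_conditions(na_molar, ct_molar)
  convergence_config(var_threshold, cfg$max_iter)
  optimizer_config(cfg$budget, cfg$min_overlap_len)
  structure(cfg, class = "design_config")
}

#' One-call oligonucleotide design
#'
#' Runs the full pipeline: 3'-tail parity fix, near-equal initial split,
#' iterative boundary refinement and, in gapped mode, the pruned
#' depth-first end-shrink optimization, then assembles the oligo set.
#'
#' @param seq input DNA sequence (character scalar, A/C/G/T, typically
#'   200 bp to 3 kb).
#' @param config a \code{\link{design_config}}.
#' @param params an \code{nn_params} object.
#' @return An \code{oligo_set} (see \code{\link{build_gapped}}) with an
#'   additional \code{design} element recording the config, tail,
#'   refinement history and (gapped mode) optimizer statistics.
#' @examples
#' set.seed(1)
#' gene <- random_gene(sequence_spec(length = 300, seed = 42))
#' oset <- design(gene, design_config(mode = "gapless"))
#' oset$std_overlap_tm
#' @export
design <- function(seq, config = design_config(), params = nn_params()) {
  cond <- thermo_conditions(config$na_molar, config$ct_molar)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  seq <- stage("input", dna_sequence(seq))
  tl <- stage("tail", apply_tail(seq, config$target_len, config$seed,
                                 params, cond))
  plan0 <- stage("split", initial_split(nchar(tl$seq), config$target_len,
                                        config$min_overlap_len))
  ref <- stage("refine", refine(tl$seq, plan0, params, cond,
                                convergence_config(config$var_threshold,
                                                   config$max_iter)))
  opt <- NULL
  if (config$mode == "gapped") {
    opt <- stage("dfs", dfs_optimize(tl$seq, ref$plan, params, cond,
                                     optimizer_config(config$budget,
                                                      config$min_overlap_len)))
    assignment <- opt$assignment
  } else {
    assignment <- zero_assignment(ref$plan$L)
  }
  oset <- stage("build", build_gapped(tl$seq, ref$plan, assignment,
                                      params, cond))
  oset$design <- list(config = config, tail = tl$tail,
                      input_length = nchar(seq),
                      initial_sd = ref$initial_sd,
                      refine_history = ref$history,
                      optimizer = if (!is.null(opt))
                        opt[c("mean_tm", "std_tm", "nodes_explored",
                              "pruned")])
  oset
}

#' @export
print.oligo_set <- function(x, ...) {
  cat(sprintf("Oligo set: %d oligos over %d bp (%s assembly)\n",
              nrow(x$oligos), x$plan$n,
              if (nrow(x$gaps)) "gapped" else "gapless"))
  cat(sprintf("  overlaps: %d, Tm mean %.2f C, std %.2f C\n",
              nrow(x$overlaps), x$mean_overlap_tm, x$std_overlap_tm))
  cat(sprintf("  oligo lengths: %d-%d bp; gaps: %d (%d bases)\n",
              min(x$oligos$length), max(x$oligos$length),
              nrow(x$gaps), sum(x$gaps$end - x$gaps$start)))
  cat(sprintf("  forward primer: %s\n  reverse primer: %s\n",
              x$primers$forward, x$primers$reverse))
  invisible(x)
}
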