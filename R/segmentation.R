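# Segmentation of the input sequence into overlap regions.
#
# A segmentation plan is a strictly increasing vector of 0-based cut
# positions b_0 = 0 < b_1 < ... < b_L = n; segment i is the half-open
# interval [b_{i-1}, b_i).  Each segment is one overlap region of the
# final assembly (the terminal segments double as the PCR primers).

#' Create a segmentation plan
#'
#' @param boundaries integer vector of 0-based cut positions, starting at
#'   0 and ending at the sequence length, strictly increasing.
#' @param n sequence length in bp.
#' @param min_overlap_len minimum segment length in bp (default 15); this
#'   is the hard validity floor (the post-shrink floor of the end-shrink
#'   optimizer).
#' @param seg_min,seg_max soft band for unshrunk overlap lengths in bp
#'   (defaults 20 and 30: splitting at 20-30 bp gives overlaps of
#'   20-30 bp and oligos of 40-60 bp).  The refiner will not move a
#'   boundary so that a segment leaves this band, but a plan whose
#'   segments already violate it is still valid.
#' @return An object of class \code{segmentation_plan} with elements
#'   \code{boundaries}, \code{n}, \code{L} (number of segments).
#' @export
segmentation_plan <- function(boundaries, n,
                              min_overlap_len = 15L,
                              seg_min = 20L, seg_max = 30L) {
  boundaries <- as.integer(boundaries)
  n <- as.integer(n)
  if (boundaries[1L] != 0L || boundaries[length(boundaries)] != n)
    stop("boundaries must start at 0 and end at n", call. = FALSE)
  if (any(diff(boundaries) <= 0L))
    stop("boundaries must be strictly increasing", call. = FALSE)
  if (any(diff(boundaries) < min_overlap_len))
    stop(sprintf("segment shorter than min_overlap_len = %d bp",
                 min_overlap_len), call. = FALSE)
  structure(list(boundaries = boundaries, n = n,
                 L = length(boundaries) - 1L,
                 min_overlap_len = as.integer(min_overlap_len),
                 seg_min = as.integer(seg_min),
                 seg_max = as.integer(seg_max)),
            class = "segmentation_plan")
}

segment_lengths <- function(plan) diff(plan$boundaries)

# Segment count for an n-bp sequence: round(n / target_len) when the
# resulting near-equal lengths stay inside the [seg_min, seg_max] band,
# else the closest count that does (ties toward fewer segments).
# Shared by initial_split() and the tail parity rule.
split_count <- function(n, target_len, seg_min = 20L, seg_max = 30L) {
  L_band <- seq.int(max(2L, ceiling(n / seg_max)),
                    max(2L, floor(n / seg_min)))
  L_band <- L_band[n %/% L_band >= seg_min &
                   (n %/% L_band) + (n %% L_band > 0L) <= seg_max]
  L_target <- max(2L, as.integer(round(n / target_len)))
  if (length(L_band))
    L_band[order(abs(L_band - L_target), L_band)][1L]
  else L_target                        # band unattainable: fall back
}

#' Initial near-equal split
#'
#' Divides \code{[0, n)} into \code{L} segments of near-equal length
#' (differing by at most 1 bp), distributing the leftover one base at a
#' time from the left.  \code{L} is \code{round(n / target_len)}
#' whenever that keeps all segments inside the \code{[seg_min,
#' seg_max]} overlap-length band; otherwise the closest segment count
#' that does (so that splitting at 20-30 bp always yields overlaps of
#' 20-30 bp and oligos of 40-60 bp).
#'
#' @param n sequence length in bp (must be at least \code{2 * target_len}).
#' @param target_len target overlap length in bp, 15-40.
#' @inheritParams segmentation_plan
#' @return A \code{segmentation_plan}.
#' @examples
#' initial_split(100, 25)$boundaries # 0 25 50 75 100
#' @export
initial_split <- function(n, target_len = 25L, min_overlap_len = 15L,
                          seg_min = 20L, seg_max = 30L) {
  n <- as.integer(n); target_len <- as.integer(target_len)
  if (target_len < 15L || target_len > 40L)
    stop("target_len must be in [15, 40] bp", call. = FALSE)
  if (n < 2L * target_len)
    stop(sprintf(
      "sequence too short to split: %d bp; need at least 2*target_len = %d bp",
      n, 2L * target_len), call. = FALSE)
  L <- split_count(n, target_len, seg_min, seg_max)
  base_len <- n %/% L
  extra <- n %% L          # first `extra` segments get one extra base
  lens <- rep(base_len, L)
  if (extra > 0L) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
  segmentation_plan(cumsum(c(0L, lens)), n, min_overlap_len,
                    seg_min, seg_max)
}

#' Per-segment melting temperatures
#'
#' @param seq the full input sequence (character scalar, A/C/G/T).
#' @param plan a \code{segmentation_plan} over \code{seq}.
#' @param params an \code{nn_params} object.
#' @param cond a \code{thermo_conditions} object.
#' @return Numeric vector of length \code{plan$L}: Tm in degrees Celsius
#'   of each segment.
#' @export
segment_tms <- function(seq, plan, params = nn_params(),
                        cond = thermo_conditions()) {
  prof <- tm_profile(seq, params, cond)
  if (prof$n != plan$n)
    stop("plan does not match sequence length", call. = FALSE)
  b <- plan$boundaries
  prof$tm(b[-length(b)], b[-1L])
}

# population standard deviation (divide by length), the convention used
# for all overlap-Tm spread statistics in this package
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(sum((x - m)^2) / length(x))
}

#' Convergence settings for boundary refinement
#'
#' @param var_threshold stop when the drop in overlap-Tm standard
#'   deviation between successive sweeps falls below this value, in
#'   degrees Celsius (default 0.001, which empirically yields rapid
#'   convergence).
#' @param max_iter sweep cap (default 1000).
#' @param max_shift largest per-sweep displacement of a single boundary,
#'   in bp.  The default \code{Inf} lets each boundary jump to the
#'   variance-minimizing position anywhere in its feasible window (exact
#'   coordinate descent); \code{max_shift = 1} restores the unit move
#'   set, which converges much more slowly and stalls in local minima on
#'   Tm-heterogeneous sequences.
#' @return An object of class \code{convergence_config}.
#' @export
convergence_config <- function(var_threshold = 0.001, max_iter = 1000L,
                               max_shift = Inf) {
  stopifnot(is.numeric(var_threshold), var_threshold > 0,
            max_iter >= 1L, max_shift >= 1)
  structure(list(var_threshold = var_threshold,
                 max_iter = as.integer(max_iter),
                 max_shift = max_shift),
            class = "convergence_config")
}

#' Iterative boundary refinement
#'
#' Repeatedly sweeps the internal boundaries left to right.  Each
#' boundary is moved, within \code{cfg$max_shift} bases and respecting
#' \code{min_overlap_len}, to the position minimizing the standard
#' deviation of the full segment-Tm vector; only strictly improving
#' moves are accepted (ties prefer no move, then the smaller
#' displacement, then leftward).  Sweeping stops when the drop in
#' standard deviation between successive sweeps falls below
#' \code{cfg$var_threshold}, or after \code{cfg$max_iter} sweeps (with a
#' warning).
#'
#' @inheritParams segment_tms
#' @param cfg a \code{convergence_config}.
#' @return A list with the refined \code{plan}, the final segment
#'   \code{tms}, \code{initial_sd} (the segment-Tm standard deviation of
#'   the input plan), and \code{history}: the standard deviation after
#'   each sweep (non-increasing; a plan that is already converged yields
#'   a history of length 1).
#' @export
refine <- function(seq, plan, params = nn_params(),
                   cond = thermo_conditions(),
                   cfg = convergence_config()) {
  if (plan$L < 2L) stop("refinement needs at least two segments",
                        call. = FALSE)
  prof <- tm_profile(seq, params, cond)
  if (prof$n != plan$n)
    stop("plan does not match sequence length", call. = FALSE)
  b <- plan$boundaries
  L <- plan$L
  mol <- plan$min_overlap_len
  tms <- prof$tm(b[-(L + 1L)], b[-1L])
  sd_cur <- pop_sd(tms)
  initial_sd <- sd_cur
  history <- numeric(0L)
  for (iter in seq_len(cfg$max_iter)) {
    sd_prev <- sd_cur
    for (j in 2:L) {            # internal boundaries b[j], 1-based index
      # allowed length window per adjacent segment: the [seg_min,
      # seg_max] band, never below min_overlap_len, and never worse
      # than the segment's current violation (if any)
      len_l <- b[j] - b[j - 1L]
      len_r <- b[j + 1L] - b[j]
      lo_len_l <- min(max(mol, plan$seg_min), len_l)
      hi_len_l <- max(plan$seg_max, len_l)
      lo_len_r <- min(max(mol, plan$seg_min), len_r)
      hi_len_r <- max(plan$seg_max, len_r)
      lo <- max(b[j - 1L] + lo_len_l, b[j + 1L] - hi_len_r,
                b[j] - cfg$max_shift)
      hi <- min(b[j - 1L] + hi_len_l, b[j + 1L] - lo_len_r,
                b[j] + cfg$max_shift)
      nb <- setdiff(lo:hi, b[j])
      if (!length(nb)) next
      t_left <- prof$tm(rep(b[j - 1L], length(nb)), nb)
      t_right <- prof$tm(nb, rep(b[j + 1L], length(nb)))
      # variance with segments j-1, j replaced, via running sums
      s1 <- sum(tms) - tms[j - 1L] - tms[j] + t_left + t_right
      s2 <- sum(tms^2) - tms[j - 1L]^2 - tms[j]^2 +
        t_left^2 + t_right^2
      sds <- sqrt(pmax(s2 / L - (s1 / L)^2, 0))
      # strict improvement; ties toward smaller displacement, then left
      ord <- order(sds, abs(nb - b[j]), nb)
      k <- ord[1L]
      if (sds[k] < sd_cur) {
        cand <- tms
        cand[j - 1L] <- t_left[k]
        cand[j] <- t_right[k]
        s_new <- pop_sd(cand)   # two-pass recompute for stability
        if (s_new < sd_cur) {
          b[j] <- nb[k]
          tms <- cand
          sd_cur <- s_new
        }
      }
    }
    history <- c(history, sd_cur)
    if (sd_prev - sd_cur < cfg$var_threshold) break
    if (iter == cfg$max_iter)
      warning("refine: max_iter reached before convergence", call. = FALSE)
  }
  list(plan = segmentation_plan(b, plan$n, mol, plan$seg_min,
                                plan$seg_max),
       tms = tms,
       initial_sd = initial_sd,
       history = history)
}

#' Serialize a plan to a BED-like table
#'
#' @inheritParams segment_tms
#' @param id sequence identifier for the first column.
#' @return A data.frame with columns \code{chrom}, \code{start},
#'   \code{end} (0-based half-open) and \code{tm}.
#' @export
plan_to_bed <- function(seq, plan, params = nn_params(),
                        cond = thermo_conditions(), id = "seq") {
  b <- plan$boundaries
  data.frame(chrom = id,
             start = b[-length(b)],
             end = b[-1L],
             tm = segment_tms(seq, plan, params, cond))
}
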