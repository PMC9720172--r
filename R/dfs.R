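# Depth-first search over per-overlap end shrinks.
#
# Each overlap i may lose a_i bases from its left end and b_i bases from
# its right end (a_i + b_i <= budget B, and the effective overlap keeps
# at least min_overlap_len bases).  The search explores overlaps left to
# right; a branch is cut when an admissible lower bound on the final
# overlap-Tm standard deviation already exceeds the best complete
# assignment found.  Shrunk bases become single-strand gaps in the gapped
# build; the first overlap's left end and the last overlap's right end
# are pinned (shrink 0) so the PCR primers stay anchored on the template
# termini.

#' Optimizer settings for the end-shrink search
#'
#' @param budget maximum total bases shrinkable per overlap (left + right),
#'   default 3.  Larger budgets allow more and longer gaps.
#' @param min_overlap_len minimum effective overlap length after
#'   shrinking, in bp (default 15, floor 10).
#' @param prune enable branch-and-bound pruning (default TRUE).  Pruning
#'   never changes the result, only the work done.
#' @param one_end restrict shrinking to the right end only
#'   (\code{a_i = 0} for all overlaps); default FALSE (both ends).
#' @return An object of class \code{optimizer_config}.
#' @export
optimizer_config <- function(budget = 3L, min_overlap_len = 15L,
                             prune = TRUE, one_end = FALSE) {
  budget <- as.integer(budget)
  min_overlap_len <- as.integer(min_overlap_len)
  if (budget < 0L) stop("budget must be >= 0", call. = FALSE)
  if (min_overlap_len < 10L)
    stop("min_overlap_len must be >= 10 bp", call. = FALSE)
  structure(list(budget = budget, min_overlap_len = min_overlap_len,
                 prune = isTRUE(prune), one_end = isTRUE(one_end)),
            class = "optimizer_config")
}

#' Extract a shrunk overlap subsequence
#'
#' @inheritParams segment_tms
#' @param i overlap (segment) index, 1-based.
#' @param a bases removed from the left end.
#' @param b bases removed from the right end.
#' @param min_overlap_len required residual length in bp.
#' @return The subsequence \code{[b_{i-1}+a, b_i-b)} as a character
#'   scalar.
#' @export
shrunk_overlap <- function(seq, plan, i, a, b, min_overlap_len = 15L) {
  bo <- plan$boundaries
  stopifnot(i >= 1L, i <= plan$L, a >= 0L, b >= 0L)
  s <- bo[i] + a
  e <- bo[i + 1L] - b
  if (e - s < min_overlap_len)
    stop(sprintf(
      "overlap %d: shrink (%d,%d) leaves %d bp < min_overlap_len %d",
      i, a, b, e - s, min_overlap_len), call. = FALSE)
  substr(seq, s + 1L, e)
}

#' Population standard deviation of overlap melting temperatures
#'
#' The spread statistic reported everywhere in this package: population
#' convention (divide by the number of overlaps, not n-1).
#'
#' @param tms numeric vector of overlap Tm values, length >= 2.
#' @return Non-negative numeric scalar, same units as \code{tms}.
#' @examples
#' overlap_std(c(68, 72)) # 2
#' @export
overlap_std <- function(tms) {
  if (length(tms) < 2L)
    stop("need at least two overlap Tm values", call. = FALSE)
  pop_sd(tms)
}

# Enumerate candidate (a, b) shrinks for one overlap: total ascending,
# then a ascending -- the fixed exploration / tie-break order.
shrink_candidates <- function(budget, max_total, one_end = FALSE,
                              pin_left = FALSE, pin_right = FALSE) {
  out <- list()
  for (tot in 0:min(budget, max_total)) {
    for (a in 0:tot) {
      b <- tot - a
      if (one_end && a > 0L) next
      if (pin_left && a > 0L) next
      if (pin_right && b > 0L) next
      out[[length(out) + 1L]] <- c(a = a, b = b)
    }
  }
  do.call(rbind, out)
}

#' Depth-first minimization of overlap-Tm spread by end shrinking
#'
#' Explores, overlap by overlap from left to right, every shrink pair
#' \code{(a, b)} with \code{a + b <= budget} that respects the overlap
#' length floor, and returns the assignment minimizing the population
#' standard deviation of the effective overlap melting temperatures.
#' With pruning enabled, a partial assignment is abandoned when even the
#' most favorable completion (remaining overlaps hitting the running mean
#' exactly) could not beat the best complete assignment found so far;
#' this bound is admissible, so pruning never changes the optimum.  Ties
#' in the final standard deviation are broken toward the smaller total
#' shrink (fewer gap bases), then the lexicographically smaller
#' assignment.
#'
#' @inheritParams segment_tms
#' @param cfg an \code{optimizer_config}.
#' @return An object of class \code{optimization_result}: list with
#'   \code{assignment} (L x 2 integer matrix of (a, b) shrinks),
#'   \code{overlap_tms}, \code{mean_tm}, \code{std_tm},
#'   \code{nodes_explored} and \code{pruned} counts.
#' @export
dfs_optimize <- function(seq, plan, params = nn_params(),
                         cond = thermo_conditions(),
                         cfg = optimizer_config()) {
  if (plan$L < 2L)
    stop("need at least two overlaps", call. = FALSE)
  prof <- tm_profile(seq, params, cond)
  if (prof$n != plan$n)
    stop("plan does not match sequence length", call. = FALSE)
  L <- plan$L
  bo <- plan$boundaries
  lens <- diff(bo)
  mol <- cfg$min_overlap_len

  # Per-overlap candidate tables: shrinks, effective Tm, total shrink.
  cand <- vector("list", L)
  for (i in seq_len(L)) {
    ab <- shrink_candidates(cfg$budget, lens[i] - mol, cfg$one_end,
                            pin_left = (i == 1L), pin_right = (i == L))
    if (is.null(ab) || nrow(ab) == 0L)
      stop(sprintf("overlap %d admits no shrink candidates", i),
           call. = FALSE)
    tm <- prof$tm(bo[i] + ab[, "a"], bo[i + 1L] - ab[, "b"])
    # candidates sharing a Tm are dominated by the (total, a)-first one:
    # identical std contribution, never a better tie-break
    keep <- !duplicated(tm)
    cand[[i]] <- list(ab = ab[keep, , drop = FALSE], tm = tm[keep],
                      tot = (ab[, "a"] + ab[, "b"])[keep])
  }

  nodes <- 0L
  pruned <- 0L
  best_sd <- Inf
  best_tot <- Inf
  best_pick <- integer(L)      # candidate row index per overlap
  pick <- integer(L)

  tm_of <- function(p) vapply(seq_len(L),
                              function(i) cand[[i]]$tm[p[i]], numeric(1L))
  tot_of <- function(p) sum(vapply(seq_len(L),
                                   function(i) cand[[i]]$tot[p[i]],
                                   integer(1L)))

  # assignment comparison for exact ties in std: smaller total shrink,
  # then lexicographically smaller (a_1, b_1, a_2, b_2, ...)
  lex_smaller <- function(p, q) {
    for (i in seq_len(L)) {
      ai <- cand[[i]]$ab[p[i], ]; aj <- cand[[i]]$ab[q[i], ]
      if (ai["a"] != aj["a"]) return(ai["a"] < aj["a"])
      if (ai["b"] != aj["b"]) return(ai["b"] < aj["b"])
    }
    FALSE
  }

  # Lower-bound machinery.  For a partial assignment over overlaps
  # 1..k with fixed Tms t_1..t_k, any completion's final sum of squares
  # about its own mean mu* satisfies
  #   SS_final = min_mu [ sum_fixed (t_i - mu)^2 + sum_rem (t_c(i) - mu)^2 ]
  #           >= min_mu [ SS_k + k (mu - m_k)^2
  #                       + sum_rem dist(mu, [lo_i, hi_i])^2 ]
  # where [lo_i, hi_i] is overlap i's candidate-Tm range.  The right-hand
  # side is convex piecewise-quadratic in mu and minimized in closed form
  # per breakpoint interval; the suffix interval tables below are
  # precomputed once.  The bound is admissible, so pruning never changes
  # the returned optimum (verified against the prune-off oracle).
  sorted_tm <- lapply(cand, function(ci) sort(ci$tm))
  lo <- vapply(sorted_tm, `[`, numeric(1L), 1L)
  hi <- vapply(sorted_tm, function(t) t[length(t)], numeric(1L))
  # suffix[[k]]: piecewise representation of
  #   F_k(mu) = sum_{i>k} min_c (t_ic - mu)^2
  # as interval-constant (S, Q) with F_k(mu) = Q - 2 S mu + N mu^2.
  # Breakpoints are the midpoints between adjacent candidate Tms of the
  # remaining overlaps; crossing one switches that overlap's nearest
  # candidate, updating S and Q by the candidate difference.
  suffix <- vector("list", L)
  for (k in (L - 1L):1L) {
    ids <- (k + 1L):L
    ev_mid <- unlist(lapply(sorted_tm[ids], function(t)
      if (length(t) > 1L) (t[-1L] + t[-length(t)]) / 2))
    ev_dS <- unlist(lapply(sorted_tm[ids], function(t)
      if (length(t) > 1L) diff(t)))
    ev_dQ <- unlist(lapply(sorted_tm[ids], function(t)
      if (length(t) > 1L) diff(t^2)))
    if (is.null(ev_mid)) {
      ev_mid <- ev_dS <- ev_dQ <- numeric(0)
    }
    o <- order(ev_mid)
    S <- c(0, cumsum(ev_dS[o])) + sum(lo[ids])
    Q <- c(0, cumsum(ev_dQ[o])) + sum(lo[ids]^2)
    suffix[[k]] <- list(left = c(-Inf, ev_mid[o]),
                        right = c(ev_mid[o], Inf),
                        S = S, Q = Q, N = length(ids))
  }
  # Best achievable final SS from prefix stats (k, s1, ss_k): minimize
  #   ss_k + k (mu - m_k)^2 + F_k(mu)
  # over mu, exactly, by closed form per interval.  Because the
  # remaining overlaps decouple given mu, this is not a relaxation: the
  # bound equals the optimal completion's final sum of squares.
  suffix_bound <- function(k, s1, ss_k) {
    sf <- suffix[[k]]
    mu <- pmin(pmax((s1 + sf$S) / (k + sf$N), sf$left), sf$right)
    h <- ss_k + k * mu^2 - 2 * s1 * mu + s1 * s1 / k +
      sf$Q - 2 * mu * sf$S + sf$N * mu^2
    sqrt(max(min(h), 0) / L)
  }

  # Incumbent seeding: a cheap greedy pass over a grid of target
  # temperatures (each overlap takes its candidate closest to the
  # target) gives the branch-and-bound a strong starting bound.  Every
  # greedy assignment lies inside the search space and the admissible
  # bound only discards provably worse subtrees, so seeding changes the
  # work done, never the optimum returned.
  consider <- function(p) {
    s <- pop_sd(tm_of(p))
    tt <- tot_of(p)
    if (s < best_sd ||
        (s == best_sd &&
         (tt < best_tot || (tt == best_tot && lex_smaller(p, best_pick))))) {
      best_sd <<- s
      best_tot <<- tt
      best_pick <<- p
    }
  }
  if (cfg$prune) {
    # Exact seed by a one-dimensional scan: because the sum of squares
    # about the mean equals min over mu of the sum of squares about mu,
    # the unconstrained optimum of the std objective is
    #   min_mu F(mu),  F(mu) = sum_i min_c (t_ic - mu)^2,
    # a piecewise-quadratic function whose pieces are delimited by the
    # midpoints of adjacent candidate Tms.  Seeding the incumbent with
    # its argmin makes the subsequent depth-first certification sharp.
    mids <- unlist(lapply(sorted_tm, function(t)
      if (length(t) > 1L) (t[-1L] + t[-length(t)]) / 2))
    edges <- sort(unique(c(min(lo) - 1, mids, max(hi) + 1)))
    reps <- (edges[-1L] + edges[-length(edges)]) / 2
    nearest <- vapply(sorted_tm, function(t)
      t[pmin(pmax(findInterval(reps, (t[-1L] + t[-length(t)]) / 2) + 1L,
                  1L), length(t))], numeric(length(reps)))
    nearest <- matrix(nearest, nrow = length(reps))
    mu_star <- pmin(pmax(rowMeans(nearest), edges[-length(edges)]),
                    edges[-1L])
    fval <- rowSums((nearest - mu_star)^2)
    mu_opt <- mu_star[which.min(fval)]
    consider(vapply(cand, function(ci)
      which.min(abs(ci$tm - mu_opt)), integer(1L)))
  }

  # depth-first over overlaps; running sum / sum of squares of the fixed
  # overlap Tms give the admissible bound sqrt(SS_about_running_mean / L).
  # The bound check carries a tiny relative slack so that floating-point
  # noise in the incremental sums can never prune an exact tie; complete
  # assignments are re-scored with the same two-pass formula the rest of
  # the package (and the exhaustive oracle) uses.
  recurse <- function(k, s1, s2, tot) {
    for (r in seq_len(nrow(cand[[k]]$ab))) {
      nodes <<- nodes + 1L
      t <- cand[[k]]$tm[r]
      ns1 <- s1 + t
      ns2 <- s2 + t * t
      ntot <- tot + cand[[k]]$tot[r]
      if (cfg$prune && is.finite(best_sd)) {
        ss_k <- max(ns2 - ns1 * ns1 / k, 0)  # SS of fixed Tms about mean
        bound <- if (k < L) suffix_bound(k, ns1, ss_k)
                 else sqrt(ss_k / L)
        if (bound > best_sd + 1e-12 * (1 + best_sd)) {
          pruned <<- pruned + 1L
          next
        }
      }
      if (k == L) {
        pick[k] <<- r
        sd_full <- pop_sd(vapply(seq_len(L),
                                 function(i) cand[[i]]$tm[pick[i]],
                                 numeric(1L)))
        if (sd_full < best_sd ||
            (sd_full == best_sd &&
             (ntot < best_tot ||
              (ntot == best_tot && lex_smaller(pick, best_pick))))) {
          best_sd <<- sd_full
          best_tot <<- ntot
          best_pick <<- pick
        }
      } else {
        pick[k] <<- r
        recurse(k + 1L, ns1, ns2, ntot)
      }
    }
  }
  recurse(1L, 0, 0, 0L)

  ab <- t(vapply(seq_len(L),
                 function(i) cand[[i]]$ab[best_pick[i], ],
                 integer(2L)))
  colnames(ab) <- c("a", "b")
  tms <- vapply(seq_len(L), function(i) cand[[i]]$tm[best_pick[i]],
                numeric(1L))
  structure(list(assignment = ab,
                 overlap_tms = tms,
                 mean_tm = mean(tms),
                 std_tm = pop_sd(tms),
                 nodes_explored = nodes,
                 pruned = pruned),
            class = "optimization_result")
}
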