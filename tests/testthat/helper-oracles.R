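# Independent oracles, deliberately sharing no code with the package.
#
# tm_oracle(): a from-scratch nearest-neighbor Tm computed by an explicit
# per-position loop over the SantaLucia (1998) unified table (values typed
# in here independently of inst/extdata), the two-state Tm equation and
# the Owczarzy (2004) monovalent correction on 1/Tm.
#
# dfs_oracle(): exhaustive enumeration of every shrink assignment with
# the documented (std, total shrink, lexicographic) tie-break.

ORACLE_NN <- list(
  AA = c(-7.9, -22.2), TT = c(-7.9, -22.2),
  AT = c(-7.2, -20.4), TA = c(-7.2, -21.3),
  CA = c(-8.5, -22.7), TG = c(-8.5, -22.7),
  GT = c(-8.4, -22.4), AC = c(-8.4, -22.4),
  CT = c(-7.8, -21.0), AG = c(-7.8, -21.0),
  GA = c(-8.2, -22.2), TC = c(-8.2, -22.2),
  CG = c(-10.6, -27.2), GC = c(-9.8, -24.4),
  GG = c(-8.0, -19.9), CC = c(-8.0, -19.9))

oracle_revcomp <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_nn_sum <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  dH <- 0; dS <- 0
  for (i in 1:(n - 1)) {
    v <- ORACLE_NN[[paste0(ch[i], ch[i + 1])]]
    dH <- dH + v[1]
    dS <- dS + v[2]
  }
  for (e in ch[c(1, n)]) {
    if (e == "A" || e == "T") { dH <- dH + 2.3; dS <- dS + 4.1 }
    else { dH <- dH + 0.1; dS <- dS - 2.8 }
  }
  if (seq == oracle_revcomp(seq)) dS <- dS - 1.4
  c(dH = dH, dS = dS)
}

tm_oracle <- function(seq, na = 0.05, ct = 1e-6) {
  hs <- oracle_nn_sum(seq)
  x <- if (seq == oracle_revcomp(seq)) 1 else 4
  tm1 <- 1000 * hs[["dH"]] / (hs[["dS"]] + 1.9872 * log(ct / x))
  ch <- strsplit(seq, "")[[1]]
  fgc <- sum(ch == "G" | ch == "C") / length(ch)
  inv <- 1 / tm1 + (4.29 * fgc - 3.95) * 1e-5 * log(na) +
    9.40e-6 * log(na)^2
  1 / inv - 273.15
}

oracle_pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# all shrink candidates for one overlap, in (total, a) order, honoring
# the terminal pins
oracle_candidates <- function(seg_len, budget, i, L, floor_len = 15) {
  out <- list()
  for (tot in 0:min(budget, seg_len - floor_len)) for (a in 0:tot) {
    b <- tot - a
    if (i == 1 && a > 0) next
    if (i == L && b > 0) next
    out[[length(out) + 1]] <- c(a = a, b = b)
  }
  do.call(rbind, out)
}

# exhaustive minimum over all assignments; returns list(std, assignment)
dfs_oracle <- function(seq, plan, budget, na = 0.05, ct = 1e-6) {
  bo <- plan$boundaries
  L <- plan$L
  lens <- diff(bo)
  cands <- lapply(seq_len(L), function(i) {
    ab <- oracle_candidates(lens[i], budget, i, L)
    tm <- apply(ab, 1, function(r)
      tm_oracle(substr(seq, bo[i] + r["a"] + 1, bo[i + 1] - r["b"]),
                na, ct))
    list(ab = ab, tm = tm)
  })
  grid <- expand.grid(lapply(cands, function(ci) seq_len(nrow(ci$ab))))
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    idx <- as.integer(grid[r, ])
    tms <- vapply(seq_len(L), function(i) cands[[i]]$tm[idx[i]], 0)
    ab <- do.call(rbind, lapply(seq_len(L),
                                function(i) cands[[i]]$ab[idx[i], ]))
    key <- list(std = oracle_pop_sd(tms), tot = sum(ab), ab = ab)
    if (is.null(best) || oracle_better(key, best)) best <- key
  }
  best
}

oracle_better <- function(x, y) {
  if (x$std != y$std) return(x$std < y$std)
  if (x$tot != y$tot) return(x$tot < y$tot)
  xf <- as.vector(t(x$ab)); yf <- as.vector(t(y$ab))
  d <- which(xf != yf)
  length(d) > 0 && xf[d[1]] < yf[d[1]]
}

# deterministic random A/C/G/T string without touching the suite's RNG
# decisions: uses the package generator, which restores RNG state
rand_seq <- function(len, seed, gc = 0.5) {
  substr(random_gene(sequence_spec(max(len, 50), gc_fraction = gc,
                                   seed = seed)), 1, len)
}
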