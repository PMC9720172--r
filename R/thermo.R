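# Nearest-neighbor melting-temperature engine.
#
# Duplex dH/dS are sums over adjacent dinucleotide stacks plus initiation
# terms (split by terminal A.T vs G.C) and a symmetry correction for
# self-complementary duplexes.  Tm at 1 M Na+ follows
#   Tm[K] = 1000*dH / (dS + R*ln(CT/x))
# and monovalent salt is corrected on the reciprocal temperature
# (Owczarzy 2004, eq. 22); full provenance in the parameter file header
# (inst/extdata/santalucia1998_unified_nn.tsv).

# gas constant, cal/(mol K)
.R_GAS <- 1.9872

#' Validate and normalize a DNA sequence
#'
#' Accepts a character scalar over the alphabet A/C/G/T (case-insensitive)
#' and returns the upper-cased sequence.  Ambiguity codes (N, R, Y, ...),
#' gaps and whitespace are rejected: chemical synthesis requires a fully
#' specified sequence.
#'
#' @param x character scalar, the candidate sequence.
#' @param min_len minimum accepted length in bp (default 1).
#' @return The validated, upper-cased sequence as a character scalar.
#' @examples
#' dna_sequence("acgtACGT")
#' @export
dna_sequence <- function(x, min_len = 1L) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("sequence must be a single character string", call. = FALSE)
  x <- toupper(x)
  bad <- gregexpr("[^ACGT]", x)[[1L]]
  if (bad[1L] != -1L) {
    chars <- substring(x, bad, bad)
    stop(sprintf(
      "sequence contains non-ACGT character(s): %s",
      paste(sprintf("'%s' at position %d", chars, bad), collapse = ", ")),
      call. = FALSE)
  }
  if (nchar(x) < min_len)
    stop(sprintf("sequence too short: %d bp (minimum %d bp)",
                 nchar(x), min_len), call. = FALSE)
  x
}

#' Reverse complement of a DNA sequence
#'
#' @param seq character scalar over A/C/G/T.
#' @return The Watson-Crick reverse complement, 5'->3'.
#' @examples
#' reverse_complement("AAAC") # "GTTT"
#' @export
reverse_complement <- function(seq) {
  seq <- dna_sequence(seq)
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1L]]), collapse = ""))
}

#' Load a nearest-neighbor parameter set
#'
#' Reads a TSV with columns \code{stack}, \code{dH_kcal_mol},
#' \code{dS_cal_molK}.  The 16 dinucleotide rows carry the stacking terms;
#' reserved rows \code{INIT_AT}/\code{INIT_GC} carry the per-terminal
#' duplex initiation terms and \code{SYM} the symmetry correction for
#' self-complementary duplexes.  The default file ships the SantaLucia
#' (1998) unified set.
#'
#' @param path path to the parameter TSV; default is the packaged
#'   SantaLucia 1998 unified set.
#' @return An object of class \code{nn_params}: a list with named numeric
#'   vectors \code{dH}, \code{dS} (indexed by dinucleotide), and scalars
#'   \code{init_dH_AT}, \code{init_dS_AT}, \code{init_dH_GC},
#'   \code{init_dS_GC}, \code{sym_dH}, \code{sym_dS}.
#' @export
nn_params <- function(path = system.file("extdata",
                                         "santalucia1998_unified_nn.tsv",
                                         package = "oligodesign")) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("stack", "dH_kcal_mol", "dS_cal_molK") %in% names(tab)))
  stacks <- c("AA","AC","AG","AT","CA","CC","CG","CT",
              "GA","GC","GG","GT","TA","TC","TG","TT")
  miss <- setdiff(c(stacks, "INIT_AT", "INIT_GC", "SYM"), tab$stack)
  if (length(miss))
    stop("parameter file missing rows: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(is.finite(tab$dH_kcal_mol)) || !all(is.finite(tab$dS_cal_molK)))
    stop("non-finite thermodynamic parameters", call. = FALSE)
  row <- function(k) tab[match(k, tab$stack), , drop = FALSE]
  dH <- stats::setNames(tab$dH_kcal_mol[match(stacks, tab$stack)], stacks)
  dS <- stats::setNames(tab$dS_cal_molK[match(stacks, tab$stack)], stacks)
  structure(list(
    dH = dH, dS = dS,
    init_dH_AT = row("INIT_AT")$dH_kcal_mol,
    init_dS_AT = row("INIT_AT")$dS_cal_molK,
    init_dH_GC = row("INIT_GC")$dH_kcal_mol,
    init_dS_GC = row("INIT_GC")$dS_cal_molK,
    sym_dH = row("SYM")$dH_kcal_mol,
    sym_dS = row("SYM")$dS_cal_molK),
    class = "nn_params")
}

#' Thermodynamic conditions for melting-temperature calculation
#'
#' @param na_molar monovalent cation concentration in mol/L (default
#'   0.05 M, a conventional assembly buffer).
#' @param ct_molar total oligonucleotide strand concentration in mol/L
#'   (default 1e-6 M).
#' @return An object of class \code{thermo_conditions}.
#' @export
thermo_conditions <- function(na_molar = 0.05, ct_molar = 1e-6) {
  if (!is.numeric(na_molar) || length(na_molar) != 1L || na_molar <= 0)
    stop("na_molar must be a positive number (mol/L)", call. = FALSE)
  if (!is.numeric(ct_molar) || length(ct_molar) != 1L || ct_molar <= 0)
    stop("ct_molar must be a positive number (mol/L)", call. = FALSE)
  structure(list(na_molar = na_molar, ct_molar = ct_molar),
            class = "thermo_conditions")
}

is_self_complementary <- function(seq) {
  identical(seq, reverse_complement(seq))
}

#' Nearest-neighbor enthalpy and entropy sums
#'
#' Sums stacking terms over the n-1 adjacent dinucleotides, adds the
#' initiation terms for the two terminal base pairs, and the symmetry
#' correction if the sequence is self-complementary.
#'
#' @param seq character scalar over A/C/G/T, length >= 2.
#' @param params an \code{nn_params} object.
#' @return Named numeric vector \code{c(dH = kcal/mol, dS = cal/(mol K))}.
#' @export
nn_sum <- function(seq, params = nn_params()) {
  seq <- dna_sequence(seq)
  n <- nchar(seq)
  if (n < 2L)
    stop("sequence too short for nearest-neighbor model (need >= 2 bp)",
         call. = FALSE)
  st <- substring(seq, 1:(n - 1L), 2:n)
  dH <- sum(params$dH[st])
  dS <- sum(params$dS[st])
  ends <- substring(seq, c(1L, n), c(1L, n))
  for (e in ends) {
    if (e %in% c("A", "T")) {
      dH <- dH + params$init_dH_AT
      dS <- dS + params$init_dS_AT
    } else {
      dH <- dH + params$init_dH_GC
      dS <- dS + params$init_dS_GC
    }
  }
  if (is_self_complementary(seq)) {
    dH <- dH + params$sym_dH
    dS <- dS + params$sym_dS
  }
  c(dH = unname(dH), dS = unname(dS))
}

# Core Tm from precomputed dH (kcal/mol), dS (cal/mol K), GC fraction and
# symmetry factor; vectorized over dH/dS/fgc.  Shared by the public API and
# the O(1) windowed-Tm profile used by segmentation and the DFS.
tm_from_sums <- function(dH, dS, fgc, x, cond) {
  denom <- dS + .R_GAS * log(cond$ct_molar / x)
  if (any(denom >= 0))
    stop("non-physical duplex: dS + R*ln(CT/x) must be negative",
         call. = FALSE)
  tm1m <- 1000 * dH / denom
  if (any(tm1m <= 0))
    stop("non-physical duplex: negative absolute temperature", call. = FALSE)
  lna <- log(cond$na_molar)
  inv <- 1 / tm1m + (4.29 * fgc - 3.95) * 1e-5 * lna + 9.40e-6 * lna * lna
  1 / inv - 273.15
}

#' Duplex melting temperature
#'
#' Nearest-neighbor melting temperature of the duplex formed by \code{seq}
#' and its perfect complement, in degrees Celsius.  Uses
#' \code{Tm(1M Na+) = 1000*dH / (dS + R ln(CT/x))} with \code{x = 4} for
#' non-self-complementary duplexes (1 for self-complementary, detected
#' automatically), followed by the Owczarzy (2004) monovalent-salt
#' correction on 1/Tm.  See the parameter file header for the exact
#' formulas.
#'
#' @inheritParams nn_sum
#' @param cond a \code{thermo_conditions} object.
#' @return Melting temperature in degrees Celsius (numeric scalar).
#' @examples
#' melting_temperature("ACGTACGTACGTACGTACGTACGT")
#' @export
melting_temperature <- function(seq, params = nn_params(),
                                cond = thermo_conditions()) {
  seq <- dna_sequence(seq)
  hs <- nn_sum(seq, params)
  n <- nchar(seq)
  fgc <- (n - nchar(gsub("[GC]", "", seq))) / n
  x <- if (is_self_complementary(seq)) 1 else 4
  tm_from_sums(hs[["dH"]], hs[["dS"]], fgc, x, cond)
}

# Precomputed profile over a fixed sequence allowing O(1) Tm of any window
# [start, end) in 0-based half-open coordinates.  Initiation terms depend
# only on the window's terminal bases; the symmetry correction is applied
# when the window happens to be self-complementary (rare for gene
# fragments but kept for exactness with melting_temperature()).
tm_profile <- function(seq, params = nn_params(), cond = thermo_conditions()) {
  seq <- dna_sequence(seq, min_len = 2L)
  n <- nchar(seq)
  base <- strsplit(seq, "", fixed = TRUE)[[1L]]
  st <- paste0(base[-n], base[-1L])
  cumH <- c(0, cumsum(params$dH[st]))
  cumS <- c(0, cumsum(params$dS[st]))
  is_gc <- base %in% c("G", "C")
  cumGC <- c(0L, cumsum(is_gc))
  initH <- ifelse(is_gc, params$init_dH_GC, params$init_dH_AT)
  initS <- ifelse(is_gc, params$init_dS_GC, params$init_dS_AT)
  force(cond)
  list(
    n = n,
    seq = seq,
    substr = function(start, end) substr(seq, start + 1L, end),
    # Tm of window [start, end), 0-based half-open; vectorized
    tm = function(start, end) {
      len <- end - start
      stopifnot(all(start >= 0L), all(end <= n), all(len >= 2L))
      dH <- cumH[end] - cumH[start + 1L] + initH[start + 1L] + initH[end]
      dS <- cumS[end] - cumS[start + 1L] + initS[start + 1L] + initS[end]
      fgc <- (cumGC[end + 1L] - cumGC[start + 1L]) / len
      x <- rep(4, length(start))
      sub <- substring(seq, start + 1L, end)
      selfc <- vapply(sub, is_self_complementary, logical(1L),
                      USE.NAMES = FALSE)
      if (any(selfc)) {
        dH[selfc] <- dH[selfc] + params$sym_dH
        dS[selfc] <- dS[selfc] + params$sym_dS
        x[selfc] <- 1
      }
      unname(tm_from_sums(dH, dS, fgc, x, cond))
    })
}
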