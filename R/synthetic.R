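# Seeded synthetic-sequence generators.  All generators are pure
# functions of their spec: they save and restore the caller's RNG state,
# so fixtures are reproducible and never perturb user code.

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification for a synthetic test gene
#'
#' @param length sequence length in bp (minimum 50).
#' @param gc_fraction target GC fraction in \code{[0, 1]} (default 0.5).
#' @param seed integer seed; fixes the sequence completely.
#' @param motif_inserts optional list of \code{list(position =, motif =)}
#'   entries (0-based position) spliced over the random background to
#'   build Tm-heterogeneous stress cases.
#' @return An object of class \code{sequence_spec}.
#' @export
sequence_spec <- function(length, gc_fraction = 0.5, seed = 1L,
                          motif_inserts = NULL) {
  length <- as.integer(length)
  if (length < 50L) stop("length must be >= 50 bp", call. = FALSE)
  if (gc_fraction < 0 || gc_fraction > 1)
    stop("gc_fraction must be in [0, 1]", call. = FALSE)
  structure(list(length = length, gc_fraction = gc_fraction,
                 seed = as.integer(seed), motif_inserts = motif_inserts),
            class = "sequence_spec")
}

#' Generate a random test gene
#'
#' Independent draws per position: G/C with probability
#' \code{gc_fraction} (split evenly between G and C), A/T otherwise.
#' Deterministic for a fixed spec.
#'
#' @param spec a \code{\link{sequence_spec}}.
#' @return A character scalar over A/C/G/T of the requested length.
#' @export
random_gene <- function(spec) {
  stopifnot(inherits(spec, "sequence_spec"))
  g <- spec$gc_fraction / 2
  a <- (1 - spec$gc_fraction) / 2
  s <- with_local_seed(spec$seed,
    paste(sample(c("A", "C", "G", "T"), spec$length, replace = TRUE,
                 prob = c(a, g, g, a)), collapse = ""))
  for (mi in spec$motif_inserts) {
    motif <- dna_sequence(mi$motif)
    pos <- as.integer(mi$position)
    if (pos < 0L || pos + nchar(motif) > spec$length)
      stop(sprintf("motif at position %d (length %d) out of bounds",
                   pos, nchar(motif)), call. = FALSE)
    substr(s, pos + 1L, pos + nchar(motif)) <- motif
  }
  s
}

#' Generate a GC-gradient stress gene
#'
#' Per-position GC probability ramps linearly from about 30\% at the 5'
#' end to about 70\% at the 3' end, forcing the boundary refiner and the
#' end-shrink search to produce unequal segment lengths (the
#' high-GC-content stress case).
#'
#' @param length sequence length in bp (minimum 200).
#' @param seed integer seed.
#' @return A character scalar over A/C/G/T.
#' @export
gc_gradient_gene <- function(length, seed = 1L) {
  length <- as.integer(length)
  if (length < 200L) stop("length must be >= 200 bp", call. = FALSE)
  p_gc <- seq(0.3, 0.7, length.out = length)
  with_local_seed(seed, {
    gc <- stats::runif(length) < p_gc
    strong <- sample(c("G", "C"), length, replace = TRUE)
    weak <- sample(c("A", "T"), length, replace = TRUE)
    paste(ifelse(gc, strong, weak), collapse = "")
  })
}

gc_fraction_of <- function(seq) {
  (nchar(seq) - nchar(gsub("[GC]", "", seq))) / nchar(seq)
}
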