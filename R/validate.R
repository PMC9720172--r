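# Structural invariant checks for an emitted oligo set.  Used by the
# test suite and by the `validate` CLI subcommand; every check works
# from the emitted oligo strings and coordinates alone, so a report can
# be re-validated without the original input.

# Project an oligo's 5'->3' string back onto the sense strand of the
# template interval [start, end).
sense_projection <- function(oligo_row) {
  if (oligo_row$strand == "sense") oligo_row$sequence
  else reverse_complement(oligo_row$sequence)
}

#' Check the structural invariants of an oligo set
#'
#' Verifies: alternating strands; mutual consistency of every pair of
#' oligos wherever their template intervals intersect (duplex regions
#' must be exact reverse complements); full two-strand coverage of the
#' template; single-strand gaps lying strictly inside an opposite-strand
#' oligo; primer identity with the first/last effective overlap; and, if
#' the set carries its template sequence, exact reconstruction.
#'
#' @param x an \code{oligo_set} (from \code{\link{design}},
#'   \code{\link{build_gapless}}, \code{\link{build_gapped}} or
#'   \code{\link{read_report_tsv}}).
#' @return Character vector of violation messages; empty when the set is
#'   structurally sound.
#' @export
check_oligo_set <- function(x) {
  bad <- character(0)
  ol <- x$oligos
  n_ol <- nrow(ol)
  if (n_ol < 1L) return("no oligos")

  want <- rep(c("sense", "antisense"), length.out = n_ol)
  if (!identical(ol$strand, want) &&
      !identical(ol$strand, rep(c("antisense", "sense"),
                                length.out = n_ol)))
    bad <- c(bad, "strands do not strictly alternate")

  n <- max(ol$end)
  if (min(ol$start) != 0L)
    bad <- c(bad, "first oligo does not start at template position 0")

  # rebuild the template from sense projections; any disagreement
  # between two oligos covering the same base is a duplex violation
  tpl <- rep(NA_character_, n)
  for (j in seq_len(n_ol)) {
    proj <- strsplit(sense_projection(ol[j, ]), "", fixed = TRUE)[[1L]]
    idx <- (ol$start[j] + 1L):ol$end[j]
    if (length(proj) != length(idx)) {
      bad <- c(bad, sprintf("oligo %d: length does not match coordinates",
                            ol$index[j]))
      next
    }
    seen <- !is.na(tpl[idx])
    if (any(tpl[idx][seen] != proj[seen]))
      bad <- c(bad, sprintf(
        "oligo %d: duplex mismatch with a previous oligo at template %s",
        ol$index[j],
        paste(idx[seen][tpl[idx][seen] != proj[seen]] - 1L,
              collapse = ",")))
    tpl[idx] <- proj
  }
  if (anyNA(tpl))
    bad <- c(bad, sprintf("template bases covered by no oligo: %s",
                          paste(which(is.na(tpl)) - 1L, collapse = ",")))
  template <- paste(tpl, collapse = "")
  if (!is.null(x$sequence) && !anyNA(tpl) &&
      !identical(template, x$sequence))
    bad <- c(bad, "reconstructed template differs from the input sequence")

  # adjacent oligos must share a duplex overlap (interval intersection)
  for (j in seq_len(n_ol - 1L)) {
    s <- max(ol$start[j], ol$start[j + 1L])
    e <- min(ol$end[j], ol$end[j + 1L])
    if (e - s < 1L) {
      bad <- c(bad, sprintf("oligos %d and %d do not overlap",
                            ol$index[j], ol$index[j + 1L]))
      next
    }
    sub_of <- function(k) {
      if (ol$strand[k] == "sense")
        substr(ol$sequence[k], s - ol$start[k] + 1L, e - ol$start[k])
      else
        substr(ol$sequence[k], ol$end[k] - e + 1L, ol$end[k] - s)
    }
    sense_k <- if (ol$strand[j] == "sense") j else j + 1L
    anti_k <- if (sense_k == j) j + 1L else j
    if (!identical(sub_of(anti_k), reverse_complement(sub_of(sense_k))))
      bad <- c(bad, sprintf(
        "overlap of oligos %d/%d is not an exact reverse complement",
        ol$index[j], ol$index[j + 1L]))
  }

  # strand coverage: every base on >= 1 strand; gaps strictly inside an
  # opposite-strand oligo
  cover <- function(strand) {
    v <- logical(n)
    for (j in which(ol$strand == strand))
      v[(ol$start[j] + 1L):ol$end[j]] <- TRUE
    v
  }
  sense_cov <- cover("sense"); anti_cov <- cover("antisense")
  if (!all(sense_cov | anti_cov))
    bad <- c(bad, "template bases uncovered on both strands")
  if (!is.null(x$gaps) && nrow(x$gaps)) {
    for (g in seq_len(nrow(x$gaps))) {
      gs <- x$gaps$start[g]; ge <- x$gaps$end[g]
      opp <- x$gaps$strand[g] == "sense"  # gap ON sense -> spanned by antisense
      spanning <- which((ol$strand == "antisense") == opp &
                        ol$start < gs & ol$end > ge)
      if (!length(spanning))
        bad <- c(bad, sprintf(
          "gap [%d,%d) not strictly inside any opposite-strand oligo",
          gs, ge))
    }
  }

  if (!is.null(x$primers) && !is.null(x$overlaps) && !anyNA(tpl)) {
    ov <- x$overlaps
    fwd <- substr(template, ov$start[1L] + 1L, ov$end[1L])
    rev <- reverse_complement(substr(template, ov$start[nrow(ov)] + 1L,
                                     ov$end[nrow(ov)]))
    if (!identical(x$primers$forward, fwd))
      bad <- c(bad, "forward primer does not equal the first overlap")
    if (!identical(x$primers$reverse, rev))
      bad <- c(bad, "reverse primer is not the reverse complement of the last overlap")
  }
  bad
}
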