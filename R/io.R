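# Sequence ingestion and report writers (FASTA via Biostrings, TSV,
# JSON design record).

#' Read a DNA sequence from FASTA, raw text, or a string
#'
#' If \code{x} names an existing file it is read from disk: FASTA when
#' the first non-blank character is \code{>} (single record only),
#' otherwise as raw sequence text (whitespace stripped).  Any other
#' string is treated as the sequence itself.
#'
#' @param x path or sequence string.
#' @return Validated upper-case sequence (character scalar).
#' @export
read_sequence <- function(x) {
  if (!is.character(x) || length(x) != 1L)
    stop("input must be a single path or sequence string", call. = FALSE)
  if (file.exists(x) && !dir.exists(x)) {
    head <- readLines(x, n = 1L, warn = FALSE)
    if (length(head) == 0L) stop("empty input file", call. = FALSE)
    if (startsWith(trimws(head), ">")) {
      recs <- Biostrings::readDNAStringSet(x)
      if (length(recs) == 0L)
        stop("FASTA contains no records", call. = FALSE)
      if (length(recs) > 1L)
        stop(sprintf(
          "FASTA contains %d records (need exactly one): %s",
          length(recs), paste(names(recs), collapse = "; ")),
          call. = FALSE)
      return(dna_sequence(as.character(recs[[1L]])))
    }
    x <- paste(readLines(x, warn = FALSE), collapse = "")
  }
  x <- gsub("[[:space:]]", "", x)
  if (!nzchar(x)) stop("empty input sequence", call. = FALSE)
  dna_sequence(x)
}

fmt_tm <- function(x) sprintf("%.2f", x)

#' Write the oligo set as FASTA
#'
#' One record per oligo with header
#' \code{oligo_<index>|<strand>|<start>-<end>|len=<bp>|Tm=<C>}
#' (coordinates 0-based half-open on the template), plus the two primers
#' as additional records.
#'
#' @param x an \code{oligo_set}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_oligos_fasta <- function(x, path) {
  ol <- x$oligos
  hdr <- sprintf("oligo_%d|%s|%d-%d|len=%d|Tm=%s",
                 ol$index, ol$strand, ol$start, ol$end, ol$length,
                 fmt_tm(ol$oligo_tm))
  seqs <- c(ol$sequence, x$primers$forward, x$primers$reverse)
  ov <- x$overlaps
  hdr <- c(hdr,
           sprintf("primer_forward|sense|%d-%d|len=%d|Tm=%s",
                   ov$start[1L], ov$end[1L], nchar(x$primers$forward),
                   fmt_tm(ov$tm[1L])),
           sprintf("primer_reverse|antisense|%d-%d|len=%d|Tm=%s",
                   ov$start[nrow(ov)], ov$end[nrow(ov)],
                   nchar(x$primers$reverse), fmt_tm(ov$tm[nrow(ov)])))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write the TSV design report
#'
#' Columns: index, strand, start, end, length, sequence, oligo_tm,
#' left_overlap_tm, right_overlap_tm (Tm at 2 decimal places; population
#' standard deviation convention).  Footer comment lines carry the
#' overlap-Tm mean/std, the thermodynamic conditions and the appended
#' tail.
#'
#' @inheritParams write_oligos_fasta
#' @return \code{path}, invisibly.
#' @export
write_report_tsv <- function(x, path) {
  ol <- x$oligos
  tab <- data.frame(
    index = ol$index, strand = ol$strand, start = ol$start,
    end = ol$end, length = ol$length, sequence = ol$sequence,
    oligo_tm = fmt_tm(ol$oligo_tm),
    left_overlap_tm = fmt_tm(x$overlaps$tm[ol$left_overlap]),
    right_overlap_tm = fmt_tm(x$overlaps$tm[ol$right_overlap]),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tail <- if (!is.null(x$design) && nzchar(x$design$tail %||% ""))
    x$design$tail else "-"
  writeLines(c(
    sprintf("# mean_overlap_tm\t%s", fmt_tm(x$mean_overlap_tm)),
    sprintf("# std_overlap_tm\t%s", fmt_tm(x$std_overlap_tm)),
    sprintf("# conditions: Na=%g, CT=%g", x$conditions$na_molar,
            x$conditions$ct_molar),
    sprintf("# tail=%s", tail)), con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read back a TSV design report
#'
#' Parses a report written by \code{\link{write_report_tsv}} into a
#' minimal \code{oligo_set} sufficient for \code{\link{check_oligo_set}}.
#'
#' @param path report path.
#' @return An \code{oligo_set} (without thermodynamic metadata).
#' @export
read_report_tsv <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("index", "strand", "start", "end", "length", "sequence")
  if (!all(need %in% names(tab)))
    stop("report is missing required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  structure(list(oligos = tab, gaps = NULL, primers = NULL,
                 overlaps = NULL, sequence = NULL),
            class = "oligo_set")
}

#' Serialize the full design record to JSON
#'
#' The record contains everything needed to reproduce the run: the
#' design configuration (including the seed), the tail, the plan
#' boundaries, the shrink assignment, per-oligo and per-overlap tables
#' and the refinement/optimizer statistics.
#'
#' @inheritParams write_oligos_fasta
#' @return \code{path}, invisibly.
#' @export
write_design_json <- function(x, path) {
  rec <- list(
    config = unclass(x$design$config),
    input_length = x$design$input_length,
    tail = x$design$tail %||% "",
    sequence = x$sequence,
    plan = list(boundaries = x$plan$boundaries, n = x$plan$n,
                L = x$plan$L),
    assignment = x$assignment,
    overlaps = x$overlaps,
    oligos = x$oligos,
    gaps = x$gaps,
    primers = x$primers,
    mean_overlap_tm = x$mean_overlap_tm,
    std_overlap_tm = x$std_overlap_tm,
    initial_sd = x$design$initial_sd,
    refine_history = x$design$refine_history,
    optimizer = x$design$optimizer,
    conditions = unclass(x$conditions))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a design configuration from JSON
#'
#' Accepts either a bare configuration object or a full design record
#' (as written by \code{\link{write_design_json}}), and round-trips
#' through \code{\link{design_config}} so all bounds are re-validated.
#'
#' @param path JSON file path.
#' @return A \code{design_config}.
#' @export
read_design_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$config)) obj <- obj$config
  design_config(target_len = obj$target_len, mode = obj$mode,
                var_threshold = obj$var_threshold, budget = obj$budget,
                min_overlap_len = obj$min_overlap_len,
                na_molar = obj$na_molar, ct_molar = obj$ct_molar,
                seed = obj$seed, max_iter = obj$max_iter)
}
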