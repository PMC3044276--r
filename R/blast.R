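# BLAST tabular (outfmt 6) input and the score filters applied before any
# assignment. The ranking key throughout is the bit score.

BLAST6_COLS <- c("read_id", "subject_id", "pident", "align_length",
                 "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read BLAST tabular output
#'
#' Parses 12-column outfmt-6 lines (`qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`). Lines with fewer than
#' 12 fields, a non-numeric bit score or e-value, or a negative e-value are
#' counted and skipped with a warning. Gzip-compressed files are accepted.
#' Hits are returned sorted by read id, descending bit score, then ascending
#' subject accession (the deterministic tie-break used everywhere).
#'
#' @param path File path.
#' @return A data frame of class `"blast_hits"` with columns
#'   `read_id`, `subject_id`, `pident`, `evalue`, `bitscore` (numeric) and
#'   the remaining outfmt-6 columns carried opaquely as character.
#'   Attributes `n_lines` (non-comment input lines) and `n_rejected`.
#' @export
read_blast <- function(path) {
  lines <- read_lines_any(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  n_lines <- length(lines)
  if (!n_lines) {
    out <- data.frame(read_id = character(0), subject_id = character(0),
                      pident = numeric(0), align_length = character(0),
                      mismatch = character(0), gapopen = character(0),
                      qstart = character(0), qend = character(0),
                      sstart = character(0), send = character(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      stringsAsFactors = FALSE)
    return(structure(out, n_lines = 0L, n_rejected = 0L,
                     class = c("blast_hits", "data.frame")))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 12L
  get <- function(i) vapply(parts[ok], `[[`, character(1), i)
  bitscore <- suppressWarnings(as.numeric(get(12L)))
  evalue <- suppressWarnings(as.numeric(get(11L)))
  pident <- suppressWarnings(as.numeric(get(3L)))
  good <- is.finite(bitscore) & is.finite(evalue) & evalue >= 0
  n_rejected <- sum(!ok) + sum(!good)
  if (n_rejected > 0L)
    warning(n_rejected, " malformed BLAST line(s) skipped in ", path)
  out <- data.frame(
    read_id = get(1L)[good], subject_id = get(2L)[good],
    pident = pident[good], align_length = get(4L)[good],
    mismatch = get(5L)[good], gapopen = get(6L)[good],
    qstart = get(7L)[good], qend = get(8L)[good],
    sstart = get(9L)[good], send = get(10L)[good],
    evalue = evalue[good], bitscore = bitscore[good],
    stringsAsFactors = FALSE)
  out <- out[order(out$read_id, -out$bitscore, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_lines = n_lines, n_rejected = n_rejected,
            class = c("blast_hits", "data.frame"))
}

#' Filter hits by bit-score floor and top-percent window
#'
#' Retains hits with `bitscore >= min_score`, then — per read — those within
#' `top_percent` of the best retained score, i.e.
#' `bitscore >= (1 - top_percent/100) * max(retained bitscore)`.
#' The floor is applied first, then the window; the operation is idempotent
#' and preserves the sort order.
#'
#' @param hits A `blast_hits` data frame (any subset of rows).
#' @param min_score Bit-score floor (>= 0). Default 35 bits.
#' @param top_percent Window width in percent of the best score, in
#'   \[0, 100\]. Default 10.
#' @return The filtered `blast_hits` data frame.
#' @export
filter_hits <- function(hits, min_score = 35, top_percent = 10) {
  if (min_score < 0) stop("'min_score' must be >= 0")
  if (top_percent < 0 || top_percent > 100)
    stop("'top_percent' must be in [0, 100]")
  hh <- hits[hits$bitscore >= min_score, , drop = FALSE]
  if (nrow(hh)) {
    best <- stats::ave(hh$bitscore, hh$read_id, FUN = max)
    hh <- hh[hh$bitscore >= (1 - top_percent / 100) * best, , drop = FALSE]
  }
  rownames(hh) <- NULL
  class(hh) <- c("blast_hits", "data.frame")
  hh
}
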