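# Per-read assignment: SEED functional role and KEGG orthology by best
# mapped hit, taxon by lowest common ancestor of all retained mapped hits.

#' Assignment parameters
#'
#' The import defaults: a 35-bit score floor, a 10% top-score window, and a
#' minimum support of 5 reads per taxonomy node (consumed by
#' [apply_min_support()]).
#'
#' @param min_score Bit-score floor, bits (>= 0).
#' @param top_percent Top-percent window, in \[0, 100\].
#' @param min_support Minimum reads per taxonomy node (>= 1).
#' @return An `"assign_params"` list.
#' @export
assign_params <- function(min_score = 35, top_percent = 10, min_support = 5) {
  if (min_support < 1) stop("'min_support' must be >= 1")
  if (min_score < 0) stop("'min_score' must be >= 0")
  if (top_percent < 0 || top_percent > 100)
    stop("'top_percent' must be in [0, 100]")
  structure(list(min_score = min_score, top_percent = top_percent,
                 min_support = min_support),
            class = "assign_params")
}

BIN_NOHITS <- "NoHits"
BIN_NOTASSIGNED <- "NotAssigned"

new_assignments <- function(df, kind, sample = NULL) {
  rownames(df) <- NULL
  structure(df, kind = kind, sample = sample,
            class = c("assignments", "data.frame"))
}

# shared core: hits above the score floor joined to a mapping, with the
# top-percent window applied *within the mapped subset* — an unmapped top
# hit must not mask a usable mapped hit below it (the best mapped hit is
# what defines the assignment)
mapped_filtered <- function(hits, map, params) {
  f <- hits[hits$bitscore >= params$min_score, , drop = FALSE]
  tgt <- unname(map[f$subject_id])
  keep <- !is.na(tgt)
  m <- f[keep, , drop = FALSE]
  m$target <- tgt[keep]
  if (nrow(m)) {
    best <- stats::ave(m$bitscore, m$read_id, FUN = max)
    m <- m[m$bitscore >= (1 - params$top_percent / 100) * best, , drop = FALSE]
  }
  m <- m[order(m$read_id, -m$bitscore, m$subject_id), , drop = FALSE]
  m
}

bin_rows <- function(read_ids, kind, bin) {
  n <- length(read_ids)
  data.frame(read_id = read_ids, kind = rep(kind, n), target = rep(bin, n),
             bitscore = rep(NA_real_, n), stringsAsFactors = FALSE)
}

finish_assignments <- function(assigned, hits, all_reads, kind, sample) {
  with_hits <- unique(hits$read_id)
  not_assigned <- setdiff(with_hits, assigned$read_id)
  out <- rbind(assigned, bin_rows(not_assigned, kind, BIN_NOTASSIGNED))
  if (!is.null(all_reads)) {
    no_hits <- setdiff(unique(as.character(all_reads)), with_hits)
    out <- rbind(out, bin_rows(no_hits, kind, BIN_NOHITS))
  }
  out <- out[order(out$read_id), , drop = FALSE]
  new_assignments(out, kind, sample)
}

#' Assign reads to SEED functional roles
#'
#' Each read is assigned to the functional role of its highest-scoring
#' mapped hit: hits below the bit-score floor are discarded, the top-percent
#' window is applied within the mapped (role-carrying) hits, and the best
#' survivor wins. An unmapped hit scoring above all mapped ones therefore
#' does not block assignment. Ties in bit score
#' are broken by ascending subject accession. A read with no surviving hits
#' at all is binned `NoHits` (only reads listed in `all_reads` but absent
#' from `hits` are treated as hitless); a read whose surviving hits map to
#' no known role is `NotAssigned`.
#'
#' @param hits A `blast_hits` data frame (one sample).
#' @param fun_map A `function_map` (accession -> role).
#' @param params An [assign_params()] list.
#' @param all_reads Optional character vector: the full read universe, used
#'   to populate the `NoHits` bin.
#' @param strict If `TRUE`, only the single top filtered hit is considered:
#'   if it is unmapped the read is `NotAssigned` even when a lower mapped
#'   hit exists. Default `FALSE` (best *mapped* hit wins).
#' @param sample Optional sample id carried as an attribute.
#' @return An `"assignments"` data frame: `read_id`, `kind` (`"seed-role"`),
#'   `target` (role name or bin), `bitscore` of the supporting hit.
#' @export
assign_seed <- function(hits, fun_map, params = assign_params(),
                        all_reads = NULL, strict = FALSE, sample = NULL) {
  kind <- "seed-role"
  if (strict) {
    f <- filter_hits(hits, params$min_score, params$top_percent)
    top <- f[!duplicated(f$read_id), , drop = FALSE]
    tgt <- unname(fun_map[top$subject_id])
    ok <- !is.na(tgt)
    assigned <- data.frame(read_id = top$read_id[ok],
                           kind = rep(kind, sum(ok)),
                           target = tgt[ok], bitscore = top$bitscore[ok],
                           stringsAsFactors = FALSE)
  } else {
    m <- mapped_filtered(hits, fun_map, params)
    best <- m[!duplicated(m$read_id), , drop = FALSE]
    assigned <- data.frame(read_id = best$read_id,
                           kind = rep(kind, nrow(best)),
                           target = best$target, bitscore = best$bitscore,
                           stringsAsFactors = FALSE)
  }
  finish_assignments(assigned, hits, all_reads, kind, sample)
}

#' Assign reads to KEGG orthologies
#'
#' The best filtered hit *for which a KO is known* wins — not the overall
#' best hit. Bins as in [assign_seed()].
#'
#' @inheritParams assign_seed
#' @param ko_map A `ko_map` (accession -> KO id).
#' @return An `"assignments"` data frame with `kind = "ko"`.
#' @export
assign_ko <- function(hits, ko_map, params = assign_params(),
                      all_reads = NULL, sample = NULL) {
  m <- mapped_filtered(hits, ko_map, params)
  best <- m[!duplicated(m$read_id), , drop = FALSE]
  assigned <- data.frame(read_id = best$read_id,
                         kind = rep("ko", nrow(best)),
                         target = best$target, bitscore = best$bitscore,
                         stringsAsFactors = FALSE)
  finish_assignments(assigned, hits, all_reads, "ko", sample)
}

#' Assign reads to taxa by lowest common ancestor
#'
#' For each read the taxa of all filtered, mapped hits are collected and the
#' read is placed on their LCA in the taxonomy — the most specific taxon
#' consistent with every retained hit. Mapped taxa absent from the taxonomy
#' are dropped (dangling; counted in a warning); a read left with no usable
#' taxa is `NotAssigned`.
#'
#' @inheritParams assign_seed
#' @param taxon_map A `taxon_map` (accession -> taxon id).
#' @param tax The taxonomy `hierarchy`.
#' @return An `"assignments"` data frame with `kind = "taxon"`; `bitscore`
#'   is the best supporting hit's score.
#' @export
assign_taxon <- function(hits, taxon_map, tax, params = assign_params(),
                         all_reads = NULL, sample = NULL) {
  m <- mapped_filtered(hits, taxon_map, params)
  known <- m$target %in% tax$nodes
  if (any(!known))
    warning(sum(!known), " hit(s) with taxa absent from the taxonomy dropped")
  m <- m[known, , drop = FALSE]
  if (nrow(m)) {
    taxa_by_read <- split(m$target, m$read_id)
    score_by_read <- vapply(split(m$bitscore, m$read_id), max, numeric(1))
    node <- vapply(taxa_by_read, function(ts) lca(tax, unique(ts)),
                   character(1))
    assigned <- data.frame(read_id = names(taxa_by_read),
                           kind = rep("taxon", length(taxa_by_read)),
                           target = unname(node),
                           bitscore = unname(score_by_read),
                           stringsAsFactors = FALSE)
  } else {
    assigned <- data.frame(read_id = character(0), kind = character(0),
                           target = character(0), bitscore = numeric(0),
                           stringsAsFactors = FALSE)
  }
  finish_assignments(assigned, hits, all_reads, "taxon", sample)
}

#' Reads assigned within selected taxa
#'
#' Returns the ids of reads whose assigned taxon is one of the selected
#' nodes or a descendant of one — the read set used to restrict KEGG
#' pathway analysis to part of the taxonomy.
#'
#' @param assignments Taxon `"assignments"` from [assign_taxon()].
#' @param tax The taxonomy `hierarchy`.
#' @param selected Character vector of taxon node ids (may be empty).
#' @return Character vector of read ids.
#' @export
reads_under_taxa <- function(assignments, tax, selected) {
  selected <- unique(as.character(selected))
  if (!length(selected)) return(character(0))
  check_nodes(tax, selected)
  wanted <- unique(unlist(lapply(selected, descendants, h = tax)))
  assignments$read_id[assignments$target %in% wanted]
}

#' Write / read a per-read assignment table
#'
#' TSV with header `read_id  kind  target  bitscore` — the machine-readable
#' twin of drilling down to individual reads and their matches.
#'
#' @param x An `"assignments"` data frame.
#' @param path File path.
#' @return `path` (writer) / the `"assignments"` data frame (reader).
#' @export
write_assignments <- function(x, path) {
  df <- as.data.frame(x)
  df$bitscore <- ifelse(is.na(df$bitscore), "",
                        formatC(df$bitscore, format = "g", digits = 10))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignments
#' @param sample Optional sample id attached to the result.
#' @export
read_assignments <- function(path, sample = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$bitscore <- suppressWarnings(as.numeric(df$bitscore))
  kind <- if (nrow(df)) df$kind[df$kind != ""][1L] else NA_character_
  new_assignments(df, kind, sample)
}
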