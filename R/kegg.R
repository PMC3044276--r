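# KEGG pathway aggregation: KO assignments -> per-pathway hit counts,
# display scaling, multi-sample presence patterns, and taxon-restricted
# analysis. A KO belonging to k pathways contributes one hit to each (no
# fractional splitting); per-read uniqueness stays auditable via the KO
# table.

UNMAPPED_PATHWAY <- "unmapped-KO"

as_ko_table <- function(ko_assignments) {
  if (inherits(ko_assignments, "assignments"))
    ko_assignments <- list(ko_assignments)
  dfs <- lapply(seq_along(ko_assignments), function(i) {
    a <- ko_assignments[[i]]
    s <- attr(a, "sample")
    if (is.null(s)) s <- names(ko_assignments)[i]
    if (is.null(s) || !nzchar(s)) s <- paste0("sample", i)
    real <- a[!(a$target %in% c(BIN_NOHITS, BIN_NOTASSIGNED)), , drop = FALSE]
    if (!nrow(real))
      return(data.frame(read_id = character(0), sample = character(0),
                        ko = character(0), stringsAsFactors = FALSE))
    data.frame(read_id = real$read_id, sample = s, ko = real$target,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, dfs)
}

#' Count KO hits per KEGG pathway
#'
#' Every read's KO contributes one hit to each pathway containing that KO.
#' KOs absent from the pathway map are tallied under a synthetic
#' `"unmapped-KO"` pathway with a warning. Pathways are ordered by total
#' hits, descending.
#'
#' @param ko_assignments A KO `"assignments"` data frame, or a list of them
#'   (one per sample; sample ids from their `sample` attribute or the list
#'   names).
#' @param pm A `"pathway_map"` from [read_pathway_map()].
#' @return A `"pathway_profiles"` object: list with `table` (data frame
#'   `pathway_id`, `pathway_name`, `ko`, `sample`, `count`), `totals`
#'   (`pathway_id`, `pathway_name`, `total`, sorted descending) and
#'   `samples`.
#' @export
pathway_counts <- function(ko_assignments, pm) {
  kt <- as_ko_table(ko_assignments)
  samples <- unique(kt$sample)
  if (!nrow(kt)) {
    empty <- data.frame(pathway_id = character(0), pathway_name = character(0),
                        ko = character(0), sample = character(0),
                        count = numeric(0), stringsAsFactors = FALSE)
    return(structure(list(table = empty,
                          totals = data.frame(pathway_id = character(0),
                                              pathway_name = character(0),
                                              total = numeric(0)),
                          samples = samples),
                     class = "pathway_profiles"))
  }
  pws <- pm$pathways[kt$ko]
  unmapped <- vapply(pws, is.null, logical(1))
  if (any(unmapped)) {
    warning(sum(unmapped), " KO hit(s) not in the pathway map; counted under '",
            UNMAPPED_PATHWAY, "'")
    pws[unmapped] <- list(UNMAPPED_PATHWAY)
  }
  reps <- lengths(pws)
  long <- data.frame(pathway_id = unlist(pws, use.names = FALSE),
                     ko = rep(kt$ko, reps),
                     sample = rep(kt$sample, reps),
                     stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(count = rep(1, nrow(long))),
                          long[c("pathway_id", "ko", "sample")], sum)
  nm <- pm$label[agg$pathway_id]
  nm[is.na(nm)] <- agg$pathway_id[is.na(nm)]
  agg$pathway_name <- unname(nm)
  agg <- agg[order(agg$pathway_id, agg$ko, agg$sample),
             c("pathway_id", "pathway_name", "ko", "sample", "count")]
  rownames(agg) <- NULL
  tot <- stats::aggregate(list(total = agg$count),
                          agg[c("pathway_id", "pathway_name")], sum)
  tot <- tot[order(-tot$total, tot$pathway_id), , drop = FALSE]
  rownames(tot) <- NULL
  structure(list(table = agg, totals = tot, samples = samples),
            class = "pathway_profiles")
}

#' @export
print.pathway_profiles <- function(x, ...) {
  cat("<pathway_profiles> ", nrow(x$totals), " pathways, ",
      length(unique(x$table$ko)), " KOs, ", length(x$samples),
      " sample(s)\n", sep = "")
  print(utils::head(x$totals, 10L))
  invisible(x)
}

#' Scale KO abundances for display
#'
#' Maps per-KO counts to \[0, 1\] as the color channel for a pathway-map
#' renderer: linear (`count / max`) or log (`log1p(count) / log1p(max)`).
#' Any KO with at least one read scales strictly above 0, so a barely
#' present enzyme remains distinguishable from an absent one; the most
#' abundant KO scales to 1. An all-zero profile yields all zeros.
#'
#' @param counts Named numeric vector of per-KO counts (or a
#'   `"pathway_profiles"` plus `pathway_id` to scale one pathway's KOs,
#'   summed over samples).
#' @param mode `"linear"` or `"log"`.
#' @param pathway_id Required when `counts` is a `"pathway_profiles"`.
#' @return Named numeric vector of scaled values in \[0, 1\].
#' @export
scale_abundance <- function(counts, mode = c("linear", "log"),
                            pathway_id = NULL) {
  mode <- match.arg(mode)
  if (inherits(counts, "pathway_profiles")) {
    if (is.null(pathway_id)) stop("'pathway_id' required for pathway_profiles")
    tab <- counts$table[counts$table$pathway_id == pathway_id, , drop = FALSE]
    if (!nrow(tab)) stop("unknown pathway id: ", pathway_id)
    counts <- vapply(split(tab$count, tab$ko), sum, numeric(1))
  }
  mx <- max(counts)
  if (mx <= 0) return(counts * 0)
  switch(mode,
         linear = counts / mx,
         log = log1p(counts) / log1p(mx))
}

#' Per-KO presence and abundance across samples for one pathway
#'
#' @param pp A `"pathway_profiles"` object.
#' @param pathway_id Pathway to inspect.
#' @return Data frame: one row per KO in the pathway, one count column per
#'   sample, and a `pattern` column naming the subset of samples in which
#'   the KO was hit (comma-separated).
#' @export
compare_pathway <- function(pp, pathway_id) {
  tab <- pp$table[pp$table$pathway_id == pathway_id, , drop = FALSE]
  if (!nrow(tab)) stop("unknown pathway id: ", pathway_id)
  kos <- sort(unique(tab$ko))
  samples <- pp$samples
  m <- matrix(0, length(kos), length(samples),
              dimnames = list(kos, samples))
  m[cbind(tab$ko, tab$sample)] <- tab$count
  pattern <- apply(m > 0, 1L, function(r) paste(samples[r], collapse = ","))
  out <- data.frame(ko = kos, m, pattern = unname(pattern),
                    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Pathway counts restricted to reads from selected taxa
#'
#' Identical to [pathway_counts()] applied only to reads whose taxonomic
#' assignment falls within the selected clades (see [reads_under_taxa()]).
#'
#' @param ko_assignments KO `"assignments"` (one data frame or a list, as in
#'   [pathway_counts()]).
#' @param taxon_assignments Matching taxon `"assignments"` (same shape).
#' @param tax The taxonomy `hierarchy`.
#' @param selected Character vector of taxon node ids.
#' @param pm A `"pathway_map"`.
#' @return A `"pathway_profiles"` object.
#' @export
restricted_pathway_counts <- function(ko_assignments, taxon_assignments,
                                      tax, selected, pm) {
  if (inherits(ko_assignments, "assignments"))
    ko_assignments <- list(ko_assignments)
  if (inherits(taxon_assignments, "assignments"))
    taxon_assignments <- list(taxon_assignments)
  if (length(ko_assignments) != length(taxon_assignments))
    stop("need one taxon assignment table per KO assignment table")
  restricted <- lapply(seq_along(ko_assignments), function(i) {
    keep <- reads_under_taxa(taxon_assignments[[i]], tax, selected)
    a <- ko_assignments[[i]]
    new_assignments(a[a$read_id %in% keep, , drop = FALSE],
                    attr(a, "kind"), attr(a, "sample"))
  })
  names(restricted) <- names(ko_assignments)
  pathway_counts(restricted, pm)
}

#' Write pathway report files
#'
#' Writes `pathway_summary.tsv` (`pathway_id`, `pathway_name`, `total`) and
#' one `pathway_<id>.tsv` per pathway (per-KO counts per sample, presence
#' pattern, and linearly scaled abundance).
#'
#' @param pp A `"pathway_profiles"` object.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_pathway_report <- function(pp, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, "pathway_summary.tsv")
  utils::write.table(pp$totals, paths, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (pid in pp$totals$pathway_id) {
    cmp <- compare_pathway(pp, pid)
    tot <- rowSums(cmp[, pp$samples, drop = FALSE])
    cmp$scaled <- round(scale_abundance(stats::setNames(tot, cmp$ko)), 6)
    p <- file.path(out_dir, paste0("pathway_", gsub("[^A-Za-z0-9._-]", "_", pid),
                                   ".tsv"))
    utils::write.table(cmp, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
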