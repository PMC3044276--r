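# Per-sample count profiles on a hierarchy: reads assigned exactly at a
# node vs. summarized over the subtree rooted there, plus the NoHits /
# NotAssigned bins. SEED-role assignments are placed on *every* leaf
# carrying the role (multi-labeled tree view) while a unique-read tally per
# role is kept alongside so conservation stays auditable.

new_count_profile <- function(sample, kind, assigned, summarized, bins,
                              role_counts, tree) {
  structure(list(sample = sample, kind = kind, assigned = assigned,
                 summarized = summarized, bins = bins,
                 role_counts = role_counts, tree = tree),
            class = "count_profile")
}

#' @export
print.count_profile <- function(x, ...) {
  cat("<count_profile> sample '", x$sample, "' (", x$kind, "): ",
      sum(x$assigned), " tree-view placements, root summarized = ",
      x$summarized[[x$tree$root]],
      ", NoHits = ", x$bins[["NoHits"]],
      ", NotAssigned = ", x$bins[["NotAssigned"]], "\n", sep = "")
  invisible(x)
}

# bottom-up: summarized(n) = assigned(n) + sum over children of summarized
summarize_counts <- function(h, assigned) {
  summ <- assigned
  ord <- names(sort(h$depth, decreasing = TRUE))
  for (n in ord) {
    p <- h$parent[[n]]
    if (!is.na(p)) summ[[p]] <- summ[[p]] + summ[[n]]
  }
  summ
}

#' Build a per-sample count profile over a hierarchy
#'
#' Taxon assignments are counted at their node. SEED-role assignments are
#' counted at every leaf bearing the role: a read whose role labels k leaves
#' contributes k to the tree-view counts but 1 to the per-role unique-read
#' tally in `role_counts`. A role labeling no leaf routes its reads to the
#' `NotAssigned` bin with a warning.
#'
#' @param assignments An `"assignments"` data frame of one kind and sample
#'   (`"seed-role"` or `"taxon"`).
#' @param h The matching `hierarchy`.
#' @param sample Sample id (defaults to the attribute on `assignments`).
#' @return A `"count_profile"`: `assigned` and `summarized` named numeric
#'   vectors over all nodes of `h`, `bins` (`NoHits`, `NotAssigned`),
#'   `role_counts` (unique reads per role; SEED only), and the hierarchy in
#'   `tree`.
#' @export
build_profile <- function(assignments, h,
                          sample = attr(assignments, "sample")) {
  kind <- attr(assignments, "kind")
  if (is.null(kind) || is.na(kind))
    kind <- if (nrow(assignments)) assignments$kind[[1L]] else "taxon"
  if (!kind %in% c("seed-role", "taxon"))
    stop("profiles are defined for 'seed-role' and 'taxon' assignments, not '",
         kind, "'")
  if (is.null(sample)) sample <- "sample1"

  zero <- stats::setNames(numeric(length(h$nodes)), h$nodes)
  assigned <- zero
  bins <- c(NoHits = sum(assignments$target == BIN_NOHITS),
            NotAssigned = sum(assignments$target == BIN_NOTASSIGNED))
  real <- assignments[!(assignments$target %in%
                          c(BIN_NOHITS, BIN_NOTASSIGNED)), , drop = FALSE]
  role_counts <- NULL

  if (kind == "taxon") {
    ok <- real$target %in% h$nodes
    if (any(!ok)) {
      warning(sum(!ok), " read(s) assigned to unknown taxa -> NotAssigned")
      bins[["NotAssigned"]] <- bins[["NotAssigned"]] + sum(!ok)
    }
    tab <- table(real$target[ok])
    assigned[names(tab)] <- as.numeric(tab)
  } else {
    per_role <- table(real$target)
    role_counts <- stats::setNames(numeric(0), character(0))
    for (r in names(per_role)) {
      lv <- leaves_for_role(h, r)
      if (!length(lv)) {
        warning("role '", r, "' labels no leaf -> ", per_role[[r]],
                " read(s) NotAssigned")
        bins[["NotAssigned"]] <- bins[["NotAssigned"]] + per_role[[r]]
      } else {
        assigned[lv] <- assigned[lv] + as.numeric(per_role[[r]])
        role_counts[r] <- as.numeric(per_role[[r]])
      }
    }
  }
  new_count_profile(sample, kind, assigned, summarize_counts(h, assigned),
                    bins, role_counts, h)
}

#' Promote under-supported taxonomy nodes to their parents
#'
#' Every node (except the root) whose assigned count is positive but below
#' `min_support` has its reads moved to its immediate parent; promotion runs
#' deepest-first, so promoted reads can cascade further up until every
#' populated node meets the threshold. The total number of assigned reads is
#' conserved; the `NoHits`/`NotAssigned` bins are exempt.
#'
#' @param profile A taxonomy `"count_profile"`.
#' @param min_support Minimum reads per node (>= 1).
#' @param h The taxonomy (defaults to the profile's own tree).
#' @return The adjusted `"count_profile"` (summarized counts recomputed).
#' @export
apply_min_support <- function(profile, min_support, h = profile$tree) {
  if (min_support < 1) stop("'min_support' must be >= 1")
  assigned <- profile$assigned
  ord <- names(sort(h$depth, decreasing = TRUE))
  for (n in ord) {
    p <- h$parent[[n]]
    if (is.na(p)) next
    cnt <- assigned[[n]]
    if (cnt > 0 && cnt < min_support) {
      assigned[[p]] <- assigned[[p]] + cnt
      assigned[[n]] <- 0
    }
  }
  new_count_profile(profile$sample, profile$kind, assigned,
                    summarize_counts(h, assigned), profile$bins,
                    profile$role_counts, h)
}

same_tree <- function(a, b) {
  identical(a$parent, b$parent) && identical(a$label, b$label) &&
    identical(a$role, b$role)
}

#' Join per-sample profiles into a node-by-sample comparison table
#'
#' @param profiles List of `"count_profile"` objects over one hierarchy.
#' @param mode Count type per cell: `"summarized"` (subtree totals) or
#'   `"assigned"` (exact placements).
#' @return A `"comparison_table"`: list with `counts` (matrix, rows = nodes
#'   nonzero in at least one sample in depth-first order, columns = samples),
#'   `bins` (2-row matrix), `samples`, `tree`, `mode`.
#' @export
join_profiles <- function(profiles, mode = c("summarized", "assigned")) {
  mode <- match.arg(mode)
  if (!length(profiles)) stop("no profiles to join")
  h <- profiles[[1L]]$tree
  for (p in profiles[-1L])
    if (!same_tree(h, p$tree))
      stop("structural error: profiles are over different hierarchies")
  samples <- vapply(profiles, `[[`, character(1), "sample")
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  full <- vapply(profiles, function(p) p[[mode]][h$nodes], numeric(length(h$nodes)))
  full <- matrix(full, nrow = length(h$nodes),
                 dimnames = list(h$nodes, samples))
  ord <- dfs_order(h)
  keep <- ord[rowSums(full[ord, , drop = FALSE]) > 0]
  counts <- full[keep, , drop = FALSE]
  bins <- vapply(profiles, function(p) p$bins[c("NoHits", "NotAssigned")],
                 numeric(2))
  bins <- matrix(bins, nrow = 2,
                 dimnames = list(c("NoHits", "NotAssigned"), samples))
  structure(list(counts = counts, bins = bins, samples = samples,
                 tree = h, mode = mode),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("<comparison_table> ", nrow(x$counts), " nodes x ", length(x$samples),
      " samples (", x$mode, " counts)\n", sep = "")
  invisible(x)
}

#' Normalize a comparison table to relative abundances
#'
#' @param table A `"comparison_table"`.
#' @param mode `"relative"` (each column divided by its total) or `"none"`.
#' @return The (possibly rescaled) `"comparison_table"`.
#' @export
normalize_table <- function(table, mode = c("relative", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(table)
  tot <- colSums(table$counts)
  if (any(tot <= 0))
    stop("degenerate input: zero-total sample(s) in relative mode: ",
         paste(table$samples[tot <= 0], collapse = ", "))
  table$counts <- sweep(table$counts, 2L, tot, "/")
  table
}

#' Per-role unique-read count matrix
#'
#' The default input to the ecological distance indices: one row per
#' functional role, unique-read counts (a multi-labeled role counts each
#' read once, not once per leaf), so no read is double-counted and no node
#' is mixed with its ancestors.
#'
#' @param profiles List of SEED `"count_profile"` objects.
#' @return Numeric matrix, roles x samples.
#' @export
role_table <- function(profiles) {
  samples <- vapply(profiles, `[[`, character(1), "sample")
  roles <- sort(unique(unlist(lapply(profiles, function(p) names(p$role_counts)))))
  m <- matrix(0, nrow = length(roles), ncol = length(samples),
              dimnames = list(roles, samples))
  for (j in seq_along(profiles)) {
    rc <- profiles[[j]]$role_counts
    if (length(rc)) m[names(rc), j] <- rc
  }
  m
}

#' Write / read a count profile
#'
#' TSV with header `node  label  assigned  summarized`; the two bins are
#' appended as pseudo-rows with label `bin`. Rows follow depth-first order.
#'
#' @param profile A `"count_profile"`.
#' @param path File path.
#' @param all_nodes Write all nodes, including all-zero ones (default keeps
#'   the file small by dropping rows with no reads anywhere below).
#' @return `path` (writer) / a `"count_profile"` (reader).
#' @export
write_profile <- function(profile, path, all_nodes = FALSE) {
  h <- profile$tree
  ord <- dfs_order(h)
  if (!all_nodes) ord <- ord[profile$summarized[ord] > 0]
  df <- data.frame(node = ord, label = h$label[ord],
                   assigned = profile$assigned[ord],
                   summarized = profile$summarized[ord],
                   stringsAsFactors = FALSE)
  df <- rbind(df, data.frame(node = names(profile$bins), label = "bin",
                             assigned = unname(profile$bins),
                             summarized = unname(profile$bins)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param h The `hierarchy` the profile was written against.
#' @param sample Sample id for the restored profile (defaults to file name).
#' @param kind Assignment kind of the restored profile.
#' @export
read_profile <- function(path, h, sample = NULL, kind = "taxon") {
  if (is.null(sample)) {
    sample <- sub("\\.gz$", "", basename(path))
    sample <- sub("\\.(tsv|txt)$", "", sample)
    sample <- sub("\\.(seed|tax)_profile$", "", sample)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  binrows <- df$label == "bin" & df$node %in% c("NoHits", "NotAssigned")
  bins <- c(NoHits = 0, NotAssigned = 0)
  bins[df$node[binrows]] <- df$assigned[binrows]
  df <- df[!binrows, , drop = FALSE]
  check_nodes(h, df$node)
  assigned <- stats::setNames(numeric(length(h$nodes)), h$nodes)
  assigned[df$node] <- df$assigned
  new_count_profile(sample, kind, assigned, summarize_counts(h, assigned),
                    bins, NULL, h)
}

#' Write / read a per-role unique-read count table
#'
#' TSV with header `role  reads`, one row per functional role.
#'
#' @param profile A SEED `"count_profile"`.
#' @param path File path.
#' @return `path` (writer) / named numeric vector (reader).
#' @export
write_role_counts <- function(profile, path) {
  rc <- profile$role_counts
  if (is.null(rc)) rc <- stats::setNames(numeric(0), character(0))
  rc <- rc[order(names(rc))]
  df <- data.frame(role = names(rc), reads = unname(rc),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_role_counts
#' @export
read_role_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df$reads), as.character(df$role))
}

#' Write a comparison table as TSV
#'
#' Columns `node`, `label`, then one column per sample; bin rows appended.
#'
#' @param table A `"comparison_table"`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_comparison_table <- function(table, path) {
  h <- table$tree
  df <- data.frame(node = rownames(table$counts),
                   label = h$label[rownames(table$counts)],
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  bins <- data.frame(node = rownames(table$bins), label = "bin",
                     table$bins, check.names = FALSE,
                     stringsAsFactors = FALSE)
  utils::write.table(rbind(df, bins), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
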