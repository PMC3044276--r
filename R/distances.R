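# Pairwise sample distances from a count table: six ecological indices plus
# UniFrac on the hierarchy. All indices operate on per-sample relative
# abundances; Bray-Curtis, Kulczynski, Goodall and normalized UniFrac live
# in [0, 1].

new_distance_matrix <- function(m, index) {
  diag(m) <- 0
  m <- (m + t(m)) / 2  # enforce exact symmetry against rounding
  structure(m, index = index, class = c("distance_matrix", "matrix"))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("<distance_matrix> ", attr(x, "index"), ", ", nrow(x), " samples\n",
      sep = "")
  print(unclass(x), ...)
  invisible(x)
}

table_counts <- function(x) {
  if (inherits(x, "comparison_table")) x$counts
  else as.matrix(x)
}

rel_cols <- function(m) {
  tot <- colSums(m)
  if (any(tot <= 0))
    stop("degenerate input: zero-total sample(s): ",
         paste(colnames(m)[tot <= 0], collapse = ", "))
  sweep(m, 2L, tot, "/")
}

#' Ecological distance between samples
#'
#' Computes a pairwise distance matrix from a features-by-samples count
#' table (typically the per-role unique-read counts from [role_table()], so
#' that no node is mixed with its ancestors). Columns are converted to
#' relative abundances first. With columns x, y over rows i:
#' \describe{
#'   \item{bray-curtis}{`sum |x_i - y_i| / sum (x_i + y_i)`}
#'   \item{euclidean}{`sqrt(sum (x_i - y_i)^2)`}
#'   \item{hellinger}{`sqrt(sum (sqrt(x_i) - sqrt(y_i))^2)`}
#'   \item{chi-square}{`sqrt(sum (x_i - y_i)^2 / w_i)` with `w_i` the row's
#'     mean relative abundance over all samples; zero-mass rows dropped}
#'   \item{kulczynski}{`1 - (sum min(x_i,y_i)/sum x_i + sum min(x_i,y_i)/sum y_i)/2`}
#'   \item{goodall}{probabilistic similarity: per row,
#'     `s_i(j,k) = 1 - |x_ij - x_ik| / range_i` (zero-range rows skipped);
#'     `p_i(j,k)` = fraction of all sample pairs with similarity at least
#'     `s_i(j,k)`; Fisher's combination `chi^2 = -2 sum_i log p_i` on `2m`
#'     d.f.; similarity = lower-tail probability; distance = 1 - similarity.
#'     Requires at least 3 samples (with 2 the rank-based p-values are
#'     constant and the index is uninformative).}
#' }
#'
#' @param x A `"comparison_table"` or a numeric matrix (rows = features,
#'   columns = samples).
#' @param index One of `"goodall"`, `"bray-curtis"`, `"euclidean"`,
#'   `"hellinger"`, `"chi-square"`, `"kulczynski"`.
#' @return A `"distance_matrix"`: symmetric, zero diagonal.
#' @export
ecological_distance <- function(x, index = c("goodall", "bray-curtis",
                                             "euclidean", "hellinger",
                                             "chi-square", "kulczynski")) {
  index <- match.arg(index)
  m <- table_counts(x)
  if (ncol(m) < 2L) stop("need at least 2 samples")
  X <- rel_cols(m)
  n <- ncol(X)
  if (index == "goodall") {
    if (n < 3L) stop("goodall requires >= 3 samples")
    return(new_distance_matrix(goodall_matrix(X), index))
  }
  if (index == "chi-square") {
    w <- rowMeans(X)
    keep <- w > 0
    X <- X[keep, , drop = FALSE]
    w <- w[keep]
  }
  d <- matrix(0, n, n, dimnames = list(colnames(X), colnames(X)))
  for (j in seq_len(n - 1L)) for (k in seq(j + 1L, n)) {
    xj <- X[, j]; xk <- X[, k]
    v <- switch(index,
      "bray-curtis" = sum(abs(xj - xk)) / sum(xj + xk),
      "euclidean"   = sqrt(sum((xj - xk)^2)),
      "hellinger"   = sqrt(sum((sqrt(xj) - sqrt(xk))^2)),
      "chi-square"  = sqrt(sum((xj - xk)^2 / w)),
      "kulczynski"  = 1 - 0.5 * (sum(pmin(xj, xk)) / sum(xj) +
                                 sum(pmin(xj, xk)) / sum(xk)))
    d[j, k] <- d[k, j] <- v
  }
  new_distance_matrix(d, index)
}

goodall_matrix <- function(X) {
  n <- ncol(X)
  rng <- apply(X, 1L, max) - apply(X, 1L, min)
  X <- X[rng > 0, , drop = FALSE]
  rng <- rng[rng > 0]
  m <- nrow(X)
  d <- matrix(0, n, n, dimnames = list(colnames(X), colnames(X)))
  if (m == 0L) return(d)  # all rows constant: samples indistinguishable
  pr <- which(upper.tri(d), arr.ind = TRUE)
  np <- nrow(pr)
  # per-row similarities for every sample pair
  S <- matrix(0, m, np)
  for (i in seq_len(m))
    S[i, ] <- 1 - abs(X[i, pr[, 1L]] - X[i, pr[, 2L]]) / rng[i]
  # p_i(pair) = fraction of pairs at least as similar on row i
  chi2 <- numeric(np)
  for (i in seq_len(m)) {
    s <- S[i, ]
    p <- vapply(s, function(v) mean(s >= v), numeric(1))
    chi2 <- chi2 - 2 * log(p)
  }
  dist <- stats::pchisq(chi2, df = 2 * m, lower.tail = FALSE)
  d[pr] <- dist
  d[pr[, c(2L, 1L)]] <- dist
  d
}

#' UniFrac distance on a hierarchy
#'
#' Branch-based dissimilarity with unit branch lengths (one branch above
#' every non-root node). For each sample the subtree mass on a branch is the
#' summarized read count below it. Unweighted UniFrac is the fraction of
#' populated branches populated by exactly one of the two samples; the
#' weighted-normalized variant is
#' `sum_b |A_b/A_T - B_b/B_T| / sum_b (A_b/A_T + B_b/B_T)`.
#'
#' @param table A `"comparison_table"` over the nodes of `h` (either
#'   `assigned` or `summarized` mode; assigned counts are summarized
#'   internally).
#' @param h The `hierarchy` (defaults to the table's own tree).
#' @param variant `"unweighted"` or `"weighted-normalized"`.
#' @return A `"distance_matrix"` with entries in \[0, 1\].
#' @export
unifrac <- function(table, h = table$tree,
                    variant = c("unweighted", "weighted-normalized")) {
  variant <- match.arg(variant)
  counts <- table_counts(table)
  check_nodes(h, rownames(counts))
  full <- matrix(0, length(h$nodes), ncol(counts),
                 dimnames = list(h$nodes, colnames(counts)))
  full[rownames(counts), ] <- counts
  mode <- if (inherits(table, "comparison_table")) table$mode else "assigned"
  summ <- if (mode == "summarized") full
          else apply(full, 2L, function(col) summarize_counts(h, col))
  tot <- summ[h$root, ]
  if (any(tot <= 0))
    stop("degenerate input: sample(s) with zero total mass: ",
         paste(colnames(summ)[tot <= 0], collapse = ", "))
  branches <- setdiff(h$nodes, h$root)
  B <- summ[branches, , drop = FALSE]
  n <- ncol(B)
  d <- matrix(0, n, n, dimnames = list(colnames(B), colnames(B)))
  for (j in seq_len(n - 1L)) for (k in seq(j + 1L, n)) {
    a <- B[, j]; b <- B[, k]
    v <- if (variant == "unweighted") {
      any_pop <- a > 0 | b > 0
      sum(xor(a > 0, b > 0)) / sum(any_pop)
    } else {
      pa <- a / tot[j]; pb <- b / tot[k]
      sum(abs(pa - pb)) / sum(pa + pb)
    }
    d[j, k] <- d[k, j] <- v
  }
  new_distance_matrix(d, paste0("unifrac-", variant))
}

fmt6 <- function(x) formatC(x, digits = 6, format = "f")

#' Write a distance matrix
#'
#' Three dialects: `"phylip"` (square matrix, first line the sample count,
#' names padded to 10 characters), `"nexus"` (a `DISTANCES` block with
#' `TRIANGLE=BOTH`), and `"edge-tsv"` (`sample_a  sample_b  distance`, one
#' row per unordered pair). Values are written with 6 decimal digits,
#' locale-independent.
#'
#' @param dm A `"distance_matrix"` (any symmetric matrix with dimnames).
#' @param path Output file.
#' @param format `"phylip"`, `"nexus"` or `"edge-tsv"`.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path,
                                  format = c("phylip", "nexus", "edge-tsv")) {
  format <- match.arg(format)
  m <- unclass(dm)
  ids <- rownames(m)
  n <- nrow(m)
  lines <- switch(format,
    phylip = c(sprintf("%5d", n),
               vapply(seq_len(n), function(i)
                 paste0(formatC(ids[i], width = -10), " ",
                        paste(fmt6(m[i, ]), collapse = " ")),
                 character(1))),
    nexus = c("#NEXUS", "", "BEGIN TAXA;",
              paste0("  DIMENSIONS NTAX=", n, ";"),
              paste0("  TAXLABELS ", paste(ids, collapse = " "), ";"),
              "END;", "", "BEGIN DISTANCES;",
              "  FORMAT TRIANGLE=BOTH DIAGONAL LABELS;",
              "  MATRIX",
              vapply(seq_len(n), function(i)
                paste0("    ", ids[i], " ",
                       paste(fmt6(m[i, ]), collapse = " ")),
                character(1)),
              "  ;", "END;"),
    `edge-tsv` = {
      pr <- which(upper.tri(m), arr.ind = TRUE)
      pr <- pr[order(pr[, 1L], pr[, 2L]), , drop = FALSE]
      c("sample_a\tsample_b\tdistance",
        paste(ids[pr[, 1L]], ids[pr[, 2L]], fmt6(m[pr]), sep = "\t"))
    })
  writeLines(lines, path)
  invisible(path)
}

#' Read back a PHYLIP square distance matrix
#'
#' @param path File written by [write_distance_matrix()] (phylip format) or
#'   any whitespace-separated square PHYLIP matrix.
#' @return A `"distance_matrix"`.
#' @export
read_phylip_distance <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1L]))
  if (is.na(n) || length(lines) < n + 1L)
    stop("malformed PHYLIP distance file: ", path)
  ids <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1L]]
    ids[i] <- f[1L]
    m[i, ] <- as.numeric(f[-1L][seq_len(n)])
  }
  dimnames(m) <- list(ids, ids)
  new_distance_matrix(m, "phylip")
}
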