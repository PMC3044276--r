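# Shared tiny trees, hit-table constructors and independent brute-force
# oracles. The oracles deliberately use different algorithms from the
# package (path intersection, explicit per-branch enumeration, exhaustive
# scans) so agreement is meaningful.

tiny_seed_tree <- function() {
  # root -> S1 {L1:RoleX, L2:RoleY}, S2 {L3:RoleX}  (RoleX multi-labeled)
  hierarchy(child = c("S1", "S2", "L1", "L2", "L3"),
            parent = c("seed_root", "seed_root", "S1", "S1", "S2"),
            role = c(NA, NA, "RoleX", "RoleY", "RoleX"))
}

tiny_tax <- function() {
  # tax_root -> A {B, C}, D
  hierarchy(child = c("A", "B", "C", "D"),
            parent = c("tax_root", "A", "A", "tax_root"))
}

make_hits <- function(read_id, subject_id, bitscore) {
  df <- data.frame(read_id = read_id, subject_id = subject_id,
                   bitscore = as.numeric(bitscore),
                   evalue = 10^(-as.numeric(bitscore) / 4),
                   pident = rep(90, length(read_id)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$read_id, -df$bitscore, df$subject_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("blast_hits", "data.frame")
  df
}

write_blast_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

blast_line <- function(read, subj, score, evalue = "1e-10") {
  paste(read, subj, "90.0", "100", "5", "1", "1", "100", "1", "100",
        evalue, format(score), sep = "\t")
}

rand_tree <- function(n, prefix = "n") {
  ids <- paste0(prefix, sample.int(10 * n, n))
  parent <- c(NA_character_,
              vapply(seq_len(n - 1L) + 1L,
                     function(i) ids[sample.int(i - 1L, 1L)], character(1)))
  hierarchy(ids, parent)
}

# --- oracles -----------------------------------------------------------------

# LCA by full ancestor-path intersection
oracle_lca <- function(h, nodes) {
  paths <- lapply(unique(nodes), function(n) ancestors(h, n))
  common <- Reduce(intersect, paths)
  common[which.max(h$depth[common])]
}

# exhaustive re-evaluation of the filter rule for one read's hits
oracle_filter <- function(scores, min_score, top_percent) {
  kept <- scores >= min_score
  if (!any(kept)) return(kept)
  kept & scores >= (1 - top_percent / 100) * max(scores[kept])
}

# best mapped hit by exhaustive scan: score floor on all hits, top-percent
# window within the mapped subset, max score wins, ties -> smallest accession
oracle_best_mapped <- function(subjects, scores, map, params) {
  mapped <- scores >= params$min_score & subjects %in% names(map)
  if (!any(mapped)) return(NULL)
  mapped <- mapped &
    scores >= (1 - params$top_percent / 100) * max(scores[mapped])
  best <- max(scores[mapped])
  cand <- subjects[mapped & scores == best]
  acc <- sort(cand)[1L]
  list(target = unname(map[[acc]]), bitscore = best)
}

oracle_assign_taxon <- function(subjects, scores, map, tax, params) {
  mapped <- scores >= params$min_score & subjects %in% names(map)
  if (!any(mapped)) return(NULL)
  mapped <- mapped &
    scores >= (1 - params$top_percent / 100) * max(scores[mapped])
  taxa <- unname(map[subjects[mapped]])
  taxa <- taxa[taxa %in% tax$nodes]
  if (!length(taxa)) return(NULL)
  oracle_lca(tax, taxa)
}

# UniFrac by explicit enumeration of every branch's descendant leaf set
oracle_unifrac <- function(assigned, h, variant) {
  nodes <- rownames(assigned)
  branch_mass <- function(b, col)
    sum(assigned[vapply(nodes, function(n) b %in% ancestors(h, n),
                        logical(1)), col])
  branches <- setdiff(h$nodes, h$root)
  samples <- colnames(assigned)
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  tot <- vapply(samples, function(s) sum(assigned[, s]), numeric(1))
  for (j in seq_len(n - 1L)) for (k in seq(j + 1L, n)) {
    a <- vapply(branches, branch_mass, numeric(1), col = j)
    b <- vapply(branches, branch_mass, numeric(1), col = k)
    v <- if (variant == "unweighted") {
      sum(xor(a > 0, b > 0)) / sum(a > 0 | b > 0)
    } else {
      pa <- a / tot[j]; pb <- b / tot[k]
      sum(abs(pa - pb)) / sum(pa + pb)
    }
    d[j, k] <- d[k, j] <- v
  }
  d
}

expect_symmetric_zero_diag <- function(dm) {
  m <- unclass(dm)
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, nrow(m)))
}
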