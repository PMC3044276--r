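seed_assignments <- function(targets, sample = "s1") {
  n <- length(targets)
  structure(data.frame(read_id = if (n) paste0("r", seq_len(n)) else character(0),
                       kind = rep("seed-role", n), target = targets,
                       bitscore = rep(50, n), stringsAsFactors = FALSE),
            kind = "seed-role", sample = sample,
            class = c("assignments", "data.frame"))
}

test_that("single-leaf roles place one read, summarized bottom-up", {
  h <- tiny_seed_tree()
  p <- build_profile(seed_assignments("RoleY"), h)
  expect_equal(unname(p$assigned["L2"]), 1)
  expect_equal(unname(p$summarized["S1"]), 1)
  expect_equal(unname(p$summarized[h$root]), 1)
})

test_that("a multi-labeled role counts at every leaf but once per read", {
  h <- tiny_seed_tree()
  p <- build_profile(seed_assignments("RoleX"), h)  # leaves L1 (S1), L3 (S2)
  expect_equal(unname(p$assigned[c("L1", "L3")]), c(1, 1))
  expect_equal(unname(p$summarized[c("S1", "S2")]), c(1, 1))
  expect_equal(unname(p$summarized[h$root]), 2)     # tree-view count
  expect_equal(unname(p$role_counts["RoleX"]), 1)   # unique-read audit
})

test_that("zero assignments give an all-zero profile; unknown roles bin", {
  h <- tiny_seed_tree()
  p0 <- build_profile(seed_assignments(character(0)), h)
  expect_true(all(p0$assigned == 0))
  expect_warning(p1 <- build_profile(seed_assignments("GhostRole"), h),
                 "no leaf")
  expect_equal(unname(p1$bins["NotAssigned"]), 1)
})

test_that("summarized counts satisfy the subtree recurrence everywhere", {
  set.seed(17)
  h <- rand_tree(25)
  counts <- stats::setNames(stats::rpois(25, 1.5), h$nodes)
  a <- structure(data.frame(read_id = paste0("r", seq_len(sum(counts))),
                            kind = "taxon",
                            target = rep(names(counts), counts),
                            bitscore = 50, stringsAsFactors = FALSE),
                 kind = "taxon", sample = "s1",
                 class = c("assignments", "data.frame"))
  p <- build_profile(a, h)
  for (n in h$nodes) {
    kids <- h$children[[n]]
    expect_equal(p$summarized[[n]],
                 p$assigned[[n]] + sum(p$summarized[kids]))
    # and against an independent subtree enumeration
    expect_equal(p$summarized[[n]], sum(p$assigned[descendants(h, n)]))
  }
})

test_that("build_profile is additive over disjoint read sets", {
  h <- tiny_seed_tree()
  a <- seed_assignments(c("RoleX", "RoleY"))
  b <- seed_assignments(c("RoleY", "RoleY"))
  b$read_id <- paste0("x", b$read_id)
  both <- structure(rbind(as.data.frame(a), as.data.frame(b)),
                    kind = "seed-role", sample = "s1",
                    class = c("assignments", "data.frame"))
  pa <- build_profile(a, h); pb <- build_profile(b, h)
  pc <- build_profile(both, h)
  expect_equal(pc$assigned, pa$assigned + pb$assigned)
  expect_equal(pc$summarized, pa$summarized + pb$summarized)
})

test_that("joining profiles preserves columns and totals", {
  h <- tiny_seed_tree()
  p1 <- build_profile(seed_assignments(c("RoleX", "RoleY"), "s1"), h)
  p2 <- build_profile(seed_assignments(c("RoleX", "RoleY"), "s2"), h)
  tab <- join_profiles(list(p1, p2), "summarized")
  expect_equal(tab$counts[, "s1"], tab$counts[, "s2"])
  expect_equal(unname(colSums(tab$bins)), c(0, 0))

  p3 <- build_profile(seed_assignments("RoleY", "s3"), h)
  tab3 <- join_profiles(list(p1, p3), "assigned")
  expect_equal(unname(tab3$counts[, "s1"]),
               unname(p1$assigned[rownames(tab3$counts)]))
  expect_equal(unname(tab3$counts[, "s3"]),
               unname(p3$assigned[rownames(tab3$counts)]))

  other <- build_profile(seed_assignments("RoleX"), tiny_seed_tree())
  other$tree$label[1] <- "changed"
  expect_error(join_profiles(list(p1, other)), "different hierarchies")
})

test_that("relative normalization makes columns sum to one", {
  h <- tiny_seed_tree()
  p1 <- build_profile(seed_assignments(c("RoleX", "RoleX", "RoleY"), "s1"), h)
  p2 <- build_profile(seed_assignments(c("RoleY", "RoleY"), "s2"), h)
  tab <- join_profiles(list(p1, p2), "assigned")
  rel <- normalize_table(tab, "relative")
  expect_equal(unname(colSums(rel$counts)), c(1, 1), tolerance = 1e-12)
  expect_equal(normalize_table(tab, "none"), tab)

  pz <- build_profile(seed_assignments(character(0), "s0"), h)
  tz <- join_profiles(list(p1, pz), "assigned")
  expect_error(normalize_table(tz, "relative"), "s0")
})

test_that("profiles round-trip through TSV writers", {
  h <- tiny_tax()
  a <- structure(data.frame(read_id = c("r1", "r2", "r3"), kind = "taxon",
                            target = c("B", "B", "NotAssigned"),
                            bitscore = c(40, 41, NA),
                            stringsAsFactors = FALSE),
                 kind = "taxon", sample = "s1",
                 class = c("assignments", "data.frame"))
  p <- build_profile(a, h)
  f <- tempfile(fileext = ".tsv")
  write_profile(p, f)
  p2 <- read_profile(f, h, sample = "s1")
  expect_equal(p2$assigned, p$assigned)
  expect_equal(p2$summarized, p$summarized)
  expect_equal(p2$bins, p$bins)

  sp <- build_profile(seed_assignments(c("RoleX", "RoleY", "RoleY")), h = tiny_seed_tree())
  rf <- tempfile(fileext = ".tsv")
  write_role_counts(sp, rf)
  expect_equal(read_role_counts(rf), sp$role_counts[sort(names(sp$role_counts))])
})

test_that("the worked-example assignment report reproduces printed ratios", {
  rep1 <- assignment_report(1408, c(`MG-RAST` = 831, MEGAN = 727))
  expect_equal(rep1$pct_of_reference[2], 100 * 727 / 831)
  rep2 <- assignment_report(209073, c(`MG-RAST` = 86167, MEGAN = 97748))
  expect_gt(rep2$pct_of_reference[2], 100)  # more assignments than reference
  expect_equal(rep2$pct_of_total[2], 100 * 97748 / 209073)
})
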