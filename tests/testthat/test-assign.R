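fm <- structure(c(accA = "RoleX", accB = "RoleY"),
                class = c("function_map", "accession_map"))
km <- structure(c(accB = "K00001", accC = "K00002"),
                class = c("ko_map", "accession_map"))

test_that("seed assignment takes the best mapped hit and bins the rest", {
  hits <- make_hits("r1", c("accA", "accB"), c(60, 50))
  a <- assign_seed(hits, fm)
  expect_equal(a$target, "RoleX")
  expect_equal(a$bitscore, 60)

  # top hit unmapped: the best *mapped* hit wins
  hits2 <- make_hits("r1", c("accZ", "accB"), c(60, 50))
  expect_equal(assign_seed(hits2, fm)$target, "RoleY")
  # ... unless strict mode is requested
  expect_equal(assign_seed(hits2, fm, strict = TRUE)$target, "NotAssigned")

  # zero hits -> NoHits (read known only through the universe)
  empty <- make_hits(character(0), character(0), numeric(0))
  a0 <- assign_seed(empty, fm, all_reads = "r9")
  expect_equal(a0$target, "NoHits")

  # no filtered hit mapped -> NotAssigned
  a1 <- assign_seed(make_hits("r1", "accZ", 80), fm)
  expect_equal(a1$target, "NotAssigned")
})

test_that("KO assignment uses the best hit with a known KO, with tie-break", {
  hits <- make_hits("r1", c("accA", "accB"), c(80, 70))  # accA has no KO
  expect_equal(assign_ko(hits, km)$target, "K00001")

  expect_equal(assign_ko(make_hits("r1", "accA", 80), km)$target,
               "NotAssigned")

  # equal scores: lexicographically smaller accession wins, regardless of
  # input order
  t1 <- make_hits("r1", c("accC", "accB"), c(70, 70))
  t2 <- make_hits("r1", c("accB", "accC"), c(70, 70))
  expect_equal(assign_ko(t1, km)$target, "K00001")  # accB < accC
  expect_equal(assign_ko(t2, km)$target, "K00001")
})

test_that("assignment is invariant under hit order and monotone in min_score", {
  set.seed(7)
  accs <- paste0("acc", 1:12)
  map <- structure(stats::setNames(sample(c("R1", "R2", "R3"), 8, TRUE),
                                   accs[1:8]),
                   class = c("function_map", "accession_map"))
  for (rep in 1:15) {
    n <- sample(1:20, 1)
    base <- data.frame(read_id = "r1",
                       subject_id = sample(accs, n, replace = TRUE),
                       bitscore = round(stats::runif(n, 20, 100), 1),
                       stringsAsFactors = FALSE)
    perm <- base[sample(nrow(base)), ]
    h1 <- make_hits(base$read_id, base$subject_id, base$bitscore)
    h2 <- make_hits(perm$read_id, perm$subject_id, perm$bitscore)
    expect_equal(assign_seed(h1, map)$target, assign_seed(h2, map)$target)

    lo <- assign_seed(h1, map, assign_params(min_score = 35))$target
    hi <- assign_seed(h1, map, assign_params(min_score = 80))$target
    if (lo %in% c("NoHits", "NotAssigned"))
      expect_true(hi %in% c("NoHits", "NotAssigned"))
  }
})

test_that("taxon assignment is the LCA of filtered mapped hits", {
  tax <- tiny_tax()
  tm <- structure(c(acc1 = "B", acc2 = "C", acc3 = "D"),
                  class = c("taxon_map", "accession_map"))
  # siblings B and C -> genus A
  a <- assign_taxon(make_hits(c("r1", "r1"), c("acc1", "acc2"), c(80, 78)),
                    tm, tax)
  expect_equal(a$target, "A")
  # single mapped hit -> that taxon
  expect_equal(assign_taxon(make_hits("r1", "acc1", 80), tm, tax)$target, "B")
  # filter first, then LCA: 85 is outside the 10% window of 100
  a2 <- assign_taxon(make_hits(c("r1", "r1"), c("acc1", "acc2"), c(100, 85)),
                     tm, tax)
  expect_equal(a2$target, "B")
})

test_that("assignments match the exhaustive brute-force oracle", {
  set.seed(123)
  params <- assign_params()
  for (rep in 1:30) {
    tax <- rand_tree(sample(5:50, 1), prefix = "t")
    accs <- paste0("acc", 1:15)
    map_fun <- structure(
      stats::setNames(sample(c("R1", "R2", "R3", "R4"), 10, TRUE), accs[1:10]),
      class = c("function_map", "accession_map"))
    map_tax <- structure(
      stats::setNames(sample(tax$nodes, 10, TRUE), accs[1:10]),
      class = c("taxon_map", "accession_map"))
    reads <- paste0("r", 1:3)
    df <- data.frame(
      read_id = sample(reads, 25, replace = TRUE),
      subject_id = sample(accs, 25, replace = TRUE),
      bitscore = round(stats::runif(25, 10, 120), 1),
      stringsAsFactors = FALSE)
    hits <- make_hits(df$read_id, df$subject_id, df$bitscore)
    a_seed <- assign_seed(hits, map_fun, params)
    a_ko <- assign_ko(hits, map_fun, params)  # same semantics as a KO map
    a_tax <- assign_taxon(hits, map_tax, tax, params)
    for (r in reads) {
      sub <- df[df$read_id == r, ]
      want <- oracle_best_mapped(sub$subject_id, sub$bitscore, map_fun, params)
      got <- a_seed$target[a_seed$read_id == r]
      if (is.null(want)) expect_equal(got, "NotAssigned")
      else {
        expect_equal(got, want$target)
        expect_equal(a_seed$bitscore[a_seed$read_id == r], want$bitscore)
      }
      expect_equal(a_ko$target[a_ko$read_id == r],
                   if (is.null(want)) "NotAssigned" else want$target)
      want_t <- oracle_assign_taxon(sub$subject_id, sub$bitscore, map_tax,
                                    tax, params)
      got_t <- a_tax$target[a_tax$read_id == r]
      if (is.null(want_t)) expect_equal(got_t, "NotAssigned")
      else expect_equal(got_t, want_t)
      # placed taxon is an ancestor-or-self of every retained hit taxon
      if (!is.null(want_t)) {
        kept <- oracle_filter(sub$bitscore, params$min_score,
                              params$top_percent)
        taxa <- unname(map_tax[sub$subject_id[kept]])
        taxa <- taxa[!is.na(taxa)]
        for (tx in taxa) expect_true(got_t %in% ancestors(tax, tx))
      }
    }
  }
})

test_that("assignment tables round-trip through TSV", {
  hits <- make_hits(c("r1", "r2"), c("accA", "accZ"), c(60, 50))
  a <- assign_seed(hits, fm, all_reads = c("r1", "r2", "r3"), sample = "s1")
  f <- tempfile(fileext = ".tsv")
  write_assignments(a, f)
  a2 <- read_assignments(f, sample = "s1")
  expect_equal(a2$target, a$target)
  expect_equal(a2$read_id, a$read_id)
  expect_equal(a2$bitscore, a$bitscore)
})
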