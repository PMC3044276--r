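INDICES <- c("goodall", "bray-curtis", "euclidean", "hellinger",
             "chi-square", "kulczynski")

test_that("hand-evaluated Bray-Curtis and boundary cases hold", {
  m <- cbind(s1 = c(1, 2, 3), s2 = c(3, 2, 1))
  expect_equal(ecological_distance(m, "bray-curtis")["s1", "s2"], 1 / 3)

  disj <- cbind(a = c(5, 0, 2, 0), b = c(0, 1, 0, 4))
  expect_equal(ecological_distance(disj, "bray-curtis")["a", "b"], 1)
  expect_equal(ecological_distance(disj, "kulczynski")["a", "b"], 1)
})

test_that("identical samples are at distance zero for every index", {
  # 8 samples so Goodall's rank-based p-values have enough pairs to resolve
  # a duplicated pair (its Fisher tail decays with the pair count)
  set.seed(4)
  m <- matrix(stats::rpois(80, 4) + 1, nrow = 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:8)))
  m[, 2] <- m[, 1] * 2  # same relative profile as sample 1
  for (idx in INDICES) {
    d <- ecological_distance(m, idx)
    tol <- if (idx == "goodall") 1e-4 else 1e-12
    expect_lt(d["s1", "s2"], tol)
    expect_symmetric_zero_diag(d)
  }
})

test_that("indices match vegan on random tables where both are defined", {
  skip_if_not_installed("vegan")
  set.seed(12)
  m <- matrix(stats::rpois(60, 5) + 1, nrow = 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:6)))
  rel <- sweep(m, 2, colSums(m), "/")
  bc <- as.matrix(vegan::vegdist(t(rel), "bray"))
  expect_equal(unclass(ecological_distance(m, "bray-curtis")), bc,
               tolerance = 1e-12, ignore_attr = TRUE)
  eu <- as.matrix(stats::dist(t(rel)))
  expect_equal(unclass(ecological_distance(m, "euclidean")), eu,
               tolerance = 1e-12, ignore_attr = TRUE)
  ku <- as.matrix(vegan::vegdist(t(rel), "kulczynski"))
  expect_equal(unclass(ecological_distance(m, "kulczynski")), ku,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("hellinger and chi-square follow their stated formulas", {
  set.seed(21)
  m <- matrix(stats::rpois(40, 3), nrow = 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:4)))
  m[1, ] <- 0  # zero-mass row must be dropped by chi-square
  rel <- sweep(m, 2, colSums(m), "/")
  hel <- ecological_distance(m, "hellinger")
  chi <- ecological_distance(m, "chi-square")
  w <- rowMeans(rel)
  for (j in 1:3) for (k in (j + 1):4) {
    expect_equal(hel[j, k], sqrt(sum((sqrt(rel[, j]) - sqrt(rel[, k]))^2)))
    keep <- w > 0
    expect_equal(chi[j, k],
                 sqrt(sum((rel[keep, j] - rel[keep, k])^2 / w[keep])))
  }
})

test_that("goodall behaves as a probabilistic index on >= 3 samples", {
  set.seed(3)
  m <- matrix(stats::rpois(50, 6) + 1, nrow = 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:5)))
  d <- ecological_distance(m, "goodall")
  expect_symmetric_zero_diag(d)
  expect_true(all(d >= 0 & d <= 1))
  expect_error(ecological_distance(m[, 1:2], "goodall"), ">= 3 samples")
})

test_that("bounded indices stay in [0,1] on random tables", {
  set.seed(8)
  for (rep in 1:5) {
    m <- matrix(stats::rpois(8 * 5, 3), nrow = 8,
                dimnames = list(paste0("f", 1:8), paste0("s", 1:5)))
    m <- m + 1  # avoid zero-total columns
    for (idx in INDICES) {
      d <- ecological_distance(m, idx)
      expect_symmetric_zero_diag(d)
      if (idx %in% c("bray-curtis", "kulczynski", "goodall"))
        expect_true(all(d >= 0 & d <= 1))
    }
  }
})

test_that("unifrac separates disjoint leaves and vanishes for identical ones", {
  h <- hierarchy(c("L1", "L2"), c("root", "root"))
  m <- cbind(a = c(4, 0), b = c(0, 7))
  rownames(m) <- c("L1", "L2")
  expect_equal(unifrac(m, h, "unweighted")["a", "b"], 1)
  expect_equal(unifrac(m, h, "weighted-normalized")["a", "b"], 1)
  same <- cbind(a = c(4, 2), b = c(8, 4))
  rownames(same) <- c("L1", "L2")
  expect_equal(unifrac(same, h, "unweighted")["a", "b"], 0)
  expect_equal(unifrac(same, h, "weighted-normalized")["a", "b"], 0)
  zero <- cbind(a = c(1, 0), b = c(0, 0))
  rownames(zero) <- c("L1", "L2")
  expect_error(unifrac(zero, h, "unweighted"), "zero total")
})

test_that("unifrac equals the brute-force branch enumeration on random trees", {
  set.seed(77)
  for (rep in 1:15) {
    h <- rand_tree(10)
    m <- matrix(stats::rpois(10 * 3, 1.2), nrow = 10,
                dimnames = list(h$nodes, paste0("s", 1:3)))
    m[1, ] <- m[1, ] + 1  # guarantee nonzero totals
    for (v in c("unweighted", "weighted-normalized")) {
      got <- unclass(unifrac(m, h, v))
      want <- oracle_unifrac(m, h, v)
      expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
      expect_true(all(got >= 0 & got <= 1))
    }
  }
})

test_that("weighted unifrac on a star tree reduces to a Bray-Curtis form", {
  # star: every leaf hangs off the root; branch masses are the leaf masses,
  # so the normalized weighted sum coincides with Bray-Curtis on relative
  # abundances. Checked numerically, not assumed.
  set.seed(14)
  leaves <- paste0("L", 1:8)
  h <- hierarchy(leaves, rep("root", 8))
  m <- matrix(stats::rpois(16, 5) + 1, nrow = 8,
              dimnames = list(leaves, c("a", "b")))
  wu <- unifrac(m, h, "weighted-normalized")["a", "b"]
  bc <- ecological_distance(m, "bray-curtis")["a", "b"]
  expect_equal(wu, bc, tolerance = 1e-12)
  expect_equal(wu, oracle_unifrac(m, h, "weighted-normalized")["a", "b"],
               tolerance = 1e-12)
})

test_that("matrix writers emit the three dialects and phylip round-trips", {
  m <- matrix(c(0, 0.25, 0.25, 0), 2, 2,
              dimnames = list(c("s1", "s2"), c("s1", "s2")))
  dm <- structure(m, index = "test", class = c("distance_matrix", "matrix"))
  fp <- tempfile(fileext = ".dist")
  write_distance_matrix(dm, fp, "phylip")
  expect_equal(trimws(readLines(fp)[1]), "2")
  rt <- read_phylip_distance(fp)
  expect_equal(unclass(rt), m, ignore_attr = TRUE)

  fn <- tempfile(fileext = ".nex")
  write_distance_matrix(dm, fn, "nexus")
  nx <- readLines(fn)
  expect_equal(nx[1], "#NEXUS")
  expect_true(any(grepl("BEGIN DISTANCES;", nx)))

  # 8 samples -> 28 undirected edges
  set.seed(2)
  m8 <- matrix(stats::runif(64), 8, 8,
               dimnames = list(paste0("s", 1:8), paste0("s", 1:8)))
  m8 <- (m8 + t(m8)) / 2; diag(m8) <- 0
  fe <- tempfile(fileext = ".tsv")
  write_distance_matrix(m8, fe, "edge-tsv")
  expect_equal(length(readLines(fe)) - 1L, 28L)
})
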