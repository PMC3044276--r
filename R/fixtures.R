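# Deterministic synthetic-fixture generator: hierarchies, mapping tables and
# BLAST tabular files with a known ground-truth assignment per read, so the
# whole pipeline is testable without any reference database. All randomness
# flows from the single seed in the spec; with the same seed the generated
# bundle is byte-identical across runs.

#' Specify a synthetic fixture
#'
#' Defaults describe a small but non-degenerate study: a 3-level ternary
#' taxonomy, a SEED tree of 5 subsystems with 4 roles each (25% of roles
#' multi-labeled under a second subsystem), 120 reference accessions, one
#' sample of 100 reads with up to 3 distractor hits per read, and no noise.
#' Intended hits are drawn to dominate all distractors by more than the
#' default top-percent window, so the ground truth is unambiguous unless
#' `noise_rate` triggers, in which case a higher-scoring hit to a
#' wrong-role accession overrides the intended one.
#'
#' @param seed Integer seed; fully determines the generated bytes.
#' @param tax_depth,tax_branching Taxonomy shape (levels below the root;
#'   children per internal node).
#' @param n_subsystems,roles_per_subsystem SEED shape.
#' @param multilabel_fraction Fraction of roles labeling a second leaf under
#'   a different subsystem, in \[0, 1\].
#' @param n_refs Number of reference accessions (>= number of roles).
#' @param n_reads Reads per sample.
#' @param max_distractors Maximum extra (never-winning) hits per read.
#' @param noise_rate Probability that a read's top hit maps to a wrong role,
#'   in \[0, 1\].
#' @param samples Named list of per-sample role-abundance weight vectors
#'   (length = number of roles); `NULL` means one sample, uniform weights.
#' @return A `"fixture_spec"` list.
#' @export
fixture_spec <- function(seed = 1L, tax_depth = 3L, tax_branching = 3L,
                         n_subsystems = 5L, roles_per_subsystem = 4L,
                         multilabel_fraction = 0.25, n_refs = 120L,
                         n_reads = 100L, max_distractors = 3L,
                         noise_rate = 0, samples = NULL) {
  if (noise_rate < 0 || noise_rate > 1) stop("'noise_rate' must be in [0, 1]")
  if (multilabel_fraction < 0 || multilabel_fraction > 1)
    stop("'multilabel_fraction' must be in [0, 1]")
  n_roles <- n_subsystems * roles_per_subsystem
  if (n_refs < n_roles) stop("'n_refs' must be >= number of roles")
  if (is.null(samples)) samples <- list(sample1 = rep(1, n_roles))
  if (is.null(names(samples)) || any(!nzchar(names(samples))))
    stop("'samples' must be a named list")
  for (w in samples)
    if (length(w) != n_roles || any(w < 0) || sum(w) <= 0)
      stop("each sample weight vector must be nonnegative of length ", n_roles)
  structure(list(seed = as.integer(seed), tax_depth = as.integer(tax_depth),
                 tax_branching = as.integer(tax_branching),
                 n_subsystems = as.integer(n_subsystems),
                 roles_per_subsystem = as.integer(roles_per_subsystem),
                 multilabel_fraction = multilabel_fraction,
                 n_refs = as.integer(n_refs), n_reads = as.integer(n_reads),
                 max_distractors = as.integer(max_distractors),
                 noise_rate = noise_rate, samples = samples),
            class = "fixture_spec")
}

make_taxonomy <- function(depth, branching) {
  child <- "tax_root"
  parent <- NA_character_
  frontier <- "tax_root"
  counter <- 0L
  for (lev in seq_len(depth)) {
    nxt <- character(0)
    for (p in frontier) {
      for (k in seq_len(branching)) {
        counter <- counter + 1L
        id <- sprintf("t%03d", counter)
        child <- c(child, id)
        parent <- c(parent, p)
        nxt <- c(nxt, id)
      }
    }
    frontier <- nxt
  }
  hierarchy(child, parent, label = paste0("Taxon ", child))
}

make_seed_tree <- function(n_sub, roles_per, multilabel_fraction) {
  n_roles <- n_sub * roles_per
  roles <- sprintf("Role_%03d", seq_len(n_roles))
  ss <- sprintf("SS%02d", seq_len(n_sub))
  child <- c("seed_root", ss)
  parent <- c(NA_character_, rep("seed_root", n_sub))
  role <- c(NA_character_, rep(NA_character_, n_sub))
  for (s in seq_len(n_sub)) for (j in seq_len(roles_per)) {
    i <- (s - 1L) * roles_per + j
    child <- c(child, sprintf("%s_L%02d", ss[s], j))
    parent <- c(parent, ss[s])
    role <- c(role, roles[i])
  }
  # multi-label: first floor(f * n_roles) roles get a second leaf under the
  # next subsystem over
  n_multi <- floor(multilabel_fraction * n_roles)
  for (i in seq_len(n_multi)) {
    s <- (i - 1L) %/% roles_per + 1L
    s2 <- s %% n_sub + 1L
    child <- c(child, sprintf("%s_X%02d", ss[s2], i))
    parent <- c(parent, ss[s2])
    role <- c(role, roles[i])
  }
  hierarchy(child, parent, label = child, role = role)
}

make_pathway_map <- function(n_roles) {
  kos <- sprintf("K%05d", seq_len(n_roles))
  np <- max(2L, ceiling(n_roles / 8))
  pw <- sprintf("P%03d", seq_len(np))
  ko <- kos
  pid <- pw[(seq_len(n_roles) - 1L) %% np + 1L]
  # every third KO sits in a second pathway
  extra <- seq(3L, n_roles, by = 3L)
  ko <- c(ko, kos[extra])
  pid <- c(pid, pw[extra %% np + 1L])
  structure(list(pathways = lapply(split(pid, ko), unique),
                 label = stats::setNames(paste("Pathway", pw), pw)),
            class = "pathway_map")
}

fixture_classes <- function(x, kind) {
  structure(x, class = c(paste0(kind, "_map"), "accession_map"))
}

#' Generate a synthetic fixture bundle
#'
#' Builds the taxonomy and SEED hierarchies, the accession mapping tables,
#' per-sample BLAST outfmt-6 hit tables and the ground-truth table, all
#' determined by `spec$seed`. When `out_dir` is given the bundle is also
#' written to disk (`taxonomy.tsv`, `seed.tsv`, `acc2role.tsv`,
#' `acc2taxon.tsv`, `acc2ko.tsv`, `ko2pathway.tsv`, `<sample>.blast.tsv`,
#' `truth.tsv`, `fixture.config`), byte-identically across runs with the
#' same seed.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Optional output directory (created if needed).
#' @return Invisibly, a list: `spec`, `tax_tree`, `seed_tree`, `fun_map`,
#'   `taxon_map`, `ko_map`, `pathway_map`, `hits` (named list of
#'   `blast_hits` per sample), `blast_lines` (raw outfmt-6 lines per
#'   sample), `truth` (data frame `read_id`, `sample`, `accession`, `role`,
#'   `taxon`, `ko`) and, when written, `files`.
#' @export
generate_fixture <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  tax <- make_taxonomy(spec$tax_depth, spec$tax_branching)
  seed_tree <- make_seed_tree(spec$n_subsystems, spec$roles_per_subsystem,
                              spec$multilabel_fraction)
  n_roles <- spec$n_subsystems * spec$roles_per_subsystem
  roles <- sprintf("Role_%03d", seq_len(n_roles))
  kos <- stats::setNames(sprintf("K%05d", seq_len(n_roles)), roles)
  pm <- make_pathway_map(n_roles)
  tax_leaves <- sort(leaves(tax))

  acc <- sprintf("acc%04d", seq_len(spec$n_refs))
  role_of_acc <- c(roles, sample(roles, spec$n_refs - n_roles, replace = TRUE))
  taxon_of_acc <- sample(tax_leaves, spec$n_refs, replace = TRUE)
  ko_of_acc <- unname(kos[role_of_acc])
  names(role_of_acc) <- names(taxon_of_acc) <- names(ko_of_acc) <- acc
  accs_by_role <- split(acc, role_of_acc)

  hit_line <- function(read, subject, score) {
    len <- sample(80:250, 1L)
    sstart <- sample(1:400, 1L)
    paste(read, subject, sprintf("%.1f", stats::runif(1, 60, 99)),
          len, sample(0:20, 1L), sample(0:3, 1L), 1L, len, sstart,
          sstart + len - 1L, sprintf("%.1e", 10^(-score / 4)),
          sprintf("%.1f", score), sep = "\t")
  }

  truth <- list()
  blast_lines <- list()
  for (s in names(spec$samples)) {
    w <- spec$samples[[s]]
    lines <- character(0)
    if (spec$n_reads > 0) {
      for (r in seq_len(spec$n_reads)) {
        rid <- sprintf("%s_r%04d", s, r)
        true_role <- roles[sample.int(n_roles, 1L, prob = w)]
        pool <- accs_by_role[[true_role]]
        a <- pool[sample.int(length(pool), 1L)]
        best <- sample(75:95, 1L)
        lines <- c(lines, hit_line(rid, a, best))
        nd <- sample.int(spec$max_distractors + 1L, 1L) - 1L
        if (nd > 0L) {
          hi <- floor(0.85 * best)  # below the 10% window of the winner
          for (k in seq_len(nd)) {
            da <- acc[sample.int(spec$n_refs, 1L)]
            lines <- c(lines, hit_line(rid, da, sample(20:hi, 1L)))
          }
        }
        if (spec$noise_rate > 0 && stats::runif(1) < spec$noise_rate) {
          repeat {
            na <- acc[sample.int(spec$n_refs, 1L)]
            if (role_of_acc[[na]] != true_role) break
          }
          lines <- c(lines, hit_line(rid, na, best + 12))
        }
        truth[[length(truth) + 1L]] <- data.frame(
          read_id = rid, sample = s, accession = a, role = true_role,
          taxon = unname(taxon_of_acc[[a]]), ko = unname(ko_of_acc[[a]]),
          stringsAsFactors = FALSE)
      }
    }
    blast_lines[[s]] <- lines
  }
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(read_id = character(0), sample = character(0),
                           accession = character(0), role = character(0),
                           taxon = character(0), ko = character(0),
                           stringsAsFactors = FALSE)

  parse_lines <- function(lines) {
    tf <- tempfile(fileext = ".blast.tsv")
    on.exit(unlink(tf))
    writeLines(lines, tf)
    read_blast(tf)
  }
  hits <- lapply(blast_lines, parse_lines)

  bundle <- list(spec = spec, tax_tree = tax, seed_tree = seed_tree,
                 fun_map = fixture_classes(role_of_acc, "function"),
                 taxon_map = fixture_classes(taxon_of_acc, "taxon"),
                 ko_map = fixture_classes(ko_of_acc, "ko"),
                 pathway_map = pm, hits = hits, blast_lines = blast_lines,
                 truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- c(taxonomy = file.path(out_dir, "taxonomy.tsv"),
               seed = file.path(out_dir, "seed.tsv"),
               acc2role = file.path(out_dir, "acc2role.tsv"),
               acc2taxon = file.path(out_dir, "acc2taxon.tsv"),
               acc2ko = file.path(out_dir, "acc2ko.tsv"),
               ko2pathway = file.path(out_dir, "ko2pathway.tsv"),
               truth = file.path(out_dir, "truth.tsv"),
               config = file.path(out_dir, "fixture.config"))
    write_hierarchy(tax, files[["taxonomy"]])
    write_hierarchy(seed_tree, files[["seed"]])
    writeLines(paste(acc, role_of_acc, sep = "\t"), files[["acc2role"]])
    writeLines(paste(acc, taxon_of_acc, sep = "\t"), files[["acc2taxon"]])
    writeLines(paste(acc, ko_of_acc, sep = "\t"), files[["acc2ko"]])
    pw_lines <- unlist(lapply(sort(names(pm$pathways)), function(k)
      paste(k, pm$pathways[[k]], pm$label[pm$pathways[[k]]], sep = "\t")))
    writeLines(pw_lines, files[["ko2pathway"]])
    utils::write.table(truth, files[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    cfg <- c(paste0("seed=", spec$seed),
             paste0("tax_depth=", spec$tax_depth),
             paste0("tax_branching=", spec$tax_branching),
             paste0("n_subsystems=", spec$n_subsystems),
             paste0("roles_per_subsystem=", spec$roles_per_subsystem),
             paste0("multilabel_fraction=", spec$multilabel_fraction),
             paste0("n_refs=", spec$n_refs),
             paste0("n_reads=", spec$n_reads),
             paste0("max_distractors=", spec$max_distractors),
             paste0("noise_rate=", spec$noise_rate),
             vapply(names(spec$samples), function(s)
               paste0("sample.", s, ".weights=",
                      paste(spec$samples[[s]], collapse = ",")),
               character(1)))
    writeLines(cfg, files[["config"]])
    for (s in names(blast_lines)) {
      p <- file.path(out_dir, paste0(s, ".blast.tsv"))
      writeLines(blast_lines[[s]], p)
      files[paste0("blast.", s)] <- p
    }
    bundle$files <- files
  }
  invisible(bundle)
}

#' Eight-sample mesocosm-like fixture spec
#'
#' A canned spec emulating the shape of a paired metagenome /
#' metatranscriptome mesocosm experiment: 8 samples — 4 DNA and 4 cDNA —
#' over the default SEED tree, where the cDNA (expression) condition
#' up-weights half of the functional roles about 6-fold and down-weights
#' the rest, with mild per-replicate jitter. DNA replicates therefore
#' resemble each other, cDNA replicates resemble each other, and the two
#' conditions separate under any abundance-based distance.
#'
#' @param seed Integer seed.
#' @param n_reads Reads per sample (default 240).
#' @return A `"fixture_spec"` with 8 samples.
#' @export
eight_sample_bergen_like <- function(seed = 1L, n_reads = 240L) {
  set.seed(as.integer(seed))
  n_sub <- 5L; roles_per <- 4L
  n_roles <- n_sub * roles_per
  expressed <- seq_len(n_roles %/% 2L)
  samples <- list()
  for (b in 1:4) {
    jit <- exp(stats::rnorm(n_roles, 0, 0.15))
    samples[[sprintf("bag%d_DNA", b)]] <- jit
  }
  for (b in 1:4) {
    w <- exp(stats::rnorm(n_roles, 0, 0.15))
    w[expressed] <- w[expressed] * 6
    w[-expressed] <- w[-expressed] * 0.4
    samples[[sprintf("bag%d_cDNA", b)]] <- w
  }
  fixture_spec(seed = seed, n_subsystems = n_sub,
               roles_per_subsystem = roles_per, n_reads = n_reads,
               samples = samples)
}

#' End-to-end recovery of ground truth from a fixture bundle
#'
#' Runs the full assignment pipeline (SEED role, taxon via LCA, KO) on each
#' sample's hits and scores it against the bundle's truth table.
#'
#' @param bundle A bundle from [generate_fixture()].
#' @param params An [assign_params()] list.
#' @return Named numeric vector: percent of reads whose recovered role /
#'   taxon / KO equals the ground truth.
#' @export
evaluate_recovery <- function(bundle, params = assign_params()) {
  ok <- c(role = 0, taxon = 0, ko = 0)
  n <- 0L
  for (s in names(bundle$hits)) {
    tr <- bundle$truth[bundle$truth$sample == s, , drop = FALSE]
    if (!nrow(tr)) next
    h <- bundle$hits[[s]]
    a_role <- assign_seed(h, bundle$fun_map, params, all_reads = tr$read_id)
    a_tax <- assign_taxon(h, bundle$taxon_map, bundle$tax_tree, params,
                          all_reads = tr$read_id)
    a_ko <- assign_ko(h, bundle$ko_map, params, all_reads = tr$read_id)
    pick <- function(a) stats::setNames(a$target, a$read_id)[tr$read_id]
    ok[["role"]] <- ok[["role"]] + sum(pick(a_role) == tr$role)
    ok[["taxon"]] <- ok[["taxon"]] + sum(pick(a_tax) == tr$taxon)
    ok[["ko"]] <- ok[["ko"]] + sum(pick(a_ko) == tr$ko)
    n <- n + nrow(tr)
  }
  if (n == 0L) return(ok * NA_real_)
  100 * ok / n
}
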