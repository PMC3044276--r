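---
title: "Methods: functional and taxonomic binning of metagenome BLAST output"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional and taxonomic binning of metagenome BLAST output}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`metafun` answers the three standard questions about a shotgun metagenome or
metatranscriptome, starting from a tabular BLAST comparison of the reads
against a protein reference database:

1. *Who is out there?* Each read is placed on a node of a taxonomy by the
   lowest-common-ancestor (LCA) of its significant hits.
2. *What are they doing?* Each read is assigned to a SEED functional role
   and to a KEGG orthology (KO), and KO hits are aggregated into pathway
   abundance tables.
3. *How do datasets compare?* Per-sample count profiles over a hierarchy are
   joined and compared with ecological distance indices and UniFrac.

Everything downstream of BLAST is recomputed from plain text files: no
binary session formats, no services, no reference databases are required to
exercise the code (a seeded generator produces structurally faithful
stand-ins with known ground truth).

# Data model

A **hierarchy** is a rooted tree of string-identified nodes (one parent per
non-root node, no cycles; validated on construction with the offending node
named on failure). Two variants are used:

* the **taxonomy**, a single-labeled tree, and
* the **SEED classification**, in which internal nodes are subsystems and
  leaves carry functional-role names. The SEED tree is *multi-labeled*: the
  same role may label leaves under several subsystems, because a function
  can participate in more than one biological process.

The interchange format is a three/four-column TSV edge list
(`child`, `parent`, `label`, optional `role`); Newick is accepted read-only
(via `ape`), with branch lengths ignored and unit lengths assumed. Mapping
tables (accession to role, taxon, or KO; KO to pathways) are header-less
TSVs. Targets missing from the hierarchy ("dangling", as happens when a
mapping file and a tree drift apart between releases) are warnings, and
reads hitting them fall into the `NotAssigned` bin rather than aborting a
run.

# Read assignment

## Score filtering

Two parameters gate which hits count, with the conventional import
defaults:

| parameter     | default | meaning                                             |
|---------------|---------|-----------------------------------------------------|
| `min_score`   | 35 bits | absolute bit-score floor                            |
| `top_percent` | 10 %    | retain hits within 10% of the best retained score   |
| `min_support` | 5 reads | minimum reads per taxonomy node (see promotion)     |

`filter_hits()` applies the floor first, then the window against the best
retained score; the operation is idempotent and its tie order is fixed
(descending bit score, then ascending subject accession), so every
assignment is deterministic and independent of input order.

## Functional roles and KOs: best mapped hit

A read is assigned to the functional role (or KO) of its best *mapped* hit.
One design point deserves emphasis: the top-percent window is applied
**within the mapped subset** of a read's hits, not against the overall best
hit. If the single best hit has no known role but a hit a few bits lower
does, the read is still assigned — the unmapped hit carries no functional
information and should not veto the mapped one. (KO assignment is defined
exactly this way — "the best hit for which a KO is known" — and role
assignment is given the same semantics for symmetry; a `strict` flag
restores the harsher reading in which an unmapped top hit forces
`NotAssigned`.) A read with no hits at all is binned `NoHits`; a read whose
surviving hits map to nothing is `NotAssigned`. Each read receives exactly
one role and one KO — no fractional or multiple assignment.

## Taxa: lowest common ancestor with minimum support

For taxonomic binning the taxa of *all* filtered mapped hits are collected
and the read is placed on their LCA — the most specific taxon consistent
with every retained hit, so conserved genes drift toward the root and
clade-specific genes stay near the leaves. After profiling, **min-support
promotion** moves the reads of any node attracting fewer than `min_support`
reads (but more than zero) to its immediate parent. Promotion runs
deepest-first to a fixpoint, so promoted reads can cascade; the total read
count is conserved and the two bins are exempt. Reads are moved, never
discarded.

`reads_under_taxa()` inverts the taxonomic assignment: given a set of taxon
nodes it returns every read assigned at those nodes or below, which is how
KEGG pathway analysis is restricted to a clade of interest.

# Count profiles

`build_profile()` turns per-read assignments into two vectors over the
hierarchy: `assigned(n)` (reads placed exactly at *n*) and `summarized(n)`
(reads anywhere in the subtree of *n*, computed bottom-up so that
`summarized(n) = assigned(n) + sum over children of summarized`).

The multi-labeled SEED tree forces a counting convention. A read whose role
labels *k* leaves is displayed at **every** such leaf — that is what a
multi-labeled tree view shows, and it keeps each subsystem's total
meaningful — so the tree-view counts intentionally sum to more than the
number of reads when *k* > 1. To keep conservation auditable, a per-role
**unique-read** tally is kept alongside (`role_counts`): summed over roles
it equals the number of functionally assigned reads exactly. Both views are
exported; whether a shared role "belongs" once or twice in subsystem totals
is a presentation question, and emitting both audits sidesteps it.

Profiles over the same hierarchy join into a node-by-sample
`comparison_table` (rows in depth-first order for stable diffs, missing
nodes zero-filled, bins carried separately), with optional per-column
relative normalization (zero-total columns are a named, fatal degeneracy).

# Comparing samples

## Input level for the indices

Mixing a node with its ancestors would count every read twice, so the six
abundance indices are computed by default on the **functional-role
unique-read table** (`role_table()`): one row per role, each read counted
once. Any features-by-samples matrix is accepted for other designs.
Columns are converted to relative abundances before any index.

## The six indices

With relative-abundance columns $x, y$ over rows $i$:

* Bray–Curtis: $\sum_i |x_i-y_i| \,/\, \sum_i (x_i+y_i)$
* Euclidean: $\sqrt{\sum_i (x_i-y_i)^2}$
* Hellinger: $\sqrt{\sum_i (\sqrt{x_i}-\sqrt{y_i})^2}$
* Chi-square: $\sqrt{\sum_i (x_i-y_i)^2 / w_i}$, $w_i$ the row's mean
  relative abundance over all samples (zero-mass rows dropped)
* Kulczynski: $1-\tfrac12\left(\frac{\sum_i \min(x_i,y_i)}{\sum_i x_i} +
  \frac{\sum_i \min(x_i,y_i)}{\sum_i y_i}\right)$
* Goodall: the probabilistic similarity described next.

## Goodall's index — this package's variant

Goodall's 1966 probabilistic similarity is named in the comparative-
metagenomics literature without an operational formula, so the
implementation here is one concrete, documented choice (alternates are
pluggable). Per feature row $i$ the similarity of samples $j,k$ is
$s_i(j,k) = 1 - |x_{ij}-x_{ik}|/\mathrm{range}_i$ (rows with zero range are
skipped — they cannot discriminate). Each similarity is converted to a
rank-based tail probability $p_i(j,k)$: the fraction of all sample pairs
whose similarity on row $i$ is at least $s_i(j,k)$. Fisher's method
combines rows, $\chi^2 = -2\sum_i \ln p_i$ on $2m$ d.f.; the pair's
similarity is the lower-tail probability and the distance its complement.

Two consequences of this construction are worth knowing:

* **At least 3 samples are required.** With two samples there is a single
  pair, every $p_i = 1$, and the index is uninformative; the function
  errors rather than returning a constant.
* **"Identical samples are at distance 0" holds asymptotically.** A
  duplicated pair has the minimal possible $p_i = 1/\binom{n}{2}$ per row,
  giving a Fisher tail that decays with the number of samples and rows
  (about $10^{-7}$ at 8 samples and 10 informative rows). Tests therefore
  assert near-zero, not exact zero, for this index.

## UniFrac

Both variants run directly on the count hierarchy with unit branch lengths
(one branch above each non-root node); the mass of a branch is the
summarized count below it. Unweighted UniFrac is the fraction of populated
branches populated by exactly one of the two samples; the
weighted-normalized variant is
$\sum_b |A_b/A_T - B_b/B_T| \,/\, \sum_b (A_b/A_T + B_b/B_T)$. On a star
tree this reduces numerically to Bray–Curtis on relative abundances, which
the test suite verifies against a brute-force branch-enumeration oracle
rather than assuming.

Distance matrices are written with 6 decimal digits, locale-independent, as
PHYLIP square matrices, NEXUS `DISTANCES` blocks, or pair-per-row edge TSVs
for external network/ordination tools; network layout itself is out of
scope.

# KEGG pathways

Each read's KO contributes **one hit to every pathway containing that KO**
(no fractional splitting): pathway hit totals are therefore a bookkeeping
identity, $\sum_{\text{pathways}} \text{hits} = \sum_{\text{reads}}
|\text{pathways}(KO_{\text{read}})|$, which the suite asserts exactly. KOs
missing from the pathway map aggregate under a synthetic `unmapped-KO`
pathway. For display, per-KO counts scale to $[0,1]$ linearly
(`count/max`) or logarithmically (`log1p(count)/log1p(max)`); any KO with
at least one read scales strictly above zero so that a barely-expressed
enzyme remains distinguishable from an absent one. Multi-sample comparison
emits both counts and a categorical presence pattern (which subset of
samples hit each KO), since whether abundance or mere presence matters is
downstream policy. Pathway *map images* are not rendered; the scaled value
is the color channel for any renderer.

# The synthetic generator

`fixture_spec()` / `generate_fixture()` produce the full input bundle —
both hierarchies, the three accession maps, the KO-pathway map, per-sample
BLAST outfmt-6 files, and a truth table — entirely from one seed, byte-
identically across runs. Default shape, chosen once as a small but
non-degenerate study: ternary taxonomy of depth 3 (40 nodes), 5 subsystems
with 4 roles each with 25% of roles multi-labeled, 120 reference
accessions, 100 reads per sample with up to 3 distractor hits each, noise
0. Intended hits score 75–95 bits and distractors at most 85% of that, so
the intended hit always survives the 10% window alone and the ground truth
is unambiguous; with probability `noise_rate` an overriding hit 12 bits
above the intended one points at a wrong-role accession, so accuracy
degrades controllably (about $1-\text{noise}$). `eight_sample_bergen_like()`
emulates the *shape* of a paired mesocosm experiment — 4 DNA plus 4 cDNA
samples in which the expression condition up-weights half the roles about
6-fold — so the comparison code paths see realistic between-condition
structure.

What the generator does **not** emulate, and hence what passing tests do
not show: sequence-level error processes (it simulates BLAST *output*, not
reads), the size and shape of the real SEED tree (about 10,000 nodes) and
NCBI taxonomy, realistic bit-score distributions and database biases, or
correlated multi-gene structure within genomes. Recovery results on
fixtures validate the *bookkeeping and algorithms*, not annotation accuracy
on real data.

# Numerical and design choices

* Ties in bit score break by ascending subject accession, everywhere.
* Promotion order is deepest-first and therefore deterministic; a single
  deepest-first sweep reaches the fixpoint because each parent is visited
  after all its children.
* Degenerate inputs are named errors: zero-total samples in relative
  normalization and UniFrac, fewer than 2 samples for any distance, fewer
  than 3 for Goodall, unknown node/pathway ids.
* Malformed BLAST lines are counted and skipped (parsed + rejected =
  non-comment lines), never silently dropped.
* Exported tables order rows by depth-first traversal; matrix output uses
  6 decimals; all writers produce locale-independent ASCII.
* Test and acceptance problem sizes — trees of 5–50 nodes, up to 20 hits
  per read, 8 samples of 40–240 reads, 10 seeds per noise level — were
  chosen as the smallest sizes at which every code path (multi-labeling,
  cascaded promotion, window edge cases, degenerate bins) is exercised.

# Known limitations

* The six-index set and the Goodall operationalization are this package's
  choices; other lineages of "Goodall's index" (e.g. pairing functions
  other than Fisher's) will give different absolute values.
* LCA parameters are shared with the import defaults; there is no
  per-analysis re-estimation of `min_score`/`top_percent`.
* Only tabular BLAST (outfmt 6) is parsed; pairwise text BLAST, SAM and
  DIAMOND formats are out of scope, as are rarefaction and significance
  testing of distances.
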