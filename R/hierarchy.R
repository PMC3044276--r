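#' Construct a rooted hierarchy
#'
#' A hierarchy is a rooted tree of named nodes: the NCBI-style taxonomy, or
#' the SEED classification in which internal nodes are subsystems and leaves
#' carry functional-role names. The SEED tree is *multi-labeled*: the same
#' role name may label several leaves sitting under different subsystems.
#'
#' @param child Character vector of node ids, one row per node.
#' @param parent Character vector of parent ids, parallel to `child`. The
#'   root is marked by `NA`, an empty string, or `parent == child`; a parent
#'   id that never appears in `child` is also accepted as an implicit root
#'   (at most one such id may exist).
#' @param label Optional display names, parallel to `child` (defaults to the
#'   node ids).
#' @param role Optional functional-role names for leaves (SEED variant);
#'   parallel to `child`, `NA`/empty for non-leaf rows.
#' @return An object of class `"hierarchy"`: a list with elements `nodes`,
#'   `parent` (named, `NA` at the root), `children`, `depth` (root = 0),
#'   `label`, `role` (named character over role-labeled leaves) and `root`.
#' @examples
#' h <- hierarchy(c("A", "B", "C"), c("root", "A", "A"))
#' lca(h, c("B", "C"))
#' @export
hierarchy <- function(child, parent, label = NULL, role = NULL) {
  child <- as.character(child)
  parent <- as.character(parent)
  if (length(child) != length(parent))
    stop("'child' and 'parent' must have the same length")
  if (anyDuplicated(child))
    stop("duplicate node id(s): ",
         paste(unique(child[duplicated(child)]), collapse = ", "))

  is_root_row <- is.na(parent) | parent == "" | parent == child
  parent[is_root_row] <- NA_character_

  nodes <- child
  implied <- setdiff(parent[!is.na(parent)], nodes)
  if (length(implied) > 1L)
    stop("multiple roots: parent ids not defined as nodes: ",
         paste(implied, collapse = ", "))
  if (length(implied) == 1L) {
    nodes <- c(implied, nodes)
    parent <- c(NA_character_, parent)
    child <- c(implied, child)
    if (!is.null(label)) label <- c(implied, label)
    if (!is.null(role)) role <- c(NA_character_, role)
    is_root_row <- c(TRUE, is_root_row)
  }

  roots <- nodes[is.na(parent)]
  if (length(roots) == 0L)
    stop("structural error: no root found (cycle covering all nodes?)")
  if (length(roots) > 1L)
    stop("structural error: multiple roots: ", paste(roots, collapse = ", "))
  root <- roots

  names(parent) <- nodes
  children <- split(nodes[!is.na(parent)], parent[!is.na(parent)])
  children <- children[intersect(nodes, names(children))]

  # breadth-first sweep from the root; unreached nodes sit on a cycle
  depth <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  depth[root] <- 0L
  frontier <- root
  while (length(frontier)) {
    kids <- unlist(children[frontier], use.names = FALSE)
    if (!length(kids)) break
    depth[kids] <- depth[parent[kids]] + 1L
    frontier <- kids
  }
  if (anyNA(depth)) {
    off <- names(depth)[is.na(depth)][1L]
    stop("structural error: cycle detected involving node '", off, "'")
  }

  if (is.null(label)) label <- nodes
  label <- as.character(label)
  if (length(label) != length(nodes))
    stop("'label' must be parallel to 'child'")
  label[is.na(label) | label == ""] <- nodes[is.na(label) | label == ""]
  names(label) <- nodes

  role_vec <- character(0)
  if (!is.null(role)) {
    role <- as.character(role)
    if (length(role) != length(nodes))
      stop("'role' must be parallel to 'child'")
    keep <- !is.na(role) & role != ""
    role_vec <- stats::setNames(role[keep], nodes[keep])
    has_kids <- nodes %in% names(children)
    bad <- intersect(names(role_vec), nodes[has_kids])
    if (length(bad))
      stop("role names may only label leaves; internal node(s): ",
           paste(bad, collapse = ", "))
  }

  structure(
    list(nodes = nodes, parent = parent, children = children,
         depth = depth, label = label, role = role_vec, root = root),
    class = "hierarchy"
  )
}

#' @export
print.hierarchy <- function(x, ...) {
  cat("<hierarchy> ", length(x$nodes), " nodes, ",
      length(leaves(x)), " leaves, depth ", max(x$depth),
      if (length(x$role)) paste0(", ", length(unique(x$role)),
                                 " functional roles (multi-labeled)"),
      "\n", sep = "")
  invisible(x)
}

#' Leaves of a hierarchy
#' @param h A `hierarchy`.
#' @return Character vector of leaf node ids.
#' @export
leaves <- function(h) {
  setdiff(h$nodes, names(h$children))
}

#' Ancestor path of a node
#'
#' @param h A `hierarchy`.
#' @param node A node id.
#' @return Character vector from `node` (inclusive) up to the root.
#' @export
ancestors <- function(h, node) {
  check_nodes(h, node)
  out <- character(h$depth[[node]] + 1L)
  i <- 1L
  while (!is.na(node)) {
    out[i] <- node
    node <- h$parent[[node]]
    i <- i + 1L
  }
  out
}

#' Descendants of a node (inclusive)
#' @param h A `hierarchy`.
#' @param node A node id.
#' @return Character vector: `node` and every node below it.
#' @export
descendants <- function(h, node) {
  check_nodes(h, node)
  out <- node
  frontier <- node
  while (length(frontier)) {
    kids <- unlist(h$children[frontier], use.names = FALSE)
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

check_nodes <- function(h, nodes) {
  unknown <- setdiff(nodes, h$nodes)
  if (length(unknown))
    stop("unknown node id(s): ", paste(unknown, collapse = ", "))
  invisible(TRUE)
}

#' Lowest common ancestor of a node set
#'
#' The deepest node that is an ancestor-or-self of every node in the set.
#' Used to place a read at the most specific taxon consistent with all of
#' its BLAST hits.
#'
#' @param h A `hierarchy`.
#' @param nodes Nonempty character vector of node ids.
#' @return A single node id.
#' @export
lca <- function(h, nodes) {
  nodes <- unique(as.character(nodes))
  if (!length(nodes)) stop("'nodes' must be nonempty")
  check_nodes(h, nodes)
  Reduce(function(a, b) lca2(h, a, b), nodes)
}

# pairwise LCA by depth equalization + joint climb
lca2 <- function(h, a, b) {
  da <- h$depth[[a]]
  db <- h$depth[[b]]
  while (da > db) { a <- h$parent[[a]]; da <- da - 1L }
  while (db > da) { b <- h$parent[[b]]; db <- db - 1L }
  while (a != b) { a <- h$parent[[a]]; b <- h$parent[[b]] }
  a
}

#' Leaves carrying a functional role
#'
#' In the multi-labeled SEED tree one role may label several leaves under
#' different subsystems; all of them are returned.
#'
#' @param h A SEED-variant `hierarchy` (with roles).
#' @param role A functional-role name (exact string match).
#' @return Character vector of leaf ids (possibly empty).
#' @export
leaves_for_role <- function(h, role) {
  names(h$role)[h$role == role]
}

#' Functional roles present in a hierarchy
#' @param h A `hierarchy`.
#' @return Character vector of distinct role names.
#' @export
hierarchy_roles <- function(h) {
  unique(unname(h$role))
}

# depth-first (preorder) node ordering; children visited in sorted order so
# exports are stable across runs
dfs_order <- function(h) {
  out <- character(length(h$nodes))
  stack <- h$root
  i <- 0L
  while (length(stack)) {
    n <- stack[1L]
    stack <- stack[-1L]
    i <- i + 1L
    out[i] <- n
    kids <- h$children[[n]]
    if (length(kids)) stack <- c(sort(kids), stack)
  }
  out
}

#' Read a hierarchy from disk
#'
#' Two formats are accepted: a tab-delimited edge list with a header line
#' `child  parent  label  [role]` (`#` comment lines allowed; the root row
#' may point to itself, be empty, or be omitted entirely when some node's
#' parent never occurs as a child), and Newick (read via
#' [ape::read.tree()]; labels only, branch lengths are ignored and unit
#' lengths assumed).
#'
#' @param path File path. Files ending in `.nwk`, `.newick` or `.tre` are
#'   parsed as Newick when `format = "auto"`.
#' @param format `"auto"`, `"edge-tsv"` or `"newick"`.
#' @return A `hierarchy`.
#' @export
read_hierarchy <- function(path, format = c("auto", "edge-tsv", "newick")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(nwk|newick|tre)$", path, ignore.case = TRUE))
      "newick" else "edge-tsv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "newick") return(newick_to_hierarchy(path))

  df <- utils::read.delim(path, comment.char = "#", quote = "",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("child", "parent")
  if (!all(need %in% names(df)))
    stop("edge-tsv hierarchy needs columns 'child' and 'parent'; found: ",
         paste(names(df), collapse = ", "))
  hierarchy(df$child, df$parent,
            label = if ("label" %in% names(df)) df$label,
            role = if ("role" %in% names(df)) df$role)
}

newick_to_hierarchy <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("failed to parse Newick file: ", path)
  ntip <- length(tr$tip.label)
  nint <- tr$Nnode
  int_lab <- tr$node.label
  if (is.null(int_lab) || !length(int_lab))
    int_lab <- paste0("n", seq_len(nint))
  int_lab[is.na(int_lab) | int_lab == ""] <-
    paste0("n", which(is.na(int_lab) | int_lab == ""))
  id <- c(tr$tip.label, int_lab)
  if (anyDuplicated(id))
    stop("Newick tree has duplicate node labels: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  parent <- stats::setNames(rep(NA_character_, length(id)), id)
  parent[id[tr$edge[, 2L]]] <- id[tr$edge[, 1L]]
  hierarchy(id, unname(parent[id]))
}

#' Write a hierarchy as an edge-list TSV
#'
#' Rows are emitted in depth-first order; the root row points to itself.
#' Reading the file back yields a hierarchy with the same parent relation,
#' labels and roles.
#'
#' @param h A `hierarchy`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hierarchy <- function(h, path) {
  ord <- dfs_order(h)
  par <- h$parent[ord]
  par[is.na(par)] <- ord[is.na(par)]
  has_role <- length(h$role) > 0L
  hdr <- paste(c("child", "parent", "label", if (has_role) "role"),
               collapse = "\t")
  rows <- paste(ord, par, h$label[ord], sep = "\t")
  if (has_role) {
    rl <- h$role[ord]
    rl[is.na(rl)] <- ""
    rows <- paste(rows, rl, sep = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
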