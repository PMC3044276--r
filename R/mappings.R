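# Mapping tables: reference accession -> functional role / taxon / KO, and
# KO -> pathway membership. TSV stand-ins for the seed2ncbi-style dumps.

read_lines_any <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con)
}

#' Read an accession mapping table
#'
#' Tab-delimited, no header: `accession<TAB>target` (extra columns ignored,
#' `#` comments allowed). Targets are functional-role names
#' (`kind = "function"`), taxon node ids (`"taxon"`), or KEGG orthology ids
#' (`"ko"`). A duplicate accession with conflicting targets is a format
#' error; exact duplicate rows are collapsed.
#'
#' @param path File path (optionally gzip-compressed).
#' @param kind `"function"`, `"taxon"` or `"ko"`.
#' @return Named character vector (accession -> target) with class
#'   `"function_map"`, `"taxon_map"` or `"ko_map"`.
#' @export
read_mapping <- function(path, kind = c("function", "taxon", "ko")) {
  kind <- match.arg(kind)
  lines <- read_lines_any(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  cls <- c(paste0(sub("^function$", "function", kind), "_map"), "accession_map")
  if (!length(lines)) {
    warning("empty mapping file: ", path)
    return(structure(stats::setNames(character(0), character(0)),
                     class = cls))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 2L
  if (any(short))
    warning(sum(short), " malformed mapping line(s) skipped in ", path)
  parts <- parts[!short]
  acc <- vapply(parts, `[[`, character(1), 1L)
  tgt <- vapply(parts, `[[`, character(1), 2L)
  d <- unique(data.frame(acc = acc, tgt = tgt, stringsAsFactors = FALSE))
  dup <- unique(d$acc[duplicated(d$acc)])
  if (length(dup))
    stop("conflicting mapping(s) for accession(s): ",
         paste(dup, collapse = ", "))
  structure(stats::setNames(d$tgt, d$acc), class = cls)
}

#' Read a KO-to-pathway membership table
#'
#' Tab-delimited, no header: `ko<TAB>pathway_id[<TAB>pathway_name]`, one row
#' per (KO, pathway) pair; a KO may belong to multiple pathways.
#'
#' @param path File path.
#' @return A `"pathway_map"`: list with `pathways` (named list KO -> character
#'   vector of pathway ids) and `label` (named character, pathway id -> name).
#' @export
read_pathway_map <- function(path) {
  lines <- read_lines_any(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty pathway map: ", path)
    return(structure(list(pathways = list(), label = character(0)),
                     class = "pathway_map"))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 2L
  if (any(!ok))
    warning(sum(!ok), " malformed pathway-map line(s) skipped in ", path)
  parts <- parts[ok]
  ko <- vapply(parts, `[[`, character(1), 1L)
  pw <- vapply(parts, `[[`, character(1), 2L)
  nm <- vapply(parts, function(p) if (length(p) >= 3L) p[[3L]] else p[[2L]],
               character(1))
  label <- stats::setNames(nm, pw)
  label <- label[!duplicated(names(label))]
  structure(list(pathways = lapply(split(pw, ko), unique), label = label),
            class = "pathway_map")
}

#' Check mapping targets against a hierarchy
#'
#' Targets that do not exist in the hierarchy (a role labeling no leaf, a
#' taxon id absent from the taxonomy) are *dangling*: reads whose best hit
#' lands on them are routed to the NotAssigned bin rather than failing the
#' run, mirroring version drift between mapping files and trees.
#'
#' @param map A `function_map` or `taxon_map` from [read_mapping()].
#' @param h The matching `hierarchy`.
#' @param warn Emit a warning when dangling entries are found.
#' @return Character vector of accessions with dangling targets.
#' @export
validate_mapping <- function(map, h, warn = TRUE) {
  known <- if (inherits(map, "function_map")) unique(unname(h$role))
           else h$nodes
  dangling <- names(map)[!(unname(map) %in% known)]
  if (warn && length(dangling))
    warning(length(dangling), " mapping target(s) not present in hierarchy; ",
            "reads hitting them will be NotAssigned")
  dangling
}
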