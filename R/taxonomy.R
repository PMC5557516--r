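#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
NULL

new_taxonomy <- function(parent, rank, name, merged, root_id) {
  structure(
    list(parent = parent, rank = rank, name = name, merged = merged,
         root_id = root_id),
    class = "taxonomy"
  )
}

#' Load an NCBI-style taxonomy dump
#'
#' Parses `nodes.dmp`, `names.dmp` and (optionally) `merged.dmp` in the
#' standard NCBI dump dialect: fields separated by `"\t|\t"`, rows terminated
#' by `"\t|"`. Only columns 1-3 of the nodes file (taxid, parent taxid, rank),
#' the "scientific name" rows of the names file, and columns 1-2 of the merged
#' file are used. Tools built against different taxonomy versions are
#' reconciled against this one tree: stale identifiers are redirected through
#' the merged map and name/rank lookups use this tree's definitions.
#'
#' @param nodes_path Path to a `nodes.dmp`-dialect file.
#' @param names_path Path to a `names.dmp`-dialect file.
#' @param merged_path Optional path to a `merged.dmp`-dialect file.
#' @return A `taxonomy` object with named integer/character vectors `parent`,
#'   `rank`, `name`, `merged` and the detected `root_id`.
#' @export
load_taxonomy <- function(nodes_path, names_path, merged_path = NULL) {
  for (p in c(nodes_path, names_path, merged_path)) {
    if (!file.exists(p)) abort(paste0("taxonomy file not found: ", p))
  }
  nodes <- parse_dmp(nodes_path, min_cols = 3L)
  taxid <- suppressWarnings(as.integer(nodes[[1L]]))
  if (anyNA(taxid)) {
    abort(sprintf("non-integer taxid in %s at line %d",
                  nodes_path, which(is.na(taxid))[1L]))
  }
  parent_id <- suppressWarnings(as.integer(nodes[[2L]]))
  if (anyNA(parent_id)) {
    abort(sprintf("non-integer parent taxid in %s at line %d",
                  nodes_path, which(is.na(parent_id))[1L]))
  }
  parent <- stats::setNames(parent_id, taxid)
  rank <- stats::setNames(normalize_rank(nodes[[3L]]), taxid)

  # root is the node that is its own parent (taxid 1 in NCBI dumps)
  root_id <- taxid[taxid == parent_id]
  if (length(root_id) != 1L) {
    abort(sprintf("taxonomy in %s must have exactly one self-parented root, found %d",
                  nodes_path, length(root_id)))
  }
  missing_parent <- setdiff(parent_id, taxid)
  if (length(missing_parent) > 0L) {
    abort(sprintf("node(s) in %s reference absent parent taxid(s): %s",
                  nodes_path, paste(utils::head(missing_parent, 5L), collapse = ", ")))
  }

  nm <- parse_dmp(names_path, min_cols = 2L)
  if (ncol(nm) >= 4L) nm <- nm[normalize_rank(nm[[4L]]) == "scientific name", , drop = FALSE]
  nm_taxid <- suppressWarnings(as.integer(nm[[1L]]))
  if (anyNA(nm_taxid)) {
    abort(sprintf("non-integer taxid in %s at line %d",
                  names_path, which(is.na(nm_taxid))[1L]))
  }
  name <- stats::setNames(nm[[2L]], nm_taxid)

  merged <- stats::setNames(integer(0), character(0))
  if (!is.null(merged_path)) {
    mg <- parse_dmp(merged_path, min_cols = 2L)
    if (nrow(mg) > 0L) {
      old <- suppressWarnings(as.integer(mg[[1L]]))
      new <- suppressWarnings(as.integer(mg[[2L]]))
      if (anyNA(old) || anyNA(new)) {
        abort(sprintf("non-integer taxid in %s at line %d",
                      merged_path, which(is.na(old) | is.na(new))[1L]))
      }
      keep <- !(old %in% taxid)  # merged keys must not shadow live nodes
      merged <- stats::setNames(new[keep], old[keep])
    }
  }

  tree <- new_taxonomy(parent, rank, name, merged, root_id)
  check_acyclic(tree)
  tree
}

# NCBI dump dialect: "\t|\t" field separator, "\t|" row terminator.
parse_dmp <- function(path, min_cols) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(as.data.frame(matrix(character(0), ncol = min_cols),
                         stringsAsFactors = FALSE))
  }
  lines <- sub("\t\\|$", "", lines)
  fields <- strsplit(lines, "\t|\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < min_cols)) {
    abort(sprintf("malformed row in %s at line %d (expected >= %d fields)",
                  path, which(ncols < min_cols)[1L], min_cols))
  }
  nc <- max(ncols)
  mat <- t(vapply(fields, function(f) c(f, rep(NA_character_, nc - length(f))),
                  character(nc)))
  as.data.frame(mat, stringsAsFactors = FALSE)
}

check_acyclic <- function(tree) {
  n <- length(tree$parent)
  for (start in as.integer(names(tree$parent))) {
    cur <- start
    steps <- 0L
    while (cur != tree$root_id) {
      cur <- tree$parent[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > n) {
        abort(sprintf("taxonomy contains a cycle reachable from taxid %d", start))
      }
    }
  }
  invisible(tree)
}

#' @export
print.taxonomy <- function(x, ...) {
  cat(sprintf("<taxonomy> %d nodes, %d merged ids, root %d\n",
              length(x$parent), length(x$merged), x$root_id))
  invisible(x)
}

#' Resolve taxon identifiers against a taxonomy
#'
#' Returns the input taxid where it is a live node, the redirection target
#' where it appears in the merged map, and `NA` where it is unknown. Absence
#' is a value, not an error: callers drop unresolvable entries with a counted
#' warning, because real tool outputs carry stale identifiers.
#'
#' @param tree A `taxonomy` from [load_taxonomy()].
#' @param taxids Integer vector of taxon identifiers.
#' @return Integer vector the same length as `taxids`, `NA` for unknown ids.
#' @export
resolve_taxid <- function(tree, taxids) {
  stopifnot(inherits(tree, "taxonomy"))
  taxids <- as.integer(taxids)
  key <- as.character(taxids)
  out <- taxids
  live <- key %in% names(tree$parent)
  redir <- !live & key %in% names(tree$merged)
  out[redir] <- unname(tree$merged[key[redir]])
  out[!live & !redir] <- NA_integer_
  out
}

#' Look up a taxon by scientific name
#'
#' Case-insensitive exact match on scientific name, optionally constrained to
#' a rank. A name carried by several live nodes (a homonym) resolves to `NA`
#' with a warning rather than guessing.
#'
#' @param tree A `taxonomy`.
#' @param name Scientific name to look up.
#' @param rank Optional rank the match must have.
#' @return A single taxid, or `NA` if absent or ambiguous.
#' @export
resolve_name <- function(tree, name, rank = NULL) {
  stopifnot(inherits(tree, "taxonomy"))
  hits <- names(tree$name)[tolower(tree$name) == tolower(trimws(name))]
  if (!is.null(rank)) {
    hits <- hits[tree$rank[hits] == normalize_rank(rank)]
  }
  if (length(hits) == 0L) return(NA_integer_)
  if (length(hits) > 1L) {
    warn(sprintf("name '%s' is ambiguous (%d matches); returning NA", name,
                 length(hits)))
    return(NA_integer_)
  }
  as.integer(hits)
}

#' Fixed-rank lineage of a taxon
#'
#' Walks the parent chain from `taxid` to the root, collecting only the nodes
#' whose rank is one of [fixed_ranks()]. The taxon itself is included under
#' its own rank when that rank is fixed; "no rank" strain nodes and other
#' off-ladder nodes contribute nothing, so a strain maps to its species
#' ancestor, genus, and so on.
#'
#' @param tree A `taxonomy`.
#' @param taxid A single resolvable taxid.
#' @return Named integer vector, names are fixed ranks present on the chain,
#'   ordered broadest to narrowest.
#' @export
lineage_at_ranks <- function(tree, taxid) {
  stopifnot(inherits(tree, "taxonomy"))
  key <- as.character(taxid)
  if (!key %in% names(tree$parent)) {
    abort(sprintf("taxid %s is not a live node; resolve_taxid() it first", key))
  }
  out <- stats::setNames(rep(NA_integer_, 7L), fixed_ranks())
  cur <- as.integer(taxid)
  repeat {
    rk <- tree$rank[[as.character(cur)]]
    if (rk %in% fixed_ranks()) out[[rk]] <- cur
    if (cur == tree$root_id) break
    cur <- tree$parent[[as.character(cur)]]
  }
  out[!is.na(out)]
}

# Deepest fixed-rank node on a taxid's lineage (species for a strain,
# the taxon itself when already at a fixed rank); NA_integer_ if the chain
# touches no fixed rank at all.
project_to_fixed <- function(tree, taxid) {
  lin <- lineage_at_ranks(tree, taxid)
  if (length(lin) == 0L) return(NA_integer_)
  unname(lin[[length(lin)]])
}

#' Write a taxonomy as NCBI-style dump files
#'
#' Emits `nodes.dmp`, `names.dmp` and `merged.dmp` in the dialect accepted by
#' [load_taxonomy()], so synthetic trees round-trip through the standard
#' reader.
#'
#' @param tree A `taxonomy`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the three file paths.
#' @export
write_taxonomy_dump <- function(tree, dir) {
  stopifnot(inherits(tree, "taxonomy"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(nodes = file.path(dir, "nodes.dmp"),
                names = file.path(dir, "names.dmp"),
                merged = file.path(dir, "merged.dmp"))
  ids <- names(tree$parent)
  writeLines(paste0(ids, "\t|\t", tree$parent[ids], "\t|\t", tree$rank[ids],
                    "\t|"), paths$nodes)
  nm_ids <- names(tree$name)
  writeLines(paste0(nm_ids, "\t|\t", tree$name[nm_ids],
                    "\t|\t\t|\tscientific name\t|"), paths$names)
  if (length(tree$merged) > 0L) {
    writeLines(paste0(names(tree$merged), "\t|\t", tree$merged, "\t|"),
               paths$merged)
  } else {
    writeLines(character(0), paths$merged)
  }
  invisible(paths)
}
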